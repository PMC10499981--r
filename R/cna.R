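# Arm-level copy-number burden (length-weighted aggregation of segment
# log2 ratios), amplification/deletion calls, group frequency tests and
# CNA -> protein cis-effect screening.
#
# Coordinates are 0-based half-open throughout; [read_segments()] converts
# conventional 1-based SEG input on the way in.

#' Arm-level copy-number burden
#'
#' For each sample and arm, segments are clipped to the arm interval and their
#' log2 ratios aggregated with the overlap length as weight. The default is
#' the length-weighted mean, which stays on the log2-ratio scale and is
#' directly comparable to the call cutoff; `aggregate = "sum"` gives the
#' literal length-weighted sum (sum of overlap_length x log2_ratio). Segments
#' spanning an arm boundary are split at the boundary. Arms with no covering
#' segment are NA.
#'
#' @param segments data.frame with `sample, chrom, start, end, log2_ratio`
#'   (0-based half-open).
#' @param arms data.frame with `arm, chrom, start, end`.
#' @param aggregate "mean" (default) or "sum".
#' @return numeric matrix samples x arms.
#' @export
arm_burden <- function(segments, arms, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (any(segments$end <= segments$start)) stop("segments must have end > start")
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, length(samples), nrow(arms),
                dimnames = list(samples, arms$arm))
  for (a in seq_len(nrow(arms))) {
    seg_a <- segments[segments$chrom == arms$chrom[a], , drop = FALSE]
    if (nrow(seg_a) == 0L) next
    ov_start <- pmax(seg_a$start, arms$start[a])
    ov_end <- pmin(seg_a$end, arms$end[a])
    len <- pmax(0, ov_end - ov_start)
    keep <- len > 0
    if (!any(keep)) next
    wsum <- tapply(len[keep] * seg_a$log2_ratio[keep], seg_a$sample[keep], sum)
    lsum <- tapply(len[keep], seg_a$sample[keep], sum)
    val <- if (aggregate == "mean") wsum / lsum else wsum
    out[names(val), a] <- val
  }
  out
}

#' Amplification/deletion call from a log2 ratio
#'
#' `amp` when the value is at least `+cutoff`, `del` when at most `-cutoff`,
#' otherwise `neutral`; comparisons are inclusive so a value exactly at the
#' printed cutoff qualifies. NA values give NA calls.
#'
#' @param value numeric log2 ratio(s).
#' @param cutoff call threshold (default 1).
#' @return character vector of calls.
#' @export
call_amp_del <- function(value, cutoff = 1) {
  out <- ifelse(value >= cutoff, "amp",
         ifelse(value <= -cutoff, "del", "neutral"))
  out[!is.finite(value)] <- NA_character_
  out
}

#' Per-arm alteration-frequency test between two groups
#'
#' For each arm, a 2x2 Fisher exact test (altered vs not x group), two-sided,
#' with BH adjustment across arms.
#'
#' @param calls character matrix samples x arms of calls from
#'   [call_amp_del()] (NA treated as not altered).
#' @param groups two-level factor/character per sample (rows of `calls`).
#' @param altered which calls count as altered (default `c("amp", "del")`).
#' @return data.frame arm/odds_ratio/p/q plus per-group altered counts.
#' @export
group_freq_test <- function(calls, groups, altered = c("amp", "del")) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  alt <- matrix(calls %in% altered, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  g1 <- groups == levels(groups)[1L]
  res <- lapply(seq_len(ncol(alt)), function(a) {
    tb <- matrix(c(sum(alt[g1, a]), sum(!alt[g1, a]),
                   sum(alt[!g1, a]), sum(!alt[!g1, a])), 2, 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tb)
    data.frame(arm = colnames(alt)[a],
               altered_1 = tb[1, 1], n_1 = sum(g1),
               altered_2 = tb[2, 1], n_2 = sum(!g1),
               odds_ratio = ft$odds_ratio, p = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Copy-number cis-effect screen
#'
#' Spearman correlation between a gene's copy-number value (arm/band burden
#' or call-coded value) and the same gene's protein abundance across samples.
#' A cis-effect is declared when rho > 0 with BH-adjusted p below `alpha`
#' (a deletion lowering the protein gives a positive correlation). Genes with
#' a constant vector are reported with NA.
#'
#' @param cna numeric matrix samples x genes of copy-number values.
#' @param protein numeric matrix samples x genes of protein abundances
#'   (columns matched to `cna` by name).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame gene/rho/p/q/cis_effect.
#' @export
cis_effect <- function(cna, protein, alpha = 0.05) {
  genes <- intersect(colnames(cna), colnames(protein))
  if (length(genes) == 0L) stop("no shared genes between cna and protein")
  smp <- intersect(rownames(cna), rownames(protein))
  if (length(smp) < 5L) stop("need >= 5 paired samples")
  res <- lapply(genes, function(g) {
    x <- cna[smp, g]; y <- protein[smp, g]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 5L || length(unique(x[ok])) < 2L ||
        length(unique(y[ok])) < 2L)
      return(data.frame(gene = g, rho = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    sp <- spearman(x[ok], y[ok])
    data.frame(gene = g, rho = sp$rho, p = sp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out$cis_effect <- !is.na(out$q) & out$rho > 0 & out$q < alpha
  out
}
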