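# Single-sample gene-set enrichment (ssGSEA) with the PTM-SEA-style
# permutation normalization, plus the scores built on it: DNA damage response
# score and regulon (transcription-factor) activity.

#' Enrichment scoring parameters
#'
#' Defaults follow the PTM-SEA parameterization used throughout the analysis:
#' rank sample normalization, weight exponent 0.75, area-under-running-score
#' statistic, 1000 permutations for NES, minimum overlap 5.
#'
#' @param weight weight exponent applied to rank-normalized values (>= 0).
#' @param sample_norm "rank" (values replaced by ranks) or "none".
#' @param n_permutations permutations for the NES denominator (>= 1).
#' @param min_overlap minimal |set intersect profile| to score a set.
#' @param output "NES" (permutation-normalized) or "ES".
#' @param seed integer seed controlling tie shuffling and permutations.
#' @return list of class `enrichment_params`.
#' @export
enrichment_params <- function(weight = 0.75,
                              sample_norm = c("rank", "none"),
                              n_permutations = 1000L,
                              min_overlap = 5L,
                              output = c("NES", "ES"),
                              seed = 1L) {
  sample_norm <- match.arg(sample_norm)
  output <- match.arg(output)
  stopifnot(weight >= 0, n_permutations >= 1, min_overlap >= 1)
  structure(list(weight = weight, sample_norm = sample_norm,
                 n_permutations = as.integer(n_permutations),
                 min_overlap = as.integer(min_overlap),
                 output = output, seed = as.integer(seed)),
            class = "enrichment_params")
}

# order profile features descending; ties are broken by a seeded random
# ordering of the (sorted) feature names, so the resolution is unbiased,
# reproducible, and invariant to the input feature order
.profile_order <- function(values, seed) {
  nm <- names(values)
  tie <- withr_seed(seed, sample(sort(nm)))
  order(-values, match(nm, tie))
}

# evaluate an expression under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# area under the running enrichment score from hit positions in the sorted
# profile; closed form of the running-sum area:
# each increment at position p contributes to RES_i for all i >= p, i.e.
# inc * (N - p + 1); the area is divided by N
.es_from_positions <- function(hit_pos, weights_sorted, n) {
  nh <- length(hit_pos)
  if (nh == 0L || nh == n) stop("set must be a proper subset of the profile")
  w_hit <- weights_sorted[hit_pos]
  wsum <- sum(w_hit)
  tail_all <- n * (n + 1) / 2                 # sum over positions of (N-p+1)
  tail_hit <- sum(n - hit_pos + 1)
  if (wsum <= 0) {
    hit_part <- 0
  } else {
    hit_part <- sum(w_hit * (n - hit_pos + 1)) / wsum
  }
  miss_part <- (tail_all - tail_hit) / (n - nh)
  (hit_part - miss_part) / n
}

#' Single-sample enrichment score (area under the running score)
#'
#' Features are sorted by (rank-normalized) value, descending. The running
#' score increments by `|r|^weight / sum(|r_hits|^weight)` at set members and
#' decrements by `1/(N - n_set)` elsewhere; the returned ES is the signed
#' area under this running score (mean of the running score over positions).
#'
#' @param profile named numeric vector: one sample's feature values.
#' @param gene_set character vector of member feature ids.
#' @param params an [enrichment_params()] object.
#' @return enrichment score, or NA with attribute `skipped` naming the reason
#'   when the overlap is below `min_overlap`.
#' @export
ssgsea_es <- function(profile, gene_set, params = enrichment_params()) {
  members <- unique(gene_set)
  hits <- names(profile) %in% members
  if (sum(hits) < params$min_overlap) {
    out <- NA_real_
    attr(out, "skipped") <- "min.overlap"
    return(out)
  }
  vals <- if (params$sample_norm == "rank") rank(profile) else abs(profile)
  ord <- .profile_order(profile, params$seed)
  w_sorted <- abs(vals[ord])^params$weight
  hit_pos <- which(hits[ord])
  .es_from_positions(hit_pos, w_sorted, length(profile))
}

#' Permutation-normalized enrichment score (NES)
#'
#' ES divided by the mean absolute ES of size-matched random feature sets
#' drawn without replacement from the profile; the sign of the ES is
#' preserved.
#'
#' @inheritParams ssgsea_es
#' @return NES, or skipped NA as in [ssgsea_es()].
#' @export
ssgsea_nes <- function(profile, gene_set, params = enrichment_params()) {
  es <- ssgsea_es(profile, gene_set, params)
  if (is.na(es)) return(es)
  n <- length(profile)
  nh <- sum(names(profile) %in% unique(gene_set))
  vals <- if (params$sample_norm == "rank") rank(profile) else abs(profile)
  ord <- .profile_order(profile, params$seed)
  w_sorted <- abs(vals[ord])^params$weight
  perm_es <- withr_seed(params$seed + 1L, {
    vapply(seq_len(params$n_permutations), function(i) {
      pos <- sort(sample.int(n, nh))
      .es_from_positions(pos, w_sorted, n)
    }, 0)
  })
  denom <- mean(abs(perm_es))
  if (denom == 0) stop("degenerate profile: permutation ES are all zero")
  es / denom
}

#' Score a matrix of samples against a gene-set collection
#'
#' One score per retained (set, sample) pair; sets whose overlap with the
#' matrix features is below `min_overlap` are skipped and reported.
#'
#' @param am `abundance_matrix` on the log2 scale.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param params an [enrichment_params()] object; `output` selects ES or NES.
#' @return matrix sets x samples with attribute `skipped` (named character
#'   vector of skip reasons).
#' @export
score_matrix <- function(am, sets, params = enrichment_params()) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (am$scale != "log2FOT") stop("matrix must be on the log2 scale")
  v <- am$values
  scorer <- if (params$output == "NES") ssgsea_nes else ssgsea_es
  out <- matrix(NA_real_, length(sets), ncol(v),
                dimnames = list(names(sets), colnames(v)))
  skipped <- character(0)
  for (s in seq_along(sets)) {
    for (j in seq_len(ncol(v))) {
      profile <- v[, j]
      es <- scorer(profile, sets[[s]], params)
      if (!is.null(attr(es, "skipped"))) {
        skipped[names(sets)[s]] <- attr(es, "skipped")
        break
      }
      out[s, j] <- es
    }
  }
  out <- out[!rownames(out) %in% names(skipped), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' DNA damage response score
#'
#' Per marker (a DDR-substrate phosphoprotein), the matrix values are
#' standardized to mean 0 / SD 1 across samples (sample SD, n-1); the score of
#' a sample is the mean of its standardized marker values. Markers with zero
#' variance across samples are dropped with a warning.
#'
#' @param am phosphoprotein `abundance_matrix` (any scale; values are used
#'   as-is).
#' @param markers character vector of marker feature ids.
#' @return list of class `ddr_score`: `scores` (named per-sample vector) and
#'   `markers_used`.
#' @export
ddr_score <- function(am, markers) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (ncol(am$values) < 2L) stop("need >= 2 samples to standardize")
  present <- intersect(markers, rownames(am$values))
  if (length(present) == 0L) stop("no DDR marker present in the matrix")
  sub <- am$values[present, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance marker(s) dropped")
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0L) stop("all markers have zero variance")
  }
  z <- t(scale(t(sub)))  # per-marker standardization across samples
  scores <- colMeans(z, na.rm = TRUE)
  structure(list(scores = scores, markers_used = rownames(sub)),
            class = "ddr_score")
}

#' Regulon (transcription-factor) activity
#'
#' ssGSEA scores of target-gene sets; regulons with fewer than `min_size`
#' members present in the matrix are skipped.
#'
#' @param am `abundance_matrix` on the log2 scale.
#' @param regulons named list: regulator -> character vector of target ids.
#' @param min_size minimal regulon size (default 10).
#' @param params an [enrichment_params()] object.
#' @return activity matrix regulons x samples (skipped regulons reported via
#'   attribute `skipped`).
#' @export
regulon_activity <- function(am, regulons, min_size = 10L,
                             params = enrichment_params()) {
  params$min_overlap <- max(params$min_overlap, as.integer(min_size))
  score_matrix(am, regulons, params)
}
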