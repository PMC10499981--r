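# Label-free quantification chain: tryptic observable-peptide counting,
# iBAQ, FOT normalization with flooring, match-between-runs RT modeling,
# detection filtering and floor imputation.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# fully tryptic digestion: cleave C-terminal to K/R, not before P,
# zero missed cleavages
.digest_tryptic <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  substring(sequence, starts, ends)
}

#' Count theoretically observable tryptic peptides
#'
#' In-silico digestion of a protein sequence: fully tryptic peptides (cleavage
#' C-terminal to K/R, suppressed before proline, zero missed cleavages) with
#' length between 7 and 30 amino acids. This count is the iBAQ denominator.
#'
#' @param protein_sequence uppercase amino-acid string (20 standard residues).
#' @param length_range allowed peptide length, default `c(7, 30)`.
#' @return integer count of observable peptides.
#' @export
count_observable_peptides <- function(protein_sequence,
                                      length_range = c(7L, 30L)) {
  if (!is.character(protein_sequence) || length(protein_sequence) != 1L ||
      nchar(protein_sequence) == 0L)
    stop("protein_sequence must be a single non-empty string")
  aa <- strsplit(protein_sequence, "")[[1]]
  bad <- which(!aa %in% .AA20)
  if (length(bad))
    stop(sprintf("illegal amino acid '%s' at position %d", aa[bad[1]], bad[1]))
  peps <- .digest_tryptic(protein_sequence)
  len <- nchar(peps)
  sum(len >= length_range[1] & len <= length_range[2])
}

#' iBAQ for one protein in one run
#'
#' Summed peptide intensity divided by the number of theoretically observable
#' peptides.
#'
#' @param intensities numeric vector of peptide intensities (>= 1 value).
#' @param n_observable observable-peptide count; 0 with nonzero evidence
#'   cannot be normalized and is an error (the caller should exclude the
#'   protein from the run).
#' @return iBAQ value.
#' @export
compute_ibaq <- function(intensities, n_observable) {
  if (length(intensities) < 1L) stop("need >= 1 evidence row")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (n_observable < 1L)
    stop("protein with no observable peptide cannot be iBAQ-normalized")
  sum(intensities) / n_observable
}

#' FOT normalization of per-run iBAQ values
#'
#' Fraction of total: each protein's iBAQ divided by the run's total iBAQ,
#' multiplied by 1e5. Values below 1e-5 are then replaced with 1e-5 (the
#' floor); the pre-floor values sum to 1e5 exactly.
#'
#' @param ibaq named numeric vector of per-protein iBAQ values, all >= 0 and
#'   at least one positive.
#' @param floor apply the 1e-5 floor (default TRUE). With `floor = FALSE`
#'   the raw proportional values are returned (useful for conservation
#'   checks).
#' @return FOT vector on the x1e5 scale.
#' @export
normalize_fot <- function(ibaq, floor = TRUE) {
  if (any(ibaq < 0)) stop("iBAQ values must be >= 0")
  tot <- sum(ibaq)
  if (tot <= 0) stop("no identified proteins: all iBAQ values are zero")
  fot <- ibaq / tot * 1e5
  if (floor) fot[fot < 1e-5] <- 1e-5
  fot
}

#' Fit a retention-time transfer model between runs
#'
#' Least-squares regression of target-run retention times on reference-run
#' retention times for peptides identified in both runs. Degree-1 and degree-2
#' polynomials are fitted and the one with the higher adjusted R-squared is
#' retained (ties go to the linear model).
#'
#' @param rt_reference,rt_target paired anchor retention times (minutes),
#'   at least 6 pairs so the quadratic retains residual degrees of freedom.
#' @return object of class `rt_model` with `degree`, `coefficients`,
#'   `r_squared`, `n_anchor`.
#' @export
fit_rt_model <- function(rt_reference, rt_target) {
  if (length(rt_reference) != length(rt_target)) stop("anchors must be paired")
  n <- length(rt_reference)
  if (n < 6L) stop("insufficient anchors: need >= 6 shared peptides")
  if (length(unique(rt_reference)) < 3L)
    stop("degenerate anchors: reference retention times are not spread")
  fits <- lapply(1:2, function(d)
    lm(rt_target ~ poly(rt_reference, d, raw = TRUE)))
  adj <- vapply(fits, function(f)
    suppressWarnings(summary(f)$adj.r.squared), 0)
  # ties (within numerical noise) go to the simpler linear model
  degree <- if (adj[2] > adj[1] + 1e-10) 2L else 1L
  f <- fits[[degree]]
  structure(list(degree = degree,
                 coefficients = unname(coef(f)),
                 r_squared = suppressWarnings(summary(f)$r.squared),
                 n_anchor = n),
            class = "rt_model")
}

#' Predict target retention time from an rt_model
#' @param object an `rt_model`.
#' @param rt_reference reference retention times.
#' @param ... unused.
#' @export
predict.rt_model <- function(object, rt_reference, ...) {
  b <- object$coefficients
  out <- b[1] + b[2] * rt_reference
  if (object$degree == 2L) out <- out + b[3] * rt_reference^2
  out
}

#' Match between runs
#'
#' Transfers peptide identifications from a reference run to a target run.
#' An RT model is fitted on peptides identified in both runs; for each peptide
#' present in the reference but absent from the target, a record is added if
#' the target run has an extracted-ion chromatogram (XIC) for that peptide
#' within `rt_tolerance` of the model-predicted retention time. Transferred
#' records carry `observed = FALSE` so they can be excluded downstream.
#'
#' @param reference,target peptide-evidence data.frames with columns
#'   `run_id, peptide, protein, intensity, rt, observed`.
#' @param target_xics data.frame of candidate XICs in the target run with
#'   columns `peptide, rt, intensity` (the peptide key stands in for the m/z
#'   lookup of the instrument software).
#' @param rt_tolerance maximal |predicted - observed| RT difference (minutes).
#' @return target evidence augmented with transferred rows.
#' @export
match_between_runs <- function(reference, target, target_xics,
                               rt_tolerance = 1) {
  shared <- intersect(reference$peptide, target$peptide)
  ref_sh <- reference[match(shared, reference$peptide), ]
  tgt_sh <- target[match(shared, target$peptide), ]
  model <- fit_rt_model(ref_sh$rt, tgt_sh$rt)
  hidden <- reference[!reference$peptide %in% target$peptide, , drop = FALSE]
  if (nrow(hidden) == 0L) return(target)
  pred_rt <- predict(model, hidden$rt)
  rows <- lapply(seq_len(nrow(hidden)), function(i) {
    cand <- target_xics[target_xics$peptide == hidden$peptide[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    d <- abs(cand$rt - pred_rt[i])
    if (min(d) > rt_tolerance) return(NULL)
    best <- which.min(d)
    data.frame(run_id = target$run_id[1], peptide = hidden$peptide[i],
               protein = hidden$protein[i], intensity = cand$intensity[best],
               rt = cand$rt[best], observed = FALSE,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(target)
  rbind(target, do.call(rbind, rows))
}

#' Detection filtering and floor imputation
#'
#' Keeps features detected in strictly more than `min_detect` of the samples,
#' imputes missing entries with the 1e-5 floor, and log2-transforms. The
#' missingness mask is preserved on the result.
#'
#' @param am `abundance_matrix` on the FOT scale (missing entries NA or
#'   flagged in the mask).
#' @param min_detect detection fraction threshold (default 0.3, strict
#'   inequality).
#' @return `abundance_matrix` on the log2FOT scale.
#' @export
filter_and_impute <- function(am, min_detect = 0.3) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (am$scale != "FOT") stop("input must be on the FOT scale")
  if (ncol(am$values) < 1L) stop("matrix needs >= 1 sample")
  detected <- rowMeans(!am$missing)
  keep <- detected > min_detect
  if (!any(keep)) {
    warning("no feature detected in more than ",
            round(100 * min_detect), "% of samples; empty matrix")
  }
  v <- am$values[keep, , drop = FALSE]
  miss <- am$missing[keep, , drop = FALSE]
  v[miss] <- 1e-5
  v[!miss & v < 1e-5] <- 1e-5  # guard: floor any stray sub-floor value
  abundance_matrix(log2(v), scale = "log2FOT", missing = miss)
}
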