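# Single-base-substitution mutational signatures: 96-context catalogs
# (pyrimidine-strand convention), de-novo extraction by KL-divergence NMF,
# and refitting against a reference signature set with weight thresholding.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")

#' Canonical 96 trinucleotide-context categories
#'
#' Order is substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank
#' (A, C, G, T), then 3' flank (A, C, G, T); categories are written as e.g.
#' `A[C>T]G`. All catalogs and signature sets in this package use this order.
#'
#' @return character vector of length 96.
#' @export
sbs_contexts <- function() {
  out <- character(0)
  for (s in .SUBS) for (f5 in .BASES) for (f3 in .BASES)
    out <- c(out, sprintf("%s[%s]%s", f5, s, f3))
  out
}

#' Build a 96-context mutation catalog
#'
#' Bins single-nucleotide substitutions into the 96 trinucleotide categories.
#' Records with a purine reference (A/G) are reverse-complemented to the
#' pyrimidine strand before binning. Indels and records with ambiguous bases
#' are skipped; the number of skips is attached as an attribute.
#'
#' @param mutations data.frame with columns `sample`, `ref`, `alt`,
#'   `flank5`, `flank3` (single bases).
#' @param samples optional character vector fixing the catalog's row set
#'   (samples without mutations get all-zero rows).
#' @return integer matrix samples x 96 with attribute `n_skipped`.
#' @export
build_catalog <- function(mutations, samples = NULL) {
  ctx <- sbs_contexts()
  if (is.null(samples)) samples <- unique(mutations$sample)
  cat_mat <- matrix(0L, length(samples), 96L,
                    dimnames = list(samples, ctx))
  if (nrow(mutations) == 0L) {
    attr(cat_mat, "n_skipped") <- 0L
    return(cat_mat)
  }
  ref <- toupper(mutations$ref); alt <- toupper(mutations$alt)
  f5 <- toupper(mutations$flank5); f3 <- toupper(mutations$flank3)
  ok <- ref %in% .BASES & alt %in% .BASES & f5 %in% .BASES & f3 %in% .BASES &
    ref != alt & nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!ok)
  ref <- ref[ok]; alt <- alt[ok]; f5 <- f5[ok]; f3 <- f3[ok]
  smp <- mutations$sample[ok]
  pur <- ref %in% c("A", "G")
  # reverse complement purine-reference records onto the pyrimidine strand:
  # flanks swap and complement along with ref/alt
  ref2 <- ifelse(pur, .COMPLEMENT[ref], ref)
  alt2 <- ifelse(pur, .COMPLEMENT[alt], alt)
  f5_2 <- ifelse(pur, .COMPLEMENT[f3], f5)
  f3_2 <- ifelse(pur, .COMPLEMENT[f5], f3)
  key <- sprintf("%s[%s>%s]%s", f5_2, ref2, alt2, f3_2)
  tab <- table(factor(smp, levels = samples), factor(key, levels = ctx))
  cat_mat <- matrix(as.integer(tab), nrow = length(samples),
                    dimnames = list(samples, ctx))
  attr(cat_mat, "n_skipped") <- n_skipped
  cat_mat
}

# generalized KL divergence D(V || WH), the NMF objective for count data
.kl_div <- function(V, WH) {
  WH <- pmax(WH, 1e-12)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' De-novo signature extraction by NMF
#'
#' Factorizes the 96 x samples count matrix V ~ W H with multiplicative
#' updates minimizing the generalized Kullback-Leibler divergence (the
#' count-appropriate objective). The best of `n_restarts` random restarts by
#' final objective is returned; signature columns are normalized to sum 1
#' with exposures rescaled accordingly.
#'
#' @param catalog samples x 96 count matrix from [build_catalog()].
#' @param k factorization rank (number of signatures), `1 <= k <= min(96, n)`.
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed (restart r uses seed + r).
#' @param max_iter,tol iteration control for the multiplicative updates.
#' @return list with `signatures` (96 x k, columns sum to 1), `exposures`
#'   (k x samples), `objective`, and `objective_trace` of the winning restart.
#' @export
nmf_extract <- function(catalog, k, n_restarts = 10L, seed = 1L,
                        max_iter = 2000L, tol = 1e-8) {
  V <- t(catalog)  # 96 x samples
  n <- ncol(V)
  if (k < 1L || k > min(96L, n)) stop("rank k out of bounds")
  if (all(V == 0)) stop("catalog is all zero")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- withr_seed(seed + r, {
      W <- matrix(runif(96 * k, 0.1, 1), 96, k)
      H <- matrix(runif(k * n, 0.1, 1), k, n)
      trace <- numeric(0)
      obj_old <- Inf
      for (it in seq_len(max_iter)) {
        WH <- pmax(W %*% H, 1e-12)
        W <- W * ((V / WH) %*% t(H)) / pmax(matrix(rowSums(H), 96, k,
                                                   byrow = TRUE), 1e-12)
        WH <- pmax(W %*% H, 1e-12)
        H <- H * (t(W) %*% (V / WH)) / pmax(matrix(colSums(W), k, n), 1e-12)
        obj <- .kl_div(V, W %*% H)
        trace <- c(trace, obj)
        if (is.finite(obj_old) && obj_old - obj < tol * max(1, obj)) break
        obj_old <- obj
      }
      list(W = W, H = H, objective = obj, trace = trace)
    })
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  csum <- colSums(best$W)
  W <- sweep(best$W, 2L, csum, "/")
  H <- sweep(best$H, 1L, csum, "*")
  colnames(W) <- rownames(H) <- paste0("Sig", seq_len(k))
  rownames(W) <- sbs_contexts()
  colnames(H) <- rownames(catalog)
  list(signatures = W, exposures = H, objective = best$objective,
       objective_trace = best$trace)
}

#' Refit one sample's catalog against reference signatures
#'
#' Non-negative least squares fit of the count-normalized catalog against the
#' reference signature matrix. Weights are normalized to sum 1; signatures
#' with weight below `threshold` are removed and the remaining set is
#' re-fitted (iterating until stable) and renormalized. When every weight
#' falls below the threshold the result is flagged `unassigned`.
#'
#' @param counts length-96 count vector (one catalog row), >= 1 mutation.
#' @param reference 96 x k matrix of signature probability vectors (columns
#'   sum to 1), context order as [sbs_contexts()].
#' @param threshold minimal retained weight (default 0.08).
#' @return list of class `exposure_result`: `weights` (named, retained,
#'   summing to 1), `residual` (L2 norm of the restricted fit), `dominant`,
#'   `unassigned`, `tie`.
#' @export
refit_signatures <- function(counts, reference, threshold = 0.08) {
  counts <- as.numeric(counts)
  if (sum(counts) < 1) stop("sample has no mutations to refit")
  if (nrow(reference) != 96L) stop("reference must be 96 x k")
  target <- counts / sum(counts)
  sig_ids <- colnames(reference)
  fit_subset <- function(cols) {
    A <- reference[, cols, drop = FALSE]
    w <- pracma::lsqnonneg(A, target)$x
    names(w) <- cols
    w
  }
  active <- sig_ids
  repeat {
    w_raw <- fit_subset(active)
    if (sum(w_raw) == 0) {
      active <- character(0)
      break
    }
    w <- w_raw / sum(w_raw)
    drop_ <- names(w)[w < threshold]
    if (length(drop_) == 0L) break
    active <- setdiff(active, drop_)
    if (length(active) == 0L) break
  }
  if (length(active) == 0L) {
    return(structure(list(weights = setNames(numeric(0), character(0)),
                          residual = sqrt(sum(target^2)),
                          dominant = "none", unassigned = TRUE, tie = FALSE),
                     class = "exposure_result"))
  }
  w_raw <- fit_subset(active)
  resid <- sqrt(sum((reference[, active, drop = FALSE] %*% w_raw - target)^2))
  w <- w_raw / sum(w_raw)
  mx <- max(w)
  top <- sort(names(w)[w >= mx - 1e-12])
  structure(list(weights = w, residual = resid,
                 dominant = top[1L], unassigned = FALSE,
                 tie = length(top) > 1L),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  if (x$unassigned) {
    cat("exposure_result: unassigned (all weights below threshold)\n")
  } else {
    cat("exposure_result: dominant", x$dominant,
        sprintf("(residual %.3g)\n", x$residual))
    print(round(x$weights, 3))
  }
  invisible(x)
}

#' Assign per-sample dominant-signature groups
#'
#' Labels each sample with its dominant (argmax-weight) signature; ties go to
#' the lexicographically smaller id and are flagged; unassigned samples are
#' labelled "none". When histology classes are supplied, a class x signature
#' cross-tabulation is attached for Sankey-style reporting.
#'
#' @param exposures named list of `exposure_result` objects (one per sample).
#' @param classes optional named vector of histology classes per sample.
#' @return data.frame sample/label/tie, with attribute `crosstab` when
#'   classes are given.
#' @export
assign_signature_groups <- function(exposures, classes = NULL) {
  out <- data.frame(
    sample = names(exposures),
    label = vapply(exposures, function(e) e$dominant, ""),
    tie = vapply(exposures, function(e) isTRUE(e$tie), TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(classes)) {
    attr(out, "crosstab") <- table(class = classes[out$sample],
                                   signature = out$label)
  }
  out
}

#' Read a reference signature TSV
#'
#' Expects 96 rows in the canonical context order (first column `context`,
#' remaining columns one signature each, columns summing to 1).
#'
#' @param path input TSV.
#' @return 96 x k numeric matrix.
#' @export
read_signatures_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), sbs_contexts()))
    stop("signature file must list the 96 contexts in canonical order")
  m
}
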