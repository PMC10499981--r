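# Rank-based statistical primitives used throughout the analysis.
#
# These are deliberately self-contained: the exact-enumeration conventions
# (Wilcoxon enumeration cutover, probability-mass two-sided Fisher test,
# step-up BH) are part of the analysis contract and are cross-checked against
# the base-R equivalents in the test suite.

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test for a difference between two groups. For small
#' problems (`n1 + n2 <= 14` in `auto` mode) the p-value is exact, computed by
#' enumerating all `choose(n1+n2, n1)` group assignments of the observed ranks;
#' otherwise a normal approximation with tie correction and (optionally)
#' continuity correction is used. The statistic is the rank sum W of `x`.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param mode "auto" (exact when total n <= 14), "exact", or "approx".
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation (default TRUE).
#' @return list with `statistic` (rank sum of x), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx"),
                              continuity = TRUE) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  use_exact <- switch(mode, exact = TRUE, approx = FALSE, auto = n <= 14L)
  if (use_exact) {
    # exact permutation distribution of the rank sum over all assignments
    idx <- utils::combn(n, n1)
    ws <- colSums(matrix(r[idx], nrow = n1))
    m <- ncol(idx)
    eps <- 1e-9
    p_lo <- sum(ws <= w + eps) / m
    p_hi <- sum(ws >= w - eps) / m
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v <= 0) return(list(statistic = w, p_value = 1, method = "approx"))
    d <- w - mu
    if (continuity) d <- sign(d) * max(0, abs(d) - 0.5)
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "approx"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Kruskal-Wallis test
#'
#' H statistic with tie correction and chi-square p-value on k-1 degrees of
#' freedom. All-identical observations give H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 1L)) stop("each group needs >= 1 observation")
  all_v <- unlist(groups, use.names = FALSE)
  n <- length(all_v)
  r <- rank(all_v)
  g <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(list(statistic = 0, p_value = 1,
                             df = length(groups) - 1L))
  h <- h / corr
  df <- length(groups) - 1L
  list(statistic = h, p_value = pchisq(h, df, lower.tail = FALSE), df = df)
}

# log hypergeometric pmf via lgamma; own code so base dhyper stays an
# independent oracle
.lhyper <- function(a, r1, r2, c1) {
  lchoose_ <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  lchoose_(r1, a) + lchoose_(r2, c1 - a) - lchoose_(r1 + r2, c1)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: with margins fixed, sum
#' the hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table. A zero margin gives p = 1 by convention.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of counts.
#' @return list with `p_value`, `odds_ratio` (sample OR, may be Inf/NaN).
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- if (is.matrix(table)) matrix(as.numeric(table), 2, 2)
        else matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (any(tb < 0) || any(tb != round(tb))) stop("counts must be non-negative integers")
  a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  or <- (a * d) / (b * c_)
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0)
    return(list(p_value = 1, odds_ratio = or))
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  lp <- .lhyper(support, r1, r2, c1)
  lobs <- .lhyper(a, r1, r2, c1)
  keep <- lp <= lobs + 1e-7
  p <- min(1, sum(exp(lp[keep])))
  list(p_value = p, odds_ratio = or)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m/j) p_(j)`, clipped at 1 and
#' mapped back to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-value vector in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Spearman rank correlation
#'
#' rho from average-tie ranks. The p-value uses the t approximation for
#' `n >= 10` and exact permutation enumeration for smaller samples. Constant
#' input yields an undefined correlation (rho = NA).
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `rho`, `p_value`, `method`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need >= 3 pairs")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, method = "undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t-approx"
  } else {
    # exact permutation null of rho under exchangeability
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  }
  list(rho = rho, p_value = p, method = method)
}

# all permutations of 1..n (n <= 9 in practice: exact Spearman branch)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    if (pos == 1L) cbind(n, sub, deparse.level = 0)
    else if (pos == n) cbind(sub, n, deparse.level = 0)
    else cbind(sub[, 1:(pos - 1L), drop = FALSE], n,
               sub[, pos:(n - 1L), drop = FALSE], deparse.level = 0)
  }))
}

#' Differential protein panel between two groups
#'
#' Features are tested on the log2 scale with the Wilcoxon rank-sum test,
#' BH-adjusted across features; fold change is the ratio of group means on the
#' raw FOT scale (imputed floor values included). Qualifying features have
#' adjusted p below `alpha` and fold change above `fold_bounds[1]` (up in
#' group A) or below `fold_bounds[2]` (up in group B).
#'
#' @param am `abundance_matrix` on the log2FOT scale (FOT values recovered as
#'   `2^value` for fold changes).
#' @param labels factor/character of length ncol with exactly two levels;
#'   group A is the first level.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param fold_bounds numeric length 2: up / down fold-change bounds
#'   (default `c(2, 0.5)`).
#' @return object of class `panel_definition`: lists `up_a`, `up_b`, the
#'   thresholds, and a per-feature `table`.
#' @export
differential_panel <- function(am, labels, alpha = 0.05,
                               fold_bounds = c(2, 0.5)) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (am$scale != "log2FOT") stop("matrix must be on the log2 scale")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two groups")
  ia <- labels == levels(labels)[1L]
  ib <- labels == levels(labels)[2L]
  if (sum(ia) < 3L || sum(ib) < 3L) stop("both groups need >= 3 samples")
  v <- am$values
  fot <- 2^v
  pvals <- apply(v, 1L, function(row)
    wilcoxon_rank_sum(row[ia], row[ib], mode = "auto")$p_value)
  fold <- rowMeans(fot[, ia, drop = FALSE]) / rowMeans(fot[, ib, drop = FALSE])
  q <- bh_adjust(pvals)
  up_a <- rownames(v)[q < alpha & fold > fold_bounds[1L]]
  up_b <- rownames(v)[q < alpha & fold < fold_bounds[2L]]
  if (length(up_a) + length(up_b) == 0L)
    warning("no feature passed both thresholds; empty panel")
  tab <- data.frame(feature = rownames(v), p = pvals, q = q,
                    fold_change = fold,
                    direction = ifelse(rownames(v) %in% up_a, "up_a",
                                ifelse(rownames(v) %in% up_b, "up_b", "ns")),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(up_a = up_a, up_b = up_b, alpha = alpha,
                 fold_bounds = fold_bounds, groups = levels(labels),
                 table = tab),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("differential panel: %d up in %s, %d up in %s (q < %g, FC > %g or < %g)\n",
              length(x$up_a), x$groups[1], length(x$up_b), x$groups[2],
              x$alpha, x$fold_bounds[1], x$fold_bounds[2]))
  invisible(x)
}
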