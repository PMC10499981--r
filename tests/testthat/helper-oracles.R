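# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# character-walk tryptic digestion (no vectorized index tricks)
oracle_digest_count <- function(sequence, lo = 7, hi = 30) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  lens <- integer(0)
  start <- 1L
  for (i in seq_len(n)) {
    boundary <- i == n ||
      (aa[i] %in% c("K", "R") && aa[i + 1L] != "P")
    if (boundary) {
      lens <- c(lens, i - start + 1L)
      start <- i + 1L
    }
  }
  sum(lens >= lo & lens <= hi)
}

# explicit running-sum ssGSEA ES (cumsum of increments, then mean);
# valid for tie-free profiles where the descending order is unambiguous
oracle_ssgsea_es <- function(profile, gene_set, weight = 0.75) {
  ord <- order(profile, decreasing = TRUE)
  r <- rank(profile)[ord]
  hit <- names(profile)[ord] %in% gene_set
  w <- abs(r)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / sum(!hit))
  mean(cumsum(inc))
}

# Newton-Raphson on the Breslow partial likelihood, scalar covariate
oracle_cox_beta <- function(time, event, x, tol = 1e-12) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
  beta <- 0
  for (it in 1:100) {
    U <- 0; info <- 0
    for (i in which(e_s == 1)) {
      risk <- t_s >= t_s[i]
      w <- exp(beta * x_s[risk])
      m1 <- sum(w * x_s[risk]) / sum(w)
      m2 <- sum(w * x_s[risk]^2) / sum(w)
      U <- U + x_s[i] - m1
      info <- info + m2 - m1^2
    }
    step <- U / info
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# BFGS on the exact regularized-logistic objective (z-scaled features,
# unpenalized intercept), independent of the package's Newton solver
oracle_logistic_theta <- function(X, y01, lambda) {
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr,
             scale = sqrt(colMeans(sweep(X, 2, ctr)^2)))
  X1 <- cbind(1, Z)
  obj <- function(theta) {
    eta <- drop(X1 %*% theta)
    yt <- 2 * y01 - 1
    m <- -yt * eta
    mean(ifelse(m > 30, m, log1p(exp(m)))) + lambda / 2 * sum(theta[-1]^2)
  }
  grad <- function(theta) {
    p <- plogis(drop(X1 %*% theta))
    g <- drop(crossprod(X1, p - y01)) / nrow(X1)
    g[-1] <- g[-1] + lambda * theta[-1]
    g
  }
  optim(rep(0, ncol(X1)), obj, grad, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-16))$par
}

# direct per-cutpoint scan of the standardized log-rank-score statistic,
# with Nelson-Aalen hazard from survfit and explicit subset sums
oracle_maxstat <- function(marker, time, event, minprop = 0.1) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  H <- stats::stepfun(fit$time, c(0, cumsum(fit$n.event / fit$n.risk)))
  a <- event - H(time)
  n <- length(marker)
  abar <- mean(a)
  s2 <- sum((a - abar)^2) / (n - 1)
  cuts <- sort(unique(marker))
  cuts <- cuts[-length(cuts)]
  best <- -Inf
  for (cv in cuts) {
    m <- sum(marker <= cv)
    if (m < ceiling(minprop * n) || m > floor((1 - minprop) * n)) next
    S <- sum(a[marker <= cv])
    z <- (S - m * abar) / sqrt(m * (n - m) / (n - 1) * s2)
    best <- max(best, abs(z))
  }
  best
}

# small random two-class dataset for classifier checks
make_logistic_data <- function(n = 30, p = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  beta <- rnorm(p)
  y01 <- rbinom(n, 1, plogis(drop(X %*% beta)))
  if (length(unique(y01)) < 2 || min(table(y01)) < 2) {
    y01[1:2] <- 0; y01[3:4] <- 1
  }
  list(X = X, y01 = y01,
       y = factor(ifelse(y01 == 1, "pos", "neg"), levels = c("neg", "pos")))
}
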