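# Survival analysis: Kaplan-Meier, log-rank, univariate Cox (Breslow ties),
# and maximally selected cutpoint dichotomization with permutation-adjusted
# significance. KM / log-rank / Cox are computed through the survival
# package; the cutpoint scan is implemented here.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function. Samples censored exactly
#' at an event time are counted at risk at that time (standard convention).
#'
#' @param time positive event/censoring times (months).
#' @param event 1 = event (death), 0 = censored.
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival` at each
#'   observed time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Chi-square statistic `(O - E)^2 / V` with hypergeometric variance summed
#' over event times, 1 degree of freedom.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level factor/character per sample.
#' @return list with `statistic`, `p_value` (NA when the variance is zero).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("need exactly two groups")
  if (sum(event) < 1L) stop("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd_$chisq
  if (!is.finite(stat)) return(list(statistic = NA_real_, p_value = NA_real_))
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson with Breslow handling of tied event
#' times (Efron available via `ties`). The hazard ratio is `exp(beta)` with
#' a Wald 95% confidence interval.
#'
#' @param time,event as in [km_estimate()].
#' @param x scalar covariate per sample (non-constant).
#' @param ties "breslow" (default) or "efron".
#' @return list of class `cox_fit`: `beta`, `hr`, `ci` (length 2), `se`,
#'   `p_value` (Wald), `score` (score statistic at beta = 0), `converged`.
#' @export
cox_univariate <- function(time, event, x, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (length(unique(x)) < 2L) stop("covariate is constant")
  if (sum(event) < 1L) stop("need at least one event")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, ties = ties))
      attr(f, "nonconverged") <- TRUE
      f
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  structure(list(beta = beta, hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
                 se = se,
                 p_value = 2 * pnorm(-abs(beta / se)),
                 score = unname(fit$score),
                 converged = !isTRUE(attr(fit, "nonconverged"))),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: HR %.3f (95%% CI %.3f-%.3f), Wald p %.3g%s\n",
              x$hr, x$ci[1], x$ci[2], x$p_value,
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

# log-rank scores: event indicator minus Nelson-Aalen cumulative hazard at
# each subject's time; the two-group log-rank numerator is the sum of these
# scores over one group, which makes the cutpoint scan a linear rank statistic
.logrank_scores <- function(time, event) {
  ot <- order(time)
  t_s <- time[ot]; e_s <- event[ot]
  n <- length(time)
  ev_times <- unique(t_s[e_s == 1])
  scores <- numeric(n)
  cumhaz <- 0
  # walk event times in order; n at risk = subjects with time >= t
  risk_idx <- n
  na_at <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    tk <- ev_times[k]
    nr <- sum(t_s >= tk)
    dk <- sum(t_s == tk & e_s == 1)
    cumhaz <- cumhaz + dk / nr
    na_at[k] <- cumhaz
  }
  # cumulative hazard evaluated at each subject's own time
  ch_fun <- stats::stepfun(ev_times, c(0, na_at))
  out <- event - ch_fun(time)
  out
}

# max over admissible cutpoints of |standardized sum of scores in the
# low group|; cum_scores are scores ordered by marker, cuts are the
# admissible "low-group size" values
.max_std_stat <- function(scores_by_marker, cuts, n, s_mean, s_var) {
  cs <- cumsum(scores_by_marker)
  m <- cuts
  e <- m * s_mean
  v <- m * (n - m) / (n - 1) * s_var
  z <- (cs[m] - e) / sqrt(v)
  list(max = max(abs(z)), z = z)
}

#' Maximally selected survival cutpoint
#'
#' Scans every admissible dichotomization of a continuous marker (both sides
#' at least `minprop` of the samples) and selects the cutpoint maximizing the
#' standardized log-rank-score statistic (the maximally-selected rank
#' statistic with log-rank scores, as used for optimal biomarker cutoffs).
#' The selection-adjusted p-value is obtained by permuting the marker
#' `n_perm` times and re-maximizing, so the multiplicity of the scan is
#' accounted for.
#'
#' @param marker numeric marker per sample (non-constant).
#' @param time,event as in [km_estimate()].
#' @param minprop minimal fraction of samples on each side (default 0.1).
#' @param n_perm permutations for the adjusted p (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `cutpoint` (midpoint of the selected gap), `statistic`
#'   (max standardized statistic), `p_value` (permutation), `logrank_at_cut`
#'   (naive log-rank test at the selected cutpoint).
#' @export
optimal_cutpoint <- function(marker, time, event, minprop = 0.1,
                             n_perm = 1000L, seed = 1L) {
  n <- length(marker)
  stopifnot(length(time) == n, length(event) == n)
  if (length(unique(marker)) < 2L) stop("marker is constant")
  scores <- .logrank_scores(time, event)
  ord <- order(marker)
  m_sorted <- marker[ord]
  s_sorted <- scores[ord]
  lo <- ceiling(minprop * n); hi <- floor((1 - minprop) * n)
  # cutpoints sit between distinct marker values only
  cand <- which(diff(m_sorted) > 0)
  cand <- cand[cand >= lo & cand <= hi]
  if (length(cand) == 0L) stop("no admissible cutpoint under minprop")
  s_mean <- mean(scores)
  s_var <- sum((scores - s_mean)^2) / (n - 1)
  if (s_var == 0) stop("degenerate survival data: all log-rank scores equal")
  obs <- .max_std_stat(s_sorted, cand, n, s_mean, s_var)
  best <- cand[which.max(abs(obs$z))]
  cutpoint <- (m_sorted[best] + m_sorted[best + 1L]) / 2
  perm_max <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      .max_std_stat(s_sorted[sample.int(n)], cand, n, s_mean, s_var)$max
    }, 0)
  })
  p <- (1 + sum(perm_max >= obs$max - 1e-12)) / (n_perm + 1)
  grp <- ifelse(marker <= cutpoint, "low", "high")
  naive <- logrank_test(time, event, grp)
  list(cutpoint = cutpoint, statistic = obs$max, p_value = p,
       logrank_at_cut = naive)
}
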