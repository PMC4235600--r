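#' Nagelkerke R-squared for a Cox model
#'
#' `R2 = 1 - exp(-(2/n) * (l(beta_hat) - l(0)))`, the proportion-of-variation
#' summary based on the log partial likelihood at the estimate and at zero.
#'
#' @param loglik_hat log partial likelihood at the maximizer.
#' @param loglik_null log partial likelihood at `beta = 0`; must not exceed
#'   `loglik_hat` (a maximizer cannot be worse than the null).
#' @param n sample size of the fitted model.
#' @return value in `[0, 1)`.
#' @examples
#' nagelkerke_r2(-10, -10, 50)       # 0: the fit explains nothing
#' nagelkerke_r2(-75, -100, 50)      # 1 - exp(-1)
#' @export
nagelkerke_r2 <- function(loglik_hat, loglik_null, n) {
  check_loglik_pair(loglik_hat, loglik_null)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  1 - exp(-(2 / n) * (loglik_hat - loglik_null))
}

#' Likelihood ratio statistic for a Cox model
#'
#' `LR = (-2 l(0)) - (-2 l(beta_hat)) = 2 (l(beta_hat) - l(0)) >= 0`; larger
#' values indicate a better-fitting model.
#'
#' @inheritParams nagelkerke_r2
#' @return non-negative scalar.
#' @export
likelihood_ratio <- function(loglik_hat, loglik_null) {
  check_loglik_pair(loglik_hat, loglik_null)
  2 * (loglik_hat - loglik_null)
}

check_loglik_pair <- function(loglik_hat, loglik_null) {
  if (loglik_hat < loglik_null - 1e-8)
    stop("loglik_hat < loglik_null: not a maximized fit", call. = FALSE)
  invisible(TRUE)
}

#' Gonen-Heller concordance probability estimate (CPE)
#'
#' Model-based pairwise concordance of a proportional-hazards fit. It is a
#' function of the regression coefficients and the covariate distribution
#' only - the observed event and censoring times are not used. For each
#' unordered sample pair the concordance probability under the PH model is
#' `1 / (1 + exp(-|d|))` with `d` the difference of linear predictors; CPE
#' averages these over all pairs. `beta = 0` gives 0.5; the value approaches
#' 1 (perfect discrimination) as the linear predictors separate.
#'
#' Note: unlike rank-based concordance, CPE is not invariant to rescaling
#' `beta` with `x` fixed - doubling all coefficients moves the value toward 1.
#'
#' @param beta fitted coefficient vector.
#' @param x samples-by-features covariate matrix (>= 2 rows).
#' @return value in `[0.5, 1)` up to pair ties.
#' @export
cpe <- function(beta, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = length(beta))
  if (nrow(x) < 2) stop("CPE needs at least 2 samples", call. = FALSE)
  cpe_from_lp(prognostic_index(x, beta))
}

#' @rdname cpe
#' @param lp precomputed linear predictors (`x %*% beta`).
#' @export
cpe_from_lp <- function(lp) {
  n <- length(lp)
  if (n < 2) stop("CPE needs at least 2 samples", call. = FALSE)
  d <- abs(outer(lp, lp, "-"))
  mean(1 / (1 + exp(-d[upper.tri(d)])))
}

#' Harrell's concordance index
#'
#' Fraction of usable sample pairs whose risk-score ordering agrees with
#' their survival ordering: a pair is usable when the shorter observed time
#' ends in an event; the pair counts as concordant when that sample has the
#' higher prognostic index, and tied indices count 1/2. Pairs made
#' non-comparable by censoring are excluded. Computed via
#' `survival::concordance` with higher scores mapping to shorter survival.
#'
#' @param pi prognostic index (higher = higher predicted risk).
#' @param time,event observed survival outcome aligned with `pi`.
#' @return value in `[0, 1]`; 0.5 for a completely random score, 1 for a
#'   perfect rule.
#' @export
c_index <- function(pi, time, event) {
  if (length(pi) != length(time) || length(time) != length(event))
    stop("pi, time and event must have equal length", call. = FALSE)
  cc <- survival::concordance(survival::Surv(time, event) ~ pi, reverse = TRUE)
  usable <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (!is.finite(cc$concordance) || usable == 0)
    stop("no usable pairs: concordance undefined", call. = FALSE)
  unname(cc$concordance)
}

#' Inverse-probability-of-censoring weighted Brier score
#'
#' Squared error between the predicted survival probability and the observed
#' at-risk status, weighted to remove censoring bias (the Graf scheme):
#' `BS(t) = (1/N) sum_i w_i(t) (p_i(t) - o_i(t))^2` with `o_i(t) = 1` if
#' sample i is still at risk at t. Weights use the Kaplan-Meier estimate
#' `G` of the censoring distribution: samples with an observed event at
#' `T_i <= t` get `1/G(T_i-)`, samples still at risk get `1/G(t)`, and
#' samples censored by `t` get 0. Terms whose weight is undefined
#' (`G = 0`) are dropped with a warning.
#'
#' @param surv_prob predicted survival probabilities, a samples-by-times
#'   matrix aligned with `times` (a vector is accepted for one time point).
#' @param times evaluation time grid.
#' @param time,event observed outcome of the scored samples; also used to
#'   estimate the censoring distribution unless `cens_fn` is given.
#' @param cens_fn optional right-continuous step function `G(t)` for the
#'   censoring survival distribution.
#' @return numeric vector `BS(t)` over the grid.
#' @export
brier_score <- function(surv_prob, times, time, event, cens_fn = NULL) {
  if (is.null(dim(surv_prob))) surv_prob <- matrix(surv_prob, ncol = length(times))
  if (ncol(surv_prob) != length(times))
    stop("surv_prob must have one column per time point", call. = FALSE)
  if (nrow(surv_prob) != length(time))
    stop("surv_prob must have one row per sample", call. = FALSE)
  if (is.null(cens_fn)) cens_fn <- censoring_km(time, event)
  n <- length(time)
  g_at_event <- cens_fn(time - 1e-12)      # left limit G(T-)
  dropped <- FALSE
  bs <- vapply(seq_along(times), function(j) {
    t <- times[j]
    o <- as.numeric(time > t)
    w <- numeric(n)
    idx_event <- time <= t & event == 1
    w[idx_event] <- 1 / g_at_event[idx_event]
    gt <- cens_fn(t)
    w[time > t] <- if (gt > 0) 1 / gt else NA_real_
    bad <- !is.finite(w)
    if (any(bad)) { dropped <<- TRUE; w[bad] <- 0 }
    sum(w * (surv_prob[, j] - o)^2) / n
  }, numeric(1))
  if (dropped)
    warning("censoring KM reached 0 before some evaluation times; ",
            "affected terms dropped", call. = FALSE)
  bs
}

#' Integrated Brier score
#'
#' Time-normalized integral of the IPCW Brier score,
#' `IBS = (1/tau) integral_0^tau BS(t) dt`, by the trapezoid rule over the
#' evaluation grid with `BS(0) = 0` prepended (every sample is at risk at
#' time zero and a valid survival curve starts at 1). By default the grid is
#' the set of unique observed event times and `tau` is the largest event
#' time.
#'
#' @inheritParams brier_score
#' @param times evaluation grid; defaults to the unique event times.
#' @param tau upper integration limit; defaults to `max(times)`.
#' @return scalar in `[0, 1]`.
#' @export
integrated_brier <- function(surv_prob, times = NULL, time, event,
                             cens_fn = NULL, tau = NULL) {
  if (is.null(times)) times <- sort(unique(time[event == 1]))
  if (length(times) < 1) stop("no event times to integrate over", call. = FALSE)
  if (is.null(tau)) tau <- max(times)
  bs <- brier_score(surv_prob, times, time, event, cens_fn)
  keep <- times <= tau
  grid <- c(0, times[keep])
  vals <- c(0, bs[keep])
  sum(diff(grid) * (head(vals, -1) + tail(vals, -1)) / 2) / tau
}

# Kaplan-Meier estimate of the censoring survival function, as a
# right-continuous step function with G(0) = 1.
censoring_km <- function(time, event) {
  km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  stepfun(km$time, c(1, km$surv))
}
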