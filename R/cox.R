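#' Fit a Cox proportional-hazards model on a covariate matrix
#'
#' Thin matrix interface to the Newton-Raphson partial-likelihood maximizer
#' of the survival package (`coxph.fit`), returning the pieces the rest of
#' the pipeline needs: coefficients, model-based standard errors from the
#' observed information, and the log partial likelihood at the estimate and
#' at zero. Covariates are mean-centered internally for numerical stability;
#' this changes neither the estimate nor the likelihoods. Ties are handled
#' with the Breslow approximation by default (simulated times are continuous,
#' so the choice is immaterial there); Efron is available.
#'
#' @param x numeric covariate matrix, samples in rows (a vector is taken as
#'   a single column).
#' @param time positive follow-up times.
#' @param event event indicators in \{0, 1\}; at least one event is required.
#' @param ties `"breslow"` or `"efron"`.
#' @param iter_max maximum Newton-Raphson iterations.
#' @param eps relative convergence tolerance on the log partial likelihood.
#' @return An object of class `cox_fit`: list with `coefficients`, `se`,
#'   `var` (covariance matrix), `loglik` (at the estimate), `loglik_null`,
#'   `n`, `n_event`, `iter`, `converged`, and `flags` (character vector;
#'   non-empty when the fit hit the iteration cap or a monotone-likelihood /
#'   infinite-coefficient guard fired).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' f <- fit_cox(x, rexp(20, exp(x[, 1] * 0.5)), rep(1, 20))
#' f$coefficients
#' @export
fit_cox <- function(x, time, event, ties = c("breslow", "efron"),
                    iter_max = 25, eps = 1e-9) {
  ties <- match.arg(ties)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (anyNA(x) || anyNA(time) || anyNA(event))
    stop("missing values are not allowed in a Cox fit", call. = FALSE)
  if (length(time) != nrow(x) || length(event) != nrow(x))
    stop("time/event length must match nrow(x)", call. = FALSE)
  if (any(time <= 0)) stop("all times must be strictly positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph.fit(xc, survival::Surv(time, event),
                        strata = NULL, offset = NULL,
                        init = rep(0, ncol(x)),
                        control = survival::coxph.control(iter.max = iter_max,
                                                          eps = eps),
                        weights = NULL, method = ties, rownames = NULL),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- as.vector(fit$coefficients)
  if (anyNA(beta)) flags <- c(flags, "singular or unidentified coefficient")
  v <- as.matrix(fit$var)
  converged <- fit$iter < iter_max && !anyNA(beta)
  if (!converged && !anyNA(beta))
    flags <- c(flags, sprintf("iteration cap (%d) reached", iter_max))
  structure(list(coefficients = setNames(beta, colnames(x)),
                 se = setNames(sqrt(pmax(diag(v), 0)), colnames(x)),
                 var = v,
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 n = nrow(x), n_event = sum(event),
                 iter = fit$iter, converged = converged, flags = flags,
                 ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: %d covariate(s), %d samples, %d events (%s ties)\n",
              length(x$coefficients), x$n, x$n_event, x$ties))
  print(data.frame(coef = x$coefficients, se = x$se,
                   z = x$coefficients / x$se))
  cat(sprintf("loglik %.4f (null %.4f), %d iterations%s\n", x$loglik,
              x$loglik_null, x$iter,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Univariate Cox Wald screen over all genes
#'
#' Fits a single-covariate Cox model per gene and returns the absolute Wald
#' statistic `|beta / se(beta)|` used to rank genes by their marginal
#' association with survival. Genes whose fit fails (zero variance,
#' non-finite statistic) receive `-Inf` and are never selected; failures are
#' flagged, never propagated as errors. Screening fits use a tighter
#' iteration cap for speed; the scores are deterministic given the data.
#'
#' @param x genes-by-samples expression matrix (rownames are gene ids).
#' @param time,event survival outcome, one entry per sample (column of `x`).
#' @param ties tie handling passed to the per-gene fits.
#' @param iter_max per-gene iteration cap.
#' @return data frame with one row per gene, in input order: `gene`, `beta`,
#'   `se`, `statistic` (= `|beta/se|`, `-Inf` for failed fits) and `ok`.
#' @examples
#' sim <- simulate_bt(bt_sim_spec(n_genes = 300, n_samples = 60), seed = 1)
#' sc <- wald_screen(sim$expression, sim$survival$time, sim$survival$event)
#' head(sc[order(sc$statistic, decreasing = TRUE), ])
#' @export
wald_screen <- function(x, time, event, ties = c("breslow", "efron"),
                        iter_max = 10) {
  ties <- match.arg(ties)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (ncol(x) != length(time))
    stop("x must be genes x samples with one column per survival record",
         call. = FALSE)
  y <- survival::Surv(time, event)
  ctl <- survival::coxph.control(iter.max = iter_max)
  fit1 <- function(g) {
    v <- x[g, ]
    if (sd(v) == 0) return(c(NA_real_, NA_real_))
    f <- tryCatch(suppressWarnings(
      survival::coxph.fit(matrix(v - mean(v), ncol = 1), y,
                          strata = NULL, offset = NULL, init = 0,
                          control = ctl, weights = NULL, method = ties,
                          rownames = NULL)),
      error = function(e) NULL)
    if (is.null(f) || anyNA(f$coefficients) || !is.finite(f$var) || f$var <= 0)
      return(c(NA_real_, NA_real_))
    c(f$coefficients[1], sqrt(f$var[1]))
  }
  bs <- vapply(seq_len(nrow(x)), fit1, numeric(2))
  stat <- abs(bs[1, ] / bs[2, ])
  ok <- is.finite(stat)
  stat[!ok] <- -Inf
  data.frame(gene = rownames(x), beta = bs[1, ], se = bs[2, ],
             statistic = stat, ok = ok, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Prognostic index (linear risk score)
#'
#' `PI = X beta`, one value per sample: the linear predictor of a Cox model
#' evaluated with train-estimated coefficients, typically on held-out
#' feature rows.
#'
#' @param x samples-by-features matrix.
#' @param beta coefficient vector of length `ncol(x)`.
#' @return numeric vector of length `nrow(x)`.
#' @export
prognostic_index <- function(x, beta) {
  if (is.null(dim(x))) x <- matrix(x, ncol = length(beta))
  if (ncol(x) != length(beta))
    stop(sprintf("dimension mismatch: %d feature columns vs %d coefficients",
                 ncol(x), length(beta)), call. = FALSE)
  drop(x %*% beta)
}

#' Breslow baseline survival estimator
#'
#' Step-function estimate of the baseline survival `S0(t)` at covariate
#' value zero: `S0(t) = exp(-H0(t))` with the Breslow cumulative hazard
#' `H0(t) = sum_{t_j <= t} d_j / sum_{l in R_j} exp(lp_l)`. With all linear
#' predictors zero it reduces to the Nelson-Aalen-based estimator.
#' Evaluation beyond the last observed event time carries the last value.
#'
#' @param time,event the (training) survival outcome.
#' @param lp linear predictors on the same scale as those later passed to
#'   [survival_curve()] (i.e., uncentered `X beta`).
#' @return An object of class `breslow_baseline`: list with sorted unique
#'   event `times`, `surv` (`S0` at those times), and `fn`, a right-continuous
#'   step function with `S0(0) = 1`.
#' @export
breslow_baseline <- function(time, event, lp = rep(0, length(time))) {
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  ut <- sort(unique(time[event == 1]))
  elp <- exp(lp)
  inc <- vapply(ut, function(t) sum(event == 1 & time == t) / sum(elp[time >= t]),
                numeric(1))
  s0 <- exp(-cumsum(inc))
  structure(list(times = ut, surv = s0, fn = stepfun(ut, c(1, s0))),
            class = "breslow_baseline")
}

#' Per-sample survival curves under a Cox model
#'
#' `S(t | x) = S0(t) ^ exp(PI)` for each prognostic index, evaluated on a
#' time grid.
#'
#' @param baseline a [breslow_baseline()] object.
#' @param pi prognostic index vector (uncentered linear predictors).
#' @param times evaluation grid; defaults to the baseline's event times.
#' @return matrix of survival probabilities, `length(pi)` rows by
#'   `length(times)` columns.
#' @export
survival_curve <- function(baseline, pi, times = baseline$times) {
  s0 <- baseline$fn(times)
  out <- outer(exp(pi), seq_along(times), function(e, j) s0[j]^e)
  colnames(out) <- signif(times, 6)
  out
}
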