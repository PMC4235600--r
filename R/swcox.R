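#' Supervised dimension-reduction Cox model
#'
#' The package's core estimator. Genes are screened on the training data
#' with univariate Cox Wald statistics, the top `n_genes` are compressed to
#' a low-dimensional feature matrix by the chosen reducer (level-1 Haar
#' wavelet approximation coefficients by default; supervised principal
#' components or sequential PLS-Cox components as comparators), and a
#' multivariate Cox proportional-hazards model is fitted on the features.
#' Optional clinical covariates bypass the reduction and enter the final
#' model directly.
#'
#' @param x genes-by-samples training expression matrix with gene ids as
#'   rownames and sample ids as colnames.
#' @param time,event training survival outcome, one entry per sample.
#' @param method,n_genes,gene_order,var_threshold,n_components,screen passed
#'   to [fit_reducer()].
#' @param clinical optional samples-by-covariates numeric matrix or data
#'   frame of clinical covariates (pre-encoded numerically, no missing
#'   values), row-aligned with the samples; appended to the reduced features
#'   before the final fit.
#' @param ties tie handling for all Cox fits.
#' @return An object of class `swcox`: list with the `reducer`, the stage-2
#'   `fit` (a [fit_cox()] object over the reduced + clinical features), the
#'   training `features`, prognostic index `pi_train`, the Breslow
#'   `baseline` survival estimator of the fitted model, and the training
#'   outcome. The usual model methods are provided: `print`, `summary`,
#'   `coef`, [predict.swcox()], `residuals` and `plot`.
#' @examples
#' sim <- simulate_bt(bt_sim_spec(n_genes = 300, n_samples = 60), seed = 1)
#' fit <- swcox(sim$expression, sim$survival$time, sim$survival$event,
#'              method = "wavelet", n_genes = 10)
#' fit
#' head(predict(fit, sim$expression))        # prognostic index
#' @export
swcox <- function(x, time, event, method = c("wavelet", "pca", "pls"),
                  n_genes = 40, gene_order = c("wald", "abs_wald", "original"),
                  var_threshold = 0.75, n_components = NULL, screen = NULL,
                  clinical = NULL, ties = c("breslow", "efron")) {
  method <- match.arg(method)
  ties <- match.arg(ties)
  if (ncol(x) != length(time) || length(time) != length(event))
    stop("x must have one column per survival record", call. = FALSE)
  if (is.null(screen)) screen <- wald_screen(x, time, event, ties = ties)
  reducer <- fit_reducer(x, time, event, method = method, n_genes = n_genes,
                         gene_order = gene_order,
                         var_threshold = var_threshold,
                         n_components = n_components, screen = screen,
                         ties = ties)
  feats <- predict(reducer, x)
  if (!is.null(clinical)) feats <- with_clinical(feats, clinical)
  fit <- fit_cox(feats, time, event, ties = ties)
  pi_train <- prognostic_index(feats, fit$coefficients)
  structure(list(reducer = reducer, fit = fit, features = feats,
                 screen = screen, pi_train = pi_train,
                 baseline = breslow_baseline(time, event, pi_train),
                 time = time, event = event,
                 clinical_names = colnames(clinical),
                 method = method, n_genes = n_genes,
                 call = match.call()),
            class = "swcox")
}

#' Combine reduced genomic features with clinical covariates
#'
#' Column-binds the reduced feature matrix and the clinical covariates ahead
#' of the final multivariate Cox fit. Clinical covariates are not screened
#' or reduced. When both carry row names they must agree (no silent
#' realignment); missing values are an error - no imputation is attempted.
#'
#' @param features samples-by-features numeric matrix.
#' @param clinical samples-by-covariates numeric matrix or data frame;
#'   `NULL` or zero columns return `features` unchanged.
#' @return the augmented feature matrix.
#' @export
with_clinical <- function(features, clinical) {
  if (is.null(clinical) || NCOL(clinical) == 0) return(features)
  cl <- as.matrix(clinical)
  if (!is.numeric(cl))
    stop("clinical covariates must be numeric (encode categories first)",
         call. = FALSE)
  if (anyNA(cl)) stop("missing clinical values are not allowed", call. = FALSE)
  if (nrow(cl) != nrow(features))
    stop("clinical rows must match the number of samples", call. = FALSE)
  if (!is.null(rownames(cl)) && !is.null(rownames(features)) &&
      !identical(rownames(cl), rownames(features)))
    stop("clinical sample ids do not align with the feature matrix",
         call. = FALSE)
  if (is.null(colnames(cl))) colnames(cl) <- paste0("clin", seq_len(ncol(cl)))
  cbind(features, cl)
}

#' Predict from a supervised dimension-reduction Cox model
#'
#' @param object a fitted [swcox()] model.
#' @param newdata genes-by-samples expression matrix containing the selected
#'   gene ids.
#' @param type `"lp"` (prognostic index, the default), `"risk"`
#'   (`exp(lp)`), or `"survival"` (per-sample survival curves on `times`).
#' @param newclinical clinical covariates for the new samples; required
#'   (and only allowed) when the model was fitted with clinical covariates.
#' @param times evaluation grid for `type = "survival"`; defaults to the
#'   training event times.
#' @param ... unused.
#' @return a numeric vector (lp/risk) or a samples-by-times matrix.
#' @export
predict.swcox <- function(object, newdata, type = c("lp", "risk", "survival"),
                          newclinical = NULL, times = NULL, ...) {
  type <- match.arg(type)
  feats <- predict(object$reducer, newdata)
  if (!is.null(object$clinical_names) || !is.null(newclinical)) {
    if (is.null(newclinical))
      stop("model was fitted with clinical covariates; supply newclinical",
           call. = FALSE)
    feats <- with_clinical(feats, newclinical)
  }
  pi <- prognostic_index(feats, object$fit$coefficients)
  switch(type,
         lp = pi,
         risk = exp(pi),
         survival = survival_curve(object$baseline, pi,
                                   times %||% object$baseline$times))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.swcox <- function(object, ...) object$fit$coefficients

#' @export
print.swcox <- function(x, ...) {
  cat(sprintf("Supervised %s Cox model: %d screened genes -> %d feature(s)",
              x$method, x$n_genes, ncol(x$features)), "\n")
  cat(sprintf("  %d samples, %d events; loglik %.3f (null %.3f)%s\n",
              x$fit$n, x$fit$n_event, x$fit$loglik, x$fit$loglik_null,
              if (x$fit$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Summary of a supervised dimension-reduction Cox model
#'
#' Reports the coefficient table of the stage-2 Cox fit together with the
#' apparent (training-sample) evaluation criteria of the fitted model:
#' Harrell's C-index, the Gonen-Heller concordance probability, Nagelkerke's
#' R-squared and the likelihood ratio statistic. Apparent values are
#' optimistic for high-dimensional fits; use [run_experiment()] for
#' held-out assessment.
#'
#' @param object a fitted [swcox()] model.
#' @param ... unused.
#' @export
summary.swcox <- function(object, ...) {
  f <- object$fit
  z <- f$coefficients / f$se
  out <- list(
    call = object$call, method = object$method, n_genes = object$n_genes,
    coefficients = data.frame(coef = f$coefficients, se = f$se, z = z,
                              p = 2 * pnorm(-abs(z))),
    apparent = c(c_index = c_index(object$pi_train, object$time, object$event),
                 cpe = cpe_from_lp(object$pi_train),
                 r2 = nagelkerke_r2(f$loglik, f$loglik_null, f$n),
                 lr = likelihood_ratio(f$loglik, f$loglik_null)),
    n = f$n, n_event = f$n_event, converged = f$converged)
  class(out) <- "summary.swcox"
  out
}

#' @export
print.summary.swcox <- function(x, ...) {
  cat(sprintf("Supervised %s Cox model (%d screened genes)\n", x$method,
              x$n_genes))
  print(round(x$coefficients, 4))
  cat(sprintf("\nApparent criteria (n = %d, events = %d):\n", x$n, x$n_event))
  print(round(x$apparent, 4))
  invisible(x)
}

#' Martingale residuals of the fitted model
#'
#' `event_i - H0(t_i) exp(PI_i)` with the Breslow cumulative baseline hazard
#' of the training fit.
#'
#' @param object a fitted [swcox()] model.
#' @param ... unused.
#' @export
residuals.swcox <- function(object, ...) {
  h0 <- -log(pmax(object$baseline$fn(object$time), .Machine$double.xmin))
  object$event - h0 * exp(object$pi_train)
}

#' Plot the gene screen of a fitted model
#'
#' Ranked absolute Wald statistics of the training screen with the selected
#' genes highlighted - a scree-style view of how sharply the marginal
#' survival association separates the retained genes from the rest.
#'
#' @param x a fitted [swcox()] model.
#' @param n_show how many top-ranked genes to draw.
#' @param ... passed to `plot`.
#' @export
plot.swcox <- function(x, n_show = 200, ...) {
  st <- sort(x$screen$statistic[is.finite(x$screen$statistic)],
             decreasing = TRUE)
  n_show <- min(n_show, length(st))
  plot(seq_len(n_show), head(st, n_show),
       xlab = "gene rank", ylab = "|Wald statistic|",
       main = sprintf("Supervised screen (%s, top %d kept)", x$method,
                      x$n_genes), ...)
  abline(v = x$n_genes + 0.5, lty = 2)
  invisible(x)
}
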