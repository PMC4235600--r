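#' Repeated train/test split evaluation of the supervised reducers
#'
#' Runs the full benchmarking harness: the data are split `n_reps` times
#' into a training fraction (2/3 by default) and a held-out remainder, with
#' one shared partition per repetition used by every method and gene count,
#' so per-repetition differences between methods are paired. For each
#' repetition, genes are screened once on the training split; each
#' (method, gene count) cell then fits its reducer and stage-2 Cox model on
#' the training split, computes the prognostic index (PI) on both splits,
#' and scores five criteria on two bases:
#' \describe{
#'   \item{apparent}{training-sample values of the fitted model: Harrell's
#'     C-index and Gonen-Heller CPE of the training PI, Nagelkerke R-squared
#'     and likelihood ratio from the stage-2 partial likelihoods
#'     (n = training size), and the IPCW integrated Brier score of the
#'     model's own training-set survival curves. Apparent values include
#'     the optimism of fitting many features to few samples.}
#'   \item{heldout}{test-split values: C-index of the test PI against the
#'     test outcome; R-squared, likelihood ratio and CPE from a
#'     single-covariate Cox model of the test outcome on the test PI
#'     (n = test size); the integrated Brier score `ibs` of survival curves
#'     predicted by the \emph{training} model (training Breslow baseline
#'     raised to `exp(PI)`), with IPCW weights from the test split's
#'     censoring Kaplan-Meier - the standard prediction-error scheme; and
#'     `ibs_refit`, the same score with curves rebuilt from the test-split
#'     PI refit's own Breslow baseline (a recalibrated variant that measures
#'     discrimination of the PI rather than calibration of the training
#'     model). In the apparent basis `ibs_refit` equals `ibs`, because
#'     refitting the training outcome on the training PI reproduces the
#'     stage-2 model.}
#' }
#'
#' Splits are stratified on the event indicator by default so the event
#' fraction is comparable across repetitions; a split whose training half
#' has no events is redrawn (and logged). A cell whose stage-2 fit does not
#' converge is recorded as missing for that repetition and logged.
#' Per-repetition seeds are `seed + rep`, so any single repetition is
#' reproducible in isolation.
#'
#' @param x genes-by-samples expression matrix.
#' @param time,event survival outcome, one entry per sample.
#' @param methods subset of `c("wavelet", "pca", "pls")`.
#' @param gene_counts vector of screen sizes (each >= 2). For each split the
#'   PLS component count is fixed to the supervised-PCA count obtained on
#'   the same training submatrix.
#' @param n_reps number of random splits.
#' @param train_fraction training fraction in (0, 1); the training size is
#'   `floor(train_fraction * n)` exactly (66 of 100 samples at 2/3).
#' @param seed master seed (integer). Required for reproducibility; when
#'   `NULL` a seed is drawn and recorded in the result.
#' @param stratify stratify splits on the event indicator.
#' @param gene_order,var_threshold,ties passed to [swcox()].
#' @param clinical optional samples-by-covariates numeric matrix appended to
#'   every cell's reduced features (rows aligned with the columns of `x`).
#' @param verbose print one line per repetition.
#' @return An object of class `swc_experiment` holding the per-repetition
#'   metric arrays for both bases, the shared split indices, the plan, and a
#'   log of redraws/failed cells. See [summary.swc_experiment()],
#'   [difference_report()], [write_results()].
#' @examples
#' sim <- simulate_bt(bt_sim_spec(n_genes = 300, n_samples = 60), seed = 7)
#' ex <- run_experiment(sim$expression, sim$survival$time, sim$survival$event,
#'                      methods = c("wavelet", "pca"), gene_counts = c(10, 4),
#'                      n_reps = 3, seed = 7)
#' summary(ex)
#' @export
run_experiment <- function(x, time, event,
                           methods = c("wavelet", "pca", "pls"),
                           gene_counts = c(40, 30, 20, 10),
                           n_reps = 50, train_fraction = 2 / 3, seed = NULL,
                           stratify = TRUE,
                           gene_order = c("wald", "abs_wald", "original"),
                           var_threshold = 0.75, clinical = NULL,
                           ties = c("breslow", "efron"), verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  gene_order <- match.arg(gene_order)
  ties <- match.arg(ties)
  n <- ncol(x)
  if (length(time) != n || length(event) != n)
    stop("time/event must have one entry per sample (column of x)",
         call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (any(gene_counts < 2)) stop("gene_counts must all be >= 2", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(1e8, 1)
  if (seed + n_reps >= 2^31) stop("seed too large", call. = FALSE)
  if (!is.null(clinical)) {
    clinical <- as.matrix(clinical)
    if (nrow(clinical) != n)
      stop("clinical must have one row per sample", call. = FALSE)
  }

  cells <- expand.grid(method = methods, n_genes = gene_counts,
                       stringsAsFactors = FALSE)
  cell_id <- paste(cells$method, cells$n_genes, sep = "_")
  metrics <- c("c_index", "cpe", "r2", "lr", "ibs", "ibs_refit")
  empty <- matrix(NA_real_, n_reps, nrow(cells),
                  dimnames = list(NULL, cell_id))
  values <- list(apparent = setNames(rep(list(empty), length(metrics)),
                                     metrics),
                 heldout = setNames(rep(list(empty), length(metrics)),
                                    metrics))
  splits <- vector("list", n_reps)
  n_redraw <- 0L; failed <- character(0)

  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    repeat {
      tr <- draw_split(n, train_fraction, event, stratify)
      if (sum(event[tr]) >= 1) break
      n_redraw <- n_redraw + 1L
    }
    splits[[r]] <- tr
    te <- setdiff(seq_len(n), tr)
    xt <- x[, tr, drop = FALSE]; yt <- time[tr]; et <- event[tr]
    xe <- x[, te, drop = FALSE]; ye <- time[te]; ee <- event[te]
    scr <- wald_screen(xt, yt, et, ties = ties)
    grid_te <- sort(unique(ye[ee == 1]))
    for (ci in seq_len(nrow(cells))) {
      m <- cells$method[ci]; ng <- cells$n_genes[ci]
      cell <- cell_id[ci]
      res <- tryCatch({
        k <- NULL
        if (m == "pls") {
          # component count pinned to the PCA rule on the same train split
          pc_red <- fit_reducer(xt, yt, et, method = "pca", n_genes = ng,
                                var_threshold = var_threshold, screen = scr,
                                ties = ties)
          k <- pc_red$n_components
        }
        mod <- swcox(xt, yt, et, method = m, n_genes = ng,
                     gene_order = gene_order, var_threshold = var_threshold,
                     n_components = k, screen = scr,
                     clinical = if (is.null(clinical)) NULL
                                else clinical[tr, , drop = FALSE],
                     ties = ties)
        if (!mod$fit$converged) stop("stage-2 Cox fit did not converge")
        score_cell(mod, xe, ye, ee, grid_te,
                   if (is.null(clinical)) NULL
                   else clinical[te, , drop = FALSE])
      }, error = function(e) {
        failed <<- c(failed, sprintf("rep %d %s: %s", r, cell,
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(res))
        for (b in names(values))
          for (mt in metrics)
            values[[b]][[mt]][r, ci] <- res[[b]][[mt]]
    }
    if (verbose)
      message(sprintf("rep %d/%d done (train events %d)", r, n_reps,
                      sum(et)))
  }
  structure(list(values = values, cells = cells, splits = splits,
                 plan = list(methods = methods, gene_counts = gene_counts,
                             n_reps = n_reps,
                             train_fraction = train_fraction, seed = seed,
                             stratify = stratify, gene_order = gene_order,
                             var_threshold = var_threshold, ties = ties,
                             n_samples = n,
                             clinical = !is.null(clinical)),
                 log = list(n_redraw = n_redraw, failed = failed)),
            class = "swc_experiment")
}

# Event-stratified train/test partition; train size is floor(frac * n)
# exactly (2/3 of 100 samples -> 66), with the event stratum getting
# round(frac * n_events) slots.
draw_split <- function(n, frac, event, stratify) {
  n_train <- floor(frac * n)
  if (!stratify) return(sort(sample(n, n_train)))
  ev_idx <- which(event == 1); cen_idx <- which(event == 0)
  n1 <- min(length(ev_idx), max(0, round(frac * length(ev_idx))))
  n0 <- n_train - n1
  if (n0 > length(cen_idx)) { n1 <- n1 + (n0 - length(cen_idx)); n0 <- length(cen_idx) }
  sort(c(sample(ev_idx, n1), sample(cen_idx, n0)))
}

# Score one fitted cell on both bases; returns list(apparent=, heldout=).
score_cell <- function(mod, x_test, y_test, e_test, grid_te, clin_test) {
  f <- mod$fit
  app <- list(
    c_index = c_index(mod$pi_train, mod$time, mod$event),
    cpe = cpe_from_lp(mod$pi_train),
    r2 = nagelkerke_r2(f$loglik, f$loglik_null, f$n),
    lr = likelihood_ratio(f$loglik, f$loglik_null),
    ibs = integrated_brier(survival_curve(mod$baseline, mod$pi_train),
                           times = mod$baseline$times, mod$time, mod$event))
  # in-sample, the PI refit coincides with the stage-2 model itself
  app$ibs_refit <- app$ibs
  pi_te <- predict(mod, x_test, newclinical = clin_test)
  held <- list(c_index = NA_real_, cpe = NA_real_, r2 = NA_real_,
               lr = NA_real_, ibs = NA_real_, ibs_refit = NA_real_)
  held$c_index <- tryCatch(c_index(pi_te, y_test, e_test),
                           error = function(e) NA_real_)
  refit <- tryCatch(fit_cox(matrix(pi_te, ncol = 1), y_test, e_test,
                            ties = f$ties),
                    error = function(e) NULL)
  if (!is.null(refit) && refit$converged) {
    held$r2 <- nagelkerke_r2(refit$loglik, refit$loglik_null, refit$n)
    held$lr <- likelihood_ratio(refit$loglik, refit$loglik_null)
    held$cpe <- cpe_from_lp(refit$coefficients[1] * pi_te)
  }
  if (length(grid_te)) {
    held$ibs <- tryCatch(
      integrated_brier(survival_curve(mod$baseline, pi_te, grid_te),
                       times = grid_te, y_test, e_test),
      error = function(e) NA_real_)
    # alternative: curves rebuilt from the test-split PI refit
    if (!is.null(refit) && refit$converged) {
      lp_te <- refit$coefficients[1] * pi_te
      bl_te <- tryCatch(breslow_baseline(y_test, e_test, lp_te),
                        error = function(e) NULL)
      if (!is.null(bl_te))
        held$ibs_refit <- tryCatch(
          integrated_brier(survival_curve(bl_te, lp_te, grid_te),
                           times = grid_te, y_test, e_test),
          error = function(e) NA_real_)
    }
  }
  list(apparent = app, heldout = held)
}

#' Aggregate an experiment into a mean +/- se table
#'
#' @param object a [run_experiment()] result.
#' @param basis `"apparent"` or `"heldout"`.
#' @param ... unused.
#' @return data frame with one row per (method, gene count) cell and, for
#'   each criterion, the across-split mean and standard error of the mean
#'   (`sd / sqrt(n_splits)` over non-missing repetitions).
#' @export
summary.swc_experiment <- function(object, basis = c("apparent", "heldout"),
                                   ...) {
  basis <- match.arg(basis)
  v <- object$values[[basis]]
  out <- object$cells
  for (mt in names(v)) {
    m <- v[[mt]]
    out[[paste0(mt, "_mean")]] <- colMeans(m, na.rm = TRUE)
    nn <- colSums(!is.na(m))
    out[[paste0(mt, "_se")]] <- apply(m, 2, sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  }
  out$n_splits <- colSums(!is.na(v[[1]]))
  rownames(out) <- NULL
  out
}

#' @export
print.swc_experiment <- function(x, digits = 3, ...) {
  p <- x$plan
  cat(sprintf("Repeated-split experiment: %d reps, train %d/%d samples, seed %d\n",
              p$n_reps, floor(p$train_fraction * p$n_samples), p$n_samples,
              p$seed))
  for (b in c("apparent", "heldout")) {
    cat(sprintf("\n%s criteria (mean over splits):\n", b))
    s <- summary(x, basis = b)
    show <- s[, c("method", "n_genes", paste0(c("c_index", "cpe", "r2", "lr",
                                                "ibs"), "_mean"))]
    names(show) <- sub("_mean", "", names(show))
    print(format(show, digits = digits), row.names = FALSE)
  }
  if (length(x$log$failed))
    cat(sprintf("\n%d cell fits failed (see $log$failed)\n",
                length(x$log$failed)))
  invisible(x)
}

#' Paired per-split differences between two methods
#'
#' Because every repetition uses one shared train/test partition for all
#' methods, per-repetition metric differences are paired. This reports, for
#' each gene count and criterion, the per-repetition differences
#' `method_a - method_b` and their median and quartiles.
#'
#' @param experiment a [run_experiment()] result containing both methods.
#' @param method_a,method_b method names to contrast.
#' @param basis `"apparent"` or `"heldout"`.
#' @return An object of class `swc_diff`: list with `diffs` (per-rep
#'   difference matrices per metric, columns = gene counts) and `summary`
#'   (data frame of median and quartiles).
#' @export
difference_report <- function(experiment, method_a = "wavelet",
                              method_b = "pca",
                              basis = c("apparent", "heldout")) {
  basis <- match.arg(basis)
  pm <- experiment$plan$methods
  if (!all(c(method_a, method_b) %in% pm))
    stop(sprintf("experiment does not contain both methods (%s)",
                 paste(pm, collapse = ", ")), call. = FALSE)
  v <- experiment$values[[basis]]
  counts <- experiment$plan$gene_counts
  diffs <- lapply(v, function(m) {
    d <- m[, paste(method_a, counts, sep = "_"), drop = FALSE] -
         m[, paste(method_b, counts, sep = "_"), drop = FALSE]
    colnames(d) <- as.character(counts)
    d
  })
  summ <- do.call(rbind, lapply(names(diffs), function(mt) {
    q <- apply(diffs[[mt]], 2, quantile, probs = c(0.25, 0.5, 0.75),
               na.rm = TRUE)
    data.frame(metric = mt, n_genes = counts, q1 = q[1, ], median = q[2, ],
               q3 = q[3, ], row.names = NULL)
  }))
  structure(list(method_a = method_a, method_b = method_b, basis = basis,
                 diffs = diffs, summary = summ),
            class = "swc_diff")
}

#' @export
print.swc_diff <- function(x, digits = 3, ...) {
  cat(sprintf("Per-split differences (%s - %s, %s basis):\n", x$method_a,
              x$method_b, x$basis))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
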