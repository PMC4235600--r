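#' Fit a supervised dimension reducer
#'
#' All three reducers share one train/apply contract: genes are ranked on the
#' training data by the absolute univariate Cox Wald statistic
#' ([wald_screen()]), the top `n_genes` are retained, and a method-specific
#' transform maps the selected genes of any conforming expression matrix to a
#' low-dimensional feature matrix. Applying a fitted reducer uses only
#' train-derived state (selected gene ids, gene order, centering vectors,
#' loadings), so no test information leaks into the features.
#'
#' Methods:
#' \describe{
#'   \item{`"wavelet"`}{level-1 discrete Haar approximation coefficients of
#'     the selected genes, giving `ceiling(n_genes / 2)` features per sample.
#'     Because the Haar approximation averages adjacent genes, the within-set
#'     gene order matters; see `gene_order`.}
#'   \item{`"pca"`}{principal components of the train submatrix (per-gene
#'     centering with train means); keeps the smallest number of components
#'     whose cumulative explained variance reaches `var_threshold`.}
#'   \item{`"pls"`}{sequential PLS-Cox components: the first weight vector is
#'     the normalized vector of per-gene univariate Cox coefficients on the
#'     (train-centered) submatrix; each subsequent component is built the
#'     same way on the residual matrix after deflating by the previous score.
#'     The component count defaults to the PCA rule applied to the same
#'     train submatrix, matching the convention of the evaluation harness.}
#' }
#'
#' @param x genes-by-samples training expression matrix.
#' @param time,event training survival outcome (one entry per column of `x`).
#' @param method `"wavelet"`, `"pca"` or `"pls"`.
#' @param n_genes number of genes to retain from the Wald screen (>= 2).
#' @param gene_order within-set ordering of the selected genes before the
#'   wavelet transform: `"wald"` (default) sorts by the signed Wald statistic
#'   `beta/se` in decreasing order, so genes whose expression raises the
#'   hazard sit together and genes that lower it sit together and the Haar
#'   pairwise averages do not cancel opposing effects; `"abs_wald"` sorts by
#'   decreasing `|beta/se|`; `"original"` keeps the input row order. Ignored
#'   by `"pca"`/`"pls"`, which are order-invariant.
#' @param var_threshold cumulative-variance rule for the PCA component count
#'   (also sets the default PLS component count).
#' @param n_components optional explicit PLS component count (the evaluation
#'   harness passes the PCA count from the same split).
#' @param screen optional precomputed [wald_screen()] data frame for `x`
#'   (avoids rescreening when several reducers share one training split).
#' @param ties tie handling for internal Cox fits.
#' @return An object of class `swc_reducer` with the selected gene ids (in
#'   transform order), their screen statistics, and method state. Use
#'   [predict.swc_reducer()] to extract features.
#' @examples
#' sim <- simulate_bt(bt_sim_spec(n_genes = 300, n_samples = 60), seed = 1)
#' red <- fit_reducer(sim$expression, sim$survival$time, sim$survival$event,
#'                    method = "wavelet", n_genes = 10)
#' dim(predict(red, sim$expression))   # 60 samples x 5 features
#' @export
fit_reducer <- function(x, time, event,
                        method = c("wavelet", "pca", "pls"),
                        n_genes = 40,
                        gene_order = c("wald", "abs_wald", "original"),
                        var_threshold = 0.75, n_components = NULL,
                        screen = NULL, ties = c("breslow", "efron")) {
  method <- match.arg(method)
  gene_order <- match.arg(gene_order)
  ties <- match.arg(ties)
  if (n_genes < 2) stop("n_genes must be >= 2", call. = FALSE)
  if (n_genes > nrow(x))
    stop(sprintf("n_genes = %d exceeds the %d genes available", n_genes,
                 nrow(x)), call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(screen)) screen <- wald_screen(x, time, event, ties = ties)
  sel <- order(screen$statistic, decreasing = TRUE)[seq_len(n_genes)]
  z_signed <- screen$beta[sel] / screen$se[sel]
  ord <- switch(gene_order,
                wald = order(z_signed, decreasing = TRUE),
                abs_wald = seq_len(n_genes),         # already |stat|-sorted
                original = order(sel))
  sel <- sel[ord]
  genes <- screen$gene[sel]
  red <- structure(list(method = method, n_genes = n_genes, genes = genes,
                        statistic = screen$statistic[sel],
                        z = (screen$beta / screen$se)[sel],
                        gene_order = gene_order),
                   class = "swc_reducer")
  xt <- t(x[genes, , drop = FALSE])        # samples x selected genes
  if (method == "wavelet") {
    red$n_features <- ceiling(n_genes / 2)
    red$n_pad <- n_genes %% 2L
  } else if (method == "pca") {
    if (all(apply(xt, 2, sd) == 0))
      stop("degenerate (zero-variance) gene submatrix; PCA undefined",
           call. = FALSE)
    pc <- prcomp(xt, center = TRUE, scale. = FALSE)
    share <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(share >= var_threshold)[1]
    red$center <- pc$center
    red$rotation <- pc$rotation[, seq_len(k), drop = FALSE]
    red$n_components <- k
    red$var_share <- share[k]
    red$n_features <- k
  } else {
    k <- n_components
    if (is.null(k)) {
      pc <- prcomp(xt, center = TRUE, scale. = FALSE)
      k <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= var_threshold)[1]
    }
    if (k < 1) stop("n_components must be >= 1", call. = FALSE)
    pls <- fit_pls_cox(xt, time, event, k, ties)
    red$center <- pls$center
    red$weights <- pls$weights
    red$loadings <- pls$loadings
    red$n_components <- ncol(pls$weights)
    red$n_features <- ncol(pls$weights)
  }
  red
}

# Sequential PLS-Cox: weight vectors are normalized per-gene univariate Cox
# coefficients; the matrix is deflated by each score before the next
# component. Returns train-derived state only.
fit_pls_cox <- function(xt, time, event, k, ties) {
  ctr <- colMeans(xt)
  r <- sweep(xt, 2, ctr)
  y <- survival::Surv(time, event)
  ctl <- survival::coxph.control(iter.max = 10)
  w_mat <- p_mat <- NULL
  for (j in seq_len(k)) {
    w <- vapply(seq_len(ncol(r)), function(g) {
      v <- r[, g]
      if (sd(v) == 0) return(0)
      f <- tryCatch(suppressWarnings(
        survival::coxph.fit(matrix(v, ncol = 1), y, strata = NULL,
                            offset = NULL, init = 0, control = ctl,
                            weights = NULL, method = ties, rownames = NULL)),
        error = function(e) NULL)
      if (is.null(f) || anyNA(f$coefficients)) 0 else f$coefficients[1]
    }, numeric(1))
    if (all(w == 0)) {
      warning(sprintf("PLS-Cox stopped at %d component(s): residual matrix %s",
                      j - 1L, "carries no Cox signal (rank exhausted)"),
              call. = FALSE)
      break
    }
    w <- w / sqrt(sum(w^2))
    score <- drop(r %*% w)
    p <- drop(crossprod(r, score)) / sum(score^2)
    w_mat <- cbind(w_mat, w)
    p_mat <- cbind(p_mat, p)
    r <- r - outer(score, p)
  }
  if (is.null(w_mat))
    stop("PLS-Cox failed: no component could be extracted", call. = FALSE)
  list(center = ctr, weights = w_mat, loadings = p_mat)
}

#' Apply a fitted reducer to an expression matrix
#'
#' Extracts the reducer's selected genes (matched by gene id, so permuting
#' the rows of `newdata` does not change the output) and applies the
#' train-derived transform. The survival outcome is never consulted.
#'
#' @param object a [fit_reducer()] result.
#' @param newdata genes-by-samples expression matrix containing the selected
#'   gene ids.
#' @param ... unused.
#' @return samples-by-features numeric matrix.
#' @export
predict.swc_reducer <- function(object, newdata, ...) {
  if (is.null(rownames(newdata)))
    rownames(newdata) <- paste0("g", seq_len(nrow(newdata)))
  missing_genes <- setdiff(object$genes, rownames(newdata))
  if (length(missing_genes))
    stop(sprintf("newdata lacks %d selected gene(s), e.g. %s",
                 length(missing_genes), missing_genes[1]), call. = FALSE)
  xt <- t(newdata[object$genes, , drop = FALSE])
  out <- switch(object$method,
    wavelet = haar_approx1(xt),
    pca = sweep(xt, 2, object$center) %*% object$rotation,
    pls = {
      r <- sweep(xt, 2, object$center)
      k <- ncol(object$weights)
      sc <- matrix(0, nrow(r), k,
                   dimnames = list(rownames(r), paste0("pls", seq_len(k))))
      for (j in seq_len(k)) {
        sc[, j] <- r %*% object$weights[, j]
        r <- r - outer(sc[, j], object$loadings[, j])
      }
      sc
    })
  rownames(out) <- colnames(newdata)
  out
}

#' @export
print.swc_reducer <- function(x, ...) {
  cat(sprintf("Supervised %s reducer: %d genes -> %d feature(s)\n",
              x$method, x$n_genes, x$n_features))
  if (x$method == "pca")
    cat(sprintf("  %d components, cumulative variance %.3f\n",
                x$n_components, x$var_share))
  if (x$method == "pls")
    cat(sprintf("  %d PLS-Cox component(s)\n", x$n_components))
  cat("  top genes:", paste(head(x$genes, 8), collapse = ", "),
      if (x$n_genes > 8) "..." else "", "\n")
  invisible(x)
}
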