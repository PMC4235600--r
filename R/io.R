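#' Read a genes-by-samples expression matrix from TSV
#'
#' Expected layout: a header row of sample ids, a first column of gene ids,
#' and numeric expression values (genes in rows). Files with samples in
#' rows can be loaded with `transpose = TRUE`. Duplicate ids, non-numeric
#' cells and missing values are rejected with an error naming the offender.
#'
#' @param path TSV file path.
#' @param transpose set to `TRUE` when the file stores samples in rows.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs an id column plus data",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated id '%s' in %s", ids[duplicated(ids)][1], path),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stop(sprintf("non-numeric expression column '%s' in %s",
                 names(df[-1])[bad], path), call. = FALSE)
  }
  if (anyDuplicated(colnames(m)))
    stop(sprintf("duplicated id '%s' in %s",
                 colnames(m)[duplicated(colnames(m))][1], path), call. = FALSE)
  if (any(!is.finite(m)))
    stop(sprintf("missing or non-finite expression values in %s (first at row %d)",
                 path, which(!is.finite(m), arr.ind = TRUE)[1, 1]),
         call. = FALSE)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  m
}

#' Read a survival table from TSV
#'
#' Expected columns: `sample`, `time`, `event`, plus any number of numeric
#' clinical covariate columns. Times must be strictly positive and events
#' in \{0, 1\}.
#'
#' @param path TSV file path.
#' @return data frame with validated `sample`, `time`, `event` and any
#'   additional covariate columns.
#' @export
read_survival <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop(sprintf("survival file %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$sample))
    stop(sprintf("duplicated sample id '%s' in %s",
                 df$sample[duplicated(df$sample)][1], path), call. = FALSE)
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_t))
    stop(sprintf("non-positive or missing time at row %d of %s", bad_t[1],
                 path), call. = FALSE)
  bad_e <- which(!(df$event %in% c(0, 1)))
  if (length(bad_e))
    stop(sprintf("event outside {0,1} at row %d of %s", bad_e[1], path),
         call. = FALSE)
  df$event <- as.integer(df$event)
  df
}

#' Align an expression matrix with a survival table by sample id
#'
#' Harmonizes sample order by the id intersection. By default the two
#' inputs must describe exactly the same samples; with
#' `allow_subset = TRUE` the intersection is used (counts are reported via
#' a message, never silently).
#'
#' @param x genes-by-samples matrix (colnames are sample ids).
#' @param surv a [read_survival()]-style data frame.
#' @param allow_subset permit partial overlap.
#' @return list with the aligned `expression` matrix and `survival` data
#'   frame (identical sample order).
#' @export
align_samples <- function(x, surv, allow_subset = FALSE) {
  common <- intersect(colnames(x), surv$sample)
  if (length(common) == 0) stop("no sample ids in common", call. = FALSE)
  if (!allow_subset &&
      (length(common) < ncol(x) || length(common) < nrow(surv)))
    stop(sprintf("sample ids do not fully overlap (%d common, %d expression, %d survival); use allow_subset",
                 length(common), ncol(x), nrow(surv)), call. = FALSE)
  message(sprintf("aligned %d samples (%d expression, %d survival records)",
                  length(common), ncol(x), nrow(surv)))
  list(expression = x[, common, drop = FALSE],
       survival = surv[match(common, surv$sample), , drop = FALSE])
}

#' @rdname read_expression
#' @param x genes-by-samples matrix to write.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_survival
#' @param surv survival data frame to write.
#' @export
write_survival <- function(surv, path) {
  write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write experiment results as TSV
#'
#' One row per (basis, method, gene count) cell with the across-split mean
#' and standard error of each criterion, mirroring the layout of the
#' benchmark tables.
#'
#' @param experiment a [run_experiment()] result.
#' @param path output TSV path.
#' @param per_rep_path optional second path receiving the per-repetition
#'   values in long format (basis, rep, method, n_genes, metric, value),
#'   which [difference_report()]-style summaries can be rebuilt from.
#' @return invisibly, `path`.
#' @export
write_results <- function(experiment, path, per_rep_path = NULL) {
  tabs <- lapply(c("apparent", "heldout"), function(b) {
    s <- summary(experiment, basis = b)
    cbind(basis = b, s)
  })
  write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(per_rep_path)) {
    long <- do.call(rbind, lapply(c("apparent", "heldout"), function(b) {
      do.call(rbind, lapply(names(experiment$values[[b]]), function(mt) {
        m <- experiment$values[[b]][[mt]]
        data.frame(basis = b, rep = rep(seq_len(nrow(m)), ncol(m)),
                   cell = rep(colnames(m), each = nrow(m)),
                   metric = mt, value = as.vector(m))
      }))
    }))
    write.table(long, per_rep_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
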