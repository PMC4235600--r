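#' One level of the orthonormal Haar filter bank
#'
#' Splits a signal into approximation (pairwise scaled sums) and detail
#' (pairwise scaled differences) coefficients:
#' `a_k = (x[2k-1] + x[2k]) / sqrt(2)`, `d_k = (x[2k-1] - x[2k]) / sqrt(2)`.
#' The orthonormal scaling preserves energy, so for even-length input
#' `sum(a^2) + sum(d^2) == sum(x^2)` up to rounding. Odd-length signals are
#' padded by replicating the final element once before filtering; the pad is
#' recorded in the result.
#'
#' @param x numeric vector, length >= 2.
#' @return list with `approx`, `detail` (each of length `ceiling(length(x)/2)`)
#'   and `n_pad` (0 or 1).
#' @examples
#' haar_step(c(3, 3))   # detail vanishes for a constant pair
#' haar_step(1:4)
#' @seealso [haar_decompose()], [inverse_haar_step()]
#' @export
haar_step <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("haar_step() needs a numeric signal of length >= 2", call. = FALSE)
  n_pad <- length(x) %% 2L
  if (n_pad) x <- c(x, x[length(x)])
  odd <- x[seq(1, length(x), by = 2)]
  even <- x[seq(2, length(x), by = 2)]
  list(approx = (odd + even) / sqrt(2),
       detail = (odd - even) / sqrt(2),
       n_pad = n_pad)
}

#' Invert one Haar filter-bank step
#'
#' Exact inverse of [haar_step()] for unpadded (even-length) input:
#' `x[2k-1] = (a_k + d_k)/sqrt(2)`, `x[2k] = (a_k - d_k)/sqrt(2)`. When the
#' forward step padded the signal, the reconstructed pad position is dropped.
#'
#' @param approx,detail coefficient vectors of equal length.
#' @param n_pad number of padded positions to drop from the tail (0 or 1).
#' @return the reconstructed signal.
#' @export
inverse_haar_step <- function(approx, detail, n_pad = 0) {
  if (length(approx) != length(detail))
    stop("approximation and detail vectors must have equal length", call. = FALSE)
  x <- numeric(2 * length(approx))
  x[seq(1, length(x), by = 2)] <- (approx + detail) / sqrt(2)
  x[seq(2, length(x), by = 2)] <- (approx - detail) / sqrt(2)
  if (n_pad > 0) x <- x[seq_len(length(x) - n_pad)]
  x
}

#' Pyramid discrete Haar wavelet decomposition
#'
#' Repeatedly applies [haar_step()] to the approximation branch: level 1
#' splits the signal into approximation `c1` and detail `d1`; level 2 splits
#' `c1` into `c2` and `d2`; and so on. Coefficient counts halve per level
#' (up to padding). Only level 1 is used by the supervised-wavelet reducer;
#' deeper levels are exposed for completeness.
#'
#' @param x numeric signal.
#' @param levels decomposition depth, >= 1; `2^levels` must not exceed the
#'   padded signal length.
#' @return An object of class `haar_dwt`: list with `approx` (final-level
#'   approximation), `detail` (list of detail vectors, level 1 first),
#'   `levels`, `n_pad` (per-level pad record), `filter` (the low/high-pass
#'   taps) and `n` (input length).
#' @examples
#' w <- haar_decompose(rep(2, 8), levels = 3)
#' w$approx                     # 2 * 2^(3/2); all details are zero
#' @export
haar_decompose <- function(x, levels = 1) {
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  if (2^levels > length(x) + length(x) %% 2L)
    stop(sprintf("levels = %d too deep for signal of length %d",
                 levels, length(x)), call. = FALSE)
  detail <- vector("list", levels)
  n_pad <- integer(levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- haar_step(a)
    a <- s$approx
    detail[[l]] <- s$detail
    n_pad[l] <- s$n_pad
  }
  structure(list(approx = a, detail = detail, levels = levels, n_pad = n_pad,
                 filter = list(h = c(1, 1) / sqrt(2), h1 = c(1, -1) / sqrt(2)),
                 n = length(x)),
            class = "haar_dwt")
}

#' Reconstruct a signal from its Haar pyramid decomposition
#'
#' Exact (to rounding) for inputs whose length was divisible by `2^levels`;
#' padded positions are dropped on the way back, so reconstruction after
#' padding is approximate at the right edge.
#'
#' @param w a `haar_dwt` object.
#' @return numeric vector of length `w$n`.
#' @export
haar_reconstruct <- function(w) {
  a <- w$approx
  for (l in rev(seq_len(w$levels)))
    a <- inverse_haar_step(a, w$detail[[l]], w$n_pad[l])
  a
}

#' @export
print.haar_dwt <- function(x, ...) {
  cat(sprintf("Haar DWT: %d-point signal, %d level(s); approximation length %d\n",
              x$n, x$levels, length(x$approx)))
  invisible(x)
}

# Level-1 Haar approximation coefficients for each row of a samples x genes
# matrix; replicates the last column when the gene count is odd.
haar_approx1 <- function(m) {
  p <- ncol(m)
  if (p < 2) stop("need at least 2 genes for the Haar transform", call. = FALSE)
  if (p %% 2L) m <- cbind(m, m[, p, drop = FALSE])
  out <- (m[, seq(1, ncol(m), by = 2), drop = FALSE] +
          m[, seq(2, ncol(m), by = 2), drop = FALSE]) / sqrt(2)
  colnames(out) <- paste0("haar_a", seq_len(ncol(out)))
  out
}
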