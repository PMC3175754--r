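#' Normalized reconstruction error (EOF)
#'
#' Percentage normalized Euclidean error
#' \eqn{100\,\|\hat x - x\|_2 / \|x\|_2}, computed by default over the
#' stacked coordinate vector (all axes concatenated). Both surfaces should
#' be centered at the origin so the denominator is scale-meaningful.
#'
#' @param reconstructed,reference numeric vectors or N x 3 matrices of
#'   equal size.
#' @param per_axis if `TRUE` and the inputs are N x 3, return one EOF per
#'   coordinate axis instead of the stacked value.
#' @return EOF in percent (scalar, or length-3 vector when `per_axis`).
#' @examples
#' eof(1.01 * diag(3), diag(3))   # 1.0
#' @export
eof <- function(reconstructed, reference, per_axis = FALSE) {
  xh <- as.matrix(reconstructed)
  x <- as.matrix(reference)
  if (!all(dim(xh) == dim(x))) stop("dimension mismatch")
  if (per_axis && ncol(x) > 1L) {
    nrms <- sqrt(colSums(x^2))
    if (any(nrms == 0)) stop("zero reference norm")
    return(100 * sqrt(colSums((xh - x)^2)) / nrms)
  }
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("zero reference norm")
  100 * sqrt(sum((xh - x)^2)) / nrm
}

#' Directed Hausdorff distance between point sets
#'
#' One-sided max-min Euclidean distance
#' \eqn{d(x, x') = \max_{p \in x} \min_{p' \in x'} \|p - p'\|_2},
#' the point-to-vertex-set form. Row-chunked so large vertex sets do not
#' materialize the full cross-distance matrix.
#'
#' @param x,x_ref point sets as n x 3 (or n x d) matrices.
#' @return Directed Hausdorff distance (same units as the coordinates,
#'   typically mm).
#' @seealso [hausdorff_distance()] for the symmetric version.
#' @export
directed_hausdorff <- function(x, x_ref) {
  x <- as.matrix(x)
  x_ref <- as.matrix(x_ref)
  if (nrow(x) == 0L || nrow(x_ref) == 0L) stop("empty point set")
  if (ncol(x) != ncol(x_ref)) stop("dimension mismatch")
  q2 <- rowSums(x_ref^2)
  worst <- 0
  chunk <- 512L
  for (s in seq(1L, nrow(x), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(x))
    xs <- x[s:e, , drop = FALSE]
    # squared distances via the expansion |p|^2 - 2 p.q + |q|^2
    d2 <- outer(rowSums(xs^2), q2, "+") - 2 * tcrossprod(xs, x_ref)
    worst <- max(worst, max(apply(d2, 1L, min)))
  }
  sqrt(max(worst, 0))
}

#' Symmetric Hausdorff distance
#'
#' @inheritParams directed_hausdorff
#' @return `max(d(x, x_ref), d(x_ref, x))`.
#' @export
hausdorff_distance <- function(x, x_ref) {
  max(directed_hausdorff(x, x_ref), directed_hausdorff(x_ref, x))
}

#' Per-vertex error field and percentile summaries
#'
#' Euclidean distance per corresponded vertex between a reconstruction and
#' its reference, with requested percentiles (linear interpolation between
#' order statistics, `stats::quantile` type 7).
#'
#' @param reconstructed,reference N x 3 matrices in corresponded vertex
#'   order.
#' @param percentiles numeric vector of probabilities in `[0, 1]`.
#' @return List with `errors` (length-N vector) and `percentiles` (named
#'   numeric vector).
#' @export
pointwise_error_field <- function(reconstructed, reference,
                                  percentiles = c(0.9, 0.95)) {
  xh <- as.matrix(reconstructed)
  x <- as.matrix(reference)
  if (!all(dim(xh) == dim(x))) stop("length mismatch")
  err <- sqrt(rowSums((xh - x)^2))
  list(errors = err,
       percentiles = stats::quantile(err, probs = percentiles, names = TRUE))
}

#' Sparsity statistics of a set of block-sparse codes
#'
#' Mean and sample (n-1) standard deviation of the l0 norms of the padded
#' code vectors.
#'
#' @param codes list of `"block_sparse_code"` objects (or a numeric vector
#'   of l0 counts).
#' @return Named numeric vector `c(mu = ..., sigma = ...)`; `sigma` is 0
#'   for a single code.
#' @export
sparsity_stats <- function(codes) {
  if (length(codes) == 0L) stop("empty code set")
  l0 <- if (is.numeric(codes)) codes
        else vapply(codes, function(cd) sum(cd$padded != 0), numeric(1L))
  c(mu = mean(l0),
    sigma = if (length(l0) > 1L) stats::sd(l0) else 0)
}

#' Evaluation report for a set of coded surfaces
#'
#' Collects per-surface EOF, directed Hausdorff distance and sparsity into
#' a data frame mirroring the usual reporting layout (per-surface rows plus
#' min / 95th percentile / mean summary attributes).
#'
#' @param reconstructions list of N x 3 reconstructed coordinate matrices.
#' @param references list of matching reference matrices.
#' @param codes optional list of per-surface code lists (for sparsity).
#' @return A data frame with columns `surface`, `eof_percent`,
#'   `hausdorff_mm`, `l0`; summary rows are attached as the `"summary"`
#'   attribute.
#' @export
evaluation_report <- function(reconstructions, references, codes = NULL) {
  stopifnot(length(reconstructions) == length(references))
  n <- length(reconstructions)
  eofs <- vapply(seq_len(n), function(k)
    eof(reconstructions[[k]], references[[k]]), numeric(1L))
  hd <- vapply(seq_len(n), function(k)
    directed_hausdorff(reconstructions[[k]], references[[k]]), numeric(1L))
  l0 <- if (!is.null(codes))
    vapply(codes, function(cs)
      sum(vapply(cs, function(cd) sum(cd$padded != 0), numeric(1L))),
      numeric(1L))
  else rep(NA_real_, n)
  out <- data.frame(surface = seq_len(n), eof_percent = eofs,
                    hausdorff_mm = hd, l0 = l0)
  summ <- data.frame(
    statistic = c("min", "p95", "mean", "sd"),
    eof_percent = c(min(eofs), stats::quantile(eofs, 0.95, names = FALSE),
                    mean(eofs), stats::sd(eofs)),
    hausdorff_mm = c(min(hd), stats::quantile(hd, 0.95, names = FALSE),
                     mean(hd), stats::sd(hd)))
  attr(out, "summary") <- summ
  out
}
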