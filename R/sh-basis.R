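#' Spherical parameterization of surface samples
#'
#' Bundles per-sample polar angles \eqn{\theta \in [0, \pi]} and azimuthal
#' angles \eqn{\phi \in [0, 2\pi)} into a validated parameterization object.
#' Every corresponded surface of a cohort shares one such parameterization,
#' typically induced by the icosphere ray directions
#' (see [sphere_directions_to_parameterization()]).
#'
#' @param theta numeric vector of polar angles in radians, in `[0, pi]`.
#' @param phi numeric vector of azimuthal angles in radians; values are
#'   wrapped into `[0, 2*pi)`.
#' @return An object of class `"sh_parameterization"` with elements `theta`,
#'   `phi` and `n_samples`.
#' @export
sh_parameterization <- function(theta, phi) {
  theta <- as.numeric(theta)
  phi <- as.numeric(phi)
  if (length(theta) != length(phi))
    stop("theta and phi must have equal length")
  if (length(theta) == 0L)
    stop("parameterization must contain at least one sample")
  if (any(!is.finite(theta)) || any(!is.finite(phi)))
    stop("angles must be finite")
  if (any(theta < -1e-12 | theta > pi + 1e-12))
    stop("theta must lie in [0, pi]")
  theta <- pmin(pmax(theta, 0), pi)
  phi <- phi %% (2 * pi)
  structure(list(theta = theta, phi = phi, n_samples = length(theta)),
            class = "sh_parameterization")
}

# Fully normalized associated Legendre functions \bar P_l^m(cos theta) with
# Condon-Shortley phase, all 0 <= m <= l <= L, by the standard three-term
# recurrence (stable at high degree, unlike the factorial-scaled form).
# Returns an n x (L+1)(L+2)/2 matrix; column index via .plm_index().
.plm_index <- function(l, m) l * (l + 1L) / 2L + m + 1L

.nalf_all <- function(L, theta) {
  ct <- cos(theta)
  st <- sin(theta)
  n <- length(theta)
  ncols <- (L + 1L) * (L + 2L) / 2L
  P <- matrix(0, n, ncols)
  P[, 1L] <- sqrt(1 / (4 * pi))
  if (L == 0L) return(P)
  # diagonal: \bar P_mm, the minus sign carries the Condon-Shortley phase
  for (m in seq_len(L)) {
    P[, .plm_index(m, m)] <-
      -sqrt((2 * m + 1) / (2 * m)) * st * P[, .plm_index(m - 1L, m - 1L)]
  }
  # first off-diagonal: \bar P_{m+1,m}
  for (m in 0:(L - 1L)) {
    P[, .plm_index(m + 1L, m)] <- sqrt(2 * m + 3) * ct * P[, .plm_index(m, m)]
  }
  # remaining terms
  if (L >= 2L) {
    for (l in 2:L) {
      mm <- 0:(l - 2L)
      for (m in mm) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[, .plm_index(l, m)] <-
          a * (ct * P[, .plm_index(l - 1L, m)] - b * P[, .plm_index(l - 2L, m)])
      }
    }
  }
  P
}

#' Evaluate a real orthonormal spherical harmonic
#'
#' Real (tesseral) spherical harmonics with Condon-Shortley phase:
#' for \eqn{m > 0} the \eqn{\sqrt{2}\,\bar P_l^m(\cos\theta)\cos m\phi}
#' cosine combination, for \eqn{m < 0} the sine combination, and the zonal
#' harmonic \eqn{\bar P_l^0(\cos\theta)} for \eqn{m = 0}, where
#' \eqn{\bar P_l^m} are the fully normalized associated Legendre functions.
#' The set is orthonormal under the spherical measure
#' \eqn{\sin\theta\, d\theta\, d\phi}.
#'
#' @param l degree, non-negative integer.
#' @param m order, integer with `|m| <= l`.
#' @param theta polar angle(s) in radians, in `[0, pi]`.
#' @param phi azimuthal angle(s) in radians.
#' @return Numeric vector of harmonic values, recycled over `theta`/`phi`.
#' @examples
#' real_sh_value(0, 0, 0.3, 1.1)       # 1/(2*sqrt(pi))
#' real_sh_value(1, 0, 0, 0)           # sqrt(3/(4*pi))
#' @export
real_sh_value <- function(l, m, theta, phi) {
  l <- as.integer(l)
  m <- as.integer(m)
  if (length(l) != 1L || length(m) != 1L || is.na(l) || is.na(m) || l < 0L)
    stop("l must be a single non-negative integer and m a single integer")
  if (abs(m) > l)
    stop("invalid order: |m| must not exceed the degree l")
  n <- max(length(theta), length(phi))
  theta <- rep_len(as.numeric(theta), n)
  phi <- rep_len(as.numeric(phi), n)
  P <- .nalf_all(l, theta)
  pl <- P[, .plm_index(l, abs(m))]
  if (m == 0L) pl
  else if (m > 0L) sqrt(2) * pl * cos(m * phi)
  else sqrt(2) * pl * sin(-m * phi)
}

#' Build the discretized spherical-harmonic basis matrix
#'
#' Evaluates all real harmonics up to degree `L` at the parameterization
#' samples, giving the \eqn{N \times (L+1)^2} design matrix with columns in
#' the fixed order (0,0), (1,-1), (1,0), (1,1), ..., (L,L).
#'
#' @param param an [sh_parameterization()].
#' @param L maximum spherical-harmonic degree, non-negative integer.
#' @return Object of class `"harmonic_basis"`: list with `matrix`
#'   (N x (L+1)^2), `degree`, and `column_order` (two-column matrix of
#'   (l, m) pairs).
#' @export
build_basis <- function(param, L) {
  stopifnot(inherits(param, "sh_parameterization"))
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 0L)
    stop("invalid degree: L must be a single non-negative integer")
  P <- .nalf_all(L, param$theta)
  n <- param$n_samples
  ncols <- (L + 1L)^2
  Y <- matrix(0, n, ncols)
  lm <- matrix(0L, ncols, 2L, dimnames = list(NULL, c("l", "m")))
  j <- 0L
  for (l in 0:L) {
    for (m in (-l):l) {
      j <- j + 1L
      lm[j, ] <- c(l, m)
      pl <- P[, .plm_index(l, abs(m))]
      Y[, j] <-
        if (m == 0L) pl
        else if (m > 0L) sqrt(2) * pl * cos(m * param$phi)
        else sqrt(2) * pl * sin(-m * param$phi)
    }
  }
  structure(list(matrix = Y, degree = L, column_order = lm, param = param,
                 cache = new.env(parent = emptyenv())),
            class = "harmonic_basis")
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat("Discretized real spherical-harmonic basis\n")
  cat(sprintf("  degree L = %d, %d columns, %d samples\n",
              x$degree, ncol(x$matrix), nrow(x$matrix)))
  invisible(x)
}

#' Least-squares spherical-harmonic decomposition of one coordinate axis
#'
#' Fits harmonic coefficients to surface samples by QR-based least squares,
#' \eqn{\hat f = \arg\min_f \|Y f - x\|_2}. Requires at least as many
#' samples as basis columns and a full-rank design.
#'
#' @param samples numeric vector of length N (one coordinate function).
#' @param basis a `"harmonic_basis"` built on the same parameterization.
#' @return Object of class `"sh_coefficients"`: list with `values`
#'   (length (L+1)^2) and `degree`.
#' @export
shd_fit <- function(samples, basis) {
  stopifnot(inherits(basis, "harmonic_basis"))
  samples <- as.numeric(samples)
  Y <- basis$matrix
  if (length(samples) != nrow(Y))
    stop("samples length does not match the basis parameterization")
  if (nrow(Y) < ncol(Y))
    stop(sprintf(
      "underdetermined fit: %d samples for %d basis columns; need N >= (L+1)^2",
      nrow(Y), ncol(Y)))
  qrY <- .basis_qr(basis)
  f <- qr.coef(qrY, samples)
  sh_coefficients(f, basis$degree)
}

# QR of the basis matrix, memoized in the basis cache environment (one basis
# serves all three axes and every surface of a cohort).
.basis_qr <- function(basis) {
  if (!is.null(basis$cache$qr)) return(basis$cache$qr)
  qrY <- qr(basis$matrix)
  if (qrY$rank < ncol(basis$matrix))
    stop(sprintf(
      "conditioning error: basis matrix has numerical rank %d < %d columns",
      qrY$rank, ncol(basis$matrix)))
  basis$cache$qr <- qrY
  qrY
}

#' Construct a harmonic coefficient vector
#'
#' @param values numeric vector of length `(degree+1)^2`.
#' @param degree maximum degree L.
#' @return Object of class `"sh_coefficients"`.
#' @export
sh_coefficients <- function(values, degree) {
  degree <- as.integer(degree)
  values <- as.numeric(values)
  if (length(values) != (degree + 1L)^2)
    stop("coefficient vector length must equal (L+1)^2")
  structure(list(values = values, degree = degree), class = "sh_coefficients")
}

#' Reconstruct coordinate samples from harmonic coefficients
#'
#' Evaluates \eqn{x = Y f} on the basis parameterization.
#'
#' @param coeffs an `"sh_coefficients"` object (or bare numeric vector of
#'   matching length).
#' @param basis a `"harmonic_basis"` of the same degree.
#' @return Numeric vector of length N.
#' @export
shd_reconstruct <- function(coeffs, basis) {
  stopifnot(inherits(basis, "harmonic_basis"))
  if (inherits(coeffs, "sh_coefficients")) {
    if (coeffs$degree != basis$degree)
      stop("degree mismatch between coefficients and basis")
    v <- coeffs$values
  } else {
    v <- as.numeric(coeffs)
    if (length(v) != ncol(basis$matrix))
      stop("degree mismatch between coefficients and basis")
  }
  drop(basis$matrix %*% v)
}

#' Spherical-harmonic decomposition of a full surface
#'
#' Applies [shd_fit()] to each coordinate axis of an N x 3 vertex matrix.
#' The x, y and z coordinate functions are treated independently throughout
#' the pipeline.
#'
#' @param coords N x 3 numeric matrix of vertex coordinates.
#' @param basis a `"harmonic_basis"` on the surface's parameterization.
#' @return List of three `"sh_coefficients"` objects named `x`, `y`, `z`.
#' @export
fit_surface <- function(coords, basis) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  out <- lapply(1:3, function(a) shd_fit(coords[, a], basis))
  names(out) <- c("x", "y", "z")
  out
}

#' Tabulate per-axis harmonic coefficients
#'
#' Flattens the three per-axis coefficient vectors into a long-format data
#' frame (columns `l`, `m`, `axis`, `value`), suitable for CSV export.
#'
#' @param coeff_list list of three `"sh_coefficients"` as from
#'   [fit_surface()].
#' @return A data frame with one row per (l, m, axis).
#' @export
coefficients_table <- function(coeff_list) {
  stopifnot(length(coeff_list) == 3L)
  L <- coeff_list[[1L]]$degree
  lm <- do.call(rbind, lapply(0:L, function(l) cbind(l = l, m = (-l):l)))
  do.call(rbind, lapply(seq_along(coeff_list), function(a) {
    data.frame(l = lm[, 1L], m = lm[, 2L],
               axis = c("x", "y", "z")[a],
               value = coeff_list[[a]]$values)
  }))
}
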