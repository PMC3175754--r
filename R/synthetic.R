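#' Planted union-of-subspaces deformation model
#'
#' Specifies a generator for synthetic deformation cohorts whose per-axis
#' harmonic coefficient vectors lie (up to optional Gaussian noise) in a
#' small union of low-dimensional subspaces around a base shape — the
#' structural assumption the dictionary-learning pipeline is built on,
#' realized exactly and with known ground truth.
#'
#' @param L spherical-harmonic degree of the cohort; ambient dimension is
#'   `(L+1)^2`.
#' @param dims integer vector of planted subspace dimensions `n_i` (length
#'   J).
#' @param base_coeffs optional list of three `"sh_coefficients"` (x, y, z)
#'   of the base shape; `NULL` plants the subspaces around the origin of
#'   coefficient space (deformation-only vectors).
#' @param amplitude standard deviation of the in-subspace combination
#'   weights (units of the base shape's scale).
#' @param noise_sd standard deviation of additive coefficient noise (0 for
#'   noiseless cohorts).
#' @param seed RNG seed; the planted bases are drawn deterministically
#'   from it.
#' @return Object of class `"planted_model"`: list with `L`, `dims`,
#'   `bases` (list of J orthonormal `(L+1)^2 x n_i` matrices), `base_coeffs`,
#'   `amplitude`, `noise_sd`, `seed`.
#' @export
planted_model <- function(L, dims, base_coeffs = NULL, amplitude = 0.05,
                          noise_sd = 0, seed = 1L) {
  L <- as.integer(L)
  dims <- as.integer(dims)
  if (any(dims < 1L)) stop("subspace dimensions must be positive")
  p <- (L + 1L)^2
  if (sum(dims) > p) stop("planted dimensions exceed the ambient dimension")
  set.seed(seed)
  bases <- lapply(dims, function(d) qr.Q(qr(matrix(stats::rnorm(p * d), p, d))))
  # identifiability: principal angles between planted subspaces must be
  # bounded away from zero (random subspaces in high ambient dimension are
  # nearly orthogonal; this guards tiny-ambient configurations)
  if (length(bases) > 1L) {
    for (i in seq_along(bases)[-1L]) for (j in seq_len(i - 1L)) {
      sv <- svd(crossprod(bases[[i]], bases[[j]]))$d
      if (max(sv) > cos(10 * pi / 180))
        stop("planted subspaces are not identifiable (principal angle < 10 degrees); change the seed or reduce dims")
    }
  }
  structure(list(L = L, dims = dims, bases = bases,
                 base_coeffs = base_coeffs, amplitude = amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "planted_model")
}

#' Base shape on an icosphere parameterization
#'
#' Analytic star-shaped base surfaces sampled at icosphere directions:
#' a unit sphere, an axis-aligned ellipsoid, or a "bumpy" sphere with a
#' fixed band-limited radial perturbation (degrees 2-6) giving organ-like
#' asymmetry.
#'
#' @param kind `"sphere"`, `"ellipsoid"`, or `"bumpy"`.
#' @param frequency icosphere subdivision frequency (>= 2).
#' @param axes semi-axes for the ellipsoid (length 3).
#' @param bump_amplitude radial perturbation scale for `"bumpy"`.
#' @param seed seed controlling the bumpy perturbation coefficients.
#' @return A `"corresponded_surface"` on the frequency-`frequency`
#'   icosphere.
#' @export
make_base_shape <- function(kind = c("sphere", "ellipsoid", "bumpy"),
                            frequency = 8, axes = c(1, 0.7, 0.5),
                            bump_amplitude = 0.08, seed = 1L) {
  kind <- match.arg(kind)
  frequency <- as.integer(frequency)
  if (frequency < 2L) stop("frequency must be at least 2")
  ico <- build_icosphere(frequency)
  param <- sphere_directions_to_parameterization(ico)
  dirs <- ico$vertices
  r <- switch(kind,
    sphere = rep(1, nrow(dirs)),
    ellipsoid = 1 / sqrt((dirs[, 1L] / axes[1L])^2 +
                         (dirs[, 2L] / axes[2L])^2 +
                         (dirs[, 3L] / axes[3L])^2),
    bumpy = {
      set.seed(seed)
      pert <- numeric(nrow(dirs))
      for (l in 2:6) for (m in (-l):l)
        pert <- pert + stats::rnorm(1L, sd = 1 / l^2) *
          real_sh_value(l, m, param$theta, param$phi)
      1 + bump_amplitude * pert / max(abs(pert))
    })
  structure(list(mesh = surface_mesh(dirs * r, ico$faces, validate = FALSE),
                 param = param, frequency = frequency),
            class = "corresponded_surface")
}

#' Sample a corresponded cohort from a planted model
#'
#' Draws `K` training and `M` test surfaces whose per-axis coefficient
#' vectors are `base + A_j w + noise` for a planted subspace `j` (cycled
#' deterministically for balanced memberships, then per-surface random
#' weights), and emits them as corresponded meshes through
#' [shd_reconstruct()]. Ground-truth memberships are returned for recovery
#' tests.
#'
#' @param model a [planted_model()].
#' @param K training-cohort size; must be at least `sum(dims + 1)` so each
#'   planted subspace is identifiable.
#' @param M test-cohort size (>= 1).
#' @param basis optional `"harmonic_basis"`; when supplied, surfaces are
#'   emitted as meshes on its parameterization, otherwise only coefficient
#'   matrices are returned.
#' @param sphere optional `"icosphere"` providing mesh connectivity for
#'   the emitted surfaces (defaults to none; coordinates only).
#' @param seed RNG seed for the draws (defaults to the model seed + 1).
#' @return List with per-axis coefficient matrices `F_train`, `F_test`
#'   (each `(L+1)^2 x K` / `x M`), `train_membership`, `test_membership`,
#'   and (when `basis` is given) lists `train_surfaces`, `test_surfaces`
#'   of N x 3 coordinate matrices.
#' @export
sample_planted_cohort <- function(model, K, M = 1L, basis = NULL,
                                  sphere = NULL, seed = model$seed + 1L) {
  stopifnot(inherits(model, "planted_model"))
  J <- length(model$dims)
  if (K < sum(model$dims + 1L))
    stop(sprintf(
      "K = %d too small for identifiability; need at least sum(dims + 1) = %d",
      K, sum(model$dims + 1L)))
  if (M < 1L) stop("M must be at least 1")
  p <- (model$L + 1L)^2
  base <- if (is.null(model$base_coeffs)) replicate(3, numeric(p), simplify = FALSE)
          else lapply(model$base_coeffs, function(cf) cf$values)
  set.seed(seed)
  draw_set <- function(n) {
    membership <- rep_len(seq_len(J), n)
    Fs <- lapply(1:3, function(a) {
      matrix(0, p, n)
    })
    for (k in seq_len(n)) {
      j <- membership[k]
      A <- model$bases[[j]]
      for (a in 1:3) {
        w <- stats::rnorm(model$dims[j], sd = model$amplitude)
        f <- base[[a]] + drop(A %*% w)
        if (model$noise_sd > 0)
          f <- f + stats::rnorm(p, sd = model$noise_sd)
        Fs[[a]][, k] <- f
      }
    }
    list(F = Fs, membership = membership)
  }
  tr <- draw_set(K)
  te <- draw_set(M)
  out <- list(F_train = tr$F, F_test = te$F,
              train_membership = tr$membership,
              test_membership = te$membership,
              model = model)
  if (!is.null(basis)) {
    emit <- function(Fs) lapply(seq_len(ncol(Fs[[1L]])), function(k)
      vapply(1:3, function(a) shd_reconstruct(Fs[[a]][, k], basis),
             numeric(nrow(basis$matrix))))
    out$train_surfaces <- emit(tr$F)
    out$test_surfaces <- emit(te$F)
    out$basis <- basis
    if (!is.null(sphere)) out$faces <- sphere$faces
  }
  out
}

#' Apply a localized bump ("poke" or "grasp") deformation
#'
#' Gaussian radial displacement emulating an instrument poking (inward) or
#' grasping/pulling (outward) the surface:
#' \eqn{r \mapsto r \mp a \exp(-\gamma^2 / (2 w^2))} where \eqn{\gamma} is
#' the angular distance to the bump center. Correspondence is preserved
#' (the parameterization is untouched).
#'
#' @param surface a `"corresponded_surface"`.
#' @param center_direction unit 3-vector; bump center direction.
#' @param amplitude displacement at the center, in the mesh's units.
#' @param width angular standard deviation of the bump in radians.
#' @param sign `"push"` (inward, radius decreases) or `"pull"` (outward).
#' @return The deformed `"corresponded_surface"`.
#' @export
apply_bump_deformation <- function(surface, center_direction, amplitude,
                                   width, sign = c("push", "pull")) {
  stopifnot(inherits(surface, "corresponded_surface"))
  sign <- match.arg(sign)
  if (width <= 0) stop("width must be positive")
  d <- center_direction / sqrt(sum(center_direction^2))
  v <- surface$mesh$vertices
  r <- sqrt(rowSums(v^2))
  u <- v / r
  ang <- acos(pmin(pmax(drop(u %*% d), -1), 1))
  disp <- amplitude * exp(-ang^2 / (2 * width^2))
  rnew <- if (sign == "push") r - disp else r + disp
  if (any(rnew <= 0))
    stop("push amplitude collapses the surface through the origin")
  surface$mesh$vertices <- u * rnew
  surface
}

#' Generate a dual-layer (shell) cohort with planted structure
#'
#' Interior surfaces are drawn from a planted model; each exterior surface
#' is the interior offset outward by `shell_gap` along the radial
#' direction, plus its own correlated planted deformation, so the stacked
#' interior+exterior coefficient vectors lie in a union of planted
#' subspaces of the doubled coefficient space.
#'
#' @param model a [planted_model()] for the stacked space: its bases must
#'   have `2 (L+1)^2` rows (build with `planted_model(L, dims)` on the
#'   stacked ambient by passing `stacked = TRUE` here and a model of the
#'   plain `L`), or pass `NULL` `base_coeffs` and let this function stack.
#' @param basis a `"harmonic_basis"` shared by both layers.
#' @param shell_gap outward offset of the exterior layer (> 0).
#' @param K,M training and test counts.
#' @param seed RNG seed.
#' @return List with `training` and `test` lists of dual-layer surfaces
#'   (each a list with `interior`/`exterior` `"corresponded_surface"`),
#'   the stacked coefficient matrices, and memberships.
#' @export
make_dual_layer_cohort <- function(model, basis, shell_gap, K, M = 1L,
                                   seed = model$seed + 1L) {
  stopifnot(inherits(model, "planted_model"),
            inherits(basis, "harmonic_basis"))
  if (shell_gap <= 0) stop("shell_gap must be positive")
  p2 <- 2L * (basis$degree + 1L)^2
  if (nrow(model$bases[[1L]]) != p2)
    stop("model must be planted in the stacked (doubled) coefficient space")
  p <- p2 / 2L
  param <- basis$param
  # base: interior unit sphere, exterior offset by shell_gap
  f_sphere <- fit_surface(cbind(
    sin(param$theta) * cos(param$phi),
    sin(param$theta) * sin(param$phi),
    cos(param$theta)), basis)
  base_stacked <- lapply(1:3, function(a)
    c(f_sphere[[a]]$values, (1 + shell_gap) * f_sphere[[a]]$values))
  J <- length(model$dims)
  set.seed(seed)
  draw <- function(n) {
    membership <- rep_len(seq_len(J), n)
    Fs <- lapply(1:3, function(a) matrix(0, p2, n))
    for (k in seq_len(n)) {
      A <- model$bases[[membership[k]]]
      for (a in 1:3) {
        w <- stats::rnorm(ncol(A), sd = model$amplitude)
        f <- base_stacked[[a]] + drop(A %*% w)
        if (model$noise_sd > 0) f <- f + stats::rnorm(p2, sd = model$noise_sd)
        Fs[[a]][, k] <- f
      }
    }
    list(F = Fs, membership = membership)
  }
  to_surfaces <- function(Fs) {
    lapply(seq_len(ncol(Fs[[1L]])), function(k) {
      xin <- vapply(1:3, function(a)
        shd_reconstruct(Fs[[a]][seq_len(p), k], basis),
        numeric(param$n_samples))
      xex <- vapply(1:3, function(a)
        shd_reconstruct(Fs[[a]][p + seq_len(p), k], basis),
        numeric(param$n_samples))
      rin <- sqrt(rowSums(xin^2)); rex <- sqrt(rowSums(xex^2))
      if (any(rex <= rin))
        stop("self-intersecting shell: exterior layer touches the interior (reduce amplitude or increase shell_gap)")
      mk <- function(xyz) structure(
        list(mesh = surface_mesh(xyz, matrix(integer(0), 0L, 3L),
                                 validate = FALSE),
             param = param, frequency = NA_integer_),
        class = "corresponded_surface")
      list(interior = mk(xin), exterior = mk(xex))
    })
  }
  tr <- draw(K)
  te <- draw(M)
  list(training = to_surfaces(tr$F), test = to_surfaces(te$F),
       F_train = tr$F, F_test = te$F,
       train_membership = tr$membership, test_membership = te$membership,
       base_stacked = base_stacked)
}
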