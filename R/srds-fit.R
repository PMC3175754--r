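#' Fit a sparse structured-dictionary representation of a deformation cohort
#'
#' The main model-fitting entry point. Given a training cohort of
#' corresponded surfaces (every surface sampled at the same spherical
#' parameterization, e.g. by [ray_cast_resample()]), `srds` runs the full
#' pipeline per coordinate axis:
#' \enumerate{
#'   \item spherical-harmonic decomposition of every training surface
#'     ([fit_surface()]), giving the coefficient matrix F;
#'   \item orthogonal subspace pursuit on the normalized columns of F
#'     ([learn_dictionary()]) followed by pruning ([prune_subspaces()]),
#'     giving the structured harmonic dictionary D;
#'   \item factorization F = DC into block-sparse training codes
#'     ([factorize()]) and the spatial dictionary G = YD
#'     ([build_spatial_dictionary()]).
#' }
#' Held-out surfaces are then coded with [predict.srds()].
#'
#' @param surfaces list of training surfaces: `"corresponded_surface"`
#'   objects or N x 3 coordinate matrices sharing one parameterization.
#' @param L maximum spherical-harmonic degree.
#' @param param an [sh_parameterization()]; inferred from the first
#'   corresponded surface when omitted.
#' @param epsilon,eta,e_max,delta,min_cluster_size pipeline thresholds,
#'   see [osp_config()].
#' @param config an [osp_config()] overriding the individual threshold
#'   arguments when supplied.
#' @return Object of class `"srds"`: list with `basis`, `config`, `axes`
#'   (per-axis list with `F`, `dictionary`, `codes`, `C`, `spatial`),
#'   `train_eof` (per-surface stacked EOF, percent), `n_surfaces`, `call`.
#' @examples
#' base <- make_base_shape("sphere", frequency = 4)
#' mdl <- planted_model(4, dims = c(2, 2), amplitude = 0.05, seed = 7)
#' basis <- build_basis(base$param, 4)
#' coh <- sample_planted_cohort(mdl, K = 12, M = 3, basis = basis)
#' fit <- srds(coh$train_surfaces, L = 4, param = base$param)
#' fit
#' @export
srds <- function(surfaces, L = 10, param = NULL,
                 epsilon = 0.005, eta = 0.01, e_max = 50, delta = 0.005,
                 min_cluster_size = 2, config = NULL) {
  cl <- match.call()
  if (is.null(config))
    config <- osp_config(epsilon = epsilon, eta = eta, e_max = e_max,
                         delta = delta, min_cluster_size = min_cluster_size)
  if (length(surfaces) < 2L)
    stop("at least 2 training surfaces are required")
  if (is.null(param)) {
    if (!inherits(surfaces[[1L]], "corresponded_surface"))
      stop("param must be supplied when surfaces are bare coordinate matrices")
    param <- surfaces[[1L]]$param
  }
  coords <- lapply(surfaces, surface_coords)
  N <- vapply(coords, nrow, integer(1L))
  if (length(unique(N)) != 1L)
    stop("all training surfaces must share one vertex count")
  basis <- build_basis(param, L)
  K <- length(coords)

  Fml <- lapply(1:3, function(a)
    vapply(coords, function(xyz) shd_fit(xyz[, a], basis)$values,
           numeric((L + 1L)^2)))
  axes <- lapply(1:3, function(a) {
    Fn <- normalize_columns(Fml[[a]])
    D <- prune_subspaces(learn_dictionary(Fn, config), Fn, config)
    fac <- factorize(Fn, D)
    Gd <- build_spatial_dictionary(basis, D)
    list(F = Fn, dictionary = D, codes = fac$codes, C = fac$C,
         assignments = fac$assignments, spatial = Gd)
  })
  names(axes) <- c("x", "y", "z")

  fitted_surfs <- lapply(seq_len(K), function(k)
    vapply(1:3, function(a)
      reconstruct_training_code(axes[[a]], k), numeric(N[1L])))
  train_eof <- vapply(seq_len(K), function(k)
    eof(fitted_surfs[[k]], coords[[k]]), numeric(1L))

  structure(list(basis = basis, config = config, axes = axes,
                 train_coords = coords, fitted_surfaces = fitted_surfs,
                 train_eof = train_eof, n_surfaces = K, call = cl),
            class = "srds")
}

# spatial reconstruction of training column k of one axis, on the raw scale
reconstruct_training_code <- function(ax, k) {
  cd <- ax$codes[[k]]
  drop(ax$spatial$blocks[[cd$block_id]] %*% cd$in_block) * cd$norm
}

#' @export
print.srds <- function(x, ...) {
  cat("Sparse structured-dictionary surface representation\n\n")
  cat(sprintf("Training surfaces: %d, N = %d vertices, degree L = %d\n",
              x$n_surfaces, nrow(x$basis$matrix), x$basis$degree))
  dims <- vapply(x$axes, function(a) {
    d <- vapply(a$dictionary$subspaces, function(s) s$dim, integer(1L))
    sprintf("J = %d, I = %d (dims %s)", length(d), sum(d),
            paste(d, collapse = "+"))
  }, "")
  for (a in names(x$axes)) cat(sprintf("  axis %s: %s\n", a, dims[[a]]))
  cat(sprintf("Training EOF: mean %.4g%%, max %.4g%%\n",
              mean(x$train_eof), max(x$train_eof)))
  invisible(x)
}

#' @export
summary.srds <- function(object, ...) {
  stats_ax <- lapply(object$axes, function(a) {
    sp <- sparsity_stats(a$codes)
    d <- vapply(a$dictionary$subspaces, function(s) s$dim, integer(1L))
    c(J = length(d), I = sum(d), mu = unname(sp["mu"]),
      sigma = unname(sp["sigma"]))
  })
  out <- list(axes = do.call(rbind, stats_ax),
              train_eof = object$train_eof,
              config = object$config,
              uncovered = lapply(object$axes, function(a)
                attr(a$dictionary, "uncovered")))
  class(out) <- "summary.srds"
  out
}

#' @export
print.summary.srds <- function(x, ...) {
  cat("Per-axis dictionary and training sparsity:\n")
  print(round(x$axes, 3))
  cat(sprintf(
    "\nTraining EOF (%%): min %.4g, mean %.4g, max %.4g\n",
    min(x$train_eof), mean(x$train_eof), max(x$train_eof)))
  nun <- sum(lengths(x$uncovered))
  if (nun > 0)
    cat(sprintf("Note: %d training column(s) exceed eta after pruning\n", nun))
  cat(sprintf(
    "Thresholds: epsilon = %g, eta = %g, e_max = %d, delta = %g\n",
    x$config$epsilon, x$config$eta, x$config$e_max, x$config$delta))
  invisible(x)
}

#' Extract block-sparse training coefficients
#'
#' @param object an `"srds"` fit.
#' @param axis `"x"`, `"y"`, `"z"`, or `"all"` for a named list.
#' @param ... unused.
#' @return The I x K block-sparse coefficient matrix of one axis (on the
#'   normalized training scale), or a list of the three.
#' @export
coef.srds <- function(object, axis = c("all", "x", "y", "z"), ...) {
  axis <- match.arg(axis)
  if (axis == "all") lapply(object$axes, `[[`, "C")
  else object$axes[[axis]]$C
}

#' @export
fitted.srds <- function(object, ...) object$fitted_surfaces

#' @export
residuals.srds <- function(object, ...) {
  lapply(seq_len(object$n_surfaces), function(k)
    object$train_coords[[k]] - object$fitted_surfaces[[k]])
}

#' Code and reconstruct held-out surfaces with a fitted dictionary
#'
#' Each test surface's coordinate functions are projected onto every
#' spatial dictionary block ([code_test_surface()]), encoded in the chosen
#' block, optionally truncated at `delta`, and reconstructed.
#'
#' @param object an `"srds"` fit.
#' @param newdata list of test surfaces (`"corresponded_surface"` or
#'   N x 3 matrices on the training parameterization).
#' @param strategy `"best_fit"` (default) or `"threshold"` block selection.
#' @param delta coefficient truncation threshold; defaults to the fitted
#'   configuration's value. Use 0 to disable truncation.
#' @param ... unused.
#' @return Object of class `"srds_prediction"`: list with `codes` (per
#'   surface, per axis), `reconstructions` (N x 3 matrices), `eof`
#'   (stacked, percent), `l0` (total per surface, after truncation) and
#'   `l0_raw` (before truncation).
#' @export
predict.srds <- function(object, newdata,
                         strategy = c("best_fit", "threshold"),
                         delta = object$config$delta, ...) {
  strategy <- match.arg(strategy)
  coords <- lapply(newdata, surface_coords)
  N <- nrow(object$basis$matrix)
  bad <- which(vapply(coords, nrow, integer(1L)) != N)
  if (length(bad) > 0L)
    stop(sprintf("test surface %d has a mismatched vertex count", bad[1L]))
  res <- lapply(coords, function(xyz) {
    per_axis <- lapply(1:3, function(a) {
      Gd <- object$axes[[a]]$spatial
      cd <- code_test_surface(xyz[, a], Gd, strategy = strategy,
                              eta = object$config$eta)
      raw_l0 <- sum(cd$in_block != 0)
      if (delta > 0) cd <- truncate_code(cd, delta, Gd, xyz[, a])
      list(code = cd, raw_l0 = raw_l0)
    })
    rec <- vapply(1:3, function(a)
      reconstruct(per_axis[[a]]$code, object$axes[[a]]$spatial),
      numeric(N))
    list(codes = lapply(per_axis, `[[`, "code"),
         raw_l0 = sum(vapply(per_axis, `[[`, numeric(1L), "raw_l0")),
         reconstruction = rec,
         eof = eof(rec, xyz))
  })
  structure(list(
    codes = lapply(res, `[[`, "codes"),
    reconstructions = lapply(res, `[[`, "reconstruction"),
    eof = vapply(res, `[[`, numeric(1L), "eof"),
    l0 = vapply(res, function(r)
      sum(vapply(r$codes, function(cd) sum(cd$padded != 0), numeric(1L))),
      numeric(1L)),
    l0_raw = vapply(res, `[[`, numeric(1L), "raw_l0"),
    strategy = strategy, delta = delta),
    class = "srds_prediction")
}

#' @export
print.srds_prediction <- function(x, ...) {
  cat(sprintf(
    "Block-sparse coding of %d surface(s) [%s, delta = %g]\n",
    length(x$eof), x$strategy, x$delta))
  cat(sprintf("  EOF (%%): mean %.4g, max %.4g\n", mean(x$eof), max(x$eof)))
  cat(sprintf("  l0 per surface (3 axes): mean %.3g (untruncated %.3g)\n",
              mean(x$l0), mean(x$l0_raw)))
  invisible(x)
}

#' Diagnostic plot of a fitted representation
#'
#' Two base-graphics panels: per-surface training EOF, and the learned
#' block dimensions per axis.
#'
#' @param x an `"srds"` fit.
#' @param ... forwarded to [graphics::barplot()].
#' @export
plot.srds <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$train_eof, names.arg = seq_along(x$train_eof),
                    xlab = "training surface", ylab = "EOF (%)",
                    main = "Training reconstruction error", ...)
  dims <- lapply(x$axes, function(a)
    vapply(a$dictionary$subspaces, function(s) s$dim, integer(1L)))
  nmax <- max(lengths(dims))
  m <- vapply(dims, function(d) c(d, rep(0L, nmax - length(d))),
              integer(nmax))
  graphics::barplot(m, beside = TRUE, names.arg = names(x$axes),
                    xlab = "axis", ylab = "subspace dimension",
                    main = "Learned block dimensions")
  invisible(x)
}

#' Serialize a fitted dictionary to a portable JSON archive
#'
#' Writes everything needed to code new surfaces without the training
#' data: the parameterization, degree, thresholds, and per-axis block
#' bases with offsets and training column norms, plus free-form provenance.
#'
#' @param fit an `"srds"` fit.
#' @param path output `.json` file path.
#' @param provenance optional named list (e.g. training file names) stored
#'   verbatim.
#' @return `path`, invisibly.
#' @export
write_srds_archive <- function(fit, path, provenance = list()) {
  stopifnot(inherits(fit, "srds"))
  arch <- list(
    format = "srds-dictionary",
    version = 1L,
    degree = fit$basis$degree,
    theta = fit$basis$param$theta,
    phi = fit$basis$param$phi,
    config = unclass(fit$config),
    axes = lapply(fit$axes, function(a) list(
      dims = vapply(a$dictionary$subspaces, function(s) s$dim, integer(1L)),
      # flat column-major data per block (a list of matrices of equal shape
      # would be read back as one 3-d array)
      bases = lapply(a$dictionary$subspaces,
                     function(s) as.numeric(s$basis)),
      column_norms = a$F$column_norms)),
    provenance = provenance)
  jsonlite::write_json(arch, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a dictionary archive written by [write_srds_archive()]
#'
#' @param path archive file path.
#' @return A reduced `"srds"` object (no training surfaces or codes)
#'   usable with [predict.srds()].
#' @export
read_srds_archive <- function(path) {
  arch <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(arch$format, "srds-dictionary"))
    stop("not an srds dictionary archive")
  param <- sh_parameterization(arch$theta, arch$phi)
  basis <- build_basis(param, arch$degree)
  cfg <- do.call(osp_config, arch$config[c("epsilon", "eta", "e_max",
                                           "delta", "min_cluster_size")])
  p <- (arch$degree + 1L)^2
  axes <- lapply(arch$axes, function(ax) {
    blist <- if (is.matrix(ax$bases)) asplit(ax$bases, 1L) else ax$bases
    subs <- lapply(seq_along(ax$dims), function(i) {
      B <- matrix(as.numeric(blist[[i]]), nrow = p, ncol = ax$dims[i])
      structure(list(basis = B, dim = ncol(B), member_ids = integer(0)),
                class = "subspace")
    })
    D <- .make_dictionary(subs, (arch$degree + 1L)^2, cfg, ax$column_norms)
    list(F = NULL, dictionary = D, codes = NULL, C = NULL,
         spatial = build_spatial_dictionary(basis, D))
  })
  names(axes) <- c("x", "y", "z")
  structure(list(basis = basis, config = cfg, axes = axes,
                 train_coords = NULL, fitted_surfaces = NULL,
                 train_eof = NULL, n_surfaces = NA_integer_,
                 call = quote(read_srds_archive())),
            class = "srds")
}
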