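#' Block-sparse code of one coordinate function
#'
#' A code whose support is confined to a single dictionary block: the
#' selected block id, the dense in-block coefficients, and bookkeeping for
#' rescaling (`norm`, the multiplier restoring the original surface scale)
#' and truncation (`scale`, the reference scale against which `delta` is
#' compared).
#'
#' @param block_id selected subspace index (1-based).
#' @param in_block numeric vector of in-block coefficients.
#' @param dictionary the `"harmonic_dictionary"` (or `"spatial_dictionary"`)
#'   the code refers to; only block layout is retained.
#' @param residual relative representation residual.
#' @param norm scale multiplier applied at reconstruction (1 for codes
#'   computed on raw-scale data).
#' @param scale reference scale for truncation thresholds; defaults to the
#'   l2 norm of `in_block`.
#' @return Object of class `"block_sparse_code"` with fields `block_id`,
#'   `in_block`, `padded` (length-I zero-padded vector), `residual`,
#'   `norm`, `scale`, `block_dims`, `block_offsets`.
#' @export
block_sparse_code <- function(block_id, in_block, dictionary,
                              residual = NA_real_, norm = 1,
                              scale = NULL) {
  dims <- vapply(dictionary$subspaces, function(s) s$dim, integer(1L))
  offsets <- dictionary$block_offsets
  I <- dictionary$total_dim
  block_id <- as.integer(block_id)
  if (block_id < 1L || block_id > length(dims)) stop("invalid block id")
  in_block <- as.numeric(in_block)
  if (length(in_block) != dims[block_id])
    stop("in-block coefficient length does not match the block dimension")
  padded <- numeric(I)
  padded[offsets[block_id] + seq_len(dims[block_id])] <- in_block
  if (is.null(scale)) scale <- sqrt(sum(in_block^2))
  structure(list(block_id = block_id, in_block = in_block, padded = padded,
                 residual = residual, norm = norm, scale = scale,
                 block_dims = dims, block_offsets = offsets),
            class = "block_sparse_code")
}

#' @export
print.block_sparse_code <- function(x, ...) {
  cat(sprintf(
    "Block-sparse code: block %d (dim %d), l0 = %d of %d, residual %.3g\n",
    x$block_id, x$block_dims[x$block_id], sum(x$in_block != 0),
    length(x$padded), x$residual))
  invisible(x)
}

#' Map the harmonic dictionary to the spatial domain
#'
#' Forms G = Y D block-wise: each spatial block is \eqn{G_i = Y A_i} of
#' size N x n_i, preserving the block structure of the harmonic dictionary.
#'
#' @param basis a `"harmonic_basis"` with `(L+1)^2` columns equal to the
#'   dictionary's ambient dimension.
#' @param D a `"harmonic_dictionary"`.
#' @return Object of class `"spatial_dictionary"`: list with `blocks`
#'   (list of N x n_i matrices), `subspaces` (block layout mirror),
#'   `total_dim`, `block_offsets`, `basis`, `harmonic` (the source D).
#' @export
build_spatial_dictionary <- function(basis, D) {
  stopifnot(inherits(basis, "harmonic_basis"),
            inherits(D, "harmonic_dictionary"))
  if (length(D$subspaces) == 0L) stop("empty dictionary")
  if (ncol(basis$matrix) != D$ambient_dim)
    stop("basis column count does not match the dictionary ambient dimension")
  blocks <- lapply(D$subspaces, function(s) basis$matrix %*% s$basis)
  structure(list(blocks = blocks,
                 subspaces = D$subspaces,
                 total_dim = D$total_dim,
                 block_offsets = D$block_offsets,
                 basis = basis,
                 harmonic = D),
            class = "spatial_dictionary")
}

#' @export
print.spatial_dictionary <- function(x, ...) {
  cat(sprintf(
    "Spatial dictionary G = YD: %d blocks, N = %d, I = %d\n",
    length(x$blocks), nrow(x$blocks[[1L]]), x$total_dim))
  invisible(x)
}

#' Code a test coordinate function over the spatial dictionary
#'
#' Least-squares-projects the sample vector onto every spatial block and
#' encodes it in one block. With `strategy = "best_fit"` the block with
#' minimal relative residual wins (ties to the lowest index); with
#' `strategy = "threshold"` the first block (ascending index) whose
#' relative residual is at most `eta` is taken, falling back to best-fit
#' with a warning when none qualifies.
#'
#' @param h numeric vector of length N (one coordinate axis of a
#'   corresponded test surface).
#' @param Gd a `"spatial_dictionary"`.
#' @param strategy `"best_fit"` (default) or `"threshold"`.
#' @param eta threshold for the `"threshold"` strategy.
#' @return A [block_sparse_code()]; `residual` is the relative residual
#'   \eqn{\|h - \hat h\|/\|h\|}.
#' @export
code_test_surface <- function(h, Gd, strategy = c("best_fit", "threshold"),
                              eta = 0.01) {
  stopifnot(inherits(Gd, "spatial_dictionary"))
  strategy <- match.arg(strategy)
  h <- as.numeric(h)
  N <- nrow(Gd$blocks[[1L]])
  if (length(h) != N)
    stop(sprintf("test vector length %d does not match N = %d", length(h), N))
  hn <- sqrt(sum(h^2))
  fit_block <- function(i) {
    G <- Gd$blocks[[i]]
    cf <- qr.coef(qr(G), h)
    cf[is.na(cf)] <- 0
    r <- sqrt(sum((h - drop(G %*% cf))^2))
    list(coef = cf, rel = if (hn > 0) r / hn else 0)
  }
  chosen <- NULL
  if (strategy == "threshold") {
    for (i in seq_along(Gd$blocks)) {
      ft <- fit_block(i)
      if (ft$rel <= eta) { chosen <- list(i = i, fit = ft); break }
    }
    if (is.null(chosen))
      warning("no block met the threshold; falling back to best fit")
  }
  if (is.null(chosen)) {
    fits <- lapply(seq_along(Gd$blocks), fit_block)
    rels <- vapply(fits, `[[`, numeric(1L), "rel")
    i <- which.min(rels)     # first minimum = lowest block index on ties
    chosen <- list(i = i, fit = fits[[i]])
  }
  block_sparse_code(chosen$i, chosen$fit$coef, Gd,
                    residual = chosen$fit$rel, norm = 1)
}

#' Truncate small code entries
#'
#' Zeroes in-block coefficients with absolute value below
#' `delta * code$scale` (truncation operates on the normalized coefficient
#' scale, so `delta` has the same meaning for training and test codes);
#' the block id is unchanged and the residual is recomputed against the
#' supplied dictionary when given.
#'
#' @param code a `"block_sparse_code"`.
#' @param delta truncation threshold, >= 0.
#' @param Gd optional `"spatial_dictionary"` and `h` reference samples for
#'   residual recomputation.
#' @param h optional reference sample vector matching `Gd`.
#' @return The truncated `"block_sparse_code"`.
#' @export
truncate_code <- function(code, delta, Gd = NULL, h = NULL) {
  stopifnot(inherits(code, "block_sparse_code"))
  if (delta < 0) stop("delta must be non-negative")
  keep <- abs(code$in_block) >= delta * code$scale
  code$in_block[!keep] <- 0
  rows <- code$block_offsets[code$block_id] + seq_along(code$in_block)
  code$padded[rows] <- code$in_block
  if (!is.null(Gd) && !is.null(h)) {
    hn <- sqrt(sum(h^2))
    rec <- drop(Gd$blocks[[code$block_id]] %*% code$in_block) * code$norm
    code$residual <- if (hn > 0) sqrt(sum((h - rec)^2)) / hn else 0
  } else if (all(!keep)) {
    code$residual <- 1
  }
  code
}

#' Reconstruct coordinate samples from a block-sparse code
#'
#' Evaluates \eqn{\hat x = G_i c} (equivalently \eqn{G \tilde c}) and
#' applies the stored scale multiplier.
#'
#' @param code a `"block_sparse_code"`.
#' @param Gd the `"spatial_dictionary"` the code was computed against.
#' @return Numeric vector of length N.
#' @export
reconstruct <- function(code, Gd) {
  stopifnot(inherits(code, "block_sparse_code"),
            inherits(Gd, "spatial_dictionary"))
  if (Gd$total_dim != length(code$padded))
    stop("code and dictionary dimensions do not match")
  drop(Gd$blocks[[code$block_id]] %*% code$in_block) * code$norm
}

#' Greedy re-pursuit coding against raw training atoms
#'
#' Comparison baseline: instead of using the learned block structure, a
#' test coefficient vector is re-approximated by greedy orthogonal pursuit
#' directly over all normalized training coefficient columns (same greedy
#' rule as [pursue_atoms()]). Used to check that structured coding matches
#' the accuracy of per-surface re-pursuit.
#'
#' @param f numeric harmonic coefficient vector of the test surface (raw
#'   scale).
#' @param F training `"coefficient_matrix"` (or raw matrix).
#' @param epsilon pursuit stopping threshold (on the normalized scale).
#' @param e_max maximum atoms.
#' @return List with `approx` (the approximating coefficient vector on the
#'   raw scale), `indices`, `l0`, and `residual` (relative).
#' @export
repursuit_code <- function(f, F, epsilon = 0.005, e_max = 50) {
  F <- normalize_columns(F)
  f <- as.numeric(f)
  fn <- sqrt(sum(f^2))
  if (fn == 0) stop("zero test vector")
  pur <- pursue_atoms(f / fn, F$columns, epsilon, e_max)
  if (length(pur$indices) == 0L)
    return(list(approx = numeric(length(f)), indices = integer(0),
                l0 = 0L, residual = 1))
  S <- F$columns[, pur$indices, drop = FALSE]
  cf <- qr.coef(qr(S), f / fn)
  cf[is.na(cf)] <- 0
  approx <- drop(S %*% cf) * fn
  list(approx = approx, indices = pur$indices, l0 = length(pur$indices),
       residual = sqrt(sum((f - approx)^2)) / fn)
}

#' Stacked dual-layer spherical-harmonic system
#'
#' Block-diagonal operator for organs with interior and exterior walls:
#' stacked coefficients `[f_in; f_ex]` (length `2 (L+1)^2`) map to stacked
#' samples (length `N1 + N2`), with the interior output depending only on
#' `f_in` and the exterior only on `f_ex`.
#'
#' @param interior_basis,exterior_basis `"harmonic_basis"` objects of the
#'   same degree (sample counts may differ).
#' @return Object of class `"dual_layer_system"`: list with `interior`,
#'   `exterior`, `degree`, `n_interior`, `n_exterior`, and methods-friendly
#'   fields; use [dual_layer_fit()] / [dual_layer_reconstruct()].
#' @export
build_dual_layer_system <- function(interior_basis, exterior_basis) {
  stopifnot(inherits(interior_basis, "harmonic_basis"),
            inherits(exterior_basis, "harmonic_basis"))
  if (interior_basis$degree != exterior_basis$degree)
    stop("degree mismatch between interior and exterior bases")
  structure(list(interior = interior_basis, exterior = exterior_basis,
                 degree = interior_basis$degree,
                 n_interior = nrow(interior_basis$matrix),
                 n_exterior = nrow(exterior_basis$matrix)),
            class = "dual_layer_system")
}

#' @export
print.dual_layer_system <- function(x, ...) {
  p <- (x$degree + 1L)^2
  cat(sprintf(
    "Dual-layer SH system: (%d + %d) x %d block-diagonal operator, L = %d\n",
    x$n_interior, x$n_exterior, 2L * p, x$degree))
  invisible(x)
}

#' Fit stacked dual-layer coefficients
#'
#' Because the stacked operator is block-diagonal, the least-squares fit
#' separates into independent per-layer fits.
#'
#' @param sys a `"dual_layer_system"`.
#' @param samples_in,samples_ex per-layer coordinate sample vectors.
#' @return Numeric vector `[f_in; f_ex]` of length `2 (L+1)^2`.
#' @export
dual_layer_fit <- function(sys, samples_in, samples_ex) {
  stopifnot(inherits(sys, "dual_layer_system"))
  c(shd_fit(samples_in, sys$interior)$values,
    shd_fit(samples_ex, sys$exterior)$values)
}

#' Apply the stacked dual-layer operator
#'
#' @param sys a `"dual_layer_system"`.
#' @param f_stacked stacked coefficient vector `[f_in; f_ex]`.
#' @return List with `interior` (length N1) and `exterior` (length N2)
#'   sample vectors.
#' @export
dual_layer_reconstruct <- function(sys, f_stacked) {
  stopifnot(inherits(sys, "dual_layer_system"))
  p <- (sys$degree + 1L)^2
  if (length(f_stacked) != 2L * p)
    stop("stacked coefficient length must be 2 (L+1)^2")
  list(interior = shd_reconstruct(f_stacked[seq_len(p)], sys$interior),
       exterior = shd_reconstruct(f_stacked[p + seq_len(p)], sys$exterior))
}

#' Dual-layer training and coding pipeline
#'
#' Runs the full structured-sparse pipeline on stacked interior+exterior
#' coefficient vectors: per axis, each training pair is fitted per layer,
#' the coefficients are stacked, a dictionary is learned on the stacked
#' vectors, and every test pair is coded with one block-sparse code per
#' axis and reconstructed jointly on both layers.
#'
#' @param training list of dual-layer surfaces, each a list with elements
#'   `interior` and `exterior` (each a `"corresponded_surface"`).
#' @param test like `training` (may be empty).
#' @param sys a `"dual_layer_system"` built on the cohort's two
#'   parameterizations.
#' @param cfg an [osp_config()].
#' @return List with per-axis `dictionaries`, `train` and `test` entries
#'   carrying `codes` and reconstructed layer coordinate matrices, and the
#'   per-surface stacked EOF percentages.
#' @export
dual_layer_pipeline <- function(training, test = list(), sys,
                                cfg = osp_config()) {
  stopifnot(inherits(sys, "dual_layer_system"))
  if (length(training) < 2L) stop("at least 2 training surfaces are required")
  get_xyz <- function(s, layer) surface_coords(s[[layer]])
  n_in <- vapply(training, function(s) nrow(get_xyz(s, "interior")), integer(1L))
  n_ex <- vapply(training, function(s) nrow(get_xyz(s, "exterior")), integer(1L))
  if (any(n_in != sys$n_interior) || any(n_ex != sys$n_exterior))
    stop("inconsistent layer vertex counts across the cohort")
  if (sys$n_interior == 0L || sys$n_exterior == 0L)
    stop("degenerate dual-layer input: a layer has no vertices (use the single-layer path)")

  stacked_coeffs <- function(surfs) {
    lapply(1:3, function(a) {
      vapply(surfs, function(s)
        dual_layer_fit(sys, get_xyz(s, "interior")[, a],
                       get_xyz(s, "exterior")[, a]),
        numeric(2L * (sys$degree + 1L)^2))
    })
  }
  Ftr <- stacked_coeffs(training)

  axes <- vector("list", 3L)
  for (a in 1:3) {
    Fn <- normalize_columns(Ftr[[a]])
    D <- prune_subspaces(learn_dictionary(Fn, cfg), Fn, cfg)
    fac <- factorize(Fn, D)
    axes[[a]] <- list(F = Fn, D = D, fac = fac)
  }

  code_stacked <- function(fvec, ax) {
    fn <- sqrt(sum(fvec^2))
    Dm <- ax$D
    rels <- vapply(Dm$subspaces, function(s)
      sqrt(sum((fvec - drop(s$basis %*% crossprod(s$basis, fvec)))^2)) / fn,
      numeric(1L))
    i <- which.min(rels)
    ck <- drop(crossprod(Dm$subspaces[[i]]$basis, fvec))
    block_sparse_code(i, ck, Dm, residual = rels[i], norm = 1)
  }

  eval_set <- function(surfs, coeffs, use_codes = NULL) {
    lapply(seq_along(surfs), function(k) {
      codes <- lapply(1:3, function(a) {
        if (!is.null(use_codes)) {
          cd <- use_codes[[a]]$fac$codes[[k]]
          cd$in_block <- cd$in_block * cd$norm  # back to raw scale
          cd$norm <- 1
          cd
        } else code_stacked(coeffs[[a]][, k], axes[[a]])
      })
      rec <- lapply(1:3, function(a) {
        A <- axes[[a]]$D$subspaces[[codes[[a]]$block_id]]$basis
        fhat <- drop(A %*% codes[[a]]$in_block)
        dual_layer_reconstruct(sys, fhat)
      })
      rec_in <- vapply(rec, `[[`, numeric(sys$n_interior), "interior")
      rec_ex <- vapply(rec, `[[`, numeric(sys$n_exterior), "exterior")
      xin <- get_xyz(surfs[[k]], "interior")
      xex <- get_xyz(surfs[[k]], "exterior")
      list(codes = codes, interior = rec_in, exterior = rec_ex,
           eof = eof(rbind(rec_in, rec_ex), rbind(xin, xex)))
    })
  }

  train_out <- eval_set(training, Ftr, use_codes = axes)
  test_out <- if (length(test) > 0L) eval_set(test, stacked_coeffs(test))
              else list()
  list(dictionaries = lapply(axes, `[[`, "D"),
       system = sys,
       train = train_out,
       test = test_out,
       train_eof = vapply(train_out, `[[`, numeric(1L), "eof"),
       test_eof = if (length(test_out)) vapply(test_out, `[[`, numeric(1L), "eof")
                  else numeric(0))
}
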