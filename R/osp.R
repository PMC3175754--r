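#' Configuration for subspace pursuit and coding
#'
#' Holds the thresholds of the dictionary-learning and coding pipeline:
#' `epsilon` stops the greedy subspace pursuit when the seed's residual
#' drops below it, `eta` is the clustering threshold (a vector belongs to a
#' subspace if its projection residual is at most `eta`), `e_max` caps the
#' number of pursuit iterations (hence subspace dimension), and `delta`
#' truncates small code entries. Defaults are the standard operating point
#' epsilon = 0.005, eta = 0.01, e_max = 50, delta = 0.005.
#'
#' @param epsilon pursuit residual threshold, `0 < epsilon <= eta`.
#' @param eta clustering residual threshold.
#' @param e_max maximum pursuit iterations (>= 1).
#' @param delta coefficient truncation threshold (>= 0).
#' @param min_cluster_size subspaces attracting fewer members than this are
#'   pruned (default 2).
#' @param seed_policy `"first"` (deterministic first remaining column,
#'   default) or `"random"`.
#' @param seed RNG seed used when `seed_policy = "random"`.
#' @return Object of class `"osp_config"`.
#' @export
osp_config <- function(epsilon = 0.005, eta = 0.01, e_max = 50,
                       delta = 0.005, min_cluster_size = 2,
                       seed_policy = c("first", "random"), seed = 1L) {
  seed_policy <- match.arg(seed_policy)
  if (!(epsilon > 0)) stop("epsilon must be positive")
  if (epsilon > eta) stop("epsilon must not exceed eta")
  if (e_max < 1) stop("e_max must be at least 1")
  if (delta < 0) stop("delta must be non-negative")
  if (min_cluster_size < 1) stop("min_cluster_size must be at least 1")
  structure(list(epsilon = epsilon, eta = eta, e_max = as.integer(e_max),
                 delta = delta, min_cluster_size = as.integer(min_cluster_size),
                 seed_policy = seed_policy, seed = as.integer(seed)),
            class = "osp_config")
}

#' Normalize training coefficient columns
#'
#' Scales every column of a coefficient matrix to unit l2 norm, recording
#' the original norms (needed to rescale reconstructions back to the
#' original surface scale).
#'
#' @param F_raw numeric matrix, one harmonic coefficient vector per column.
#' @return Object of class `"coefficient_matrix"`: list with unit-norm
#'   `columns` and `column_norms`.
#' @export
normalize_columns <- function(F_raw) {
  if (inherits(F_raw, "coefficient_matrix")) return(F_raw)
  F_raw <- as.matrix(F_raw)
  nrms <- sqrt(colSums(F_raw^2))
  zero <- which(nrms <= .Machine$double.eps * nrow(F_raw))
  if (length(zero) > 0L)
    stop(sprintf("degenerate training vector: column %d has zero norm",
                 zero[1L]))
  structure(list(columns = sweep(F_raw, 2L, nrms, "/"), column_norms = nrms),
            class = "coefficient_matrix")
}

#' Greedy orthogonal pursuit of atoms approximating a seed vector
#'
#' Orthogonal-matching-pursuit style selection: repeatedly pick the pool
#' atom most correlated (absolute inner product) with the current residual,
#' re-fit the seed by least squares on all selected atoms, and update the
#' residual. Stops when the residual l2 norm is at most `epsilon` or `e_max`
#' atoms have been selected. Ties go to the lowest column index.
#'
#' @param seed numeric unit vector to be approximated.
#' @param pool numeric matrix of candidate atoms (columns); must not
#'   contain the seed itself.
#' @param epsilon residual stopping threshold.
#' @param e_max maximum number of atoms.
#' @return List with `indices` (selected pool columns in selection order)
#'   and `residual_norm`.
#' @export
pursue_atoms <- function(seed, pool, epsilon, e_max) {
  seed <- as.numeric(seed)
  pool <- as.matrix(pool)
  if (ncol(pool) == 0L)
    return(list(indices = integer(0), residual_norm = sqrt(sum(seed^2))))
  sel <- integer(0)
  resid <- seed
  repeat {
    if (sqrt(sum(resid^2)) <= epsilon || length(sel) >= e_max) break
    corr <- abs(drop(crossprod(pool, resid)))
    corr[sel] <- -Inf
    if (all(!is.finite(corr))) break
    best <- which.max(corr)      # which.max takes the first (lowest) index on ties
    if (corr[best] <= .Machine$double.eps * 10) break  # residual orthogonal to pool
    sel <- c(sel, best)
    S <- pool[, sel, drop = FALSE]
    cf <- qr.coef(qr(S), seed)
    cf[is.na(cf)] <- 0
    resid <- seed - drop(S %*% cf)
    if (length(sel) >= ncol(pool)) break
  }
  list(indices = sel, residual_norm = sqrt(sum(resid^2)))
}

#' Orthonormal subspace from selected atoms
#'
#' Singular value decomposition of the selected atom set; the subspace basis
#' is the leading left singular vectors up to the numerical rank (relative
#' tolerance 1e-10), so collinear atoms do not inflate the dimension.
#'
#' @param selected matrix whose columns are the chosen atoms.
#' @param member_ids optional indices of training columns clustered to the
#'   subspace (attached to the result).
#' @return Object of class `"subspace"`: list with orthonormal `basis`,
#'   `dim`, and `member_ids`.
#' @export
orthonormalize_subspace <- function(selected, member_ids = integer(0)) {
  selected <- as.matrix(selected)
  if (ncol(selected) < 1L) stop("at least one atom is required")
  sv <- svd(selected)
  tol <- 1e-10 * sv$d[1L]
  r <- max(1L, sum(sv$d > tol))
  structure(list(basis = sv$u[, seq_len(r), drop = FALSE],
                 dim = r, member_ids = as.integer(member_ids)),
            class = "subspace")
}

# residual of projecting columns of X onto an orthonormal basis A
.projection_residuals <- function(X, A) {
  X <- as.matrix(X)
  P <- A %*% crossprod(A, X)
  sqrt(colSums((X - P)^2))
}

#' Cluster pool vectors to a subspace
#'
#' Returns the indices of pool columns whose orthogonal-projection residual
#' onto the subspace is at most `eta` (for an orthonormal basis the
#' least-squares projection is \eqn{A A^T f}).
#'
#' @param F_pool unit-norm coefficient matrix (`"coefficient_matrix"` or
#'   bare matrix).
#' @param sub a `"subspace"`.
#' @param eta clustering threshold.
#' @return Integer vector of selected column indices.
#' @export
cluster_to_subspace <- function(F_pool, sub, eta) {
  X <- if (inherits(F_pool, "coefficient_matrix")) F_pool$columns else as.matrix(F_pool)
  unname(which(.projection_residuals(X, sub$basis) <= eta))
}

#' Learn a structured union-of-subspaces dictionary
#'
#' Orthogonal subspace pursuit over normalized training coefficient
#' vectors: a seed column is chosen (first remaining by default), atoms
#' approximating it are pursued greedily from the full training set minus
#' the seed, the selected set is orthonormalized by SVD into a subspace,
#' and every remaining column within `eta` of that subspace is clustered to
#' it and removed. This repeats until all columns are clustered. The result
#' is an ordered union of orthonormal blocks whose concatenation is the
#' structured dictionary D with total dimension I.
#'
#' @param F a `"coefficient_matrix"` (see [normalize_columns()]) or a raw
#'   matrix with K >= 2 columns.
#' @param cfg an [osp_config()].
#' @return Object of class `"harmonic_dictionary"`: list with `subspaces`
#'   (list of `"subspace"`), `total_dim`, `block_offsets` (0-based start of
#'   each block), `ambient_dim`, `config`, and `column_norms`.
#' @seealso [prune_subspaces()], [factorize()]
#' @export
learn_dictionary <- function(F, cfg = osp_config()) {
  F <- normalize_columns(F)
  X <- F$columns
  K <- ncol(X)
  if (K < 2L) stop("at least 2 training vectors are required")
  remaining <- seq_len(K)
  subspaces <- list()
  if (cfg$seed_policy == "random") {
    rng <- .seeded_rng(cfg$seed)
  }
  while (length(remaining) > 0L) {
    seed_pos <- if (cfg$seed_policy == "first") 1L
                else rng(length(remaining))
    seed_idx <- remaining[seed_pos]
    seed <- X[, seed_idx]
    pool_idx <- setdiff(seq_len(K), seed_idx)  # full training set minus seed
    pur <- pursue_atoms(seed, X[, pool_idx, drop = FALSE],
                        cfg$epsilon, cfg$e_max)
    atoms <- if (length(pur$indices) > 0L)
      X[, pool_idx[pur$indices], drop = FALSE]
    else matrix(seed, ncol = 1L)   # nothing pursued: span the seed itself
    sub <- orthonormalize_subspace(atoms)
    cand <- setdiff(remaining, seed_idx)
    members <- cand[.projection_residuals(X[, cand, drop = FALSE],
                                          sub$basis) <= cfg$eta]
    sub$member_ids <- sort(c(seed_idx, members))
    subspaces[[length(subspaces) + 1L]] <- sub
    remaining <- setdiff(remaining, sub$member_ids)
  }
  .make_dictionary(subspaces, nrow(X), cfg, F$column_norms)
}

.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- seed
  function(n) {
    # deterministic auxiliary generator, independent of the global RNG
    env$state <- (1103515245 * env$state + 12345) %% 2147483648
    (env$state %% n) + 1L
  }
}

.make_dictionary <- function(subspaces, ambient_dim, cfg, column_norms) {
  subspaces <- lapply(subspaces, function(s) { s$dim <- as.integer(s$dim); s })
  dims <- vapply(subspaces, function(s) s$dim, integer(1L))
  offsets <- c(0L, cumsum(dims))[seq_along(dims)]
  structure(list(subspaces = subspaces,
                 total_dim = sum(dims),
                 block_offsets = as.integer(offsets),
                 ambient_dim = as.integer(ambient_dim),
                 config = cfg,
                 column_norms = column_norms),
            class = "harmonic_dictionary")
}

#' @export
print.harmonic_dictionary <- function(x, ...) {
  dims <- vapply(x$subspaces, function(s) s$dim, integer(1L))
  cat(sprintf(
    "Structured harmonic dictionary: J = %d subspaces, I = %d, ambient %d\n",
    length(dims), x$total_dim, x$ambient_dim))
  cat("  block dims:", paste(dims, collapse = " "), "\n")
  invisible(x)
}

#' Dense matrix form of the structured dictionary
#'
#' @param D a `"harmonic_dictionary"`.
#' @return The ambient x I concatenation of all block bases.
#' @export
dictionary_matrix <- function(D) {
  do.call(cbind, lapply(D$subspaces, function(s) s$basis))
}

#' Prune redundant subspaces
#'
#' Re-partitions every training column to its minimal-residual subspace,
#' drops subspaces attracting fewer than `min_cluster_size` members, and
#' re-partitions once more among the survivors. Columns whose final
#' residual exceeds `eta` are reported in the `uncovered` attribute of the
#' result (their ids) rather than silently accepted.
#'
#' @param D a `"harmonic_dictionary"` from [learn_dictionary()].
#' @param F the training `"coefficient_matrix"` (or raw matrix).
#' @param cfg an [osp_config()]; defaults to the one stored in `D`.
#' @return A pruned `"harmonic_dictionary"` with updated memberships; the
#'   `uncovered` attribute lists columns with residual above `eta`.
#' @export
prune_subspaces <- function(D, F, cfg = D$config) {
  F <- normalize_columns(F)
  X <- F$columns
  assign_best <- function(subs) {
    R <- vapply(subs, function(s) .projection_residuals(X, s$basis),
                numeric(ncol(X)))
    R <- matrix(R, nrow = ncol(X))
    dims <- vapply(subs, function(s) s$dim, integer(1L))
    # near-exact residual ties (a subspace nested in another represents the
    # same vectors) go to the larger block so the nested one empties out
    block <- vapply(seq_len(nrow(R)), function(k) {
      r <- R[k, ]
      cand <- which(r <= min(r) + 1e-9)
      cand[which.max(dims[cand])]
    }, integer(1L))
    list(block = block, resid = R[cbind(seq_len(nrow(R)), block)])
  }
  a1 <- assign_best(D$subspaces)
  counts <- tabulate(a1$block, nbins = length(D$subspaces))
  keep <- which(counts >= cfg$min_cluster_size)
  if (length(keep) == 0L) {
    warning("pruning would remove every subspace; keeping the best-populated one")
    keep <- which.max(counts)
  }
  survivors <- D$subspaces[keep]
  a2 <- assign_best(survivors)
  for (i in seq_along(survivors))
    survivors[[i]]$member_ids <- which(a2$block == i)
  out <- .make_dictionary(survivors, D$ambient_dim, cfg, F$column_norms)
  attr(out, "uncovered") <- which(a2$resid > cfg$eta)
  attr(out, "final_residuals") <- a2$resid
  out
}

#' Factorize training coefficients over the dictionary
#'
#' Computes the block-sparse coefficient matrix C with F = D C: for a
#' column clustered to subspace i with orthonormal basis A_i the in-block
#' coefficients are \eqn{c_k = A_i^T f_k}, zero-padded into block i's
#' position of the length-I dictionary coordinate vector.
#'
#' @param F training `"coefficient_matrix"` (or raw matrix; normalized
#'   internally).
#' @param D a `"harmonic_dictionary"` whose memberships cover all columns.
#' @return List with `C` (I x K block-sparse matrix on the normalized
#'   scale), `codes` (list of [block_sparse_code()] per column), and
#'   `assignments` (block id per column).
#' @export
factorize <- function(F, D) {
  F <- normalize_columns(F)
  X <- F$columns
  K <- ncol(X)
  assign <- rep(NA_integer_, K)
  for (i in seq_along(D$subspaces))
    assign[D$subspaces[[i]]$member_ids] <- i
  if (anyNA(assign))
    stop(sprintf("unassigned training column(s): %s",
                 paste(utils::head(which(is.na(assign)), 5L), collapse = ", ")))
  C <- matrix(0, D$total_dim, K)
  codes <- vector("list", K)
  for (k in seq_len(K)) {
    i <- assign[k]
    A <- D$subspaces[[i]]$basis
    ck <- drop(crossprod(A, X[, k]))
    rows <- D$block_offsets[i] + seq_len(D$subspaces[[i]]$dim)
    C[rows, k] <- ck
    resid <- sqrt(sum((X[, k] - drop(A %*% ck))^2))
    codes[[k]] <- block_sparse_code(
      block_id = i, in_block = ck, dictionary = D,
      residual = resid, norm = F$column_norms[k], scale = 1)
  }
  list(C = C, codes = codes, assignments = assign)
}
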