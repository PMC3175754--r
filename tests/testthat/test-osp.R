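# Orthogonal subspace pursuit: normalization, greedy atom selection,
# SVD orthonormalization, clustering, dictionary learning, pruning, and
# the F = DC factorization.

test_that("column normalization records norms and rejects zero columns", {
  set.seed(2)
  Fm <- matrix(rnorm(40 * 10), 40, 10)
  Fm[, 3] <- Fm[, 3] * 5 / sqrt(sum(Fm[, 3]^2))
  Fn <- normalize_columns(Fm)
  expect_true(all(abs(sqrt(colSums(Fn$columns^2)) - 1) < 1e-12))
  expect_equal(Fn$column_norms[3], 5)
  expect_equal(Fn$columns * rep(Fn$column_norms, each = 40), Fm)
  Fm[, 7] <- 0
  expect_error(normalize_columns(Fm), "column 7")
})

test_that("greedy pursuit handles exact, 2-sparse, and orthogonal seeds", {
  set.seed(4)
  pool <- qr.Q(qr(matrix(rnorm(50 * 6), 50, 6)))
  # seed identical to a pool atom
  r1 <- pursue_atoms(pool[, 4], pool, 1e-6, 10)
  expect_equal(r1$indices, 4L)
  expect_lt(r1$residual_norm, 1e-10)
  # seed an even mixture of two orthogonal atoms
  seed2 <- (pool[, 1] + pool[, 2]) / sqrt(2)
  r2 <- pursue_atoms(seed2, pool, 1e-6, 10)
  expect_setequal(r2$indices, c(1L, 2L))
  expect_lt(r2$residual_norm, 1e-6)
  # seed orthogonal to the whole pool: no epsilon-solution exists
  seed3 <- qr.Q(qr(cbind(pool, rnorm(50))))[, 7]
  r3 <- pursue_atoms(seed3, pool, 1e-6, 4)
  expect_equal(r3$residual_norm, 1, tolerance = 1e-9)
  # empty pool
  r4 <- pursue_atoms(seed3, matrix(numeric(0), 50, 0), 1e-6, 4)
  expect_equal(r4$indices, integer(0))
  expect_equal(r4$residual_norm, 1, tolerance = 1e-12)
})

test_that("orthonormalization uses the numerical rank of the atom set", {
  set.seed(5)
  a <- rnorm(20); a <- a / sqrt(sum(a^2))
  s1 <- orthonormalize_subspace(cbind(a))
  expect_equal(s1$dim, 1L)
  expect_lt(max(abs(abs(crossprod(s1$basis, a)) - 1)), 1e-12)
  s2 <- orthonormalize_subspace(cbind(a, a))
  expect_equal(s2$dim, 1L)
  A <- matrix(rnorm(20 * 3), 20, 3)
  s3 <- orthonormalize_subspace(A)
  expect_equal(s3$dim, 3L)
  expect_lt(max(abs(crossprod(s3$basis) - diag(3))), 1e-10)
  P1 <- s3$basis %*% t(s3$basis)
  Q <- qr.Q(qr(A))
  expect_lt(max(abs(P1 - Q %*% t(Q))), 1e-9)
})

test_that("clustering thresholds the orthogonal-projection residual", {
  set.seed(6)
  B <- qr.Q(qr(matrix(rnorm(30 * 2), 30, 2)))
  sub <- structure(list(basis = B, dim = 2L), class = "subspace")
  inside <- drop(B %*% c(0.6, -0.8))
  ortho <- qr.Q(qr(cbind(B, rnorm(30))))[, 3]
  eta <- 0.01
  mixed <- sqrt(1 - (eta / 2)^2) * drop(B %*% c(1, 0)) + (eta / 2) * ortho
  pool <- cbind(inside, ortho, mixed)
  expect_equal(cluster_to_subspace(pool, sub, eta), c(1L, 3L))
})

test_that("dictionary learning recovers planted unions of subspaces", {
  # all vectors in one 3-dim subspace collapse to a single block
  set.seed(8)
  B <- qr.Q(qr(matrix(rnorm(50 * 3), 50, 3)))
  Fm <- B %*% matrix(rnorm(3 * 15), 3, 15)
  D1 <- learn_dictionary(normalize_columns(Fm), osp_config())
  expect_equal(length(D1$subspaces), 1L)
  expect_lte(D1$subspaces[[1]]$dim, 3L)
  expect_equal(sort(D1$subspaces[[1]]$member_ids), 1:15)
  # J = 3 disjoint 5-dim subspaces in ambient 441, 20 vectors each
  mdl <- planted_model(20, dims = c(5, 5, 5), amplitude = 1, seed = 3)
  coh <- sample_planted_cohort(mdl, K = 60, M = 5, seed = 4)
  Fn <- normalize_columns(coh$F_train[[1]])
  D <- prune_subspaces(learn_dictionary(Fn, osp_config()), Fn, osp_config())
  expect_equal(length(D$subspaces), 3L)
  pd <- vapply(D$subspaces, function(s)
    min(vapply(mdl$bases, function(B)
      max(abs(s$basis %*% t(s$basis) - B %*% t(B))), 1)), 1)
  expect_lt(max(pd), 1e-6)
  expect_lt(max(attr(D, "final_residuals")), 0.01)
  expect_length(attr(D, "uncovered"), 0)
  expect_error(learn_dictionary(matrix(rnorm(10), 10, 1)), "at least 2")
})

test_that("memberships cover the training set disjointly", {
  coh <- fix_sphere_cohort()
  for (a in 1:2) {
    Fn <- normalize_columns(coh$F_train[[a]])
    D <- learn_dictionary(Fn, osp_config())
    ids <- unlist(lapply(D$subspaces, `[[`, "member_ids"))
    expect_equal(sort(ids), seq_len(ncol(Fn$columns)))
    expect_false(any(duplicated(ids)))
    dims <- vapply(D$subspaces, `[[`, integer(1), "dim")
    expect_true(all(dims >= 1 & dims <= osp_config()$e_max))
    expect_equal(D$total_dim, sum(dims))
    expect_equal(D$block_offsets, c(0L, cumsum(dims))[seq_along(dims)])
  }
})

test_that("pruning drops nested and unpopulated subspaces but keeps coverage", {
  set.seed(11)
  B <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  Fm <- B %*% matrix(rnorm(3 * 12), 3, 12)
  Fn <- normalize_columns(Fm)
  sub_small <- orthonormalize_subspace(Fn$columns[, 1:2])  # rank 2, nested
  sub_full <- orthonormalize_subspace(Fn$columns[, 1:5])   # rank 3, full
  D <- srds:::.make_dictionary(list(sub_small, sub_full), 40, osp_config(),
                               Fn$column_norms)
  Dp <- prune_subspaces(D, Fn)
  expect_equal(length(Dp$subspaces), 1L)
  expect_equal(Dp$subspaces[[1]]$dim, 3L)
  expect_equal(sort(Dp$subspaces[[1]]$member_ids), 1:12)
  # min_cluster_size = 1 only drops empty subspaces
  Dp1 <- prune_subspaces(D, Fn, osp_config(min_cluster_size = 1))
  counts <- lengths(lapply(Dp1$subspaces, `[[`, "member_ids"))
  expect_true(all(counts >= 1))
})

test_that("factorization is block-sparse with the documented layout", {
  # block layout J = 3 with dims (4, 3, 2): a column in block 2 occupies
  # 0-based positions 4..6, i.e. the 5th to 7th dictionary columns
  set.seed(13)
  bases <- lapply(c(4, 3, 2), function(d) qr.Q(qr(matrix(rnorm(30 * d), 30, d))))
  subs <- lapply(bases, function(B) {
    structure(list(basis = B, dim = ncol(B), member_ids = integer(0)),
              class = "subspace")
  })
  f1 <- drop(bases[[2]] %*% c(1, -2, 0.5))
  f1 <- f1 / sqrt(sum(f1^2))
  subs[[2]]$member_ids <- 1L
  D <- srds:::.make_dictionary(subs, 30, osp_config(), 1)
  fac <- factorize(cbind(f1), D)
  support <- which(fac$C[, 1] != 0)
  expect_equal(support, 5:7)
  expect_equal(fac$codes[[1]]$block_id, 2L)
  expect_lt(max(abs(dictionary_matrix(D) %*% fac$C[, 1] - f1)), 1e-12)
  # full-cohort factorization residual bounded by the clustering threshold
  coh <- fix_sphere_cohort()
  Fn <- normalize_columns(coh$F_train[[1]])
  cfg <- osp_config()
  D2 <- prune_subspaces(learn_dictionary(Fn, cfg), Fn, cfg)
  fac2 <- factorize(Fn, D2)
  rel <- norm(Fn$columns - dictionary_matrix(D2) %*% fac2$C, "F") /
    norm(Fn$columns, "F")
  expect_lte(rel, cfg$eta)
  l0 <- colSums(fac2$C != 0)
  expect_true(all(l0 <= cfg$e_max))
  # support confined to one block per column
  dims <- vapply(D2$subspaces, `[[`, integer(1), "dim")
  blocks <- rep(seq_along(dims), dims)
  expect_true(all(vapply(seq_len(ncol(fac2$C)), function(k)
    length(unique(blocks[fac2$C[, k] != 0])) == 1L, TRUE)))
})

test_that("learning is deterministic and epsilon controls dictionary size", {
  coh <- fix_sphere_cohort(noise_sd = 5e-4)
  Fn <- normalize_columns(coh$F_train[[1]])
  D1 <- learn_dictionary(Fn, osp_config())
  D2 <- learn_dictionary(Fn, osp_config())
  expect_identical(lapply(D1$subspaces, `[[`, "basis"),
                   lapply(D2$subspaces, `[[`, "basis"))
  Is <- vapply(c(0.001, 0.005, 0.01), function(eps) {
    cfg <- osp_config(epsilon = eps)
    prune_subspaces(learn_dictionary(Fn, cfg), Fn, cfg)$total_dim
  }, 1L)
  expect_monotone(Is, "nonincreasing")
})
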