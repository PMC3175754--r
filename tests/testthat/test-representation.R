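# Spatial dictionary, block-sparse coding of test surfaces, truncation,
# reconstruction, the greedy re-pursuit baseline, and the dual-layer system.

make_toy_spatial <- function(seed = 17, dims = c(3, 2), L = 4, f = 4) {
  basis <- fix_basis(f, L)
  set.seed(seed)
  p <- (L + 1)^2
  subs <- lapply(dims, function(d) {
    B <- qr.Q(qr(matrix(rnorm(p * d), p, d)))
    structure(list(basis = B, dim = d, member_ids = integer(0)),
              class = "subspace")
  })
  D <- srds:::.make_dictionary(subs, p, osp_config(), 1)
  list(basis = basis, D = D, Gd = build_spatial_dictionary(basis, D))
}

test_that("spatial dictionary blocks are exactly Y times the harmonic blocks", {
  toy <- make_toy_spatial()
  for (i in seq_along(toy$Gd$blocks))
    expect_lt(max(abs(toy$Gd$blocks[[i]] -
                      toy$basis$matrix %*% toy$D$subspaces[[i]]$basis)), 1e-12)
  # one 1-dim canonical block reproduces the first basis column
  e1 <- structure(list(basis = diag(25)[, 1, drop = FALSE], dim = 1L,
                       member_ids = integer(0)), class = "subspace")
  D1 <- srds:::.make_dictionary(list(e1), 25, osp_config(), 1)
  G1 <- build_spatial_dictionary(toy$basis, D1)
  expect_equal(drop(G1$blocks[[1]]), toy$basis$matrix[, 1])
  expect_error(build_spatial_dictionary(fix_basis(4, 3), toy$D), "ambient")
})

test_that("coding selects the right block and reproduces in-span surfaces", {
  toy <- make_toy_spatial()
  set.seed(19)
  h <- drop(toy$Gd$blocks[[2]] %*% c(1.3, -0.4))
  cd <- code_test_surface(h, toy$Gd)
  expect_equal(cd$block_id, 2L)
  expect_lt(cd$residual, 1e-10)
  expect_lt(max(abs(reconstruct(cd, toy$Gd) - h)), 1e-9)
  # reconstruction through G equals reconstruction through Y D
  rec_g <- reconstruct(cd, toy$Gd)
  rec_yd <- drop(toy$basis$matrix %*%
                 (dictionary_matrix(toy$D) %*% cd$padded)) * cd$norm
  expect_lt(max(abs(rec_g - rec_yd)), 1e-10)
  expect_error(code_test_surface(h[-1], toy$Gd), "length")
})

test_that("threshold strategy scans in order and falls back with a warning", {
  toy <- make_toy_spatial()
  h <- drop(toy$Gd$blocks[[2]] %*% c(1, 1))
  cd <- code_test_surface(h, toy$Gd, strategy = "threshold", eta = 1e-8)
  expect_equal(cd$block_id, 2L)
  # a vector far from every block triggers the best-fit fallback
  set.seed(23)
  far <- rnorm(nrow(toy$Gd$blocks[[1]]))
  expect_warning(code_test_surface(far, toy$Gd, strategy = "threshold",
                                   eta = 1e-10),
                 "falling back")
})

test_that("symmetric two-block ties resolve to the lowest block index", {
  basis <- fix_basis(4, 4)
  # two 1-dim blocks from distinct harmonics; target equidistant from both
  mk <- function(j) structure(list(basis = diag(25)[, j, drop = FALSE],
                                   dim = 1L, member_ids = integer(0)),
                              class = "subspace")
  D <- srds:::.make_dictionary(list(mk(2), mk(3)), 25, osp_config(), 1)
  Gd <- build_spatial_dictionary(basis, D)
  h <- drop(basis$matrix %*% (diag(25)[, 2] + diag(25)[, 3]))
  cd <- code_test_surface(h, Gd)
  expect_equal(cd$block_id, 1L)
})

test_that("truncation is monotone in delta and zeroes out at huge delta", {
  toy <- make_toy_spatial(dims = c(5))
  set.seed(29)
  h <- drop(toy$Gd$blocks[[1]] %*% c(2, 0.5, 0.1, 0.02, 0.004))
  cd <- code_test_surface(h, toy$Gd)
  cd0 <- truncate_code(cd, 0, toy$Gd, h)
  expect_equal(cd0$in_block, cd$in_block)
  grid <- c(0, 1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.05, 0.08, 0.1)
  l0 <- numeric(length(grid)); res <- numeric(length(grid))
  for (i in seq_along(grid)) {
    ct <- truncate_code(cd, grid[i], toy$Gd, h)
    l0[i] <- sum(ct$padded != 0)
    res[i] <- ct$residual
    expect_equal(ct$block_id, cd$block_id)
  }
  expect_monotone(l0, "nonincreasing")
  expect_monotone(res, "nondecreasing")
  all_gone <- truncate_code(cd, 10)
  expect_true(all(all_gone$padded == 0))
  expect_equal(all_gone$residual, 1)
  zero_code <- block_sparse_code(1, numeric(5), toy$D)
  expect_true(all(reconstruct(zero_code, toy$Gd) == 0))
})

test_that("coding a training surface reproduces its training factorization", {
  # cohort with well-separated planted subspaces so block assignment is
  # unambiguous between the harmonic and spatial routes
  basis <- fix_basis(8, 10)
  mdl <- planted_model(10, dims = c(4, 4, 4), amplitude = 1, seed = 67)
  coh <- sample_planted_cohort(mdl, K = 30, M = 2, basis = basis, seed = 68)
  fit <- srds(coh$train_surfaces, L = 10, param = basis$param)
  for (k in c(3, 17)) for (a in 1:3) {
    ax <- fit$axes[[a]]
    cd_test <- code_test_surface(coh$train_surfaces[[k]][, a], ax$spatial)
    cd_train <- ax$codes[[k]]
    expect_equal(cd_test$block_id, cd_train$block_id)
    expect_equal(cd_test$in_block, cd_train$in_block * cd_train$norm,
                 tolerance = 1e-9)
  }
})

test_that("structured coding matches greedy re-pursuit accuracy", {
  coh <- fix_sphere_cohort()
  basis <- fix_basis(8, 10)
  fit <- srds(coh$train_surfaces, L = 10, param = basis$param)
  pred <- predict(fit, coh$test_surfaces, delta = 0)
  expect_true(all(pred$l0 <= 3 * fit$config$e_max))
  rp <- vapply(seq_along(coh$test_surfaces), function(k) {
    recs <- vapply(1:3, function(a) {
      f <- shd_fit(coh$test_surfaces[[k]][, a], basis)$values
      shd_reconstruct(repursuit_code(f, fit$axes[[a]]$F)$approx, basis)
    }, numeric(642))
    eof(recs, coh$test_surfaces[[k]])
  }, 1)
  expect_lte(mean(pred$eof), 2 * mean(rp))
  # every produced code is confined to exactly one block
  for (cds in pred$codes) for (cd in cds) {
    dims <- cd$block_dims
    blocks <- rep(seq_along(dims), dims)
    nz <- which(cd$padded != 0)
    expect_true(length(unique(blocks[nz])) <= 1L)
  }
})

test_that("dual-layer operator is block-diagonal and separable", {
  basis <- fix_basis(4, 6)
  sys <- build_dual_layer_system(basis, basis)
  p <- (6 + 1)^2
  set.seed(31)
  f_in <- rnorm(p)
  # zero exterior coefficients give an identically zero exterior layer
  out <- dual_layer_reconstruct(sys, c(f_in, numeric(p)))
  expect_true(all(out$exterior == 0))
  expect_lt(max(abs(out$interior - shd_reconstruct(f_in, basis))), 1e-10)
  # stacked fit separates into the two single-layer fits
  xin <- rnorm(162); xex <- rnorm(162)
  fs <- dual_layer_fit(sys, xin, xex)
  expect_equal(fs[seq_len(p)], shd_fit(xin, basis)$values, tolerance = 1e-10)
  expect_equal(fs[p + seq_len(p)], shd_fit(xex, basis)$values,
               tolerance = 1e-10)
  expect_error(build_dual_layer_system(basis, fix_basis(4, 5)), "degree")
})

test_that("stacked operator dimensions match a bladder-scale configuration", {
  # interior 4434 and exterior 4274 samples at degree 30 give a
  # (4434 + 4274) x 2*961 block-diagonal system
  set.seed(37)
  mkparam <- function(n) {
    z <- seq(-1 + 1 / n, 1 - 1 / n, length.out = n)
    sh_parameterization(acos(z), (pi * (3 - sqrt(5)) * seq_len(n)) %% (2 * pi))
  }
  b_in <- build_basis(mkparam(4434), 30)
  b_ex <- build_basis(mkparam(4274), 30)
  sys <- build_dual_layer_system(b_in, b_ex)
  expect_equal(sys$n_interior + sys$n_exterior, 8708L)
  expect_equal(2L * (sys$degree + 1L)^2, 1922L)
  f <- c(rnorm(961), rnorm(961))
  out <- dual_layer_reconstruct(sys, f)
  expect_length(out$interior, 4434L)
  expect_length(out$exterior, 4274L)
})

test_that("dual-layer pipeline represents planted shell cohorts", {
  basis <- fix_basis(4, 6)
  p2 <- 2 * (6 + 1)^2
  mdl <- planted_model(6, dims = c(3, 3), amplitude = 0.02, seed = 8)
  set.seed(8)
  mdl$bases <- lapply(mdl$dims, function(d) qr.Q(qr(matrix(rnorm(p2 * d), p2, d))))
  coh <- make_dual_layer_cohort(mdl, basis, shell_gap = 0.3, K = 12, M = 4,
                                seed = 9)
  sys <- build_dual_layer_system(basis, basis)
  out <- dual_layer_pipeline(coh$training, coh$test, sys, osp_config())
  expect_true(all(out$train_eof < 1))
  expect_true(all(out$test_eof < 1.5))
  # identical interior and exterior layers reconstruct identically
  twin <- lapply(coh$training, function(s) list(interior = s$interior,
                                                exterior = s$interior))
  out2 <- dual_layer_pipeline(twin, list(), sys, osp_config())
  expect_lt(max(abs(out2$train[[1]]$interior - out2$train[[1]]$exterior)),
            1e-8)
  # zeroing one layer's code sub-block zeroes only that layer
  cd <- out$train[[1]]$codes[[1]]
  A <- out$dictionaries[[1]]$subspaces[[cd$block_id]]$basis
  fhat <- drop(A %*% cd$in_block)
  p <- p2 / 2
  fhat[p + seq_len(p)] <- 0
  rec <- dual_layer_reconstruct(sys, fhat)
  expect_true(all(rec$exterior == 0))
  expect_false(all(rec$interior == 0))
})
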