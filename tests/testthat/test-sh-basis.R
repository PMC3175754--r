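# Real spherical-harmonic basis: closed forms, an independently computed
# reference (scipy.special.sph_harm_y real combinations, frozen), discrete
# orthonormality under area-weighted quadrature, and least-squares fitting.

test_that("real_sh_value matches closed forms and the frozen reference", {
  expect_equal(real_sh_value(0, 0, 0.77, 2.1), 1 / (2 * sqrt(pi)))
  expect_equal(real_sh_value(1, 0, 0, 0), sqrt(3 / (4 * pi)))
  expect_equal(real_sh_value(1, 1, 0, 0), 0)
  # frozen independent reference values (sqrt(2) Re/Im combinations of the
  # complex harmonics with Condon-Shortley phase)
  ref <- list(
    list(2, 1, 0.7, 2.3, 0.35867355749364704),
    list(3, -2, 1.2, 4.0, 0.4501104649052495),
    list(5, 5, 2.0, 0.9, 0.08600990408006855),
    list(10, -7, 1.9, 5.5, -0.21814311274931758),
    list(20, 13, 0.4, 3.3, -0.00226003591515023),
    list(30, -30, 1.5, 2.2, -0.024575791478002543))
  for (r in ref)
    expect_equal(real_sh_value(r[[1]], r[[2]], r[[3]], r[[4]]), r[[5]],
                 tolerance = 1e-12)
  expect_error(real_sh_value(2, 3, 0.5, 0.5), "invalid order")
})

test_that("build_basis has the documented shape and column order", {
  param <- sh_parameterization(c(0.2, 1.1, 2.4), c(0.3, 3.1, 5.9))
  b0 <- build_basis(param, 0)
  expect_equal(dim(b0$matrix), c(3L, 1L))
  expect_true(all(abs(b0$matrix - 1 / (2 * sqrt(pi))) < 1e-15))
  b20 <- build_basis(param, 20)
  expect_equal(ncol(b20$matrix), 441L)
  ico <- fix_icosphere(1)
  b1 <- build_basis(sphere_directions_to_parameterization(ico), 1)
  expect_equal(dim(b1$matrix), c(12L, 4L))
  expect_equal(b1$column_order[, "l"], c(0L, 1L, 1L, 1L))
  expect_equal(b1$column_order[, "m"], c(0L, -1L, 0L, 1L))
  # entries agree with scalar evaluation
  p <- sphere_directions_to_parameterization(ico)
  expect_equal(b1$matrix[3, 4],
               real_sh_value(1, 1, p$theta[3], p$phi[3]))
  expect_error(build_basis(param, -1), "invalid degree")
  expect_true(all(colSums(abs(b20$matrix)) > 0))
})

test_that("discrete Gram matrix is near-identity under vertex-area weights", {
  # quadrature check of orthonormality: sum_k w_k Y_lm(k) Y_l'm'(k) with
  # w_k the per-vertex share of the sphere area (one third of incident
  # triangle areas) approximates the continuous inner product
  for (L in c(4, 10)) {
    ico <- fix_icosphere(2 * L)
    basis <- fix_basis(2 * L, L)
    v <- ico$vertices
    f <- ico$faces + 1L
    a <- v[f[, 1], ]; b <- v[f[, 2], ]; cc <- v[f[, 3], ]
    cr <- cbind(
      (b - a)[, 2] * (cc - a)[, 3] - (b - a)[, 3] * (cc - a)[, 2],
      (b - a)[, 3] * (cc - a)[, 1] - (b - a)[, 1] * (cc - a)[, 3],
      (b - a)[, 1] * (cc - a)[, 2] - (b - a)[, 2] * (cc - a)[, 1])
    area <- 0.5 * sqrt(rowSums(cr^2))
    w <- numeric(nrow(v))
    for (j in 1:3) {
      agg <- tapply(area / 3, f[, j], sum)
      w[as.integer(names(agg))] <- w[as.integer(names(agg))] + agg
    }
    w <- w * 4 * pi / sum(w)
    G <- crossprod(basis$matrix * w, basis$matrix)
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-2)
  }
})

test_that("least-squares fit recovers band-limited functions exactly", {
  basis <- fix_basis(8, 10)
  set.seed(31)
  fstar <- rnorm(121)
  x <- shd_reconstruct(fstar, basis)
  fhat <- shd_fit(x, basis)
  expect_lt(sqrt(sum((fhat$values - fstar)^2)) / sqrt(sum(fstar^2)), 1e-8)
  expect_equal(shd_reconstruct(fhat, basis), x, tolerance = 1e-8)
  # constant function maps entirely to the (0,0) coefficient
  fc <- shd_fit(rep(2.5, nrow(basis$matrix)), basis)
  expect_equal(fc$values[1], 2.5 * 2 * sqrt(pi), tolerance = 1e-8)
  expect_lt(max(abs(fc$values[-1])), 1e-8)
  # sphere x-coordinate is a pure degree-1 harmonic
  ico <- fix_icosphere(8)
  fx <- shd_fit(ico$vertices[, 1], basis)
  en <- fx$values^2
  expect_gt(sum(en[2:4]) / sum(en), 0.999)
})

test_that("fit is linear and errors are raised for bad inputs", {
  basis <- fix_basis(8, 10)
  set.seed(7)
  x <- rnorm(642); y <- rnorm(642)
  fl <- shd_fit(2 * x - 3 * y, basis)$values
  expect_equal(fl, 2 * shd_fit(x, basis)$values - 3 * shd_fit(y, basis)$values,
               tolerance = 1e-10)
  small <- sh_parameterization(c(0.4, 1.2), c(0.1, 2))
  expect_error(shd_fit(c(1, 2), build_basis(small, 3)), "underdetermined")
  expect_error(shd_reconstruct(sh_coefficients(numeric(16), 3), basis),
               "degree mismatch")
  # coincident sampling points make the design rank-deficient
  dup <- sh_parameterization(rep(0.7, 30), rep(1.1, 30))
  expect_error(shd_fit(rnorm(30), build_basis(dup, 4)), "rank")
})

test_that("fit_surface decomposes axes independently and handles degeneracy", {
  basis <- fix_basis(8, 4)
  ico <- fix_icosphere(8)
  cf <- fit_surface(ico$vertices, basis)
  rec <- vapply(cf, function(f) shd_reconstruct(f, basis), numeric(642))
  expect_true(all(eof(rec, ico$vertices, per_axis = TRUE) < 0.1))
  zero <- fit_surface(matrix(0, 642, 3), basis)
  expect_true(all(vapply(zero, function(f) max(abs(f$values)), 1) == 0))
  tab <- coefficients_table(cf)
  expect_equal(nrow(tab), 3 * 25)
  expect_equal(tab$value[tab$axis == "x"], cf$x$values)
})
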