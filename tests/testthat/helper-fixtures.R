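# Shared fixtures, all generated in code. Memoized so each expensive object
# is built once per test run.
.fix <- new.env(parent = emptyenv())

fix_icosphere <- function(f) {
  key <- paste0("ico", f)
  if (is.null(.fix[[key]])) .fix[[key]] <- build_icosphere(f)
  .fix[[key]]
}

fix_basis <- function(f, L) {
  key <- sprintf("basis_%d_%d", f, L)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- build_basis(
      sphere_directions_to_parameterization(fix_icosphere(f)), L)
  .fix[[key]]
}

# sphere-based deformation cohort on a frequency-8 icosphere at L = 10
fix_sphere_cohort <- function(noise_sd = 0, seed = 5) {
  key <- sprintf("coh_%g_%d", noise_sd, seed)
  if (is.null(.fix[[key]])) {
    base <- make_base_shape("sphere", frequency = 8)
    basis <- fix_basis(8, 10)
    f0 <- fit_surface(surface_coords(base), basis)
    mdl <- planted_model(10, dims = c(4, 4, 4), base_coeffs = f0,
                         amplitude = 0.03, noise_sd = noise_sd, seed = seed)
    .fix[[key]] <- sample_planted_cohort(mdl, K = 30, M = 10, basis = basis,
                                         seed = seed + 1)
  }
  .fix[[key]]
}

# non-star-shaped "dumbbell": two overlapping spheres superimposed in one
# mesh, both containing the origin, so every ray crosses both surfaces
fix_dumbbell <- function() {
  if (is.null(.fix$dumbbell)) {
    ico <- fix_icosphere(4)
    v1 <- sweep(ico$vertices * 0.45, 2L, c(0.3, 0, 0), "+")
    v2 <- sweep(ico$vertices * 0.45, 2L, c(-0.3, 0, 0), "+")
    n <- nrow(ico$vertices)
    .fix$dumbbell <- surface_mesh(rbind(v1, v2),
                                  rbind(ico$faces, ico$faces + n),
                                  validate = FALSE)
  }
  .fix$dumbbell
}

expect_monotone <- function(x, direction = c("nonincreasing", "nondecreasing"),
                            tol = 1e-12) {
  direction <- match.arg(direction)
  d <- diff(x)
  if (direction == "nonincreasing") expect_true(all(d <= tol))
  else expect_true(all(d >= -tol))
}
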