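# shared fixtures and independent oracles for the test suite

rb82 <- dynodose::default_nuclide()
sched7 <- dynodose::default_schedule()
lam82 <- dynodose::decay_constant(rb82)

# independent quadrature oracle for the TIA integral (kBq s / mL)
tia_quadrature <- function(a1, a2, mu1, mu2, lambda) {
  f <- function(t) (a1 * exp(-mu1 * t) + a2 * exp(-mu2 * t)) * exp(-lambda * t)
  stats::integrate(f, 0, 50 * log(2) / lambda, rel.tol = 1e-10,
                   subdivisions = 2000L)$value
}

# one-organ phantom: a cube of `half*2+1` voxels per edge in a small grid
one_organ_phantom <- function(a1 = 10, a2 = -10, mu1 = 1e-4, mu2 = 0.05,
                              half = 4, grid = c(16L, 16L, 16L),
                              voxel_size_mm = 4, body_a1 = 0,
                              center = round(grid / 2)) {
  specs <- list(
    list(organ_id = 1L, name = "organ", shape = "box",
         center = center, half_size = rep(half, 3),
         a1 = a1, a2 = a2, mu1 = mu1, mu2 = mu2, carve_id = NULL))
  if (body_a1 > 0) {
    scale <- body_a1 / a1
    specs <- c(specs, list(list(organ_id = 0L, name = "body", shape = "box",
                                center = c(0, 0, 0), half_size = c(0, 0, 0),
                                a1 = a1 * scale, a2 = a2 * scale, mu1 = mu1,
                                mu2 = mu2, carve_id = NULL)))
  }
  dynodose::generate_phantom(specs, grid, voxel_size_mm)
}
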