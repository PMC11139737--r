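test_that("tail rate: fitted when falling, physical fallback otherwise", {
  k <- tail_rate(2, 1, 0, 76, lam82)
  expect_equal(as.numeric(k), log(2) / 76, tolerance = 1e-12)
  expect_false(attr(k, "fallback"))
  k2 <- tail_rate(1, 1, 0, 76, lam82)
  expect_equal(as.numeric(k2), lam82)
  expect_true(attr(k2, "fallback"))
  k3 <- tail_rate(1, 0, 0, 76, lam82)
  expect_equal(as.numeric(k3), lam82)
  expect_error(tail_rate(1, 1, 76, 76, lam82), "greater")
})

test_that("two-point trapezoid plus tail matches hand arithmetic", {
  # midpoints 15/45 s, physical values 4/2: trapezoid 30*3 = 90,
  # rectangle edge 15*4 = 60, tail rate ln2/30, tail 2/(ln2/30)
  got <- trapezoid_tail_integral(c(15, 45), c(4, 2), lam82,
                                 left_edge = "rectangle")
  expect_equal(as.numeric(got), 90 + 60 + 2 / (log(2) / 30), tolerance = 1e-12)
  # triangle edge replaces 60 by 30
  got_tri <- trapezoid_tail_integral(c(15, 45), c(4, 2), lam82,
                                     left_edge = "triangle")
  expect_equal(as.numeric(got_tri), 90 + 30 + 2 / (log(2) / 30),
               tolerance = 1e-12)
  expect_error(trapezoid_tail_integral(15, 4, lam82), "two time points")
})

test_that("pure physical decay integrates to the mean lifetime within 2%", {
  # constant decay-corrected value c: physical curve is c*exp(-lambda t),
  # exact integral c/lambda; the rectangle edge matches a signal already
  # at speed in the first frame
  ph <- one_organ_phantom(a1 = 6, a2 = 0, mu1 = 0, mu2 = 0)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tmap <- voxel_tia_map(img, rb82, injected_MBq = 400,
                        left_edge = "rectangle")
  voxel_mL <- (img$voxel_size_mm / 10)^3
  exact <- seconds_to_hours(6 / lam82 * voxel_mL / 1000) / 400
  vals <- tmap$voxels[ph$labels$voxels == 1L]
  expect_equal(unique(round(vals / exact, 6)), 1, tolerance = 0.02)
  expect_equal(tmap$tail_fallback_fraction, 0)
})

test_that("zero image gives a zero TIA map and zero dose map", {
  ph <- one_organ_phantom(a1 = 0, a2 = 0, mu1 = 0, mu2 = 0)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tmap <- voxel_tia_map(img, rb82, 400)
  expect_true(all(tmap$voxels == 0))
  dmap <- dose_map_local(tmap, rb82)
  expect_true(all(dmap$voxels == 0))
})

test_that("voxel TIA respects the physical bound on noiseless data", {
  # for a biological curve that is non-increasing from injection, no voxel
  # can hold more cumulated activity than its first-midpoint concentration
  # extrapolated to t = 0 and decaying at the physical rate
  ph <- one_organ_phantom(a1 = 10, a2 = 0, mu1 = 1e-4, mu2 = 0)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tmap <- voxel_tia_map(img, rb82, 400)
  voxel_mL <- (img$voxel_size_mm / 10)^3
  bound <- seconds_to_hours(img$voxels[, , , 1] / lam82 * voxel_mL / 1000) / 400
  expect_true(all(tmap$voxels <= bound + 1e-15))
  # rising curves: still finite and non-negative everywhere
  ph2 <- one_organ_phantom()
  img2 <- simulate_frames(ph2$labels, ph2$kinetics, sched7, rb82)
  tmap2 <- voxel_tia_map(img2, rb82, 400)
  expect_true(all(is.finite(tmap2$voxels)) && all(tmap2$voxels >= 0))
})

test_that("local-mode dose reproduces hand unit arithmetic", {
  # one voxel of 8 mm^3, density 1, TIA 1 MBq h, 1 MeV per decay:
  # 3600e6 decays * 1.602e-13 J / 8e-6 kg = 72.09 Gy
  tmap <- structure(list(voxels = array(1, dim = c(1L, 1L, 1L)),
                         voxel_size_mm = 2, tail_fallback_fraction = 0,
                         left_edge = "rectangle"), class = "tia_map")
  nuc <- nuclide_spec("unit", half_life_s = 76,
                      mean_energy_per_decay_MeV = 1)
  dmap <- dose_map_local(tmap, nuc, density_g_per_mL = 1)
  expect_equal(dmap$voxels[1] / 1e6, 72.09, tolerance = 1e-3)  # uGy -> Gy
  # doubling density halves dose; dose linear in TIA and energy
  dmap2 <- dose_map_local(tmap, nuc, density_g_per_mL = 2)
  expect_equal(dmap2$voxels[1], dmap$voxels[1] / 2)
  nuc2 <- nuclide_spec("unit2", 76, mean_energy_per_decay_MeV = 3)
  expect_equal(dose_map_local(tmap, nuc2)$voxels[1], 3 * dmap$voxels[1])
  tmap2 <- tmap; tmap2$voxels <- tmap$voxels * 5
  expect_equal(dose_map_local(tmap2, nuc)$voxels[1], 5 * dmap$voxels[1])
})

test_that("kernel mode with a delta kernel equals local mode", {
  ph <- one_organ_phantom()
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tmap <- voxel_tia_map(img, rb82, 400)
  local <- dose_map_local(tmap, rb82)
  kern <- dose_map_kernel(tmap, delta_kernel(), rb82)
  expect_lt(max(abs(kern$voxels - local$voxels)), 1e-10 * max(local$voxels))
  expect_error(dose_map_kernel(tmap, array(1, dim = c(2L, 2L, 2L)), rb82),
               "odd-sized")
  bad <- gaussian_kernel(1, 1); bad[1] <- -bad[1]
  expect_error(dose_map_kernel(tmap, bad, rb82), ">= 0")
})

test_that("kernel convolution conserves energy", {
  ph <- one_organ_phantom()
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tmap <- voxel_tia_map(img, rb82, 400)
  local <- dose_map_local(tmap, rb82)
  kern <- dose_map_kernel(tmap, gaussian_kernel(sigma_vox = 1, half_width = 3),
                          rb82)
  # uniform density: total energy ~ sum of dose * mass ~ sum of dose
  expect_equal(sum(kern$voxels), sum(local$voxels), tolerance = 0.01)

  # uniform activity away from edges: kernel dose equals local dose
  interior <- array(FALSE, dim = dim(tmap$voxels))
  interior[5:12, 5:12, 5:12] <- TRUE
  tflat <- structure(list(voxels = array(1e-6, dim = dim(tmap$voxels)),
                          voxel_size_mm = 4, tail_fallback_fraction = 0,
                          left_edge = "rectangle"), class = "tia_map")
  lflat <- dose_map_local(tflat, rb82)
  kflat <- dose_map_kernel(tflat, gaussian_kernel(1, 3), rb82)
  expect_equal(kflat$voxels[interior], lflat$voxels[interior],
               tolerance = 1e-6)
})

test_that("organ dose from the map is the organ mean", {
  ph <- one_organ_phantom()
  dmap <- structure(list(voxels = array(2.5, dim = dim(ph$labels$voxels)),
                         voxel_size_mm = 4, mode = "local"),
                    class = "dose_map")
  od <- organ_dose_from_map(dmap, ph$labels)
  expect_equal(unname(od[["organ"]]), 2.5)
  small <- structure(list(voxels = array(1, dim = c(2L, 2L, 2L)),
                          voxel_size_mm = 4, mode = "local"),
                     class = "dose_map")
  expect_error(organ_dose_from_map(small, ph$labels), "grids differ")
})

test_that("local-mode organ dose equals TIA per mass times energy factor", {
  ph <- one_organ_phantom()
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tmap <- voxel_tia_map(img, rb82, 400)
  dmap <- dose_map_local(tmap, rb82)
  od <- organ_dose_from_map(dmap, ph$labels)
  sel <- ph$labels$voxels == 1L
  voxel_mL <- (img$voxel_size_mm / 10)^3
  organ_tia <- sum(tmap$voxels[sel])                   # MBq h / MBq
  mass_kg <- sum(sel) * voxel_mL / 1000
  expected <- organ_tia * 3600 * 1e6 *
    rb82$mean_energy_per_decay_MeV * 1.602e-13 / mass_kg * 1e6
  expect_equal(unname(od[["organ"]]), expected, tolerance = 1e-6)
})
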