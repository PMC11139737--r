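test_that("TAC extraction returns organ means, volumes and state", {
  ph <- one_organ_phantom(a1 = 7, a2 = 0, mu1 = 0, mu2 = 0)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tacs <- extract_tacs(img, ph$labels, injected_MBq = 400)
  expect_s3_class(tacs, "tac_table")
  expect_equal(nrow(tacs), 7)
  expect_equal(tacs$mean_kBq_per_mL, rep(7, 7), tolerance = 1e-12)
  expect_equal(tacs$volume_mL[1], ph$kinetics$organ$volume_mL)
  expect_true(attr(tacs, "decay_corrected"))

  # grid mismatch and empty organ error paths
  small <- label_map(array(1L, dim = c(2L, 2L, 2L)), c(`1` = "organ"))
  expect_error(extract_tacs(img, small, 400), "grids differ")
  empty_legend <- label_map(ph$labels$voxels, c(`1` = "organ", `5` = "ghost"))
  expect_error(extract_tacs(img, empty_legend, 400), "no voxels")
})

test_that("extracted TACs reproduce analytic frame averages exactly", {
  ph <- one_organ_phantom(a1 = 10, a2 = -10, mu1 = 1e-4, mu2 = 0.05)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tacs <- extract_tacs(img, ph$labels, 400)
  f <- frame_decay_correction_factor(sched7$start_s, sched7$end_s, lam82)
  analytic <- vapply(seq_len(7), function(j) {
    f[j] * stats::integrate(function(t) true_activity(ph$kinetics$organ, t, lam82),
                            sched7$start_s[j], sched7$end_s[j],
                            rel.tol = 1e-12)$value / sched7$dur_s[j]
  }, numeric(1))
  expect_equal(tacs$mean_kBq_per_mL[order(tacs$frame)], analytic,
               tolerance = 1e-10)
})

test_that("remainder row balances whole-body activity", {
  # organs tile only part of the body: background carries activity too
  ph <- one_organ_phantom(a1 = 10, a2 = 0, mu1 = 0, mu2 = 0, body_a1 = 10)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tacs0 <- extract_tacs(img, ph$labels, 400)
  tacs <- add_remainder(tacs0, img)
  expect_true("total body (remainder)" %in% tacs$organ)
  act <- organ_activity(tacs)
  voxel_mL <- (img$voxel_size_mm / 10)^3
  for (j in 1:7) {
    wb <- sum(img$voxels[, , , j]) * voxel_mL / 1000
    expect_equal(sum(act$activity_MBq[act$frame == j]), wb, tolerance = 1e-9)
  }
  # organ and body share the same uniform concentration: remainder fraction
  # is the background volume fraction
  n_organ <- sum(ph$labels$voxels == 1L)
  frac <- 1 - n_organ / length(ph$labels$voxels)
  rem <- act[act$organ == "total body (remainder)" & act$frame == 1, ]
  wb1 <- sum(img$voxels[, , , 1]) * voxel_mL / 1000
  expect_equal(rem$activity_MBq / wb1, frac, tolerance = 1e-9)
})

test_that("remainder is ~zero when organs tile the whole body", {
  vox <- array(1L, dim = c(6L, 6L, 6L))
  vox[4:6, , ] <- 2L
  labels <- label_map(vox, c(`1` = "left", `2` = "right"), voxel_size_mm = 4)
  kin <- list(organ_kinetics(1L, "left", a1 = 5, a2 = 0),
              organ_kinetics(2L, "right", a1 = 3, a2 = 0))
  img <- simulate_frames(labels, kin, sched7, rb82)
  tacs <- add_remainder(extract_tacs(img, labels, 400), img)
  rem <- tacs[tacs$organ == "total body (remainder)", ]
  expect_equal(rem$mean_kBq_per_mL, rep(0, 7), tolerance = 1e-12)
})

test_that("decay uncorrection at frame midpoints, and its inverse", {
  ph <- one_organ_phantom(a1 = 1, a2 = 0, mu1 = 0, mu2 = 0)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tacs <- extract_tacs(img, ph$labels, 400)
  un <- uncorrect_decay(tacs, lam82)
  expect_false(attr(un, "decay_corrected"))
  # frame 1 midpoint 15 s: 1.0 -> exp(-lambda * 15) = 0.8722
  expect_equal(un$mean_kBq_per_mL[un$frame == 1], 0.8722, tolerance = 1e-4)
  expect_error(uncorrect_decay(un, lam82), "already")
  re <- recorrect_decay(un, lam82)
  expect_equal(re$mean_kBq_per_mL, tacs$mean_kBq_per_mL, tolerance = 1e-14)
  expect_error(recorrect_decay(re, lam82), "already")
  # lambda = 0 is the identity
  un0 <- uncorrect_decay(tacs, 0)
  expect_equal(un0$mean_kBq_per_mL, tacs$mean_kBq_per_mL)
})

test_that("organ TACs are invariant under relabeling of ids", {
  ph <- one_organ_phantom()
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  t1 <- extract_tacs(img, ph$labels, 400)
  relabeled <- ph$labels
  relabeled$voxels[relabeled$voxels == 1L] <- 42L
  relabeled$legend <- c(`42` = "organ")
  t2 <- extract_tacs(img, relabeled, 400)
  expect_equal(t1$mean_kBq_per_mL, t2$mean_kBq_per_mL)
  expect_equal(t1$volume_mL, t2$volume_mL)
})

test_that("uncorrected whole-body activity is non-increasing over frames", {
  # closed system: constant biological concentration everywhere, so the
  # physical whole-body activity can only decay
  ph <- one_organ_phantom(a1 = 10, a2 = 0, mu1 = 0, mu2 = 0, body_a1 = 5)
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tacs <- add_remainder(extract_tacs(img, ph$labels, 400), img)
  un <- organ_activity(uncorrect_decay(tacs, lam82))
  wb <- vapply(1:7, function(j) sum(un$activity_MBq[un$frame == j]),
               numeric(1))
  expect_true(all(diff(wb) < 1e-12))
})

test_that("TAC CSV round-trips values, schedule and metadata", {
  ph <- one_organ_phantom()
  img <- simulate_frames(ph$labels, ph$kinetics, sched7, rb82)
  tacs <- extract_tacs(img, ph$labels, 407)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_csv(tacs, path)
  back <- read_tac_csv(path)
  expect_equal(back$mean_kBq_per_mL, tacs$mean_kBq_per_mL)
  expect_equal(attr(back, "injected_MBq"), 407)
  expect_equal(attr(back, "schedule")$mid_s, sched7$mid_s)
})
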