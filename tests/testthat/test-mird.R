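toy_svalues <- function() {
  load_svalues(system.file("extdata", "svalues_synthetic_toy.csv",
                           package = "dynodose", mustWork = TRUE))
}

toy_tia <- function(organs, values) {
  structure(data.frame(organ_id = seq_along(organs), organ = organs,
                       tia_MBq_h_per_MBq = values,
                       a1 = NA, a2 = NA, mu1_per_s = NA, mu2_per_s = NA,
                       residual_rms = NA, method = "fixture"),
            class = c("tia_table", "data.frame"))
}

test_that("S-value loader validates and retrieves entries", {
  s <- toy_svalues()
  expect_equal(nrow(s$entries), 9)
  expect_equal(get_svalue(s, "heart_wall", "heart_wall"), 2.0)
  expect_equal(get_svalue(s, "Heart wall", "Lungs"), 0.3)
  expect_equal(get_svalue(s, "liver", "nonexistent"), 0)
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("phantom,source,target,s_mGy_per_MBq_h",
               "t,a,a,1.0", "t,a,a,2.0"), dup)
  expect_error(load_svalues(dup), "duplicate")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("phantom,source,target,s_mGy_per_MBq_h", "t,a,a,-1"), neg)
  expect_error(load_svalues(neg), "negative")
})

test_that("organ-name aliases resolve content/wall and remainder dialects", {
  expect_equal(normalize_organ("Urinary bladder content"),
               "urinary_bladder_contents")
  expect_equal(normalize_organ("Heart content"), "heart_contents")
  expect_equal(normalize_organ(c("Total body", "total body (remainder)")),
               c("remainder", "remainder"))
  expect_equal(normalize_organ("Lung"), "lungs")
})

test_that("MIRD doses follow D = sum over sources of TIA x S", {
  # diagonal toy table: dose = TIA * S(T<-T) * 1000
  s_diag <- svalue_table("diag", c("liver", "remainder"),
                         c("liver", "liver"), c(1, 0))
  rep1 <- organ_doses(toy_tia(c("liver", "Total body"), c(0.002, 0)), s_diag)
  expect_equal(rep1$dose_uGy_per_MBq[rep1$target == "liver"], 2.0)

  # two sources by hand: 0.001*3 + 0.002*0.5 = 0.004 mGy/MBq = 4 uGy/MBq
  s2 <- svalue_table("toy2", c("a", "b", "b"), c("a", "a", "b"), c(3, 0.5, 1))
  rep2 <- organ_doses(toy_tia(c("a", "b"), c(0.001, 0.002)), s2)
  expect_equal(rep2$dose_uGy_per_MBq[rep2$target == "a"], 4.0)

  # zero TIA -> zero doses
  rep0 <- organ_doses(toy_tia(c("a", "b"), c(0, 0)), s2)
  expect_equal(rep0$dose_uGy_per_MBq, c(0, 0))
})

test_that("unresolved sources stop the computation by name", {
  s2 <- svalue_table("toy2", c("a"), c("a"), c(3))
  expect_error(organ_doses(toy_tia(c("a", "mystery"), c(1e-3, 1e-3)), s2),
               "mystery")
  expect_error(organ_doses(toy_tia(c("a", "Total body"), c(1e-3, 1e-3)), s2),
               "remainder")
})

test_that("organ doses are linear in TIA and order-invariant", {
  s <- toy_svalues()
  organs <- c("heart_wall", "lungs", "remainder")
  v <- c(0.0003, 0.002, 0.023)
  r1 <- organ_doses(toy_tia(organs, v), s)
  r2 <- organ_doses(toy_tia(organs, 2.5 * v), s)
  expect_equal(r2$dose_uGy_per_MBq, 2.5 * r1$dose_uGy_per_MBq)
  perm <- c(3, 1, 2)
  r3 <- organ_doses(toy_tia(organs[perm], v[perm]), s)
  expect_identical(r1$dose_uGy_per_MBq, r3$dose_uGy_per_MBq)
})

test_that("effective dose obeys the ICRP-103 weighting identities", {
  w1 <- tissue_weights("liver", 1.0, remainder_organs = character(0))
  expect_equal(effective_dose(c(liver = 1), w1), 1)

  w <- load_tissue_weights()
  expect_equal(sum(w$weights), 1)
  # all organs at dose d -> E = d
  all_orgs <- c(setdiff(names(w$weights), "remainder"), w$remainder_organs)
  doses <- stats::setNames(rep(0.7, length(all_orgs)), all_orgs)
  expect_equal(effective_dose(doses, w), 0.7)
  expect_equal(effective_dose(2 * doses, w), 1.4)

  # absent named tissues draw a warning and contribute zero
  expect_warning(effective_dose(c(liver = 1), w), "contribute 0")
  expect_error(tissue_weights(c("a", "b"), c(0.5, 0.4)), "sum to 1")
})

test_that("rest-vs-stress relative differences match the published pairs", {
  expect_equal(rest_stress_relative_difference(0.502, 0.553), -9.2)
  expect_equal(rest_stress_relative_difference(0.757, 0.745), 1.6)
  expect_equal(rest_stress_relative_difference(0.593, 0.597), -0.7)
  expect_equal(rest_stress_relative_difference(3, 3), 0.0)
  expect_error(rest_stress_relative_difference(1, 0), "stress")
})

test_that("dose ranges across subjects come straight from the tables", {
  t3 <- reference_table("mird_doses")
  expect_equal(unname(dose_range_summary(t3[, c("organ", grep("^p", names(t3), value = TRUE))],
                                         "Heart wall")),
               c(1.84, 2.78))
  t4 <- reference_table("voxel_doses")
  expect_equal(unname(dose_range_summary(t4, "Kidneys")), c(3.22, 5.37))
  single <- data.frame(organ = "Liver", p1_rest = 0.9)
  expect_equal(unname(dose_range_summary(single, "liver")), c(0.9, 0.9))
  expect_error(dose_range_summary(single, "spleen"), "absent")
})

test_that("any non-negative S-table keeps doses non-negative and E bounded", {
  t2 <- reference_table("tia")
  tia <- toy_tia(t2$organ, t2$p1_rest)
  w <- load_tissue_weights()
  # target vocabulary covering every weighted tissue, so E is a convex
  # combination of organ doses
  targets <- unique(c(tia$organ, setdiff(names(w$weights), "remainder"),
                      w$remainder_organs))
  s <- synthetic_svalue_table(targets)
  rep <- organ_doses(tia, s)
  expect_true(all(rep$dose_uGy_per_MBq >= 0))
  E <- suppressWarnings(effective_dose(rep, w))
  expect_gte(E, min(rep$dose_uGy_per_MBq))
  expect_lte(E, max(rep$dose_uGy_per_MBq))
})
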