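#' Load a bundled reference dose-study table
#'
#' Published per-subject tables from a three-subject rubidium-chloride
#' dynamic whole-body study ship with the package as plain CSV: subject
#' characteristics and injected activities, normalized TIA per source
#' organ, MIRD organ doses, voxel-dosimetry organ doses, and effective
#' doses, each with rest and stress columns per subject (and an ICRP 128
#' reference column where published).
#'
#' @param table One of `"subjects"`, `"tia"`, `"mird_doses"`,
#'   `"voxel_doses"`, `"effective"`.
#' @return A data frame.
#' @export
reference_table <- function(table = c("subjects", "tia", "mird_doses",
                                      "voxel_doses", "effective")) {
  table <- match.arg(table)
  file <- switch(table,
                 subjects = "table1_subjects.csv",
                 tia = "table2_tia.csv",
                 mird_doses = "table3_doses.csv",
                 voxel_doses = "table4_voxel_doses.csv",
                 effective = "table5_effective.csv")
  utils::read.csv(system.file("extdata", "paper_tables", file,
                              package = "dynodose", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Synthetic S-value table for a phantom's organ set
#'
#' A stand-in for proprietary reference-phantom S-values, labelled
#' synthetic throughout: self-dose dominates, anatomical neighbours see a
#' small cross-dose, and the remainder irradiates everything weakly. Good
#' enough to exercise the MIRD arithmetic end to end; carries no claim
#' about any real phantom.
#'
#' @param organs Character vector of source/target organ names.
#' @param self,cross,from_remainder S-values (mGy per MBq h) for
#'   self-dose, organ-to-organ cross dose, and remainder-to-organ dose.
#' @return An `svalue_table` with phantom id `"synthetic_phantom"`.
#' @export
synthetic_svalue_table <- function(organs, self = 1.5, cross = 0.05,
                                   from_remainder = 0.02) {
  organs <- unique(normalize_organ(organs))
  organs <- setdiff(organs, "remainder")
  src <- tgt <- character(0); S <- numeric(0)
  for (a in organs) {
    for (b in organs) {
      src <- c(src, a); tgt <- c(tgt, b)
      S <- c(S, if (a == b) self else cross)
    }
  }
  src <- c(src, rep("remainder", length(organs)))
  tgt <- c(tgt, organs)
  S <- c(S, rep(from_remainder, length(organs)))
  svalue_table("synthetic_phantom", src, tgt, S)
}

#' Compare a per-organ result table against a reference column
#'
#' @param values Named numeric vector (organ -> value) or data frame with
#'   `organ` plus one numeric column.
#' @param reference Named numeric vector of reference values.
#' @return Data frame `organ, value, reference, ratio, difference,
#'   exceeds_reference`, joined on normalized organ names.
#' @export
compare_to_reference <- function(values, reference) {
  if (is.data.frame(values)) {
    ncol_num <- which(vapply(values, is.numeric, logical(1)))[1]
    values <- stats::setNames(values[[ncol_num]], values$organ)
  }
  names(values) <- normalize_organ(names(values))
  names(reference) <- normalize_organ(names(reference))
  shared <- intersect(names(values), names(reference))
  shared <- shared[!is.na(reference[shared])]
  if (length(shared) == 0) {
    stop("no shared organ vocabulary between result and reference",
         call. = FALSE)
  }
  data.frame(organ = shared,
             value = unname(values[shared]),
             reference = unname(reference[shared]),
             ratio = unname(values[shared] / reference[shared]),
             difference = unname(values[shared] - reference[shared]),
             exceeds_reference = unname(values[shared] > reference[shared]))
}

#' Summary statistics of a bundled or computed dose study
#'
#' Collapses per-subject dose tables into the headline numbers of a
#' dosimetry study: per-organ min-max dose ranges for both dose methods,
#' the effective-dose range, and per-subject rest-vs-stress relative
#' differences of the effective dose.
#'
#' @param mird_doses,voxel_doses Data frames with `organ` and per-subject
#'   numeric columns (`<subject>_rest` / `<subject>_stress`).
#' @param effective One-row data frame in the same layout.
#' @param organs Organs to summarise.
#' @return A list with `mird_range`, `voxel_range` (data frames),
#'   `effective_range` (min/max), `effective_range_printed` (2 decimals),
#'   and `rest_stress_pct` (named by subject).
#' @export
study_summary <- function(mird_doses = reference_table("mird_doses"),
                          voxel_doses = reference_table("voxel_doses"),
                          effective = reference_table("effective"),
                          organs = c("Heart wall", "Kidneys", "Lungs")) {
  subj_cols <- function(df) {
    grep("_(rest|stress)$", names(df), value = TRUE)
  }
  range_df <- function(df) {
    do.call(rbind, lapply(organs, function(og) {
      r <- dose_range_summary(df[, c("organ", subj_cols(df))], og)
      data.frame(organ = og, min = r[["min"]], max = r[["max"]])
    }))
  }
  eff_cols <- subj_cols(effective)
  eff <- unlist(effective[1, eff_cols])
  subjects <- unique(sub("_(rest|stress)$", "", eff_cols))
  rs <- vapply(subjects, function(s) {
    rest_stress_relative_difference(eff[[paste0(s, "_rest")]],
                                    eff[[paste0(s, "_stress")]])
  }, numeric(1))
  names(rs) <- subjects
  eff_range <- c(min = min(eff), max = max(eff))
  list(mird_range = range_df(mird_doses),
       voxel_range = range_df(voxel_doses),
       effective_range = eff_range,
       effective_range_printed = sprintf("%.2f-%.2f", eff_range[["min"]],
                                         eff_range[["max"]]),
       rest_stress_pct = rs)
}

#' Read a simulated study back from disk
#'
#' Counterpart of [write_study()]: reads the dynamic NIfTI, the label-map
#' NIfTI and the ground-truth JSON.
#'
#' @param dir Directory written by [write_study()].
#' @param voxel_size_mm Voxel size of the stored volumes (mm).
#' @return A list with `image` (a `dynamic_image`), `labels` (a
#'   [label_map()]) and `truth` (the parsed ground-truth list).
#' @export
read_study <- function(dir, voxel_size_mm = 4) {
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  fr <- truth$schedule
  if (!is.matrix(fr)) fr <- do.call(rbind, fr)
  sched <- frame_schedule(fr[, 1], fr[, 2])
  vox <- as.array(RNifti::readNifti(file.path(dir, "dynamic.nii.gz")))
  lab <- as.array(RNifti::readNifti(file.path(dir, "labels.nii.gz")))
  storage.mode(lab) <- "integer"
  labels <- label_map(lab, unlist(truth$legend),
                      voxel_size_mm = voxel_size_mm)
  image <- dynamic_image(vox, voxel_size_mm, sched,
                         decay_corrected = isTRUE(truth$decay_corrected))
  list(image = image, labels = labels, truth = truth)
}

#' Run the full synthetic dosimetry pipeline for one scan
#'
#' Phantom -> dynamic frames -> TAC extraction with remainder -> kinetic
#' TIA table -> MIRD organ doses and effective dose -> voxel TIA and dose
#' maps -> organ doses from the map. The single entry point the analysis
#' scripts, the tests and the acceptance checks all drive.
#'
#' @param injected_MBq Injected activity (MBq).
#' @param nuclide,schedule Acquisition physics; defaults are the bundled
#'   rubidium configuration and seven-frame schedule.
#' @param organ_specs Phantom layout/kinetics; see [default_organ_specs()].
#' @param grid_shape,voxel_size_mm Phantom grid.
#' @param noise_scale Poisson noise scale for [simulate_frames()].
#' @param jitter Kinetic amplitude jitter across replicates.
#' @param seed RNG seed (jitter + noise).
#' @param svalues An `svalue_table`; default: a synthetic table over the
#'   phantom's organs.
#' @param weights A `tissue_weights`; default: bundled ICRP-103 factors.
#' @param subject,condition Metadata strings.
#' @return A list: `phantom`, `image`, `tacs`, `tia` (fitted table),
#'   `tia_truth` (closed-form ground truth per organ), `mird` (dose
#'   report), `effective_uSv_per_MBq`, `tia_map`, `dose_map`,
#'   `voxel_organ_doses`.
#' @export
run_scan <- function(injected_MBq = 400,
                     nuclide = default_nuclide(),
                     schedule = default_schedule(),
                     organ_specs = default_organ_specs(),
                     grid_shape = c(40L, 40L, 60L),
                     voxel_size_mm = 4,
                     noise_scale = 0, jitter = 0, seed = NULL,
                     svalues = NULL, weights = load_tissue_weights(),
                     subject = "synthetic", condition = "rest") {
  lambda <- decay_constant(nuclide)
  ph <- generate_phantom(organ_specs, grid_shape, voxel_size_mm,
                         jitter = jitter, seed = seed)
  img <- simulate_frames(ph$labels, ph$kinetics, schedule, nuclide,
                         noise_scale = noise_scale,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  tacs <- extract_tacs(img, ph$labels, injected_MBq)
  tacs <- add_remainder(tacs, img)
  tia <- tia_table(tacs, nuclide)
  truth <- vapply(ph$kinetics, function(k) {
    integral <- k$a1 / (lambda + k$mu1) + k$a2 / (lambda + k$mu2)
    seconds_to_hours(integral * k$volume_mL / 1000) / injected_MBq
  }, numeric(1))
  if (is.null(svalues)) {
    svalues <- synthetic_svalue_table(tia$organ)
  }
  mird <- organ_doses(tia, svalues, subject = subject, condition = condition)
  eff <- suppressWarnings(effective_dose(mird, weights))
  tmap <- voxel_tia_map(img, nuclide, injected_MBq)
  dmap <- dose_map_local(tmap, nuclide)
  vdose <- organ_dose_from_map(dmap, ph$labels)
  list(phantom = ph, image = img, tacs = tacs, tia = tia,
       tia_truth = truth, mird = mird, effective_uSv_per_MBq = eff,
       tia_map = tmap, dose_map = dmap, voxel_organ_doses = vdose)
}
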