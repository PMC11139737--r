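#!/usr/bin/env Rscript
# MIRD branch: organ absorbed doses from the fitted TIA tables using a
# synthetic S-value table (self-dose dominant; real reference-phantom
# S-values are proprietary and not bundled), then ICRP-103 effective dose.
# Writes per-scan dose CSVs and a study-level summary under results/mird/.

library(dynodose)

tia_root <- file.path("results", "tia")
out_root <- file.path("results", "mird")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

files <- list.files(tia_root, pattern = "_tia\\.csv$", full.names = TRUE)
if (length(files) == 0) stop("run analysis/03_fit_tia.R first")

weights <- load_tissue_weights()
eff <- list()
for (f in files) {
  scan <- sub("_tia\\.csv$", "", basename(f))
  tia <- utils::read.csv(f, stringsAsFactors = FALSE)
  class(tia) <- c("tia_table", "data.frame")
  svals <- synthetic_svalue_table(
    c(tia$organ, setdiff(names(weights$weights), "remainder"),
      weights$remainder_organs))
  parts <- strsplit(scan, "_")[[1]]
  rep <- organ_doses(tia, svals, subject = parts[1], condition = parts[2])
  utils::write.csv(rep, file.path(out_root, paste0(scan, "_doses.csv")),
                   row.names = FALSE)
  E <- suppressWarnings(effective_dose(rep, weights))
  eff[[scan]] <- data.frame(subject = parts[1], condition = parts[2],
                            effective_uSv_per_MBq = E)
  cat(sprintf("%s: max organ dose %.3g uGy/MBq (%s), E = %.3g uSv/MBq\n",
              scan, max(rep$dose_uGy_per_MBq),
              rep$target[which.max(rep$dose_uGy_per_MBq)], E))
}
eff <- do.call(rbind, eff)
utils::write.csv(eff, file.path(out_root, "effective_doses.csv"),
                 row.names = FALSE)

wide <- stats::reshape(eff, idvar = "subject", timevar = "condition",
                       direction = "wide")
rs <- rest_stress_relative_difference(
  wide$effective_uSv_per_MBq.rest, wide$effective_uSv_per_MBq.stress)
cat("rest-vs-stress effective-dose differences [%]:",
    paste(sprintf("%s %.1f", wide$subject, rs), collapse = ", "), "\n")
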