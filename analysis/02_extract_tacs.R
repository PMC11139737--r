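#!/usr/bin/env Rscript
# Read the simulated scans back from NIfTI and extract per-organ
# time-activity curves (plus the total-body remainder row); write one TAC
# CSV per scan under results/tacs/.

library(dynodose)

sim_root <- file.path("results", "sim")
out_root <- file.path("results", "tacs")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

scans <- list.dirs(sim_root, recursive = FALSE)
if (length(scans) == 0) stop("run analysis/01_simulate.R first")

for (dir in scans) {
  study <- read_study(dir)
  tacs <- extract_tacs(study$image, study$labels,
                       injected_MBq = study$truth$injected_MBq)
  tacs <- add_remainder(tacs, study$image)
  out <- file.path(out_root, paste0(basename(dir), ".csv"))
  write_tac_csv(tacs, out)
  peak <- max(tacs$mean_kBq_per_mL)
  cat(sprintf("%s: %d organs, peak %.1f kBq/mL -> %s\n",
              basename(dir), length(unique(tacs$organ)), peak, out))
}
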