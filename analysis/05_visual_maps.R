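#!/usr/bin/env Rscript

# Step 5 — colour-coded per-patient visual reports.
#
# Renders the TPM visual map (risk-coloured 13x13 grid per needle depth,
# annotated with cancer core lengths) for the first few cancer-bearing
# patients of the simulated cohort, with a machine-readable JSON per map.

suppressPackageStartupMessages({
  library(tpm3d)
  library(dplyr)
})

dir.create("results/maps", showWarnings = FALSE, recursive = TRUE)
files <- list.files("results/cohort", pattern = "^P\\d+\\.csv$",
                    full.names = TRUE)
n_done <- 0L
for (f in files) {
  cores <- read_core_table(f)
  if (!any(vapply(cores$foci, nrow, 0L) > 0)) next
  vm <- render_visual_map(cores)
  pid <- unique(cores$patient_id)
  save_visual_map(vm, png_path = file.path("results/maps",
                                           paste0(pid, ".png")),
                  json_path = file.path("results/maps", paste0(pid, ".json")))
  n_done <- n_done + 1L
  if (n_done >= 4L) break
}
message(sprintf("rendered %d visual maps under results/maps/", n_done))
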