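#!/usr/bin/env Rscript

# Step 4 — hotspot recovery against planted ground truth.
#
# One large Gleason 3+3 lesion per prostate with a 2 mm Gleason 4+4 focus at
# a controlled lateral offset (0 / 5 / 10 / 15 mm from the lesion centre).
# The pipeline should call offset-0 lesions concordant, the rest discordant,
# and recover the planted offset as the 3-D hotspot distance.

suppressPackageStartupMessages({
  library(tpm3d)
  library(dplyr)
  library(ggplot2)
})

coh <- make_offset_cohort(offsets = c(0, 5, 10, 15), n_per_offset = 10,
                          seed = 20260924L)
rep <- analyze_cohort(coh, ccl_modes = "separate")
m <- inner_join(rep,
                coh$truth |> select(patient_id, offset_mm, truth_concordant),
                by = "patient_id")

by_offset <- m |>
  group_by(offset_mm) |>
  summarise(n = dplyr::n(),
            classified_correctly = mean(concordant == truth_concordant),
            median_recovered_mm = median(distance_mm, na.rm = TRUE),
            median_abs_error_mm = median(abs(distance_mm - offset_mm),
                                         na.rm = TRUE))
print(by_offset)
readr::write_csv(by_offset, "results/hotspot_recovery.csv")

p <- ggplot(filter(m, !concordant),
            aes(factor(offset_mm), distance_mm)) +
  geom_boxplot(width = 0.4, outlier.shape = NA) +
  geom_jitter(width = 0.08, alpha = 0.6, size = 1.2) +
  geom_point(aes(y = offset_mm), colour = "red", shape = 4, size = 3) +
  labs(x = "planted focus offset (mm)",
       y = "recovered 3-D hotspot distance (mm)",
       title = "Discordant hotspot distances recover the planted offsets") +
  theme_minimal()
ggsave("results/hotspot_recovery.png", p, width = 6, height = 4, dpi = 150)
message("wrote results/hotspot_recovery.csv and .png")
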