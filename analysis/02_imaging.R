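#!/usr/bin/env Rscript
# Exercise the imaging chain on two batches: render raw hypercubes,
# round-trip them through ENVI, calibrate with their dark/white frames,
# segment the beans, extract per-bean mean spectra, and compare them
# with the generator's bean spectra.

library(beanspec)

out <- "results/02_imaging"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(sim_config(seed = 1L))
meta <- study$chemistry$meta
wl <- study$wavelengths

set.seed(2L)  # pixel jitter and frame noise
summary_rows <- NULL
for (b in c("B01", "B02")) {
  rows <- which(meta$batch_id == b)
  hc <- generate_hypercube(study$spectra[[1]][rows, ], wl, layout = c(2, 5))
  path <- file.path(out, paste0("cube_", b))
  write_envi(hc$raw, path)
  cube <- read_envi(path)
  refl <- calibrate_reflectance(cube, hc$dark, hc$white)
  mask <- segment_beans(refl)
  agree <- mean((mask == hc$mask)[hc$mask > 0])
  rel_dev <- sapply(seq_along(rows), function(i) {
    rec <- extract_mean_spectrum(refl, mask, i)$values
    max(abs(rec - study$spectra[[1]][rows[i], ]) /
          study$spectra[[1]][rows[i], ])
  })
  cat(sprintf("%s: %d beans found, %.1f%% pixel agreement, max rel. deviation %.3f%%\n",
              b, max(mask), 100 * agree, 100 * max(rel_dev)))
  summary_rows <- rbind(summary_rows,
                        data.frame(batch = b, beans_found = max(mask),
                                   pixel_agreement = agree,
                                   max_rel_deviation = max(rel_dev)))
}
write.csv(summary_rows, file.path(out, "imaging_summary.csv"),
          row.names = FALSE)
cat("Extraction errors are dominated by the 5% per-pixel jitter averaged",
    "over ~150 bean pixels.\n")
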