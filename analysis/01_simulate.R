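#!/usr/bin/env Rscript
# Simulate the single-bean study: 25 batches x 10 beans, both bean
# sides scanned over ~900-2500 nm, with ground-truth volatile profiles.
# Writes the reference tables and one example batch as an ENVI cube.

library(beanspec)

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
study <- simulate_study(cfg)
meta <- study$chemistry$meta

cat(sprintf("Simulated %d beans (%d batches x %d per batch), %d robusta.\n",
            nrow(meta), cfg$n_batches, cfg$beans_per_batch,
            sum(meta$species == "robusta")))

# ground truth: per-bean relative peak areas (% of total), plus design
write.csv(cbind(meta[, c("bean_id", "batch_id", "species")],
                as.data.frame(study$profiles)),
          file.path(out, "true_profiles.csv"), row.names = FALSE)
write.csv(data.frame(wavelength_nm = study$wavelengths),
          file.path(out, "wavelengths.csv"), row.names = FALSE)

# species contrast in the ground truth
roster <- load_roster()
cls <- t(apply(study$profiles, 1, group_by_class, roster = roster))
for (sp in c("arabica", "robusta"))
  cat(sprintf("%8s: pyrazines %.2f%%, aldehydes %.2f%% of total area\n", sp,
              mean(cls[meta$species == sp, "Pyrazine"]),
              mean(cls[meta$species == sp, "Aldehyde"])))

# one example batch rendered as a raw hypercube with its references
rows <- which(meta$batch_id == "B01")
hc <- generate_hypercube(study$spectra[[1]][rows, ], study$wavelengths,
                         layout = c(2, 5))
write_envi(hc$raw, file.path(out, "batch_B01_side1"))
write.csv(as.data.frame(hc$mask), file.path(out, "batch_B01_mask.csv"),
          row.names = FALSE)
cat(sprintf("Wrote example cube (%d x %d x %d) for batch B01 to %s.\n",
            dim(hc$raw$data)[1], dim(hc$raw$data)[2], dim(hc$raw$data)[3],
            out))
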