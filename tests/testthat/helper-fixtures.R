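# Shared fixtures: small deterministic study objects built in code.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_batches = 4, beans_per_batch = 5, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A small noise-free imaging scene: one batch of 10 beans on a 2x5 grid.
noiseless_scene <- function(seed = 7L) {
  cfg <- sim_config(n_batches = 1, beans_per_batch = 10, seed = seed)
  st <- simulate_study(cfg)
  hc <- generate_hypercube(st$spectra[[1]], st$wavelengths,
                           layout = c(2, 5), pixel_jitter = 0,
                           frame_noise_sd = 0)
  list(study = st, cube = hc)
}

# Averaged-side SNV-pretreated spectra and class-sum responses.
study_design_matrix <- function(study, method = "snv") {
  R <- (study$spectra[[1]] + study$spectra[[2]]) / 2
  keep <- band_window(study$wavelengths)
  X <- pretreat_matrix(R[, keep, drop = FALSE], study$wavelengths[keep],
                       pretreat_spec(method))
  rownames(X) <- study$chemistry$meta$bean_id
  X
}
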