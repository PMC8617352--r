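test_that("configuration validation catches bad counts and proportions", {
  expect_error(sim_config(n_batches = 0), "configuration error")
  expect_error(sim_config(beans_per_batch = 2.5), "configuration error")
  expect_error(sim_config(robusta_fraction = 1.2), "configuration error")
  expect_error(sim_config(signal_r2 = -0.1), "configuration error")
})

test_that("the design yields n_batches x beans_per_batch beans", {
  set.seed(1)
  chem <- generate_chemistry(sim_config(n_batches = 25, beans_per_batch = 10))
  expect_equal(nrow(chem$meta), 250)
  expect_equal(nrow(chem$concentrations), 250)
  expect_equal(length(unique(chem$meta$batch_id)), 25)
  expect_true(all(chem$concentrations >= 0))
  expect_true(all(is.finite(chem$z)))
})

test_that("a fixed seed fully determines the simulated study", {
  a <- simulate_study(tiny_config())
  b <- simulate_study(tiny_config())
  expect_identical(a$chemistry$concentrations, b$chemistry$concentrations)
  expect_identical(a$spectra, b$spectra)
  c2 <- simulate_study(tiny_config(seed = 12L))
  expect_false(identical(a$spectra[[1]], c2$spectra[[1]]))
})

test_that("robusta beans run higher in pyrazines and lower in aldehydes", {
  roster <- load_roster()
  n_big <- sim_config(n_batches = 1000, beans_per_batch = 10,
                      robusta_fraction = 1, seed = 5)
  set.seed(n_big$seed)
  rob <- generate_chemistry(n_big, roster)
  n_big$robusta_fraction <- 0
  set.seed(n_big$seed)
  ara <- generate_chemistry(n_big, roster)
  pyr <- roster$name[roster$chemical_class == "Pyrazine"]
  ald <- roster$name[roster$chemical_class == "Aldehyde"]
  d_pyr <- mean(rowSums(rob$concentrations[, pyr])) -
    mean(rowSums(ara$concentrations[, pyr]))
  d_ald <- mean(rowSums(rob$concentrations[, ald])) -
    mean(rowSums(ara$concentrations[, ald]))
  expect_gt(d_pyr, 0)
  expect_lt(d_ald, 0)
  # magnitude agrees with the configured +/-0.5 SD factor shift
  exp_pyr <- sum(beanspec:::COMPOUND_MEANS[pyr]) *
    n_big$factor_cv * n_big$species_shift
  expect_equal(d_pyr, exp_pyr, tolerance = 0.1)
})

test_that("profiles are closed to 100% and scale invariant", {
  conc <- c(a = 1, b = 1, c = 2)
  expect_equal(unname(chemistry_to_profile(conc)), c(25, 25, 50))
  expect_equal(chemistry_to_profile(conc), chemistry_to_profile(7 * conc))
  set.seed(3)
  chem <- generate_chemistry(tiny_config())
  prof <- profiles_matrix(chem)
  expect_equal(unname(rowSums(prof)), rep(100, nrow(prof)),
               tolerance = 1e-9)
  expect_error(chemistry_to_profile(c(a = 0, b = 0)), "degenerate")
  expect_error(chemistry_to_profile(c(a = -1, b = 2)), "non-negative")
})

test_that("compound abundances correlate more within than between classes", {
  roster <- load_roster()
  cfg <- sim_config(n_batches = 100, beans_per_batch = 10, seed = 21)
  set.seed(cfg$seed)
  chem <- generate_chemistry(cfg, roster)
  cc <- stats::cor(chem$concentrations)
  same_class <- outer(roster$chemical_class, roster$chemical_class, "==")
  diag(same_class) <- NA
  within <- mean(cc[same_class & !is.na(same_class)])
  between <- mean(cc[!same_class & !is.na(same_class)])
  expect_gt(within, between)
  expect_gt(within, 0.5)
})

test_that("the forward model is deterministic given the latent factors", {
  cfg <- tiny_config(noise_sd = 0, scatter_sd = 0)
  set.seed(1)
  chem <- generate_chemistry(cfg)
  b1 <- bean_chemistry(chem, 1)
  b2 <- b1; b2$bean_id <- "clone"
  s1 <- profile_to_spectrum(b1, cfg)
  s2 <- profile_to_spectrum(b2, cfg)
  expect_identical(s1$values, s2$values)
  expect_equal(s1$mode, "reflectance")
  expect_true(all(s1$values > 0 & s1$values <= 1))
})

test_that("reflectance stays in (0, 1] for every simulated bean", {
  st <- simulate_study(tiny_config(scatter_sd = 0.15, noise_sd = 0.01))
  for (side in st$spectra) {
    expect_true(all(side > 0))
    expect_true(all(side <= 1))
  }
})

test_that("a noiseless design recovers the latent factors exactly", {
  cfg <- sim_config(n_batches = 10, beans_per_batch = 10, signal_r2 = 1,
                    noise_sd = 0, scatter_sd = 0, seed = 17)
  st <- simulate_study(cfg)
  # absorbance is exactly linear in the expressed factors
  A <- -log10(st$spectra[[1]])
  x <- st$chemistry$x
  for (k in seq_len(ncol(x))) {
    fit <- stats::lm.fit(cbind(1, A), x[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, k] - mean(x[, k]))^2)
    expect_equal(r2, 1, tolerance = 1e-9)
  }
  # after SNV the per-spectrum SD rescaling is mildly nonlinear in the
  # factors, so recovery is near- but not machine-exact
  S <- pretreat_matrix(st$spectra[[1]], st$wavelengths, pretreat_spec("snv"))
  fit <- stats::lm.fit(cbind(1, S), x[, 1])
  r2 <- 1 - sum(fit$residuals^2) / sum((x[, 1] - mean(x[, 1]))^2)
  expect_gt(r2, 0.999)
})

test_that("hypercube layout, masks and background obey the scene contract", {
  sc <- noiseless_scene()
  hc <- sc$cube
  expect_equal(max(hc$mask), 10)
  expect_equal(length(unique(hc$mask[hc$mask > 0])), 10)
  # background darker than beans at 1100 nm
  b <- which.min(abs(sc$study$wavelengths - 1100))
  plane <- hc$raw$data[, , b]
  expect_lt(mean(plane[hc$mask == 0]), mean(plane[hc$mask > 0]))
  # overfull layout errors
  expect_error(generate_hypercube(sc$study$spectra[[1]],
                                  sc$study$wavelengths, layout = c(1, 5)),
               "layout error")
})
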