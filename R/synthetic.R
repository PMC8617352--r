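# Synthetic single-bean study generator.
#
# No raw HSI scans or GC-MS profiles are publicly deposited for this
# kind of single-bean study, so the package carries a generative model
# with known ground truth: a low-rank latent-factor model of bean
# chemistry whose factors are expressed in the SWIR spectrum as
# Gaussian absorption bands at the overtone/combination wavelengths
# commonly assigned to roasted-coffee constituents.

# Latent roast factors and the chemical classes they drive.  Pyrazines,
# other heterocyclic N compounds and pyrroles share one Maillard factor
# (their common biochemical origin); Strecker aldehydes a second; sugar
# caramelisation products a third; phenolics and acids a fourth.
FACTOR_NAMES <- c("maillard_n", "strecker", "caramel", "phenolic_acid")

CLASS_FACTOR <- c("Pyrazine" = "maillard_n", "Heterocyclic N" = "maillard_n",
                  "Pyrrole" = "maillard_n", "Aldehyde" = "strecker",
                  "Ketone" = "caramel", "Furan" = "caramel",
                  "Alcohol" = "caramel", "Ester" = "caramel",
                  "Acetate" = "caramel", "Sulphide" = "caramel",
                  "Phenolic" = "phenolic_acid", "Acid" = "phenolic_acid")

# Mean relative abundance (arbitrary units) per roster compound, in
# roster (elution) order.  Chosen so class totals resemble a medium
# roast: pyrazines ~25% of total, acetic acid and furfuryl alcohol
# dominant singles, trace guaiacols.
COMPOUND_MEANS <- c(
  "acetaldehyde" = 0.8, "2-methylfuran" = 0.4, "3-methylbutanal" = 0.15,
  "2,3-butanedione" = 0.3, "2,3-pentanedione" = 0.25, "hexanal" = 0.1,
  "1-methyl-1H-pyrrole" = 0.4, "pyridine" = 8, "pyrazine" = 2.5,
  "2-methyl-pyrazine" = 8, "acetoin" = 0.2, "acetol" = 1.5,
  "2,5-dimethylpyrazine" = 3.5, "2,6-dimethylpyrazine" = 3.8,
  "ethylpyrazine" = 1.7, "2,3-dimethylpyrazine" = 1.0,
  "1-hydroxy-2-butanone" = 0.12, "3-ethylpyridine" = 0.17,
  "2-ethyl-6-methylpyrazine" = 1.9, "2-ethyl-5-methylpyrazine" = 1.2,
  "2-ethyl-3-methylpyrazine" = 0.8, "2,3-diethylpyrazine" = 0.05,
  "3-ethyl-2,5-dimethylpyrazine" = 1.5, "acetic acid" = 15,
  "furfural" = 6, "acetoxyacetone" = 0.35,
  "furfurylmethyl sulphide" = 0.15, "2-ethyl-3,5-dimethylpyrazine" = 0.05,
  "furaneol" = 0.35, "2-acetylfuran" = 1.2, "ethyl propanoate" = 0.3,
  "2-furanmethanol acetate" = 1.1, "propanoic acid" = 1.0,
  "5-methylfurfural" = 3.5, "2,3-butanediol" = 0.08,
  "2-formyl-1-methylpyrrole" = 0.5, "gamma-butyrolactone" = 0.35,
  "2-furanmethanol" = 9, "3-methyl-butanoic acid" = 1.1,
  "N-acetyl-4(H)-pyridine" = 0.22,
  "3-hydroxy-4,5-dimethyl-2(5H)-furanone" = 0.2,
  "3-methoxy-5-methyl-2-cyclopenten-1-one" = 0.07,
  "3-methyl-2-butenoic acid" = 0.01,
  "3-methyl-1,2-cyclopentanedione" = 0.7, "guaiacol" = 0.65,
  "2-(1H-pyrrol-2-yl)-ethanone" = 0.5, "2-formylpyrrole" = 0.9,
  "phenol" = 0.9, "4-ethylguaiacol" = 0.05, "4-vinylguaiacol" = 0.5)

# SWIR absorption bands (nm) used by the spectral forward model:
# O-H/N-H 1st overtones (1435, 1450), C-H 1st overtone (1680), O-H/CO
# combination and 2nd-overtone region (1940, 1975, 2050, 2100), and
# N-H/O-H/C-H combination bands (2276, 2300).
BAND_CENTRES <- c(1435, 1450, 1680, 1940, 1975, 2050, 2100, 2276, 2300)
BAND_WIDTHS  <- c(20, 22, 30, 50, 40, 40, 50, 28, 30)

# Per-factor weights on the absorption bands (rows follow FACTOR_NAMES).
FACTOR_BAND_WEIGHTS <- matrix(c(
  0.6, 0.8, 0.1, 0.0, 0.3, 0.7, 0.2, 0.1, 0.8,
  0.1, 0.0, 0.7, 0.5, 0.8, 0.2, 0.1, 0.6, 0.0,
  0.3, 0.2, 0.4, 0.7, 0.1, 0.5, 0.6, 0.3, 0.2,
  0.7, 0.3, 0.2, 0.1, 0.4, 0.1, 0.5, 0.7, 0.4),
  nrow = 4, byrow = TRUE,
  dimnames = list(FACTOR_NAMES, NULL))

FACTOR_BAND_AMPLITUDE <- 0.04  # absorbance units per unit latent score

#' Simulation configuration
#'
#' Defines the synthetic study: 25 batches of 10 beans each, scanned on
#' both sides over ~900-2500 nm, with a configurable fraction of the
#' latent chemistry variance expressed in the spectrum.
#'
#' @param n_batches Number of coffee batches (default 25).
#' @param beans_per_batch Beans sampled per batch (default 10).
#' @param robusta_fraction Fraction of batches that are Robusta; batches
#'   are single-species, as commercial lots are.
#' @param signal_r2 Proportion of each latent factor's variance
#'   (including the species shifts, scaled accordingly) that is
#'   expressed in the spectrum; this is the ceiling on the
#'   cross-validated R2 attainable by any downstream model, and 0 makes
#'   the spectrum carry no chemical information at all.
#' @param noise_sd SD of i.i.d. spectral noise, absorbance units.
#' @param scatter_sd SD of the log multiplicative scatter gain; the
#'   additive baseline offset SD is 0.4 x this value.
#' @param species_shift Robusta mean shift, in latent-factor SD units,
#'   applied +ve to the Maillard/pyrazine factor and -ve to the
#'   Strecker/aldehyde factor.
#' @param batch_icc Intraclass correlation of latent factors within a
#'   batch (batch-level share of unit factor variance).
#' @param factor_cv Relative concentration change per latent-factor SD.
#' @param class_wobble SD of the per-bean class-specific relative
#'   deviation shared by compounds of one class.
#' @param compound_noise SD of the per-compound idiosyncratic relative
#'   deviation.
#' @param n_bands Spectral channels across 900-2500 nm (default 256,
#'   ~6 nm sampling).
#' @param seed Integer seed; fully determines all outputs of
#'   [simulate_study()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_batches = 25, beans_per_batch = 10,
                       robusta_fraction = 0.2, signal_r2 = 0.7,
                       noise_sd = 0.002, scatter_sd = 0.05,
                       species_shift = 0.5, batch_icc = 0.3,
                       factor_cv = 0.15, class_wobble = 0.015,
                       compound_noise = 0.015, n_bands = 256,
                       seed = 1L) {
  if (n_batches < 1 || beans_per_batch < 1 ||
      n_batches != round(n_batches) || beans_per_batch != round(beans_per_batch))
    stop("configuration error: counts must be positive integers")
  for (p in c(robusta_fraction, signal_r2))
    if (is.na(p) || p < 0 || p > 1)
      stop("configuration error: proportions must lie in [0, 1]")
  if (noise_sd < 0 || scatter_sd < 0)
    stop("configuration error: noise scales must be non-negative")
  if (n_bands < 16) stop("configuration error: n_bands too small")
  structure(list(n_batches = as.integer(n_batches),
                 beans_per_batch = as.integer(beans_per_batch),
                 robusta_fraction = robusta_fraction,
                 signal_r2 = signal_r2, noise_sd = noise_sd,
                 scatter_sd = scatter_sd, species_shift = species_shift,
                 batch_icc = batch_icc, factor_cv = factor_cv,
                 class_wobble = class_wobble,
                 compound_noise = compound_noise,
                 n_bands = as.integer(n_bands), seed = as.integer(seed)),
            class = "sim_config")
}

#' Wavelength grid of the simulated camera
#' @param config A [sim_config()].
#' @return Numeric vector of wavelengths (nm), 900-2500.
#' @export
sim_wavelengths <- function(config) {
  seq(900, 2500, length.out = config$n_bands)
}

#' Generate bean-level chemistry with known ground truth
#'
#' Draws batch- and bean-level latent roast factors (unit variance,
#' split into a spectrally expressed part of variance `signal_r2` and
#' an unexpressed remainder), applies the Robusta species shifts
#' (higher pyrazine-factor, lower aldehyde-factor means), and maps
#' factors to non-negative per-compound relative abundances; compounds
#' of one chemical class share a factor plus a small class-level
#' deviation, giving positive within-class correlation.
#'
#' Uses the current RNG state; call via [simulate_study()] (which seeds
#' from `config$seed`) for fully reproducible output.
#'
#' @param config A [sim_config()].
#' @param roster Compound roster, default [load_roster()].
#' @return A `bean_chemistry_set`: list with `meta` (bean_index,
#'   bean_id, batch_id, species), latent factor matrices `z` (full) and
#'   `x` (spectrally expressed part), and `concentrations`
#'   (beans x compounds, arbitrary units).
#' @export
generate_chemistry <- function(config, roster = load_roster()) {
  stopifnot(inherits(config, "sim_config"))
  nb <- config$n_batches; bpb <- config$beans_per_batch
  n <- nb * bpb
  s <- config$signal_r2; icc <- config$batch_icc
  n_rob <- round(config$robusta_fraction * nb)
  rob_batches <- if (n_rob > 0) sample.int(nb, n_rob) else integer(0)
  batch <- rep(seq_len(nb), each = bpb)
  species <- ifelse(batch %in% rob_batches, "robusta", "arabica")
  bean_id <- sprintf("B%02d_%02d", batch, rep(seq_len(bpb), nb))

  K <- length(FACTOR_NAMES)
  draw_factor <- function() {
    b <- matrix(stats::rnorm(nb * K, sd = sqrt(icc)), nb, K)
    u <- matrix(stats::rnorm(n * K, sd = sqrt(1 - icc)), n, K)
    b[batch, , drop = FALSE] + u
  }
  v <- draw_factor()   # expressed component (unit variance)
  w <- draw_factor()   # unexpressed component (unit variance)
  shift <- matrix(0, n, K, dimnames = list(NULL, FACTOR_NAMES))
  shift[species == "robusta", "maillard_n"] <- config$species_shift
  shift[species == "robusta", "strecker"] <- -config$species_shift
  # expressed part: the spectral signature carries the share sqrt(s) of
  # both the bean-level variation and the species shift, so signal_r2=0
  # leaves the spectrum fully uninformative about the chemistry
  x <- sqrt(s) * (v + shift)
  z <- x + sqrt(1 - s) * w + (1 - sqrt(s)) * shift
  colnames(x) <- colnames(z) <- FACTOR_NAMES

  cls <- roster$chemical_class
  fac <- CLASS_FACTOR[cls]
  mu <- COMPOUND_MEANS[roster$name]
  if (anyNA(mu)) stop("generator means missing for some roster compounds")
  classes <- unique(cls)
  h <- matrix(stats::rnorm(n * length(classes), sd = config$class_wobble),
              n, length(classes), dimnames = list(NULL, classes))
  e <- matrix(stats::rnorm(n * nrow(roster), sd = config$compound_noise),
              n, nrow(roster))
  rel <- 1 + config$factor_cv * z[, fac, drop = FALSE] +
    h[, cls, drop = FALSE] + e
  conc <- pmax(rel, 0) %*% diag(mu)
  colnames(conc) <- roster$name
  rownames(conc) <- bean_id

  structure(list(meta = data.frame(bean_index = seq_len(n),
                                   bean_id = bean_id,
                                   batch_id = sprintf("B%02d", batch),
                                   species = species,
                                   stringsAsFactors = FALSE),
                 z = z, x = x, concentrations = conc,
                 config = config),
            class = "bean_chemistry_set")
}

#' Extract one bean's chemistry record
#' @param set A `bean_chemistry_set`.
#' @param i Bean index.
#' @return List with `bean_id`, `batch_id`, `species`, `latent_factors`,
#'   `expressed_factors`, `true_concentrations`.
#' @export
bean_chemistry <- function(set, i) {
  stopifnot(inherits(set, "bean_chemistry_set"),
            i >= 1, i <= nrow(set$meta))
  list(bean_index = i,
       bean_id = set$meta$bean_id[i],
       batch_id = set$meta$batch_id[i],
       species = set$meta$species[i],
       latent_factors = set$z[i, ],
       expressed_factors = set$x[i, ],
       true_concentrations = set$concentrations[i, ])
}

#' Convert concentrations to a relative peak-area profile
#'
#' Closes a bean's concentration vector to percentages of the total,
#' the form in which GC-MS volatile profiles are reported.
#'
#' @param chem A bean record from [bean_chemistry()], or a named
#'   non-negative concentration vector.
#' @return Named vector of relative peak areas summing to 100.
#' @export
chemistry_to_profile <- function(chem) {
  conc <- if (is.list(chem)) chem$true_concentrations else chem
  if (any(conc < 0)) stop("concentrations must be non-negative")
  tot <- sum(conc)
  if (tot <= 0) stop("degenerate input: all-zero concentration vector")
  100 * conc / tot
}

#' Relative peak-area profiles for a whole chemistry set
#' @param set A `bean_chemistry_set`.
#' @return beans x compounds matrix of % relative peak areas.
#' @export
profiles_matrix <- function(set) {
  t(apply(set$concentrations, 1, chemistry_to_profile))
}

# Per-factor loading spectra: Gaussian bands at the fixed centre list,
# orthogonalized (over the band grid) to the constant and the baseline
# spectrum so the per-spectrum SD used by SNV is constant to first
# order in the factors and SNV recovery of the factors stays unbiased.
factor_loading_spectra <- function(wavelengths) {
  nb <- length(BAND_CENTRES)
  G <- sapply(seq_len(nb), function(b)
    exp(-0.5 * ((wavelengths - BAND_CENTRES[b]) / BAND_WIDTHS[b])^2))
  G <- t(FACTOR_BAND_AMPLITUDE * FACTOR_BAND_WEIGHTS %*% t(G))  # bands x K
  M <- cbind(1, baseline_absorbance(wavelengths))
  G - M %*% solve(crossprod(M), crossprod(M, G))
}

# Smooth roasted-bean baseline absorbance (water/oil dominated).
baseline_absorbance <- function(wl) {
  0.55 + 0.25 * exp(-((wl - 1450) / 90)^2) +
    0.45 * exp(-((wl - 1930) / 110)^2) +
    0.12 * exp(-((wl - 2280) / 120)^2) +
    1e-4 * (wl - 900)
}

#' Simulate one bean-side reflectance spectrum
#'
#' Forward model: absorbance = baseline + sum over latent factors of
#' (expressed factor score) x (Gaussian-band loading spectrum), then a
#' multiplicative scatter gain (lognormal) and additive offset, plus
#' i.i.d. noise; returned as reflectance R = 10^(-absorbance) clipped
#' to (0, 1].
#'
#' Scatter and noise are drawn from the current RNG state; seed via
#' [simulate_study()] for reproducibility.
#'
#' @param chem A bean record from [bean_chemistry()].
#' @param config A [sim_config()].
#' @return A `bean_spectrum` in reflectance mode.
#' @export
profile_to_spectrum <- function(chem, config) {
  wl <- sim_wavelengths(config)
  G <- factor_loading_spectra(wl)
  absorb <- baseline_absorbance(wl) +
    as.vector(G %*% chem$expressed_factors[FACTOR_NAMES])
  gain <- exp(stats::rnorm(1, 0, config$scatter_sd))
  offset <- stats::rnorm(1, 0, 0.4 * config$scatter_sd)
  absorb <- gain * absorb + offset +
    stats::rnorm(length(wl), 0, config$noise_sd)
  refl <- pmin(pmax(10^(-absorb), .Machine$double.xmin), 1)
  new_spectrum(wl, refl, "reflectance")
}

#' Simulate the full single-bean study
#'
#' Seeds the RNG from `config$seed` and generates, in a fixed order,
#' the bean chemistry, true volatile profiles, and two per-bean
#' reflectance spectra (the two scanned bean sides, with independent
#' scatter and noise).
#'
#' @param config A [sim_config()].
#' @param roster Compound roster.
#' @return List with `chemistry`, `profiles` (beans x compounds, %),
#'   `wavelengths`, and `spectra` (list of two beans x bands
#'   reflectance matrices, one per side).
#' @export
simulate_study <- function(config = sim_config(), roster = load_roster()) {
  set.seed(config$seed)
  chem_set <- generate_chemistry(config, roster)
  profiles <- profiles_matrix(chem_set)
  n <- nrow(chem_set$meta)
  wl <- sim_wavelengths(config)
  sides <- lapply(1:2, function(side) {
    m <- t(vapply(seq_len(n), function(i)
      profile_to_spectrum(bean_chemistry(chem_set, i), config)$values,
      numeric(length(wl))))
    rownames(m) <- chem_set$meta$bean_id
    m
  })
  list(chemistry = chem_set, profiles = profiles, wavelengths = wl,
       spectra = sides, config = config)
}

#' Render beans into a raw hypercube with reference frames
#'
#' Lays beans out on a rectangular grid as ellipses (semi-axes 6 x 4
#' pixels) over a dark tray background, converts reflectance to raw
#' sensor counts via `raw = dark + R * (white - dark)`, and emits the
#' matching dark-current and white-reference frame stacks plus the
#' ground-truth label mask.
#'
#' @param spectra beans x bands matrix of reflectance values.
#' @param wavelengths Wavelength vector (nm).
#' @param layout `c(rows, cols)` grid; must hold all beans.
#' @param pixel_jitter Relative SD of per-pixel multiplicative jitter
#'   within a bean (default 0.05; set 0 for a noiseless cube).
#' @param frame_noise_sd SD (counts) of per-frame sensor noise on the
#'   dark/white acquisitions.
#' @param n_frames Number of dark/white frames acquired (default 100).
#' @return List with `raw` (a `hypercube`), `dark` and `white` (frames x
#'   samples x bands arrays), and `mask` (lines x samples integer
#'   label matrix, 0 = background).
#' @export
generate_hypercube <- function(spectra, wavelengths,
                               layout = c(2, 5), pixel_jitter = 0.05,
                               frame_noise_sd = 2, n_frames = 100) {
  n <- nrow(spectra)
  rows <- layout[1]; cols <- layout[2]
  if (rows * cols < n)
    stop("layout error: grid of ", rows, "x", cols,
         " cannot hold ", n, " beans without overlap")
  semi_l <- 6; semi_s <- 4          # ellipse semi-axes (pixels)
  cell_l <- 20; cell_s <- 16; margin <- 6
  lines <- rows * cell_l + 2 * margin
  samples <- cols * cell_s + 2 * margin
  nb <- length(wavelengths)

  mask <- matrix(0L, lines, samples)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% cols; c <- (i - 1) %% cols
    cl <- margin + r * cell_l + cell_l / 2
    cs <- margin + c * cell_s + cell_s / 2
    for (l in seq_len(lines)) for (s in seq_len(samples)) {
      if (((l - cl) / semi_l)^2 + ((s - cs) / semi_s)^2 <= 1)
        mask[l, s] <- i
    }
  }

  dark_mean <- outer(rep(1, samples), rep(1200, nb)) +
    30 * sin(2 * pi * seq_len(samples) / samples)
  envelope <- 0.35 + 0.65 * exp(-((wavelengths - 1300) / 500)^2)
  white_mean <- dark_mean + 13000 * outer(
    0.97 + 0.06 * cos(2 * pi * seq_len(samples) / samples), envelope)

  bg <- 0.04 + 0.01 * exp(-((wavelengths - 1100) / 300)^2)
  refl <- array(rep(bg, each = lines * samples), c(lines, samples, nb))
  for (i in seq_len(n)) {
    idx <- which(mask == i)
    jit <- if (pixel_jitter > 0)
      1 + stats::rnorm(length(idx), 0, pixel_jitter) else rep(1, length(idx))
    for (b in seq_len(nb)) {
      plane <- refl[, , b]
      plane[idx] <- pmin(pmax(spectra[i, b] * jit, 1e-6), 1)
      refl[, , b] <- plane
    }
  }

  raw <- array(0, c(lines, samples, nb))
  for (b in seq_len(nb)) {
    dm <- matrix(dark_mean[, b], lines, samples, byrow = TRUE)
    wm <- matrix(white_mean[, b], lines, samples, byrow = TRUE)
    raw[, , b] <- dm + refl[, , b] * (wm - dm)
  }

  frame_stack <- function(mean_sb) {
    a <- array(rep(mean_sb, each = n_frames), c(n_frames, samples, nb))
    if (frame_noise_sd > 0)
      a <- a + array(stats::rnorm(length(a), 0, frame_noise_sd), dim(a))
    a
  }
  list(raw = new_hypercube(raw, wavelengths, mode = "raw",
                           meta = list(source = "synthetic")),
       dark = frame_stack(dark_mean),
       white = frame_stack(white_mean),
       mask = mask)
}
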