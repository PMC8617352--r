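# End-to-end orchestration: simulate -> (optionally image/calibrate/
# segment/extract) -> pre-treat -> PLS2 with segmented CV -> metrics
# tables -> regression vectors -> segregation report.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic study.
#' @param pretreatments Character vector of pre-treatments compared
#'   (subset of log1R, snv, sg2).
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param target_sets Which response groupings to model: any of
#'   `"class"` (chemical-class sums + aldehyde/pyrazine ratio) and
#'   `"descriptor"` (odorant-series sums + positive/negative ratio).
#' @param lv_max Largest latent-variable count scanned.
#' @param n_segments Cross-validation segments (default 20).
#' @param lv_tolerance Parsimony slack for [select_lv()].
#' @param segregation_target Attribute sorted on in the segregation
#'   trial (default the pyrazine class sum).
#' @param segregation_fraction Tail fraction selected (default 0.10).
#' @param via_cubes If TRUE, route every bean through full hypercube
#'   rendering, ENVI round trip, calibration, segmentation and
#'   extraction; if FALSE (default) use the generator's bean spectra
#'   directly (identical up to imaging noise, much faster).
#' @param trim Drop detector-edge bands outside 950-2450 nm.
#' @param out_dir Optional directory for CSV/markdown artefacts.
#' @param seed Overrides `sim$seed` and seeds every stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       pretreatments = c("log1R", "snv", "sg2"),
                       sg_window = 11, sg_polyorder = 2,
                       target_sets = c("class", "descriptor"),
                       lv_max = 20, n_segments = 20, lv_tolerance = 0.02,
                       segregation_target = "Pyrazine",
                       segregation_fraction = 0.10,
                       via_cubes = FALSE, trim = TRUE,
                       out_dir = NULL, seed = NULL) {
  pretreatments <- match.arg(pretreatments, c("log1R", "snv", "sg2"),
                             several.ok = TRUE)
  target_sets <- match.arg(target_sets, c("class", "descriptor"),
                           several.ok = TRUE)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, pretreatments = pretreatments,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 target_sets = target_sets, lv_max = lv_max,
                 n_segments = n_segments, lv_tolerance = lv_tolerance,
                 segregation_target = segregation_target,
                 segregation_fraction = segregation_fraction,
                 via_cubes = via_cubes, trim = trim, out_dir = out_dir),
            class = "run_config")
}

#' Grouped response matrix for a set of profiles
#'
#' @param profiles beans x compounds matrix of relative peak areas (%).
#' @param roster Compound roster.
#' @param target_sets As in [run_config()].
#' @return beans x targets matrix: class sums (plus
#'   `Aldehydes/Pyrazines`) and/or descriptor sums (plus
#'   `Positive/Negative`); constant-zero classes are dropped.
#' @export
response_matrix <- function(profiles, roster = load_roster(),
                            target_sets = c("class", "descriptor")) {
  out <- NULL
  if ("class" %in% target_sets) {
    cs <- t(apply(profiles, 1, group_by_class, roster = roster))
    cs <- cs[, colSums(cs) > 0, drop = FALSE]
    ratio <- apply(profiles, 1, function(p)
      aldehyde_pyrazine_ratio(group_by_class(p, roster)))
    out <- cbind(cs, `Aldehydes/Pyrazines` = ratio)
  }
  if ("descriptor" %in% target_sets) {
    ds <- t(apply(profiles, 1, group_by_descriptor, roster = roster))
    pn <- apply(profiles, 1, positive_negative_ratio, roster = roster)
    out <- cbind(out, ds, `Positive/Negative` = pn)
  }
  out
}

# Bean spectra via the full imaging chain: render one hypercube per
# batch and side, ENVI round trip, calibrate, segment, extract.
spectra_via_cubes <- function(study, tmp_dir = tempfile("cubes")) {
  dir.create(tmp_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- study$chemistry$meta
  wl <- study$wavelengths
  out <- lapply(study$spectra, function(side_mat) {
    m <- matrix(NA_real_, nrow(meta), length(wl),
                dimnames = list(meta$bean_id, NULL))
    for (b in unique(meta$batch_id)) {
      rows <- which(meta$batch_id == b)
      hc <- generate_hypercube(side_mat[rows, , drop = FALSE], wl,
                               layout = c(2, 5))
      path <- file.path(tmp_dir, paste0("cube_", b))
      write_envi(hc$raw, path)
      cube <- read_envi(path)
      refl <- calibrate_reflectance(cube, hc$dark, hc$white)
      mask <- segment_beans(refl)
      if (max(mask) != length(rows))
        stop("pipeline stage segment: found ", max(mask),
             " beans in batch ", b, ", expected ", length(rows))
      for (i in seq_along(rows))
        m[rows[i], ] <- extract_mean_spectrum(refl, mask, i)$values
      unlink(paste0(path, c(".hdr", ".dat")))
    }
    m
  })
  out
}

#' Run the full analysis pipeline
#'
#' Simulates the study at the configured design, obtains per-bean
#' reflectance spectra (via the imaging chain or directly), averages
#' the two scanned sides, then for every configured pre-treatment fits
#' PLS2 models to the grouped responses with segmented cross-validation,
#' selects the latent-variable count by the parsimony rule, assembles
#' the metrics table, extracts regression vectors, and runs the
#' segregation trial with the best pre-treatment's model.
#'
#' @param config A [run_config()].
#' @return List with `study`, `responses`, per-pretreatment `models`
#'   and `cv` results, `lv_choice`, `metrics` (the combined table),
#'   `regression_vectors`, and `segregation`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  # fail fast: resolve the segregation target against the configured
  # groupings before any simulation or fitting
  allowed <- c(
    if ("class" %in% config$target_sets)
      c(CHEMICAL_CLASSES, "Aldehydes/Pyrazines"),
    if ("descriptor" %in% config$target_sets)
      c(ODOUR_DESCRIPTORS, "Positive/Negative"))
  if (!(config$segregation_target %in% allowed))
    stop("validation error: unknown segregation target '",
         config$segregation_target, "'")
  roster <- load_roster()
  study <- simulate_study(config$sim, roster)
  meta <- study$chemistry$meta
  wl <- study$wavelengths

  sides <- if (config$via_cubes) spectra_via_cubes(study) else study$spectra
  R <- (sides[[1]] + sides[[2]]) / 2   # average the two scanned sides
  rownames(R) <- meta$bean_id
  keep <- if (config$trim) band_window(wl) else rep(TRUE, length(wl))
  wl_used <- wl[keep]
  R <- R[, keep, drop = FALSE]

  Y <- response_matrix(study$profiles, roster, config$target_sets)

  plan <- cv_plan(meta$bean_id, n_segments = config$n_segments,
                  batch = meta$batch_id, seed = config$sim$seed)

  fits <- list(); cvs <- list(); lv_choice <- integer(0)
  metrics <- NULL
  for (pm in config$pretreatments) {
    spec <- pretreat_spec(pm, config$sg_window, config$sg_polyorder)
    X <- pretreat_matrix(R, wl_used, spec)
    cv <- cross_validate(X, Y, config$lv_max, plan)
    lv <- select_lv(cv, config$lv_tolerance)
    fit <- fit_pls2(X, Y, n_lv = lv, wavelengths = wl_used)
    met <- compute_metrics(Y, predict(fit, X), cv$predictions[, , lv])
    met <- cbind(pretreatment = pm, lv = lv, met)
    fits[[pm]] <- fit; cvs[[pm]] <- cv; lv_choice[pm] <- lv
    metrics <- rbind(metrics, met)
  }
  metrics <- report_metrics_table(metrics)

  # segregate with the pre-treatment whose target model cross-validates best
  tgt <- config$segregation_target
  best_pm <- metrics$pretreatment[metrics$response == tgt][
    which.max(metrics$r2_cv[metrics$response == tgt])]
  spec <- pretreat_spec(best_pm, config$sg_window, config$sg_polyorder)
  X_best <- pretreat_matrix(R, wl_used, spec)
  segregation <- run_segregation_trial(
    X_best, fits[[best_pm]], tgt, study$profiles, roster,
    fraction = config$segregation_fraction)

  reg_vectors <- lapply(fits, function(f)
    stats::setNames(lapply(colnames(Y), function(r)
      regression_vector(f, r)), colnames(Y)))

  result <- list(config = config, study = study, responses = Y,
                 wavelengths = wl_used, spectra = R, plan = plan,
                 models = fits, cv = cvs, lv_choice = lv_choice,
                 metrics = metrics, regression_vectors = reg_vectors,
                 segregation = segregation, best_pretreatment = best_pm)
  if (!is.null(config$out_dir)) write_report(result, config$out_dir)
  invisible(result)
}

#' Assemble the combined metrics table
#'
#' One row per (pre-treatment, target): latent variables, calibration
#' R2/RMSE, cross-validation R2/RMSE and RPD, rows sorted stably by
#' pre-treatment then target.
#'
#' @param metrics data.frame accumulated over pre-treatments with
#'   columns pretreatment, lv, response, r2_cal, rmse_cal, r2_cv,
#'   rmse_cv, rpd.
#' @return The sorted table.
#' @export
report_metrics_table <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0) stop("no fitted targets")
  ord <- order(match(metrics$pretreatment, unique(metrics$pretreatment)),
               match(metrics$response, unique(metrics$response)))
  out <- metrics[ord, c("pretreatment", "lv", "response", "r2_cal",
                        "rmse_cal", "r2_cv", "rmse_cv", "rpd")]
  rownames(out) <- NULL
  out
}

# Write pipeline artefacts (CSV tables + a small markdown report).
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metrics,
                   file.path(out_dir, "metrics_by_pretreatment.csv"),
                   row.names = FALSE)
  for (pm in names(result$cv)) {
    rc <- result$cv[[pm]]$rmsecv
    utils::write.csv(data.frame(lv = seq_len(nrow(rc)), rc,
                                check.names = FALSE),
                     file.path(out_dir, paste0("rmsecv_", pm, ".csv")),
                     row.names = FALSE)
    rv <- do.call(cbind, c(list(
      wavelength = result$regression_vectors[[pm]][[1]]$wavelength),
      lapply(result$regression_vectors[[pm]], function(d) d$coefficient)))
    utils::write.csv(as.data.frame(rv),
                     file.path(out_dir, paste0("regression_vectors_",
                                               pm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(result$segregation$summary,
                   file.path(out_dir, "segregation_summary.csv"),
                   row.names = FALSE)
  md <- c("# Single-bean aroma prediction report",
          "",
          sprintf("Seed: %d; design: %d batches x %d beans; CV: %d segments.",
                  result$config$sim$seed, result$config$sim$n_batches,
                  result$config$sim$beans_per_batch,
                  result$config$n_segments),
          sprintf("Chosen latent variables: %s.",
                  paste(sprintf("%s = %d", names(result$lv_choice),
                                result$lv_choice), collapse = ", ")),
          sprintf("Segregation target %s (fraction %.2f, pretreatment %s).",
                  result$segregation$target, result$segregation$fraction,
                  result$best_pretreatment),
          "",
          "See metrics_by_pretreatment.csv and segregation_summary.csv.")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
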