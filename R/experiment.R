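#' Configuration for an end-to-end synthetic experiment
#'
#' Bundles the study conditions: how many linear and subunit model cells
#' to simulate, the image set, trial counts, fitting settings, the
#' smoothing-scale grid, and which analysis stages to run. Per-stage
#' seeds are derived deterministically from the master seed.
#'
#' @param n_linear,n_subunit numbers of ground-truth linear and
#'   rectified-subunit cells.
#' @param n_images number of images (default 300, split 150/150 into
#'   training and held-out test images).
#' @param n_trials trials per image (default 10).
#' @param size_px,pixel_pitch image geometry.
#' @param spectral_exponent image amplitude-spectrum exponent.
#' @param rf_sigma_px range of ground-truth RF SDs, pixels (circular).
#' @param subunit_sigma subunit SD, micrometers.
#' @param target_fano trial-to-trial noise level.
#' @param restarts SC-model restarts per fit.
#' @param species inclusion/window preset.
#' @param scales smoothing-scale grid for the scale sweep, micrometers.
#' @param stages character vector of stages to run, a subset of
#'   `c("models", "paired", "scale_sweep")`.
#' @param seed master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_linear = 4, n_subunit = 4, n_images = 300,
                              n_trials = 10, size_px = 64, pixel_pitch = 7.5,
                              spectral_exponent = 1,
                              rf_sigma_px = c(6, 10), subunit_sigma = 15,
                              target_fano = 0.3, restarts = 20,
                              species = "salamander",
                              scales = seq(0, 195, by = 15),
                              stages = c("models", "paired"),
                              seed = 1) {
  stages <- if (length(stages) == 0) character(0)
  else match.arg(stages, c("models", "paired", "scale_sweep"),
                 several.ok = TRUE)
  structure(as.list(environment()), class = "experiment_config")
}

#' Run an end-to-end synthetic experiment
#'
#' Generates a shared natural-like image set, simulates ground-truth
#' linear and subunit cells, applies the inclusion filter, fits LN and SC
#' models on a training split and evaluates them on held-out images, runs
#' the paired-difference analysis, and optionally the smoothing-scale
#' sweep. Cells that fail a stage are logged and skipped. The result
#' carries a manifest (config, derived seeds, package version) from which
#' every number can be recomputed.
#'
#' @param config an [experiment_config()].
#' @return List with `cells` (per-cell data.frame), `population`
#'   (summary statistics including the paired Wilcoxon signed-rank test
#'   of LN vs SC performance), `scale_curves` (when run), `manifest`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$stages) == 0)
    stop("nothing to run: no stages enabled", call. = FALSE)
  cfg <- config
  images <- generate_images(cfg$n_images, size_px = cfg$size_px,
                            pixel_pitch = cfg$pixel_pitch,
                            spectral_exponent = cfg$spectral_exponent,
                            seed = derive_seed(cfg$seed, "images"))
  n_cells <- cfg$n_linear + cfg$n_subunit
  kinds <- rep(c("linear", "subunit"), c(cfg$n_linear, cfg$n_subunit))
  rows <- vector("list", n_cells)
  curves <- list()
  for (ci in seq_len(n_cells)) {
    row <- tryCatch(
      run_one_cell(ci, kinds[ci], images, cfg, curves_env = environment()),
      error = function(e) {
        warning(sprintf("cell %d skipped: %s", ci, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    rows[[ci]] <- row
  }
  cells <- do.call(rbind, rows)
  if (is.null(cells) || nrow(cells) == 0)
    stop("no cells survived the pipeline", call. = FALSE)
  population <- summarize_population(cells)
  manifest <- list(
    config = unclass(config),
    derived_seeds = list(images = derive_seed(cfg$seed, "images"),
                         cells = "derive_seed(seed, paste0('cell', i))"),
    package_version = as.character(utils::packageVersion("rgcsc")),
    r_version = R.version.string)
  list(cells = cells, population = population, scale_curves = curves,
       manifest = manifest)
}

run_one_cell <- function(ci, kind, images, cfg, curves_env) {
  sd_cell <- derive_seed(cfg$seed, paste0("cell", ci))
  rf <- with_seed(sd_cell, {
    s <- runif(1, cfg$rf_sigma_px[1], cfg$rf_sigma_px[2])
    cx <- runif(1, 0.4, 0.6) * (cfg$size_px - 1)
    cy <- runif(1, 0.4, 0.6) * (cfg$size_px - 1)
    gaussian_rf(c(cx, cy), diag(s^2, 2), pixel_pitch = cfg$pixel_pitch)
  })
  cell <- synthetic_cell(rf, polarity = "OFF", kind = kind,
                         subunit_sigma = cfg$subunit_sigma,
                         noise = noise_spec(target_fano = cfg$target_fano))
  counts <- simulate_flash_responses(cell, images, cfg$n_trials,
                                     seed = derive_seed(sd_cell, "resp"))
  inc <- inclusion_filter(counts, species = cfg$species)
  mean_counts <- rowMeans(counts)
  row <- data.frame(cell_id = ci, kind = kind,
                    diameter_um = effective_diameter(rf),
                    included = inc$include,
                    mean_fano = fano_factors(counts)$cell,
                    r2_ln = NA_real_, r2_sc = NA_real_,
                    improvement = NA_real_, w = NA_real_,
                    r_dlsc_dspikes = NA_real_, r_dimean_dspikes = NA_real_,
                    optimal_scale_um = NA_real_)
  if (!inc$include) return(row)
  ft <- feature_table(images, rf, polarity = cell$polarity)
  if ("models" %in% cfg$stages) {
    split <- split_train_test(length(images), seed = derive_seed(sd_cell, "split"))
    ln <- fit_ln(ft$i_mean[split$train], mean_counts[split$train],
                 seed = derive_seed(sd_cell, "ln"))
    sc <- fit_sc(ft$i_mean[split$train], ft$lsc[split$train],
                 mean_counts[split$train], restarts = cfg$restarts,
                 seed = derive_seed(sd_cell, "sc"))
    ev_ln <- evaluate_predictions(predict(ln, ft[split$test, ]),
                                  mean_counts[split$test])
    ev_sc <- evaluate_predictions(predict(sc, ft[split$test, ]),
                                  mean_counts[split$test])
    row$r2_ln <- ev_ln$r2
    row$r2_sc <- ev_sc$r2
    row$improvement <- prediction_improvement(ev_sc$r2, ev_ln$r2)
    row$w <- sc$w
  }
  if ("paired" %in% cfg$stages) {
    pc <- pair_correlations(make_pairs(ft, mean_counts))
    row$r_dlsc_dspikes <- pc$r_dlsc_dspikes
    row$r_dimean_dspikes <- pc$r_dimean_dspikes
  }
  if ("scale_sweep" %in% cfg$stages) {
    curve <- scale_sweep(images, rf, counts, scales = cfg$scales,
                         restarts = max(3, cfg$restarts %/% 4),
                         seed = derive_seed(sd_cell, "sweep"))
    row$optimal_scale_um <- optimal_scale(curve)$optimal_scale_um
    curves_env$curves[[as.character(ci)]] <- curve
  }
  row
}

summarize_population <- function(cells) {
  inc <- cells[cells$included & is.finite(cells$r2_ln), , drop = FALSE]
  out <- list(n_cells = nrow(cells), n_included = sum(cells$included))
  if (nrow(inc) >= 2) {
    out$r2_ln_mean <- mean(inc$r2_ln); out$r2_ln_sd <- sd(inc$r2_ln)
    out$r2_sc_mean <- mean(inc$r2_sc); out$r2_sc_sd <- sd(inc$r2_sc)
    out$improvement_mean <- mean(inc$improvement)
    out$improvement_median <- median(inc$improvement)
    wt <- tryCatch(wilcox.test(inc$r2_sc, inc$r2_ln, paired = TRUE),
                   error = function(e) NULL)
    out$wilcoxon_p <- if (!is.null(wt)) wt$p.value else NA_real_
  }
  by_kind <- split(inc$improvement, inc$kind)
  out$improvement_by_kind <- lapply(by_kind, function(x)
    list(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_))
  out
}
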