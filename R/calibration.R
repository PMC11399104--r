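#' Density-recall calibration line
#'
#' The fraction of missed localizations, and hence the recovered DOL,
#' depends linearly on the emitter density. The calibration stores the
#' ordinary-least-squares line `recall = cf_slope * density + cf_offset`
#' fitted on simulated data processed with the same settings as real data,
#' together with its validity range and a fingerprint of those settings.
#'
#' @param cf_slope recall change per (emitters/um^2).
#' @param cf_offset recall at zero density, in (0, 1.05].
#' @param density_range_um2 density interval `c(lo, hi)` the line was
#'   fitted on.
#' @param r_squared fit quality.
#' @param provenance settings fingerprint (hash) + seed.
#' @return Object of class `prodol_calibration`.
#' @export
density_calibration <- function(cf_slope, cf_offset, density_range_um2,
                                r_squared = NA_real_, provenance = "") {
  if (cf_offset <= 0 || cf_offset > 1.05) {
    stop("cf_offset must be in (0, 1.05]", call. = FALSE)
  }
  denom <- cf_slope * density_range_um2 + cf_offset
  if (any(denom <= 0)) {
    stop("correction denominator is non-positive inside the density range; calibration rejected",
         call. = FALSE)
  }
  structure(list(cf_slope = cf_slope, cf_offset = cf_offset,
                 density_range_um2 = density_range_um2,
                 r_squared = r_squared, provenance = provenance),
            class = "prodol_calibration")
}

#' @export
print.prodol_calibration <- function(x, ...) {
  cat(sprintf("<density calibration> recall = %.4f x density + %.4f (R^2 = %.3f, range %.2f-%.2f /um^2)\n",
              x$cf_slope, x$cf_offset, x$r_squared,
              x$density_range_um2[1], x$density_range_um2[2]))
  invisible(x)
}

#' Calibrate the density-recall line from simulations
#'
#' For each density of the grid, `n_replicates` cells are simulated and
#' processed with the full pipeline (segmentation, localization,
#' registration, cutoff optimization) using exactly the analysis settings
#' that will be used on real data. The recall of each cell is its measured
#' degree of colocalization divided by the known true DOL; recall and
#' measured in-mask target density are pooled per simulated density, and
#' the calibration line is the weighted OLS fit over those pooled points
#' (weights: pooled reference counts, the binomial sample size behind each
#' recall value).
#'
#' @param sim_cfg a [sim_config()] describing the imaging conditions;
#'   `probe_density_um2` and `true_dol` are overridden per grid point.
#' @param analysis_cfg an [analysis_config()].
#' @param density_grid_um2 at least 3 probe densities (emitters/um^2). The
#'   default spans up to 0.9 probes/um^2 so that at the calibration DOL of
#'   0.5 the measured target densities cover the densities met when
#'   analyzing highly labeled samples, avoiding extrapolation of the line.
#' @param true_dol labeling probability used for calibration, in (0, 1].
#' @param n_replicates simulated cells per density.
#' @param seed master RNG seed.
#' @return A [density_calibration()].
#' @export
calibrate_recall <- function(sim_cfg = sim_config(),
                             analysis_cfg = analysis_config(),
                             density_grid_um2 = c(0.05, 0.15, 0.3, 0.45,
                                                  0.6, 0.75, 0.9),
                             true_dol = 0.5, n_replicates = 12L, seed = 1L) {
  if (length(density_grid_um2) < 3L) {
    stop("density grid needs at least 3 points", call. = FALSE)
  }
  if (true_dol <= 0 || true_dol > 1) stop("true_dol must be in (0, 1]",
                                          call. = FALSE)
  seeds <- derive_seeds(seed, length(density_grid_um2))
  pts <- list()
  for (i in seq_along(density_grid_um2)) {
    cfg_i <- sim_cfg
    cfg_i$probe_density_um2 <- density_grid_um2[i]
    cfg_i$true_dol <- true_dol
    cells <- simulate_experiment(cfg_i, n_cells = n_replicates,
                                 seed = seeds[i])
    res <- analyze_experiment(cells, analysis_cfg)$results
    res <- res[res$qc_flags == "", , drop = FALSE]
    if (nrow(res)) {
      # aggregate to one point per simulated density: per-cell density and
      # DOC share detection noise, which would bias a per-cell regression
      area <- res$n_reference / res$ref_density_um2
      pts[[length(pts) + 1L]] <- data.frame(
        density = sum(res$density_measured_um2 * area) / sum(area),
        recall = sum(res$degree_of_colocalization * res$n_reference) /
          sum(res$n_reference) / true_dol,
        w = sum(res$n_reference))
    }
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 3L) {
    stop("too few usable calibration densities", call. = FALSE)
  }
  # pooled recall is a binomial fraction of the pooled reference count, so
  # the line is inverse-variance weighted by that count
  fit <- lm(recall ~ density, data = pts, weights = pts$w)
  cf <- coef(fit)
  r2 <- summary(fit)$r.squared
  density_calibration(
    cf_slope = unname(cf["density"]), cf_offset = unname(cf["(Intercept)"]),
    density_range_um2 = range(pts$density), r_squared = r2,
    provenance = paste0(settings_hash(unclass(analysis_cfg)), ":seed", seed))
}

#' Correct a degree of colocalization for density-dependent recall
#'
#' `DOL = DOC / (cf_slope * density + cf_offset)`. The result is clipped
#' to `[0, 1.5]`; values above 1 trigger a warning, as do densities
#' outside the calibration range.
#'
#' @param doc measured degree of colocalization.
#' @param density_measured_um2 reference localizations per um^2 of cell.
#' @param calibration a [density_calibration()].
#' @return The corrected DOL fraction.
#' @export
correct_dol <- function(doc, density_measured_um2, calibration) {
  rng <- calibration$density_range_um2
  if (density_measured_um2 < rng[1] || density_measured_um2 > rng[2]) {
    warning(sprintf("density %.3f/um^2 outside calibration range [%.3f, %.3f]",
                    density_measured_um2, rng[1], rng[2]))
  }
  denom <- calibration$cf_slope * density_measured_um2 + calibration$cf_offset
  if (denom <= 0) stop("correction denominator <= 0", call. = FALSE)
  dol <- doc / denom
  if (dol > 1) warning(sprintf("corrected DOL %.3f exceeds 1", dol))
  min(max(dol, 0), 1.5)
}
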