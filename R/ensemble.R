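#' Ensemble DOL from absorbance spectroscopy
#'
#' Labels per molecule from a UV-Vis measurement of a labeled protein:
#' `DOL = Abs_label * eps_target / (eps_label * (Abs_280 -
#' correction_280 * Abs_label))`, where `correction_280` accounts for the
#' label's own absorbance at 280 nm.
#'
#' @param abs_280 absorbance at 280 nm (protein).
#' @param abs_label absorbance at the label peak (e.g. 652 nm for SiR).
#' @param eps_target protein molar extinction coefficient (1/M/cm).
#' @param eps_label label molar extinction coefficient (1/M/cm).
#' @param correction_280 label 280 nm correction factor.
#' @return Mean labels per molecule.
#' @export
ensemble_dol <- function(abs_280, abs_label, eps_target, eps_label,
                         correction_280 = 0) {
  if (eps_target <= 0 || eps_label <= 0) {
    stop("extinction coefficients must be > 0", call. = FALSE)
  }
  if (abs_280 < 0 || abs_label < 0) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  corrected <- abs_280 - correction_280 * abs_label
  if (corrected <= 0) {
    stop("corrected protein absorbance is non-positive", call. = FALSE)
  }
  abs_label * eps_target / (eps_label * corrected)
}

#' Mean label count among labeled molecules
#'
#' Given the distribution of label counts per labeled molecule (from a
#' photon-statistics counting experiment), returns the pseudo-ensemble DOL
#' `sum(k * fraction(k))`.
#'
#' @param distribution named numeric vector or list mapping integer label
#'   counts (>= 1) to fractions; fractions must be non-negative and sum
#'   to 1.
#' @return Mean labels among labeled molecules.
#' @export
pseudo_ensemble_dol <- function(distribution) {
  fr <- unlist(distribution)
  if (length(fr) == 0L) stop("empty label-number distribution", call. = FALSE)
  k <- as.numeric(names(fr))
  if (anyNA(k) || any(k < 1)) {
    stop("distribution names must be integer label counts >= 1",
         call. = FALSE)
  }
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("fractions must be >= 0 and sum to 1", call. = FALSE)
  }
  sum(k * fr)
}

#' Fraction of unlabeled molecules
#'
#' The ensemble DOL averages over all molecules while the label-number
#' distribution only sees labeled ones, so
#' `unlabeled = 1 - ensemble_dol / labeled_mean`.
#'
#' @param ensemble_dol labels per molecule over all molecules (> 0).
#' @param labeled_mean mean labels among labeled molecules
#'   (>= `ensemble_dol`).
#' @return The unlabeled fraction in `[0, 1)`.
#' @export
unlabeled_fraction <- function(ensemble_dol, labeled_mean) {
  if (ensemble_dol <= 0) stop("ensemble_dol must be > 0", call. = FALSE)
  if (labeled_mean < ensemble_dol) {
    stop("labeled_mean < ensemble_dol: inconsistent inputs", call. = FALSE)
  }
  1 - ensemble_dol / labeled_mean
}

#' Round a fraction to a reporting percentage
#'
#' Round-half-away-from-zero to the nearest integer percent (so 0.0797
#' reports as 8).
#'
#' @param fraction a fraction.
#' @return Integer percent.
#' @export
dol_percent <- function(fraction) {
  p <- 100 * fraction
  sign(p) * floor(abs(p) + 0.5)
}

#' Extrapolate per-cluster copy numbers from labeled counts and DOL
#'
#' `copies = count / dol`; the relative standard error combines the
#' count's and the DOL's relative errors in quadrature.
#'
#' @param cluster_counts per-cluster labeled-molecule counts (>= 0).
#' @param dol degree of labeling used for extrapolation, in (0, 1].
#' @param dol_se standard error of `dol`.
#' @param count_se per-cluster count standard errors (default 0).
#' @return data.frame with `copies` and `copies_se`.
#' @export
copies_per_cluster <- function(cluster_counts, dol, dol_se = 0,
                               count_se = 0) {
  if (dol <= 0 || dol > 1) stop("dol must be in (0, 1]", call. = FALSE)
  copies <- cluster_counts / dol
  rel <- sqrt(ifelse(cluster_counts > 0, (count_se / cluster_counts)^2, 0) +
                (dol_se / dol)^2)
  data.frame(copies = copies, copies_se = copies * rel)
}

#' Log-normal fit of a positive-valued distribution
#'
#' Maximum-likelihood log-normal fit (mean and SD of the log values, the
#' SD with denominator n). Reported with the geometric mean
#' `exp(mu_log)` and its standard error by the delta method,
#' `gm * sigma_log / sqrt(n)`.
#'
#' @param values positive values, at least 3.
#' @return List with `mu_log`, `sigma_log`, `geometric_mean`,
#'   `se_geometric_mean`, `n`.
#' @export
fit_lognormal <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (any(values <= 0)) stop("all values must be > 0 for a log-normal fit",
                             call. = FALSE)
  lv <- log(values)
  n <- length(lv)
  mu <- mean(lv)
  sig <- sqrt(sum((lv - mu)^2) / n)
  gm <- exp(mu)
  list(mu_log = mu, sigma_log = sig, geometric_mean = gm,
       se_geometric_mean = gm * sig / sqrt(n), n = n)
}
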