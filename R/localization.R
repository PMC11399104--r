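#' Spot detection and fitting settings
#'
#' @param dog_low_px,dog_high_px band-pass sigmas (px) of the detection
#'   filter, bracketing the PSF scale.
#' @param peak_threshold_k detection threshold in units of the robust noise
#'   SD (MAD) of the filtered image.
#' @param fit_window_px odd fitting-box size, >= 5.
#' @param max_emitters_per_fit 1-3; above 1 a residual-driven refit adds
#'   emitters and keeps the model with the lower BIC.
#' @param sigma_window_fraction half-width of the PSF-width acceptance
#'   window around the modal sigma, as a fraction (default 0.5, i.e. +/-50%).
#' @param psf_sigma_nm initial PSF width for the fit (nm).
#' @return Object of class `prodol_detection`.
#' @export
detection_settings <- function(dog_low_px = 1, dog_high_px = 2,
                               peak_threshold_k = 4, fit_window_px = 7L,
                               max_emitters_per_fit = 3L,
                               sigma_window_fraction = 0.5,
                               psf_sigma_nm = 150) {
  fit_window_px <- as.integer(fit_window_px)
  if (fit_window_px %% 2L != 1L || fit_window_px < 5L) {
    stop("fit_window_px must be odd and >= 5", call. = FALSE)
  }
  if (!max_emitters_per_fit %in% 1:3) {
    stop("max_emitters_per_fit must be 1, 2 or 3", call. = FALSE)
  }
  structure(list(dog_low_px = dog_low_px, dog_high_px = dog_high_px,
                 peak_threshold_k = peak_threshold_k,
                 fit_window_px = fit_window_px,
                 max_emitters_per_fit = as.integer(max_emitters_per_fit),
                 sigma_window_fraction = sigma_window_fraction,
                 psf_sigma_nm = psf_sigma_nm),
            class = "prodol_detection")
}

#' Detect candidate spots as local maxima of a band-pass image
#'
#' Difference-of-Gaussians filtering followed by thresholding at
#' `peak_threshold_k` robust noise SDs and 8-neighborhood non-maximum
#' suppression. Candidates too close to the frame edge for a full fitting
#' window are dropped. Output order is row-major (deterministic).
#'
#' @param image an [image2d()].
#' @param settings a [detection_settings()].
#' @return Integer matrix with columns `row`, `col` (1-based pixel indices).
#' @export
detect_candidates <- function(image, settings = detection_settings()) {
  p <- image$pixels
  if (diff(range(p)) <= 0) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  }
  lo <- as.matrix(EBImage::gblur(p, sigma = settings$dog_low_px))
  hi <- as.matrix(EBImage::gblur(p, sigma = settings$dog_high_px))
  dog <- lo - hi
  thr <- settings$peak_threshold_k * mad(dog)
  w <- settings$fit_window_px
  # local maxima in the 8-neighborhood: emitters further apart than one
  # pixel stay separate candidates even when their windows overlap
  mx <- as.matrix(EBImage::dilate(dog, EBImage::makeBrush(3L, "box")))
  is_peak <- dog > thr & dog >= mx - 1e-12
  h <- w %/% 2L
  nr <- nrow(p); nc <- ncol(p)
  is_peak[c(seq_len(h), nr - seq_len(h) + 1L), ] <- FALSE
  is_peak[, c(seq_len(h), nc - seq_len(h) + 1L)] <- FALSE
  idx <- which(is_peak)
  if (length(idx) == 0L) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  }
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  o <- order(rr, cc)
  cbind(row = rr[o], col = cc[o])
}

#' Fit candidate spots with sub-pixel accuracy
#'
#' Per candidate, a least-squares fit of a symmetric pixel-integrated 2D
#' Gaussian plus constant background over the fitting window
#' (Levenberg-Marquardt, compiled). When `max_emitters_per_fit > 1`, a
#' residual-driven refit adds up to that many emitters (shared width) and
#' keeps the model with the lower BIC. Positions are converted to nm here,
#' exactly once. Non-converged fits and fits landing outside the window are
#' dropped and tallied in the `n_dropped` attribute.
#'
#' @param image an [image2d()].
#' @param candidates integer matrix from [detect_candidates()].
#' @param settings a [detection_settings()].
#' @param gain camera gain used to convert fitted counts to photons.
#' @return A [localization_set()] with positions in nm.
#' @export
fit_spots <- function(image, candidates, settings = detection_settings(),
                      gain = 1) {
  px <- image$pixel_size_nm
  empty <- localization_set(NULL, channel_name = image$channel_name,
                            pixel_size_nm = px)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  w <- settings$fit_window_px
  s0 <- settings$psf_sigma_nm / px
  fits <- cpp_fit_spots(image$pixels, candidates, w, s0,
                        settings$max_emitters_per_fit)
  n_dropped <- attr(fits, "n_dropped")
  if (nrow(fits) == 0L) {
    attr(empty, "n_dropped") <- n_dropped
    return(empty)
  }
  df <- data.frame(
    x_nm = fits[, "x_px"] * px, y_nm = fits[, "y_px"] * px,
    sigma_nm = fits[, "sigma_px"] * px,
    intensity_photons = fits[, "flux"] / gain, background = fits[, "bg"])
  # de-duplicate: refits in adjacent overlapping windows can report the
  # same molecule twice; keep the brighter of any pair closer than ~1 px
  if (nrow(df) > 1L) {
    o <- order(-df$intensity_photons)
    df <- df[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!keep[i]) next
      if (i < nrow(df)) {
        j <- (i + 1L):nrow(df)
        d2 <- (df$x_nm[j] - df$x_nm[i])^2 + (df$y_nm[j] - df$y_nm[i])^2
        keep[j[d2 < (0.75 * px)^2]] <- FALSE
      }
    }
    df <- df[keep, , drop = FALSE]
    df <- df[order(df$y_nm, df$x_nm), , drop = FALSE]
  }
  df$id <- seq_len(nrow(df))
  out <- localization_set(df, channel_name = image$channel_name,
                          pixel_size_nm = px)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter localizations by fitted PSF width
#'
#' The modal sigma is the center of the tallest histogram bin (bin width 5%
#' of the median sigma); records with sigma outside
#' `[mode * (1 - f), mode * (1 + f)]` are removed (default f = 0.5, the
#' +/-50% window around the modal PSF width).
#'
#' @param locs a [localization_set()].
#' @param sigma_window_fraction window half-width fraction `f`.
#' @return The filtered [localization_set()].
#' @export
filter_by_sigma <- function(locs, sigma_window_fraction = 0.5) {
  if (nrow(locs) == 0L) return(locs)
  s <- locs$sigma_nm
  bw <- 0.05 * median(s)
  if (bw <= 0) return(locs)
  breaks <- seq(min(s) - bw, max(s) + bw, by = bw)
  counts <- tabulate(findInterval(s, breaks), nbins = length(breaks))
  mode_bin <- which.max(counts)
  mode_s <- breaks[mode_bin] + bw / 2
  f <- sigma_window_fraction
  keep <- s >= mode_s * (1 - f) & s <= mode_s * (1 + f)
  if (!any(keep)) {
    warning("all localizations removed by the PSF-width filter")
  }
  locs_like(locs, as.data.frame(locs)[keep, , drop = FALSE])
}

#' Detect, fit and width-filter spots in one call
#'
#' @param image an [image2d()].
#' @param settings a [detection_settings()].
#' @param gain camera gain (counts per photon) for photon conversion.
#' @return A [localization_set()].
#' @export
localize_image <- function(image, settings = detection_settings(), gain = 1) {
  cand <- detect_candidates(image, settings)
  locs <- fit_spots(image, cand, settings, gain = gain)
  filter_by_sigma(locs, settings$sigma_window_fraction)
}
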