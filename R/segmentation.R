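# Gaussian blur that tolerates sigmas comparable to the image size. When the
# kernel no longer fits inside the image the blur is indistinguishable from
# the global mean, which is returned directly.
wide_gblur <- function(p, sigma) {
  max_sigma <- (min(dim(p)) - 3) / 6.5
  if (sigma <= max_sigma) {
    return(as.matrix(EBImage::gblur(p, sigma = sigma)))
  }
  matrix(mean(p), nrow(p), ncol(p))
}

#' Binary cell mask aligned to an image
#'
#' @param mask binary matrix (1 = inside cell).
#' @param pixel_size_nm pixel pitch (nm).
#' @param no_cell flag set when segmentation found no cell; downstream
#'   stages must skip the image.
#' @return Object of class `prodol_mask` with derived `area_um2` and
#'   `n_components`.
#' @export
cell_mask <- function(mask, pixel_size_nm, no_cell = FALSE) {
  mask <- (mask != 0) * 1L
  n_comp <- if (any(mask != 0)) {
    max(EBImage::bwlabel(mask))
  } else 0L
  structure(list(mask = mask, pixel_size_nm = pixel_size_nm,
                 area_um2 = sum(mask) * (pixel_size_nm / 1000)^2,
                 n_components = as.integer(n_comp),
                 no_cell = isTRUE(no_cell) || !any(mask != 0)),
            class = "prodol_mask")
}

#' @export
print.prodol_mask <- function(x, ...) {
  cat(sprintf("<prodol_mask> %d x %d px, %.1f um^2, %d component(s)%s\n",
              nrow(x$mask), ncol(x$mask), x$area_um2, x$n_components,
              if (x$no_cell) " [no cell found]" else ""))
  invisible(x)
}

#' Segment the cell footprint from the reference channel
#'
#' Pipeline: subtract the global background level (median), band-pass with
#' a difference of Gaussians (`low_sigma_px` suppresses pixel noise,
#' `high_sigma_px` removes large-scale illumination while passing the whole
#' cell body), automatic global threshold (Otsu, floored at 4 robust SDs
#' above the median so a contrast-free image yields no cell), morphological
#' closing, hole filling, and removal of components smaller than
#' `min_object_area_um2`.
#'
#' @param image reference-channel [image2d()].
#' @param low_sigma_px,high_sigma_px band-pass Gaussian sigmas (px),
#'   `low_sigma_px < high_sigma_px`. The low sigma (default 6 px) smooths
#'   single-molecule texture into the diffuse cell body; the high sigma
#'   (default 128 px) must exceed the cell diameter scale so the whole
#'   footprint passes the filter.
#' @param min_object_area_um2 minimum component area kept (um^2).
#' @param closing_radius_px radius of the closing structuring element.
#' @return A [cell_mask()]; `no_cell` is set if nothing survives cleanup.
#' @export
segment_reference <- function(image, low_sigma_px = 6, high_sigma_px = 128,
                              min_object_area_um2 = 20,
                              closing_radius_px = 6) {
  if (low_sigma_px >= high_sigma_px) {
    stop("low_sigma_px must be < high_sigma_px", call. = FALSE)
  }
  px <- image$pixel_size_nm
  p <- image$pixels
  rng <- range(p)
  if (diff(rng) <= 0) {
    return(cell_mask(matrix(0L, nrow(p), ncol(p)), px, no_cell = TRUE))
  }
  p01 <- (p - rng[1]) / diff(rng)
  p01 <- p01 - median(p01)
  lo <- as.matrix(EBImage::gblur(p01, sigma = low_sigma_px))
  hi <- wide_gblur(p01, high_sigma_px)
  filt <- lo - hi
  # pixel-level noise from the fine-grained residual, propagated through the
  # low-sigma blur; floors the threshold so contrast-free images yield no cell
  noise_px <- mad(p01 - as.matrix(EBImage::gblur(p01, sigma = 1)))
  noise_smooth <- noise_px / (2 * max(low_sigma_px, 1) * sqrt(pi))
  thr_otsu <- tryCatch(
    EBImage::otsu(EBImage::Image((filt - min(filt)) / diff(range(filt)))) *
      diff(range(filt)) + min(filt),
    error = function(e) Inf)
  thr <- max(thr_otsu, 3 * noise_smooth)
  m <- (filt > thr) * 1
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
  m <- EBImage::closing(m, brush)
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    min_px <- min_object_area_um2 / (px / 1000)^2
    keep <- which(sizes >= min_px)
    m <- matrix(as.integer(lab %in% keep & lab > 0), nrow(m), ncol(m))
  } else {
    m <- matrix(0L, nrow(m), ncol(m))
  }
  cell_mask(m, px, no_cell = !any(m != 0))
}

#' Keep localizations inside a cell mask
#'
#' A localization belongs to the pixel `floor(nm / pixel_size)`; a point
#' exactly on the mask boundary counts as inside.
#'
#' @param locs a [localization_set()].
#' @param mask a [cell_mask()].
#' @return The filtered [localization_set()].
#' @export
mask_filter <- function(locs, mask) {
  if (nrow(locs) == 0L) return(locs)
  px <- mask$pixel_size_nm
  cc <- floor(locs$x_nm / px) + 1L
  rr <- floor(locs$y_nm / px) + 1L
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  ok <- cc >= 1L & cc <= nc & rr >= 1L & rr <= nr
  ok[ok] <- mask$mask[cbind(rr[ok], cc[ok])] != 0
  locs_like(locs, as.data.frame(locs)[ok, , drop = FALSE])
}
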