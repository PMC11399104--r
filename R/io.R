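#' Single-channel image with physical pixel size
#'
#' Container for one channel of a diffraction-limited acquisition. Pixel
#' values are camera counts (or averaged counts); the physical pixel pitch
#' in nm links pixel indices to the nm coordinate system used by all
#' localization-based stages. Pixel `(r, c)` spans
#' `[(c-1)*px, c*px) x [(r-1)*px, r*px)` nm with the origin at the top-left
#' image corner.
#'
#' @param pixels numeric matrix of non-negative pixel values; both
#'   dimensions must be at least 16.
#' @param pixel_size_nm physical pixel pitch in nm.
#' @param channel_name channel label, e.g. `"reference"` or `"target"`.
#' @param n_frames_averaged number of raw frames averaged into `pixels`.
#' @return An object of class `prodol_image`.
#' @export
image2d <- function(pixels, pixel_size_nm, channel_name = "channel",
                    n_frames_averaged = 1L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  }
  if (any(dim(pixels) < 16L)) {
    stop("image dimensions must both be >= 16 px", call. = FALSE)
  }
  stopifnot_scalar(pixel_size_nm, "pixel_size_nm")
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         channel_name = as.character(channel_name),
         n_frames_averaged = as.integer(n_frames_averaged)),
    class = "prodol_image"
  )
}

#' @export
print.prodol_image <- function(x, ...) {
  cat(sprintf("<prodol_image> %s: %d x %d px, %.1f nm/px, %d frame(s) averaged\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_nm, x$n_frames_averaged))
  invisible(x)
}

# frame extent in nm as c(width_x, height_y)
frame_size_nm <- function(image) {
  c(ncol(image$pixels), nrow(image$pixels)) * image$pixel_size_nm
}

#' Read a TIFF image, averaging multi-page stacks
#'
#' Multi-page TIFFs are averaged over pages, mirroring the acquisition
#' practice of recording ten to twenty frames and averaging them per
#' measurement. Single pages pass through unchanged.
#'
#' @param path path to a TIFF file.
#' @inheritParams image2d
#' @return A [image2d()] object; `n_frames_averaged` records the page count.
#' @export
read_image <- function(path, pixel_size_nm, channel_name = "channel") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    # integer TIFFs arrive scaled to [0, 1]; restore raw camera counts
    fmt <- attr(p, "sample.format") %||% "uint"
    bits <- attr(p, "bits.per.sample") %||% 16L
    if (!identical(fmt, "float")) p <- p * (2^bits - 1)
    p
  })
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1L] else
        stop("multi-sample (colour) TIFF payloads are not supported",
             call. = FALSE)
    }
    if (length(dim(p)) != 2L) stop("TIFF page is not a 2D raster", call. = FALSE)
    p
  })
  d <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1)))) {
    stop("TIFF pages have inconsistent dimensions", call. = FALSE)
  }
  avg <- Reduce(`+`, pages) / length(pages)
  avg <- matrix(as.numeric(avg), nrow(avg), ncol(avg))  # drop TIFF attributes
  image2d(avg, pixel_size_nm, channel_name,
          n_frames_averaged = length(pages))
}

#' Write an image (or binary mask) as TIFF
#'
#' Images are written as 16-bit unsigned TIFF carrying rounded camera
#' counts (the sub-count precision of a frame average is below the noise
#' floor); masks are written as 8-bit 0/255 TIFF for universal reader
#' support.
#'
#' @param image a [image2d()] object, or a binary matrix when `mask = TRUE`.
#' @param path output path.
#' @param mask write as 8-bit 0/255 mask instead of 16-bit counts.
#' @export
write_image <- function(image, path, mask = FALSE) {
  if (mask) {
    m <- if (inherits(image, "prodol_mask")) image$mask else image
    tiff::writeTIFF((m != 0) * 1.0, path, bits.per.sample = 8L)
  } else {
    p <- image$pixels
    if (any(p < 0) || any(p > 65535)) {
      warning("pixel values clipped to the 16-bit range [0, 65535]")
      p <- pmin(pmax(p, 0), 65535)
    }
    tiff::writeTIFF(round(p) / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Set of sub-pixel localizations for one channel of one image
#'
#' The currency exchanged between localization, registration and
#' colocalization. Coordinates always carry nm units; px-to-nm conversion
#' happens exactly once, at fit time.
#'
#' @param records data.frame with columns `id`, `x_nm`, `y_nm`, `sigma_nm`,
#'   `intensity_photons`, `background` (missing metadata columns are filled
#'   with `NA`).
#' @param channel_name channel label.
#' @param image_id identifier of the source image.
#' @param pixel_size_nm pixel pitch of the source image (nm).
#' @return Object of class `prodol_locs`, a data.frame with attributes.
#' @export
localization_set <- function(records = NULL, channel_name = "channel",
                             image_id = "image", pixel_size_nm = NA_real_) {
  cols <- c("id", "x_nm", "y_nm", "sigma_nm", "intensity_photons", "background")
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  for (cc in cols) if (is.null(records[[cc]])) {
    records[[cc]] <- if (cc == "id") seq_len(nrow(records)) else NA_real_
  }
  records <- records[, cols, drop = FALSE]
  if (anyDuplicated(records$id)) {
    stop("localization ids must be unique within a set", call. = FALSE)
  }
  structure(records, class = c("prodol_locs", "data.frame"),
            channel_name = channel_name, image_id = image_id,
            pixel_size_nm = pixel_size_nm)
}

# rebuild a set with new records, keeping metadata
locs_like <- function(template, records) {
  localization_set(records,
                   channel_name = attr(template, "channel_name"),
                   image_id = attr(template, "image_id"),
                   pixel_size_nm = attr(template, "pixel_size_nm"))
}

#' @export
print.prodol_locs <- function(x, ...) {
  cat(sprintf("<prodol_locs> %s/%s: %d localization(s)\n",
              attr(x, "image_id"), attr(x, "channel_name"), nrow(x)))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

# ThunderSTORM column dialect -> native names
.ts_dialect <- c("x [nm]" = "x_nm", "y [nm]" = "y_nm", "sigma [nm]" = "sigma_nm",
                 "intensity [photon]" = "intensity_photons",
                 "bkgstd [photon]" = "background", "offset [photon]" = "background",
                 "id" = "id")

#' Read a localization table (native or ThunderSTORM CSV dialect)
#'
#' Accepts the package's own column names (`x_nm`, `y_nm`, ...) as well as
#' the ThunderSTORM dialect (`x [nm]`, `y [nm]`, `sigma [nm]`,
#' `intensity [photon]`). Positions must be in nm.
#'
#' @param path CSV file with a header row.
#' @inheritParams localization_set
#' @return A [localization_set()].
#' @export
read_localizations <- function(path, channel_name = "channel",
                               image_id = "image", pixel_size_nm = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  hits <- intersect(names(df), names(.ts_dialect))
  for (h in hits) {
    native <- .ts_dialect[[h]]
    if (is.null(df[[native]])) df[[native]] <- df[[h]]
  }
  for (needed in c("x_nm", "y_nm")) {
    if (is.null(df[[needed]])) {
      stop(sprintf("localization table lacks positional column '%s' (or a ThunderSTORM equivalent)",
                   needed), call. = FALSE)
    }
  }
  localization_set(df, channel_name, image_id, pixel_size_nm)
}

#' Write a localization table as CSV
#'
#' Deterministic output: stable row order, fixed float formatting
#' (1e-4 nm resolution, lossless for round-trips at the 1e-3 nm level).
#'
#' @param locs a [localization_set()].
#' @param path output CSV path.
#' @export
write_localizations <- function(locs, path) {
  df <- as.data.frame(locs)
  for (cc in c("x_nm", "y_nm", "sigma_nm", "intensity_photons", "background")) {
    df[[cc]] <- sprintf("%.4f", df[[cc]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- analysis configuration ------------------------------------------------

.config_defaults <- function() {
  list(
    pixel_size_nm = 160,
    segmentation = list(
      low_sigma_px = 6, high_sigma_px = 128, min_object_area_um2 = 20,
      closing_radius_px = 6
    ),
    detection = list(
      dog_low_px = 1, dog_high_px = 2, peak_threshold_k = 4,
      fit_window_px = 7L, max_emitters_per_fit = 3L,
      sigma_window_fraction = 0.5, psf_sigma_nm = 150
    ),
    registration = list(
      match_radius_nm = 500, n_iterations = 5L, min_emitters = 50L,
      max_shift_px = 3, max_rotation_deg = 5, max_scale_dev = 0.05
    ),
    coloc = list(
      t_min_nm = 0, t_max_nm = 500, t_step_nm = 10,
      normalization = "reference"
    ),
    reporting = list(min_reference_locs = 20L, statistic = "median")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key '%s%s'", path, key), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop(sprintf("config key '%s%s' must be a named list", path, key),
             call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(path, key, "$"))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Analysis configuration with validated defaults
#'
#' All tunables of the analysis stages in one nested list. Unknown keys are
#' rejected to catch typos. Defaults follow the published workflow where it
#' states values (PSF-width window fraction 0.5, registration gates of 50
#' emitters / 3 px / 5 deg / 5 percent, multi-emitter cap 3) and otherwise
#' are the package's declared choices (see the methods vignette).
#'
#' @param ... named overrides, e.g.
#'   `analysis_config(detection = list(peak_threshold_k = 5))`.
#' @return Object of class `prodol_config`.
#' @export
analysis_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(.config_defaults(), user)
  det <- cfg$detection
  if (det$fit_window_px %% 2L != 1L || det$fit_window_px < 5L) {
    stop("fit_window_px must be odd and >= 5", call. = FALSE)
  }
  if (!det$max_emitters_per_fit %in% 1:3) {
    stop("max_emitters_per_fit must be 1, 2 or 3", call. = FALSE)
  }
  if (cfg$segmentation$low_sigma_px >= cfg$segmentation$high_sigma_px) {
    stop("segmentation low_sigma_px must be < high_sigma_px", call. = FALSE)
  }
  if (!cfg$coloc$normalization %in% c("reference", "pairs_at_tmax")) {
    stop("coloc normalization must be 'reference' or 'pairs_at_tmax'",
         call. = FALSE)
  }
  structure(cfg, class = c("prodol_config", "list"))
}

#' @export
print.prodol_config <- function(x, ...) {
  cat("<prodol_config>\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# t grid in nm from config
coloc_t_grid <- function(config) {
  seq(config$coloc$t_min_nm, config$coloc$t_max_nm, by = config$coloc$t_step_nm)
}
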