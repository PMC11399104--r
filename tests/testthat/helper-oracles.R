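# Exhaustive one-to-one assignment oracle: maximize the number of pairs
# within tolerance, then minimize the total distance. Independent of the
# package's assignment solver; feasible for <= 8 points per channel.
brute_force_match <- function(ref_xy, tgt_xy, tol) {
  n <- nrow(ref_xy); m <- nrow(tgt_xy)
  best <- c(count = 0, cost = 0)
  if (n == 0 || m == 0) return(best)
  d <- sqrt(outer(ref_xy[, 1], tgt_xy[, 1], "-")^2 +
              outer(ref_xy[, 2], tgt_xy[, 2], "-")^2)
  rec <- function(i, used, count, cost) {
    if (i > n) {
      if (count > best["count"] ||
          (count == best["count"] && cost < best["cost"] - 1e-12)) {
        best <<- c(count = count, cost = cost)
      }
      return(invisible())
    }
    rec(i + 1, used, count, cost)       # leave ref i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && d[i, j] <= tol) {
        used[j] <- TRUE
        rec(i + 1, used, count + 1, cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, m), 0, 0)
  best
}

# localization set from bare coordinates
locs_from_xy <- function(x, y, pixel_size_nm = 160, sigma_nm = 150) {
  localization_set(data.frame(x_nm = x, y_nm = y,
                              sigma_nm = rep_len(sigma_nm, length(x)),
                              intensity_photons = rep_len(350, length(x)),
                              background = rep_len(10, length(x))),
                   pixel_size_nm = pixel_size_nm)
}

# render a frame with emitters at known nm positions (no blinking/bleach)
render_fixture <- function(x_nm, y_nm, frame_px = 64, pixel_size_nm = 160,
                           photons = 350, psf_sigma_nm = 150,
                           background_photons = 10, n_frames = 1L,
                           read_noise = 1.5, seed = 1L) {
  mask <- matrix(1L, frame_px, frame_px)
  gt <- place_probes(mask, 0, 0, 0, pixel_size_nm, seed = seed)
  gt$probes <- data.frame(x_nm = x_nm, y_nm = y_nm,
                          has_reference = TRUE, has_target = FALSE)
  phys <- photophysics(on_time = 1, off_time = 0, bleach_constant = 0,
                       photons_per_s = photons)
  cam <- camera_model(pixel_size_nm = pixel_size_nm, read_noise = read_noise)
  render_channel(gt, "reference", phys, cam, psf_sigma_nm, n_frames,
                 background_photons, seed = seed)
}

# small fast simulation config for unit tests (128 px frames)
small_sim_config <- function(...) {
  sim_config(frame_size_px = c(128L, 128L), ...)
}

# default calibration shared by the acceptance tests, computed once per run
.accept_cache <- new.env(parent = emptyenv())
default_calibration <- function(seed = 20240901) {
  key <- paste0("cal", seed)
  if (is.null(.accept_cache[[key]])) {
    .accept_cache[[key]] <- calibrate_recall(
      sim_config(), analysis_config(), seed = seed)
  }
  .accept_cache[[key]]
}
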