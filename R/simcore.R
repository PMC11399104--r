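#' Fluorophore photophysics parameters
#'
#' Blinking is summarized by a duty cycle `on_time / (on_time + off_time)`;
#' the two times are unitless relative durations. Bleaching is a single
#' per-acquisition constant: an emitter survives each of the `n` frames
#' with probability `1 - bleach_constant / n`, so the constant refers to
#' the whole acquisition regardless of frame count. `photons_per_s` is the
#' emitted photon rate of one fluorophore while on.
#'
#' @param on_time mean on-duration (relative units, > 0).
#' @param off_time mean off-duration (>= 0; 0 means always on).
#' @param bleach_constant per-acquisition bleaching rate (>= 0).
#' @param photons_per_s emitted photons per second while on (> 0).
#' @param labels_per_epitope integer number of fluorophores per binding site.
#' @return Object of class `prodol_photophysics`.
#' @export
photophysics <- function(on_time = 0.025, off_time = 0.01,
                         bleach_constant = 0.2, photons_per_s = 350,
                         labels_per_epitope = 1L) {
  stopifnot_scalar(on_time, "on_time")
  stopifnot_scalar(off_time, "off_time", positive = FALSE)
  stopifnot_scalar(bleach_constant, "bleach_constant", positive = FALSE)
  stopifnot_scalar(photons_per_s, "photons_per_s")
  if (off_time < 0 || bleach_constant < 0) {
    stop("off_time and bleach_constant must be >= 0", call. = FALSE)
  }
  if (labels_per_epitope < 1L) {
    stop("labels_per_epitope must be >= 1", call. = FALSE)
  }
  duty <- on_time / (on_time + off_time)
  stopifnot(duty > 0, duty <= 1)
  structure(list(on_time = on_time, off_time = off_time,
                 bleach_constant = bleach_constant,
                 photons_per_s = photons_per_s,
                 labels_per_epitope = as.integer(labels_per_epitope),
                 duty_cycle = duty),
            class = "prodol_photophysics")
}

#' Camera noise and gain model
#'
#' Emulates an EMCCD operated at unit calibrated gain: detected photons are
#' Poisson-thinned by `qe`, scaled by `gain` counts per photoelectron,
#' offset by a constant baseline, and read out with Gaussian noise.
#'
#' @param pixel_size_nm physical pixel pitch at the sample (nm).
#' @param gain counts per photoelectron (> 0).
#' @param offset baseline counts.
#' @param read_noise read noise, counts r.m.s. per frame.
#' @param qe detection probability per photon, in (0, 1].
#' @return Object of class `prodol_camera`.
#' @export
camera_model <- function(pixel_size_nm = 160, gain = 1, offset = 100,
                         read_noise = 1.5, qe = 0.9) {
  stopifnot_scalar(pixel_size_nm, "pixel_size_nm")
  stopifnot_scalar(gain, "gain")
  if (qe <= 0 || qe > 1) stop("qe must be in (0, 1]", call. = FALSE)
  structure(list(pixel_size_nm = pixel_size_nm, gain = gain, offset = offset,
                 read_noise = read_noise, qe = qe),
            class = "prodol_camera")
}

#' Simulation configuration (the study conditions)
#'
#' Defaults emulate a TIRF acquisition of membrane-anchored probes inside an
#' irregular cell footprint: 256 x 256 px at 160 nm/px, PSF sigma 150 nm,
#' 15 averaged frames, dye photophysics on/off 0.025/0.01 (duty 0.714),
#' bleaching constant 0.2, 350 photons per second, and a small chromatic
#' affine offset between the channels. The reference (eGFP) channel is
#' rendered with duty cycle 1 and mild bleaching. Unspecific target-only
#' emitters appear at `unspec_density_um2` over the whole frame.
#'
#' @param ... named overrides of the default fields.
#' @return Object of class `prodol_simconfig`.
#' @export
sim_config <- function(...) {
  defaults <- list(
    frame_size_px = c(256L, 256L),
    pixel_size_nm = 160,
    cell_area_fraction = 0.5,
    probe_density_um2 = 0.2,
    true_dol = 0.5,
    unspec_density_um2 = 0.02,
    reference_dark_fraction = 0,
    psf_sigma_nm = 150,
    n_frames = 15L,
    exposure_s = 1,
    background_photons = 10,
    cell_background_photons = 3,
    photophysics_target = photophysics(),
    photophysics_reference = photophysics(on_time = 1, off_time = 0,
                                          bleach_constant = 0.05,
                                          photons_per_s = 350),
    camera = camera_model(),
    chromatic_shift_nm = c(96, -64),
    chromatic_rotation_deg = 0.3,
    chromatic_scale = c(1.003, 0.997)
  )
  user <- list(...)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop("unknown sim_config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, user)
  cfg$camera$pixel_size_nm <- cfg$pixel_size_nm
  structure(cfg, class = c("prodol_simconfig", "list"))
}

# chromatic transform of a simulation config, about the frame center
sim_chromatic_transform <- function(config) {
  center <- rev(config$frame_size_px) * config$pixel_size_nm / 2
  affine_from_params(shift_nm = config$chromatic_shift_nm,
                     rotation_deg = config$chromatic_rotation_deg,
                     scale = config$chromatic_scale,
                     center_nm = center)
}

#' Generate an irregular single-cell region
#'
#' A star-shaped blob (radius modulated by a low-order random Fourier
#' series) centered near the frame center; connected, hole-free, and with
#' pixel-exact area matching the requested fraction where the blob fits in
#' the frame. Identical seeds give bit-identical masks.
#'
#' @param frame_size_px integer `c(rows, cols)`, both >= 16.
#' @param target_area_fraction fraction of the frame area to cover, (0, 1].
#' @param seed RNG seed.
#' @return A binary integer matrix (1 = inside cell).
#' @export
make_cell_region <- function(frame_size_px, target_area_fraction, seed) {
  frame_size_px <- as.integer(frame_size_px)
  if (any(frame_size_px < 16L)) {
    stop("frame dimensions must both be >= 16 px", call. = FALSE)
  }
  if (target_area_fraction <= 0 || target_area_fraction > 1) {
    stop("target_area_fraction must be in (0, 1]", call. = FALSE)
  }
  nr <- frame_size_px[1]; nc <- frame_size_px[2]
  if (target_area_fraction == 1) {
    return(matrix(1L, nr, nc))
  }
  with_seed(seed, {
    cy <- nr / 2 + runif(1, -0.05, 0.05) * nr
    cx <- nc / 2 + runif(1, -0.05, 0.05) * nc
    k <- 2:6
    amp <- rnorm(length(k), 0, 0.08)
    phs <- runif(length(k), 0, 2 * pi)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - 0.5
    row <- matrix(seq_len(nr), nr, nc) - 0.5
    dx <- col - cx; dy <- row - cy
    d <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    g <- 1 + Reduce(`+`, lapply(seq_along(k), function(i) {
      amp[i] * cos(k[i] * theta + phs[i])
    }))
    g <- pmax(g, 0.3)
    m <- d / g                      # pixel inside iff m <= r0
    r0 <- quantile(m, probs = target_area_fraction, type = 1, names = FALSE)
    mask <- matrix(as.integer(m <= r0), nr, nc)
    mask
  })
}

#' Place probes and unspecific emitters on a cell mask
#'
#' Probe count is Poisson with mean density x mask area; positions are
#' uniform over mask pixels. Each probe independently carries a target
#' label with probability `true_dol`; the reference fluorophore is present
#' unless dark (probability `reference_dark_fraction`, default 0).
#' Unspecific target-only emitters are Poisson over the full frame.
#'
#' @param cell_mask binary matrix from [make_cell_region()].
#' @param probe_density_um2 probes per square micron of cell area.
#' @param true_dol ground-truth labeling probability, in `[0, 1]`.
#' @param unspec_density_um2 unspecific emitters per square micron of frame.
#' @param pixel_size_nm pixel pitch (nm).
#' @param reference_dark_fraction probability that a probe's reference
#'   fluorophore is dark (default 0: every probe is reference-visible).
#' @param seed RNG seed.
#' @return Object of class `prodol_ground_truth` with elements `probes`
#'   (data.frame `x_nm`, `y_nm`, `has_reference`, `has_target`),
#'   `unspecific`, `cell_mask`, `true_dol`, `true_unspec_density`, `seed`.
#' @export
place_probes <- function(cell_mask, probe_density_um2, true_dol,
                         unspec_density_um2, pixel_size_nm,
                         reference_dark_fraction = 0, seed) {
  if (probe_density_um2 < 0 || unspec_density_um2 < 0) {
    stop("densities must be >= 0", call. = FALSE)
  }
  if (true_dol < 0 || true_dol > 1) stop("true_dol must be in [0, 1]",
                                         call. = FALSE)
  inside <- which(cell_mask != 0)
  if (length(inside) == 0L) stop("cell mask is empty: no cell", call. = FALSE)
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  px_um <- pixel_size_nm / 1000
  area_um2 <- length(inside) * px_um^2
  frame_area_um2 <- nr * nc * px_um^2
  with_seed(seed, {
    n <- rpois(1, probe_density_um2 * area_um2)
    idx <- if (n > 0) sample(inside, n, replace = TRUE) else integer(0)
    rr <- (idx - 1L) %% nr
    cc <- (idx - 1L) %/% nr
    probes <- data.frame(
      x_nm = (cc + runif(n)) * pixel_size_nm,
      y_nm = (rr + runif(n)) * pixel_size_nm,
      has_reference = runif(n) >= reference_dark_fraction,
      has_target = runif(n) < true_dol
    )
    nu <- rpois(1, unspec_density_um2 * frame_area_um2)
    unspecific <- data.frame(
      x_nm = runif(nu) * nc * pixel_size_nm,
      y_nm = runif(nu) * nr * pixel_size_nm
    )
    structure(list(frame_size_px = c(nr, nc), cell_mask = cell_mask,
                   probes = probes, unspecific = unspecific,
                   true_dol = true_dol,
                   true_unspec_density = unspec_density_um2,
                   pixel_size_nm = pixel_size_nm,
                   chromatic_transform = NULL, seed = seed),
              class = "prodol_ground_truth")
  })
}

# simulate per-emitter visible-frame counts: geometric bleaching with
# per-frame hazard bleach_constant/n_frames, then per-frame Bernoulli(duty)
visible_frames <- function(n_emitters, phys, n_frames) {
  if (n_emitters == 0L) return(integer(0))
  q <- phys$bleach_constant / n_frames
  alive <- if (q > 0) pmin(rgeom(n_emitters, q), n_frames) else
    rep(n_frames, n_emitters)
  rbinom(n_emitters, alive, phys$duty_cycle)
}

# accumulate pixel-integrated Gaussians into an expected-photon image
render_psf_sum <- function(nr, nc, x_px, y_px, flux, sigma_px) {
  img <- matrix(0, nr, nc)
  if (length(x_px) == 0L) return(img)
  half <- ceiling(4 * sigma_px + 1)
  for (e in seq_along(x_px)) {
    if (flux[e] <= 0) next
    c0 <- max(1L, floor(x_px[e]) - half + 1L)
    c1 <- min(nc, floor(x_px[e]) + half + 1L)
    r0 <- max(1L, floor(y_px[e]) - half + 1L)
    r1 <- min(nr, floor(y_px[e]) + half + 1L)
    if (c0 > c1 || r0 > r1) next  # emitter fully outside: clipped silently
    cs <- c0:c1; rs <- r0:r1
    fx <- pnorm((cs - x_px[e]) / sigma_px) - pnorm((cs - 1 - x_px[e]) / sigma_px)
    fy <- pnorm((rs - y_px[e]) / sigma_px) - pnorm((rs - 1 - y_px[e]) / sigma_px)
    img[rs, cs] <- img[rs, cs] + flux[e] * outer(fy, fx)
  }
  img
}

#' Render one channel of a simulated acquisition
#'
#' Each emitter contributes a pixel-integrated 2D Gaussian of width
#' `psf_sigma_nm`. Per-frame emission is gated by an independent Bernoulli
#' blinking process at the photophysics duty cycle, after geometric
#' bleaching. The output is the average of `n_frames` noisy frames: photon
#' shot noise (Poisson, thinned by camera `qe`), then gain, baseline offset
#' and Gaussian read noise. Deterministic under a fixed seed.
#'
#' @param ground_truth a [place_probes()] result.
#' @param channel `"reference"` or `"target"`. Target positions are mapped
#'   through `ground_truth$chromatic_transform` when present.
#' @param phys a [photophysics()] object.
#' @param camera a [camera_model()] object.
#' @param psf_sigma_nm Gaussian PSF width (nm).
#' @param n_frames number of frames recorded and averaged.
#' @param background_photons background photons per pixel per frame outside
#'   the cell; `cell_background_photons` adds diffuse cell fluorescence
#'   inside the mask.
#' @param cell_background_photons additional in-cell background.
#' @param exposure_s exposure time per frame (s).
#' @param seed RNG seed.
#' @return A [image2d()] with averaged counts.
#' @export
render_channel <- function(ground_truth, channel, phys, camera, psf_sigma_nm,
                           n_frames, background_photons = 10,
                           cell_background_photons = 0, exposure_s = 1,
                           seed = 1L) {
  stopifnot_scalar(psf_sigma_nm, "psf_sigma_nm")
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  gt <- ground_truth
  nr <- gt$frame_size_px[1]; nc <- gt$frame_size_px[2]
  px <- gt$pixel_size_nm
  pos <- switch(channel,
    reference = gt$probes[gt$probes$has_reference,
                          c("x_nm", "y_nm"), drop = FALSE],
    target = {
      sp <- gt$probes[gt$probes$has_target, c("x_nm", "y_nm"), drop = FALSE]
      p <- rbind(sp, gt$unspecific[, c("x_nm", "y_nm"), drop = FALSE])
      if (!is.null(gt$chromatic_transform)) {
        xy <- apply_affine(gt$chromatic_transform, as.matrix(p))
        p <- data.frame(x_nm = xy[, 1], y_nm = xy[, 2])
      }
      p
    },
    stop("channel must be 'reference' or 'target'", call. = FALSE)
  )
  with_seed(seed, {
    n_emit <- nrow(pos)
    vis <- visible_frames(n_emit, phys, n_frames)
    flux_tot <- vis * phys$photons_per_s * exposure_s *
      phys$labels_per_epitope
    lambda <- render_psf_sum(nr, nc, pos$x_nm / px, pos$y_nm / px,
                             flux_tot, psf_sigma_nm / px)
    lambda <- lambda + n_frames * background_photons
    if (cell_background_photons > 0) {
      lambda <- lambda + n_frames * cell_background_photons *
        (gt$cell_mask != 0)
    }
    detected <- matrix(rpois(nr * nc, camera$qe * lambda), nr, nc)
    pixels <- camera$offset + camera$gain * detected / n_frames
    if (camera$read_noise > 0) {
      pixels <- pixels +
        matrix(rnorm(nr * nc, 0, camera$read_noise / sqrt(n_frames)), nr, nc)
    }
    image2d(pixels, px, channel_name = channel,
            n_frames_averaged = as.integer(n_frames))
  })
}

#' Simulate a full dual-channel experiment
#'
#' Per cell: an irregular cell region, Poisson probe placement with
#' Bernoulli target labeling, and rendering of the reference and target
#' channels. Target ground-truth coordinates (specific and unspecific) are
#' mapped through the chromatic transform before rendering. Per-cell seeds
#' are derived deterministically from the master seed.
#'
#' @param config a [sim_config()].
#' @param n_cells number of cells (>= 1).
#' @param seed master RNG seed.
#' @return List of length `n_cells`; each element has `reference`, `target`
#'   ([image2d()]) and `ground_truth`.
#' @export
simulate_experiment <- function(config = sim_config(), n_cells = 1L, seed = 1L) {
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  seeds <- derive_seeds(seed, 3L * n_cells)
  chrom <- sim_chromatic_transform(config)
  lapply(seq_len(n_cells), function(i) {
    s <- seeds[(3L * (i - 1L) + 1L):(3L * i)]
    mask <- make_cell_region(config$frame_size_px, config$cell_area_fraction,
                             seed = s[1])
    gt <- place_probes(mask, config$probe_density_um2, config$true_dol,
                       config$unspec_density_um2, config$pixel_size_nm,
                       config$reference_dark_fraction, seed = s[2])
    gt$chromatic_transform <- chrom
    ref <- render_channel(gt, "reference", config$photophysics_reference,
                          config$camera, config$psf_sigma_nm, config$n_frames,
                          config$background_photons,
                          config$cell_background_photons,
                          config$exposure_s, seed = s[3])
    tgt <- render_channel(gt, "target", config$photophysics_target,
                          config$camera, config$psf_sigma_nm, config$n_frames,
                          config$background_photons,
                          config$cell_background_photons,
                          config$exposure_s, seed = s[3] + 1L)
    list(reference = ref, target = tgt, ground_truth = gt)
  })
}

#' Write simulation ground truth as CSV
#'
#' One row per emitter: coordinates (nm, reference frame), flags and
#' species (`probe` or `unspecific`).
#'
#' @param ground_truth a [place_probes()] result.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  p <- ground_truth$probes
  u <- ground_truth$unspecific
  df <- rbind(
    data.frame(x_nm = p$x_nm, y_nm = p$y_nm,
               has_reference = p$has_reference, has_target = p$has_target,
               species = rep("probe", nrow(p))),
    data.frame(x_nm = u$x_nm, y_nm = u$y_nm,
               has_reference = FALSE, has_target = TRUE,
               species = rep("unspecific", nrow(u)))
  )
  df$x_nm <- sprintf("%.4f", df$x_nm)
  df$y_nm <- sprintf("%.4f", df$y_nm)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
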