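#' 2D affine transform on nm coordinates
#'
#' Stored as a 2x3 matrix `[A | t]` acting as `p' = A p + t`. The
#' decomposition used for quality control and parameter averaging is
#' `A = R(theta) diag(sx, sy)` (shear fixed at 0): `theta` from the polar
#' angle `atan2(a21 - a12, a11 + a22)`, scales by projecting the columns
#' onto the rotated axes. For shear-free transforms the decomposition
#' round-trips exactly.
#'
#' @param m numeric 2x3 matrix.
#' @return Object of class `prodol_affine`.
#' @export
affine2d <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 3L))) stop("affine matrix must be 2x3",
                                      call. = FALSE)
  if (abs(det(m[, 1:2])) < 1e-12) stop("affine transform is singular",
                                       call. = FALSE)
  structure(list(m = m), class = "prodol_affine")
}

#' @export
print.prodol_affine <- function(x, ...) {
  d <- decompose_affine(x)
  cat(sprintf("<prodol_affine> shift (%.2f, %.2f) nm, rotation %.4f deg, scale (%.5f, %.5f)\n",
              d$shift_nm[1], d$shift_nm[2], d$rotation_deg,
              d$scale[1], d$scale[2]))
  invisible(x)
}

#' Identity transform
#' @return A [affine2d()] identity.
#' @export
affine_identity <- function() {
  affine2d(cbind(diag(2), c(0, 0)))
}

#' Build an affine transform from interpretable parameters
#'
#' `p' = R(theta) diag(scale) (p - center) + center + shift`.
#'
#' @param shift_nm translation `c(x, y)` in nm.
#' @param rotation_deg rotation angle in degrees (counter-clockwise in the
#'   x-right / y-down pixel coordinate convention).
#' @param scale scale factors `c(sx, sy)`.
#' @param center_nm center of rotation/scaling, default the origin.
#' @return A [affine2d()].
#' @export
affine_from_params <- function(shift_nm = c(0, 0), rotation_deg = 0,
                               scale = c(1, 1), center_nm = c(0, 0)) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% diag(scale, 2)
  t <- center_nm + shift_nm - A %*% center_nm
  affine2d(cbind(A, t))
}

#' Decompose an affine transform into shift, rotation and scales
#'
#' @param transform a [affine2d()].
#' @return List with `shift_nm`, `rotation_deg`, `scale` (length-2).
#' @export
decompose_affine <- function(transform) {
  A <- transform$m[, 1:2]
  th <- atan2(A[2, 1] - A[1, 2], A[1, 1] + A[2, 2])
  sx <- A[1, 1] * cos(th) + A[2, 1] * sin(th)
  sy <- -A[1, 2] * sin(th) + A[2, 2] * cos(th)
  list(shift_nm = as.numeric(transform$m[, 3]),
       rotation_deg = th * 180 / pi, scale = c(sx, sy))
}

# recompose from a decompose_affine() list
recompose_affine <- function(d) {
  affine_from_params(shift_nm = d$shift_nm, rotation_deg = d$rotation_deg,
                     scale = d$scale)
}

#' Apply an affine transform to an n x 2 coordinate matrix
#' @param transform a [affine2d()].
#' @param xy numeric matrix with columns x, y (nm).
#' @return Transformed matrix of the same shape.
#' @export
apply_affine <- function(transform, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  t(transform$m[, 1:2] %*% t(xy) + transform$m[, 3])
}

#' Invert an affine transform
#' @param transform a [affine2d()].
#' @return The inverse [affine2d()].
#' @export
invert_affine <- function(transform) {
  A <- transform$m[, 1:2]
  Ai <- solve(A)
  affine2d(cbind(Ai, -Ai %*% transform$m[, 3]))
}

#' Apply a transform to a localization set
#'
#' Coordinates are mapped; all other fields are preserved.
#'
#' @param locs a [localization_set()].
#' @param transform a [affine2d()].
#' @return The transformed [localization_set()].
#' @export
apply_transform <- function(locs, transform) {
  if (nrow(locs) == 0L) return(locs)
  xy <- apply_affine(transform, cbind(locs$x_nm, locs$y_nm))
  df <- as.data.frame(locs)
  df$x_nm <- xy[, 1]
  df$y_nm <- xy[, 2]
  locs_like(locs, df)
}

# quality gates for a registration: set size >= 50 emitters, shift <= 3 px,
# rotation <= 5 deg, scale deviation <= 5%; exclusion is strict (">"), so a
# shift of exactly 3 px is still accepted
qc_accept <- function(n_emitters, shift_px, rotation_deg, scale_dev,
                      min_emitters = 50L, max_shift_px = 3,
                      max_rotation_deg = 5, max_scale_dev = 0.05) {
  n_emitters >= min_emitters &&
    sqrt(sum(shift_px^2)) <= max_shift_px &&
    abs(rotation_deg) <= max_rotation_deg &&
    scale_dev <= max_scale_dev
}

# mutual nearest-neighbor pairs within radius between two coordinate sets
mutual_nn_pairs <- function(a, b, radius) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(cbind(integer(0), integer(0)))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  nn_a <- max.col(-d2, ties.method = "first")          # for each a: nearest b
  nn_b <- max.col(-t(d2), ties.method = "first")       # for each b: nearest a
  ia <- seq_len(nrow(a))
  keep <- nn_b[nn_a] == ia &
    d2[cbind(ia, nn_a)] <= radius^2
  cbind(ia[keep], nn_a[keep])
}

#' Estimate the chromatic affine transform between two channels
#'
#' Iterative closest point on localization coordinates: mutual
#' nearest-neighbor pairs within `match_radius_nm`, least-squares affine
#' fit mapping target onto reference, re-matching with the transformed
#' target, iterated until the parameters move less than 1e-3 px or
#' `n_iterations` is reached. Quality control applies the published gates:
#' localization sets under `min_emitters` and fits with more than
#' `max_shift_px` xy shift, `max_rotation_deg` rotation or
#' `max_scale_dev` scaling deviation are rejected.
#'
#' @param ref_locs,target_locs [localization_set()]s of the two channels.
#' @param match_radius_nm pairing radius (nm).
#' @param n_iterations maximum ICP iterations.
#' @param min_emitters,max_shift_px,max_rotation_deg,max_scale_dev QC gates.
#' @return List with `transform` (a [affine2d()] mapping target coordinates
#'   onto the reference frame) and `qc` (class `prodol_reg_qc`: `n_pairs`,
#'   `shift_px`, `rotation_deg`, `scale_dev`, `rms_residual_nm`,
#'   `accepted`).
#' @export
estimate_affine <- function(ref_locs, target_locs, match_radius_nm = 500,
                            n_iterations = 5L, min_emitters = 50L,
                            max_shift_px = 3, max_rotation_deg = 5,
                            max_scale_dev = 0.05) {
  px <- attr(ref_locs, "pixel_size_nm")
  if (is.na(px)) px <- attr(target_locs, "pixel_size_nm")
  if (is.na(px)) stop("pixel size unknown; cannot express QC shift in px",
                      call. = FALSE)
  ref <- cbind(ref_locs$x_nm, ref_locs$y_nm)
  tgt <- cbind(target_locs$x_nm, target_locs$y_nm)
  fail <- function(n_pairs) {
    qc <- structure(list(n_pairs = n_pairs, shift_px = c(NA_real_, NA_real_),
                         rotation_deg = NA_real_, scale_dev = NA_real_,
                         rms_residual_nm = NA_real_, accepted = FALSE),
                    class = "prodol_reg_qc")
    list(transform = affine_identity(), qc = qc)
  }
  if (nrow(ref) == 0L || nrow(tgt) == 0L) return(fail(0L))
  tr <- affine_identity()
  prev_par <- c(0, 0, 0, 1, 1)
  pairs <- NULL
  # coarse-to-fine pairing radius: a 5 degree rotation displaces points by
  # microns at the frame edge, far beyond the final matching radius
  n_iterations <- max(n_iterations, 4L)
  radii <- match_radius_nm * pmax(1, 8 / 2^(seq_len(n_iterations) - 1))
  for (it in seq_len(n_iterations)) {
    moved <- apply_affine(tr, tgt)
    pairs <- mutual_nn_pairs(ref, moved, radii[it])
    if (nrow(pairs) < 3L) return(fail(nrow(pairs)))
    # least squares affine: [tx ty 1] %*% M = [rx ry]
    X <- cbind(tgt[pairs[, 2], , drop = FALSE], 1)
    Y <- ref[pairs[, 1], , drop = FALSE]
    M <- tryCatch(qr.solve(X, Y), error = function(e) NULL)
    if (is.null(M)) return(fail(nrow(pairs)))
    tr <- affine2d(t(M))
    d <- decompose_affine(tr)
    par <- c(d$shift_nm / px, d$rotation_deg, d$scale)
    if (radii[it] <= match_radius_nm && max(abs(par - prev_par)) < 1e-3) break
    prev_par <- par
  }
  moved <- apply_affine(tr, tgt)
  res <- ref[pairs[, 1], , drop = FALSE] - moved[pairs[, 2], , drop = FALSE]
  d <- decompose_affine(tr)
  n_emitters <- min(nrow(ref), nrow(tgt))
  scale_dev <- max(abs(d$scale - 1))
  qc <- structure(list(
    n_pairs = nrow(pairs),
    shift_px = d$shift_nm / px,
    rotation_deg = d$rotation_deg,
    scale_dev = scale_dev,
    rms_residual_nm = sqrt(mean(res^2) * 2),
    accepted = qc_accept(n_emitters, d$shift_nm / px, d$rotation_deg,
                         scale_dev, min_emitters, max_shift_px,
                         max_rotation_deg, max_scale_dev)),
    class = "prodol_reg_qc")
  list(transform = tr, qc = qc)
}

#' @export
print.prodol_reg_qc <- function(x, ...) {
  cat(sprintf("<registration QC> %d pairs, shift (%.3f, %.3f) px, rot %.3f deg, scale dev %.4f, rms %.1f nm -> %s\n",
              x$n_pairs, x$shift_px[1], x$shift_px[2], x$rotation_deg,
              x$scale_dev, x$rms_residual_nm,
              if (isTRUE(x$accepted)) "accepted" else "rejected"))
  invisible(x)
}

#' Pool accepted per-image transforms into one global transform
#'
#' The decomposed parameters (shift, rotation, scales) of all accepted
#' registrations are arithmetically averaged and recomposed, giving one
#' global transformation per experiment.
#'
#' @param estimates list of `estimate_affine()` results (each with
#'   `transform` and `qc`).
#' @return A [affine2d()].
#' @export
pool_transforms <- function(estimates) {
  acc <- Filter(function(e) isTRUE(e$qc$accepted), estimates)
  if (length(acc) == 0L) {
    stop("no accepted registrations; fall back to the identity transform ",
         "(and log a warning)", call. = FALSE)
  }
  ds <- lapply(acc, function(e) decompose_affine(e$transform))
  recompose_affine(list(
    shift_nm = colMeans(do.call(rbind, lapply(ds, `[[`, "shift_nm"))),
    rotation_deg = mean(vapply(ds, `[[`, numeric(1), "rotation_deg")),
    scale = colMeans(do.call(rbind, lapply(ds, `[[`, "scale")))))
}
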