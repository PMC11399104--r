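#' One-to-one matching of reference and target localizations
#'
#' Pairs reference and target localizations within a distance tolerance so
#' that each localization is used at most once. The pairing maximizes the
#' number of pairs and, among maximum-cardinality pairings, minimizes the
#' total distance (exact sparse assignment solve); this reproduces
#' exhaustive enumeration on small instances and minimizes
#' multiple-assignment artifacts at high density.
#'
#' @param ref_locs,target_locs [localization_set()]s.
#' @param tolerance_nm pairing tolerance (nm), >= 0.
#' @return Object of class `prodol_match`: `pairs` (data.frame `ref_id`,
#'   `target_id`, `distance_nm`), `unmatched_ref_ids`,
#'   `unmatched_target_ids`.
#' @export
match_one_to_one <- function(ref_locs, target_locs, tolerance_nm) {
  if (tolerance_nm < 0) stop("tolerance_nm must be >= 0", call. = FALSE)
  ref <- cbind(ref_locs$x_nm, ref_locs$y_nm)
  tgt <- cbind(target_locs$x_nm, target_locs$y_nm)
  if (nrow(ref) == 0L || nrow(tgt) == 0L) {
    m <- integer(0)
  } else {
    m <- cpp_match_pairs(ref, tgt, tolerance_nm)
  }
  matched <- which(!is.na(m))
  dist_nm <- if (length(matched)) {
    sqrt((ref[matched, 1] - tgt[m[matched], 1])^2 +
         (ref[matched, 2] - tgt[m[matched], 2])^2)
  } else numeric(0)
  pairs <- data.frame(ref_id = ref_locs$id[matched],
                      target_id = target_locs$id[m[matched]],
                      distance_nm = dist_nm)
  structure(list(
    pairs = pairs,
    unmatched_ref_ids = setdiff(ref_locs$id, pairs$ref_id),
    unmatched_target_ids = setdiff(target_locs$id, pairs$target_id)),
    class = "prodol_match")
}

#' Rotate target localizations by 90 degrees for the random-coloc null
#'
#' Random colocalization is estimated by rotating the target channel by 90
#' degrees about the frame center relative to the reference channel, which
#' destroys specific spatial correlation while preserving the density and
#' spatial statistics of the target signals. For square frames the point
#' count is preserved; for non-square frames, rotated points landing
#' outside the frame are discarded.
#'
#' @param target_locs a [localization_set()].
#' @param frame_size_nm frame extent `c(width_x, height_y)` in nm.
#' @return The rotated [localization_set()].
#' @export
rotate_for_null <- function(target_locs, frame_size_nm) {
  if (nrow(target_locs) == 0L) return(target_locs)
  cx <- frame_size_nm[1] / 2
  cy <- frame_size_nm[2] / 2
  df <- as.data.frame(target_locs)
  x_new <- cx - (df$y_nm - cy)
  y_new <- cy + (df$x_nm - cx)
  df$x_nm <- x_new
  df$y_nm <- y_new
  keep <- df$x_nm >= 0 & df$x_nm <= frame_size_nm[1] &
    df$y_nm >= 0 & df$y_nm <= frame_size_nm[2]
  locs_like(target_locs, df[keep, , drop = FALSE])
}

# cutoff attaining the maximum of z; values within one binomial standard
# error of the maximum count as statistical ties, and the largest such
# tolerance is taken: within the z plateau F_r is still negligible while
# F_c keeps collecting the tail of true pair distances, so the right edge
# maximizes specific colocalization at equal z and is far more stable
# against sampling noise than the plateau's left edge
optimal_cutoff <- function(t_grid_nm, z, n_ref) {
  zmax <- max(z)
  se <- sqrt(max(zmax * (1 - zmax), 0) / max(n_ref, 1L))
  tied <- which(z >= zmax - se)
  t_grid_nm[tied[length(tied)]]
}

#' Colocalization-distance curve and optimal cutoff
#'
#' For each tolerance `t` of an ascending grid, the specific colocalization
#' fraction `F_c(t)` is the number of one-to-one pairs within `t` divided
#' by the number of reference localizations, and the random fraction
#' `F_r(t)` is computed identically after rotating the target channel by
#' 90 degrees. The specific colocalization score is `z(t) = F_c - F_r`;
#' the cutoff `T` is the smallest grid tolerance attaining the maximum of
#' `z`, so that specific colocalization is maximized while random
#' colocalization is kept at a minimum.
#'
#' @param ref_locs,target_locs [localization_set()]s in a common frame
#'   (registration already applied).
#' @param t_grid_nm ascending tolerance grid (nm), at least 2 points.
#' @param frame_size_nm frame extent `c(width_x, height_y)` in nm for the
#'   rotation null.
#' @param normalization `"reference"` (default) divides by the number of
#'   reference localizations; `"pairs_at_tmax"` divides by the pair count
#'   at the largest tolerance.
#' @return Object of class `prodol_coloc_curve` with `t_grid_nm`, `F_c`,
#'   `F_r`, `z`, `T_nm`, and the normalization counts `n_ref_total`,
#'   `n_c_total`, `n_r_total`.
#' @export
coloc_curve <- function(ref_locs, target_locs, t_grid_nm, frame_size_nm,
                        normalization = c("reference", "pairs_at_tmax")) {
  normalization <- match.arg(normalization)
  if (length(t_grid_nm) < 2L || is.unsorted(t_grid_nm, strictly = TRUE)) {
    stop("t_grid_nm must be ascending with at least 2 points", call. = FALSE)
  }
  n_ref <- nrow(ref_locs)
  if (n_ref == 0L) stop("empty reference set: colocalization curve undefined",
                        call. = FALSE)
  ref <- cbind(ref_locs$x_nm, ref_locs$y_nm)
  tgt <- cbind(target_locs$x_nm, target_locs$y_nm)
  rot <- rotate_for_null(target_locs, frame_size_nm)
  rotm <- cbind(rot$x_nm, rot$y_nm)
  cnt_c <- if (nrow(tgt)) cpp_match_counts(ref, tgt, t_grid_nm) else
    integer(length(t_grid_nm))
  cnt_r <- if (nrow(rotm)) cpp_match_counts(ref, rotm, t_grid_nm) else
    integer(length(t_grid_nm))
  n_c_total <- if (normalization == "reference") n_ref else
    max(cnt_c[length(cnt_c)], 1L)
  n_r_total <- if (normalization == "reference") n_ref else
    max(cnt_r[length(cnt_r)], 1L)
  F_c <- cnt_c / n_c_total
  F_r <- cnt_r / n_r_total
  z <- F_c - F_r
  T_nm <- optimal_cutoff(t_grid_nm, z, n_ref)
  structure(list(t_grid_nm = t_grid_nm, F_c = F_c, F_r = F_r, z = z,
                 T_nm = T_nm, n_ref_total = n_ref,
                 n_c_total = n_c_total, n_r_total = n_r_total,
                 counts_c = cnt_c, counts_r = cnt_r),
            class = "prodol_coloc_curve")
}

#' @export
print.prodol_coloc_curve <- function(x, ...) {
  i <- which.max(x$z)
  cat(sprintf("<coloc curve> T = %.0f nm, F_c(T) = %.3f, F_r(T) = %.3f, z(T) = %.3f (n_ref = %d)\n",
              x$T_nm, x$F_c[i], x$F_r[i], x$z[i], x$n_ref_total))
  invisible(x)
}

#' Degree of colocalization at a cutoff
#'
#' Fraction of reference localizations with a one-to-one matched target
#' localization within `T_nm`.
#'
#' @param ref_locs,target_locs [localization_set()]s in a common frame.
#' @param T_nm colocalization cutoff (nm), from a [coloc_curve()] or a
#'   user override.
#' @return A fraction in `[0, 1]`.
#' @export
degree_of_colocalization <- function(ref_locs, target_locs, T_nm) {
  n_ref <- nrow(ref_locs)
  if (n_ref == 0L) stop("zero reference localizations: DOC undefined",
                        call. = FALSE)
  if (nrow(target_locs) == 0L) return(0)
  m <- match_one_to_one(ref_locs, target_locs, T_nm)
  nrow(m$pairs) / n_ref
}

#' Unspecific label density inside the cell
#'
#' Mode `"control"` (tag-free control probe such as a membrane-anchor-only
#' eGFP construct): every in-mask target localization counts as unspecific.
#' Mode `"residual"`: in-mask target localizations not matched to a
#' reference localization within `T_nm`.
#'
#' @param target_locs target-channel [localization_set()] (registered).
#' @param mask a [cell_mask()] with positive area.
#' @param ref_locs reference [localization_set()] (required for
#'   `"residual"`).
#' @param T_nm colocalization cutoff (required for `"residual"`).
#' @param mode `"control"` or `"residual"`.
#' @return Unspecific signals per square micron of cell area.
#' @export
unspecific_density <- function(target_locs, mask, ref_locs = NULL,
                               T_nm = NULL, mode = c("control", "residual")) {
  mode <- match.arg(mode)
  if (mask$area_um2 <= 0) stop("mask area is zero", call. = FALSE)
  inside <- mask_filter(target_locs, mask)
  if (mode == "control") {
    return(nrow(inside) / mask$area_um2)
  }
  if (is.null(ref_locs) || is.null(T_nm)) {
    stop("'residual' mode needs ref_locs and T_nm", call. = FALSE)
  }
  m <- match_one_to_one(ref_locs, target_locs, T_nm)
  n_unmatched_inside <- sum(inside$id %in% m$unmatched_target_ids)
  n_unmatched_inside / mask$area_um2
}
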