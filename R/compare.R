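# Pixel-wise comparison of orientation maps across modalities.

#' Upsample a coarse orientation map to a fine grid
#'
#' Nearest-neighbor block replication: each coarse pixel's orientations,
#' counts and peak distance are copied unchanged to its `by` x `bx` block
#' of fine pixels. Truncated blocks are allowed at the image edges.
#'
#' @param coarse an `orientation_map`.
#' @param target_shape `c(rows, cols)` of the fine grid.
#' @param block `c(by, bx)` fine pixels per coarse pixel.
#' @return An `orientation_map` on the fine grid.
#' @export
upsample_to_grid <- function(coarse, target_shape, block) {
  stopifnot(inherits(coarse, "orientation_map"),
            length(target_shape) == 2L, length(block) == 2L)
  d <- dim(coarse$n_orientations)
  if (any(ceiling(target_shape / block) != d))
    stop("target_shape, block and the coarse grid are inconsistent",
         call. = FALSE)
  ridx <- pmin(d[1], (seq_len(target_shape[1]) - 1L) %/% block[1] + 1L)
  cidx <- pmin(d[2], (seq_len(target_shape[2]) - 1L) %/% block[2] + 1L)
  ori <- array(NA_real_, c(target_shape, 3L))
  for (k in 1:3) ori[, , k] <- coarse$orientations[ridx, cidx, k]
  new_orientation_map(ori,
                      coarse$n_orientations[ridx, cidx],
                      coarse$peak_distance[ridx, cidx],
                      coarse$n_peaks[ridx, cidx])
}

#' Rotate the angles of an orientation map
#'
#' Applied after external affine registration: every present orientation
#' becomes (orientation + rho) mod 180; counts and peak distances are
#' unchanged.
#'
#' @param map an `orientation_map`.
#' @param rho_deg rotation angle in degrees.
#' @return The rotated `orientation_map`.
#' @export
rotate_orientations <- function(map, rho_deg) {
  stopifnot(inherits(map, "orientation_map"))
  map$orientations <- (map$orientations + rho_deg) %% 180
  map
}

#' Signed axial angular difference
#'
#' Difference a - b between two axial (mod-180) angles, wrapped into
#' \[-90, 90): d = ((a - b + 90) mod 180) - 90. Exact +/-90 maps to -90.
#'
#' @param a_deg,b_deg axial angles in degrees (vectorized).
#' @return Signed difference(s) in \[-90, 90).
#' @export
signed_axial_difference <- function(a_deg, b_deg) {
  ((a_deg - b_deg + 90) %% 180) - 90
}

#' Crossing-aware matching of two orientation lists
#'
#' For pixels where both modalities yield two orientations, both
#' bijective pairings are evaluated and the one with the smaller mean
#' absolute angular difference is used, so that the first orientation of
#' one modality is compared with whichever orientation of the other is
#' closer, and the second with the remaining one.
#'
#' @param orients_a,orients_b numeric vectors of equal length 1 or 2
#'   (axial angles, degrees).
#' @return Signed differences (a - b) per matched pair, in \[-90, 90).
#' @export
match_and_diff <- function(orients_a, orients_b) {
  la <- length(orients_a); lb <- length(orients_b)
  if (la != lb || la < 1L || la > 2L)
    stop("orientation lists must have equal length 1 or 2", call. = FALSE)
  if (la == 1L) return(signed_axial_difference(orients_a, orients_b))
  straight <- signed_axial_difference(orients_a, orients_b)
  crossed <- signed_axial_difference(orients_a, rev(orients_b))
  if (mean(abs(crossed)) < mean(abs(straight))) crossed else straight
}

#' Compare two orientation maps pixel by pixel
#'
#' Only pixels where both maps yield the same number of orientations (one
#' or two) and the analysis mask is true are compared. Per matched pixel,
#' [match_and_diff] gives signed differences (fine - coarse); histograms
#' (1-degree bins over \[-90, 90)) and summary statistics (mean signed
#' difference, median absolute difference) are reported separately for
#' the one-orientation and two-orientation classes.
#'
#' @param fine,coarse_upsampled `orientation_map`s on the same grid.
#' @param mask optional logical matrix restricting the evaluation region.
#' @return Object of class `"comparison_result"`: `signed_diff_deg` and
#'   `abs_diff_deg` (rows x cols x 2 arrays), `matched_mask`,
#'   `histograms` (per class), `stats` (data frame).
#' @export
compare_orientation_maps <- function(fine, coarse_upsampled, mask = NULL) {
  stopifnot(inherits(fine, "orientation_map"),
            inherits(coarse_upsampled, "orientation_map"))
  d <- dim(fine$n_orientations)
  if (any(dim(coarse_upsampled$n_orientations) != d))
    stop("orientation maps must share one grid", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(all(dim(mask) == d))
  matched <- fine$n_orientations == coarse_upsampled$n_orientations &
    fine$n_orientations %in% c(1L, 2L) & mask
  sdiff <- array(NA_real_, c(d, 2L))
  for (r in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      if (!matched[r, cc]) next
      k <- fine$n_orientations[r, cc]
      dd <- match_and_diff(fine$orientations[r, cc, seq_len(k)],
                           coarse_upsampled$orientations[r, cc, seq_len(k)])
      sdiff[r, cc, seq_len(k)] <- dd
    }
  }
  breaks <- seq(-90, 90, by = 1)
  classes <- list(one = 1L, two = 2L)
  histograms <- list(); stats_rows <- list()
  for (nm in names(classes)) {
    k <- classes[[nm]]
    sel <- matched & fine$n_orientations == k
    vals <- as.numeric(apply(sdiff, 3, function(m) m[sel]))
    vals <- vals[!is.na(vals)]
    h <- hist(vals, breaks = breaks, plot = FALSE, right = FALSE)
    histograms[[nm]] <- data.frame(bin_left = utils::head(breaks, -1),
                                   count = h$counts)
    stats_rows[[nm]] <- data.frame(
      class = nm, n_pixels = sum(sel), n_differences = length(vals),
      mean_signed = if (length(vals)) mean(vals) else NA_real_,
      median_abs = if (length(vals)) stats::median(abs(vals)) else NA_real_)
  }
  structure(list(signed_diff_deg = sdiff, abs_diff_deg = abs(sdiff),
                 matched_mask = matched, histograms = histograms,
                 stats = do.call(rbind, stats_rows)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Orientation map comparison\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Prevalence of multiple fiber orientations per pixel
#'
#' Fraction of mask pixels in which each map detects two or more
#' orientations, and the percentage increase of map b over map a.
#'
#' @param map_a,map_b `orientation_map`s on the same grid.
#' @param mask optional logical matrix.
#' @return List with `frac_multi_a`, `frac_multi_b`, `pct_increase`
#'   (NA, flagged, when `frac_multi_a` is zero).
#' @export
multiplicity_stats <- function(map_a, map_b, mask = NULL) {
  d <- dim(map_a$n_orientations)
  stopifnot(all(dim(map_b$n_orientations) == d))
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  n <- sum(mask)
  fa <- sum(map_a$n_orientations >= 2L & mask) / n
  fb <- sum(map_b$n_orientations >= 2L & mask) / n
  list(frac_multi_a = fa, frac_multi_b = fb,
       pct_increase = if (fa > 0) 100 * (fb / fa - 1) else NA_real_)
}

#' Peak-distance versus inclination table
#'
#' Emits one row per evaluated pixel relating the SLI peak distance to a
#' reference fiber inclination (from 3D-sSAXS or dMRI). Following the
#' unidirectional-fiber rule, only pixels with one or two peaks, at most
#' one orientation, and a true mask are evaluated.
#'
#' @param omap an `orientation_map` (provides peak distance, peak and
#'   orientation counts).
#' @param alpha_map matrix of reference inclinations (degrees),
#'   co-registered with `omap`.
#' @param mask optional logical matrix.
#' @param region_labels optional integer/character matrix naming regions.
#' @return Data frame with columns `region`, `alpha_deg`, `delta_deg`.
#' @export
distance_inclination_scatter <- function(omap, alpha_map, mask = NULL,
                                         region_labels = NULL) {
  d <- dim(omap$n_orientations)
  stopifnot(all(dim(alpha_map) == d))
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (is.null(region_labels)) region_labels <- matrix(1L, d[1], d[2])
  sel <- mask & omap$n_peaks %in% c(1L, 2L) & omap$n_orientations <= 1L &
    !is.na(omap$peak_distance) & !is.na(alpha_map)
  idx <- which(sel)
  data.frame(region = region_labels[idx],
             alpha_deg = alpha_map[idx],
             delta_deg = omap$peak_distance[idx])
}

#' Axial dot-product comparison of two 3D vector maps
#'
#' Per-pixel axial dot product |u . v| of two unit-vector maps (e.g. main
#' fiber orientations from dMRI and 3D-sSAXS), the corresponding angular
#' difference arccos|u . v| in degrees, its histogram and median over the
#' mask, optionally gated by a fractional-anisotropy threshold.
#'
#' @param vectors_a,vectors_b rows x cols x 3 arrays.
#' @param mask optional logical matrix.
#' @param fa optional FA matrix; with `fa_threshold`, only pixels with
#'   `fa > fa_threshold` enter the statistics.
#' @param fa_threshold FA gate (e.g. 0.2), NULL for none.
#' @return List with `dot` (matrix), `angular_diff_deg` (matrix),
#'   `median_angular_diff_deg`, `histogram`, `n_excluded` (zero-length
#'   vectors inside the mask).
#' @export
dot_product_map <- function(vectors_a, vectors_b, mask = NULL,
                            fa = NULL, fa_threshold = NULL) {
  da <- dim(vectors_a)
  stopifnot(length(da) == 3L, da[3] == 3L, all(dim(vectors_b) == da))
  d <- da[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  na2 <- sqrt(vectors_a[, , 1]^2 + vectors_a[, , 2]^2 + vectors_a[, , 3]^2)
  nb2 <- sqrt(vectors_b[, , 1]^2 + vectors_b[, , 2]^2 + vectors_b[, , 3]^2)
  dot <- abs(vectors_a[, , 1] * vectors_b[, , 1] +
             vectors_a[, , 2] * vectors_b[, , 2] +
             vectors_a[, , 3] * vectors_b[, , 3]) / (na2 * nb2)
  dot <- pmin(dot, 1)
  zero <- (na2 == 0 | nb2 == 0)
  n_excluded <- sum(zero & mask, na.rm = TRUE)
  dot[zero] <- NA_real_
  ang <- acos(dot) * 180 / pi
  sel <- mask & !is.na(dot)
  if (!is.null(fa) && !is.null(fa_threshold)) sel <- sel & fa > fa_threshold
  vals <- ang[sel]
  h <- hist(vals, breaks = seq(0, 90, by = 1), plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  list(dot = dot, angular_diff_deg = ang,
       median_angular_diff_deg = if (length(vals)) stats::median(vals) else NA_real_,
       histogram = data.frame(bin_left = seq(0, 89, by = 1), count = h$counts),
       n_excluded = n_excluded)
}
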