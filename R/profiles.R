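#' Cyclic azimuthal intensity profile
#'
#' The common currency of all modalities: the intensity I(phi) of a
#' scattering pattern as a function of the azimuth phi around the pattern
#' center, on an equally spaced cyclic grid covering \[0, 360). Bin k is
#' labelled by the start of its segment, so bin centers are
#' 0, w, 2w, ... with `bin_width_deg = w = 360 / n`.
#'
#' @param values numeric intensities, one per bin.
#' @param bin_centers_deg optional bin labels; defaults to
#'   `seq(0, 360 - w, by = w)`.
#' @param valid logical per bin; bins without usable data are FALSE.
#' @return Object of class `"azimuthal_profile"`.
#' @export
azimuthal_profile <- function(values, bin_centers_deg = NULL, valid = NULL) {
  n <- length(values)
  if (n < 1L) stop("empty profile", call. = FALSE)
  w <- 360 / n
  if (is.null(bin_centers_deg)) bin_centers_deg <- seq(0, 360 - w, by = w)
  if (length(bin_centers_deg) != n)
    stop("bin_centers_deg length must match values", call. = FALSE)
  if (any(abs(diff(bin_centers_deg) - w) > 1e-9))
    stop("bins must be equally spaced over [0, 360)", call. = FALSE)
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(values = as.numeric(values),
                 bin_centers_deg = as.numeric(bin_centers_deg),
                 bin_width_deg = w,
                 valid = as.logical(valid)),
            class = "azimuthal_profile")
}

#' @export
print.azimuthal_profile <- function(x, ...) {
  cat("Azimuthal profile:", length(x$values), "bins of", x$bin_width_deg,
      "deg,", sum(!x$valid), "invalid\n")
  invisible(x)
}

#' SAXS detector geometry
#'
#' @param frame_shape integer `c(rows, cols)` of the detector frame.
#' @param beam_center `c(row, col)` of the beam center, 1-based pixel
#'   coordinates (may be fractional); must lie inside the frame.
#' @param q_per_pixel reciprocal-space calibration, nm^-1 per detector
#'   pixel of radial distance; must be positive.
#' @param mask logical matrix marking usable detector pixels (TRUE =
#'   usable); defaults to all usable. Dead areas and the beamstop are
#'   FALSE.
#' @return Object of class `"detector_geometry"`.
#' @export
detector_geometry <- function(frame_shape, beam_center, q_per_pixel,
                              mask = NULL) {
  stopifnot(length(frame_shape) == 2L, length(beam_center) == 2L)
  frame_shape <- as.integer(frame_shape)
  if (q_per_pixel <= 0) stop("q_per_pixel must be > 0", call. = FALSE)
  if (beam_center[1] < 1 || beam_center[1] > frame_shape[1] ||
      beam_center[2] < 1 || beam_center[2] > frame_shape[2])
    stop("beam_center must lie inside the frame", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, frame_shape[1], frame_shape[2])
  stopifnot(all(dim(mask) == frame_shape))
  structure(list(frame_shape = frame_shape,
                 beam_center = as.numeric(beam_center),
                 q_per_pixel = as.numeric(q_per_pixel), mask = mask),
            class = "detector_geometry")
}

#' 2D scattering pattern
#'
#' For SLI scatterometry the center is the point of maximum intensity
#' (ties broken towards the smallest row, then column); for SAXS it is the
#' beam center from the detector geometry.
#'
#' @param data intensity matrix.
#' @param center optional `c(row, col)`; computed from `geometry` (SAXS)
#'   or the intensity argmax (SLI) when NULL.
#' @param geometry optional [detector_geometry] (SAXS only).
#' @param valid_mask logical matrix of usable pixels; defaults to the
#'   geometry mask, or all-TRUE.
#' @return Object of class `"scattering_pattern"`.
#' @export
scattering_pattern <- function(data, center = NULL, geometry = NULL,
                               valid_mask = NULL) {
  stopifnot(is.matrix(data))
  if (is.null(valid_mask))
    valid_mask <- if (is.null(geometry)) matrix(TRUE, nrow(data), ncol(data)) else geometry$mask
  stopifnot(all(dim(valid_mask) == dim(data)))
  if (is.null(center)) {
    if (!is.null(geometry)) {
      center <- geometry$beam_center
    } else {
      if (!any(valid_mask) || all(data[valid_mask] == 0))
        stop("all-zero pattern: center undefined", call. = FALSE)
      # argmax; ties resolved to smallest row, then smallest column
      vals <- ifelse(valid_mask, data, -Inf)
      hits <- which(vals == max(vals), arr.ind = TRUE)
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      center <- as.numeric(hits[1, ])
    }
  }
  if (center[1] < 1 || center[1] > nrow(data) ||
      center[2] < 1 || center[2] > ncol(data))
    stop("center must lie inside the pattern", call. = FALSE)
  structure(list(data = data, center = as.numeric(center),
                 geometry = geometry, valid_mask = valid_mask),
            class = "scattering_pattern")
}

# Azimuth (degrees in [0, 360)) of pixel centers about a center point.
# Convention: measured from the +column axis towards the +row axis.
pixel_azimuth_deg <- function(rows, cols, center) {
  az <- atan2(rows - center[1], cols - center[2]) * 180 / pi
  az %% 360
}

# Segment index for azimuths: segment k covers [(k-1)w, kw); values exactly
# on a segment edge belong to the lower segment (az = kw -> segment k,
# az = 0 -> segment n).
azimuth_bin_index <- function(az, n) {
  w <- 360 / n
  r <- az / w
  idx <- ceiling(r - 1e-9)
  idx[idx < 1L] <- n
  idx
}

#' Assemble a scatterometry pattern for one image pixel
#'
#' In SLI scatterometry the sample is illuminated from a dense grid of
#' positions and an image is taken per position; the scattering pattern of
#' one image pixel is assembled by reading that pixel's intensity out of
#' every image: pattern\[i, j\] is the pixel's intensity under illumination
#' position (i, j).
#'
#' @param stack 4-D array `(grid_i, grid_j, rows, cols)` of images indexed
#'   by illumination position. Missing illumination positions may be NA.
#' @param pixel `c(row, col)` of the image pixel.
#' @return A [scattering_pattern] with the illumination grid's shape;
#'   missing positions are marked invalid.
#' @export
assemble_scatterometry_pattern <- function(stack, pixel) {
  stopifnot(length(dim(stack)) == 4L, length(pixel) == 2L)
  d <- dim(stack)
  if (pixel[1] < 1 || pixel[1] > d[3] || pixel[2] < 1 || pixel[2] > d[4])
    stop("pixel outside image bounds", call. = FALSE)
  pat <- stack[, , pixel[1], pixel[2]]
  valid <- !is.na(pat)
  pat[!valid] <- 0
  scattering_pattern(pat, valid_mask = valid)
}

#' Azimuthal profile of an SLI scatterometry pattern
#'
#' Sums the intensity of every pattern pixel falling into each azimuthal
#' segment about the pattern center (the point of maximum intensity), from
#' the center out to the pattern border. Each pixel counts once; the
#' center pixel itself has no azimuth and is excluded.
#'
#' @param pattern a [scattering_pattern].
#' @param bin_width_deg segment width in degrees (default 1, i.e. 360
#'   bins).
#' @return An [azimuthal_profile].
#' @export
sli_pattern_to_profile <- function(pattern, bin_width_deg = 1) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  n <- round(360 / bin_width_deg)
  if (abs(n * bin_width_deg - 360) > 1e-9)
    stop("bin_width_deg must divide 360", call. = FALSE)
  dat <- pattern$data
  if (all(dat[pattern$valid_mask] == 0))
    stop("all-zero pattern: center undefined", call. = FALSE)
  idx <- which(pattern$valid_mask, arr.ind = TRUE)
  rows <- idx[, 1]; cols <- idx[, 2]
  keep <- !(rows == pattern$center[1] & cols == pattern$center[2])
  rows <- rows[keep]; cols <- cols[keep]
  az <- pixel_azimuth_deg(rows, cols, pattern$center)
  bins <- azimuth_bin_index(az, n)
  vals <- rep(0, n)
  s <- tapply(dat[cbind(rows, cols)], bins, sum)
  vals[as.integer(names(s))] <- s
  azimuthal_profile(vals)
}

#' Per-pixel azimuthal profiles from an angular SLI stack
#'
#' In the angular SLI measurement the sample is illuminated from a circle
#' of azimuths at fixed polar angle; each pixel's slice series already is
#' its azimuthal profile, on bin centers equal to the illumination
#' azimuths. No resampling is performed.
#'
#' @param stack an [sli_stack] (or list with `data` array rows x cols x
#'   n_azimuths and `azimuths_deg`).
#' @return A [profile_map] with modality `"sli_angular"`.
#' @export
angular_stack_to_profiles <- function(stack) {
  validate_sli_stack(stack)
  profile_map(stack$data, bin_centers_deg = stack$azimuths_deg,
              modality = "sli_angular")
}

#' Map of azimuthal profiles on a pixel grid
#'
#' @param values array rows x cols x n_bins of intensities.
#' @param bin_centers_deg shared bin grid.
#' @param modality one of `"sli_angular"`, `"sli_scatterometry"`,
#'   `"saxs"`, `"fod"`.
#' @param valid optional logical array of the same shape as `values`.
#' @return Object of class `"profile_map"`.
#' @export
profile_map <- function(values, bin_centers_deg = NULL,
                        modality = c("sli_angular", "sli_scatterometry",
                                     "saxs", "fod"),
                        valid = NULL) {
  modality <- match.arg(modality)
  stopifnot(length(dim(values)) == 3L)
  n <- dim(values)[3]
  w <- 360 / n
  if (is.null(bin_centers_deg)) bin_centers_deg <- seq(0, 360 - w, by = w)
  stopifnot(length(bin_centers_deg) == n)
  structure(list(values = values, bin_centers_deg = bin_centers_deg,
                 bin_width_deg = w, valid = valid, modality = modality),
            class = "profile_map")
}

#' @export
print.profile_map <- function(x, ...) {
  d <- dim(x$values)
  cat("Profile map (", x$modality, "): ", d[1], " x ", d[2], " px, ",
      d[3], " bins of ", x$bin_width_deg, " deg\n", sep = "")
  invisible(x)
}

# Extract one pixel's profile from a profile map.
profile_at <- function(pmap, row, col) {
  azimuthal_profile(pmap$values[row, col, ],
                    bin_centers_deg = pmap$bin_centers_deg,
                    valid = if (is.null(pmap$valid)) NULL else pmap$valid[row, col, ])
}

#' Azimuthal profile of a SAXS pattern around the myelin ring
#'
#' Sums the unmasked detector intensities whose scattering-vector
#' magnitude q falls inside `q_band`, per azimuthal segment about the beam
#' center (default 5-degree segments, 72 bins). Segments containing no
#' usable pixel are flagged invalid.
#'
#' @param pattern a [scattering_pattern] with calibration (a
#'   [detector_geometry]).
#' @param q_band `c(qmin, qmax)` in nm^-1; when NULL, an automatic band
#'   `[0.9, 1.1] * q_peak` around the detected myelin ring is used.
#' @param bin_width_deg segment width (default 5).
#' @return An [azimuthal_profile] with invalid empty segments.
#' @export
saxs_pattern_to_profile <- function(pattern, q_band = NULL, bin_width_deg = 5) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  if (is.null(pattern$geometry))
    stop("SAXS profile extraction requires detector calibration", call. = FALSE)
  if (is.null(q_band)) {
    ring <- detect_myelin_ring(pattern)
    q_band <- c(0.9, 1.1) * ring$q_peak
  }
  if (length(q_band) != 2L || q_band[2] <= q_band[1] || q_band[1] < 0)
    stop("q_band must be c(qmin, qmax) with 0 <= qmin < qmax", call. = FALSE)
  n <- round(360 / bin_width_deg)
  if (abs(n * bin_width_deg - 360) > 1e-9)
    stop("bin_width_deg must divide 360", call. = FALSE)
  geom <- pattern$geometry
  idx <- which(pattern$valid_mask, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - pattern$center[1])^2 + (idx[, 2] - pattern$center[2])^2)
  q <- r * geom$q_per_pixel
  inband <- q >= q_band[1] & q <= q_band[2]
  idx <- idx[inband, , drop = FALSE]
  az <- pixel_azimuth_deg(idx[, 1], idx[, 2], pattern$center)
  bins <- azimuth_bin_index(az, n)
  vals <- rep(0, n)
  cnt <- tabulate(bins, nbins = n)
  if (nrow(idx) > 0) {
    s <- tapply(pattern$data[idx], bins, sum)
    vals[as.integer(names(s))] <- s
  }
  azimuthal_profile(vals, valid = cnt > 0L)
}

#' Complete a profile using the center-symmetry of SAXS patterns
#'
#' SAXS scattering patterns are center-symmetric, so I(phi) = I(phi+180).
#' Bins lost to detector electronics can be filled from their antipodal
#' counterpart: where both are valid their average is taken, where only
#' one is valid it is copied, where neither is valid the bin remains
#' invalid. Idempotent.
#'
#' @param profile an [azimuthal_profile] with an even number of bins.
#' @return The completed [azimuthal_profile].
#' @export
complete_center_symmetry <- function(profile) {
  stopifnot(inherits(profile, "azimuthal_profile"))
  n <- length(profile$values)
  if (n %% 2L != 0L)
    stop("center-symmetry completion needs an even number of bins", call. = FALSE)
  h <- n %/% 2L
  v <- profile$values; ok <- profile$valid
  out_v <- v; out_ok <- ok
  for (k in seq_len(h)) {
    a <- k; b <- k + h
    if (ok[a] && ok[b]) {
      m <- (v[a] + v[b]) / 2
      out_v[a] <- m; out_v[b] <- m
    } else if (ok[a]) {
      out_v[b] <- v[a]; out_ok[b] <- TRUE
    } else if (ok[b]) {
      out_v[a] <- v[b]; out_ok[a] <- TRUE
    }
  }
  azimuthal_profile(out_v, bin_centers_deg = profile$bin_centers_deg,
                    valid = out_ok)
}

#' Detect the myelin Bragg ring in a SAXS pattern
#'
#' Azimuthally averages the unmasked intensities into annuli of one pixel
#' radial width, locates the most prominent interior radial maximum,
#' refines its position by 3-point parabolic interpolation, and converts
#' it to the scattering-vector magnitude `q_peak` and the real-space
#' myelin periodicity `d_spacing = 2 * pi / q_peak`.
#'
#' @param pattern a [scattering_pattern] with calibration.
#' @return List with `q_peak` (nm^-1), `d_spacing` (nm) and the radial
#'   profile used (`radius_px`, `intensity`).
#' @export
detect_myelin_ring <- function(pattern) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  if (is.null(pattern$geometry))
    stop("ring detection requires detector calibration", call. = FALSE)
  idx <- which(pattern$valid_mask, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - pattern$center[1])^2 + (idx[, 2] - pattern$center[2])^2)
  rbin <- floor(r) + 1L
  sums <- tapply(pattern$data[idx], rbin, mean)
  rad <- as.integer(names(sums)) - 1L + 0.5  # annulus mid-radius in px
  y <- as.numeric(sums)
  m <- length(y)
  if (m < 3L) stop("ring not found: pattern too small", call. = FALSE)
  interior <- 2:(m - 1L)
  is_max <- y[interior] > y[interior - 1L] & y[interior] >= y[interior + 1L]
  cand <- interior[is_max]
  rng <- max(y) - min(y)
  if (length(cand) == 0L || rng <= 0)
    stop("ring not found: no radial maximum above background", call. = FALSE)
  # prominence of each candidate: drop to the higher of the flanking minima
  prom <- vapply(cand, function(i) {
    left <- min(y[1:i]); right <- min(y[i:m])
    y[i] - max(left, right)
  }, numeric(1))
  best <- cand[which.max(prom)]
  if (prom[which.max(prom)] <= 0.05 * rng)
    stop("ring not found: no radial maximum above background", call. = FALSE)
  yl <- y[best - 1L]; yc <- y[best]; yr <- y[best + 1L]
  denom <- yl - 2 * yc + yr
  off <- if (denom != 0) 0.5 * (yl - yr) / denom else 0
  r_peak <- rad[best] + off * (rad[best + 1L] - rad[best])
  q_peak <- r_peak * pattern$geometry$q_per_pixel
  list(q_peak = q_peak, d_spacing = 2 * pi / q_peak,
       radius_px = rad, intensity = y)
}
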