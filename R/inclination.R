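#' Calibration curve relating fiber inclination to SLI peak distance
#'
#' For a single fiber population, the distance Delta between the two
#' peaks of the SLI azimuthal profile decreases monotonically with the
#' out-of-plane inclination alpha, from Delta(0) = 180 degrees for
#' in-plane fibers. The functional form depends on the optics and is
#' supplied as a tabulated curve; [standin_delta_curve()] ships a
#' monotone stand-in Delta = 180 * cos(alpha) with the correct endpoints.
#'
#' @param alpha_deg increasing grid of inclinations in \[0, 90\].
#' @param delta_deg corresponding peak distances, monotone non-increasing,
#'   with Delta(0) = 180 by convention.
#' @return Object of class `"calibration_curve"` (a data frame).
#' @export
calibration_curve <- function(alpha_deg, delta_deg) {
  stopifnot(length(alpha_deg) == length(delta_deg), length(alpha_deg) >= 2L)
  if (any(diff(alpha_deg) <= 0))
    stop("alpha_deg must be strictly increasing", call. = FALSE)
  if (alpha_deg[1] < 0 || alpha_deg[length(alpha_deg)] > 90)
    stop("alpha_deg must lie in [0, 90]", call. = FALSE)
  if (any(diff(delta_deg) > 1e-9))
    stop("delta_deg must be monotone non-increasing", call. = FALSE)
  structure(data.frame(alpha_deg = as.numeric(alpha_deg),
                       delta_deg = as.numeric(delta_deg)),
            class = c("calibration_curve", "data.frame"))
}

#' @rdname calibration_curve
#' @export
standin_delta_curve <- function() {
  a <- seq(0, 90, by = 1)
  calibration_curve(a, 180 * cos(a * pi / 180))
}

#' Peak distance expected for a given inclination
#'
#' Linear interpolation on a [calibration_curve].
#'
#' @param alpha_deg inclination(s) in \[0, 90\].
#' @param curve a [calibration_curve].
#' @return Peak distance(s) Delta in degrees.
#' @export
distance_from_inclination <- function(alpha_deg, curve = standin_delta_curve()) {
  if (any(alpha_deg < 0 | alpha_deg > 90))
    stop("alpha must lie in [0, 90]", call. = FALSE)
  stats::approx(curve$alpha_deg, curve$delta_deg, xout = alpha_deg,
                rule = 2)$y
}

#' Inclination inferred from a peak distance
#'
#' Inverse interpolation of a [calibration_curve]. Peak distances outside
#' the curve's range raise an error (they are flagged, not clamped). On a
#' flat curve segment the segment's midpoint inclination is returned with
#' a warning.
#'
#' @param delta_deg peak distance(s) in degrees, within the curve range.
#' @param curve a [calibration_curve].
#' @return Inclination(s) alpha in degrees.
#' @export
inclination_from_distance <- function(delta_deg, curve = standin_delta_curve()) {
  dmax <- curve$delta_deg[1]
  dmin <- curve$delta_deg[nrow(curve)]
  if (any(delta_deg > dmax + 1e-9 | delta_deg < dmin - 1e-9))
    stop("peak distance outside the calibration curve's range", call. = FALSE)
  vapply(delta_deg, function(d) {
    d <- min(max(d, dmin), dmax)
    # intervals [i, i+1] with delta[i] >= d >= delta[i+1]
    idx <- which(curve$delta_deg[-nrow(curve)] >= d - 1e-12 &
                 curve$delta_deg[-1] <= d + 1e-12)
    flat <- idx[curve$delta_deg[idx] == curve$delta_deg[idx + 1]]
    if (length(flat) > 0) {
      warning("flat calibration segment: returning its midpoint inclination",
              call. = FALSE)
      return(mean(range(curve$alpha_deg[c(flat, flat + 1)])))
    }
    i <- idx[1]
    d0 <- curve$delta_deg[i]; d1 <- curve$delta_deg[i + 1]
    a0 <- curve$alpha_deg[i]; a1 <- curve$alpha_deg[i + 1]
    a0 + (d0 - d) / (d0 - d1) * (a1 - a0)
  }, numeric(1))
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' sqrt(l1^2 + l2^2 + l3^2), in \[0, 1\].
#'
#' @param lambda1,lambda2,lambda3 nonnegative eigenvalues (vectorized).
#' @return FA value(s).
#' @export
fa_from_eigenvalues <- function(lambda1, lambda2, lambda3) {
  if (any(lambda1 < 0 | lambda2 < 0 | lambda3 < 0))
    stop("eigenvalues must be nonnegative", call. = FALSE)
  ss <- lambda1^2 + lambda2^2 + lambda3^2
  if (any(ss == 0))
    stop("FA undefined for all-zero eigenvalues", call. = FALSE)
  sqrt(0.5 * ((lambda1 - lambda2)^2 + (lambda2 - lambda3)^2 +
              (lambda3 - lambda1)^2) / ss)
}

#' Axial dot product of two orientation vectors
#'
#' |u . v| after normalization: axial (sign-invariant) co-alignment in
#' \[0, 1\].
#'
#' @param u,v 3-vectors (normalized internally).
#' @return Scalar in \[0, 1\].
#' @export
axial_dot <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("axial_dot undefined for zero-length vectors", call. = FALSE)
  min(1, abs(sum(u * v)) / (nu * nv))
}

#' 3D unit vector from in-plane orientation and inclination
#'
#' (cos alpha cos phi, cos alpha sin phi, sin alpha): phi is the axial
#' in-plane angle, alpha the elevation out of the section (xy) plane.
#'
#' @param phi_deg in-plane orientation in \[0, 180).
#' @param alpha_deg inclination in \[0, 90\].
#' @return Unit 3-vector (or n x 3 matrix for vector inputs).
#' @export
inclination_vector <- function(phi_deg, alpha_deg) {
  if (any(phi_deg < 0 | phi_deg >= 180))
    stop("phi must lie in [0, 180)", call. = FALSE)
  if (any(alpha_deg < 0 | alpha_deg > 90))
    stop("alpha must lie in [0, 90]", call. = FALSE)
  p <- phi_deg * pi / 180; a <- alpha_deg * pi / 180
  out <- cbind(cos(a) * cos(p), cos(a) * sin(p), sin(a))
  if (length(phi_deg) == 1L && length(alpha_deg) == 1L) as.numeric(out) else out
}
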