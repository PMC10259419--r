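#' Fiber populations
#'
#' A set of fiber populations occupying one pixel (or one phantom region).
#' Each population is described by its in-plane orientation `phi` (axial,
#' degrees in \[0, 180)), its out-of-plane inclination `alpha` (degrees in
#' \[0, 90\], 0 = in the section plane, 90 = perpendicular to it), and a
#' nonnegative relative amplitude `weight`. At most three populations may
#' share a pixel.
#'
#' `tilt_sign` selects towards which side of the fiber axis the paired SLI
#' lobes collapse for inclined fibers (+1 or -1); for in-plane fibers the
#' two choices coincide.
#'
#' @param phi numeric vector of in-plane orientations, degrees in \[0, 180).
#' @param alpha numeric vector of inclinations, degrees in \[0, 90\].
#' @param weight numeric vector of nonnegative relative amplitudes.
#' @param tilt_sign +1 or -1 per population.
#' @return A data frame of class `"fiber_populations"` with one row per
#'   population.
#' @export
#' @examples
#' fiber_populations(phi = c(40, 100), alpha = 0, weight = 1)
fiber_populations <- function(phi = numeric(0), alpha = 0, weight = 1,
                              tilt_sign = 1L) {
  n <- length(phi)
  if (n > 3L) stop("at most 3 fiber populations per pixel", call. = FALSE)
  alpha <- rep_len(alpha, n)
  weight <- rep_len(weight, n)
  tilt_sign <- rep_len(as.integer(tilt_sign), n)
  if (n > 0L) {
    if (any(phi < 0 | phi >= 180)) stop("phi must lie in [0, 180)", call. = FALSE)
    if (any(alpha < 0 | alpha > 90)) stop("alpha must lie in [0, 90]", call. = FALSE)
    if (any(weight < 0)) stop("weight must be nonnegative", call. = FALSE)
    if (any(!tilt_sign %in% c(-1L, 1L))) stop("tilt_sign must be +1 or -1", call. = FALSE)
  }
  structure(
    data.frame(phi = as.numeric(phi), alpha = as.numeric(alpha),
               weight = as.numeric(weight), tilt_sign = tilt_sign),
    class = c("fiber_populations", "data.frame"))
}

as_fiber_populations <- function(x) {
  if (inherits(x, "fiber_populations")) return(x)
  if (is.null(x)) return(fiber_populations())
  if (is.list(x) && !is.data.frame(x)) {
    return(fiber_populations(
      phi = vapply(x, function(p) p$phi, numeric(1)),
      alpha = vapply(x, function(p) if (is.null(p$alpha)) 0 else p$alpha, numeric(1)),
      weight = vapply(x, function(p) if (is.null(p$weight)) 1 else p$weight, numeric(1)),
      tilt_sign = vapply(x, function(p) if (is.null(p$tilt_sign)) 1L else as.integer(p$tilt_sign), integer(1))))
  }
  fiber_populations(phi = x$phi,
                    alpha = if (is.null(x$alpha)) 0 else x$alpha,
                    weight = if (is.null(x$weight)) 1 else x$weight,
                    tilt_sign = if (is.null(x$tilt_sign)) 1L else x$tilt_sign)
}

#' Build a ground-truth fiber phantom
#'
#' Lays out rectangular regions of fiber populations on a pixel grid,
#' mimicking the configurations found in coronal brain sections:
#' unidirectional in-plane bundles (corpus-callosum-like), in-plane
#' crossings (corona-radiata-like), and inclined bundles (fornix/
#' cingulum-like). Pixels not covered by any region are background
#' (tissue mask false, no populations).
#'
#' @param layout list of region descriptors. Each region is a list with
#'   elements `name` (character), `rows` and `cols` (integer ranges
#'   `c(from, to)`, 1-based inclusive), and `populations` (a
#'   [fiber_populations] object, a data frame, or a list of
#'   `list(phi=, alpha=, weight=)` entries).
#' @param shape integer `c(rows, cols)` of the section grid.
#' @param seed optional integer; the layout itself is deterministic, the
#'   seed is recorded for provenance and reproducibility of downstream
#'   rendering.
#' @return An object of class `"phantom_section"`: a list with `shape`,
#'   `regions` (validated region descriptors), `tissue_mask` (logical
#'   matrix), `region_labels` (integer matrix, 0 = background) and `seed`.
#' @export
#' @examples
#' ph <- build_phantom(list(
#'   list(name = "cc", rows = c(1, 8), cols = c(1, 16),
#'        populations = list(list(phi = 90))),
#'   list(name = "cr", rows = c(9, 16), cols = c(1, 16),
#'        populations = list(list(phi = 30), list(phi = 120)))
#' ), shape = c(16, 16))
#' table(ph$region_labels)
build_phantom <- function(layout, shape, seed = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  shape <- as.integer(shape)
  labels <- matrix(0L, shape[1], shape[2])
  regions <- vector("list", length(layout))
  for (k in seq_along(layout)) {
    reg <- layout[[k]]
    if (is.null(reg$rows) || is.null(reg$cols))
      stop("region ", k, ": rows and cols ranges required", call. = FALSE)
    rr <- as.integer(reg$rows); cc <- as.integer(reg$cols)
    if (rr[1] < 1L || rr[2] > shape[1] || cc[1] < 1L || cc[2] > shape[2] ||
        rr[1] > rr[2] || cc[1] > cc[2])
      stop("region ", k, ": range outside the phantom grid", call. = FALSE)
    pops <- as_fiber_populations(reg$populations)
    if (nrow(pops) < 1L)
      stop("region ", k, ": at least one population required", call. = FALSE)
    block <- labels[rr[1]:rr[2], cc[1]:cc[2]]
    if (any(block != 0L))
      stop("region ", k, " overlaps region ", max(block),
           ": conflicting populations", call. = FALSE)
    labels[rr[1]:rr[2], cc[1]:cc[2]] <- k
    regions[[k]] <- list(name = if (is.null(reg$name)) paste0("region", k) else reg$name,
                         rows = rr, cols = cc, populations = pops)
  }
  structure(list(shape = shape, regions = regions,
                 tissue_mask = labels > 0L, region_labels = labels,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phantom_section")
}

#' @export
print.phantom_section <- function(x, ...) {
  cat("Phantom section", x$shape[1], "x", x$shape[2], "px,",
      length(x$regions), "region(s),",
      sum(x$tissue_mask), "tissue pixel(s)\n")
  for (k in seq_along(x$regions)) {
    r <- x$regions[[k]]
    cat(sprintf("  [%d] %-10s rows %d-%d cols %d-%d  phi = {%s}\n", k, r$name,
                r$rows[1], r$rows[2], r$cols[1], r$cols[2],
                paste(round(r$populations$phi, 1), collapse = ", ")))
  }
  invisible(x)
}

#' Populations at one phantom pixel
#'
#' @param phantom a [build_phantom] result.
#' @param row,col 1-based pixel indices.
#' @return A [fiber_populations] object (zero rows for background pixels).
#' @export
phantom_populations <- function(phantom, row, col) {
  lab <- phantom$region_labels[row, col]
  if (lab == 0L) fiber_populations() else phantom$regions[[lab]]$populations
}

#' Ground-truth per-pixel maps of a phantom
#'
#' Converts a phantom's region layout into the same per-pixel containers
#' the analysis produces, for direct comparison: an [orientation map]
#' holding each pixel's true in-plane orientations (axial, degrees) and
#' population count, and matrices of the first population's inclination
#' and the region labels.
#'
#' @param phantom a [build_phantom] result.
#' @return A list with `orientation_map` (class `"orientation_map"`),
#'   `alpha` (matrix of first-population inclination, NA on background)
#'   and `region_labels`.
#' @export
phantom_ground_truth <- function(phantom) {
  nr <- phantom$shape[1]; nc <- phantom$shape[2]
  ori <- array(NA_real_, c(nr, nc, 3L))
  n_ori <- matrix(0L, nr, nc)
  alpha <- matrix(NA_real_, nr, nc)
  for (k in seq_along(phantom$regions)) {
    reg <- phantom$regions[[k]]
    idx_r <- reg$rows[1]:reg$rows[2]; idx_c <- reg$cols[1]:reg$cols[2]
    pops <- reg$populations
    ord <- order(pops$weight, decreasing = TRUE)
    for (j in seq_along(ord))
      ori[idx_r, idx_c, j] <- pops$phi[ord[j]] %% 180
    n_ori[idx_r, idx_c] <- nrow(pops)
    alpha[idx_r, idx_c] <- pops$alpha[ord[1]]
  }
  omap <- new_orientation_map(orientations = ori, n_orientations = n_ori,
                              peak_distance = matrix(NA_real_, nr, nc),
                              n_peaks = 2L * n_ori)
  list(orientation_map = omap, alpha = alpha,
       region_labels = phantom$region_labels)
}
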