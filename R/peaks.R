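# Cyclic peak analysis of azimuthal profiles: peak detection with
# prominence filtering, width measurement, sub-bin refinement, and
# pairing of peaks into in-plane axial fiber orientations.

#' Set of detected azimuthal peaks
#'
#' @param position_deg sub-bin-refined peak azimuths in \[0, 360),
#'   strictly increasing.
#' @param prominence peak prominences (vertical distance between the peak
#'   top and the higher of its two neighboring minima).
#' @param width_deg full widths at (height - prominence/2).
#' @param profile_amplitude max - min of the source profile's valid bins.
#' @return Object of class `"peak_set"` (a data frame with the amplitude
#'   as an attribute).
#' @export
peak_set <- function(position_deg = numeric(0), prominence = numeric(0),
                     width_deg = numeric(0), profile_amplitude = NA_real_) {
  ord <- order(position_deg)
  structure(data.frame(position_deg = position_deg[ord],
                       prominence = prominence[ord],
                       width_deg = width_deg[ord]),
            profile_amplitude = profile_amplitude,
            class = c("peak_set", "data.frame"))
}

# cyclic separation in [0, 180]
cyclic_separation <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Detect peaks in a cyclic azimuthal profile
#'
#' Finds all cyclic local maxima (plateaus count once, at their center),
#' measures each peak's prominence as the vertical distance between its
#' top and the higher of the two neighboring minima, and retains only
#' peaks whose prominence exceeds `prominence_frac` of the profile's
#' total amplitude (max - min over valid bins; default 8%). Retained
#' peaks get a full width measured at (height - prominence/2) with linear
#' interpolation between bins, and single-bin peaks are refined to
#' sub-bin positions by 3-point parabolic interpolation.
#'
#' Invalid bins interrupt the profile: peaks whose neighborhood (out to
#' the adjacent valleys) contains an invalid bin are dropped.
#'
#' @param profile an [azimuthal_profile] with at least 8 valid bins.
#' @param prominence_frac relative prominence threshold (default 0.08).
#' @return A [peak_set]; empty for constant profiles.
#' @export
#' @examples
#' v <- rep(1, 24); v[c(3, 15)] <- 5  # peaks at 30 and 210 deg
#' find_peaks_cyclic(azimuthal_profile(v))
find_peaks_cyclic <- function(profile, prominence_frac = 0.08) {
  stopifnot(inherits(profile, "azimuthal_profile"))
  v <- profile$values
  ok <- profile$valid
  n <- length(v)
  if (sum(ok) < 8L)
    stop("profile must have at least 8 valid bins", call. = FALSE)
  amp <- max(v[ok]) - min(v[ok])
  if (amp == 0) return(peak_set(profile_amplitude = 0))
  w <- profile$bin_width_deg
  lab0 <- profile$bin_centers_deg[1]

  vv <- v
  vv[!ok] <- NA_real_

  # rotate so index 1 starts a new run (value differs from its cyclic
  # predecessor); guaranteed to exist since the profile is not constant
  run_break <- function(a, b) {
    (is.na(a) != is.na(b)) | (!is.na(a) & !is.na(b) & a != b)
  }
  differs <- which(run_break(vv, vv[c(n, seq_len(n - 1L))]))
  start <- differs[1]
  rot <- ((seq_len(n) + start - 2L) %% n) + 1L  # rotated -> original index
  rv <- vv[rot]

  # run-length encode the rotated profile
  runs_end <- c(which(run_break(rv[seq_len(n - 1L)], rv[seq_len(n - 1L) + 1L])), n)
  runs_start <- c(1L, utils::head(runs_end, -1L) + 1L)
  run_val <- rv[runs_start]
  nr <- length(run_val)
  if (nr < 2L) return(peak_set(profile_amplitude = amp))

  prev_val <- run_val[c(nr, seq_len(nr - 1L))]
  next_val <- run_val[c(seq_len(nr - 1L) + 1L, 1L)]
  is_peak <- !is.na(run_val) &
    (!is.na(prev_val) & run_val > prev_val) &
    (!is.na(next_val) & run_val > next_val)
  pk_runs <- which(is_peak)
  if (length(pk_runs) == 0L) return(peak_set(profile_amplitude = amp))

  # valley (minimum value) in the gap after each peak run, up to the next
  # peak run (cyclically); NA if the gap contains an invalid bin
  gap_min_after <- function(k_idx) {
    pos <- match(k_idx, pk_runs)
    nxt <- pk_runs[pos %% length(pk_runs) + 1L]
    ridx <- if (nxt > k_idx) (k_idx + 1L):(nxt - 1L)
            else if (nxt == k_idx) setdiff(seq_len(nr), k_idx)
            else c(if (k_idx < nr) (k_idx + 1L):nr else integer(0),
                   if (nxt > 1L) 1L:(nxt - 1L) else integer(0))
    if (length(ridx) == 0L) return(NA_real_)
    vals <- run_val[ridx]
    if (anyNA(vals)) return(NA_real_)
    min(vals)
  }
  valley_after <- vapply(pk_runs, gap_min_after, numeric(1))
  np <- length(pk_runs)
  valley_before <- valley_after[c(np, seq_len(np - 1L))]
  prom <- run_val[pk_runs] - pmax(valley_before, valley_after)

  keep <- !is.na(prom) & prom > prominence_frac * amp
  pk_runs <- pk_runs[keep]; prom <- prom[keep]
  if (length(pk_runs) == 0L) return(peak_set(profile_amplitude = amp))

  # positions: plateau center, or parabolic refinement for single bins
  pos_deg <- numeric(length(pk_runs))
  width_deg <- numeric(length(pk_runs))
  for (j in seq_along(pk_runs)) {
    k <- pk_runs[j]
    i0 <- runs_start[k]; i1 <- runs_end[k]
    mid <- (i0 + i1) / 2              # rotated, 1-based (may be .5)
    top <- run_val[k]
    if (i0 == i1) {
      yl <- rv[(i0 - 2L) %% n + 1L]; yr <- rv[i0 %% n + 1L]
      denom <- yl - 2 * top + yr
      off <- if (!is.na(yl) && !is.na(yr) && denom != 0)
        max(-0.5, min(0.5, 0.5 * (yl - yr) / denom)) else 0
      mid <- i0 + off
    }
    # map rotated fractional index to degrees
    orig <- (start - 1L + (mid - 1L)) %% n    # 0-based fractional bin
    pos_deg[j] <- (lab0 + orig * w) %% 360

    # width at top - prom/2, walking out from the run edges
    h <- top - prom[j] / 2
    left_x <- NA_real_
    i <- i0
    for (s in seq_len(n)) {
      iprev <- (i - 2L) %% n + 1L
      a <- rv[iprev]
      if (is.na(a)) break
      if (a < h) {
        frac <- (rv[i] - h) / (rv[i] - a)
        left_x <- (i - 1L) - frac
        break
      }
      i <- iprev
    }
    right_x <- NA_real_
    i <- i1
    for (s in seq_len(n)) {
      inext <- i %% n + 1L
      a <- rv[inext]
      if (is.na(a)) break
      if (a < h) {
        frac <- (rv[i] - h) / (rv[i] - a)
        right_x <- (i - 1L) + frac
        break
      }
      i <- inext
    }
    width_deg[j] <- if (is.na(left_x) || is.na(right_x)) NA_real_
      else ((right_x - left_x) %% n) * w
  }
  peak_set(pos_deg, prom, width_deg, profile_amplitude = amp)
}

# enumerate all ways to partition peaks into antipodal-tolerance pairs
# plus leftovers; returns the pairing maximizing the number of pairs,
# tie-broken by minimal total deviation from 180 degrees
best_antipodal_pairing <- function(positions, pair_tol_deg) {
  m <- length(positions)
  dev <- outer(positions, positions,
               function(a, b) 180 - cyclic_separation(a, b))
  admissible <- dev <= pair_tol_deg  # separation >= 180 - tol
  best <- list(pairs = matrix(integer(0), 0, 2), total_dev = Inf)
  recurse <- function(remaining, pairs, total_dev) {
    if (length(remaining) < 2L) {
      npairs <- nrow(pairs)
      if (npairs > nrow(best$pairs) ||
          (npairs == nrow(best$pairs) && total_dev < best$total_dev))
        best <<- list(pairs = pairs, total_dev = total_dev)
      return(invisible())
    }
    i <- remaining[1]
    # leave i unpaired
    recurse(remaining[-1], pairs, total_dev)
    for (j in remaining[-1]) {
      if (admissible[i, j])
        recurse(setdiff(remaining, c(i, j)), rbind(pairs, c(i, j)),
                total_dev + dev[i, j])
    }
  }
  recurse(seq_len(m), matrix(integer(0), 0, 2), 0)
  best$pairs
}

#' Pair azimuthal peaks into in-plane fiber orientations
#'
#' A fiber orientation corresponds to a pair of azimuthal peaks lying
#' 180 +/- `pair_tol_deg` degrees apart; its orientation is the circular
#' mid-position of the pair, modulo 180. In scattering modalities (SLI,
#' SAXS) the lobes are perpendicular to the fiber so the mid-position is
#' the fiber orientation itself; for FODs sampled in-plane the lobes lie
#' along the fiber and 90 degrees are added. When more than two peaks
#' admit several pairings, the pairing maximizing the number of pairs is
#' chosen, tie-broken by minimal total deviation from 180 degrees.
#' Leftover (unpairable) peaks yield no orientation. At most three
#' orientations are returned, sorted by the summed prominence of their
#' peak pairs.
#'
#' @param peaks a [peak_set] (already prominence-filtered).
#' @param pair_tol_deg tolerance around 180 degrees (default 35).
#' @param mode `"scattering"` (lobes perpendicular to the fiber) or
#'   `"fod"` (lobes along the fiber).
#' @return Numeric vector of axial orientations in \[0, 180), possibly
#'   empty.
#' @export
#' @examples
#' pk <- peak_set(c(30, 210), prominence = c(4, 4), width_deg = c(30, 30))
#' pair_peaks_to_orientations(pk)  # 120
pair_peaks_to_orientations <- function(peaks, pair_tol_deg = 35,
                                       mode = c("scattering", "fod")) {
  mode <- match.arg(mode)
  stopifnot(inherits(peaks, "peak_set"))
  m <- nrow(peaks)
  if (m < 2L) return(numeric(0))
  pairs <- best_antipodal_pairing(peaks$position_deg, pair_tol_deg)
  if (nrow(pairs) == 0L) return(numeric(0))
  ori <- numeric(nrow(pairs)); score <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p1 <- peaks$position_deg[pairs[k, 1]]
    p2 <- peaks$position_deg[pairs[k, 2]]
    mid <- ((p1 + p2) / 2) %% 180
    if (mode == "fod") mid <- (mid + 90) %% 180
    ori[k] <- mid
    score[k] <- peaks$prominence[pairs[k, 1]] + peaks$prominence[pairs[k, 2]]
  }
  ori <- ori[order(score, decreasing = TRUE)]
  utils::head(ori, 3L)
}

#' Peak distance of a profile
#'
#' The cyclic separation of a profile's two peaks, reported in
#' \[0, 180\]: 180 degrees for in-plane fibers, shrinking with fiber
#' inclination in SLI. Profiles with one peak yield zero; profiles with
#' no peaks or more than two peaks yield NA (not interpretable).
#'
#' @param peaks a [peak_set].
#' @return Delta in degrees, or NA.
#' @export
peak_distance <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  m <- nrow(peaks)
  if (m == 0L || m > 2L) return(NA_real_)
  if (m == 1L) return(0)
  cyclic_separation(peaks$position_deg[1], peaks$position_deg[2])
}

new_orientation_map <- function(orientations, n_orientations, peak_distance,
                                n_peaks) {
  structure(list(orientations = orientations,
                 n_orientations = n_orientations,
                 peak_distance = peak_distance,
                 n_peaks = n_peaks),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat("Orientation map:", nrow(x$n_orientations), "x", ncol(x$n_orientations),
      "px; pixels by orientation count:\n")
  print(table(factor(x$n_orientations, levels = 0:3)))
  invisible(x)
}

#' Per-pixel peak analysis of a profile map
#'
#' Runs [find_peaks_cyclic], [pair_peaks_to_orientations] and
#' [peak_distance] on every pixel of a [profile_map], and computes the
#' descriptive parameter maps of the profiles (average, maximum, minimum
#' intensity; mean prominence and mean width over retained peaks).
#'
#' @param pmap a [profile_map].
#' @param prominence_frac relative prominence threshold (default 0.08).
#' @param pair_tol_deg pairing tolerance around 180 degrees (default 35).
#' @param mode `"scattering"` or `"fod"`, see
#'   [pair_peaks_to_orientations].
#' @param single_peak_orientation if TRUE, pixels with exactly one peak
#'   are assigned the low-confidence orientation (peak + 90) mod 180
#'   (scattering mode; the peak position itself in fod mode). Off by
#'   default: the pairing rule requires a peak pair.
#' @return List with `orientation_map` (class `"orientation_map"`:
#'   `orientations` rows x cols x 3, `n_orientations`, `peak_distance`,
#'   `n_peaks`) and `parameter_maps` (class `"parameter_maps"`:
#'   `average`, `maximum`, `minimum`, `mean_prominence`, `mean_width`).
#' @export
analyze_profile_map <- function(pmap, prominence_frac = 0.08,
                                pair_tol_deg = 35,
                                mode = c("scattering", "fod"),
                                single_peak_orientation = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(pmap, "profile_map"))
  d <- dim(pmap$values)
  nr <- d[1]; nc <- d[2]
  ori <- array(NA_real_, c(nr, nc, 3L))
  n_ori <- matrix(0L, nr, nc)
  pdist <- matrix(NA_real_, nr, nc)
  n_pk <- matrix(0L, nr, nc)
  avg <- matrix(NA_real_, nr, nc); mx <- avg; mn <- avg
  mprom <- matrix(NA_real_, nr, nc); mwidth <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      prof <- profile_at(pmap, r, cc)
      vals <- prof$values[prof$valid]
      avg[r, cc] <- mean(vals); mx[r, cc] <- max(vals); mn[r, cc] <- min(vals)
      pk <- find_peaks_cyclic(prof, prominence_frac)
      n_pk[r, cc] <- nrow(pk)
      pdist[r, cc] <- peak_distance(pk)
      if (nrow(pk) > 0L) {
        mprom[r, cc] <- mean(pk$prominence)
        mwidth[r, cc] <- mean(pk$width_deg)
      }
      o <- pair_peaks_to_orientations(pk, pair_tol_deg, mode)
      if (length(o) == 0L && single_peak_orientation && nrow(pk) == 1L) {
        o <- if (mode == "scattering") (pk$position_deg + 90) %% 180
             else pk$position_deg %% 180
      }
      if (length(o) > 0L) {
        n_ori[r, cc] <- length(o)
        ori[r, cc, seq_along(o)] <- o
      }
    }
  }
  list(orientation_map = new_orientation_map(ori, n_ori, pdist, n_pk),
       parameter_maps = structure(list(average = avg, maximum = mx,
                                       minimum = mn, mean_prominence = mprom,
                                       mean_width = mwidth),
                                  class = "parameter_maps"))
}
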