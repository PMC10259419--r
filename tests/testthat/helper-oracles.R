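# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Naive cyclic peak finder: scan every bin; a peak is a bin strictly
# greater than both cyclic neighbors; its prominence is the drop to the
# higher of the two neighboring minima, found by walking outward to the
# adjacent peaks. No plateau handling: intended for tie-free profiles.
bf_find_peaks <- function(values, prominence_frac = 0.08) {
  n <- length(values)
  at <- function(i) values[(i - 1) %% n + 1]
  peaks <- integer(0)
  for (i in seq_len(n)) {
    if (at(i) > at(i - 1) && at(i) > at(i + 1)) peaks <- c(peaks, i)
  }
  if (length(peaks) == 0) {
    return(data.frame(bin = integer(0), prominence = numeric(0)))
  }
  amp <- max(values) - min(values)
  is_peak <- seq_len(n) %in% peaks
  prom <- vapply(peaks, function(i) {
    # walk outward to the neighboring minima: the lowest value reached
    # before the next peak on each side (the whole rest of the circle
    # for a lone peak)
    leftmin <- at(i - 1)
    j <- i - 1
    while (!is_peak[(j - 1) %% n + 1] && j > i - n) {
      leftmin <- min(leftmin, at(j))
      j <- j - 1
    }
    rightmin <- at(i + 1)
    j <- i + 1
    while (!is_peak[(j - 1) %% n + 1] && j < i + n) {
      rightmin <- min(rightmin, at(j))
      j <- j + 1
    }
    at(i) - max(leftmin, rightmin)
  }, numeric(1))
  keep <- prom > prominence_frac * amp
  data.frame(bin = peaks[keep], prominence = prom[keep])
}

# Exhaustive pairing oracle: enumerates every partition of the peak
# positions into pairs and singletons, keeps only partitions whose pairs
# all satisfy the antipodal tolerance, and returns the orientations of a
# partition with the maximum number of pairs and, among those, minimal
# total deviation from 180 degrees.
bf_pair_orientations <- function(positions, tol = 35) {
  sep <- function(a, b) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  all_partitions <- function(idx) {
    if (length(idx) == 0) return(list(list()))
    i <- idx[1]
    out <- list()
    for (p in all_partitions(idx[-1])) out <- c(out, list(p))  # i single
    for (j in idx[-1]) {
      rest <- setdiff(idx, c(i, j))
      for (p in all_partitions(rest)) out <- c(out, list(c(p, list(c(i, j)))))
    }
    out
  }
  best <- NULL; best_n <- -1; best_dev <- Inf
  for (p in all_partitions(seq_along(positions))) {
    devs <- vapply(p, function(pr) 180 - sep(positions[pr[1]], positions[pr[2]]),
                   numeric(1))
    if (any(devs > tol)) next
    if (length(p) > best_n || (length(p) == best_n && sum(devs) < best_dev)) {
      best <- p; best_n <- length(p); best_dev <- sum(devs)
    }
  }
  if (is.null(best) || length(best) == 0) return(numeric(0))
  sort(vapply(best, function(pr) {
    ((positions[pr[1]] + positions[pr[2]]) / 2) %% 180
  }, numeric(1)))
}

# Real spherical harmonics via pracma's associated Legendre functions
# (an implementation path independent of the package's recurrence).
oracle_sh_basis <- function(directions, lmax) {
  directions <- rbind(directions)
  directions <- directions / sqrt(rowSums(directions^2))
  ct <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  K <- sum(2 * seq(0, lmax, by = 2) + 1)
  out <- matrix(0, nrow(directions), K)
  j <- 0
  for (l in seq(0, lmax, by = 2)) {
    # pracma::legendre(l, x): (l+1) x n matrix of P_l^m, m = 0..l, with
    # the Condon-Shortley phase
    P <- if (l == 0) matrix(1, 1, length(ct)) else pracma::legendre(l, ct)
    for (m in (-l):l) {
      j <- j + 1
      am <- abs(m)
      norm <- sqrt((2 * l + 1) / (4 * pi) *
                     factorial(l - am) / factorial(l + am))
      # package convention: Nbar_m^m built with -sqrt((2m+1)/(2m)) * sin,
      # which equals the Condon-Shortley P_l^m; signs match directly
      plm <- norm * P[am + 1, ]
      out[, j] <- if (m == 0) plm
        else if (m > 0) sqrt(2) * plm * cos(m * phi)
        else sqrt(2) * plm * sin(am * phi)
    }
  }
  out
}

# Simple tie-free random cyclic profile: mixture of von Mises bumps plus
# jitter, guaranteed free of exact ties.
random_profile <- function(n_bins, n_bumps = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- 360 / n_bins
  bins <- seq(0, 360 - w, by = w)
  v <- rep(0.5, n_bins)
  for (k in seq_len(n_bumps)) {
    ctr <- runif(1, 0, 360)
    kap <- runif(1, 2, 15)
    v <- v + runif(1, 0.3, 1.5) * exp(kap * (cos((bins - ctr) * pi / 180) - 1))
  }
  v <- v + runif(n_bins, 0, 1e-3)
  azimuthal_profile(v)
}

# Default two-region phantom used across tests: a unidirectional
# corpus-callosum-like band over an in-plane crossing region.
demo_phantom <- function(shape = c(16, 16), phi_single = 70,
                         phi_cross = c(40, 100)) {
  build_phantom(list(
    list(name = "cc", rows = c(1, shape[1] %/% 2), cols = c(1, shape[2]),
         populations = list(list(phi = phi_single))),
    list(name = "cr", rows = c(shape[1] %/% 2 + 1, shape[1]),
         cols = c(1, shape[2]),
         populations = list(list(phi = phi_cross[1]),
                            list(phi = phi_cross[2])))
  ), shape = shape)
}

# SAXS detector geometry used across tests: large enough that per-segment
# pixel-count aliasing is small relative to real anisotropy (myelin ring
# at ~100 px radius).
saxs_test_geom <- function(n = 256, q_per_pixel = 0.0036) {
  detector_geometry(c(n, n), c(n / 2 + 0.5, n / 2 + 0.5), q_per_pixel)
}
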