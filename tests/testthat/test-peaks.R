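test_that("two spikes on a flat background are found with exact prominence", {
  v <- rep(1, 24); v[c(3, 15)] <- 5  # bins at 30 and 210 deg
  pk <- find_peaks_cyclic(azimuthal_profile(v))
  expect_equal(pk$position_deg, c(30, 210))
  expect_equal(pk$prominence, c(4, 4))
})

test_that("constant profiles yield an empty peak set", {
  pk <- find_peaks_cyclic(azimuthal_profile(rep(2, 24)))
  expect_equal(nrow(pk), 0)
  expect_equal(attr(pk, "profile_amplitude"), 0)
})

test_that("sub-threshold bumps are rejected by the 8% prominence rule", {
  v <- rep(1, 36)
  v[c(5, 23)] <- 5                  # main peaks, prominence 4
  v[14] <- 1.2                      # bump prominence 0.2 < 0.08 * 4 = 0.32
  pk <- find_peaks_cyclic(azimuthal_profile(v))
  expect_equal(nrow(pk), 2)
  # a bump just above threshold is kept
  v[14] <- 1 + 0.33
  pk2 <- find_peaks_cyclic(azimuthal_profile(v))
  expect_equal(nrow(pk2), 3)
})

test_that("peaks spanning the 0/360 wrap are detected once", {
  v <- rep(0.5, 24)
  v[24] <- 2; v[1] <- 3; v[2] <- 2  # shoulders around a max at bin 1 (0 deg)
  pk <- find_peaks_cyclic(azimuthal_profile(v))
  expect_equal(nrow(pk), 1)
  expect_lt(min(pk$position_deg, 360 - pk$position_deg), 15)
})

test_that("plateau peaks are reported once, at the plateau center", {
  v <- rep(1, 24); v[c(7, 8)] <- 4  # plateau over bins at 90 and 105 deg
  pk <- find_peaks_cyclic(azimuthal_profile(v))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position_deg, 97.5)
})

test_that("invalid bins interrupting a peak's neighborhood drop it", {
  v <- rep(1, 24); v[c(3, 15)] <- 5
  ok <- rep(TRUE, 24); ok[c(8, 9, 10, 20, 21)] <- FALSE
  pk <- find_peaks_cyclic(azimuthal_profile(v, valid = ok))
  expect_equal(nrow(pk), 0)
})

test_that("profiles with fewer than 8 valid bins are rejected", {
  expect_error(find_peaks_cyclic(azimuthal_profile(rep(1, 6))), "8 valid")
  v <- runif(24); ok <- c(rep(TRUE, 7), rep(FALSE, 17))
  expect_error(find_peaks_cyclic(azimuthal_profile(v, valid = ok)), "8 valid")
})

test_that("peak finder matches the brute-force oracle on random profiles", {
  for (seed in 1:25) {
    n <- sample(c(16, 24, 36, 48), 1)
    prof <- random_profile(n, n_bumps = sample(1:4, 1), seed = seed)
    got <- find_peaks_cyclic(prof)
    want <- bf_find_peaks(prof$values)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want) > 0) {
      w <- 360 / n
      want_pos <- sort((want$bin - 1) * w)
      got_sorted <- got[order(got$position_deg), ]
      # refined positions stay within one bin of the oracle's bin position
      expect_lt(max(cyclic_separation(got_sorted$position_deg, want_pos)),
                w + 1e-9)
      expect_equal(sort(got_sorted$prominence), sort(want$prominence),
                   tolerance = 1e-12, info = paste("seed", seed))
    }
  }
})

test_that("peak analysis is shift-equivariant and scale-invariant", {
  prof <- random_profile(24, n_bumps = 2, seed = 42)
  base <- find_peaks_cyclic(prof)
  base_ori <- pair_peaks_to_orientations(base)
  for (k in c(3, 11, 17)) {
    shifted <- azimuthal_profile(c(utils::tail(prof$values, -k),
                                   utils::head(prof$values, k)))
    # value at bin b of `shifted` is the original bin b + k: peaks move
    # to lower azimuth by k bins, i.e. original position - k * 15
    got <- find_peaks_cyclic(shifted)
    expect_equal(sort(got$position_deg %% 360),
                 sort((base$position_deg - k * 15) %% 360),
                 tolerance = 1e-9)
    expect_equal(peak_distance(got), peak_distance(base), tolerance = 1e-9)
    got_ori <- pair_peaks_to_orientations(got)
    expect_equal(sort(got_ori), sort((base_ori - k * 15) %% 180),
                 tolerance = 1e-9)
  }
  for (c_ in c(0.25, 7)) {
    scaled <- find_peaks_cyclic(azimuthal_profile(c_ * prof$values))
    expect_equal(scaled$position_deg, base$position_deg)
    expect_equal(scaled$prominence, c_ * base$prominence)
    expect_equal(scaled$width_deg, base$width_deg, tolerance = 1e-9)
  }
})

test_that("peak width is the full width at height minus half prominence", {
  # triangular peak: values 1,3,5,3,1 around bin 7 on a baseline of 1
  v <- rep(1, 24); v[5:9] <- c(1, 3, 5, 3, 1)
  pk <- find_peaks_cyclic(azimuthal_profile(v))
  expect_equal(nrow(pk), 1)
  # prominence 4, measure height 5 - 2 = 3: crossings at linear
  # interpolation between bins 5..6 and 8..9, each at offset 1/2 bin
  expect_equal(pk$width_deg, 2 * 15, tolerance = 1e-9)
})

test_that("antipodal peak pairs give the circular mid-position mod 180", {
  mk <- function(pos) peak_set(pos, prominence = rep(1, length(pos)),
                               width_deg = rep(20, length(pos)))
  expect_equal(pair_peaks_to_orientations(mk(c(0, 180))), 90)
  expect_equal(pair_peaks_to_orientations(mk(c(30, 210))), 120)
  expect_equal(sort(pair_peaks_to_orientations(mk(c(30, 90, 210, 270)))),
               c(0, 120))
  expect_equal(pair_peaks_to_orientations(mk(c(10, 175))), 92.5)
  # three equally spaced peaks: no pair within 180 +/- 35
  expect_equal(length(pair_peaks_to_orientations(mk(c(0, 120, 240)))), 0)
  # fod mode: lobes lie along the fiber, orientation is rotated by 90
  expect_equal(pair_peaks_to_orientations(mk(c(0, 180)), mode = "fod"), 0)
})

test_that("pairing matches the exhaustive-partition oracle", {
  set.seed(99)
  for (rep_ in 1:20) {
    m <- sample(2:6, 1)
    pos <- sort(runif(m, 0, 360))
    pk <- peak_set(pos, prominence = rep(1, m), width_deg = rep(20, m))
    got <- sort(pair_peaks_to_orientations(pk))
    want <- utils::head(bf_pair_orientations(pos), 3)
    if (length(got) == length(want)) {
      expect_equal(got, sort(want), tolerance = 1e-9)
    } else {
      # implementation caps at 3 orientations
      expect_lte(length(got), 3)
      expect_gt(length(want), 3)
    }
  }
})

test_that("peak distance follows the one-or-two-peaks rule", {
  mk <- function(pos) peak_set(pos, prominence = rep(1, length(pos)),
                               width_deg = rep(20, length(pos)))
  expect_true(is.na(peak_distance(mk(numeric(0)))))
  expect_equal(peak_distance(mk(45)), 0)
  expect_equal(peak_distance(mk(c(30, 210))), 180)
  expect_equal(peak_distance(mk(c(40, 180))), 140)
  expect_true(is.na(peak_distance(mk(c(10, 90, 170)))))
})

test_that("profile-map analysis recovers phantom orientations end to end", {
  ph <- demo_phantom(c(8, 10))
  st <- render_sli_stack(ph, noise = "none")
  res <- analyze_profile_map(angular_stack_to_profiles(st))
  om <- res$orientation_map
  # unidirectional region: one orientation ~70, peak distance ~180
  expect_true(all(om$n_orientations[1:4, ] == 1L))
  expect_lt(max(abs(om$orientations[1:4, , 1] - 70)), 2.4)
  expect_lt(max(abs(om$peak_distance[1:4, ] - 180)), 15)
  # crossing region: two orientations ~{40, 100}
  expect_true(all(om$n_orientations[5:8, ] == 2L))
  lo <- pmin(om$orientations[5:8, , 1], om$orientations[5:8, , 2])
  hi <- pmax(om$orientations[5:8, , 1], om$orientations[5:8, , 2])
  expect_lt(max(abs(lo - 40)), 2.4)
  expect_lt(max(abs(hi - 100)), 2.4)
  expect_true(all(is.na(om$peak_distance[5:8, ])))  # 4 peaks
})

test_that("background pixels and parameter maps behave", {
  ph <- build_phantom(list(list(rows = c(1, 2), cols = c(1, 6),
                                populations = list(list(phi = 20)))),
                      shape = c(4, 6))
  st <- render_sli_stack(ph, noise = "none", baseline = 0.25)
  res <- analyze_profile_map(angular_stack_to_profiles(st))
  om <- res$orientation_map; pmaps <- res$parameter_maps
  expect_true(all(om$n_peaks[3:4, ] == 0L))
  expect_true(all(om$n_orientations[3:4, ] == 0L))
  expect_equal(pmaps$average[3:4, ], matrix(0.25, 2, 6))
  expect_true(all(is.na(pmaps$mean_prominence[3:4, ])))
  # min <= average <= max pixel-wise
  expect_true(all(pmaps$minimum <= pmaps$average + 1e-12))
  expect_true(all(pmaps$average <= pmaps$maximum + 1e-12))
  expect_true(all(om$n_orientations <= 3L))
})

test_that("a merged high-inclination lobe is one peak with zero distance", {
  pops <- fiber_populations(phi = 30, alpha = 85)
  prof <- sli_forward_profile(pops, n_bins = 24, baseline = 0.1)
  pmap <- profile_map(array(prof$values, c(1, 1, 24)))
  off <- analyze_profile_map(pmap)
  expect_equal(off$orientation_map$n_peaks[1, 1], 1L)
  expect_equal(off$orientation_map$n_orientations[1, 1], 0L)
  expect_equal(off$orientation_map$peak_distance[1, 1], 0)
})

test_that("single-peak orientation assignment is off by default and switchable", {
  # in-plane fiber at phi = 30 with one of its perpendicular lobes
  # suppressed: a lone peak at 120 deg
  w <- 360 / 24
  bins <- seq(0, 360 - w, by = w)
  v <- 0.1 + exp(20 * (cos((bins - 120) * pi / 180) - 1))
  pmap <- profile_map(array(v, c(1, 1, 24)))
  off <- analyze_profile_map(pmap)
  expect_equal(off$orientation_map$n_peaks[1, 1], 1L)
  expect_equal(off$orientation_map$n_orientations[1, 1], 0L)
  on <- analyze_profile_map(pmap, single_peak_orientation = TRUE)
  expect_equal(on$orientation_map$n_orientations[1, 1], 1L)
  expect_equal(on$orientation_map$orientations[1, 1, 1], 30, tolerance = 1e-6)
})
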