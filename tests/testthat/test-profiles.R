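test_that("scatterometry assembly reads one pixel across the illumination grid", {
  stack <- array(0, c(5, 4, 3, 3))
  stack[3, 2, , ] <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  pat <- assemble_scatterometry_pattern(stack, c(2, 3))
  expect_equal(dim(pat$data), c(5, 4))
  expect_equal(pat$data[3, 2], stack[3, 2, 2, 3])
  expect_equal(sum(pat$data != 0), 1)  # single lit source
  expect_error(assemble_scatterometry_pattern(stack, c(4, 1)), "bounds")
})

test_that("an 80x80 illumination grid yields an 80x80 pattern", {
  stack <- array(runif(80 * 80 * 2 * 2), c(80, 80, 2, 2))
  pat <- assemble_scatterometry_pattern(stack, c(1, 2))
  expect_equal(dim(pat$data), c(80, 80))
  expect_equal(pat$data, stack[, , 1, 2])
})

test_that("missing illumination positions are marked invalid", {
  stack <- array(1, c(4, 4, 2, 2))
  stack[2, 3, , ] <- NA
  pat <- assemble_scatterometry_pattern(stack, c(1, 1))
  expect_false(pat$valid_mask[2, 3])
  expect_true(all(pat$valid_mask[-(2 + (3 - 1) * 4)]))
})

test_that("constant images assemble to a constant pattern", {
  stack <- array(0.7, c(6, 6, 2, 2))
  pat <- assemble_scatterometry_pattern(stack, c(2, 2))
  expect_true(all(pat$data == 0.7))
})

test_that("SLI pattern center is the intensity argmax with row/col tie rule", {
  d <- matrix(0.1, 7, 7)
  d[3, 5] <- 2; d[6, 2] <- 2  # tie: smaller row wins
  pat <- scattering_pattern(d)
  expect_equal(pat$center, c(3, 5))
  expect_error(scattering_pattern(matrix(0, 4, 4)), "center undefined")
})

test_that("a radially symmetric SLI pattern gives a near-constant profile", {
  n <- 121; ctr <- 61
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  d <- exp(-(r - 30)^2 / (2 * 64)); d[ctr, ctr] <- 10  # bright center
  prof <- sli_pattern_to_profile(scattering_pattern(d), bin_width_deg = 30)
  v <- prof$values
  # residual variation is pixel-grid aliasing of the wedge boundaries
  expect_lt((max(v) - min(v)) / mean(v), 0.1)
})

test_that("a single-wedge pattern fills only its segment's bin", {
  d <- matrix(0, 21, 21); d[11, 11] <- 10  # maximum -> center
  # pixels strictly inside the [45, 90) segment about the center
  d[16, 15] <- 3  # azimuth atan2(5, 4)  ~ 51.3 deg
  d[14, 13] <- 2  # azimuth atan2(3, 2)  ~ 56.3 deg
  prof <- sli_pattern_to_profile(scattering_pattern(d), bin_width_deg = 45)
  hot <- which(prof$values != 0)
  expect_equal(length(hot), 1)
  expect_equal(prof$bin_centers_deg[hot], 45)
  expect_equal(prof$values[hot], 5)
})

test_that("SLI azimuthal integration conserves total off-center intensity", {
  set.seed(11)
  d <- matrix(runif(23 * 23), 23, 23)
  d[9, 13] <- 5  # unique maximum -> center
  prof <- sli_pattern_to_profile(scattering_pattern(d))
  expect_equal(sum(prof$values), sum(d) - d[9, 13], tolerance = 1e-12)
})

test_that("angular stacks become per-pixel profiles without resampling", {
  ph <- demo_phantom(c(3, 5))
  st <- render_sli_stack(ph, noise = "none")
  pm <- angular_stack_to_profiles(st)
  expect_equal(dim(pm$values), c(3, 5, 24))
  expect_equal(pm$bin_width_deg, 15)
  p22 <- profile_at(pm, 2, 2)
  ref <- sli_forward_profile(phantom_populations(ph, 2, 2), n_bins = 24,
                             baseline = 0.1)
  expect_equal(p22$values, ref$values)
  one <- sli_stack(array(1:24, c(1, 1, 24)))
  expect_equal(dim(angular_stack_to_profiles(one)$values), c(1, 1, 24))
})

test_that("SAXS profile bins conserve the in-band intensity exactly", {
  geom <- detector_geometry(c(64, 64), c(32.5, 32.5), 0.0125)
  pat <- saxs_forward_pattern(fiber_populations(phi = 10, alpha = 15), geom)
  band <- c(0.3, 0.42)
  prof <- saxs_pattern_to_profile(pat, q_band = band)
  expect_equal(length(prof$values), 72)
  idx <- which(geom$mask, arr.ind = TRUE)
  q <- sqrt((idx[, 1] - 32.5)^2 + (idx[, 2] - 32.5)^2) * geom$q_per_pixel
  direct <- sum(pat$data[idx][q >= band[1] & q <= band[2]])
  expect_equal(sum(prof$values), direct, tolerance = 1e-12)
})

test_that("segments with no usable pixels are flagged invalid", {
  mask <- matrix(TRUE, 64, 64)
  mask[1:32, ] <- FALSE  # upper half dead (rows above the beam center)
  geom <- detector_geometry(c(64, 64), c(32.5, 32.5), 0.0125, mask = mask)
  pat <- saxs_forward_pattern(fiber_populations(), geom)
  prof <- saxs_pattern_to_profile(pat, q_band = c(0.3, 0.42))
  expect_true(any(!prof$valid))
  expect_true(any(prof$valid))
  # azimuths pointing into the dead half (180..360: -row direction) invalid
  expect_false(any(prof$valid[prof$bin_centers_deg >= 185 &
                              prof$bin_centers_deg <= 350]))
})

test_that("empty q-band is rejected", {
  geom <- detector_geometry(c(32, 32), c(16.5, 16.5), 0.025)
  pat <- saxs_forward_pattern(fiber_populations(), geom)
  expect_error(saxs_pattern_to_profile(pat, q_band = c(0.4, 0.3)), "q_band")
})

test_that("center-symmetry completion averages, copies and flags", {
  v <- c(1, 2, 3, 4, 10, 20, 30, 40)
  ok <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  out <- complete_center_symmetry(azimuthal_profile(v, valid = ok))
  expect_equal(out$values[1], (1 + 10) / 2)  # both valid: averaged
  expect_equal(out$values[5], (1 + 10) / 2)
  expect_equal(out$values[6], 2)             # copied from valid partner
  expect_equal(out$values[3], 30)
  expect_true(out$valid[6] && out$valid[3])
  expect_false(out$valid[4] && out$valid[8]) # neither valid: stays invalid
  # result satisfies I(phi) = I(phi + 180) on valid bins
  expect_equal(out$values[1:4][out$valid[1:4] & out$valid[5:8]],
               out$values[5:8][out$valid[1:4] & out$valid[5:8]])
})

test_that("center-symmetry completion is idempotent and preserves symmetric profiles", {
  set.seed(4)
  half <- runif(36)
  sym <- azimuthal_profile(c(half, half))
  expect_equal(complete_center_symmetry(sym)$values, sym$values)
  v <- runif(72)
  ok <- runif(72) > 0.3
  once <- complete_center_symmetry(azimuthal_profile(v, valid = ok))
  twice <- complete_center_symmetry(once)
  expect_equal(twice$values, once$values)
  expect_equal(twice$valid, once$valid)
})

test_that("masking a wedge of a symmetric pattern is fully recovered", {
  geom <- detector_geometry(c(64, 64), c(32.5, 32.5), 0.0125)
  pat <- saxs_forward_pattern(fiber_populations(phi = 140, alpha = 10), geom)
  full <- saxs_pattern_to_profile(pat, q_band = c(0.3, 0.42))
  # kill a 30-degree wedge of detector pixels
  idx <- which(geom$mask, arr.ind = TRUE)
  az <- atan2(idx[, 1] - 32.5, idx[, 2] - 32.5) * 180 / pi %% 360
  az <- az %% 360
  mask <- geom$mask
  mask[idx[az >= 40 & az < 70, ]] <- FALSE
  geom2 <- detector_geometry(c(64, 64), c(32.5, 32.5), 0.0125, mask = mask)
  pat2 <- scattering_pattern(pat$data * mask, geometry = geom2)
  gap <- saxs_pattern_to_profile(pat2, q_band = c(0.3, 0.42))
  completed <- complete_center_symmetry(gap)
  expect_true(all(completed$valid))
  # invalidated bins recover the full profile's values (same pixels via
  # the antipodal counterparts, which are exactly symmetric)
  lost <- which(!gap$valid)
  expect_equal(completed$values[lost], full$values[lost], tolerance = 1e-9)
})

test_that("myelin ring detection recovers q and d-spacing", {
  geom <- detector_geometry(c(64, 64), c(32.5, 32.5), 0.0125)
  pat <- saxs_forward_pattern(fiber_populations(), geom, d_spacing = 17.5)
  ring <- detect_myelin_ring(pat)
  expect_equal(ring$q_peak, 2 * pi / 17.5, tolerance = 0.02)
  expect_equal(ring$d_spacing, 17.5, tolerance = 0.02 * 17.5)
  # analytic case q = 0.2 -> d = 2 pi / 0.2
  pat2 <- saxs_forward_pattern(fiber_populations(), geom,
                               d_spacing = 2 * pi / 0.2)
  expect_equal(detect_myelin_ring(pat2)$d_spacing, 31.416, tolerance = 0.5)
  flat <- scattering_pattern(matrix(1, 64, 64), geometry = geom)
  expect_error(detect_myelin_ring(flat), "ring not found")
})

test_that("profile peak positions are rotation-equivariant", {
  geom <- saxs_test_geom()
  base <- 25
  for (shift in c(0, 35, 60)) {
    pat <- saxs_forward_pattern(fiber_populations(phi = base + shift), geom,
                                kappa_azim = 6)
    prof <- saxs_pattern_to_profile(pat, q_band = c(0.32, 0.40))
    pk <- find_peaks_cyclic(prof)
    expected <- sort(c((base + shift + 90) %% 360, (base + shift + 270) %% 360))
    expect_equal(length(pk$position_deg), 2)
    expect_lt(max(cyclic_separation(sort(pk$position_deg), expected)), 5)
  }
})

test_that("FOD sampling matches an independent spherical-harmonic oracle", {
  set.seed(21)
  co <- rnorm(45)
  prof <- sample_fod_profile(co, step_deg = 5)
  phi <- seq(0, 355, by = 5) * pi / 180
  dirs <- cbind(cos(phi), sin(phi), 0)
  oracle <- as.numeric(oracle_sh_basis(dirs, 8) %*% co)
  expect_equal(prof$values, oracle, tolerance = 1e-8)
  # antipodal symmetry is exact for even degrees
  expect_equal(prof$values[1:36], prof$values[37:72], tolerance = 1e-12)
  expect_error(sample_fod_profile(rnorm(44)), "coefficient count")
})

test_that("degree-0-only coefficients sample to a constant profile", {
  co <- c(3, rep(0, 44))
  prof <- sample_fod_profile(co)
  expect_equal(prof$values, rep(3 * sqrt(1 / (4 * pi)), 72), tolerance = 1e-12)
})
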