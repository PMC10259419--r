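# Forward models rendering ground-truth fiber populations into the three
# modalities' raw representations.

vm_lobe <- function(delta_deg, kappa) {
  exp(kappa * (cos(delta_deg * pi / 180) - 1))
}

vm_lobe180 <- function(delta_deg, kappa) {
  exp(kappa * (cos(2 * delta_deg * pi / 180) - 1))
}

#' SLI forward model: azimuthal profile of a pixel
#'
#' Scattered light leaves an in-plane fiber perpendicular to its axis, so
#' an in-plane population at orientation phi produces two azimuthal lobes
#' at phi +/- 90 degrees, 180 degrees apart. With increasing inclination
#' alpha the two lobes move towards each other: their separation is
#' Delta(alpha) from the calibration curve, and they sit at
#' c - Delta/2 and c + Delta/2 where c = phi + 180 is taken towards the
#' population's tilt azimuth (`tilt_sign` selects the other side). Lobes
#' are von Mises shaped (period 360) with concentration `kappa`, scaled by
#' the population weight, on top of an isotropic baseline.
#'
#' @param populations a [fiber_populations] object (possibly empty).
#' @param n_bins number of azimuth bins (>= 8).
#' @param kappa lobe concentration (> 0); 20 by default, giving a lobe
#'   full width at half maximum of about 31 degrees.
#' @param baseline nonnegative isotropic offset.
#' @param delta_curve a [calibration_curve] mapping inclination to lobe
#'   separation; defaults to [standin_delta_curve()].
#' @return An [azimuthal_profile] with `n_bins` bins.
#' @export
#' @examples
#' p <- sli_forward_profile(fiber_populations(phi = 0), n_bins = 24)
#' which(p$values == max(p$values))  # bins at 90 and 270 degrees
sli_forward_profile <- function(populations, n_bins = 24, kappa = 20,
                                baseline = 0, delta_curve = standin_delta_curve()) {
  populations <- as_fiber_populations(populations)
  if (n_bins < 8) stop("n_bins must be >= 8", call. = FALSE)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (baseline < 0) stop("baseline must be nonnegative", call. = FALSE)
  w <- 360 / n_bins
  bins <- seq(0, 360 - w, by = w)
  vals <- rep(baseline, n_bins)
  for (i in seq_len(nrow(populations))) {
    pop <- populations[i, ]
    delta <- distance_from_inclination(pop$alpha, delta_curve)
    ctr <- pop$phi + ifelse(pop$tilt_sign > 0, 180, 0)
    vals <- vals + pop$weight *
      (vm_lobe(bins - (ctr - delta / 2), kappa) +
       vm_lobe(bins - (ctr + delta / 2), kappa))
  }
  azimuthal_profile(vals)
}

#' Angular SLI image stack
#'
#' @param data array rows x cols x n_azimuths of intensities.
#' @param azimuths_deg illumination azimuth per slice; strictly
#'   increasing, equally spaced, covering \[0, 360).
#' @param polar_deg fixed polar illumination angle theta (default 45).
#' @return Object of class `"sli_stack"`.
#' @export
sli_stack <- function(data, azimuths_deg = NULL, polar_deg = 45) {
  stopifnot(length(dim(data)) == 3L)
  n <- dim(data)[3]
  if (is.null(azimuths_deg)) azimuths_deg <- seq(0, 360 - 360 / n, by = 360 / n)
  x <- structure(list(data = data, azimuths_deg = azimuths_deg,
                      polar_deg = polar_deg),
                 class = "sli_stack")
  validate_sli_stack(x)
  x
}

validate_sli_stack <- function(x) {
  n <- dim(x$data)[3]
  az <- x$azimuths_deg
  if (length(az) != n)
    stop("azimuths_deg length must match the number of slices", call. = FALSE)
  if (n > 1 && (any(diff(az) <= 0) || any(abs(diff(az) - 360 / n) > 1e-6)))
    stop("azimuths must be strictly increasing, equally spaced over [0, 360)",
         call. = FALSE)
  if (az[1] != 0) stop("azimuths must start at 0", call. = FALSE)
  invisible(x)
}

#' @export
print.sli_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("SLI stack:", d[1], "x", d[2], "px,", d[3], "azimuths (theta =",
      x$polar_deg, "deg)\n")
  invisible(x)
}

apply_noise <- function(x, noise = c("none", "gaussian", "poisson"),
                        sd_frac = 0.01, poisson_scale = 1000, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  switch(noise,
    none = x,
    gaussian = {
      sdev <- sd_frac * (max(x) - min(x))
      pmax(0, x + stats::rnorm(length(x), sd = sdev))
    },
    poisson = stats::rpois(length(x), lambda = pmax(0, x) * poisson_scale) / poisson_scale
  )
}

#' Render a phantom into an angular SLI stack
#'
#' Every tissue pixel's slice series equals [sli_forward_profile] on the
#' pixel's populations; background pixels carry the baseline only. Noise
#' is added per pixel and slice, reproducibly for a fixed seed.
#'
#' @param phantom a [build_phantom] result.
#' @param n_azimuths number of illumination azimuths; must divide 360
#'   evenly (default 24, i.e. 15-degree steps).
#' @param kappa,baseline,delta_curve forward-model parameters, see
#'   [sli_forward_profile]. The baseline default 0.1 represents diffuse
#'   background scatter.
#' @param noise `"none"`, `"gaussian"` (sd = `noise_sd_frac` of the
#'   noiseless dynamic range) or `"poisson"` (counts at `poisson_scale`
#'   photons per intensity unit).
#' @param noise_sd_frac Gaussian noise level as a fraction of dynamic
#'   range (default 0.01).
#' @param poisson_scale photons per intensity unit for Poisson noise.
#' @param seed integer seed for the noise realization.
#' @param polar_deg fixed polar illumination angle recorded in the stack.
#' @return An [sli_stack].
#' @export
render_sli_stack <- function(phantom, n_azimuths = 24, kappa = 20,
                             baseline = 0.1,
                             delta_curve = standin_delta_curve(),
                             noise = c("none", "gaussian", "poisson"),
                             noise_sd_frac = 0.01, poisson_scale = 1000,
                             seed = NULL, polar_deg = 45) {
  noise <- match.arg(noise)
  if (360 %% n_azimuths != 0)
    stop("n_azimuths must divide 360 evenly", call. = FALSE)
  nr <- phantom$shape[1]; nc <- phantom$shape[2]
  dat <- array(baseline, c(nr, nc, n_azimuths))
  for (k in seq_along(phantom$regions)) {
    reg <- phantom$regions[[k]]
    prof <- sli_forward_profile(reg$populations, n_bins = n_azimuths,
                                kappa = kappa, baseline = baseline,
                                delta_curve = delta_curve)
    for (b in seq_len(n_azimuths))
      dat[reg$rows[1]:reg$rows[2], reg$cols[1]:reg$cols[2], b] <- prof$values[b]
  }
  dat <- array(apply_noise(dat, noise, sd_frac = noise_sd_frac,
                           poisson_scale = poisson_scale, seed = seed),
               dim(dat))
  sli_stack(dat, polar_deg = polar_deg)
}

#' SAXS forward model: detector frame for one raster position
#'
#' The periodic myelin sheath produces a Debye-Scherrer ring at
#' q = 2*pi/d_spacing. Fiber populations make the ring anisotropic:
#' 180-degree-periodic azimuthal lobes centered perpendicular to the
#' in-plane orientation phi, with a contrast that decays with inclination
#' alpha (default decay cos(alpha), a stand-in for the qualitative
#' "less pronounced with increasing out-of-plane angle"). The pattern is
#' center-symmetric by construction before masking.
#'
#' @param populations a [fiber_populations] object (possibly empty).
#' @param geometry a [detector_geometry].
#' @param d_spacing myelin periodicity in nm (default 17.5).
#' @param anisotropy_decay function of alpha (degrees) returning the lobe
#'   contrast factor in \[0, 1\].
#' @param ring_width radial Gaussian sigma of the ring, in q units
#'   (nm^-1).
#' @param kappa_azim concentration of the period-180 azimuthal lobes.
#' @param iso_amplitude amplitude of the isotropic ring component.
#' @param noise,noise_sd_frac,poisson_scale,seed noise model as in
#'   [render_sli_stack].
#' @return A [scattering_pattern] carrying the geometry.
#' @export
saxs_forward_pattern <- function(populations, geometry, d_spacing = 17.5,
                                 anisotropy_decay = function(alpha) cos(alpha * pi / 180),
                                 ring_width = 0.02, kappa_azim = 4,
                                 iso_amplitude = 1,
                                 noise = c("none", "gaussian", "poisson"),
                                 noise_sd_frac = 0.01, poisson_scale = 1000,
                                 seed = NULL) {
  noise <- match.arg(noise)
  populations <- as_fiber_populations(populations)
  stopifnot(inherits(geometry, "detector_geometry"))
  if (d_spacing <= 0) stop("d_spacing must be > 0", call. = FALSE)
  q0 <- 2 * pi / d_spacing
  # ring must fit inside the detector: max radius reachable in every
  # azimuth is the distance to the nearest frame edge
  edge_r <- min(geometry$beam_center[1] - 1,
                geometry$frame_shape[1] - geometry$beam_center[1],
                geometry$beam_center[2] - 1,
                geometry$frame_shape[2] - geometry$beam_center[2])
  if (q0 > edge_r * geometry$q_per_pixel)
    stop("myelin ring falls outside the detector for this geometry",
         call. = FALSE)
  nr <- geometry$frame_shape[1]; nc <- geometry$frame_shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r <- sqrt((rows - geometry$beam_center[1])^2 + (cols - geometry$beam_center[2])^2)
  q <- r * geometry$q_per_pixel
  az <- pixel_azimuth_deg(rows, cols, geometry$beam_center)
  radial <- exp(-(q - q0)^2 / (2 * ring_width^2))
  azim <- matrix(iso_amplitude, nr, nc)
  for (i in seq_len(nrow(populations))) {
    pop <- populations[i, ]
    azim <- azim + pop$weight * anisotropy_decay(pop$alpha) *
      vm_lobe180(az - (pop$phi + 90), kappa_azim)
  }
  dat <- radial * azim
  dat <- matrix(apply_noise(dat, noise, sd_frac = noise_sd_frac,
                            poisson_scale = poisson_scale, seed = seed), nr, nc)
  dat[!geometry$mask] <- 0
  scattering_pattern(dat, geometry = geometry)
}

#' Emulate FOD spherical-harmonic coefficients for fiber populations
#'
#' Builds an antipodally symmetric orientation density as a mixture of
#' Watson-type lobes along each population's 3D axis (unit vector from
#' phi and alpha), and projects it onto the real even-degree
#' spherical-harmonic basis, band-limited at `lmax`. This emulates the
#' output of constrained spherical deconvolution, not the fit itself.
#'
#' @param populations a [fiber_populations] object; empty populations
#'   yield an isotropic density (only the degree-0 coefficient nonzero).
#' @param lmax even maximum degree (default 8).
#' @param kappa Watson concentration of each lobe.
#' @return Numeric coefficient vector in the ordering of
#'   [sh_basis_even()].
#' @export
fod_sh_from_populations <- function(populations, lmax = 8, kappa = 20) {
  populations <- as_fiber_populations(populations)
  lmax <- as.integer(lmax)
  if (lmax < 0L || lmax %% 2L != 0L)
    stop("lmax must be an even nonnegative integer", call. = FALSE)
  quad <- sphere_quadrature(n_theta = max(32L, 2L * lmax + 8L), n_phi = 96L)
  f <- rep(1 / (4 * pi), nrow(quad$directions))
  if (nrow(populations) > 0) {
    f <- rep(0, nrow(quad$directions))
    for (i in seq_len(nrow(populations))) {
      pop <- populations[i, ]
      mu <- inclination_vector(pop$phi, pop$alpha)
      c2 <- (quad$directions %*% mu)^2
      f <- f + pop$weight * exp(kappa * (c2 - 1))
    }
  }
  B <- sh_basis_even(quad$directions, lmax)
  as.numeric(crossprod(B, quad$weights * f))
}

#' Sample a fiber orientation distribution in the section plane
#'
#' Evaluates an even-degree real spherical-harmonic expansion at unit
#' directions lying in the plane orthogonal to `plane_normal`, in equal
#' azimuth steps, mirroring the sampling of dMRI-derived FODs at the
#' vibratome section plane. The result is 180-degree periodic by
#' antipodal symmetry.
#'
#' @param sh_coeffs coefficient vector in the ordering of
#'   [sh_basis_even()]; the length must correspond to some even lmax.
#' @param step_deg azimuth step (default 5, i.e. 72 bins).
#' @param plane_normal unit 3-vector normal to the section plane
#'   (default c(0, 0, 1): the section is the xy-plane and the profile
#'   azimuth equals the in-plane angle phi).
#' @return An [azimuthal_profile].
#' @export
sample_fod_profile <- function(sh_coeffs, step_deg = 5,
                               plane_normal = c(0, 0, 1)) {
  lmax <- even_sh_lmax(length(sh_coeffs))
  if (is.na(lmax))
    stop("coefficient count matches no even-degree expansion", call. = FALSE)
  n <- round(360 / step_deg)
  if (abs(n * step_deg - 360) > 1e-9)
    stop("step_deg must divide 360", call. = FALSE)
  nrm <- sqrt(sum(plane_normal^2))
  if (nrm == 0) stop("plane_normal must be nonzero", call. = FALSE)
  nvec <- plane_normal / nrm
  a <- if (abs(nvec[1]) < 0.99) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * nvec) * nvec
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nvec[2] * e1[3] - nvec[3] * e1[2],
          nvec[3] * e1[1] - nvec[1] * e1[3],
          nvec[1] * e1[2] - nvec[2] * e1[1])
  phi <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  dirs <- outer(cos(phi), e1) + outer(sin(phi), e2)
  vals <- as.numeric(sh_basis_even(dirs, lmax) %*% sh_coeffs)
  azimuthal_profile(vals)
}
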