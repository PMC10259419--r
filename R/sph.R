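# Real spherical harmonics, orthonormal on the unit sphere.
#
# Ordering used throughout: degrees l = 0, 2, ..., lmax (even only, for
# antipodally symmetric densities), orders m = -l, ..., +l within each
# degree. Basis convention:
#   Y_{l,0}  = Nbar_l^0(cos theta)
#   Y_{l,m}  = sqrt(2) * Nbar_l^m(cos theta) * cos(m phi),  m > 0
#   Y_{l,-m} = sqrt(2) * Nbar_l^m(cos theta) * sin(m phi),  m > 0
# with Nbar the fully normalized associated Legendre functions, computed
# by the standard stable three-term recurrence.

even_sh_n_coeffs <- function(lmax) {
  ls <- seq(0L, as.integer(lmax), by = 2L)
  sum(2L * ls + 1L)
}

# lmax from a coefficient count, or NA when no even lmax matches.
even_sh_lmax <- function(n_coeffs) {
  lmax <- 0L
  while (even_sh_n_coeffs(lmax) < n_coeffs) lmax <- lmax + 2L
  if (even_sh_n_coeffs(lmax) != n_coeffs) return(NA_integer_)
  lmax
}

# Fully normalized associated Legendre Nbar_l^m(x) for all 0 <= m <= l <=
# lmax at points x in [-1, 1]. Returns a list indexed [[l+1]][[m+1]] of
# numeric vectors. Normalization: int_{-1}^{1} (Nbar_l^m)^2 dx = 1/(2*pi)
# for m > 0 terms combined with the sqrt(2)*cos/sin azimuthal factors,
# i.e. Nbar_l^m = sqrt((2l+1)/(4pi) * (l-m)!/(l+m)!) P_l^m.
normalized_legendre <- function(lmax, x) {
  s <- sqrt(pmax(0, 1 - x^2))
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- vector("list", l + 1L)
  P[[1L]][[1L]] <- rep(sqrt(1 / (4 * pi)), length(x))
  if (lmax >= 1L) {
    for (m in 1:lmax)
      P[[m + 1L]][[m + 1L]] <- -sqrt((2 * m + 1) / (2 * m)) * s * P[[m]][[m]]
    for (m in 0:(lmax - 1L))
      P[[m + 2L]][[m + 1L]] <- sqrt(2 * m + 3) * x * P[[m + 1L]][[m + 1L]]
    if (lmax >= 2L) {
      for (m in 0:(lmax - 2L)) {
        for (l in (m + 2L):lmax) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          P[[l + 1L]][[m + 1L]] <-
            a * (x * P[[l]][[m + 1L]] - b * P[[l - 1L]][[m + 1L]])
        }
      }
    }
  }
  P
}

#' Real even-degree spherical-harmonic basis
#'
#' Evaluates the real, orthonormal spherical-harmonic basis restricted to
#' even degrees (the antipodally symmetric subspace used for fiber
#' orientation distributions) at a set of unit directions.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param lmax maximum (even) degree.
#' @return n x K matrix, K = `sum(2l+1)` over even l <= lmax, columns
#'   ordered by degree l = 0, 2, ... and order m = -l..l within degree.
#' @export
sh_basis_even <- function(directions, lmax) {
  lmax <- as.integer(lmax)
  if (lmax < 0L || lmax %% 2L != 0L)
    stop("lmax must be an even nonnegative integer", call. = FALSE)
  directions <- rbind(directions)
  nrm <- sqrt(rowSums(directions^2))
  directions <- directions / nrm
  ct <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  P <- normalized_legendre(lmax, ct)
  K <- even_sh_n_coeffs(lmax)
  out <- matrix(0, nrow(directions), K)
  j <- 0L
  for (l in seq(0L, lmax, by = 2L)) {
    for (m in (-l):l) {
      j <- j + 1L
      if (m == 0L) {
        out[, j] <- P[[l + 1L]][[1L]]
      } else if (m > 0L) {
        out[, j] <- sqrt(2) * P[[l + 1L]][[m + 1L]] * cos(m * phi)
      } else {
        out[, j] <- sqrt(2) * P[[l + 1L]][[-m + 1L]] * sin(-m * phi)
      }
    }
  }
  out
}

# Gauss-Legendre x uniform-phi spherical quadrature nodes and weights.
sphere_quadrature <- function(n_theta = 48L, n_phi = 96L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  ct <- rep(gl$x, times = n_phi)
  ph <- rep(phi, each = n_theta)
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  list(directions = dirs, weights = w)
}
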