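# Plain-text and TIFF I/O for phantoms, stacks, calibration curves and
# orientation maps.

#' Read a phantom layout from YAML
#'
#' The YAML file holds `shape: [rows, cols]` and a list `regions`, each
#' with `name`, `rows: [from, to]`, `cols: [from, to]` and `populations`
#' (list of `{phi, alpha, weight}` mappings).
#'
#' @param path YAML file path.
#' @return List with `shape` and `layout` ready for [build_phantom].
#' @export
read_phantom_layout <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$shape) || is.null(spec$regions))
    stop("phantom layout needs 'shape' and 'regions'", call. = FALSE)
  list(shape = as.integer(unlist(spec$shape)), layout = spec$regions)
}

#' Write / read an angular SLI stack as multi-page TIFF plus YAML sidecar
#'
#' One 32-bit float TIFF page per illumination azimuth; the sidecar
#' records the azimuths and the polar illumination angle. Intensities are
#' stored as-is (TIFF float pages are not range-limited).
#'
#' @param stack an [sli_stack].
#' @param path TIFF file path; the sidecar is written next to it as
#'   `<path>.yaml`.
#' @return `write_sli_stack`: the paths, invisibly. `read_sli_stack`: the
#'   [sli_stack].
#' @export
write_sli_stack <- function(stack, path) {
  validate_sli_stack(stack)
  rng <- range(stack$data)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(k) (stack$data[, , k] - rng[1]) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(path, ".yaml")
  yaml::write_yaml(list(azimuths_deg = stack$azimuths_deg,
                        polar_deg = stack$polar_deg,
                        intensity_min = rng[1], intensity_max = rng[2]), sidecar)
  invisible(c(tiff = path, sidecar = sidecar))
}

#' @rdname write_sli_stack
#' @export
read_sli_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  span <- meta$intensity_max - meta$intensity_min
  if (span <= 0) span <- 1
  dat <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) dat[, , k] <- pages[[k]] * span + meta$intensity_min
  sli_stack(dat, azimuths_deg = as.numeric(unlist(meta$azimuths_deg)),
            polar_deg = meta$polar_deg)
}

#' Write / read a calibration curve as two-column CSV
#'
#' Columns `alpha_deg`, `delta_deg`.
#'
#' @param curve a [calibration_curve].
#' @param path CSV file path.
#' @return `read_calibration_curve`: the [calibration_curve].
#' @export
write_calibration_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(unclass(curve))[c("alpha_deg", "delta_deg")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_curve
#' @export
read_calibration_curve <- function(path) {
  df <- utils::read.csv(path)
  calibration_curve(df$alpha_deg, df$delta_deg)
}

#' Write / read an orientation map as float TIFF planes plus JSON sidecar
#'
#' Planes, in order: the three orientation slots (degrees), the
#' orientation count, the peak distance, and the peak count. TIFF pages
#' hold samples in \[0, 1\], so each plane is stored scaled; the per-plane
#' offset/scale and the sentinel used for absent (NA) values are recorded
#' in the JSON sidecar along with any analysis parameters passed in
#' `params`.
#'
#' @param omap an `orientation_map`.
#' @param path TIFF file path; sidecar goes to `<path>.json`.
#' @param params optional named list recorded in the sidecar.
#' @return `read_orientation_maps`: the `orientation_map`.
#' @export
write_orientation_maps <- function(omap, path, params = list()) {
  stopifnot(inherits(omap, "orientation_map"))
  planes <- c(lapply(1:3, function(k) omap$orientations[, , k]),
              list(omap$n_orientations * 1.0,
                   omap$peak_distance,
                   omap$n_peaks * 1.0))
  sentinel <- -1
  scale <- vapply(planes, function(m) max(1, m[!is.na(m)], na.rm = TRUE),
                  numeric(1))
  offset <- rep(1, length(planes))  # shift so the sentinel maps to 0
  stored <- lapply(seq_along(planes), function(k) {
    m <- planes[[k]]
    m[is.na(m)] <- sentinel
    (m + offset[k]) / (scale[k] + offset[k])
  })
  tiff::writeTIFF(stored, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    c(list(planes = c("orientation1_deg", "orientation2_deg",
                      "orientation3_deg", "n_orientations",
                      "peak_distance_deg", "n_peaks"),
           plane_scale = scale, plane_offset = offset,
           na_sentinel = sentinel), params),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_orientation_maps
#' @export
read_orientation_maps <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- lapply(seq_along(pages), function(k) {
    m <- pages[[k]] * (meta$plane_scale[k] + meta$plane_offset[k]) -
      meta$plane_offset[k]
    m[abs(m - meta$na_sentinel) < 1e-3] <- NA_real_
    m
  })
  d <- dim(planes[[1]])
  ori <- array(NA_real_, c(d, 3L))
  for (k in 1:3) ori[, , k] <- planes[[k]]
  n_ori <- matrix(as.integer(round(planes[[4]])), d[1], d[2])
  n_pk <- matrix(as.integer(round(planes[[6]])), d[1], d[2])
  new_orientation_map(ori, n_ori, planes[[5]], n_pk)
}
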