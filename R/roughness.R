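#' Arithmetic mean roughness Ra of a detrended boundary map
#'
#' `Ra = (1 / (nx * ny)) * sum_i sum_j |z(x_i, y_j)|`, the mean absolute
#' height about the ISO mean surface. The input must be detrended (the
#' flatten step establishes the zero-mean reference).
#'
#' @param bm A `boundary_map` in state `"detrended"` (or a bare zero-mean
#'   numeric matrix of heights in micrometres).
#' @return Ra in micrometres.
#' @export
compute_ra <- function(bm) {
  z <- .detrended_heights(bm)
  mean(abs(z))
}

#' Depth of roughness Rz of a detrended boundary map
#'
#' `Rz = max(z) - min(z)`: the height difference between the highest peak
#' and the lowest valley over the evaluation region.
#'
#' @inheritParams compute_ra
#' @return Rz in micrometres.
#' @export
compute_rz <- function(bm) {
  z <- .detrended_heights(bm)
  max(z) - min(z)
}

.detrended_heights <- function(bm) {
  if (inherits(bm, "boundary_map")) {
    if (bm$state != "detrended") {
      stop("roughness is defined on a detrended boundary map; call flatten() first")
    }
    z <- bm$heights
  } else {
    stopifnot(is.matrix(bm) || is.numeric(bm))
    z <- bm
  }
  if (anyNA(z)) stop("boundary map contains missing heights")
  if (abs(mean(z)) > 1e-6) {
    stop("boundary map is not zero-mean (|mean| = ", format(mean(z)),
         " um); roughness heights must be referenced to the mean surface")
  }
  z
}

#' Roughness report with region geometry and provenance
#'
#' Convenience wrapper: accepts either a detrended `boundary_map` or an
#' [oct_volume()] (in which case the full chain segmentation -> boundary
#' extraction -> flattening is run). A fraction of columns at each lateral
#' edge is trimmed before computing Ra/Rz, to keep edge artefacts of the
#' per-B-scan quadratic fit out of the evaluation region; the trimmed map is
#' re-referenced to its own mean.
#'
#' @param x A detrended `boundary_map` or an [oct_volume()].
#' @param trim_frac Fraction of columns trimmed at each lateral edge
#'   (default 0.05).
#' @param backend,params,model Passed to [segment_volume()] when `x` is a
#'   volume.
#' @return A list of class `roughness_report`: `Ra`, `Rz` (um), `n_x`
#'   (columns used), `n_y` (slices used), `region`, `provenance`.
#' @export
roughness_report <- function(x, trim_frac = 0.05,
                             backend = "classical",
                             params = classical_params(), model = NULL) {
  prov <- list(trim_frac = trim_frac)
  if (inherits(x, "oct_volume")) {
    mask <- segment_volume(x, backend = backend, params = params,
                           model = model)
    raw <- extract_boundary(mask, axial_pitch = x$axial_pitch,
                            lateral_pitch = x$lateral_pitch,
                            slice_pitch = x$slice_pitch)
    bm <- flatten(raw)
    prov$backend <- backend
    prov$segmentation <- mask$provenance
    prov$missing_columns <- sum(raw$missing)
  } else {
    bm <- x
    prov$backend <- "precomputed-boundary"
  }
  stopifnot(inherits(bm, "boundary_map"), bm$state == "detrended")
  z <- bm$heights
  n_lat <- ncol(z)
  k <- floor(trim_frac * n_lat)
  cols <- if (k > 0) (k + 1):(n_lat - k) else seq_len(n_lat)
  z <- z[, cols, drop = FALSE]
  z <- z - mean(z)
  structure(list(
    Ra = mean(abs(z)),
    Rz = max(z) - min(z),
    n_x = ncol(z), n_y = nrow(z),
    region = list(columns = range(cols), slices = c(1L, nrow(z))),
    provenance = prov
  ), class = "roughness_report")
}

#' @export
print.roughness_report <- function(x, ...) {
  cat(sprintf("<roughness_report> Ra = %.3f um, Rz = %.3f um (%d x %d grid, backend %s)\n",
              x$Ra, x$Rz, x$n_y, x$n_x, x$provenance$backend))
  invisible(x)
}
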