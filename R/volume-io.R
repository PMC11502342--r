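#' OCT intensity volume
#'
#' A light container for a 3D OCT intensity stack. The array is indexed
#' `[depth_row, lateral_column, slice]`: each `data[, , k]` is one B-scan with
#' depth running down the rows (row 1 = shallowest, nearest the probe).
#'
#' @param data Numeric 3D array `n_depth x n_lateral x n_slices`, finite,
#'   non-negative.
#' @param axial_pitch,lateral_pitch,slice_pitch Pixel pitches in micrometres.
#' @param source Free-text provenance note.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(data, axial_pitch, lateral_pitch, slice_pitch,
                       source = "") {
  stopifnot(is.array(data), length(dim(data)) == 3,
            axial_pitch > 0, lateral_pitch > 0, slice_pitch > 0)
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(list(
    data = data,
    axial_pitch = axial_pitch,
    lateral_pitch = lateral_pitch,
    slice_pitch = slice_pitch,
    source = source
  ), class = "oct_volume")
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oct_volume> %d slices x %d depth x %d lateral (pitches %g/%g/%g um)\n",
    d[3], d[1], d[2], x$axial_pitch, x$lateral_pitch, x$slice_pitch))
  invisible(x)
}

#' Write / read an OCT volume as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per B-scan, 16-bit, intensities divided by `intensity_scale`
#' (the volume maximum) before quantization; the sidecar (`<path>.json`)
#' records pitches, dimensions and the scale so the round trip is lossless at
#' the declared quantization.
#'
#' @param vol An [oct_volume()].
#' @param path Path of the TIFF file to write (sidecar goes to `<path>.json`).
#' @return `write_volume` invisibly returns `path`; `read_volume` returns an
#'   [oct_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  scale <- max(vol$data, 1e-12)
  # quantize explicitly (round) and centre each level inside its bin so the
  # TIFF writer's truncation cannot shift a level
  pages <- lapply(seq_len(d[3]), function(s)
    pmin((round(vol$data[, , s] / scale * 65535) + 0.499) / 65535, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  header <- list(
    format = "octskin-volume",
    n_depth = d[1], n_lateral = d[2], n_slices = d[3],
    axial_pitch = vol$axial_pitch,
    lateral_pitch = vol$lateral_pitch,
    slice_pitch = vol$slice_pitch,
    intensity_scale = scale,
    source = vol$source
  )
  jsonlite::write_json(header, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar '", sidecar,
         "'; write volumes with write_volume() so pitches are recorded")
  }
  h <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != h$n_slices) {
    stop("sidecar declares ", h$n_slices, " slices but TIFF has ",
         length(pages), " pages")
  }
  if (nrow(pages[[1]]) != h$n_depth || ncol(pages[[1]]) != h$n_lateral) {
    stop("TIFF page size ", nrow(pages[[1]]), "x", ncol(pages[[1]]),
         " does not match sidecar dimensions ", h$n_depth, "x", h$n_lateral)
  }
  data <- array(0, dim = c(h$n_depth, h$n_lateral, h$n_slices))
  for (s in seq_along(pages)) data[, , s] <- pages[[s]] * h$intensity_scale
  oct_volume(data, h$axial_pitch, h$lateral_pitch, h$slice_pitch,
             source = h$source %||% "")
}

#' Write / read a binary segmentation mask as multi-page TIFF
#'
#' @param mask 3D 0/1 array (`n_depth x n_lateral x n_slices`) or an
#'   `oct_mask`.
#' @param path TIFF path.
#' @return `read_mask` returns an integer 0/1 array.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "oct_mask")) mask$labels else mask
  stopifnot(all(m %in% c(0L, 1L)))
  pages <- lapply(seq_len(dim(m)[3]), function(s) m[, , s] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  m <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) m[, , s] <- as.integer(round(pages[[s]]))
  m
}

#' Serialize a boundary map as a CSV grid plus JSON header
#'
#' Heights are written slices x columns at fixed `%.6f` precision so repeated
#' exports are byte-identical; the header records pitches, state and the
#' missing-column count.
#'
#' @param bm A `boundary_map`.
#' @param path CSV path (header goes to `<path>.json`).
#' @return `read_boundary` returns a `boundary_map`.
#' @export
write_boundary <- function(bm, path) {
  stopifnot(inherits(bm, "boundary_map"))
  lines <- apply(bm$heights, 1, function(r)
    paste(sprintf("%.6f", r), collapse = ","))
  writeLines(lines, path)
  header <- list(
    format = "octskin-boundary",
    state = bm$state,
    n_slices = nrow(bm$heights), n_lateral = ncol(bm$heights),
    axial_pitch = bm$axial_pitch,
    lateral_pitch = bm$lateral_pitch,
    slice_pitch = bm$slice_pitch,
    n_missing = sum(bm$missing)
  )
  jsonlite::write_json(header, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundary
#' @export
read_boundary <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON header '", sidecar, "'")
  h <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  heights <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(heights) <- NULL
  boundary_map(heights, state = h$state,
               axial_pitch = h$axial_pitch,
               lateral_pitch = h$lateral_pitch,
               slice_pitch = h$slice_pitch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
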