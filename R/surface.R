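#' Boundary height map of the air-skin surface
#'
#' Heights are stored slices x lateral columns in micrometres, positive
#' towards the probe (up). A `raw` map still carries the natural curvature of
#' the skin; a `detrended` map has had the per-B-scan quadratic removed and
#' is zero-mean over all entries.
#'
#' @param heights Numeric matrix `n_slices x n_lateral`, micrometres.
#' @param state `"raw"` or `"detrended"`.
#' @param axial_pitch,lateral_pitch,slice_pitch Pixel pitches in micrometres.
#' @param missing Logical matrix flagging columns whose boundary was not
#'   detected and was filled by interpolation.
#' @param rows Optional integer matrix of surface depth rows (1-based) in the
#'   source volume, kept for depth-profile alignment.
#' @return An object of class `boundary_map`.
#' @export
boundary_map <- function(heights, state = c("raw", "detrended"),
                         axial_pitch = NA_real_, lateral_pitch = NA_real_,
                         slice_pitch = NA_real_,
                         missing = NULL, rows = NULL) {
  state <- match.arg(state)
  stopifnot(is.matrix(heights), is.numeric(heights))
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(heights), ncol(heights))
  }
  stopifnot(identical(dim(missing), dim(heights)))
  structure(list(
    heights = heights, state = state,
    axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
    slice_pitch = slice_pitch,
    missing = missing, rows = rows
  ), class = "boundary_map")
}

#' @export
print.boundary_map <- function(x, ...) {
  cat(sprintf("<boundary_map:%s> %d slices x %d columns, %d interpolated\n",
              x$state, nrow(x$heights), ncol(x$heights), sum(x$missing)))
  invisible(x)
}

#' Extract the air-skin boundary from a segmentation mask
#'
#' Per A-scan column, the boundary is the depth row of the topmost skin
#' pixel, converted to a height in micrometres as
#' `(reference_row - row) * axial_pitch` so that larger heights are closer to
#' the probe. Columns with no skin pixel are flagged missing and filled by 1D
#' linear interpolation from the nearest valid neighbours within the B-scan
#' (edge columns take the nearest valid value).
#'
#' @param mask 3D 0/1 array, an `oct_mask`, or a single B-scan matrix.
#' @param axial_pitch Axial pixel pitch, micrometres.
#' @param lateral_pitch,slice_pitch Lateral pitches, micrometres (metadata).
#' @param reference_row Depth row mapping to height 0 (default: row 1).
#' @param max_missing Maximum tolerated fraction of missing columns per
#'   B-scan before the extraction errors out.
#' @return A `boundary_map` in state `"raw"`, with no remaining missing
#'   heights (flags record which columns were interpolated).
#' @export
extract_boundary <- function(mask, axial_pitch,
                             lateral_pitch = NA_real_,
                             slice_pitch = NA_real_,
                             reference_row = 1,
                             max_missing = 0.5) {
  m <- if (inherits(mask, "oct_mask")) mask$labels else mask
  if (is.matrix(m)) m <- array(m, dim = c(dim(m), 1L))
  stopifnot(length(dim(m)) == 3, axial_pitch > 0)
  n_slices <- dim(m)[3]; n_lat <- dim(m)[2]
  rows <- matrix(NA_integer_, n_slices, n_lat)
  for (s in seq_len(n_slices)) {
    rows[s, ] <- .first_positive_row(m[, , s])
  }
  missing <- is.na(rows)
  bad <- rowMeans(missing) > max_missing
  if (any(bad)) {
    stop("unreliable boundary: ", sum(bad), " B-scan(s) have more than ",
         round(100 * max_missing), "% of columns without a detected surface")
  }
  heights <- (reference_row - rows) * axial_pitch
  for (s in seq_len(n_slices)) {
    if (any(missing[s, ])) {
      heights[s, ] <- .interp_missing(heights[s, ])
      rows[s, missing[s, ]] <- as.integer(
        round(reference_row - heights[s, missing[s, ]] / axial_pitch))
    }
  }
  boundary_map(heights, state = "raw", axial_pitch = axial_pitch,
               lateral_pitch = lateral_pitch, slice_pitch = slice_pitch,
               missing = missing, rows = rows)
}

# topmost row with a positive label, per column; NA when none
.first_positive_row <- function(bscan) {
  idx <- max.col(t(bscan > 0), ties.method = "first")
  has <- colSums(bscan > 0) > 0
  out <- ifelse(has, idx, NA_integer_)
  as.integer(out)
}

.interp_missing <- function(z) {
  ok <- !is.na(z)
  if (all(ok)) return(z)
  if (sum(ok) == 1) { z[!ok] <- z[ok]; return(z) }
  x <- seq_along(z)
  stats::approx(x[ok], z[ok], xout = x, rule = 2)$y
}

#' Second-order least-squares fit of a boundary cross-section
#'
#' Ordinary least squares of `z = a x^2 + b x + c` against the lateral
#' coordinate of one B-scan boundary. Exact (to machine precision) when the
#' input is itself a quadratic.
#'
#' @param z Numeric vector of boundary heights (um); `NA`s are dropped.
#' @param x Lateral coordinates (um); default `(seq_along(z) - 1) * pitch`
#'   with unit pitch.
#' @return A list of class `curvature_fit` with `coefficients` (named
#'   `a`, `b`, `c`), `fitted`, and `residual_rms`.
#' @export
fit_curvature <- function(z, x = NULL) {
  if (is.null(x)) x <- seq_along(z) - 1
  ok <- !is.na(z) & !is.na(x)
  if (sum(ok) < 3) stop("curvature fit needs at least 3 non-missing points")
  if (length(unique(x[ok])) < 3) {
    stop("curvature fit is rank-deficient: fewer than 3 distinct lateral positions")
  }
  xs <- x[ok] - mean(x[ok])   # centred for conditioning
  X <- cbind(xs^2, xs, 1)
  fit <- stats::lm.fit(X, z[ok])
  ab <- fit$coefficients
  # un-centre: z = a(x-m)^2 + b(x-m) + c
  m <- mean(x[ok])
  a <- ab[1]; b <- ab[2] - 2 * ab[1] * m; c0 <- ab[1] * m^2 - ab[2] * m + ab[3]
  fitted_all <- a * x^2 + b * x + c0
  res <- z[ok] - fitted_all[ok]
  structure(list(
    coefficients = c(a = unname(a), b = unname(b), c = unname(c0)),
    fitted = fitted_all,
    residual_rms = sqrt(mean(res^2))
  ), class = "curvature_fit")
}

#' Flatten a raw boundary map by quadratic detrending
#'
#' Removes the natural curvature of the skin and re-references heights to
#' the mean surface (zero global mean, the ISO convention). Two estimators
#' of the per-B-scan quadratic trend are available:
#'
#' * `"biquadratic"` (default): the heights are first projected, per lateral
#'   position, onto a quadratic in the slice index, and the lateral
#'   second-order fit of each B-scan is taken on that slice-coherent trend.
#'   Anatomical curvature varies slowly across B-scans, so this estimates
#'   each B-scan's quadratic from the whole volume: texture can only leak
#'   into a handful of global trend degrees of freedom instead of three per
#'   B-scan, which keeps long-wavelength surface texture in the map. Both
#'   directions are orthogonal projections, so the operation is exactly
#'   idempotent.
#' * `"per-bscan"`: each B-scan is independently fitted ([fit_curvature()])
#'   and replaced by its residual — the literal per-cross-section
#'   procedure. On textures with long correlation lengths this absorbs a
#'   realization-dependent share of the texture into the 3 x n_slices fit
#'   coefficients, deflating Ra; it is kept for single B-scans (where the
#'   two methods coincide) and for comparison.
#'
#' A constant-across-slices lateral quadratic (the phantom's curvature
#' model) is removed exactly by both methods.
#'
#' @param bm A `boundary_map` in state `"raw"`.
#' @param method Trend estimator, see above.
#' @param slice_degree Polynomial degree of the slice-direction projection
#'   of the biquadratic method (capped at `n_slices - 1`).
#' @return A `boundary_map` in state `"detrended"` (flattening a detrended
#'   map returns it unchanged up to floating point).
#' @export
flatten <- function(bm, method = c("biquadratic", "per-bscan"),
                    slice_degree = 2L) {
  stopifnot(inherits(bm, "boundary_map"))
  method <- match.arg(method)
  h <- bm$heights
  if (anyNA(h)) stop("flatten requires interpolated (gap-free) heights")
  if (ncol(h) < 3) stop("flatten needs at least 3 lateral columns")
  x <- (seq_len(ncol(h)) - 1) * ifelse(is.na(bm$lateral_pitch), 1,
                                       bm$lateral_pitch)
  if (method == "biquadratic") {
    lat_fit <- .poly_project_rows(h, x, 2L)          # lateral quadratic per slice
    trend <- t(.poly_project_rows(t(lat_fit), seq_len(nrow(h)),
                                  min(slice_degree, nrow(h) - 1L)))
    out <- h - trend
  } else {
    out <- matrix(NA_real_, nrow(h), ncol(h))
    for (s in seq_len(nrow(h))) {
      fit <- fit_curvature(h[s, ], x)
      out[s, ] <- h[s, ] - fit$fitted
    }
  }
  out <- out - mean(out)
  boundary_map(out, state = "detrended",
               axial_pitch = bm$axial_pitch, lateral_pitch = bm$lateral_pitch,
               slice_pitch = bm$slice_pitch, missing = bm$missing,
               rows = bm$rows)
}

# orthogonal projection of each matrix row onto polynomials of `degree` in t
.poly_project_rows <- function(m, t, degree) {
  if (degree <= 0 || length(t) < 2) {
    return(matrix(rowMeans(m), nrow(m), ncol(m)))
  }
  X <- stats::poly(t, degree = min(degree, length(unique(t)) - 1L),
                   raw = FALSE)
  Q <- qr.Q(qr(cbind(1, X)))
  m %*% Q %*% t(Q)
}
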