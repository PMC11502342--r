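#' Parameters of the classical segmentation backend
#'
#' @param smooth_axial,smooth_lateral Odd boxcar window sizes (pixels) used
#'   to average speckle before the coarse surface search.
#' @param k_mad Robust threshold multiplier: the background level is
#'   `median + k_mad * MAD` of the top `bg_rows` image rows.
#' @param contrast_frac Fraction of the background-to-peak dynamic range
#'   added to the robust background level to form the detection threshold;
#'   makes the threshold invariant to global intensity scaling.
#' @param bg_rows Number of topmost rows assumed to be above the surface and
#'   used to estimate the background statistics.
#' @param refine_px Half-width (pixels) of the raw-intensity refinement
#'   window around the coarse (smoothed) surface estimate.
#' @param refine_max_cv Refinement only runs when the background
#'   coefficient of variation (MAD/median of the top rows) is below this
#'   value: at speckle-level noise the per-pixel SNR is ~1, so single-pixel
#'   decisions would only re-inject the noise the smoothing removed.
#' @param despike_window Odd running-median window (columns) used to detect
#'   outlier boundary columns.
#' @param despike_tol_px Columns whose surface deviates from the running
#'   median by more than this many pixels are replaced by it.
#' @return A list of class `classical_params`.
#' @export
classical_params <- function(smooth_axial = 3L, smooth_lateral = 7L,
                             k_mad = 6, contrast_frac = 0.25,
                             bg_rows = 8L, refine_px = 2L,
                             refine_max_cv = 0.1,
                             despike_window = 9L, despike_tol_px = 3L) {
  stopifnot(smooth_axial %% 2 == 1, smooth_lateral %% 2 == 1,
            despike_window %% 2 == 1, contrast_frac > 0, contrast_frac < 1)
  structure(as.list(environment()), class = "classical_params")
}

#' Classical (deterministic) skin segmentation of a B-scan
#'
#' Locates the air-skin surface in each A-scan column and fills the mask
#' from the surface to the image bottom. The search runs in two passes:
#' a coarse pass on a boxcar-smoothed image (speckle averaging), followed by
#' a raw-intensity refinement within a few pixels of the coarse estimate so
#' that on noiseless images the detected surface is pixel-exact. The
#' per-column surface is then despiked with a running median. The detection
#' threshold adapts to the image (robust background level plus a fixed
#' fraction of the dynamic range), so the result is invariant to global
#' intensity scaling.
#'
#' @param bscan Numeric matrix (depth x lateral), finite intensities.
#' @param params A [classical_params()].
#' @return A list of class `oct_mask` with elements `labels` (0/1 matrix or
#'   array), `backend = "classical"`, `provenance` (the parameters), and
#'   `surface_rows` (per-column detected row, `NA` where missing before
#'   interpolation).
#' @export
segment_classical <- function(bscan, params = classical_params()) {
  stopifnot(is.matrix(bscan), nrow(bscan) > params$bg_rows)
  if (!all(is.finite(bscan))) stop("B-scan intensities must be finite")
  p <- params
  sm <- .box_smooth(bscan, p$smooth_axial, p$smooth_lateral)
  bg <- bscan[seq_len(p$bg_rows), , drop = FALSE]
  bg_med <- stats::median(bg)
  bg_mad <- stats::mad(bg)
  peak <- max(sm)
  robust_bg <- bg_med + p$k_mad * bg_mad
  if (peak <= robust_bg || peak <= bg_med + 1e-12) {
    stop("no surface detected: image has no depth structure above the noise floor")
  }
  thr <- max(robust_bg, bg_med + p$contrast_frac * (peak - bg_med))

  coarse <- .first_exceed_row(sm, thr)
  coarse <- .despike(coarse, p$despike_window, p$despike_tol_px)
  if (all(is.na(coarse))) stop("no surface detected in any column")

  # refinement: first raw exceedance inside a narrow window, so quiet images
  # are pixel-exact; skipped when the background is speckle-like, where the
  # smoothed coarse estimate is the better edge localizer
  n_depth <- nrow(bscan)
  rows <- coarse
  noise_cv <- bg_mad / max(bg_med, 1e-12)
  if (p$refine_px > 0 && noise_cv < p$refine_max_cv) {
    for (j in which(!is.na(coarse))) {
      lo <- max(1L, coarse[j] - p$refine_px)
      hi <- min(n_depth, coarse[j] + p$refine_px)
      w <- which(bscan[lo:hi, j] > thr)
      rows[j] <- if (length(w)) lo + w[1] - 1L else coarse[j]
    }
    rows <- .despike(rows, p$despike_window, p$despike_tol_px)
  }

  labels <- matrix(0L, n_depth, ncol(bscan))
  for (j in which(!is.na(rows))) labels[rows[j]:n_depth, j] <- 1L
  structure(list(labels = labels, backend = "classical",
                 provenance = unclass(p), surface_rows = rows),
            class = "oct_mask")
}

#' Segment every B-scan of a volume
#'
#' @param vol An [oct_volume()].
#' @param backend `"classical"` or `"neural"`.
#' @param params [classical_params()] (classical backend).
#' @param model A trained model from [train_neural()] (neural backend).
#' @return An `oct_mask` whose `labels` is a 3D 0/1 array aligned to the
#'   volume.
#' @export
segment_volume <- function(vol, backend = c("classical", "neural"),
                           params = classical_params(), model = NULL) {
  stopifnot(inherits(vol, "oct_volume"))
  backend <- match.arg(backend)
  d <- dim(vol$data)
  labels <- array(0L, dim = d)
  for (s in seq_len(d[3])) {
    m <- if (backend == "classical") {
      segment_classical(vol$data[, , s], params)
    } else {
      if (is.null(model)) stop("neural backend requires a trained model")
      predict_neural(model, vol$data[, , s])
    }
    labels[, , s] <- m$labels
  }
  structure(list(labels = labels, backend = backend,
                 provenance = if (backend == "classical") unclass(params)
                              else model$descriptor),
            class = "oct_mask")
}

#' Mean intersection over union of two binary masks
#'
#' Mean over the two classes (background, skin) of `|A n B| / |A u B|`, on a
#' 0-100 scale. A class absent from both masks contributes IoU 1, so
#' degenerate single-class fixtures score sensibly.
#'
#' @param pred,truth 0/1 arrays or `oct_mask` objects of identical shape.
#' @return MIoU percentage in \[0, 100\]; 100 iff the masks are identical.
#' @export
miou <- function(pred, truth) {
  a <- if (inherits(pred, "oct_mask")) pred$labels else pred
  b <- if (inherits(truth, "oct_mask")) truth$labels else truth
  if (!identical(dim(a), dim(b))) {
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  iou_class <- function(av, bv) {
    uni <- sum(av | bv)
    if (uni == 0) return(1)
    sum(av & bv) / uni
  }
  100 * (iou_class(a == 1, b == 1) + iou_class(a == 0, b == 0)) / 2
}

#' Check the single-run-per-column mask invariant
#'
#' In a valid mask every A-scan column is a single contiguous run of skin
#' pixels reaching the bottom of the image (or empty).
#'
#' @param mask `oct_mask` or 0/1 array/matrix.
#' @return Logical.
#' @export
mask_is_contiguous <- function(mask) {
  m <- if (inherits(mask, "oct_mask")) mask$labels else mask
  if (is.matrix(m)) m <- array(m, dim = c(dim(m), 1L))
  for (s in seq_len(dim(m)[3])) {
    sl <- m[, , s]
    for (j in seq_len(ncol(sl))) {
      col <- sl[, j]
      ones <- which(col == 1)
      if (length(ones) == 0) next
      if (!all(diff(ones) == 1) || ones[length(ones)] != length(col)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# separable boxcar mean with replicated edges, via cumulative sums
.box_smooth <- function(mat, h, w) {
  if (h > 1) mat <- .run_mean_cols(mat, h)
  if (w > 1) mat <- t(.run_mean_cols(t(mat), w))
  mat
}

.run_mean_cols <- function(mat, k) {
  half <- (k - 1L) %/% 2L
  n <- nrow(mat)
  padded <- rbind(mat[rep(1L, half), , drop = FALSE], mat,
                  mat[rep(n, half), , drop = FALSE])
  cs <- apply(padded, 2, cumsum)
  cs <- rbind(0, cs)
  (cs[(k + 1):(n + k), , drop = FALSE] - cs[1:n, , drop = FALSE]) / k
}

# first row per column where the image exceeds thr; NA when none
.first_exceed_row <- function(img, thr) {
  ex <- img > thr
  idx <- max.col(t(ex), ties.method = "first")
  has <- colSums(ex) > 0
  out <- ifelse(has, idx, NA_integer_)
  as.integer(out)
}

# replace isolated outlier columns by the local running median; columns with
# no detection stay missing (they are interpolated later, in the surface module)
.despike <- function(rows, window, tol) {
  ok <- !is.na(rows)
  if (sum(ok) < 3) return(rows)
  filled <- round(.interp_missing(as.numeric(rows)))
  med <- stats::runmed(filled, k = min(window, .odd_floor(length(filled))),
                       endrule = "median")
  out <- as.integer(round(ifelse(abs(filled - med) > tol, med, filled)))
  out[!ok] <- NA_integer_
  out
}

.odd_floor <- function(n) if (n %% 2 == 1) n else n - 1L
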