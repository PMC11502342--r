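#' Specification of a synthetic OCT skin/plate phantom
#'
#' Collects the acquisition geometry and tissue parameters of a simulated
#' OCT volume. The defaults mirror a typical dermatology acquisition: 400
#' B-scans taken with a 25 um beam increment, 512 A-scans per B-scan, and a
#' 4 um axial pixel pitch.
#'
#' @param n_slices Number of B-scans in the volume.
#' @param n_depth Axial pixels per A-scan.
#' @param n_lateral A-scans per B-scan.
#' @param axial_pitch,lateral_pitch,slice_pitch Pixel pitches in micrometres.
#' @param surface_profile One of `"flat"`, `"sinusoid"`, `"triangle"`,
#'   `"filtered-noise"`. For `"sinusoid"` and `"triangle"`, `amplitude` is the
#'   peak height of the wave; for `"filtered-noise"` it is the arithmetic mean
#'   roughness (mean absolute height) of the generated field.
#' @param amplitude Profile amplitude in micrometres (see `surface_profile`).
#' @param period Lateral period (sinusoid/triangle) or correlation length
#'   (filtered-noise) in micrometres. Must span at least two lateral pixels.
#' @param curvature_coeff Quadratic sag of the global surface, in um per um^2;
#'   applied per B-scan as `z + curvature_coeff * (x - x0)^2` about the
#'   lateral centre `x0`.
#' @param epidermis_thickness Interval, in micrometres, between the entrance
#'   intensity peak and the dermo-epidermal junction (DEJ) valley; this is the
#'   operational definition an OCT depth profile measures.
#' @param attenuation_mu Dermal attenuation coefficient in 1/mm. The rendered
#'   dermal signal decays as `exp(-2 * mu * z)` (round-trip single scattering).
#' @param speckle `"none"` or `"multiplicative-exponential"` (fully developed
#'   speckle: each voxel is multiplied by an independent Exp(1) deviate).
#' @param noise_floor Background intensity above the surface (arbitrary units
#'   in \[0, 1\]).
#' @param surface_depth_px Depth row (1-based) at which a zero-height surface
#'   sits; leaves headroom for positive heights and curvature.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 400L,
                         n_depth = 512L,
                         n_lateral = 512L,
                         axial_pitch = 4,
                         lateral_pitch = 25,
                         slice_pitch = 25,
                         surface_profile = c("filtered-noise", "flat",
                                             "sinusoid", "triangle"),
                         amplitude = 8,
                         period = 500,
                         curvature_coeff = 0,
                         epidermis_thickness = 100,
                         attenuation_mu = 2,
                         speckle = c("multiplicative-exponential", "none"),
                         noise_floor = 0.02,
                         surface_depth_px = NULL,
                         seed = 1L) {
  surface_profile <- match.arg(surface_profile)
  speckle <- match.arg(speckle)
  stopifnot(n_slices >= 1, n_depth >= 8, n_lateral >= 4,
            axial_pitch > 0, lateral_pitch > 0, slice_pitch > 0,
            amplitude >= 0, attenuation_mu >= 0, noise_floor >= 0,
            is.finite(curvature_coeff), epidermis_thickness > 0)
  if (surface_profile %in% c("sinusoid", "triangle", "filtered-noise") &&
      period < 2 * lateral_pitch) {
    stop("profile period ", period, " um is below two lateral pixels (",
         2 * lateral_pitch, " um): the profile would alias")
  }
  spec <- structure(list(
    n_slices = as.integer(n_slices),
    n_depth = as.integer(n_depth),
    n_lateral = as.integer(n_lateral),
    axial_pitch = axial_pitch,
    lateral_pitch = lateral_pitch,
    slice_pitch = slice_pitch,
    surface_profile = surface_profile,
    amplitude = amplitude,
    period = period,
    curvature_coeff = curvature_coeff,
    epidermis_thickness = epidermis_thickness,
    attenuation_mu = attenuation_mu,
    speckle = speckle,
    noise_floor = noise_floor,
    surface_depth_px = surface_depth_px,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  .check_phantom_geometry(spec)
  spec
}

# Rendering constants of the layered intensity model (arbitrary units).
.phantom_optics <- list(
  entrance_base = 0.45,  # intensity at the detected surface pixel
  peak = 0.9,            # entrance peak intensity
  peak_depth = 8,        # um below the surface at which the peak sits
  valley = 0.25,         # DEJ valley intensity
  dermis0 = 0.55,        # dermal intensity just below the DEJ
  plate_top = 0.8,       # plate surface intensity
  plate_mu = 1           # plate bulk attenuation, 1/mm
)

# Depth row of the zero-height surface plus a validity check that the
# surface, epidermis and >= 20 dermal pixels fit inside the volume.
.phantom_layout <- function(spec) {
  sag <- abs(spec$curvature_coeff) *
    (spec$n_lateral * spec$lateral_pitch / 2)^2
  head_px <- ceiling((spec$amplitude * 2 + sag) / spec$axial_pitch) + 2
  row0 <- spec$surface_depth_px
  if (is.null(row0)) row0 <- max(head_px + 1, ceiling(spec$n_depth / 4))
  dej_px <- ceiling((.phantom_optics$peak_depth + spec$epidermis_thickness) /
                      spec$axial_pitch)
  list(row0 = row0, head_px = head_px, dej_px = dej_px)
}

.check_phantom_geometry <- function(spec) {
  lay <- .phantom_layout(spec)
  if (lay$row0 - lay$head_px < 1) {
    stop("surface heights (amplitude + curvature sag) do not fit above the ",
         "surface reference row; increase surface_depth_px or n_depth")
  }
  if (lay$row0 + lay$head_px + lay$dej_px + 20 > spec$n_depth) {
    stop("layer stack (surface + epidermis + >= 20 dermal pixels) is deeper ",
         "than n_depth = ", spec$n_depth)
  }
  invisible(spec)
}

#' Generate the ground-truth surface height field of a phantom
#'
#' Produces the texture component of the surface: a zero-mean 2D height field
#' (slices x lateral columns, micrometres), before any global curvature is
#' applied. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A numeric matrix `n_slices x n_lateral` of heights in micrometres
#'   with zero mean (up = positive, towards the probe).
#' @export
make_surface <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  x_um <- (seq_len(spec$n_lateral) - 1) * spec$lateral_pitch
  prof <- switch(spec$surface_profile,
    "flat" = rep(0, spec$n_lateral),
    "sinusoid" = spec$amplitude * sin(2 * pi * x_um / spec$period),
    "triangle" = {
      s <- (x_um / spec$period) %% 1
      spec$amplitude * (1 - 4 * abs(s - 0.5))
    },
    "filtered-noise" = NULL)
  if (is.null(prof)) {
    z <- withr::with_seed(spec$seed, .filtered_noise_field(
      spec$n_slices, spec$n_lateral,
      corr_lat_px = spec$period / spec$lateral_pitch,
      corr_slice_px = spec$period / spec$slice_pitch))
    # texture is defined orthogonal to the separable quadratic trend space:
    # a height component lying in that space is indistinguishable from
    # natural curvature, so leaving it in would make the stored truth
    # unrecoverable by any curvature-removing pipeline
    lat_fit <- .poly_project_rows(z, x_um, 2L)
    z <- z - t(.poly_project_rows(t(lat_fit), seq_len(spec$n_slices),
                                  min(2L, spec$n_slices - 1L)))
    z <- z - mean(z)
    ra0 <- mean(abs(z))
    if (ra0 > 0) z <- z * (spec$amplitude / ra0)
  } else {
    z <- matrix(prof, nrow = spec$n_slices, ncol = spec$n_lateral,
                byrow = TRUE)
    z <- z - mean(z)
  }
  z
}

# Gaussian-correlated random field via circular FFT convolution.
.filtered_noise_field <- function(nr, nc, corr_lat_px, corr_slice_px) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  kr <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = corr_slice_px / 2)
  kc <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = corr_lat_px / 2)
  K <- outer(kr, kc)
  Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) / (nr * nc)
}

#' Render a synthetic OCT volume with its exact ground truth
#'
#' Builds the intensity volume of a layered phantom: background noise floor
#' above the (curved) surface; for the `"skin"` layer model a bright entrance
#' band rising to a peak just below the surface, decaying to an intensity
#' valley at the dermo-epidermal junction, then a dermal signal decaying as
#' `exp(-2 * mu * z)`; for the `"plate"` model a bright surface with a single
#' attenuating bulk. Optional fully developed multiplicative speckle.
#'
#' @param spec A [phantom_spec()].
#' @param layer_model `"skin"` (epidermis + dermis) or `"plate"` (surface +
#'   bulk, no intensity valley).
#' @return A list with components `volume` (an [oct_volume()]) and `truth`
#'   (class `phantom_truth`: `true_surface` and `true_curved_surface` height
#'   matrices in um, `true_mask` binary array, `true_rows` integer surface
#'   rows, `true_Ra`, `true_Rz`, `epidermis_thickness`, `attenuation_mu`,
#'   `reference_row`).
#' @export
render_volume <- function(spec, layer_model = c("skin", "plate")) {
  stopifnot(inherits(spec, "phantom_spec"))
  layer_model <- match.arg(layer_model)
  .check_phantom_geometry(spec)
  lay <- .phantom_layout(spec)
  op <- .phantom_optics

  z_tex <- make_surface(spec)
  x_um <- (seq_len(spec$n_lateral) - 1) * spec$lateral_pitch
  x0 <- mean(range(x_um))
  curve <- spec$curvature_coeff * (x_um - x0)^2
  z_curved <- sweep(z_tex, 2, -curve)   # add curvature to every slice

  # surface row per (slice, column); row index grows with depth
  rows <- lay$row0 - round(z_curved / spec$axial_pitch)
  rows[] <- pmax(1L, pmin(spec$n_depth - lay$dej_px - 20L, rows))
  storage.mode(rows) <- "integer"

  depth_px <- seq_len(spec$n_depth)
  vol <- array(0, dim = c(spec$n_depth, spec$n_lateral, spec$n_slices))
  mask <- array(0L, dim = c(spec$n_depth, spec$n_lateral, spec$n_slices))
  for (s in seq_len(spec$n_slices)) {
    # depth below surface in um, negative above the surface
    D <- outer(depth_px, rows[s, ], "-") * spec$axial_pitch
    vol[, , s] <- .layer_intensity(D, spec, layer_model)
    mask[, , s] <- (D >= 0) * 1L
  }
  if (spec$speckle == "multiplicative-exponential") {
    spk_seed <- (spec$seed + 1000003L) %% 2147483647L
    vol <- vol * withr::with_seed(spk_seed,
      array(stats::rexp(length(vol)), dim = dim(vol)))
  }

  volume <- oct_volume(vol, axial_pitch = spec$axial_pitch,
                       lateral_pitch = spec$lateral_pitch,
                       slice_pitch = spec$slice_pitch,
                       source = paste0("phantom:", layer_model, ":seed=",
                                       spec$seed))
  truth <- structure(list(
    true_surface = z_tex,
    true_curved_surface = z_curved,
    true_mask = mask,
    true_rows = rows,
    true_Ra = mean(abs(z_tex)),
    true_Rz = max(z_tex) - min(z_tex),
    epidermis_thickness = if (layer_model == "skin") spec$epidermis_thickness else NA_real_,
    attenuation_mu = if (layer_model == "skin") spec$attenuation_mu else op$plate_mu,
    reference_row = lay$row0,
    spec = spec
  ), class = "phantom_truth")
  list(volume = volume, truth = truth)
}

# Intensity as a function of signed depth below the surface (um).
.layer_intensity <- function(D, spec, layer_model) {
  op <- .phantom_optics
  I <- matrix(spec$noise_floor, nrow(D), ncol(D))
  if (layer_model == "plate") {
    below <- D >= 0
    I[below] <- op$plate_top * exp(-2 * op$plate_mu * D[below] / 1000)
    return(I)
  }
  dpk <- op$peak_depth
  Te <- spec$epidermis_thickness
  rise <- D >= 0 & D < dpk
  I[rise] <- op$entrance_base + (op$peak - op$entrance_base) * D[rise] / dpk
  fall <- D >= dpk & D <= dpk + Te   # valley value sits exactly at the DEJ
  I[fall] <- op$valley + (op$peak - op$valley) *
    0.5 * (1 + cos(pi * (D[fall] - dpk) / Te))
  derm <- D > dpk + Te
  I[derm] <- op$dermis0 *
    exp(-2 * spec$attenuation_mu * (D[derm] - dpk - Te) / 1000)
  I
}

#' Roughness-standard-plate phantom with grid-exact target Ra
#'
#' Builds a periodic triangular groove profile whose amplitude is chosen so
#' that the arithmetic mean roughness of the discrete sampled surface equals
#' `Ra_target` exactly, then renders it as a two-layer plate.
#'
#' @param Ra_target Target arithmetic mean roughness in micrometres (> 0).
#' @param spec A [phantom_spec()]; its `surface_profile`, `amplitude` and
#'   `period` are overridden. The default groove period is 32 lateral pixels,
#'   an exact divisor of the default lateral extent.
#' @param period_px Groove period in lateral pixels (even, divisor of
#'   `n_lateral` for grid exactness).
#' @return As [render_volume()]; `truth$true_Ra == Ra_target` exactly.
#' @export
make_plate_phantom <- function(Ra_target, spec = phantom_spec(),
                               period_px = 32L) {
  stopifnot(Ra_target > 0, period_px >= 4, period_px %% 2 == 0)
  spec$surface_profile <- "triangle"
  spec$period <- period_px * spec$lateral_pitch
  spec$amplitude <- 1
  unit <- make_surface(spec)
  ra_unit <- mean(abs(unit - mean(unit)))
  spec$amplitude <- Ra_target / ra_unit
  .check_phantom_geometry(spec)
  render_volume(spec, layer_model = "plate")
}

#' Synthetic aging cohort of rendered skin phantoms
#'
#' Samples subject ages uniformly in `age_range` and assigns each subject a
#' ground-truth Ra of `baseline + slope * (age - age_range[1])` plus Gaussian
#' subject-level noise, then renders a skin phantom whose surface texture has
#' exactly that Ra on the sampled grid.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param age_range Length-2 numeric, years.
#' @param slope Increase of Ra with age, um/year.
#' @param baseline Ra at the lower end of `age_range`, um.
#' @param noise_sd Subject-level Gaussian noise on Ra, um.
#' @param seed Integer seed (subject i renders with seed `seed + i`).
#' @param spec Template [phantom_spec()] for the rendered volumes.
#' @return A list of records, each with `volume`, `truth`, `age`,
#'   `subject_id`.
#' @export
make_cohort <- function(n_subjects = 16L, age_range = c(15, 45),
                        slope = 0.35, baseline = 8, noise_sd = 1.5,
                        seed = 1L, spec = phantom_spec()) {
  stopifnot(n_subjects >= 3, length(age_range) == 2, noise_sd >= 0)
  draws <- withr::with_seed(seed, list(
    ages = stats::runif(n_subjects, age_range[1], age_range[2]),
    eps = stats::rnorm(n_subjects, 0, noise_sd)
  ))
  ra <- baseline + slope * (draws$ages - age_range[1]) + draws$eps
  if (any(ra <= 0)) {
    warning("clamping ", sum(ra <= 0), " negative target Ra value(s) to 0.5 um")
    ra <- pmax(ra, 0.5)
  }
  lapply(seq_len(n_subjects), function(i) {
    sp <- spec
    sp$surface_profile <- "filtered-noise"
    sp$amplitude <- ra[i]
    sp$seed <- as.integer((seed + i) %% 2147483647)
    r <- render_volume(sp, layer_model = "skin")
    list(volume = r$volume, truth = r$truth,
         age = draws$ages[i], subject_id = sprintf("S%02d", i))
  })
}
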