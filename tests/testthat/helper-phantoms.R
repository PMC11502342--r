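# Small phantom specs used across the suite. Axial pitch 8 um and a shallow
# surface keep the layer stack inside compact volumes so fixtures render in
# milliseconds.

tiny_spec <- function(...) {
  defaults <- list(n_slices = 4L, n_depth = 96L, n_lateral = 64L,
                   axial_pitch = 8, lateral_pitch = 25, slice_pitch = 25,
                   surface_profile = "sinusoid", amplitude = 12, period = 400,
                   curvature_coeff = 0, epidermis_thickness = 96,
                   attenuation_mu = 2, speckle = "none",
                   surface_depth_px = 24L, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

# mid-sized spec matching the main acquisition geometry at reduced slice count
small_skin_spec <- function(...) {
  defaults <- list(n_slices = 6L, n_depth = 256L, n_lateral = 256L,
                   surface_profile = "filtered-noise", amplitude = 8,
                   period = 500, curvature_coeff = 1e-6,
                   speckle = "multiplicative-exponential", seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

# brute-force roughness oracles (kept deliberately naive)
oracle_ra <- function(z) {
  z <- z - sum(z) / length(z)
  s <- 0
  for (v in z) s <- s + abs(v)
  s / length(z)
}

oracle_rz <- function(z) {
  z <- z - sum(z) / length(z)
  mx <- -Inf; mn <- Inf
  for (v in z) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  mx - mn
}

# brute-force MIoU from raw set counts
oracle_miou <- function(a, b) {
  iou <- function(ca, cb) {
    u <- sum(ca | cb)
    if (u == 0) 1 else sum(ca & cb) / u
  }
  100 * (iou(a == 1, b == 1) + iou(a == 0, b == 0)) / 2
}
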