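test_that("flat profile gives an identically zero surface", {
  z <- make_surface(tiny_spec(surface_profile = "flat", amplitude = 0))
  expect_true(all(z == 0))
  r <- render_volume(tiny_spec(surface_profile = "flat", amplitude = 0))
  expect_equal(r$truth$true_Ra, 0)
  expect_equal(r$truth$true_Rz, 0)
})

test_that("triangle wave roughness matches the dense-grid oracle (A/2, 2A)", {
  # period = 16 lateral pixels, an exact divisor of the extent: the sampled
  # triangle hits symmetric height levels, so discrete Ra is exactly A/2
  sp <- tiny_spec(surface_profile = "triangle", amplitude = 12.6,
                  period = 16 * 25, n_lateral = 64L)
  z <- make_surface(sp)
  expect_equal(mean(abs(z)), 6.3, tolerance = 1e-12)
  expect_equal(max(z) - min(z), 25.2, tolerance = 1e-12)
  expect_equal(oracle_ra(z[1, ]), 6.3, tolerance = 1e-9)
  expect_equal(oracle_rz(z[1, ]), 25.2, tolerance = 1e-9)
})

test_that("sinusoid Ra approaches 2A/pi as the grid refines", {
  A <- 10
  coarse <- make_surface(tiny_spec(surface_profile = "sinusoid", amplitude = A,
                                   period = 16 * 25, n_lateral = 64L))
  fine <- make_surface(phantom_spec(
    n_slices = 1L, n_depth = 96L, n_lateral = 4096L, axial_pitch = 8,
    lateral_pitch = 1, slice_pitch = 25, surface_profile = "sinusoid",
    amplitude = A, period = 1024, speckle = "none", surface_depth_px = 24L))
  target <- 2 * A / pi
  expect_lt(abs(mean(abs(fine)) - target), abs(mean(abs(coarse)) - target) + 1e-9)
  expect_equal(mean(abs(fine)), target, tolerance = 1e-3)
  expect_equal(max(fine) - min(fine), 2 * A, tolerance = 1e-6)
})

test_that("profile periods below two lateral pixels are rejected", {
  expect_error(tiny_spec(surface_profile = "sinusoid", period = 30),
               "alias")
})

test_that("rendering is bit-identical for identical spec and seed", {
  sp <- small_skin_spec(n_slices = 2L)
  r1 <- render_volume(sp)
  r2 <- render_volume(sp)
  expect_identical(r1$volume$data, r2$volume$data)
  expect_identical(r1$truth$true_surface, r2$truth$true_surface)
  r3 <- render_volume(small_skin_spec(n_slices = 2L, seed = 2L))
  expect_false(identical(r1$volume$data, r3$volume$data))
})

test_that("truth roughness equals a brute-force recomputation from the surface", {
  for (profile in c("triangle", "sinusoid", "filtered-noise")) {
    r <- render_volume(tiny_spec(surface_profile = profile, amplitude = 9,
                                 period = 400, seed = 5L))
    expect_equal(r$truth$true_Ra, oracle_ra(as.vector(r$truth$true_surface)),
                 tolerance = 1e-9)
    expect_equal(r$truth$true_Rz, oracle_rz(as.vector(r$truth$true_surface)),
                 tolerance = 1e-9)
  }
})

test_that("scaling the amplitude scales true_Ra and true_Rz linearly", {
  base <- render_volume(tiny_spec(surface_profile = "filtered-noise",
                                  amplitude = 5, seed = 9L))$truth
  scaled <- render_volume(tiny_spec(surface_profile = "filtered-noise",
                                    amplitude = 15, seed = 9L))$truth
  expect_equal(scaled$true_Ra, 3 * base$true_Ra, tolerance = 1e-9)
  expect_equal(scaled$true_Rz, 3 * base$true_Rz, tolerance = 1e-9)
})

test_that("curvature changes the curved surface but not the truth roughness", {
  flat <- render_volume(tiny_spec(curvature_coeff = 0, seed = 4L))$truth
  curved <- render_volume(tiny_spec(curvature_coeff = 5e-6, seed = 4L))$truth
  expect_identical(flat$true_Ra, curved$true_Ra)
  expect_identical(flat$true_Rz, curved$true_Rz)
  expect_identical(flat$true_surface, curved$true_surface)
  expect_false(identical(flat$true_curved_surface, curved$true_curved_surface))
})

test_that("noiseless dermal decay has exactly the constructed log slope", {
  sp <- tiny_spec(surface_profile = "flat", amplitude = 0,
                  attenuation_mu = 3, epidermis_thickness = 96)
  r <- render_volume(sp)
  col <- r$volume$data[, 1, 1]
  row0 <- r$truth$true_rows[1, 1]
  dej_px <- (8 + 96) / 8   # peak offset + thickness, in pixels
  derm <- (row0 + dej_px + 1):(row0 + dej_px + 15)
  z_mm <- (seq_along(derm) - 1) * 8 / 1000
  slope <- stats::coef(stats::lm(log(col[derm]) ~ z_mm))[2]
  expect_equal(unname(slope), -6, tolerance = 1e-9)
})

test_that("plate phantom hits the target Ra grid-exactly and scales linearly", {
  sp <- tiny_spec(n_lateral = 64L)
  p1 <- make_plate_phantom(6.3, sp)
  expect_equal(p1$truth$true_Ra, 6.3, tolerance = 1e-12)
  expect_gte(p1$truth$true_Rz, p1$truth$true_Ra)
  p2 <- make_plate_phantom(12.6, sp)
  expect_equal(p2$truth$spec$amplitude, 2 * p1$truth$spec$amplitude,
               tolerance = 1e-12)
  expect_error(make_plate_phantom(0, sp))
})

test_that("noise-free cohort with positive slope is perfectly age-ordered", {
  coh <- make_cohort(n_subjects = 5, slope = 0.3, noise_sd = 0, seed = 3L,
                     spec = tiny_spec(n_slices = 2L))
  ages <- vapply(coh, `[[`, numeric(1), "age")
  ras <- vapply(coh, function(r) r$truth$true_Ra, numeric(1))
  expect_equal(stats::cor(ages, ras), 1, tolerance = 1e-9)
  expect_true(all(ages >= 15 & ages <= 45))
})

test_that("zero-slope cohorts have no systematic age-roughness correlation", {
  rs <- vapply(1:15, function(sd) {
    coh <- make_cohort(n_subjects = 8, slope = 0, noise_sd = 1.5, seed = sd,
                       spec = tiny_spec(n_slices = 1L))
    ages <- vapply(coh, `[[`, numeric(1), "age")
    ras <- vapply(coh, function(r) r$truth$true_Ra, numeric(1))
    stats::cor(ages, ras)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("cohort size and age range can match the 16-subject study design", {
  coh <- make_cohort(n_subjects = 16, age_range = c(15, 45), seed = 2L,
                     spec = tiny_spec(n_slices = 1L))
  expect_length(coh, 16)
  ages <- vapply(coh, `[[`, numeric(1), "age")
  expect_true(all(ages >= 15 & ages <= 45))
})

test_that("layer stacks deeper than the volume are rejected", {
  expect_error(tiny_spec(n_depth = 40L), "deeper|fit")
})
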