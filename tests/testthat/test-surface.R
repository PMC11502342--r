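test_that("boundary extraction picks the topmost skin pixel per column", {
  m <- matrix(0L, 8, 3)
  m[3:8, 1] <- 1L   # boundary at row 3
  m[5:8, 2] <- 1L
  m[1:8, 3] <- 1L   # all skin: boundary at row 1
  bm <- extract_boundary(m, axial_pitch = 4)
  expect_equal(bm$heights[1, ], (1 - c(3, 5, 1)) * 4)
  expect_true(all(!bm$missing))
})

test_that("missing columns are interpolated and flagged; too many is an error", {
  m <- matrix(0L, 8, 5)
  m[3:8, c(1, 2, 4, 5)] <- 1L     # column 3 has no skin
  bm <- extract_boundary(m, axial_pitch = 4)
  expect_true(bm$missing[1, 3])
  expect_equal(bm$heights[1, 3], (1 - 3) * 4)  # linear fill between equals
  m2 <- matrix(0L, 8, 5)
  m2[3:8, 1] <- 1L                # 80% of columns missing
  expect_error(extract_boundary(m2, 4), "unreliable boundary")
})

test_that("phantom masks recover the curved surface to within half a pixel", {
  sp <- tiny_spec(surface_profile = "triangle", amplitude = 12.6,
                  period = 16 * 25, curvature_coeff = 3e-6)
  r <- render_volume(sp)
  bm <- extract_boundary(r$truth$true_mask, axial_pitch = sp$axial_pitch,
                         reference_row = r$truth$reference_row)
  err <- bm$heights - r$truth$true_curved_surface
  expect_lte(max(abs(err)), sp$axial_pitch / 2 + 1e-9)
})

test_that("quadratic inputs are fitted exactly", {
  x <- 0:40
  f <- fit_curvature(2 * x^2, x)
  expect_equal(unname(f$coefficients), c(2, 0, 0), tolerance = 1e-9)
  expect_equal(f$residual_rms, 0, tolerance = 1e-9)
  fc <- fit_curvature(rep(7, 10))
  expect_equal(unname(fc$coefficients), c(0, 0, 7), tolerance = 1e-9)
})

test_that("degenerate fits are rejected", {
  expect_error(fit_curvature(c(1, 2)), "at least 3")
  expect_error(fit_curvature(c(1, 2, 3), x = c(5, 5, 5)), "rank-deficient")
})

test_that("quadratic plus sinusoid separates into trend and texture", {
  x <- seq(0, 1000, by = 1)
  A <- 5
  z <- 1e-4 * x^2 - 0.03 * x + 2 + A * sin(2 * pi * x / 50)
  f <- fit_curvature(z, x)
  expect_equal(unname(f$coefficients[1]), 1e-4, tolerance = 1e-6)
  resid <- z - f$fitted
  expect_equal(mean(abs(resid - mean(resid))), 2 * A / pi, tolerance = 0.02)
})

test_that("flatten annihilates a pure quadratic surface", {
  sp <- tiny_spec(surface_profile = "flat", amplitude = 0,
                  curvature_coeff = 4e-6)
  r <- render_volume(sp)
  bm <- extract_boundary(r$truth$true_mask, sp$axial_pitch,
                         sp$lateral_pitch, sp$slice_pitch)
  det <- flatten(bm)
  # surviving signal is only the rounding of heights to the pixel grid
  expect_lte(compute_ra(det), sp$axial_pitch / 2)
  ideal <- boundary_map(r$truth$true_curved_surface, state = "raw",
                        axial_pitch = sp$axial_pitch,
                        lateral_pitch = sp$lateral_pitch)
  det2 <- flatten(ideal)
  expect_equal(compute_ra(det2), 0, tolerance = 1e-9)
  expect_equal(compute_rz(det2), 0, tolerance = 1e-9)
})

test_that("flatten is idempotent and produces zero-mean maps", {
  r <- render_volume(small_skin_spec(n_slices = 3L, seed = 6L))
  bm <- extract_boundary(r$truth$true_mask, 4, 25, 25)
  d1 <- flatten(bm)
  expect_lt(abs(mean(d1$heights)), 1e-9)
  d2 <- flatten(d1)
  expect_equal(d2$heights, d1$heights, tolerance = 1e-9)
})

test_that("roughness after flattening is stable across curvatures", {
  ras <- vapply(c(0, 1e-6, 3e-6), function(cc) {
    sp <- small_skin_spec(n_slices = 6L, curvature_coeff = cc, seed = 10L)
    r <- render_volume(sp)
    res <- run_pipeline(r$volume)
    res$roughness$Ra
  }, numeric(1))
  expect_lt((max(ras) - min(ras)) / min(ras), 0.02)
})

test_that("boundary maps round-trip through CSV at declared precision", {
  r <- render_volume(tiny_spec(seed = 12L))
  bm <- flatten(extract_boundary(r$truth$true_mask, 8, 25, 25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_boundary(bm, path)
  back <- read_boundary(path)
  expect_equal(back$heights, bm$heights, tolerance = 1e-6)
  expect_identical(back$state, "detrended")
  # byte-identical re-export
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_boundary(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
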