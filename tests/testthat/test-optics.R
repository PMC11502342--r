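make_profile <- function(signal, pitch = 5) {
  structure(list(signal = signal,
                 depth_um = (seq_along(signal) - 1) * pitch,
                 axial_pitch = pitch, smooth = 1L),
            class = "depth_profile")
}

test_that("constructed peak/valley profile gives the expected interval", {
  x <- 0:120
  signal <- exp(-(x - 20)^2 / 50) - 0.8 * exp(-(x - 50)^2 / 80) + 1
  pr <- make_profile(signal, pitch = 5)
  # brute-force oracle: global argmax, then argmin after it
  pk <- which.max(signal)
  vl <- pk + which.min(signal[(pk + 1):length(signal)])
  expect_equal(pk, 21); expect_equal(vl, 51)
  et <- epidermal_thickness(pr)
  expect_equal(et$peak_idx, pk)
  expect_equal(et$valley_idx, vl)
  expect_equal(et$thickness_um, 150)
})

test_that("monotone-decaying profiles raise a no-band error", {
  pr <- make_profile(exp(-(0:100) / 30))
  expect_error(epidermal_thickness(pr), "no epidermal band")
})

test_that("noiseless phantom thickness is exact; speckle stays within a pixel", {
  sp <- small_skin_spec(n_slices = 4L, speckle = "none",
                        epidermis_thickness = 100, seed = 2L)
  r <- render_volume(sp)
  res <- run_pipeline(r$volume)
  expect_equal(res$optics$epidermal_thickness_um, 100)
  sp$speckle <- "multiplicative-exponential"
  r2 <- render_volume(sp)
  res2 <- run_pipeline(r2$volume)
  expect_lte(abs(res2$optics$epidermal_thickness_um - 100), sp$axial_pitch)
})

test_that("attenuation is exact on noiseless exponentials", {
  z_mm <- (0:99) * 0.004
  pr <- make_profile(100 * exp(-6 * z_mm), pitch = 4)
  fit <- attenuation_coefficient(pr, window = c(0, 400))
  expect_equal(fit$mu_mm, 3, tolerance = 1e-9)
  expect_equal(fit$slope_per_mm, -6, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  flat <- attenuation_coefficient(make_profile(rep(2, 60)), window = c(0, 200))
  expect_equal(flat$mu_mm, 0, tolerance = 1e-12)
})

test_that("attenuation fit is invariant to global intensity scaling", {
  z_mm <- (0:60) * 0.004
  base <- make_profile(5 * exp(-4 * z_mm), pitch = 4)
  scaled <- make_profile(5000 * exp(-4 * z_mm), pitch = 4)
  f1 <- attenuation_coefficient(base, window = c(0, 240))
  f2 <- attenuation_coefficient(scaled, window = c(0, 240))
  expect_equal(f1$mu_mm, f2$mu_mm, tolerance = 1e-12)
})

test_that("short or non-positive windows are handled", {
  pr <- make_profile(exp(-(0:100) / 30))
  expect_error(attenuation_coefficient(pr, window = c(0, 10)),
               "at least 10")
  sig <- exp(-(0:50) / 30); sig[10] <- 0
  expect_warning(attenuation_coefficient(make_profile(sig), window = c(0, 200)),
                 "non-positive")
})

test_that("thickness recovery error over a phantom grid has median within a pixel", {
  errs_px <- vapply(c(80, 100, 120), function(th) {
    sp <- small_skin_spec(n_slices = 6L, epidermis_thickness = th, seed = 5L)
    r <- render_volume(sp)
    res <- run_pipeline(r$volume)
    abs(res$optics$epidermal_thickness_um - th) / sp$axial_pitch
  }, numeric(1))
  expect_lte(stats::median(errs_px), 1)
})

test_that("speckled phantoms recover attenuation within 10 percent", {
  for (mu in c(1, 3)) {
    errs <- vapply(1:2, function(sd) {
      sp <- small_skin_spec(n_slices = 6L, attenuation_mu = mu, seed = sd)
      r <- render_volume(sp)
      res <- run_pipeline(r$volume)
      abs(res$optics$attenuation_mu_mm - mu) / mu
    }, numeric(1))
    expect_lt(stats::median(errs), 0.10)
  }
})

test_that("mu estimate is stable under small window shifts on noiseless data", {
  sp <- small_skin_spec(n_slices = 2L, speckle = "none", attenuation_mu = 2,
                        seed = 4L)
  r <- render_volume(sp)
  res <- run_pipeline(r$volume)
  pr <- res$optics$profile
  base_win <- res$optics$fit_window_um
  mus <- vapply(c(-2, 0, 2) * 4, function(shift) {
    attenuation_coefficient(pr, window = base_win + shift)$mu_mm
  }, numeric(1))
  expect_lt((max(mus) - min(mus)) / mus[2], 0.05)
})

test_that("constant volumes yield a constant profile and no band", {
  vol <- oct_volume(array(0.5, c(64, 16, 2)), 4, 25, 25)
  rows <- matrix(5L, 2, 16)
  bm <- boundary_map(matrix(0, 2, 16), state = "raw", axial_pitch = 4,
                     rows = rows)
  pr <- mean_depth_profile(vol, bm)
  expect_true(all(pr$signal == 0.5))
  expect_error(epidermal_thickness(pr), "no epidermal band")
})

test_that("depth profiles are reproducible and exportable", {
  sp <- small_skin_spec(n_slices = 2L, seed = 31L)
  r <- render_volume(sp)
  m <- segment_volume(r$volume)
  b <- extract_boundary(m, 4, 25, 25)
  p1 <- mean_depth_profile(r$volume, b)
  p2 <- mean_depth_profile(r$volume, b)
  expect_identical(p1$signal, p2$signal)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(p1, path)
  back <- utils::read.csv(path)
  expect_lt(max(abs(back$mean_intensity - p1$signal)), 1e-6)
})
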