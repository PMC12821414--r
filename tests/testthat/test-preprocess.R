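test_that("SG smoothing reproduces polynomials up to its order exactly", {
  ax <- seq(800, 1800, by = 4)
  quad <- raman_spectrum(ax, 3 + 0.5 * (ax / 1000) + 2 * (ax / 1000)^2)
  out <- savitzky_golay(quad, order = 2, frame = 7)
  expect_equal(out$intensity, quad$intensity, tolerance = 1e-9)

  const <- raman_spectrum(ax, rep(42, length(ax)))
  expect_equal(savitzky_golay(const)$intensity, const$intensity,
               tolerance = 1e-12)

  cubic <- 1 + (ax / 1000)^3
  out3 <- savitzky_golay(raman_spectrum(ax, cubic), order = 3, frame = 9)
  expect_equal(out3$intensity, cubic, tolerance = 1e-9)
})

test_that("SG equals the per-window least-squares oracle, edges included", {
  set.seed(11)
  ax <- seq(1000, 1200, by = 2)
  y <- sin(ax / 20) + rnorm(length(ax), sd = 0.2)
  got <- savitzky_golay(raman_spectrum(ax, y), order = 2, frame = 7)
  expect_equal(got$intensity, sg_oracle(y, 2, 7), tolerance = 1e-9)
  got2 <- savitzky_golay(raman_spectrum(ax, y), order = 3, frame = 11)
  expect_equal(got2$intensity, sg_oracle(y, 3, 11), tolerance = 1e-9)
})

test_that("SG interior agrees with signal::sgolayfilt", {
  set.seed(12)
  y <- cumsum(rnorm(101))
  got <- savitzky_golay(y, order = 2, frame = 7)
  ref <- signal::sgolayfilt(y, p = 2, n = 7)
  expect_equal(got[4:98], ref[4:98], tolerance = 1e-9)
})

test_that("SG rejects invalid window parameters", {
  sp <- gaussian_spectrum(seq(800, 1800, 10), 1300, 50)
  expect_error(savitzky_golay(sp, order = 2, frame = 6), "odd")
  expect_error(savitzky_golay(sp, order = 7, frame = 7), "odd|greater")
})

test_that("a pure broad background is removed almost completely", {
  # slowly-varying fluorescence flank (Gaussian centered beyond the
  # window): its curvature is far below the structuring element's, so
  # the circle tracks it essentially exactly
  ax <- seq(800, 1800, by = 2)
  hump <- raman_spectrum(ax, 50 * exp(-(ax - 2400)^2 / (2 * 900^2)))
  res <- rolling_circle_baseline(hump, radius = 800, passes = 10)
  expect_lt(max(abs(res$corrected$intensity)),
            0.01 * max(hump$intensity))
})

test_that("baseline sits below a flat-plus-peak spectrum and keeps peak area", {
  ax <- seq(400, 2000, by = 1)  # full recorded span before cropping
  sigma <- 800 / 10 / (2 * sqrt(2 * log(2)))  # FWHM = radius / 10
  sp <- gaussian_spectrum(ax, 1300, sigma, amplitude = 20, offset = 100)
  res <- rolling_circle_baseline(sp, radius = 800, passes = 10)
  tol <- 1e-9 * diff(range(sp$intensity))
  expect_true(all(res$baseline <= sp$intensity + tol))
  expect_true(all(res$corrected$intensity >= -tol))
  under <- abs(ax - 1300) < 3 * sigma
  expect_lt(max(abs(res$baseline[under] - 100)), 0.02 * 20)
  got_area <- integrate_band(res$corrected, c(1100, 1500))
  true_area <- 20 * sigma * sqrt(2 * pi)
  expect_lt(abs(got_area / true_area - 1), 0.02)
})

test_that("rolling-circle equals the exhaustive circle-placement oracle", {
  set.seed(21)
  ax <- seq(1000, 1240, by = 2)  # 121 points
  y <- 30 * exp(-(ax - 1120)^2 / (2 * 150^2)) +
    8 * exp(-(ax - 1100)^2 / (2 * 6^2)) +
    5 * exp(-(ax - 1180)^2 / (2 * 9^2)) + rnorm(length(ax), sd = 0.3)
  for (r in c(60, 150)) {
    got <- rolling_circle_baseline(raman_spectrum(ax, y), radius = r,
                                   passes = 1)$baseline
    ref <- rc_oracle(y, ax, r)
    expect_equal(got, ref, tolerance = 1e-6)
  }
  # multi-pass semantics against the iterated oracle
  got3 <- rolling_circle_baseline(raman_spectrum(ax, y), radius = 60,
                                  passes = 3)$baseline
  expect_equal(got3, rc_oracle_passes(y, ax, 60, 3), tolerance = 1e-6)
})

test_that("extra passes never raise the baseline", {
  set.seed(22)
  ax <- seq(800, 1300, by = 2)
  y <- 20 * exp(-(ax - 1050)^2 / (2 * 300^2)) +
    10 * exp(-(ax - 1100)^2 / (2 * 8^2)) + rnorm(length(ax), sd = 0.4)
  sp <- raman_spectrum(ax, y)
  prev <- rolling_circle_baseline(sp, radius = 300, passes = 1)$baseline
  for (p in 2:4) {
    cur <- rolling_circle_baseline(sp, radius = 300, passes = p)$baseline
    expect_true(all(cur <= prev + 1e-12 * diff(range(y))))
    prev <- cur
  }
})

test_that("baseline is translation-equivariant and monotone in radius", {
  set.seed(23)
  ax <- seq(800, 1800, by = 5)
  y <- 10 * exp(-(ax - 1200)^2 / (2 * 500^2)) +
    4 * exp(-(ax - 1600)^2 / (2 * 12^2)) + rnorm(length(ax), sd = 0.1)
  sp <- raman_spectrum(ax, y)
  b <- rolling_circle_baseline(sp)$baseline
  bshift <- rolling_circle_baseline(raman_spectrum(ax, y + 7))$baseline
  expect_equal(bshift, b + 7, tolerance = 1e-10)

  # pointwise lower-or-equal for larger radius, within the
  # discretization allowance set by the element's edge sampling
  d <- 5; yr <- diff(range(y)); span <- 1000
  for (radii in list(c(200, 400), c(400, 800))) {
    bs <- rolling_circle_baseline(sp, radius = radii[1])$baseline
    bl <- rolling_circle_baseline(sp, radius = radii[2])$baseline
    allow <- (yr / span) * sqrt(2 * radii[1] * d + d^2)
    expect_true(all(bl <= bs + allow))
  }
})

test_that("degenerate rolling-circle inputs are rejected", {
  ax <- seq(800, 1800, by = 10)
  sp <- gaussian_spectrum(ax, 1300, 50)
  expect_error(rolling_circle_baseline(sp, radius = 5), "fewer than 3")
  expect_error(rolling_circle_baseline(sp, radius = -1), "radius")
  expect_error(rolling_circle_baseline(sp, radius = 8000), "radius")
  flat <- raman_spectrum(ax, rep(3, length(ax)))
  res <- rolling_circle_baseline(flat)
  expect_equal(res$corrected$intensity, rep(0, length(ax)))
})

test_that("cropping keeps the closed interval and composes with integration", {
  ax <- seq(400, 2000, by = 2)  # grid hits the band edges
  sp <- gaussian_spectrum(ax, 1300, 100, 5, offset = 1)
  cr <- crop_spectrum(sp, c(800, 1800))
  expect_gte(min(cr$wavenumber), 800)
  expect_lte(max(cr$wavenumber), 1800)
  expect_equal(crop_spectrum(sp, range(ax))$intensity, sp$intensity)
  expect_error(crop_spectrum(sp, c(3000, 4000)), "overlap")

  cr2 <- crop_spectrum(sp, c(1250, 1700))
  expect_equal(integrate_band(cr2, c(1250, 1700)),
               integrate_band(sp, c(1250, 1700)))
})

test_that("the preprocessing chain is deterministic and respects contracts", {
  ens <- small_ensemble()
  p1 <- preprocess_spectra(ens$set)
  p2 <- preprocess_spectra(ens$set)
  expect_identical(p1$intensity, p2$intensity)
  expect_true(all(p1$wavenumber >= 800 & p1$wavenumber <= 1800))
  # corrected >= -tol for every spectrum (tol per spectrum's range)
  tolv <- 1e-9 * apply(ens$set$intensity, 1, function(r) diff(range(r)))
  expect_true(all(p1$intensity >= -tolv))
  expect_equal(p1$manifest, ens$set$manifest)
})

test_that("preprocessing an empty set yields an empty set", {
  ax <- seq(700, 1900, 1)
  empty <- raman_set(ax, matrix(numeric(0), 0, length(ax)),
                     data.frame(producer_id = character(0),
                                pellet_id = character(0),
                                spot_id = character(0),
                                instrument = character(0)))
  out <- preprocess_spectra(empty)
  expect_equal(nrow(out$intensity), 0L)
  expect_true(all(out$wavenumber >= 800 & out$wavenumber <= 1800))
})

test_that("a second preprocessing run changes little", {
  sp <- render_spectrum(1.3, 1, baseline_amp = 1, noise_sd = 0)
  p1 <- preprocess_spectra(sp)
  p2 <- preprocess_spectra(p1)
  # near-idempotence: bounded by the normalized circle's sagitta over
  # the band clusters (~5% of range for the default radius)
  expect_lt(max(abs(p2$intensity - p1$intensity)),
            0.05 * diff(range(p1$intensity)))
})
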