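test_that("component peak tables anchor the dominant bands", {
  lig <- make_component("lignin")
  expect_equal(lig$peaks$center[which.max(lig$peaks$amplitude)], 1600)
  cel <- make_component("cellulose")
  top2 <- cel$peaks$center[order(cel$peaks$amplitude,
                                 decreasing = TRUE)][1:2]
  expect_setequal(top2, c(1095, 1123))
  ax <- default_axis()
  for (nm in c("lignin", "cellulose")) {
    sp <- render_spectrum(as.numeric(nm == "lignin"),
                          as.numeric(nm == "cellulose"), noise_sd = 0)
    expect_true(all(sp$intensity >= 0))
  }
  expect_error(make_component("bark"), "arg")
})

test_that("rendering is deterministic under a fixed RNG state", {
  set.seed(101)
  a <- render_spectrum(1, 1, baseline_amp = 1, noise_sd = 0.05)
  set.seed(101)
  b <- render_spectrum(1, 1, baseline_amp = 1, noise_sd = 0.05)
  expect_identical(a$intensity, b$intensity)
  expect_error(render_spectrum(-1, 1), "non-negative")
})

test_that("a pure-cellulose rendering leaves under 5% area in the lignin band", {
  sp <- render_spectrum(0, 1, noise_sd = 0)
  ratio_rendered <- integrate_band(sp, c(1250, 1700)) /
    integrate_band(sp, c(980, 1150))
  expect_lt(ratio_rendered, 0.05)
  truth <- true_band_areas(0, 1)
  expect_lt(truth$ratio, 0.05)
  expect_equal(ratio_rendered, truth$ratio, tolerance = 0.01)
})

test_that("doublet-partition jitter conserves band areas but moves heights", {
  base <- true_band_areas(1, 1)
  shifted <- true_band_areas(1, 1, partition = c(0.1, 0.05))
  # conservation is exact globally; within the finite bands the two
  # doublet members lose slightly different tails past the edges
  expect_equal(shifted$lignin_area, base$lignin_area, tolerance = 1e-3)
  expect_equal(shifted$cellulose_area, base$cellulose_area,
               tolerance = 1e-3)
  sp0 <- render_spectrum(1, 1, noise_sd = 0)
  sp1 <- render_spectrum(1, 1, noise_sd = 0, partition = c(0.1, 0.05))
  expect_gt(peak_height(sp1, 1096), peak_height(sp0, 1096))
})

test_that("the hierarchical generator honors its design counts", {
  ens <- small_ensemble()
  expect_equal(nrow(ens$set$intensity), 3 * 2 * 3)
  expect_equal(unname(table(ens$set$manifest$producer_id)),
               rep(6L, 3), ignore_attr = TRUE)
  expect_equal(nrow(ens$truth), nrow(ens$set$intensity))
  expect_equal(ens$truth$producer_id, ens$set$manifest$producer_id)
  expect_true(all(ens$truth$w_lignin > 0 & ens$truth$w_cellulose > 0))
})

test_that("identical seeds give bit-identical ensembles", {
  e1 <- small_ensemble(seed = 7)
  e2 <- small_ensemble(seed = 7)
  expect_identical(e1$set$intensity, e2$set$intensity)
  expect_identical(e1$truth, e2$truth)
  e3 <- small_ensemble(seed = 8)
  expect_false(identical(e1$set$intensity, e3$set$intensity))
})

test_that("disabling all jitter makes a producer's spectra identical", {
  ens <- generate_ensemble(ensemble_design(
    n_producers = 2, pellets_per_producer = 2, spots_per_pellet = 2,
    producer_licel_weights = c(1.5, 1), sigma_pellet = 0,
    sigma_spot = 0, sigma_scale = 0, sigma_res = 0,
    sigma_partition = c(0, 0), baseline_amplitude_range = c(1, 1),
    noise_sd = 0, seed = 5))
  X <- ens$set$intensity
  for (p in c("P1", "P2")) {
    rows <- which(ens$set$manifest$producer_id == p)
    expect_equal(max(apply(X[rows, ], 2, function(col)
      diff(range(col)))), 0)
  }
  expect_false(identical(X[1, ], X[5, ]))  # regimes differ
})

test_that("handheld and lab profiles agree on band areas at matched seeds", {
  des <- ensemble_design(n_producers = 2, pellets_per_producer = 2,
                         spots_per_pellet = 5,
                         producer_licel_weights = c(1.5, 1), seed = 9)
  lab <- generate_ensemble(des, instrument_profile("lab"))
  hh <- generate_ensemble(des, instrument_profile("handheld"))
  q_lab <- quantify_spots(preprocess_spectra(lab$set))
  q_hh <- quantify_spots(preprocess_spectra(hh$set))
  m_lab <- tapply(q_lab$licel_area_ratio, q_lab$producer_id, mean)
  m_hh <- tapply(q_hh$licel_area_ratio, q_hh$producer_id, mean)
  expect_true(all(abs(m_hh / m_lab - 1) < 0.10))
})

test_that("instrument profiles respect the degradation ordering", {
  lab <- instrument_profile("lab")
  hh <- instrument_profile("handheld")
  expect_gte(hh$resolution_fwhm, lab$resolution_fwhm)
  expect_gte(hh$noise_multiplier, 1)
  expect_error(instrument_profile("lab", resolution_fwhm = -1),
               "positive")
})
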