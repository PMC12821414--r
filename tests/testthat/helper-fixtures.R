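# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The default seeded study-design ensemble, preprocessed and analysed.
# Several acceptance checks share it; building it once keeps the suite
# fast.
default_analysis <- function() {
  if (is.null(.fixture_cache$default)) {
    ens <- generate_ensemble()
    proc <- preprocess_spectra(ens$set)
    spots <- quantify_spots(proc)
    pca <- fit_uncentered_pca(proc)
    .fixture_cache$default <- list(ensemble = ens, processed = proc,
                                   spots = spots, pca = pca)
  }
  .fixture_cache$default
}

# A small hierarchical ensemble for cheap structural tests.
small_ensemble <- function(seed = 42L, ...) {
  generate_ensemble(ensemble_design(n_producers = 3L,
                                    pellets_per_producer = 2L,
                                    spots_per_pellet = 3L,
                                    producer_licel_weights = c(1.5, 1, 1),
                                    seed = seed, ...))
}

# Gaussian-peak spectrum on a uniform axis.
gaussian_spectrum <- function(axis, center, sigma, amplitude = 1,
                              offset = 0) {
  raman_spectrum(axis, offset +
                   amplitude * exp(-(axis - center)^2 / (2 * sigma^2)))
}
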