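#' Default wavenumber axis of the generator
#'
#' 800-1800 cm^-1 at 1 cm^-1 spacing (1001 points). The recorded range
#' of the emulated lab instrument; the spacing is a generator parameter,
#' not an instrument constant.
#'
#' @param step Axis spacing in cm^-1.
#' @return Numeric axis.
#' @export
default_axis <- function(step = 1) seq(800, 1800, by = step)

#' Built-in lignin / cellulose component peak tables
#'
#' Gaussian component bands of the two biopolymers. The anchored
#' dominant bands are lignin 1600 cm^-1 (aryl ring breathing, with the
#' 1656 cm^-1 coniferyl shoulder) and the cellulose 1095/1123 cm^-1
#' C-C / C-O stretching doublet; the minor bands populating the
#' integration ranges (lignin 1250-1700, cellulose 980-1150 cm^-1) are
#' fixed design choices of the generator, not literature constants.
#'
#' @param name `"lignin"` or `"cellulose"`.
#' @return A list of class `component_spectrum` with a `peaks`
#'   data.frame (columns `center`, `sigma`, `amplitude`).
#' @export
make_component <- function(name = c("lignin", "cellulose")) {
  name <- match.arg(name)
  peaks <- switch(name,
    lignin = data.frame(
      center    = c(1600, 1656, 1453, 1334, 1271),
      sigma     = c(  12,   13,   11,   12,   12),
      amplitude = c(1.00, 0.30, 0.20, 0.20, 0.25)),
    cellulose = data.frame(
      center    = c(1095, 1123, 1060, 1150,  969,  898, 1338, 1380),
      sigma     = c(   8,    8,    9,    9,    9,   10,   11,   10),
      amplitude = c(1.00, 0.75, 0.30, 0.20, 0.20, 0.25, 0.035, 0.030)))
  structure(list(name = name, peaks = peaks),
            class = "component_spectrum")
}

# Gaussian FWHM -> sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Band-shape variability: transfer `delta` of amplitude from the
# secondary to the dominant band of a component's doublet, conserving
# total peak area (amplitude * sigma). Emulates crystallinity /
# condensation differences between spots.
apply_partition <- function(peaks, from, to, delta) {
  if (delta == 0) return(peaks)
  i <- which(peaks$center == to); j <- which(peaks$center == from)
  peaks$amplitude[i] <- peaks$amplitude[i] + delta
  peaks$amplitude[j] <- peaks$amplitude[j] -
    delta * peaks$sigma[i] / peaks$sigma[j]
  if (any(peaks$amplitude[c(i, j)] <= 0))
    stop("partition shift ", delta, " drives a band amplitude negative")
  peaks
}

component_peaks <- function(comp, partition_delta = 0) {
  if (comp$name == "cellulose")
    apply_partition(comp$peaks, from = 1123, to = 1095, partition_delta)
  else
    apply_partition(comp$peaks, from = 1656, to = 1600, partition_delta)
}

# Evaluate a peak table on the axis, convolved to instrumental
# resolution. Gaussian (x) Gaussian is exact: each band keeps its area
# while broadening from sigma0 to sqrt(sigma0^2 + sigma_inst^2).
eval_peaks <- function(peaks, axis, sigma_inst = 0) {
  out <- numeric(length(axis))
  for (r in seq_len(nrow(peaks))) {
    s_eff <- sqrt(peaks$sigma[r]^2 + sigma_inst^2)
    out <- out + peaks$amplitude[r] * peaks$sigma[r] / s_eff *
      exp(-(axis - peaks$center[r])^2 / (2 * s_eff^2))
  }
  out
}

# Broad fluorescence hump: Gaussian centered at 1150 cm^-1 with
# sigma 600 cm^-1, unit peak amplitude. Curvature radius is far larger
# than any Raman band width.
fluorescence_shape <- function(axis) exp(-(axis - 1150)^2 / (2 * 600^2))

#' Instrument profiles of the generator
#'
#' The lab profile emulates a benchtop system (8 cm^-1 FWHM resolution,
#' unit noise); the handheld profile is broader and noisier
#' (12 cm^-1 FWHM, 2x noise), a modest degradation consistent with
#' field-grade spectrometers.
#'
#' @param kind `"lab"` or `"handheld"`.
#' @param resolution_fwhm Instrumental broadening FWHM, cm^-1.
#' @param noise_multiplier Multiplies the design's `noise_sd`.
#' @return A list of class `instrument_profile`.
#' @export
instrument_profile <- function(kind = c("lab", "handheld"),
                               resolution_fwhm = NULL,
                               noise_multiplier = NULL) {
  kind <- match.arg(kind)
  if (is.null(resolution_fwhm))
    resolution_fwhm <- if (kind == "lab") 8 else 12
  if (is.null(noise_multiplier))
    noise_multiplier <- if (kind == "lab") 1 else 2
  if (resolution_fwhm <= 0 || noise_multiplier <= 0)
    stop("profile parameters must be positive")
  structure(list(kind = kind, resolution_fwhm = resolution_fwhm,
                 noise_multiplier = noise_multiplier),
            class = "instrument_profile")
}

#' Render one synthetic spot spectrum
#'
#' intensity(v) = w_L * L(v) + w_C * C(v) + baseline_amp * B(v) + eps(v),
#' where L and C are the built-in component spectra convolved to the
#' instrument resolution, B is a fixed broad fluorescence hump, and eps
#' is i.i.d. Gaussian noise with sd `noise_sd * noise_multiplier`
#' (drawn from R's global RNG; seed it for reproducibility). Negative
#' counts are clamped to zero, which is inactive in practice because
#' the fluorescence floor dominates the noise amplitude.
#'
#' @param w_lignin,w_cellulose Component weights, > 0 allowed to be any
#'   non-negative value.
#' @param profile An [instrument_profile()].
#' @param baseline_amp Fluorescence amplitude (same units as weights).
#' @param noise_sd Noise standard deviation before the profile
#'   multiplier.
#' @param axis Wavenumber axis.
#' @param width_scale Multiplies the instrumental broadening sigma
#'   (spot-focus variability; 1 = nominal).
#' @param partition Length-2 numeric: amplitude shifts of the cellulose
#'   1095/1123 and lignin 1600/1656 doublets (area-conserving).
#' @param meta Spot metadata.
#' @return A [raman_spectrum()].
#' @export
render_spectrum <- function(w_lignin, w_cellulose,
                            profile = instrument_profile("lab"),
                            baseline_amp = 0, noise_sd = 0,
                            axis = default_axis(), width_scale = 1,
                            partition = c(0, 0), meta = spot_meta()) {
  if (w_lignin < 0 || w_cellulose < 0)
    stop("component weights must be non-negative")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  s_inst <- fwhm_to_sigma(profile$resolution_fwhm) * width_scale
  lig <- eval_peaks(component_peaks(make_component("lignin"),
                                    partition[2]), axis, s_inst)
  cel <- eval_peaks(component_peaks(make_component("cellulose"),
                                    partition[1]), axis, s_inst)
  y <- w_lignin * lig + w_cellulose * cel +
    baseline_amp * fluorescence_shape(axis)
  if (noise_sd > 0)
    y <- y + stats::rnorm(length(axis),
                          sd = noise_sd * profile$noise_multiplier)
  raman_spectrum(axis, pmax(y, 0), meta = meta)
}

#' Closed-form band areas of a rendered spectrum
#'
#' Analytic integrals of the noise-free, baseline-free rendered signal
#' over the two integration bands, using the Gaussian error function.
#' Serves as the ground-truth oracle for the band-quantification chain.
#'
#' @inheritParams render_spectrum
#' @param bands A [default_bands()] object.
#' @return A list with `lignin_area`, `cellulose_area`, `ratio`.
#' @export
true_band_areas <- function(w_lignin, w_cellulose,
                            profile = instrument_profile("lab"),
                            bands = default_bands(), width_scale = 1,
                            partition = c(0, 0)) {
  s_inst <- fwhm_to_sigma(profile$resolution_fwhm) * width_scale
  band_area <- function(peaks, weight, interval) {
    s_eff <- sqrt(peaks$sigma^2 + s_inst^2)
    weight * sum(peaks$amplitude * peaks$sigma * sqrt(2 * pi) *
      (stats::pnorm(interval[2], peaks$center, s_eff) -
       stats::pnorm(interval[1], peaks$center, s_eff)))
  }
  lp <- component_peaks(make_component("lignin"), partition[2])
  cp <- component_peaks(make_component("cellulose"), partition[1])
  li <- band_area(lp, w_lignin, bands$lignin_area) +
    band_area(cp, w_cellulose, bands$lignin_area)
  ce <- band_area(lp, w_lignin, bands$cellulose_area) +
    band_area(cp, w_cellulose, bands$cellulose_area)
  list(lignin_area = li, cellulose_area = ce, ratio = li / ce)
}

#' Ensemble design: the emulated study layout
#'
#' Defaults emulate the study design: 8 producers x 5 pellets x 10
#' spots = 400 spectra, with a two-regime lignin preset (producers 1-3
#' at a lignin:cellulose weight ratio of 1.5, producers 4-8 at 1.0).
#' Per-spot weights are drawn hierarchically: producer mean, then
#' lognormal pellet-level jitter (`sigma_pellet`), then lognormal
#' spot-level jitter (`sigma_spot`), independently for the two
#' components. Additional per-spot nuisances emulate pellet-surface
#' heterogeneity: an overall collection-efficiency scale
#' (`sigma_scale`), instrumental-broadening jitter (`sigma_res`), and
#' area-conserving doublet-partition jitter (`sigma_partition`,
#' cellulose then lignin) that scatters single-point peak heights while
#' leaving band areas unchanged.
#'
#' @param n_producers,pellets_per_producer,spots_per_pellet Counts.
#' @param producer_licel_weights Per-producer lignin:cellulose weight
#'   ratio (cellulose weight is 1 before jitter).
#' @param sigma_pellet,sigma_spot Lognormal sdlog of the weight jitter.
#' @param sigma_scale Lognormal sdlog of the overall intensity scale.
#' @param sigma_res Lognormal sdlog of the resolution jitter.
#' @param sigma_partition Length-2 sd of the cellulose and lignin
#'   doublet partition shifts.
#' @param baseline_amplitude_range Uniform range of the fluorescence
#'   amplitude (multiplied by the spot's intensity scale).
#' @param noise_sd Detector noise sd, in units of a unit component peak.
#' @param axis Wavenumber axis.
#' @param seed Integer seed; the ensemble is fully determined by it.
#' @return A list of class `ensemble_design`.
#' @export
ensemble_design <- function(n_producers = 8L,
                            pellets_per_producer = 5L,
                            spots_per_pellet = 10L,
                            producer_licel_weights =
                              c(1.5, 1.5, 1.5, 1, 1, 1, 1, 1),
                            sigma_pellet = 0.05,
                            sigma_spot = 0.08,
                            sigma_scale = 0.20,
                            sigma_res = 0.10,
                            sigma_partition = c(0.06, 0.04),
                            baseline_amplitude_range = c(0.5, 1.5),
                            noise_sd = 0.02,
                            axis = default_axis(),
                            seed = 1234L) {
  n_producers <- as.integer(n_producers)
  pellets_per_producer <- as.integer(pellets_per_producer)
  spots_per_pellet <- as.integer(spots_per_pellet)
  if (min(n_producers, pellets_per_producer, spots_per_pellet) < 1L)
    stop("all design counts must be at least 1")
  producer_licel_weights <- rep_len(as.numeric(producer_licel_weights),
                                    n_producers)
  if (any(producer_licel_weights <= 0))
    stop("producer weight ratios must be positive")
  if (any(c(sigma_pellet, sigma_spot, sigma_scale, sigma_res,
            sigma_partition) < 0))
    stop("jitter parameters must be non-negative")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (length(baseline_amplitude_range) != 2L ||
      baseline_amplitude_range[1] > baseline_amplitude_range[2] ||
      baseline_amplitude_range[1] < 0)
    stop("`baseline_amplitude_range` must be c(lo, hi) with 0 <= lo <= hi")
  structure(list(n_producers = n_producers,
                 pellets_per_producer = pellets_per_producer,
                 spots_per_pellet = spots_per_pellet,
                 producer_licel_weights = producer_licel_weights,
                 sigma_pellet = sigma_pellet, sigma_spot = sigma_spot,
                 sigma_scale = sigma_scale, sigma_res = sigma_res,
                 sigma_partition = as.numeric(sigma_partition),
                 baseline_amplitude_range =
                   as.numeric(baseline_amplitude_range),
                 noise_sd = noise_sd, axis = as.numeric(axis),
                 seed = as.integer(seed)),
            class = "ensemble_design")
}

# truncate partition draws so amplitudes stay positive
rtrunc_norm <- function(n, sd, limit) {
  if (sd == 0) return(rep(0, n))
  pmax(pmin(stats::rnorm(n, 0, sd), limit), -limit)
}

#' Generate a hierarchical synthetic pellet ensemble
#'
#' Draws per-spot true component weights hierarchically (producer mean
#' -> pellet lognormal jitter -> spot lognormal jitter), renders every
#' spot spectrum under the instrument profile, and returns the ensemble
#' with a truth table of the generating parameters. Fully determined by
#' `design$seed`.
#'
#' @param design An [ensemble_design()].
#' @param profile An [instrument_profile()].
#' @return A list of class `pellet_ensemble`: `set` (a [raman_set()]),
#'   `truth` (data.frame of per-spot true weights and nuisances),
#'   `design`, `profile`.
#' @export
#' @examples
#' ens <- generate_ensemble(ensemble_design(n_producers = 2,
#'   pellets_per_producer = 2, spots_per_pellet = 2))
#' ens$set
generate_ensemble <- function(design = ensemble_design(),
                              profile = instrument_profile("lab")) {
  stopifnot(inherits(design, "ensemble_design"),
            inherits(profile, "instrument_profile"))
  set.seed(design$seed)
  n <- design$n_producers * design$pellets_per_producer *
    design$spots_per_pellet
  axis <- design$axis
  inten <- matrix(NA_real_, n, length(axis))
  truth <- vector("list", n)
  row <- 0L
  for (p in seq_len(design$n_producers)) {
    r_p <- design$producer_licel_weights[p]
    for (q in seq_len(design$pellets_per_producer)) {
      f_pellet <- stats::rlnorm(2, 0, design$sigma_pellet)
      for (s in seq_len(design$spots_per_pellet)) {
        f_spot <- stats::rlnorm(2, 0, design$sigma_spot)
        scale <- stats::rlnorm(1, 0, design$sigma_scale)
        w_l <- r_p * f_pellet[1] * f_spot[1] * scale
        w_c <- 1 * f_pellet[2] * f_spot[2] * scale
        width_scale <- stats::rlnorm(1, 0, design$sigma_res)
        part <- c(rtrunc_norm(1, design$sigma_partition[1], 0.30),
                  rtrunc_norm(1, design$sigma_partition[2], 0.12))
        bamp <- stats::runif(1, design$baseline_amplitude_range[1],
                             design$baseline_amplitude_range[2]) * scale
        meta <- spot_meta(producer_id = paste0("P", p),
                          pellet_id = paste0("pellet", q),
                          spot_id = paste0("spot", s),
                          instrument = profile$kind)
        sp <- render_spectrum(w_l, w_c, profile, baseline_amp = bamp,
                              noise_sd = design$noise_sd, axis = axis,
                              width_scale = width_scale,
                              partition = part, meta = meta)
        row <- row + 1L
        inten[row, ] <- sp$intensity
        truth[[row]] <- data.frame(
          producer_id = meta$producer_id, pellet_id = meta$pellet_id,
          spot_id = meta$spot_id, instrument = meta$instrument,
          w_lignin = w_l, w_cellulose = w_c, true_ratio = w_l / w_c,
          scale = scale, width_scale = width_scale,
          baseline_amp = bamp, partition_cellulose = part[1],
          partition_lignin = part[2], stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth)
  set <- raman_set(axis, inten,
                   truth[, c("producer_id", "pellet_id", "spot_id",
                             "instrument")])
  structure(list(set = set, truth = truth, design = design,
                 profile = profile),
            class = "pellet_ensemble")
}

#' @export
print.pellet_ensemble <- function(x, ...) {
  cat("Synthetic pellet ensemble:", nrow(x$set$intensity), "spectra (",
      x$design$n_producers, "producers x",
      x$design$pellets_per_producer, "pellets x",
      x$design$spots_per_pellet, "spots ),",
      x$profile$kind, "instrument, seed", x$design$seed, "\n")
  invisible(x)
}
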