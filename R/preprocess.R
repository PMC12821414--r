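#' Preprocessing parameters
#'
#' Bundles the spectral conditioning settings applied identically to
#' every spectrum: Savitzky-Golay smoothing, rolling-circle background
#' removal, and range cropping.
#'
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @param sg_frame Savitzky-Golay window length in points; odd and
#'   greater than `sg_order` (default 7).
#' @param rc_radius Rolling-circle radius in cm^-1 (default 800).
#' @param rc_passes Rolling-circle iteration count (default 10).
#' @param crop Retained wavenumber interval, `c(lo, hi)` in cm^-1
#'   (default `c(800, 1800)`).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(sg_order = 2L, sg_frame = 7L,
                              rc_radius = 800, rc_passes = 10L,
                              crop = c(800, 1800)) {
  sg_order <- as.integer(sg_order); sg_frame <- as.integer(sg_frame)
  if (sg_frame %% 2L == 0L || sg_frame <= sg_order)
    stop("`sg_frame` must be odd and greater than `sg_order`")
  if (rc_radius <= 0) stop("`rc_radius` must be positive")
  if (rc_passes < 1L) stop("`rc_passes` must be at least 1")
  if (length(crop) != 2L || crop[1] >= crop[2])
    stop("`crop` must be an interval c(lo, hi) with lo < hi")
  structure(list(sg_order = sg_order, sg_frame = sg_frame,
                 rc_radius = rc_radius, rc_passes = as.integer(rc_passes),
                 crop = as.numeric(crop)),
            class = "preprocess_params")
}

# Central SG convolution weights: least-squares polynomial of `order`
# over offsets -h..h, evaluated at 0.
sg_center_weights <- function(order, frame) {
  h <- (frame - 1L) %/% 2L
  X <- outer(seq(-h, h), 0:order, `^`)
  # first row of (X'X)^{-1} X'
  drop(solve(crossprod(X), t(X))[1, ])
}

# Polynomial least-squares fit over the truncated window, evaluated at
# the target offset. Order is reduced if the window is too short.
sg_edge_value <- function(y, offsets, order) {
  ord <- min(order, length(y) - 1L)
  X <- outer(offsets, 0:ord, `^`)
  beta <- qr.coef(qr(X), y)
  beta[1]
}

sg_smooth_vec <- function(y, order, frame) {
  n <- length(y)
  if (n < frame)
    stop("spectrum has ", n, " points; needs at least `frame` = ", frame)
  h <- (frame - 1L) %/% 2L
  wts <- sg_center_weights(order, frame)
  out <- numeric(n)
  if (n >= frame) {
    E <- stats::embed(y, frame)            # row i = y[i+frame-1] ... y[i]
    out[(h + 1L):(n - h)] <- drop(E %*% rev(wts))
  }
  for (i in seq_len(h)) {
    win <- 1L:(i + h)
    out[i] <- sg_edge_value(y[win], win - i, order)
    win <- (n - i - h + 1L):n
    out[n - i + 1L] <- sg_edge_value(y[win], win - (n - i + 1L), order)
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoother. Interior points use the
#' standard central convolution weights; at the edges the same-order
#' polynomial is fit on the truncated one-sided window (no reflection
#' padding), so no data are invented at the spectrum ends.
#'
#' @param spec A [raman_spectrum()] (or bare numeric vector).
#' @param order Polynomial order; polynomials up to this degree pass
#'   through unchanged.
#' @param frame Odd window length in points, greater than `order`.
#' @return Smoothed object of the same type as `spec`.
#' @export
#' @examples
#' w <- seq(800, 1800, by = 10)
#' savitzky_golay(raman_spectrum(w, (w / 1000)^2))  # quadratic: unchanged
savitzky_golay <- function(spec, order = 2L, frame = 7L) {
  order <- as.integer(order); frame <- as.integer(frame)
  if (frame %% 2L == 0L || frame <= order)
    stop("`frame` must be odd and greater than `order`")
  if (is.numeric(spec)) return(sg_smooth_vec(spec, order, frame))
  stopifnot(inherits(spec, "raman_spectrum"))
  raman_spectrum(spec$wavenumber,
                 sg_smooth_vec(spec$intensity, order, frame),
                 meta = spec$meta)
}

# Structuring function of the rolling circle on this axis: a
# semicircle of horizontal radius `radius` cm^-1 whose vertical
# semi-axis is radius * (intensity range / axis span), i.e. an ellipse
# invariant under rescaling of either axis.
rc_element <- function(wavenumber, radius, yrange) {
  d <- stats::median(diff(wavenumber))
  span <- wavenumber[length(wavenumber)] - wavenumber[1]
  w <- floor(radius / d)
  if (w < 1L)
    stop("rolling-circle radius ", radius, " cm-1 spans fewer than 3 ",
         "points at the axis spacing of ", signif(d, 4), " cm-1")
  x <- seq(-w, w) * d
  (yrange / span) * sqrt(pmax(radius^2 - x^2, 0))
}

#' Rolling-circle baseline estimation
#'
#' Slides a circle of the given radius beneath the spectrum; the upper
#' envelope traced by the circle follows the broad fluorescence
#' background while dipping under narrow Raman peaks. Realized as 1-D
#' grayscale morphological opening (erosion then dilation) with a
#' semicircular structuring element whose vertical semi-axis is scaled
#' by the spectrum's intensity range over the axis span. Pass k+1 opens
#' the pointwise minimum of the spectrum and the previous baseline,
#' iterating to a stable lower envelope (the opening is idempotent, so
#' the iteration converges quickly; it stops early once stationary).
#'
#' @param spec A [raman_spectrum()] (or bare numeric vector with
#'   `wavenumber` supplied).
#' @param radius Circle radius in cm^-1 (default 800). Must be positive
#'   and at most 4x the axis span.
#' @param passes Maximum iterations (default 10).
#' @param wavenumber Axis, only when `spec` is a bare vector.
#' @return A list of class `baseline_result` with elements `baseline`
#'   (numeric), `corrected` (a [raman_spectrum()] of `spec - baseline`)
#'   and `passes_used`.
#' @export
rolling_circle_baseline <- function(spec, radius = 800, passes = 10L,
                                    wavenumber = NULL) {
  if (is.numeric(spec)) {
    if (is.null(wavenumber))
      stop("supply `wavenumber` when `spec` is a bare vector")
    spec <- raman_spectrum(wavenumber, spec)
  }
  stopifnot(inherits(spec, "raman_spectrum"))
  w <- spec$wavenumber; y <- spec$intensity
  span <- w[length(w)] - w[1]
  if (radius <= 0 || radius > 4 * span)
    stop("`radius` must be in (0, 4 * axis span]; got ", radius,
         " cm-1 for a span of ", span, " cm-1")
  yrange <- max(y) - min(y)
  if (yrange == 0) {
    base <- y
  } else {
    elem <- rc_element(w, radius, yrange)
    base <- rc_open(y, elem)
    used <- 1L
    while (used < passes) {
      nxt <- rc_open(pmin(y, base), elem)
      used <- used + 1L
      if (max(abs(nxt - base)) <= 1e-12 * yrange) { base <- nxt; break }
      base <- nxt
    }
  }
  corrected <- raman_spectrum(w, y - base, meta = spec$meta)
  structure(list(baseline = base, corrected = corrected,
                 passes_used = if (yrange == 0) 0L else used),
            class = "baseline_result")
}

#' Crop a spectrum to a wavenumber interval
#'
#' Keeps the points inside the closed interval; metadata is preserved.
#'
#' @param spec A [raman_spectrum()] or [raman_set()].
#' @param interval `c(lo, hi)` in cm^-1.
#' @return Cropped object of the same class.
#' @export
crop_spectrum <- function(spec, interval = c(800, 1800)) {
  if (length(interval) != 2L || interval[1] >= interval[2])
    stop("`interval` must be c(lo, hi) with lo < hi")
  if (inherits(spec, "raman_set")) {
    keep <- spec$wavenumber >= interval[1] & spec$wavenumber <= interval[2]
    if (!any(keep))
      stop("crop interval [", interval[1], ", ", interval[2],
           "] does not overlap the axis")
    return(raman_set(spec$wavenumber[keep],
                     spec$intensity[, keep, drop = FALSE], spec$manifest))
  }
  stopifnot(inherits(spec, "raman_spectrum"))
  keep <- spec$wavenumber >= interval[1] & spec$wavenumber <= interval[2]
  if (!any(keep))
    stop("crop interval [", interval[1], ", ", interval[2],
         "] does not overlap the axis")
  raman_spectrum(spec$wavenumber[keep], spec$intensity[keep],
                 meta = spec$meta)
}

#' Preprocess an ensemble: smooth, remove background, crop
#'
#' Applies the identical conditioning chain to every spectrum:
#' Savitzky-Golay smoothing, then rolling-circle baseline removal, then
#' range cropping. Deterministic; stage order is fixed.
#'
#' @param set A [raman_set()] (or a single [raman_spectrum()]).
#' @param params A [preprocess_params()].
#' @return Object of the same class with corrected, cropped intensities.
#' @export
preprocess_spectra <- function(set, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  if (inherits(set, "raman_spectrum")) {
    sm <- savitzky_golay(set, params$sg_order, params$sg_frame)
    bc <- rolling_circle_baseline(sm, params$rc_radius, params$rc_passes)
    return(crop_spectrum(bc$corrected, params$crop))
  }
  stopifnot(inherits(set, "raman_set"))
  if (nrow(set$intensity) == 0L) {
    keep <- set$wavenumber >= params$crop[1] &
      set$wavenumber <= params$crop[2]
    return(raman_set(set$wavenumber[keep],
                     set$intensity[, keep, drop = FALSE], set$manifest))
  }
  out <- t(apply(set$intensity, 1L, function(y) {
    sm <- sg_smooth_vec(y, params$sg_order, params$sg_frame)
    sp <- raman_spectrum(set$wavenumber, sm)
    rolling_circle_baseline(sp, params$rc_radius,
                            params$rc_passes)$corrected$intensity
  }))
  crop_spectrum(raman_set(set$wavenumber, out, set$manifest), params$crop)
}
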