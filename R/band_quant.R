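#' Default lignin / cellulose band definitions
#'
#' Area bands integrate the baseline-corrected signal over lignin
#' 1250-1700 cm^-1 and cellulose 980-1150 cm^-1. Height bands take the
#' maximum corrected intensity within +/- `peak_halfwindow` of the
#' lignin 1600 cm^-1 aryl-ring band and the cellulose 1096 cm^-1 C-C/C-O
#' stretching band (the window accommodates the 1095/1096/1098 cm^-1
#' conventions for the cellulose apex).
#'
#' @param lignin_area,cellulose_area Integration intervals, cm^-1.
#' @param lignin_peak,cellulose_peak Nominal apex positions, cm^-1.
#' @param peak_halfwindow Apex search half-window, cm^-1.
#' @return A list of class `band_definitions`.
#' @export
default_bands <- function(lignin_area = c(1250, 1700),
                          cellulose_area = c(980, 1150),
                          lignin_peak = 1600,
                          cellulose_peak = 1096,
                          peak_halfwindow = 10) {
  for (iv in list(lignin_area, cellulose_area))
    if (length(iv) != 2L || iv[1] >= iv[2])
      stop("band intervals must be c(lo, hi) with lo < hi")
  if (peak_halfwindow <= 0) stop("`peak_halfwindow` must be positive")
  structure(list(lignin_area = as.numeric(lignin_area),
                 cellulose_area = as.numeric(cellulose_area),
                 lignin_peak = as.numeric(lignin_peak),
                 cellulose_peak = as.numeric(cellulose_peak),
                 peak_halfwindow = as.numeric(peak_halfwindow)),
            class = "band_definitions")
}

#' Integrate a band area
#'
#' Trapezoidal integral of the (preprocessed) intensity over the closed
#' interval, with linearly interpolated virtual samples at both exact
#' boundaries so the result is insensitive to grid alignment. No
#' additional local baseline is subtracted: the global rolling-circle
#' correction is the only background removal, and negative noise
#' undershoots are integrated as-is (unbiased under symmetric noise).
#'
#' @param spec A preprocessed [raman_spectrum()].
#' @param interval Integration interval `c(lo, hi)`, cm^-1, inside the
#'   spectrum's span.
#' @return The band area in intensity * cm^-1.
#' @export
#' @examples
#' sp <- raman_spectrum(seq(900, 1200, 5), rep(2, 61))
#' integrate_band(sp, c(980, 1150))  # 2 * 170 = 340
integrate_band <- function(spec, interval) {
  stopifnot(inherits(spec, "raman_spectrum"))
  if (length(interval) != 2L || interval[1] >= interval[2])
    stop("`interval` must be c(lo, hi) with lo < hi")
  w <- spec$wavenumber; y <- spec$intensity
  if (interval[1] < w[1] || interval[2] > w[length(w)])
    stop("integration interval [", interval[1], ", ", interval[2],
         "] extends beyond the spectrum span [", w[1], ", ",
         w[length(w)], "]")
  inside <- w > interval[1] & w < interval[2]
  ends <- stats::approx(w, y, xout = interval, method = "linear")$y
  xs <- c(interval[1], w[inside], interval[2])
  ys <- c(ends[1], y[inside], ends[2])
  sum(diff(xs) * (ys[-length(ys)] + ys[-1])) / 2
}

#' Peak height within a search window
#'
#' Maximum corrected intensity within `position +/- halfwindow`,
#' tolerating small apex shifts from calibration or composition.
#'
#' @param spec A preprocessed [raman_spectrum()].
#' @param position Nominal apex position, cm^-1.
#' @param halfwindow Search half-window, cm^-1 (default 10).
#' @return The peak height in intensity units.
#' @export
peak_height <- function(spec, position, halfwindow = 10) {
  stopifnot(inherits(spec, "raman_spectrum"))
  w <- spec$wavenumber
  lo <- position - halfwindow; hi <- position + halfwindow
  if (lo < w[1] || hi > w[length(w)])
    stop("peak window [", lo, ", ", hi,
         "] extends beyond the spectrum span")
  keep <- w >= lo & w <= hi
  max(spec$intensity[keep])
}

#' Lignin-to-cellulose ratio of one spectrum
#'
#' The Li/Ce ratio from either estimator: `"area"` divides the
#' integrated lignin band area (1250-1700 cm^-1) by the cellulose band
#' area (980-1150 cm^-1); `"height"` divides the 1600 cm^-1 peak height
#' by the 1096 cm^-1 peak height. Both are invariant under global
#' intensity rescaling of the corrected spectrum.
#'
#' @param spec A preprocessed [raman_spectrum()].
#' @param mode `"area"` or `"height"`.
#' @param bands A [default_bands()] object.
#' @return Dimensionless ratio.
#' @export
licel_ratio <- function(spec, mode = c("area", "height"),
                        bands = default_bands()) {
  mode <- match.arg(mode)
  if (mode == "area") {
    li <- integrate_band(spec, bands$lignin_area)
    ce <- integrate_band(spec, bands$cellulose_area)
  } else {
    li <- peak_height(spec, bands$lignin_peak, bands$peak_halfwindow)
    ce <- peak_height(spec, bands$cellulose_peak, bands$peak_halfwindow)
  }
  if (!is.finite(ce) || ce <= 0)
    stop("undefined Li/Ce ratio: cellulose ", mode, " statistic is ",
         signif(ce, 6), " (lignin statistic ", signif(li, 6), ")")
  li / ce
}

#' Quantify every spot of a preprocessed ensemble
#'
#' Computes per-spot band areas, peak heights, and both Li/Ce
#' estimators.
#'
#' @param set A preprocessed [raman_set()].
#' @param bands A [default_bands()] object.
#' @return A data.frame with one row per spectrum: the manifest columns
#'   plus `lignin_area`, `cellulose_area`, `licel_area_ratio`,
#'   `lignin_height`, `cellulose_height`, `licel_height_ratio`.
#' @export
quantify_spots <- function(set, bands = default_bands()) {
  stopifnot(inherits(set, "raman_set"))
  n <- nrow(set$intensity)
  res <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    sp <- get_spectrum(set, i)
    la <- integrate_band(sp, bands$lignin_area)
    ca <- integrate_band(sp, bands$cellulose_area)
    lh <- peak_height(sp, bands$lignin_peak, bands$peak_halfwindow)
    ch <- peak_height(sp, bands$cellulose_peak, bands$peak_halfwindow)
    res[i, ] <- c(la, ca, la / ca, lh, ch, lh / ch)
  }
  colnames(res) <- c("lignin_area", "cellulose_area", "licel_area_ratio",
                     "lignin_height", "cellulose_height",
                     "licel_height_ratio")
  cbind(set$manifest, as.data.frame(res))
}

#' Per-group mean, standard deviation and coefficient of variation
#'
#' Aggregates per-spot statistics at the pellet or producer level,
#' ordered deterministically by group label. Standard deviations use the
#' n-1 denominator; a group of size 1 gets sd 0 with a warning.
#'
#' @param results A data.frame from [quantify_spots()].
#' @param level `"producer"` or `"pellet"` (pellet groups are keyed by
#'   producer and pellet).
#' @param statistics Columns to summarize.
#' @return A data.frame with one row per group and statistic: columns
#'   `group_id`, `statistic`, `n`, `mean`, `sd`, `cv`.
#' @export
summarize_groups <- function(results, level = c("producer", "pellet"),
                             statistics = c("lignin_area",
                                            "cellulose_area",
                                            "licel_area_ratio",
                                            "licel_height_ratio")) {
  level <- match.arg(level)
  if (nrow(results) == 0L) stop("no results to summarize")
  statistics <- intersect(statistics, names(results))
  gid <- if (level == "producer") as.character(results$producer_id)
         else paste(results$producer_id, results$pellet_id, sep = ":")
  groups <- sort(unique(gid))
  rows <- list()
  for (g in groups) {
    sel <- gid == g
    n <- sum(sel)
    if (n == 1L)
      warning("group '", g, "' has a single spot; sd reported as 0")
    for (s in statistics) {
      v <- results[[s]][sel]
      m <- mean(v)
      sdev <- if (n > 1L) stats::sd(v) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g, statistic = s, n = n, mean = m, sd = sdev,
        cv = if (m != 0) sdev / m else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
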