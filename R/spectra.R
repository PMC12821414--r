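#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` holds one spot measurement: a strictly increasing
#' wavenumber axis (Raman shift, cm^-1), the detector intensities on that
#' axis, and the spot's provenance (producer, pellet, spot, instrument).
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1. Must be
#'   finite and strictly increasing after sorting; length >= 8.
#' @param intensity Numeric vector of detector counts, same length as
#'   `wavenumber`. Must be finite.
#' @param meta A list or one-row data.frame with elements
#'   `producer_id`, `pellet_id`, `spot_id`, `instrument`
#'   (`"lab"` or `"handheld"`). Defaults are placeholders.
#' @param check_nonnegative If `TRUE`, negative intensities are rejected
#'   (raw detector counts are non-negative). Preprocessed spectra set
#'   this to `FALSE` since baseline-corrected noise may undershoot zero.
#'
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity`, `meta`.
#' @export
#' @examples
#' sp <- raman_spectrum(800:1800, rep(100, 1001))
#' print(sp)
raman_spectrum <- function(wavenumber, intensity,
                           meta = spot_meta(),
                           check_nonnegative = FALSE) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("`wavenumber` and `intensity` must have equal length (",
         length(wavenumber), " vs ", length(intensity), ")")
  if (length(wavenumber) < 8L)
    stop("a spectrum needs at least 8 points, got ", length(wavenumber))
  if (!all(is.finite(wavenumber)))
    stop("wavenumber axis contains non-finite values")
  if (!all(is.finite(intensity)))
    stop("intensity contains non-finite values")
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]
  intensity <- intensity[o]
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis is not strictly increasing (duplicated values?)")
  if (check_nonnegative && any(intensity < 0))
    stop("raw intensities must be non-negative")
  structure(list(wavenumber = wavenumber,
                 intensity = intensity,
                 meta = as_spot_meta(meta)),
            class = "raman_spectrum")
}

#' Spot provenance metadata
#'
#' @param producer_id,pellet_id,spot_id Labels identifying the producer,
#'   the pellet within the producer, and the measurement spot on the
#'   pellet. The triple must be unique within a [raman_set()].
#' @param instrument `"lab"` or `"handheld"`.
#' @return A list of class `spot_meta`.
#' @export
spot_meta <- function(producer_id = NA_character_,
                      pellet_id = NA_character_,
                      spot_id = NA_character_,
                      instrument = "lab") {
  instrument <- match.arg(instrument, c("lab", "handheld"))
  structure(list(producer_id = as.character(producer_id),
                 pellet_id = as.character(pellet_id),
                 spot_id = as.character(spot_id),
                 instrument = instrument),
            class = "spot_meta")
}

as_spot_meta <- function(x) {
  if (inherits(x, "spot_meta")) return(x)
  x <- as.list(x)
  spot_meta(producer_id = if (is.null(x$producer_id)) NA else x$producer_id,
            pellet_id = if (is.null(x$pellet_id)) NA else x$pellet_id,
            spot_id = if (is.null(x$spot_id)) NA else x$spot_id,
            instrument = if (is.null(x$instrument)) "lab" else x$instrument)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat("Raman spectrum:", length(x$wavenumber), "points,",
      sprintf("%.1f-%.1f cm-1", x$wavenumber[1],
              x$wavenumber[length(x$wavenumber)]), "\n")
  m <- x$meta
  cat("  producer", m$producer_id, "| pellet", m$pellet_id,
      "| spot", m$spot_id, "|", m$instrument, "instrument\n")
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...,
                                xlab = expression(paste(
                                  "Raman shift (", cm^-1, ")")),
                                ylab = "Intensity (counts)", type = "l") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

#' Construct an ensemble of spectra on a shared axis
#'
#' A `raman_set` stores an ensemble as an n-by-p intensity matrix (one
#' row per spot spectrum) over one common wavenumber axis, together with
#' a manifest table of per-row provenance. Spectra acquired on different
#' grids must first be interpolated onto a shared axis with
#' [resample_to_common_axis()].
#'
#' @param wavenumber Common wavenumber axis (strictly increasing, cm^-1).
#' @param intensity Numeric matrix, rows = spectra, columns = axis points.
#' @param manifest data.frame with one row per spectrum and columns
#'   `producer_id`, `pellet_id`, `spot_id`, `instrument`. The
#'   (producer, pellet, spot) triple must be unique.
#'
#' @return An object of class `raman_set`.
#' @seealso [raman_spectrum()], [resample_to_common_axis()]
#' @export
raman_set <- function(wavenumber, intensity, manifest) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (ncol(intensity) != length(wavenumber))
    stop("intensity matrix has ", ncol(intensity),
         " columns but the axis has ", length(wavenumber), " points")
  if (length(wavenumber) >= 2 && any(diff(wavenumber) <= 0))
    stop("common wavenumber axis must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop("intensity matrix contains non-finite values")
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  need <- c("producer_id", "pellet_id", "spot_id", "instrument")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(manifest) != nrow(intensity))
    stop("manifest has ", nrow(manifest), " rows but there are ",
         nrow(intensity), " spectra")
  key <- paste(manifest$producer_id, manifest$pellet_id,
               manifest$spot_id, sep = "\r")
  if (anyDuplicated(key))
    stop("(producer, pellet, spot) triples in the manifest are not unique")
  dimnames(intensity) <- NULL
  rownames(manifest) <- NULL
  structure(list(wavenumber = wavenumber,
                 intensity = intensity,
                 manifest = manifest),
            class = "raman_set")
}

#' @export
print.raman_set <- function(x, ...) {
  cat("Raman spectrum set:", nrow(x$intensity), "spectra x",
      length(x$wavenumber), "points,",
      sprintf("%.1f-%.1f cm-1", x$wavenumber[1],
              x$wavenumber[length(x$wavenumber)]), "\n")
  cat("  producers:", paste(unique(x$manifest$producer_id),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.raman_set <- function(x) nrow(x$intensity)

#' Subset a spectrum set, keeping manifest rows aligned
#'
#' @param x A [raman_set()].
#' @param i Row (spectrum) index vector.
#' @param ... Unused.
#' @return A `raman_set` with the selected spectra and manifest rows.
#' @export
`[.raman_set` <- function(x, i, ...) {
  raman_set(x$wavenumber, x$intensity[i, , drop = FALSE],
            x$manifest[i, , drop = FALSE])
}

#' Extract one spectrum from a set
#'
#' @param x A [raman_set()].
#' @param i Single row index.
#' @return A [raman_spectrum()].
#' @export
get_spectrum <- function(x, i) {
  stopifnot(inherits(x, "raman_set"), length(i) == 1L)
  raman_spectrum(x$wavenumber, x$intensity[i, ],
                 meta = as.list(x$manifest[i, , drop = FALSE]))
}

#' @export
as.matrix.raman_set <- function(x, ...) {
  m <- x$intensity
  colnames(m) <- format(x$wavenumber, trim = TRUE)
  m
}

#' Interpolate spectra onto a common wavenumber axis
#'
#' Linearly interpolates each spectrum onto `axis`. Extrapolation is
#' refused: every spectrum must span the target axis.
#'
#' @param spectra A list of [raman_spectrum()] objects, or a single one.
#' @param axis Target wavenumber axis (strictly increasing).
#' @return A [raman_set()] on `axis`, with the manifest assembled from
#'   each spectrum's metadata.
#' @export
resample_to_common_axis <- function(spectra, axis) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  axis <- as.numeric(axis)
  if (any(diff(axis) <= 0)) stop("target axis must be strictly increasing")
  n <- length(spectra)
  if (n == 0L) stop("no spectra to resample")
  lo <- axis[1]; hi <- axis[length(axis)]
  inten <- matrix(NA_real_, n, length(axis))
  meta <- vector("list", n)
  for (k in seq_len(n)) {
    sp <- spectra[[k]]
    if (!inherits(sp, "raman_spectrum"))
      stop("element ", k, " is not a raman_spectrum")
    if (sp$wavenumber[1] > lo || sp$wavenumber[length(sp$wavenumber)] < hi)
      stop("spectrum ", k, " (producer ", sp$meta$producer_id, ", pellet ",
           sp$meta$pellet_id, ", spot ", sp$meta$spot_id,
           ") does not span the target axis [", lo, ", ", hi,
           "] cm-1; refusing to extrapolate")
    inten[k, ] <- stats::approx(sp$wavenumber, sp$intensity,
                                xout = axis, method = "linear")$y
    meta[[k]] <- unclass(sp$meta)
  }
  manifest <- do.call(rbind, lapply(meta, function(m)
    data.frame(m, stringsAsFactors = FALSE)))
  raman_set(axis, inten, manifest)
}
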