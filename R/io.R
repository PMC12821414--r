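#' Read a single two-column spectrum file
#'
#' Reads a whitespace- or comma-separated two-column text file
#' (wavenumber, intensity). Lines starting with `#` are comments. The
#' axis is sorted ascending on read; duplicated wavenumbers are averaged
#' with a warning (common in concatenated exports).
#'
#' @param path File path.
#' @param meta Spot metadata, see [spot_meta()].
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, meta = spot_meta()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("parse error in ", path, ": no data lines")
  parts <- strsplit(trimws(lines[idx]), "[,;[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("parse error in ", path, " at line ", idx[bad[1]],
         ": expected two columns, got '", lines[idx[bad[1]]], "'")
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
  nonnum <- which(rowSums(is.na(vals)) > 0)
  if (length(nonnum))
    stop("parse error in ", path, " at line ", idx[nonnum[1]],
         ": non-numeric field in '", lines[idx[nonnum[1]]], "'")
  w <- vals[, 1]; y <- vals[, 2]
  if (anyDuplicated(w)) {
    warning("duplicated wavenumbers in ", path, "; averaging duplicates")
    y <- as.numeric(tapply(y, w, mean))
    w <- sort(unique(w))
  }
  raman_spectrum(w, y, meta = meta)
}

#' Read a spectra matrix and manifest as a set
#'
#' The matrix CSV has the wavenumber axis as its first row (after an
#' ignored leading label cell, if present) and one spectrum per
#' subsequent row. The manifest CSV has columns
#' `producer_id,pellet_id,spot_id,instrument` (a `file` column is
#' carried along if present) with rows aligned to the matrix.
#'
#' @param matrix_csv Path to the spectra matrix CSV.
#' @param manifest_csv Path to the manifest CSV.
#' @return A [raman_set()].
#' @export
read_spectrum_set <- function(matrix_csv, manifest_csv) {
  if (!file.exists(matrix_csv)) stop("file not found: ", matrix_csv)
  if (!file.exists(manifest_csv)) stop("file not found: ", manifest_csv)
  raw <- utils::read.csv(matrix_csv, header = FALSE,
                         comment.char = "#",
                         stringsAsFactors = FALSE)
  if (nrow(raw) < 2L)
    stop("format error in ", matrix_csv,
         ": need a wavenumber row plus at least one spectrum row")
  # tolerate a leading label column (e.g. "wavenumber", spot ids)
  first <- suppressWarnings(as.numeric(raw[1, 1]))
  if (is.na(first)) raw <- raw[, -1, drop = FALSE]
  m <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (any(is.na(m)))
    stop("format error in ", matrix_csv, ": non-numeric cells")
  w <- m[1, ]
  inten <- m[-1, , drop = FALSE]
  if (any(diff(w) <= 0)) {
    o <- order(w)
    w <- w[o]; inten <- inten[, o, drop = FALSE]
    if (any(diff(w) <= 0))
      stop("format error in ", matrix_csv,
           ": wavenumber row has duplicates")
  }
  manifest <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE,
                              colClasses = "character")
  raman_set(w, inten, manifest)
}

#' Write a spectrum set as matrix + manifest CSV
#'
#' Inverse of [read_spectrum_set()]: numeric values are written with 12
#' significant digits so a read/write round trip is the identity well
#' within 1e-9 relative.
#'
#' @param set A [raman_set()].
#' @param matrix_csv,manifest_csv Output paths.
#' @return Invisibly, `c(matrix_csv, manifest_csv)`.
#' @export
write_spectrum_set <- function(set, matrix_csv, manifest_csv) {
  stopifnot(inherits(set, "raman_set"))
  fmt <- function(v) format(v, digits = 12, trim = TRUE,
                            scientific = FALSE)
  con <- file(matrix_csv, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(fmt(set$wavenumber), collapse = ","), con)
  for (i in seq_len(nrow(set$intensity)))
    writeLines(paste(fmt(set$intensity[i, ]), collapse = ","), con)
  utils::write.csv(set$manifest, manifest_csv, row.names = FALSE,
                   quote = FALSE)
  invisible(c(matrix_csv, manifest_csv))
}
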