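#' Spectrum and spectrum-set containers
#'
#' A `raman_spectrum` couples a strictly increasing wavenumber axis (cm^-1)
#' with one intensity trace and per-spectrum metadata. A `raman_set` stacks
#' spectra that share one axis into an n x p matrix with a metadata table —
#' the currency every pipeline stage consumes and returns.
#'
#' @param wavenumbers numeric, strictly increasing, cm^-1
#' @param intensities numeric, same length as `wavenumbers`, finite
#' @param meta list as returned by [spectrum_meta()]
#' @return `raman_spectrum()` returns an object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = spectrum_meta()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities differ in length", call. = FALSE)
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0))
    stop("wavenumber axis must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  meta <- validate_meta(meta)
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta), class = "raman_spectrum")
}

#' Per-spectrum metadata record
#'
#' @param spectrum_id,sample_id identifier strings; `sample_id` names the
#'   biological source (cell or mouse) that defines cross-validation folds
#' @param label one of `"tumor"`, `"normal"`, `"borderline"`, `"unknown"`
#' @param x_um,y_um optional stage coordinates in micrometers (maps only)
#' @param acquisition free-form named list (laser nm, power mW, exposure, ...)
#' @return a list of class `spectrum_meta`
#' @export
spectrum_meta <- function(spectrum_id = "s1", sample_id = "sample1",
                          label = "unknown", x_um = NA_real_, y_um = NA_real_,
                          acquisition = list()) {
  validate_meta(list(spectrum_id = as.character(spectrum_id),
                     sample_id = as.character(sample_id),
                     label = as.character(label),
                     x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                     acquisition = acquisition))
}

validate_meta <- function(meta) {
  stopifnot(is.list(meta))
  if (!meta$label %in% .raman_labels)
    stop(sprintf("label %s not one of {%s}", dQuote(meta$label),
                 paste(.raman_labels, collapse = ", ")), call. = FALSE)
  class(meta) <- "spectrum_meta"
  meta
}

#' Assemble spectra sharing one axis into a set
#'
#' @param axis shared wavenumber grid, strictly increasing, cm^-1
#' @param intensities numeric matrix, one spectrum per row
#' @param meta data.frame with columns `spectrum_id`, `sample_id`, `label`
#'   and optionally `x_um`, `y_um`; one row per spectrum
#' @return an object of class `raman_set`
#' @export
spectrum_set <- function(axis, intensities, meta) {
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (length(axis) >= 2L && any(diff(axis) <= 0))
    stop("axis must be strictly increasing", call. = FALSE)
  if (ncol(intensities) != length(axis))
    stop("intensity columns must match axis length", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("spectrum_id", "sample_id", "label")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(intensities) != nrow(meta))
    stop("number of spectra and metadata rows differ", call. = FALSE)
  if (anyDuplicated(meta$spectrum_id))
    stop("duplicate spectrum_id in metadata", call. = FALSE)
  bad <- setdiff(unique(meta$label), .raman_labels)
  if (length(bad))
    stop(sprintf("label(s) %s not among {%s}", paste(dQuote(bad), collapse = ", "),
                 paste(.raman_labels, collapse = ", ")), call. = FALSE)
  if (nrow(intensities) && any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (!"x_um" %in% names(meta)) meta$x_um <- NA_real_
  if (!"y_um" %in% names(meta)) meta$y_um <- NA_real_
  rownames(intensities) <- meta$spectrum_id
  structure(list(axis = axis, intensities = intensities, meta = meta),
            class = "raman_set")
}

#' @export
print.raman_set <- function(x, ...) {
  cat(sprintf("<raman_set> %d spectra x %d wavenumbers [%.1f, %.1f] cm^-1\n",
              nrow(x$intensities), length(x$axis),
              if (length(x$axis)) min(x$axis) else NA,
              if (length(x$axis)) max(x$axis) else NA))
  if (nrow(x$meta)) print(table(x$meta$label))
  invisible(x)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s (%s, %s): %d points [%.1f, %.1f] cm^-1\n",
              x$meta$spectrum_id, x$meta$sample_id, x$meta$label,
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Number of spectra in a set
#' @param set a `raman_set`
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Extract one spectrum from a set
#' @param set a `raman_set`
#' @param i row index or spectrum_id
#' @return a `raman_spectrum`
#' @export
get_spectrum <- function(set, i) {
  if (is.character(i)) i <- match(i, set$meta$spectrum_id)
  if (is.na(i) || i < 1L || i > n_spectra(set))
    stop("spectrum index out of range", call. = FALSE)
  m <- set$meta[i, , drop = FALSE]
  raman_spectrum(set$axis, set$intensities[i, ],
                 spectrum_meta(m$spectrum_id, m$sample_id, m$label,
                               m$x_um, m$y_um))
}

#' Subset a spectrum set by row
#' @param set a `raman_set`
#' @param idx logical or integer row index
#' @export
subset_spectra <- function(set, idx) {
  spectrum_set(set$axis, set$intensities[idx, , drop = FALSE],
               set$meta[idx, , drop = FALSE])
}

#' Stack single spectra (sharing one axis) into a set
#' @param spectra list of `raman_spectrum`, identical axes
#' @export
bind_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  ax <- spectra[[1L]]$wavenumbers
  for (s in spectra)
    if (length(s$wavenumbers) != length(ax) || any(s$wavenumbers != ax))
      stop("spectra do not share one axis; resample first", call. = FALSE)
  mat <- do.call(rbind, lapply(spectra, function(s) s$intensities))
  meta <- do.call(rbind, lapply(spectra, function(s)
    data.frame(spectrum_id = s$meta$spectrum_id, sample_id = s$meta$sample_id,
               label = s$meta$label, x_um = s$meta$x_um, y_um = s$meta$y_um,
               stringsAsFactors = FALSE)))
  spectrum_set(ax, mat, meta)
}

#' Band-assignment table
#'
#' Windows of Raman shift (closed intervals, cm^-1) mapped to chemical
#' assignments. Single-position bands are stored with `lo == hi`. The packaged
#' default ([default_band_table()]) lists the fingerprint-region bands used to
#' contrast glioma and normal spectra (phenylalanine 1004, lipid C-C
#' 1050-1100, amide III 1200-1300, CH2 lipid 1450, ...).
#'
#' @param lo,hi numeric window bounds, cm^-1, `lo <= hi`, within \[400, 2000\]
#' @param assignment character description of the chemical structure
#' @return data.frame of class `band_table` with columns lo, hi, assignment
#' @export
band_table <- function(lo, hi, assignment) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  assignment <- as.character(assignment)
  if (any(lo > hi))
    stop("band windows must satisfy lo <= hi", call. = FALSE)
  if (any(lo < 400 | hi > 2000))
    stop("band windows must lie within [400, 2000] cm^-1", call. = FALSE)
  structure(data.frame(lo = lo, hi = hi, assignment = assignment,
                       stringsAsFactors = FALSE),
            class = c("band_table", "data.frame"))
}
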