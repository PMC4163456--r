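#' Read spectra from plain-text files
#'
#' Two dialects are supported. `two_column`: whitespace- or comma-separated
#' `(wavenumber, intensity)` pairs, one per line, one spectrum per file.
#' `matrix_csv`: a CSV whose header row holds the wavenumber axis (first cell
#' is an id column name) and each subsequent row is one spectrum, id first.
#' Files written with a descending axis are reversed to ascending with the
#' intensities permuted accordingly, so both orderings yield identical sets.
#'
#' @param path file path
#' @param dialect `"two_column"` or `"matrix_csv"`
#' @return a [spectrum_set()] on the file's (ascending) axis; metadata carries
#'   placeholder sample ids and `"unknown"` labels until joined with
#'   [read_metadata()] output via [attach_metadata()].
#' @export
read_spectrum_file <- function(path, dialect = c("two_column", "matrix_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "two_column") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[,[:space:]]+")
    vals <- lapply(seq_along(parts), function(i) {
      v <- suppressWarnings(as.numeric(parts[[i]]))
      if (length(v) != 2L || any(is.na(v)))
        stop(sprintf("parse error in %s at line %d: %s", path, i, lines[i]),
             call. = FALSE)
      v
    })
    m <- do.call(rbind, vals)
    wn <- m[, 1L]; y <- m[, 2L]
    ord <- order(wn)
    wn <- wn[ord]; y <- y[ord]
    if (any(diff(wn) <= 0))
      stop("non-monotone wavenumber axis in ", path, call. = FALSE)
    id <- sub("\\.[^.]*$", "", basename(path))
    spectrum_set(wn, matrix(y, nrow = 1L),
                 data.frame(spectrum_id = id, sample_id = id,
                            label = "unknown", stringsAsFactors = FALSE))
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("matrix_csv needs an id column and >= 2 wavenumbers",
                            call. = FALSE)
    wn <- suppressWarnings(as.numeric(names(df)[-1L]))
    if (any(is.na(wn)))
      stop("matrix_csv header must be numeric wavenumbers", call. = FALSE)
    ids <- as.character(df[[1L]])
    mat <- as.matrix(df[, -1L, drop = FALSE])
    if (any(!is.finite(mat)))
      stop("malformed numeric intensity field in ", path, call. = FALSE)
    ord <- order(wn)
    wn <- wn[ord]; mat <- mat[, ord, drop = FALSE]
    if (length(wn) >= 2L && any(diff(wn) <= 0))
      stop("non-monotone wavenumber axis in ", path, call. = FALSE)
    dimnames(mat) <- NULL
    spectrum_set(wn, mat,
                 data.frame(spectrum_id = ids, sample_id = ids,
                            label = "unknown", stringsAsFactors = FALSE))
  }
}

#' Read per-spectrum metadata
#'
#' Required columns: `spectrum_id`, `sample_id`, `label` (one of tumor,
#' normal, borderline, unknown). Optional: `x_um`, `y_um` stage coordinates;
#' empty cells stay `NA` (legal for non-map spectra). Extra columns pass
#' through untouched.
#'
#' @param path CSV path
#' @return data.frame, one row per spectrum
#' @export
read_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("spectrum_id", "sample_id", "label")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df$spectrum_id <- as.character(df$spectrum_id)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$spectrum_id))
    stop("duplicate spectrum_id in ", path, call. = FALSE)
  bad <- setdiff(unique(df$label), .raman_labels)
  if (length(bad))
    stop(sprintf("label(s) %s not among allowed values {%s}",
                 paste(dQuote(bad), collapse = ", "),
                 paste(.raman_labels, collapse = ", ")), call. = FALSE)
  for (cc in c("x_um", "y_um"))
    if (cc %in% names(df)) df[[cc]] <- as.numeric(df[[cc]]) else df[[cc]] <- NA_real_
  df
}

#' Join externally read metadata onto a spectrum set
#' @param set a `raman_set`
#' @param meta data.frame from [read_metadata()]
#' @export
attach_metadata <- function(set, meta) {
  idx <- match(set$meta$spectrum_id, meta$spectrum_id)
  if (any(is.na(idx)))
    stop("metadata missing spectrum_id(s): ",
         paste(set$meta$spectrum_id[is.na(idx)], collapse = ", "), call. = FALSE)
  spectrum_set(set$axis, set$intensities, meta[idx, , drop = FALSE])
}

#' Read a band-assignment table from CSV
#' @param path CSV with columns lo, hi, assignment
#' @return a [band_table()]
#' @export
read_band_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("lo", "hi", "assignment")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("band table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  band_table(df$lo, df$hi, df$assignment)
}

#' The packaged default band table
#'
#' Fingerprint-region Raman bands with their chemical assignments, as used to
#' contrast glioma and normal spectra: C-C protein 950-1000, phenylalanine
#' 1004 and 1030, lipid C-C 1050-1100 and 1120-1130, phosphate backbone 1100,
#' protein C-C/C-N 1120-1200, amide III 1200-1300, CH2 1300-1350 and 1450.
#'
#' @return a [band_table()]
#' @export
default_band_table <- function() {
  read_band_table(system.file("extdata", "band_table_default.csv",
                              package = "ramandx", mustWork = TRUE))
}

#' Write / re-read a spectrum set as paired CSV files
#'
#' Writes `<prefix>_spectra.csv` (matrix_csv dialect) and
#' `<prefix>_metadata.csv`, designed so that `read_spectrumset(prefix)`
#' reproduces the set up to float round-trip (intensities are printed with
#' 17 significant digits).
#'
#' @param set a `raman_set`
#' @param prefix path prefix (directories must exist)
#' @return invisibly, the two paths written
#' @export
write_spectrumset <- function(set, prefix) {
  sp <- paste0(prefix, "_spectra.csv")
  mp <- paste0(prefix, "_metadata.csv")
  con <- try(file(sp, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write to ", sp, call. = FALSE)
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("spectrum_id", format(set$axis, digits = 17, trim = TRUE,
                                           scientific = FALSE)),
                   collapse = ","), con)
  if (n_spectra(set) > 0L) {
    rows <- vapply(seq_len(n_spectra(set)), function(i)
      paste(c(set$meta$spectrum_id[i],
              formatC(set$intensities[i, ], digits = 17, format = "g")),
            collapse = ","), character(1L))
    writeLines(rows, con)
  }
  keep <- c("spectrum_id", "sample_id", "label", "x_um", "y_um")
  write.csv(set$meta[, keep, drop = FALSE], mp, row.names = FALSE, quote = TRUE)
  invisible(c(spectra = sp, metadata = mp))
}

#' @rdname write_spectrumset
#' @export
read_spectrumset <- function(prefix) {
  sp <- paste0(prefix, "_spectra.csv")
  mp <- paste0(prefix, "_metadata.csv")
  meta <- read_metadata(mp)
  header <- strsplit(readLines(sp, n = 1L), ",")[[1L]]
  axis <- as.numeric(header[-1L])
  if (nrow(meta) == 0L)
    return(spectrum_set(axis, matrix(numeric(0), 0L, length(axis)), meta))
  set <- read_spectrum_file(sp, "matrix_csv")
  attach_metadata(set, meta)
}
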