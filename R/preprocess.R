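#' Preprocessing configuration
#'
#' Parameters for the spectral processing chain applied before any
#' statistics: cosmic-ray despiking, background subtraction, normalization to
#' the phenylalanine band near 1004 cm^-1, cropping to the 580-1800 cm^-1
#' fingerprint region, and standardization.
#'
#' @param despike_window running-median window, odd, >= 3 (points)
#' @param despike_z spike threshold in MAD units of the median residual
#' @param baseline_mode `"iterative_poly"` (modified-polyfit), `"als"`
#'   (asymmetric least squares) or `"reference_subtract"`
#' @param poly_order polynomial order for iterative_poly
#' @param als_lambda,als_p ALS smoothness and asymmetry parameters
#' @param phe_center,phe_halfwidth phenylalanine window, cm^-1 (1004 +/- 5)
#' @param fingerprint length-2 numeric, fingerprint region, cm^-1
#' @param standardize_mode `"per_spectrum"` (SNV, default), `"per_wavenumber"`
#'   (autoscaling) or `"none"`
#' @return list of class `preprocess_config`
#' @export
preprocess_config <- function(despike_window = 5L, despike_z = 8,
                              baseline_mode = c("iterative_poly", "als",
                                                "reference_subtract"),
                              poly_order = 5L, als_lambda = 1e5, als_p = 0.01,
                              phe_center = 1004, phe_halfwidth = 5,
                              fingerprint = c(580, 1800),
                              standardize_mode = c("per_spectrum",
                                                   "per_wavenumber", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  standardize_mode <- match.arg(standardize_mode)
  despike_window <- as.integer(despike_window)
  if (despike_window < 3L || despike_window %% 2L == 0L)
    stop("despike_window must be odd and >= 3", call. = FALSE)
  if (phe_halfwidth <= 0) stop("phe_halfwidth must be > 0", call. = FALSE)
  if (fingerprint[1L] >= fingerprint[2L])
    stop("fingerprint lo must be < hi", call. = FALSE)
  structure(list(despike_window = despike_window, despike_z = despike_z,
                 baseline_mode = baseline_mode, poly_order = as.integer(poly_order),
                 als_lambda = als_lambda, als_p = als_p,
                 phe_center = phe_center, phe_halfwidth = phe_halfwidth,
                 fingerprint = as.numeric(fingerprint),
                 standardize_mode = standardize_mode),
            class = "preprocess_config")
}

#' Remove cosmic-ray spikes
#'
#' Points whose residual from a running median exceeds `despike_z` times the
#' MAD of the residuals are replaced by linear interpolation between the
#' flanking unflagged points. Runs of flagged points longer than
#' `despike_window` are treated as genuine structure and left alone.
#'
#' @param s a `raman_spectrum`
#' @param cfg a [preprocess_config()]
#' @return despiked `raman_spectrum`
#' @export
remove_cosmic_rays <- function(s, cfg = preprocess_config()) {
  y <- s$intensities
  if (length(y) <= cfg$despike_window)
    stop("spectrum shorter than despike_window", call. = FALSE)
  med <- runmed(y, cfg$despike_window, endrule = "median")
  resid <- y - med
  sigma <- mad(resid)
  # floor avoids flagging float jitter on noiseless, perfectly smooth input
  sigma <- max(sigma, 1e-12 * max(1, diff(range(y))))
  flag <- abs(resid) > cfg$despike_z * sigma
  # cap run length: only spike-like (narrow) excursions are replaced
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$lengths))
    if (r$values[k] && r$lengths[k] > cfg$despike_window)
      flag[(ends[k] - r$lengths[k] + 1L):ends[k]] <- FALSE
  if (!any(flag)) return(s)
  if (all(flag)) stop("all points flagged as spikes; degenerate spectrum",
                      call. = FALSE)
  keep <- which(!flag)
  y[flag] <- approx(s$wavenumbers[keep], y[keep], xout = s$wavenumbers[flag],
                    rule = 2)$y
  raman_spectrum(s$wavenumbers, y, s$meta)
}

# modified-polyfit baseline: refit on pmin(y, fit) until the set of points
# above the fit stabilizes
.baseline_modpoly <- function(wn, y, order, maxit = 100L) {
  u <- (wn - wn[1L]) / (wn[length(wn)] - wn[1L])
  X <- outer(u, 0:order, `^`)
  ycur <- y
  prev_above <- NULL
  fit <- NULL
  for (it in seq_len(maxit)) {
    fit <- drop(X %*% qr.coef(qr(X), ycur))
    above <- y > fit
    if (!is.null(prev_above) && identical(above, prev_above)) break
    prev_above <- above
    ycur <- pmin(ycur, fit)
  }
  fit
}

# Eilers asymmetric least squares baseline
.baseline_als <- function(y, lambda, p, maxit = 10L) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Subtract the background / baseline
#'
#' `reference_subtract` subtracts a measured solvent background on the same
#' axis; `iterative_poly` fits a polynomial iteratively with points above the
#' fit excluded (modified polyfit); `als` uses asymmetric least squares.
#' Small negative values in the output are allowed (no clipping).
#'
#' @param s a `raman_spectrum`
#' @param cfg a [preprocess_config()]
#' @param reference solvent-background `raman_spectrum` (same axis),
#'   required iff `baseline_mode == "reference_subtract"`
#' @return background-corrected `raman_spectrum`
#' @export
subtract_background <- function(s, cfg = preprocess_config(), reference = NULL) {
  y <- s$intensities
  if (cfg$baseline_mode == "reference_subtract") {
    if (is.null(reference))
      stop("reference spectrum required for reference_subtract", call. = FALSE)
    if (length(reference$wavenumbers) != length(s$wavenumbers) ||
        any(reference$wavenumbers != s$wavenumbers))
      stop("reference axis does not match spectrum axis", call. = FALSE)
    base <- reference$intensities
  } else if (cfg$baseline_mode == "iterative_poly") {
    base <- .baseline_modpoly(s$wavenumbers, y, cfg$poly_order)
  } else {
    base <- .baseline_als(y, cfg$als_lambda, cfg$als_p)
  }
  raman_spectrum(s$wavenumbers, y - base, s$meta)
}

#' Normalize to the phenylalanine band
#'
#' Divides all intensities by the maximum intensity inside the
#' `phe_center +/- phe_halfwidth` window (default 1004 +/- 5 cm^-1), making
#' the sharp phenylalanine peak an internal intensity reference; afterwards
#' the window maximum equals exactly 1.
#'
#' @param s background-subtracted `raman_spectrum`
#' @param cfg a [preprocess_config()]
#' @return normalized `raman_spectrum`
#' @export
normalize_phenylalanine <- function(s, cfg = preprocess_config()) {
  lo <- cfg$phe_center - cfg$phe_halfwidth
  hi <- cfg$phe_center + cfg$phe_halfwidth
  inwin <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (!any(inwin))
    stop("axis does not cover the phenylalanine window", call. = FALSE)
  ref <- max(s$intensities[inwin])
  if (ref <= 0)
    stop("no phenylalanine reference: window maximum <= 0", call. = FALSE)
  raman_spectrum(s$wavenumbers, s$intensities / ref, s$meta)
}

#' Crop to the fingerprint region, dropping spectra that do not cover it
#'
#' Spectra whose axis does not fully contain the closed fingerprint interval
#' (default \[580, 1800\] cm^-1) are removed; survivors are cropped to exactly
#' that interval.
#'
#' @param x a `raman_set`, or a list of `raman_spectrum` with possibly
#'   heterogeneous axes
#' @param cfg a [preprocess_config()]
#' @return same shape as the input (set or list); possibly empty, with a
#'   warning when everything is dropped
#' @export
filter_fingerprint <- function(x, cfg = preprocess_config()) {
  lo <- cfg$fingerprint[1L]; hi <- cfg$fingerprint[2L]
  if (inherits(x, "raman_set")) {
    if (length(x$axis) == 0L || min(x$axis) > lo || max(x$axis) < hi) {
      warning("no spectrum covers the fingerprint region; empty set returned")
      return(spectrum_set(numeric(0),
                          matrix(numeric(0), 0L, 0L),
                          x$meta[0L, , drop = FALSE]))
    }
    keep <- x$axis >= lo & x$axis <= hi
    return(spectrum_set(x$axis[keep], x$intensities[, keep, drop = FALSE],
                        x$meta))
  }
  stopifnot(is.list(x))
  out <- list()
  for (s in x) {
    if (min(s$wavenumbers) <= lo && max(s$wavenumbers) >= hi) {
      keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
      out[[length(out) + 1L]] <-
        raman_spectrum(s$wavenumbers[keep], s$intensities[keep], s$meta)
    }
  }
  if (!length(out)) warning("all spectra dropped by the fingerprint filter")
  out
}

#' Resample spectra onto a common wavenumber grid
#'
#' Linear interpolation, no extrapolation: every spectrum's axis must span
#' the target grid.
#'
#' @param x a `raman_set` or list of `raman_spectrum`
#' @param grid target axis, strictly increasing, cm^-1
#' @return a `raman_set` on `grid`
#' @export
resample_to_grid <- function(x, grid) {
  grid <- as.numeric(grid)
  specs <- if (inherits(x, "raman_set"))
    lapply(seq_len(n_spectra(x)), function(i) get_spectrum(x, i)) else x
  out <- lapply(specs, function(s) {
    if (min(s$wavenumbers) > min(grid) || max(s$wavenumbers) < max(grid))
      stop("grid outside span of spectrum ", s$meta$spectrum_id, call. = FALSE)
    raman_spectrum(grid, approx(s$wavenumbers, s$intensities, xout = grid)$y,
                   s$meta)
  })
  bind_spectra(out)
}

#' Standardize a spectrum set
#'
#' `per_spectrum` (SNV, default): each row is transformed to mean 0 and unit
#' sd across wavenumbers. `per_wavenumber` (autoscaling): each column to mean
#' 0 and unit sd across spectra. Sample sd uses the n-1 denominator.
#'
#' @param set a `raman_set`
#' @param cfg a [preprocess_config()]; only `standardize_mode` is used
#' @return standardized `raman_set`
#' @export
standardize <- function(set, cfg = preprocess_config()) {
  mode <- cfg$standardize_mode
  if (mode == "none") return(set)
  X <- set$intensities
  if (mode == "per_spectrum") {
    m <- rowMeans(X)
    s <- apply(X, 1L, sd)
    if (any(s == 0))
      stop("zero-variance spectrum: ",
           paste(set$meta$spectrum_id[s == 0], collapse = ", "), call. = FALSE)
    X <- (X - m) / s
  } else {
    if (nrow(X) < 2L)
      stop("per_wavenumber standardization needs >= 2 spectra", call. = FALSE)
    m <- colMeans(X)
    s <- apply(X, 2L, sd)
    if (any(s == 0))
      stop("zero-variance wavenumber column(s) at ",
           paste(utils::head(set$axis[s == 0], 5L), collapse = ", "),
           call. = FALSE)
    X <- sweep(sweep(X, 2L, m), 2L, s, `/`)
  }
  spectrum_set(set$axis, X, set$meta)
}

#' Run the full preprocessing chain
#'
#' despike -> background subtraction -> phenylalanine normalization ->
#' fingerprint crop -> (optional resampling when inputs are a heterogeneous
#' list) -> standardization. The chain's output is invariant to any positive
#' rescaling of the raw intensities.
#'
#' @param x a `raman_set` or list of `raman_spectrum`
#' @param cfg a [preprocess_config()]
#' @param reference optional solvent background for `reference_subtract`
#' @param grid optional common axis for heterogeneous inputs
#' @param verbose log step summaries
#' @return a preprocessed `raman_set`
#' @export
preprocess_chain <- function(x, cfg = preprocess_config(), reference = NULL,
                             grid = NULL, verbose = FALSE) {
  specs <- if (inherits(x, "raman_set"))
    lapply(seq_len(n_spectra(x)), function(i) get_spectrum(x, i)) else x
  n0 <- length(specs)
  specs <- lapply(specs, function(s) {
    s <- remove_cosmic_rays(s, cfg)
    s <- subtract_background(s, cfg, reference)
    normalize_phenylalanine(s, cfg)
  })
  specs <- filter_fingerprint(specs, cfg)
  if (verbose)
    message(sprintf("preprocess: %d/%d spectra survive the fingerprint filter",
                    length(specs), n0))
  if (!length(specs))
    stop("no spectra left after the fingerprint filter", call. = FALSE)
  if (is.null(grid)) grid <- specs[[1L]]$wavenumbers
  set <- resample_to_grid(specs, grid)
  standardize(set, cfg)
}
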