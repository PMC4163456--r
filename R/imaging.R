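#' Integrated band intensity of one spectrum
#'
#' Trapezoidal integral of the intensity over the closed window
#' \[lo, hi\] cm^-1, with the window endpoints interpolated onto the axis
#' when they fall between grid points. Single-position bands (`lo == hi`)
#' return the (interpolated) intensity at that shift. Linear in the spectrum.
#'
#' @param s a `raman_spectrum` (preprocessed)
#' @param band length-2 numeric `c(lo, hi)`, cm^-1
#' @return scalar intensity
#' @export
band_intensity <- function(s, band) {
  lo <- band[1L]; hi <- band[2L]
  if (lo > hi) stop("band lo must be <= hi", call. = FALSE)
  wn <- s$wavenumbers
  if (lo < min(wn) || hi > max(wn))
    stop("band window outside spectrum axis", call. = FALSE)
  if (lo == hi) return(approx(wn, s$intensities, xout = lo)$y)
  inside <- wn > lo & wn < hi
  xs <- c(lo, wn[inside], hi)
  ys <- c(approx(wn, s$intensities, xout = lo)$y,
          s$intensities[inside],
          approx(wn, s$intensities, xout = hi)$y)
  sum(diff(xs) * (head(ys, -1L) + ys[-1L]) / 2)
}

#' Build a chemical map from gridded spectra
#'
#' Arranges per-node band intensities into a ny x nx image using the stage
#' coordinates (row-major: y outer, x inner; origin at the minimum
#' coordinate). Placement is by coordinates, never by row order. Coordinates
#' must form a complete rectangular grid within 1% of the step.
#'
#' @param set a `raman_set` whose metadata carries `x_um`, `y_um`
#' @param band length-2 numeric window, cm^-1 (default the 1440-1460 CH2
#'   lipid band)
#' @param mask optional ny x nx ground-truth label matrix (e.g. from
#'   [simulate_map()])
#' @return list of class `chemical_map`: nx, ny, step_um, values (ny x nx),
#'   band, mask
#' @export
build_chemical_map <- function(set, band = c(1440, 1460), mask = NULL) {
  xs <- set$meta$x_um; ys <- set$meta$y_um
  if (any(is.na(xs)) || any(is.na(ys)))
    stop("all spectra need x_um / y_um coordinates", call. = FALSE)
  # regular grid inferred from the modal coordinate step; origin at the
  # minimum coordinate
  infer_axis <- function(v) {
    u <- sort(unique(v))
    if (length(u) == 1L) return(u)
    step <- median(diff(u))
    n <- round((u[length(u)] - u[1L]) / step) + 1L
    seq(u[1L], by = step, length.out = n)
  }
  ux <- infer_axis(xs); uy <- infer_axis(ys)
  nx <- length(ux); ny <- length(uy)
  step <- if (nx > 1L) ux[2L] - ux[1L] else if (ny > 1L) uy[2L] - uy[1L] else 1
  tol <- 0.01 * step
  snap <- function(v, u) {
    i <- vapply(v, function(z) which.min(abs(u - z)), integer(1L))
    if (any(abs(v - u[i]) > tol))
      stop("coordinates not aligned to the grid", call. = FALSE)
    i
  }
  ci <- snap(xs, ux); ri <- snap(ys, uy)
  filled <- matrix(FALSE, ny, nx)
  vals <- matrix(NA_real_, ny, nx)
  for (i in seq_len(n_spectra(set))) {
    if (filled[ri[i], ci[i]])
      stop("duplicate spectra at grid node (", xs[i], ", ", ys[i], ")",
           call. = FALSE)
    vals[ri[i], ci[i]] <- band_intensity(get_spectrum(set, i), band)
    filled[ri[i], ci[i]] <- TRUE
  }
  if (!all(filled)) {
    holes <- which(!filled, arr.ind = TRUE)
    stop("missing grid nodes at (x, y) um: ",
         paste(sprintf("(%g, %g)", ux[holes[, 2L]], uy[holes[, 1L]]),
               collapse = " "), call. = FALSE)
  }
  structure(list(nx = nx, ny = ny, step_um = step, values = vals,
                 band = as.numeric(band), mask = mask,
                 x_um = ux, y_um = uy),
            class = "chemical_map")
}

#' @export
print.chemical_map <- function(x, ...) {
  cat(sprintf("<chemical_map> %d x %d pixels, step %g um, band %g-%g cm^-1\n",
              x$nx, x$ny, x$step_um, x$band[1L], x$band[2L]))
  invisible(x)
}

# Otsu threshold: maximize between-class variance over midpoints between
# consecutive sorted unique values
.otsu_threshold <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) stop("constant map: Otsu threshold undefined", call. = FALSE)
  cand <- (u[-length(u)] + u[-1L]) / 2
  n <- length(v)
  bcv <- vapply(cand, function(c) {
    lo <- v <= c
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) return(-Inf)
    w0 * (1 - w0) * (mean(v[lo]) - mean(v[!lo]))^2
  }, numeric(1L))
  cand[which.max(bcv)]
}

#' Threshold a chemical map into a binary tumor call image
#'
#' `rule = "otsu"` maximizes between-class variance of the pixel intensities;
#' `rule = "quantile"` calls exactly `ceiling(q * n)` of the brightest pixels
#' positive, ties broken deterministically by row-major pixel index. When the
#' map carries a ground-truth mask, pixel-level sensitivity and specificity
#' of the call are reported (borderline pixels are ignored).
#'
#' @param map a `chemical_map`
#' @param rule `"otsu"` or `"quantile"`
#' @param q positive fraction for the quantile rule
#' @return list of class `threshold_map`: calls (ny x nx logical), rule,
#'   threshold (otsu only), metrics ([confusion_metrics()] or NULL)
#' @export
threshold_map <- function(map, rule = c("otsu", "quantile"), q = 0.5) {
  rule <- match.arg(rule)
  v <- map$values
  if (rule == "otsu") {
    thr <- .otsu_threshold(as.numeric(v))
    calls <- v > thr
  } else {
    n <- length(v)
    k <- ceiling(q * n)
    # row-major (y outer, x inner) pixel index for deterministic ties
    rmidx <- as.numeric(matrix(seq_len(n), nrow(v), ncol(v), byrow = TRUE))
    ord <- order(-as.numeric(v), rmidx)
    calls <- matrix(FALSE, nrow(v), ncol(v))
    calls[ord[seq_len(k)]] <- TRUE
    thr <- NA_real_
  }
  metrics <- NULL
  if (!is.null(map$mask)) {
    use <- map$mask %in% c("tumor", "normal")
    truth <- map$mask[use] == "tumor"
    called <- calls[use]
    metrics <- confusion_metrics(tp = sum(truth & called),
                                 fn = sum(truth & !called),
                                 tn = sum(!truth & !called),
                                 fp = sum(!truth & called))
  }
  structure(list(calls = calls, rule = rule, threshold = thr,
                 metrics = metrics), class = "threshold_map")
}
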