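#' Band components for the synthetic spectrum generator
#'
#' One pseudo-Voigt component per default band-table row: range bands sit at
#' the window midpoint with FWHM spanning the window, single-position bands
#' get the default 15 cm^-1 FWHM. All bands except the phenylalanine 1004
#' reference carry a multiplicative `tumor_effect` (> 1 means elevated in
#' tumor), mirroring the observation that protein, lipid and nucleic-acid
#' bands run higher in glioma cells than in normal astrocytes.
#'
#' @param tumor_effect multiplicative tumor elevation applied to every band
#'   except the 1004 cm^-1 normalization reference
#' @param default_fwhm FWHM (cm^-1) for single-position bands
#' @param shape `"pseudo_voigt"`, `"gaussian"` or `"lorentzian"`
#' @param eta pseudo-Voigt Lorentzian fraction in \[0, 1\]
#' @return data.frame with columns center, width (FWHM, cm^-1),
#'   amplitude_normal, tumor_effect, shape, eta
#' @export
default_band_components <- function(tumor_effect = 2, default_fwhm = 15,
                                    shape = "pseudo_voigt", eta = 0.5) {
  bt <- default_band_table()
  width <- pmax(bt$hi - bt$lo, default_fwhm)
  eff <- ifelse(bt$lo == 1004 & bt$hi == 1004, 1, tumor_effect)
  band_components(center = (bt$lo + bt$hi) / 2, width = width,
                  amplitude_normal = 1, tumor_effect = eff,
                  shape = shape, eta = eta)
}

#' @rdname default_band_components
#' @param center band centers, cm^-1
#' @param width FWHM, cm^-1, > 0
#' @param amplitude_normal peak height in the normal class, >= 0
#' @export
band_components <- function(center, width, amplitude_normal = 1,
                            tumor_effect = 1, shape = "pseudo_voigt",
                            eta = 0.5) {
  df <- data.frame(center = as.numeric(center), width = as.numeric(width),
                   amplitude_normal = amplitude_normal,
                   tumor_effect = as.numeric(tumor_effect),
                   shape = shape, eta = eta, stringsAsFactors = FALSE)
  if (any(df$width <= 0)) stop("band width must be > 0", call. = FALSE)
  if (any(df$amplitude_normal < 0)) stop("amplitude_normal must be >= 0", call. = FALSE)
  if (any(df$tumor_effect < 0)) stop("tumor_effect must be >= 0", call. = FALSE)
  if (any(!df$shape %in% c("gaussian", "lorentzian", "pseudo_voigt")))
    stop("unknown band shape", call. = FALSE)
  df
}

#' Generator configuration
#'
#' The stated world of the synthetic experiments: pseudo-Voigt bands on a
#' 580-1800 cm^-1 axis, a positive quadratic autofluorescence baseline
#' (approximately 5x the unit peak height at 580 cm^-1), additive Gaussian
#' noise, Poisson-count cosmic-ray spikes, and lognormal per-sample amplitude
#' jitter that induces the within-cell / within-mouse correlation that
#' leave-group-out cross-validation exists to respect.
#'
#' @param bands data.frame from [band_components()]
#' @param baseline_coeffs polynomial coefficients in u = wavenumber / 1000
#'   (constant, linear, quadratic, ...); all zero disables the baseline
#' @param noise_sd additive Gaussian noise sd, a.u.
#' @param cosmic_rate expected cosmic-ray spikes per spectrum (Poisson)
#' @param cosmic_amplitude spike height as a multiple of `noise_sd`
#' @param group_sd sd of per-sample log-amplitude jitter
#' @param attenuation tissue-heterogeneity factor in (0, 1\]: the
#'   tumor-minus-normal amplitude gap is scaled by this factor (1 = cell-like)
#' @param axis_step wavenumber step, cm^-1
#' @param axis_lo,axis_hi axis range, cm^-1
#' @param seed integer RNG seed used by the experiment-level generators
#' @return list of class `generative_config`
#' @export
generative_config <- function(bands = default_band_components(),
                              baseline_coeffs = c(3.5, 1.5, 2.0),
                              noise_sd = 0.05, cosmic_rate = 0.05,
                              cosmic_amplitude = 30, group_sd = 0.1,
                              attenuation = 1, axis_step = 1,
                              axis_lo = 580, axis_hi = 1800, seed = 1L) {
  if (noise_sd < 0 || cosmic_rate < 0 || group_sd < 0)
    stop("noise_sd, cosmic_rate and group_sd must be >= 0", call. = FALSE)
  if (attenuation <= 0 || attenuation > 1)
    stop("attenuation must lie in (0, 1]", call. = FALSE)
  structure(list(bands = bands, baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd, cosmic_rate = cosmic_rate,
                 cosmic_amplitude = cosmic_amplitude, group_sd = group_sd,
                 attenuation = attenuation, axis_step = axis_step,
                 axis_lo = axis_lo, axis_hi = axis_hi,
                 seed = as.integer(seed)),
            class = "generative_config")
}

sim_axis <- function(cfg) seq(cfg$axis_lo, cfg$axis_hi, by = cfg$axis_step)

# unit-height line shapes
.peak_shape <- function(axis, center, fwhm, shape, eta) {
  g <- exp(-4 * log(2) * (axis - center)^2 / fwhm^2)
  if (shape == "gaussian") return(g)
  l <- 1 / (1 + 4 * (axis - center)^2 / fwhm^2)
  if (shape == "lorentzian") return(l)
  eta * l + (1 - eta) * g
}

# class-dependent amplitude multiplier for one band; attenuation scales the
# tumor-minus-normal gap linearly; borderline = geometric mean of the two
.class_factor <- function(effect, class, attenuation) {
  tf <- 1 + attenuation * (effect - 1)
  switch(class, normal = 1, tumor = tf, borderline = sqrt(tf),
         stop("unknown class: ", class, call. = FALSE))
}

# deterministic band sum for one class (no baseline, noise, jitter)
.band_sum <- function(axis, cfg, class, sample_effect = 0) {
  out <- numeric(length(axis))
  b <- cfg$bands
  for (k in seq_len(nrow(b))) {
    amp <- b$amplitude_normal[k] *
      .class_factor(b$tumor_effect[k], class, cfg$attenuation) *
      exp(sample_effect)
    out <- out + amp * .peak_shape(axis, b$center[k], b$width[k],
                                   b$shape[k], b$eta[k])
  }
  out
}

.baseline_eval <- function(axis, coeffs) {
  u <- axis / 1000
  drop(outer(u, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

#' Simulate one spectrum
#'
#' Intensity model: sum of class-scaled pseudo-Voigt bands, plus the
#' polynomial baseline, plus Poisson-count single-channel cosmic spikes, plus
#' iid Gaussian noise. Borderline spectra use the square root of the tumor
#' amplitude factor (geometric mean of the two classes). Uses the ambient RNG
#' stream; seed at the experiment level (or with `set.seed`) for determinism.
#'
#' @param class `"tumor"`, `"normal"` or `"borderline"`
#' @param cfg a [generative_config()]
#' @param sample_effect per-sample log-amplitude offset
#' @param meta a [spectrum_meta()] for the result
#' @return a [raman_spectrum()]
#' @export
simulate_spectrum <- function(class, cfg = generative_config(),
                              sample_effect = 0, meta = spectrum_meta(label = class)) {
  if (!class %in% c("tumor", "normal", "borderline"))
    stop("unknown class: ", class, call. = FALSE)
  axis <- sim_axis(cfg)
  y <- .band_sum(axis, cfg, class, sample_effect) +
    .baseline_eval(axis, cfg$baseline_coeffs)
  if (cfg$cosmic_rate > 0) {
    nsp <- rpois(1L, cfg$cosmic_rate)
    if (nsp > 0L) {
      pos <- sample.int(length(axis), nsp, replace = TRUE)
      y[pos] <- y[pos] + cfg$cosmic_amplitude * cfg$noise_sd
    }
  }
  if (cfg$noise_sd > 0) y <- y + rnorm(length(axis), 0, cfg$noise_sd)
  meta$label <- class
  raman_spectrum(axis, y, meta)
}

#' Experiment designs
#'
#' `cell_design()` mirrors the cell study: 58 tumor spectra over 4 glioma
#' cells (15/15/14/14) and 40 normal spectra over 2 astrocytes (20/20).
#' `tissue_design()` mirrors the tissue study: 123 spectra over 6 mouse
#' brains, each mouse contributing a tumor/normal/borderline mix.
#'
#' @return data.frame with columns sample_id, class, n_spectra
#' @export
cell_design <- function() {
  data.frame(
    sample_id = c("glioma1", "glioma2", "glioma3", "glioma4", "astro1", "astro2"),
    class = c(rep("tumor", 4L), rep("normal", 2L)),
    n_spectra = c(15L, 15L, 14L, 14L, 20L, 20L),
    stringsAsFactors = FALSE)
}

#' @rdname cell_design
#' @export
tissue_design <- function() {
  per_mouse <- list(c(9L, 9L, 3L), c(9L, 9L, 3L), c(9L, 9L, 3L),
                    c(9L, 8L, 3L), c(9L, 8L, 3L), c(9L, 8L, 3L))
  rows <- lapply(seq_along(per_mouse), function(m) {
    n <- per_mouse[[m]]
    data.frame(sample_id = sprintf("mouse%d", m),
               class = c("tumor", "normal", "borderline"),
               n_spectra = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.simulate_design <- function(design, cfg, id_prefix) {
  if (any(design$n_spectra < 1L))
    stop("each design row needs n_spectra >= 1", call. = FALSE)
  set.seed(cfg$seed)
  samples <- unique(design$sample_id)
  eff <- setNames(rnorm(length(samples), 0, cfg$group_sd), samples)
  specs <- list(); k <- 0L
  for (r in seq_len(nrow(design))) {
    for (j in seq_len(design$n_spectra[r])) {
      k <- k + 1L
      m <- spectrum_meta(sprintf("%s%04d", id_prefix, k),
                         design$sample_id[r], design$class[r])
      specs[[k]] <- simulate_spectrum(design$class[r], cfg,
                                      eff[[design$sample_id[r]]], m)
    }
  }
  bind_spectra(specs)
}

#' Simulate grouped cell / tissue experiments
#'
#' One log-amplitude effect per sample (cell or mouse) is drawn from
#' Normal(0, group_sd^2) and shared by all of that sample's spectra. The
#' tissue generator additionally attenuates the tumor-normal amplitude gap
#' (default factor 0.5) to emulate the more heterogeneous composition of a
#' tissue spot compared with a single cell.
#'
#' @param design data.frame (sample_id, class, n_spectra); defaults
#'   [cell_design()] / [tissue_design()]
#' @param cfg a [generative_config()]; its `seed` drives all randomness
#' @param attenuation tissue gap attenuation in (0, 1\]
#' @return a [spectrum_set()]
#' @export
simulate_cell_experiment <- function(design = cell_design(),
                                     cfg = generative_config()) {
  .simulate_design(design, cfg, "cell")
}

#' @rdname simulate_cell_experiment
#' @export
simulate_tissue_experiment <- function(design = tissue_design(),
                                       cfg = generative_config(),
                                       attenuation = 0.5) {
  if (attenuation <= 0 || attenuation > 1)
    stop("attenuation must lie in (0, 1]", call. = FALSE)
  cfg$attenuation <- attenuation
  .simulate_design(design, cfg, "tissue")
}

#' Simulate a mapped acquisition over a rectangular stage grid
#'
#' One spectrum per node at (i * step, j * step), i = 0..nx-1, j = 0..ny-1.
#' Nodes inside the elliptical region are tumor, nodes in a border ring
#' (ellipse scaled by `1 + border_frac`) are borderline, the rest normal.
#' The default grid reproduces the 12 x 22, 300-um-step mapping design
#' (264 spectra).
#'
#' @param nx,ny grid dimensions (columns = x, rows = y), >= 1
#' @param step_um stage step, micrometers
#' @param region `list(cx, cy, rx, ry)` ellipse in um, or `NULL` for none
#' @param cfg a [generative_config()]
#' @param border_frac relative width of the borderline ring
#' @return `list(set = raman_set with x_um/y_um, mask = ny x nx character
#'   matrix of ground-truth labels)`
#' @export
simulate_map <- function(nx = 12L, ny = 22L, step_um = 300,
                         region = list(cx = 1650, cy = 2100, rx = 900, ry = 1500),
                         cfg = generative_config(), border_frac = 0.25) {
  stopifnot(nx >= 1L, ny >= 1L, step_um > 0)
  if (!is.null(region) && (region$rx <= 0 || region$ry <= 0))
    stop("degenerate ellipse: rx and ry must be > 0", call. = FALSE)
  set.seed(cfg$seed)
  eff <- rnorm(1L, 0, cfg$group_sd)   # a map comes from one tissue slice
  mask <- matrix("normal", nrow = ny, ncol = nx)
  specs <- vector("list", nx * ny); k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      x <- (i - 1L) * step_um; y <- (j - 1L) * step_um
      cls <- "normal"
      if (!is.null(region)) {
        e <- ((x - region$cx) / region$rx)^2 + ((y - region$cy) / region$ry)^2
        if (e <= 1) cls <- "tumor"
        else if (e <= (1 + border_frac)^2) cls <- "borderline"
      }
      mask[j, i] <- cls
      k <- k + 1L
      m <- spectrum_meta(sprintf("px%03d", k), "map", cls, x_um = x, y_um = y)
      specs[[k]] <- simulate_spectrum(cls, cfg, eff, m)
    }
  }
  list(set = bind_spectra(specs), mask = mask)
}
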