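# despiking, baseline subtraction, normalization, cropping, standardization

test_that("despiking restores spike-injected spectra and leaves clean ones alone", {
  cfg <- generative_config(cosmic_rate = 0, seed = 2, group_sd = 0)
  set.seed(2)
  clean <- simulate_spectrum("normal", cfg)
  nsd <- cfg$noise_sd

  spiked <- clean
  spiked$intensities[400] <- spiked$intensities[400] + 50 * nsd
  out <- remove_cosmic_rays(spiked)
  expect_lt(max(abs(out$intensities - clean$intensities)), 3 * nsd)

  # two spikes far apart are removed independently
  spiked2 <- clean
  spiked2$intensities[c(300, 500)] <- spiked2$intensities[c(300, 500)] + 50 * nsd
  out2 <- remove_cosmic_rays(spiked2)
  expect_lt(max(abs(out2$intensities - clean$intensities)), 3 * nsd)

  # spike-free: a noiseless linear ramp passes through untouched
  ramp <- raman_spectrum(580:780, seq(1, 3, length.out = 201))
  expect_identical(remove_cosmic_rays(ramp)$intensities, ramp$intensities)
  # and a realistic noisy spectrum is not altered at default settings
  expect_identical(remove_cosmic_rays(clean)$intensities, clean$intensities)
})

test_that("despiking is idempotent and touches < 2% of channels on generator output", {
  cfg <- generative_config(seed = 4)
  set.seed(4)
  s <- simulate_spectrum("tumor", cfg)
  once <- remove_cosmic_rays(s)
  twice <- remove_cosmic_rays(once)
  expect_identical(once$intensities, twice$intensities)
  expect_lt(mean(once$intensities != s$intensities), 0.02)
})

test_that("iterative polynomial baseline: exact-fit limit and recovery under peaks", {
  cfg <- preprocess_config(baseline_mode = "iterative_poly", poly_order = 5)
  wn <- seq(580, 1800, by = 2)
  u <- wn / 1000
  base <- 3.5 + 1.5 * u + 2 * u^2

  pure <- raman_spectrum(wn, base)
  out <- subtract_background(pure, cfg)
  expect_lt(max(abs(out$intensities)) / max(abs(base)), 1e-6)

  gcfg <- noiseless_cfg(baseline_coeffs = c(3.5, 1.5, 2.0), axis_step = 2)
  s <- simulate_spectrum("normal", gcfg)
  peak_free <- wn < 900 | wn > 1560

  # ALS recovers the quadratic baseline within 5% in peak-free regions
  als <- preprocess_config(baseline_mode = "als")
  rec_als <- s$intensities - subtract_background(s, als)$intensities
  expect_lt(max(abs(rec_als[peak_free] - base[peak_free]) / base[peak_free]),
            0.05)
  # order-5 modified polyfit carries a known structural sag (~10%) where the
  # polynomial must duck under 400 cm^-1 of contiguous band mass; the bias is
  # class-independent and removed by normalization, but bound it honestly here
  rec_mp <- s$intensities - subtract_background(s, cfg)$intensities
  expect_lt(max(abs(rec_mp[peak_free] - base[peak_free]) / base[peak_free]),
            0.15)
})

test_that("reference subtraction and ALS behave at their fixed points", {
  wn <- seq(580, 1800, by = 4)
  set.seed(8)
  y <- 5 + 0.01 * wn + rnorm(length(wn), 0, 0.01)
  s <- raman_spectrum(wn, y)
  cfg <- preprocess_config(baseline_mode = "reference_subtract")
  out <- subtract_background(s, cfg, reference = s)
  expect_equal(out$intensities, rep(0, length(wn)))
  other <- raman_spectrum(wn + 1, y)
  expect_error(subtract_background(s, cfg, reference = other), "axis")
  expect_error(subtract_background(s, cfg), "reference")

  # ALS hugs a smooth lower envelope: residual small for a peakless input
  als <- preprocess_config(baseline_mode = "als")
  outa <- subtract_background(s, als)
  expect_lt(max(abs(outa$intensities)), 0.2)
})

test_that("phenylalanine normalization fixes the window maximum at 1", {
  cfg <- noiseless_cfg()
  s <- simulate_spectrum("tumor", cfg)
  pcfg <- preprocess_config()
  n1 <- normalize_phenylalanine(s, pcfg)
  win <- n1$wavenumbers >= 999 & n1$wavenumbers <= 1009
  expect_identical(max(n1$intensities[win]), 1)

  s2 <- s; s2$intensities <- 3.7 * s$intensities
  n2 <- normalize_phenylalanine(s2, pcfg)
  expect_lt(max(abs(n1$intensities - n2$intensities)), 1e-12)

  neg <- raman_spectrum(s$wavenumbers, -abs(s$intensities))
  expect_error(normalize_phenylalanine(neg, pcfg), "maximum <= 0")
})

test_that("fingerprint filter drops non-covering spectra and crops survivors", {
  mk <- function(lo, hi, id) {
    wn <- seq(lo, hi, by = 5)
    raman_spectrum(wn, rep(1, length(wn)) + wn / 1e4,
                   spectrum_meta(id, "s", "unknown"))
  }
  specs <- list(mk(500, 1900, "wide"), mk(600, 1800, "short_lo"),
                mk(580, 1800, "exact"), mk(580, 1700, "short_hi"),
                mk(575, 1805, "cover"))
  kept <- filter_fingerprint(specs)
  expect_equal(vapply(kept, function(s) s$meta$spectrum_id, ""),
               c("wide", "exact", "cover"))
  for (s in kept) {
    expect_gte(min(s$wavenumbers), 580)
    expect_lte(max(s$wavenumbers), 1800)
  }
  exact <- kept[[2]]
  expect_equal(range(exact$wavenumbers), c(580, 1800))   # boundary inclusive
  expect_warning(filter_fingerprint(list(mk(600, 1800, "x"))), "dropped")
})

test_that("resampling is exact on lines and stable on round trips", {
  wn <- seq(580, 1800, by = 1)
  ramp <- raman_spectrum(wn, 2 * wn + 1)
  sub <- seq(600, 1700, by = 3.5)
  rs <- resample_to_grid(list(ramp), sub)
  expect_equal(as.numeric(rs$intensities), 2 * sub + 1, tolerance = 1e-12)

  s <- simulate_spectrum("tumor", noiseless_cfg())
  same <- resample_to_grid(list(s), s$wavenumbers)
  expect_identical(as.numeric(same$intensities), s$intensities)

  fine <- seq(580, 1800, by = 0.5)
  rt <- resample_to_grid(resample_to_grid(list(s), fine), wn)
  peak <- max(s$intensities)
  expect_lt(max(abs(as.numeric(rt$intensities) - s$intensities)), 0.01 * peak)

  expect_error(resample_to_grid(list(s), seq(500, 1800, 1)), "span")
})

test_that("standardization meets its definitional contracts", {
  set.seed(3)
  set <- spectrum_set(1:10 * 100 + 400, matrix(rnorm(50), 5),
                      data.frame(spectrum_id = paste0("s", 1:5),
                                 sample_id = "a", label = "unknown"))
  snv <- standardize(set, preprocess_config(standardize_mode = "per_spectrum"))
  expect_lt(max(abs(rowMeans(snv$intensities))), 1e-12)
  expect_lt(max(abs(apply(snv$intensities, 1, sd) - 1)), 1e-12)

  auto <- standardize(set, preprocess_config(standardize_mode = "per_wavenumber"))
  expect_lt(max(abs(colMeans(auto$intensities))), 1e-12)
  expect_lt(max(abs(apply(auto$intensities, 2, sd) - 1)), 1e-12)

  const <- set
  const$intensities[2, ] <- 7
  expect_error(standardize(const, preprocess_config()), "s2")
})

test_that("the full chain is invariant to positive rescaling of raw input", {
  cfg <- generative_config(seed = 6)
  set.seed(6)
  set <- simulate_cell_experiment(
    design = data.frame(sample_id = c("a", "b"), class = c("tumor", "normal"),
                        n_spectra = c(3L, 3L)), cfg = cfg)
  scaled <- spectrum_set(set$axis, set$intensities * 123.4, set$meta)
  p1 <- preprocess_chain(set)
  p2 <- preprocess_chain(scaled)
  expect_lt(max(abs(p1$intensities - p2$intensities)), 1e-8)
})
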