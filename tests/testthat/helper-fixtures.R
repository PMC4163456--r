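# shared fixtures: small, fast generator configurations

# deterministic band sum only: no baseline, no noise, no spikes, no jitter
# (individual components can be switched back on by name)
noiseless_cfg <- function(..., baseline_coeffs = 0, noise_sd = 0,
                          cosmic_rate = 0, group_sd = 0, seed = 1L) {
  generative_config(baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
                    cosmic_rate = cosmic_rate, group_sd = group_sd,
                    seed = seed, ...)
}

# coarse axis (step 4 cm^-1 -> 306 points) for anything that loops
coarse_cfg <- function(..., seed = 1L) {
  generative_config(axis_step = 4, seed = seed, ...)
}

# a generator whose tumor effect is confined to one window
one_band_effect_cfg <- function(lo, hi, effect = 2, ..., seed = 1L) {
  bc <- default_band_components(tumor_effect = 1)
  hit <- bc$center >= lo & bc$center <= hi
  bc$tumor_effect[hit] <- effect
  generative_config(bands = bc, seed = seed, ...)
}

# quick preprocessed cell set for downstream modules
quick_cell_set <- function(seed = 1L, cfg = coarse_cfg(seed = seed),
                           design = cell_design()) {
  preprocess_chain(simulate_cell_experiment(design, cfg))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
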