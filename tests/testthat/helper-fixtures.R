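# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

zero_noise_design <- function(seed = 42L) {
  sg_design(sigma = 0, decoys_per_scan = 0, decoy_features = 0, seed = seed)
}

# zero-noise synthetic dataset: library, spectra, feature table
fixture_zero_noise <- function() {
  if (is.null(.fixture_env$zn)) {
    d <- zero_noise_design()
    lib <- build_compound_library(d)
    .fixture_env$zn <- list(design = d, library = lib,
                            spectra = simulate_spectra(lib, d),
                            features = simulate_feature_table(lib, d))
  }
  .fixture_env$zn
}

# scan constructor for census tests
make_scan <- function(mz, sample = "s1", rt = 5, intensity = NULL) {
  list(sample = sample, scan_id = paste0(sample, "_scan"), rt = rt,
       mz = mz,
       intensity = if (is.null(intensity)) rep(100, length(mz)) else intensity)
}

# EIC-like object from raw intensities
make_eic <- function(intensity, rt = seq_along(intensity)) {
  structure(data.frame(rt = rt, intensity = intensity),
            class = c("eic", "data.frame"))
}
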