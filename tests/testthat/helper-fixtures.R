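# Shared fixtures: small phantoms are cached so several test files can
# reuse one generation.  All fixtures are built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

test_axis <- function(step = 8) seq(600, 3600, by = step)

# noiseless, baseline-free separated-component phantom (identifiable)
clean_phantom <- function() cached("clean", make_phantom(
  "native", n_rows = 40L, n_cols = 12L, wavenumber = test_axis(),
  profiles = separated_profiles(), baseline_level = 0, noise_level = 0,
  seed = 101L))

# realistic native phantom (baseline + 2 % noise, default gradients)
noisy_phantom <- function() cached("noisy", make_phantom(
  "native", n_rows = 40L, n_cols = 12L, wavenumber = test_axis(),
  seed = 102L))

# reference spectra restricted to the fingerprint range of a truth object
truth_refs <- function(truth, lo = 800, hi = 1800) {
  sel <- truth$wavenumber >= lo & truth$wavenumber <= hi
  component_spectra(truth$spectra[, sel, drop = FALSE],
                    truth$wavenumber[sel])
}

# best spectral match of each reference constituent in an mcr_fit
match_to_truth <- function(fit, truth) {
  match_references(fit$S, truth_refs(truth))
}
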