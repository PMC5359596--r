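# Shared fixtures: all synthetic, generated in code at test time.

# A drug whose conductance fold at conc = ec50 is exactly `fold`
# (Hill midpoint: 1 + (g_max - 1)/2).
drug_with_exact_fold <- function(fold, rectification = 1) {
  drug_model(ec50 = 1e-6, hill = 1, g_max_fold = 2 * fold - 1,
             rectification = rectification)
}

# Noiseless, bleach-free, unshifted simulation parameters (closed-form
# frames) on a smaller frame for speed.
noiseless_params <- function(...) {
  args <- utils::modifyList(
    list(noise = FALSE, bleach_fraction = 0, shift_max = 0,
         frame_dim = c(128, 128), n_cells = 3, radius_range = c(18, 24)),
    list(...))
  do.call(sim_params, args)
}

# Default-noise parameters on the standard frame.
noisy_params <- function(...) sim_params(...)

# One simulated area at an exact conductance fold.
simulate_area_fold <- function(fold, sim = noiseless_params(), seed = 11,
                               shift = c(0, 0), rectification = 1, ...) {
  drug <- drug_with_exact_fold(fold, rectification)
  cells <- withr::with_seed(seed, place_cells(sim))
  simulate_passage_pair(cells, drug, conc = drug$ec50, sim = sim,
                        shift = shift, ...)
}

# Dilution series centered on 1 uM, half-decade steps (8 points).
default_series <- function() 10^seq(-8, -4.5, by = 0.5)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}
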