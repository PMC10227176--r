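# Shared fixtures: small kernels, landscapes and configs used across tests.

fig3a_kernel <- function() dispersal_kernel(d05 = 60, d30 = 700)

# kernel with a flat sigmoid at lambda = 0.5 (both medians = 1 cell),
# handy because deposition weights become powers of 1/2
half_kernel <- function() dispersal_kernel(d05 = 1, d30 = 1)

tiny_stoch_params <- function(...) {
  defaults <- list(n_tot = 200, g = 0.3, c1 = 1e-4, mu = 0.001, n_gens = 20,
                   s_init = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(stoch_params, args)
}

# independent brute-force habitability oracle: expand the repeating
# [habitat run | matrix run] pattern cell by cell
pattern_oracle <- function(x_h, x_ipd, n_cells) {
  rep(rep(c(TRUE, FALSE), times = c(x_h, x_ipd)), length.out = n_cells)
}
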