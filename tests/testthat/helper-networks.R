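# Shared fixtures: kept as functions so each test builds fresh objects.

toy_split_truth <- function(r2 = 3, upt = 10, iso = 2) {
  toy <- toy_split()
  basis <- build_flux_basis(toy)
  list(model = toy, basis = basis,
       flux = realize_fluxes(basis, free_net = c(r2 = r2),
                             fixed = c(upt = upt), exchange = c(iso = iso)))
}

toy_split_mixture <- function() {
  tracer_mixture(list(c(1, 0, 0), c(1, 1, 1)), c(0.5, 0.5))
}

toy_split_scenario <- function(seed, mid_sd = 0.025, r2 = 3) {
  tw <- toy_split_truth(r2 = r2)
  synthetic_scenario(tw$model, tw$flux, mu = 0, tracer = toy_split_mixture(),
                     panel = c("A", "D", "E", "F"), mid_sd = mid_sd,
                     rate_sd = c(upt = 0.1), seed = seed)
}

# fast fit settings for toy problems
fit_toy <- function(ds, model, n_starts = 3, seed = 1) {
  fit_fluxes(ds, model, mu = 0, uptakes = c(upt = 10), n_starts = n_starts,
             seed = seed, nm_iter = 60, n_jitter = 2)
}

expect_mid_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = tol)
}
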