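test_that("the SSR vanishes on noise-free data at the true parameters", {
  sc <- toy_split_scenario(seed = 5, mid_sd = 0)
  ds <- simulate_dataset(sc)
  ctx <- fit_context(sc$model, ds, mu = 0, uptake_free = c(upt = 10))
  th <- emuflux:::flux_to_theta(ctx, sc$flux)
  expect_lt(weighted_ssr(th, ctx), 1e-18)
})

test_that("a single rate residual contributes (r/sd)^2", {
  sc <- toy_split_scenario(seed = 5, mid_sd = 0)
  ds <- simulate_dataset(sc)
  ds$rates$value <- ds$rates$value + 0.25   # shift the upt measurement
  ctx <- fit_context(sc$model, ds, mu = 0, uptake_free = c(upt = 10))
  th <- emuflux:::flux_to_theta(ctx, sc$flux)
  expect_equal(weighted_ssr(th, ctx), (0.25 / 0.1)^2, tolerance = 1e-8)
})

test_that("chi-square acceptance threshold matches independent integration", {
  expect_equal(chi2_acceptance(100, 10, alpha = 1), 0)
  expect_error(chi2_acceptance(10, 10), "degrees of freedom")
  # independent oracle: integrate the chi-square density for dof = 115 and
  # invert for the 95% point
  dof <- 115
  dens <- function(t) t^(dof / 2 - 1) * exp(-t / 2) /
    (2^(dof / 2) * gamma(dof / 2))
  cdf <- function(x) integrate(dens, 0, x, rel.tol = 1e-10)$value
  q95 <- uniroot(function(x) cdf(x) - 0.95, c(100, 200), tol = 1e-8)$root
  expect_equal(chi2_acceptance(170, 55), q95, tolerance = 1e-6)
  expect_equal(round(chi2_acceptance(170, 55), 1), 141.0)
  # strictly increasing in dof
  th <- vapply(50:60, function(d) chi2_acceptance(d + 55, 55), 0)
  expect_true(all(diff(th) > 0))
})

test_that("noise-free toy data recover the true net flux", {
  sc <- toy_split_scenario(seed = 7, mid_sd = 0)
  ds <- simulate_dataset(sc)
  fit <- fit_toy(ds, sc$model, n_starts = 3, seed = 2)
  expect_lt(fit$ssr, 1e-10)
  expect_equal(fit$flux$net[["r2"]], 3, tolerance = 1e-3)
})

test_that("the best SSR is monotone in the number of starts", {
  sc <- toy_split_scenario(seed = 9, mid_sd = 0.025)
  ds <- simulate_dataset(sc)
  f1 <- fit_toy(ds, sc$model, n_starts = 1, seed = 11)
  f3 <- fit_toy(ds, sc$model, n_starts = 3, seed = 11)
  expect_equal(f3$trace$ssr[1], f1$trace$ssr[1], tolerance = 1e-9)
  expect_lte(min(f3$trace$ssr), min(f1$trace$ssr))
})

test_that("fits are deterministic given the seed", {
  sc <- toy_split_scenario(seed = 13, mid_sd = 0.025)
  ds <- simulate_dataset(sc)
  f1 <- fit_toy(ds, sc$model, n_starts = 2, seed = 4)
  f2 <- fit_toy(ds, sc$model, n_starts = 2, seed = 4)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$trace, f2$trace)
})

test_that("profile intervals flag a structurally undetermined cycle flux", {
  cyc <- toy_cycle()
  basis <- build_flux_basis(cyc)
  truth <- realize_fluxes(basis, free_net = c(f2 = 2), fixed = c(upt = 5))
  sc <- synthetic_scenario(cyc, truth, mu = 0,
                           tracer = tracer_mixture(list(c(1, 0), c(1, 1)),
                                                   c(0.5, 0.5)),
                           panel = c("A", "B"), mid_sd = 0.02,
                           rate_sd = c(upt = 0.1), seed = 3)
  ds <- simulate_dataset(sc)
  fit <- fit_toy(ds, cyc, n_starts = 2, seed = 1)
  ci <- confidence_intervals(fit, params = "f2", max_expand = 1.5)
  expect_true(ci$non_identifiable)
  expect_equal(ci$upper, Inf)
})

test_that("profile and linearized intervals agree on a near-linear problem", {
  sc <- toy_split_scenario(seed = 21, mid_sd = 0.01)
  ds <- simulate_dataset(sc)
  fit <- fit_toy(ds, sc$model, n_starts = 2, seed = 8)
  pr <- confidence_intervals(fit, params = "r2", mode = "profile")
  expect_false(pr$non_identifiable)
  li <- suppressWarnings(
    confidence_intervals(fit, params = "r2", mode = "linearized"))
  wp <- pr$upper - pr$lower
  wl <- li$upper - li$lower
  expect_lt(abs(wp - wl) / wp, 0.35)
  # interval covers the truth at this noise level
  expect_gt(3, pr$lower); expect_lt(3, pr$upper)
})

test_that("gradient vanishes at the optimum (first-order condition)", {
  sc <- toy_split_scenario(seed = 30, mid_sd = 0.02)
  ds <- simulate_dataset(sc)
  fit <- fit_toy(ds, sc$model, n_starts = 2, seed = 2)
  ctx <- fit$ctx
  th <- fit$theta
  h <- 1e-5
  g <- vapply(seq_along(th), function(j) {
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- max(tm[j] - h, 0)
    (weighted_ssr(tp, ctx) - weighted_ssr(tm, ctx)) / (tp[j] - tm[j])
  }, 0)
  # one-sided derivatives at active bounds may be positive; interior
  # coordinates must be stationary
  interior <- th > 1e-6 & th < 0.99
  expect_lt(max(abs(g[interior])), 0.05)
})

test_that("flux normalization reports percentages and round-trips", {
  tw <- toy_split_truth()
  map <- normalize_map(tw$flux, reference = "upt")
  expect_equal(map$percent[map$reaction == "upt"], 100)
  expect_equal(map$percent[map$reaction == "r2"], 30)
  back <- denormalize_map(map, 10)
  expect_equal(back[names(tw$flux$net)], tw$flux$net, tolerance = 1e-9)
  expect_error(normalize_map(c(a = 0), reference = "a"), "zero")
  # signs are preserved for reverse net fluxes
  map2 <- normalize_map(c(upt = 10, rev = -2), reference = "upt")
  expect_equal(map2$percent[map2$reaction == "rev"], -20)
})

test_that("NADPH accounting reproduces the printed percentages", {
  nb <- nadph_balance(c(gnd = 31.6, icd = 58.3, mez = 0), mu = 0.41,
                      nadph_coefficient = 14849, v_glc = 4086)
  expect_equal(nb$production, 121.5, tolerance = 1e-12)
  expect_equal(nb$requirement, 149.0, tolerance = 0.01)
  expect_equal(nb$gap, 27.5, tolerance = 0.01)
  z <- nadph_balance(c(gnd = 0, icd = 0, mez = 0), 0.41, 14849, 4086)
  expect_equal(z$production, 0)
  expect_equal(z$gap, z$requirement)
})

test_that("NADPH production equals the model's annotated source sum", {
  net <- cg_network()
  basis <- build_flux_basis(net)
  fs <- cg_preset_flux(basis)
  map <- normalize_map(fs)
  pm <- setNames(map$percent, map$reaction)
  from_annotation <- sum(vapply(names(net$nadph_sources), function(r) {
    net$nadph_sources[[r]] * pm[[r]]
  }, 0))
  nb <- nadph_balance(map, 0.41, net$nadph_coefficient, 4086)
  expect_equal(nb$production, from_annotation, tolerance = 1e-9)
})

test_that("carbon accounting closes and converts to molar CO2 yield", {
  net <- cg_network()
  basis <- build_flux_basis(net)
  fs <- cg_preset_flux(basis)
  cb <- carbon_balance(net, fs)
  expect_equal(cb$biomass_percent + cb$co2_percent, 100, tolerance = 1e-9)
  expect_equal(cb$co2_per_glucose,
               6 * cb$co2_percent / 100 * cb$carbon_in / (6 * fs$net[["glc_upt"]]),
               tolerance = 1e-9)
})

test_that("preset flux map matches the reported central flux split", {
  net <- cg_network()
  basis <- build_flux_basis(net)
  fs <- cg_preset_flux(basis)
  pm <- setNames(normalize_map(fs)$percent, names(fs$net))
  expect_equal(pm[["pgi"]], 66.4, tolerance = 0.002)   # 66.4 +- 7.6 reported
  expect_equal(pm[["gnd"]], 31.6, tolerance = 0.001)   # 31.6 +- 7.6
  expect_equal(pm[["icd"]], 58.3, tolerance = 0.01)    # 58.3 +- 4.2
  expect_lt(abs(pm[["pca_upt"]] - 0.3), 0.05)          # prints as 0.3
  expect_equal(pm[["pyc"]], 31.3, tolerance = 0.15)    # "31.3% via pyc"
  cb <- carbon_balance(net, fs)
  expect_equal(cb$biomass_percent, 65.6, tolerance = 0.002)
  expect_equal(cb$co2_percent, 34.4, tolerance = 0.003)
  expect_equal(cb$co2_per_glucose, 2.06, tolerance = 0.01)
})
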