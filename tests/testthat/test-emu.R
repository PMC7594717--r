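test_that("convolution behaves as a Cauchy product", {
  expect_mid_equal(mid_convolve(c(1, 0), c(0.3, 0.7)), c(0.3, 0.7, 0))
  expect_mid_equal(mid_convolve(c(0.5, 0.5), c(0.5, 0.5)),
                   c(0.25, 0.5, 0.25))
  set.seed(1)
  for (k in 1:20) {
    a <- runif(sample(2:5, 1)); b <- runif(sample(2:5, 1))
    cv <- mid_convolve(a, b)
    # total mass multiplies; entries match the direct double sum
    expect_equal(sum(cv), sum(a) * sum(b), tolerance = 1e-12)
    direct <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) for (j in seq_along(b)) {
      direct[i + j - 1] <- direct[i + j - 1] + a[i] * b[j]
    }
    expect_equal(cv, direct, tolerance = 1e-12)
  }
})

test_that("full labeling and no labeling propagate through a chain", {
  lin <- toy_linear()
  basis <- build_flux_basis(lin, fixed = "upt")
  fs <- realize_fluxes(basis, free_net = setNames(numeric(0), character(0)),
                       fixed = c(upt = 1))
  sys <- decompose(lin, backbone_emus(lin, c("A", "B")))
  full <- input_labeling(lin, tracer_mixture(list(c(1, 1)), 1))
  m <- simulate_mids(sys, fs, full)
  expect_mid_equal(m[["B|1,2"]], c(0, 0, 1))
  none <- input_labeling(lin, tracer_mixture(list(c(0, 0)), 1))
  m <- simulate_mids(sys, fs, none)
  expect_mid_equal(m[["B|1,2"]], c(1, 0, 0))
})

test_that("cleavage closure follows the atom map", {
  m <- load_network(list(
    metabolites = list(
      list(id = "Sin", carbons = 3, role = "input"),
      list(id = "C3", carbons = 3), list(id = "A1", carbons = 1),
      list(id = "B2", carbons = 2),
      list(id = "P", carbons = 3, role = "output")),
    reactions = list(
      list(id = "upt", equation = "Sin#abc -> C3#abc"),
      list(id = "cut", equation = "C3#abc -> A1#a + B2#bc"),
      list(id = "oa", equation = "A1#a -> P"),
      list(id = "ob", equation = "B2#ab -> P")),
    tracer_inputs = list(glucose = "Sin")))
  sys <- decompose(m, backbone_emus(m, c("A1", "B2")))
  keys <- names(sys$emus)
  expect_true("C3|1" %in% keys)
  expect_true("C3|2,3" %in% keys)
  expect_false("C3|1,2,3" %in% keys)  # closure is minimal
})

test_that("EMU closure of the full panel stays within measured sizes", {
  net <- cg_network(expanded = TRUE)
  sys <- decompose(net, backbone_emus(net, cg_panel()))
  sizes <- vapply(sys$emus, `[[`, 0L, "size")
  expect_lte(max(sizes), 9)  # largest measured backbone (TYR)
  expect_gt(length(sys$emus), 100)
})

test_that("unreachable targets and zero-influx pools raise errors", {
  m <- load_network(list(
    metabolites = list(
      list(id = "Sin", carbons = 1, role = "input"),
      list(id = "A", carbons = 1), list(id = "B", carbons = 1),
      list(id = "P", carbons = 1, role = "output")),
    reactions = list(
      list(id = "upt", equation = "Sin#a -> A#a"),
      list(id = "oa", equation = "A#a -> P#a"),
      list(id = "ob", equation = "B#a -> P#a")),
    tracer_inputs = list(glucose = "Sin")))
  expect_error(decompose(m, backbone_emus(m, "B")), "B")
})

test_that("EMU simulation equals the isotopomer oracle on random networks", {
  worst <- 0
  for (seed in 1:12) {
    cs <- random_toy_case(seed)
    mets <- c("A", "B", "C", "D", "E")
    sys <- decompose(cs$model, backbone_emus(cs$model, mets))
    m <- simulate_mids(sys, cs$flux, cs$tracer)
    orc <- isotopomer_oracle(cs$model, cs$flux, cs$tracer)
    nc <- setNames(cs$model$metabolites$carbons, cs$model$metabolites$id)
    for (mt in mets) {
      d <- max(abs(m[[emu_key(mt, seq_len(nc[mt]))]] - orc[[mt]]))
      worst <- max(worst, d)
    }
    sums <- vapply(m, sum, 0)
    expect_lt(max(abs(sums - 1)), 1e-9)
  }
  expect_lt(worst, 1e-9)
})

test_that("simulated MIDs are affine in any input MID entry", {
  tw <- toy_split_truth()
  sys <- decompose(tw$model, backbone_emus(tw$model, c("D", "F")))
  mk <- function(p) {
    # mixture over two species with fraction p: input MIDs are affine in p
    input_labeling(tw$model,
                   tracer_mixture(list(c(1, 0, 0), c(1, 1, 1)), c(p, 1 - p)))
  }
  f <- function(p) simulate_mids(sys, tw$flux, mk(p))[["D|1,2"]]
  y0 <- f(0.2); y1 <- f(0.8); ym <- f(0.5)
  expect_mid_equal(ym, (y0 + y1) / 2, 1e-10)  # affine => midpoint rule
})

test_that("infinite-exchange limit equilibrates educt and product MIDs", {
  m <- load_network(list(
    metabolites = list(
      list(id = "Sin", carbons = 2, role = "input"),
      list(id = "A", carbons = 2), list(id = "B", carbons = 2),
      list(id = "P", carbons = 2, role = "output")),
    reactions = list(
      list(id = "upt", equation = "Sin#ab -> A#ab"),
      list(id = "iso", equation = "A#ab <-> B#ba"),
      list(id = "out", equation = "B#ab -> P#ab")),
    tracer_inputs = list(glucose = "Sin")))
  basis <- build_flux_basis(m, fixed = "upt")
  tr <- input_labeling(m, tracer_mixture(list(c(1, 0)), 1))
  sys <- decompose(m, backbone_emus(m, c("A", "B")))
  fs <- realize_fluxes(basis, setNames(numeric(0), character(0)),
                       c(upt = 1), exchange = c(iso = 1e6))
  mm <- simulate_mids(sys, fs, tr)
  expect_mid_equal(mm[["A|1,2"]], mm[["B|1,2"]], 1e-5)
})

test_that("raising exchange never changes total carbon balances", {
  net <- cg_network()
  basis <- build_flux_basis(net)
  fs1 <- cg_preset_flux(basis)
  ex2 <- fs1$exchange
  ex2["fumh"] <- ex2["fumh"] * 50
  fs2 <- flux_state(fs1$net, ex2, basis)
  cb1 <- carbon_balance(net, fs1)
  cb2 <- carbon_balance(net, fs2)
  expect_equal(cb1$co2_percent, cb2$co2_percent, tolerance = 1e-12)
  expect_equal(fs1$net, fs2$net)
})
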