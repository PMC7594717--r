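test_that("a minimal linear chain parses into one balanced pool", {
  m <- load_network(list(
    metabolites = list(
      list(id = "A", carbons = 2, role = "input"),
      list(id = "B", carbons = 2),
      list(id = "C", carbons = 2, role = "output")),
    reactions = list(
      list(id = "r1", equation = "A#ab -> B#ab"),
      list(id = "r2", equation = "B#ab -> C#ab"))))
  s <- network_summary(m)
  expect_equal(s$n_reactions, 2)
  expect_equal(s$n_balanced, 1)
  expect_equal(s$n_nonbalanced, 2)
})

test_that("atom-map violations are parse errors naming the reaction", {
  base <- list(
    metabolites = list(
      list(id = "A", carbons = 3, role = "input"),
      list(id = "B", carbons = 2),
      list(id = "P", carbons = 2, role = "output")))
  # 3 educt carbons squeezed onto a 2-carbon product
  bad1 <- c(base, list(reactions = list(
    list(id = "bad", equation = "A#abc -> B#abc"))))
  expect_error(load_network(bad1), "bad")
  # undeclared metabolite
  bad2 <- c(base, list(reactions = list(
    list(id = "r", equation = "A#abc -> Z#abc"))))
  expect_error(load_network(bad2), "undeclared")
  # silent carbon loss into a balanced product
  bad3 <- c(base, list(reactions = list(
    list(id = "r", equation = "A#abc -> B#ab"))))
  expect_error(load_network(bad3), "carbon")
})

test_that("bundled network reports the published dimensions", {
  net <- cg_network()
  ex <- expand_scrambling(net)
  s <- network_summary(ex)
  expect_equal(s$n_reactions, 87)
  expect_equal(s$n_bidirectional, 22)
  expect_equal(s$n_unidirectional, 65)
  expect_equal(s$n_balanced, 45)
  expect_equal(s$n_nonbalanced, 4)
  basis <- build_flux_basis(net)
  expect_length(basis$free_net, 7)
  expect_length(basis$free_exchange, 20)
})

test_that("scrambling expansion mirrors symmetric pools with equal weights", {
  m <- load_network(list(
    metabolites = list(
      list(id = "In", carbons = 4, role = "input"),
      list(id = "S", carbons = 4, symmetric = TRUE),
      list(id = "P", carbons = 4, role = "output")),
    reactions = list(
      list(id = "mk", equation = "In#abcd -> S#abcd"),
      list(id = "out", equation = "S#abcd -> P#abcd"))))
  ex <- expand_scrambling(m)
  tab <- reaction_table(ex)
  mk <- tab[tab$variant_of == "mk", ]
  expect_equal(nrow(mk), 2)
  expect_equal(sum(mk$weight), 1)
  expect_setequal(mk$products, c("S#abcd", "S#dcba"))
  # a network without symmetric pools is returned unchanged
  expect_identical(expand_scrambling(toy_linear())$reactions,
                   toy_linear()$reactions)
})

test_that("scrambled MID equals the average over both orientations", {
  # condensation B + E -> D(symmetric); oracle on the expanded model must
  # equal the average of the two unscrambled orientation simulations
  cs <- random_toy_case(101)  # drew a symmetric case by construction check
  # force a symmetric pool by regenerating until present
  seed <- 101
  while (!any(cs$model$metabolites$symmetric)) {
    seed <- seed + 1
    cs <- random_toy_case(seed)
  }
  ex <- expand_scrambling(cs$model)
  sysd <- decompose(ex, backbone_emus(ex, "D"))
  scrambled <- simulate_mids(sysd, cs$flux, cs$tracer)
  nD <- cs$model$metabolites$carbons[cs$model$metabolites$id == "D"]
  key <- emu_key("D", seq_len(nD))

  unscr <- cs$model
  unscr$metabolites$symmetric <- FALSE
  m1 <- simulate_mids(decompose(unscr, backbone_emus(unscr, "D")),
                      cs$flux, cs$tracer)
  # mirrored orientation of the condensation product
  unscr2 <- unscr
  ic <- which(vapply(unscr2$reactions, function(r) {
    any(vapply(r$products, function(p) p$met == "D", TRUE))
  }, TRUE))
  for (i in ic) {
    for (j in seq_along(unscr2$reactions[[i]]$products)) {
      if (unscr2$reactions[[i]]$products[[j]]$met == "D") {
        unscr2$reactions[[i]]$products[[j]]$atoms <-
          rev(unscr2$reactions[[i]]$products[[j]]$atoms)
      }
    }
  }
  m2 <- simulate_mids(decompose(unscr2, backbone_emus(unscr2, "D")),
                      cs$flux, cs$tracer)
  expect_mid_equal(scrambled[[key]], (m1[[key]] + m2[[key]]) / 2, 1e-9)
})

test_that("flux basis determines fully constrained chains and round-trips", {
  lin <- toy_linear()
  basis <- build_flux_basis(lin, fixed = "upt")
  expect_length(basis$free_net, 0)
  fs <- realize_fluxes(basis, free_net = setNames(numeric(0), character(0)),
                       fixed = c(upt = 3.5))
  expect_equal(unname(fs$net), rep(3.5, 3))

  # round trip on the bundled network: extract then realize is the identity
  net <- cg_network()
  b <- build_flux_basis(net)
  fs0 <- cg_preset_flux(b)
  xf <- extract_free(b, fs0)
  fs1 <- realize_fluxes(b, xf$free_net, xf$fixed, xf$exchange)
  expect_equal(fs1$net, fs0$net, tolerance = 1e-9)
  expect_equal(fs1$exchange, fs0$exchange, tolerance = 1e-9)

  # balance residuals vanish for random free values
  set.seed(4)
  for (k in 1:5) {
    st <- sample_true_fluxes(b, xf$fixed, seed = k)
    res <- as.numeric(emuflux:::balanced_stoichiometry(net) %*% st$net)
    expect_lt(max(abs(res)), 1e-9 * max(abs(st$net)))
    expect_true(all(st$forward >= 0), info = "forward fluxes nonnegative")
    expect_true(all(st$backward >= 0))
  }
})

test_that("negative exchange and over-determined fixings are rejected", {
  tw <- toy_split_truth()
  expect_error(realize_fluxes(tw$basis, free_net = c(r2 = 1),
                              fixed = c(upt = 10), exchange = c(iso = -1)),
               ">= 0")
  expect_error(build_flux_basis(toy_split(), fixed = c("upt", "nosuch")),
               "nosuch")
})

test_that("scrambling leaves every pool's total throughput unchanged", {
  net <- cg_network()
  S1 <- emuflux:::balanced_stoichiometry(net)
  S2 <- emuflux:::balanced_stoichiometry(expand_scrambling(net))
  expect_equal(S1, S2[rownames(S1), colnames(S1)])
})

test_that("exchange transform is a bijection on [0, 1)", {
  x <- c(0, 0.1, 1, 7, 300)
  expect_equal(exchange_from_x01(x01_from_exchange(x, 2), 2), x)
  expect_error(exchange_from_x01(1))
})
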