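test_that("first hybridization follows the second-order closed form", {
  pool <- species_pool(c("a", "b", "c"), c(2, 0.5, 1), c(2, 0.5, 0))
  pars <- hybrid_params(rate_k = 0.3, driver_excess = 10)

  h0 <- first_hybridization(pool, pars, tau = 0)
  expect_equal(h0$ss_A, pool$tester_conc)  # no annealing at tau = 0

  h <- first_hybridization(pool, pars)
  cc <- pool$tester_conc + 10 * pool$driver_conc
  expect_equal(h$ss_A, pool$tester_conc / (1 + 0.3 * cc * 45))
  # mass conservation per species
  expect_equal(h$ss_A + h$annealed, pool$tester_conc, tolerance = 1e-12)
  expect_error(first_hybridization(pool, pars, tau = -1), ">= 0")
})

test_that("closed-form kinetics agree with numerical ODE integration", {
  # du/dt = -k u^2 for the total complementary pool; adapter-ligated tester
  # is the constant fraction t/c of it
  for (k in c(0.05, 0.5)) {
    for (cc in c(0.2, 5)) {
      sol <- deSolve::ode(y = c(u = cc), times = c(0, 12),
                          func = function(t, y, p) list(-k * y[1]^2),
                          rtol = 1e-10, atol = 1e-12)
      t_i <- 0.3 * cc
      s_num <- (t_i / cc) * sol[2, "u"]
      s_closed <- t_i / (1 + k * cc * 12)
      expect_equal(unname(s_num), s_closed, tolerance = 1e-6)
    }
  }
})

test_that("abundant shared fragments normalize toward equal single-strand levels", {
  # equally expressed in tester and driver, but 50-fold abundance difference
  pool <- species_pool(c("abundant", "scarce"), c(50, 1), c(50, 1))
  pars <- hybrid_params(rate_k = 1, driver_excess = 60)
  h <- first_hybridization(pool, pars, tau = 45)
  ratio <- h$ss_A[1] / h$ss_A[2]
  expect_lt(abs(ratio - 1), 0.05)  # k*c*tau >> 1: s_i/s_j -> 1

  # CV of remaining single strands is non-increasing in time
  pool2 <- species_pool(paste0("s", 1:6), c(100, 30, 10, 3, 1, 0.3),
                        c(100, 30, 10, 3, 1, 0.3))
  cv <- vapply(seq(0, 45, by = 5), function(tau) {
    s <- first_hybridization(pool2, pars, tau = tau)$ss_A
    stats::sd(s) / mean(s)
  }, numeric(1))
  expect_true(all(diff(cv) <= 1e-12))
})

test_that("tester-specific fragments retain more single strands at any tau > 0", {
  pool <- species_pool(c("specific", "shared"), c(1, 1), c(0, 1))
  pars <- hybrid_params(rate_k = 0.25, driver_excess = 60)
  for (tau in c(0.5, 5, 45)) {
    h <- first_hybridization(pool, pars, tau = tau)
    expect_gt(h$ss_A[1], h$ss_A[2])
  }
})

test_that("second hybridization yield is symmetric, bounded and monotone", {
  h1 <- data.frame(species_id = c("a", "b"), ss_A = c(0.4, 0.1),
                   ss_B = c(0.2, 0.1))
  pars <- hybrid_params(peg_rate_multiplier = 5)
  h2 <- second_hybridization(h1, pars)
  expect_true(all(h2$duplex_AB <= pmin(h1$ss_A, h1$ss_B) + 1e-12))
  expect_true(all(h2$duplex_AB > 0))

  # no PEG -> no rate -> zero yield
  h2z <- second_hybridization(h1, hybrid_params(peg_rate_multiplier = 0))
  expect_equal(h2z$duplex_AB, c(0, 0))

  # symmetry in A/B
  h1s <- data.frame(species_id = "a", ss_A = 0.3, ss_B = 0.7)
  h1r <- data.frame(species_id = "a", ss_A = 0.7, ss_B = 0.3)
  expect_equal(second_hybridization(h1s, pars)$duplex_AB,
               second_hybridization(h1r, pars)$duplex_AB)

  # monotone increasing in t2
  yields <- vapply(c(1, 6, 24, 96), function(t2) {
    second_hybridization(h1, hybrid_params(t2_hours = t2))$duplex_AB[1]
  }, numeric(1))
  expect_true(all(diff(yields) > 0))

  expect_error(second_hybridization(data.frame(species_id = "a"), pars),
               "ss_A")
})

test_that("suppression PCR normalizes composition and preserves rank order", {
  d <- data.frame(species_id = c("a", "b", "c"),
                  duplex_AB = c(0.5, 0.1, 0.3))
  pcr <- suppression_pcr(d)
  expect_equal(sum(pcr$share), 1)
  expect_equal(order(pcr$share), order(d$duplex_AB))
  expect_equal(suppression_pcr(data.frame(species_id = "x",
                                          duplex_AB = 2))$share, 1)
  expect_error(suppression_pcr(data.frame(species_id = "x", duplex_AB = 0)),
               "empty subtracted library")
})

test_that("SSH end-to-end enriches repressed fragments and normalizes the rest", {
  # repressed-in-driver species gains composition share over its tester share
  pool <- species_pool(c("suppressor", "shared_hi", "shared_lo"),
                       c(1, 20, 0.5), c(0.05, 20, 0.5))
  res <- run_ssh(pool)
  tester_share <- pool$tester_conc / sum(pool$tester_conc)
  expect_gt(res$share[1], tester_share[1])
  # equally expressed abundant vs scarce species end closer together
  start_ratio <- tester_share[2] / tester_share[3]
  end_ratio <- res$share[2] / res$share[3]
  expect_lt(end_ratio, start_ratio)
})

test_that("enrichment of a tester-specific species increases with driver excess", {
  pool <- species_pool(c("specific", "shared1", "shared2"),
                       c(1, 10, 2), c(0, 10, 2))
  enr <- vapply(c(1, 35, 60), function(E) {
    res <- run_ssh(pool, hybrid_params(driver_excess = E))
    res$share[1] / (pool$tester_conc[1] / sum(pool$tester_conc))
  }, numeric(1))
  expect_true(all(diff(enr) > 0))
})
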