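two_site_promoter <- function(Kd = 20, omega = 8) {
  sites <- default_promoter_sites(Kd = Kd, omega = omega)
  # restrict to one TF per site on the first two sites; leave others empty
  sites[[1]]$bindings <- tf_binding("actA", Kd, "activator", omega)
  sites[[2]]$bindings <- tf_binding("repB", Kd, "repressor")
  sites[[3]]$bindings <- sites[[3]]$bindings[0, ]
  sites[[4]]$bindings <- sites[[4]]$bindings[0, ]
  sites[[5]]$bindings <- sites[[5]]$bindings[0, ]
  promoter_config(sites = sites, rnap = 30, k_rnap = 1 / 30)
}

test_that("site regulation factors follow the occupancy form", {
  site <- tfbs_config("TFBS_AP1", dplyr::bind_rows(
    tf_binding("act", 10, "activator", 10),
    tf_binding("rep", 10, "repressor")
  ))
  # empty occupancy
  expect_equal(site_regulation_factor(site, c(act = 0, rep = 0)), 1)
  # one activator at [a] = Kd with omega 10: (1 + 10) / (1 + 1)
  expect_equal(site_regulation_factor(site, c(act = 10, rep = 0)), 5.5)
  # saturating repressor annihilates
  expect_lt(site_regulation_factor(site, c(act = 0, rep = 1e9)), 1e-6)
  expect_error(site_regulation_factor(site, c(act = -1, rep = 0)),
               "negative")
  expect_error(site_regulation_factor(site, c(act = 1)), "absent")
})

test_that("promoter factor is the product of site factors", {
  pc <- two_site_promoter()
  st0 <- c(actA = 0, repB = 0)
  expect_equal(promoter_regulation_factor(pc, st0), 1)
  st <- c(actA = 20, repB = 20)
  f1 <- site_regulation_factor(pc$sites[[1]], st)
  f2 <- site_regulation_factor(pc$sites[[2]], st)
  expect_equal(promoter_regulation_factor(pc, st), f1 * f2)
  # a fully repressed site annihilates the product
  expect_lt(promoter_regulation_factor(pc, c(actA = 20, repB = 1e12)), 1e-9)
})

test_that("product decomposition matches brute-force occupancy enumeration", {
  pc <- two_site_promoter(Kd = 15, omega = 6)
  for (st in list(c(actA = 0, repB = 0), c(actA = 15, repB = 15),
                  c(actA = 50, repB = 5), c(actA = 3, repB = 80))) {
    P_product <- p_rnap_bound(promoter_regulation_factor(pc, st), pc)
    P_enum <- enumerate_p_rnap(pc, st)
    expect_equal(P_product, P_enum, tolerance = 1e-12)
  }
})

test_that("RNAP binding probability is bounded and monotone", {
  pc <- two_site_promoter()
  expect_equal(p_rnap_bound(1, pc), 0.5) # z = 1 at F_reg = 1
  expect_equal(p_rnap_bound(0, pc), 0)
  expect_gt(p_rnap_bound(1e9, pc), 1 - 1e-6)
  # monotone in activator, antitone in repressor
  a_grid <- seq(0, 200, by = 25)
  Pa <- vapply(a_grid, function(a) {
    p_rnap_bound(promoter_regulation_factor(pc, c(actA = a, repB = 30)), pc)
  }, numeric(1))
  expect_false(is.unsorted(Pa))
  r_grid <- seq(0, 200, by = 25)
  Pr <- vapply(r_grid, function(r) {
    p_rnap_bound(promoter_regulation_factor(pc, c(actA = 30, repB = r)), pc)
  }, numeric(1))
  expect_false(is.unsorted(rev(Pr)))
  expect_true(all(Pa >= 0 & Pa <= 1 & Pr >= 0 & Pr <= 1))
})

test_that("mRNA kinetics reach ksynth P / kdeg and decay exponentially", {
  pc <- promoter_config()
  # steady states from the printed constants at full occupancy
  expect_equal(5e-5 / 2.7e-4, 0.1852, tolerance = 1e-4)
  expect_equal(5e-5 / 5.7e-6, 8.772, tolerance = 1e-4)
  expect_equal(mrna_rate("MYC", 1, 5e-5 / 2.7e-4, pc), 0)
  expect_equal(mrna_rate("CCND1", 1, 5e-5 / 5.7e-6, pc), 0, tolerance = 1e-12)
  # P = 0: pure exponential decay
  m0 <- 3
  kdeg <- pc$genes$MYC$kdeg
  f <- function(t) m0 * exp(-kdeg * t)
  expect_equal(mrna_rate("MYC", 0, m0, pc), -kdeg * m0)
  # convergence from any start (linear ODE, forward Euler on fine grid)
  target <- 5e-5 * 0.4 / 2.7e-4
  x <- 10; dt <- 1
  for (i in 1:(3600 * 18)) x <- x + dt * mrna_rate("MYC", 0.4, x, pc)
  expect_lt(abs(x - target) / target, 1e-3)
  expect_error(mrna_rate("nope", 0.5, 1, pc), "unknown gene")
})

test_that("half-lives follow ln(2)/kdeg, with MYC under the 2 h bound", {
  expect_equal(mrna_half_life(2.7e-4), log(2) / 2.7e-4 / 3600)
  expect_equal(mrna_half_life(2.7e-4), 0.7131, tolerance = 1e-4)
  expect_lt(mrna_half_life(2.7e-4), 2)
  expect_equal(mrna_half_life(5.7e-6), 33.78, tolerance = 1e-3)
  expect_equal(mrna_half_life(log(2) / 3600), 1)
  expect_error(mrna_half_life(0), "kdeg")
  # the kdeg asymmetry: MYC relaxes ~47x faster than CCND1
  expect_equal(2.7e-4 / 5.7e-6, 47.37, tolerance = 1e-3)
})

test_that("the MEK-inhibition CCND1 destabilization follows the ERKPP ratio", {
  kdeg <- 5.7e-6
  expect_equal(ccnd1_kdeg_modifier(kdeg, 50, 50), kdeg) # ratio 1: unchanged
  # 80% ERK inhibition: ratio 5
  expect_equal(ccnd1_kdeg_modifier(kdeg, 50, 10), 2.85e-5)
  expect_warning(out <- ccnd1_kdeg_modifier(kdeg, 50, 0), "floor")
  expect_equal(out, kdeg / 1e-6)
})
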