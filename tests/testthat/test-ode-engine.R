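test_that("initial state puts each pool on the unbound basic species", {
  m <- binding_model(A = 100, B = 50)
  st <- initialize_state(m)
  expect_equal(st, c(A = 100, B = 50, AB = 0))
  # genotype directives act before integration
  m2 <- toy_model()
  st_null <- initialize_state(
    m2, genotype("g", mutation("null", "SMAD4")))
  expect_equal(st_null[["SMAD4"]], 0)
  st_pl <- initialize_state(
    m2, genotype("g", mutation("partial_loss", "PTEN", fraction = 0.6)))
  expect_equal(st_pl[["PTEN"]],
               0.6 * toy_parameters()$conc[["PTEN"]])
  expect_error(
    initialize_state(m2, genotype("g", mutation("null", "NOT_A_SPECIES"))),
    "unknown species"
  )
})

test_that("the assembled rate function matches direct substitution", {
  m <- binding_model(kon = 1e-3, koff = 1e-2)
  f <- build_rhs(m)
  d <- f(c(A = 10, B = 10, AB = 0))
  expect_equal(d[["AB"]], 1e-3 * 10 * 10) # 0.1 nM/s
  expect_equal(d[["A"]], -0.1)
  d2 <- f(c(A = 0, B = 0, AB = 20))
  expect_equal(d2[["AB"]], -1e-2 * 20)

  cm <- cycle_model(E = 10, P = 0, S = 10, k_kin = 1e-3)
  fc <- build_rhs(cm)
  expect_equal(fc(initialize_state(cm))[["S_p"]], 1e-3 * 10 * 10)

  # Michaelis-Menten saturates at kcat [E]
  mm <- network_model(
    species = dplyr::bind_rows(
      species_decl("E", "basic", 5),
      species_decl("S", "basic", 1e6),
      species_decl("S_p", "modified", 0, composition = "S")
    ),
    catalytic = catalytic_reaction("c", "E", "S", "S_p", 0.1,
                                   law = "michaelis_menten", Km = 10)
  )
  v <- build_rhs(mm)(initialize_state(mm))[["S_p"]]
  expect_equal(v, 0.1 * 5 * 1e6 / (10 + 1e6))
  expect_lt(abs(v - 0.1 * 5), 1e-4)
})

test_that("equilibration reproduces the closed-form binding equilibrium", {
  m <- binding_model(A = 100, B = 100, kon = 1e-3, koff = 1e-2)
  eq <- equilibrate(m)
  expect_true(attr(eq, "converged"))
  ab_star <- binding_equilibrium(100, 100, 10)
  expect_lt(abs(eq[["AB"]] - ab_star) / ab_star, 1e-6)
  expect_lt(abs(ab_star - 72.98438), 1e-4)

  # property: random pool sizes and affinities against the quadratic
  set.seed(11)
  for (k in 1:8) {
    At <- stats::runif(1, 10, 500)
    Bt <- stats::runif(1, 10, 500)
    Kd <- 10^stats::runif(1, -1, 2)
    kon <- 1e-3
    m2 <- binding_model(A = At, B = Bt, kon = kon, koff = kon * Kd)
    eq2 <- equilibrate(m2)
    expect_lt(abs(eq2[["AB"]] - binding_equilibrium(At, Bt, Kd)) /
                binding_equilibrium(At, Bt, Kd), 1e-6)
  }

  # kon = 0: no complex ever forms
  m0 <- binding_model(kon = 0, koff = 1e-2)
  expect_equal(equilibrate(m0)[["AB"]], 0)

  # idempotence
  eq_again <- equilibrate(m, state = eq)
  expect_rel_equal(eq_again, eq, 1e-8)
  expect_equal(attr(eq_again, "t_equilibration"), 0)
})

test_that("equilibration past the horizon warns and flags non-convergence", {
  m <- binding_model()
  st <- initialize_state(m)
  s <- solver_settings(t_max_equilibration = 5)
  expect_warning(eq <- equilibrate(m, st, s), "t_max")
  expect_false(attr(eq, "converged"))
})

test_that("a phospho cycle reaches its analytic steady-state fraction", {
  k_kin <- 3e-4; k_pho <- 2e-4; E <- 8; P <- 12
  m <- cycle_model(E = E, P = P, S = 100, k_kin = k_kin, k_pho = k_pho)
  eq <- equilibrate(m)
  odds <- k_kin * E / (k_pho * P)
  expect_lt(abs(eq[["S_p"]] / 100 - odds / (1 + odds)), 1e-6)
})

test_that("simulation is stable under tolerance halving and clips underflow", {
  m <- toy_model()
  eq <- toy_equilibrium()
  s1 <- solver_settings(rel_tol = 1e-8)
  s2 <- solver_settings(rel_tol = 5e-9)
  sim1 <- simulate_model(m, state0 = eq, t_end = 1800, settings = s1)
  sim2 <- simulate_model(m, state0 = eq, t_end = 1800, settings = s2)
  end1 <- sim1$conc[nrow(sim1$conc), ]
  end2 <- sim2$conc[nrow(sim2$conc), ]
  keep <- end2 > 1e-6
  expect_lt(max(abs(end1[keep] - end2[keep]) / end2[keep]), 1e-3)
  expect_true(all(sim1$conc >= 0))

  # zero-rate model: constant trajectory
  mz <- binding_model(kon = 0, koff = 0)
  simz <- simulate_model(mz, t_end = 1000)
  expect_equal(simz$conc[nrow(simz$conc), ], simz$conc[1, ])
})

test_that("simulation results tidy into long tibbles", {
  m <- binding_model()
  sim <- simulate_model(m, t_end = 100, n_out = 11)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time", "species", "concentration"))
  expect_equal(nrow(td), 11 * 3)
  expect_s3_class(autoplot(sim), "ggplot")
})
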