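test_that("the toy generator is deterministic and self-consistent", {
  m1 <- make_toy_mim(toy_spec(seed = 5))
  m2 <- make_toy_mim(toy_spec(seed = 5))
  expect_identical(m1$species, m2$species)
  expect_identical(m1$reversible, m2$reversible)
  expect_identical(m1$catalytic, m2$catalytic)
  expect_equal(m1$manifest$n_processes, n_rate_processes(m1))
  expect_equal(m1$manifest$n_processes,
               2L * m1$manifest$n_reversible + m1$manifest$n_catalytic)
  expect_error(make_toy_mim(toy_spec(pathways = character(0))),
               "no pathway")
})

test_that("pathway flags control the generated wiring", {
  m_full <- toy_model()
  expect_true(all(c("DC", "Axin_GSK3B", "CTNNB1") %in% m_full$species$id))
  m_nownt <- make_toy_mim(toy_spec(pathways = c("egf_mapk", "pi3k_akt")))
  expect_false(any(c("DC", "Axin_GSK3B", "APC", "CTNNB1") %in%
                     m_nownt$species$id))
  m_nofb <- make_toy_mim(toy_spec(include_feedback = FALSE))
  expect_false("receptor_feedback" %in% m_nofb$catalytic$id)
  expect_true("receptor_feedback" %in% m_full$catalytic$id)
  # each generated variant passes full validation
  expect_silent(validate_network_model(m_nownt))
  expect_silent(validate_network_model(m_nofb))
})

test_that("the untreated toy sits mid-range with signatures intact", {
  m <- toy_model()
  eq <- toy_equilibrium()
  sim <- simulate_model(m, state0 = eq, t_end = 1800, n_out = 7)
  erk <- phospho_ratio(sim, "ERK", 1800)
  akt <- phospho_ratio(sim, "AKT", 1800)
  expect_gt(erk, 0.3); expect_lt(erk, 0.6)
  expect_gt(akt, 0.3); expect_lt(akt, 0.6)
  P <- p_rnap_bound(promoter_regulation_factor(m$promoter, eq), m$promoter)
  expect_equal(P, 0.5, tolerance = 0.02)
})

test_that("pseudo-experiments are seeded, reproducible and noise-consistent", {
  plan <- treatment_plan(list(list(label = "CI1040", inhibitors = "CI1040")),
                         mrna_readout_times = 14400)
  ci <- calibrated_inhibitor("CI1040", 0.80, "ERK")
  spec <- toy_spec(seed = 31, noise = list(cv = 0.1, n_replicates = 2))
  g <- genotype_preset("physiologic")
  e1 <- make_pseudo_experiments(toy_model(), g, plan, spec,
                                inhibitors = list(CI1040 = ci))
  e2 <- make_pseudo_experiments(toy_model(), g, plan, spec,
                                inhibitors = list(CI1040 = ci))
  expect_identical(e1, e2)
  expect_equal(nrow(e1),
               2 * nrow(run_experiment(toy_model(), g, plan,
                                       inhibitors = list(CI1040 = ci))))
  # the noise-free limit equals the simulated readouts
  spec0 <- toy_spec(seed = 31, noise = list(cv = 1e-9, n_replicates = 2))
  e0 <- make_pseudo_experiments(toy_model(), g, plan, spec0,
                                inhibitors = list(CI1040 = ci))
  truth <- run_experiment(toy_model(), g, plan,
                          inhibitors = list(CI1040 = ci))
  joined <- dplyr::inner_join(e0, truth,
                              by = c("treatment", "endpoint", "time_s"),
                              suffix = c("_noisy", "_true"))
  expect_equal(joined$value_noisy, joined$value_true, tolerance = 1e-6)
})

test_that("end-to-end validation recovers strong correlation at low noise", {
  panel <- graded_panel()
  g <- genotype_preset("physiologic")
  truth <- run_experiment(toy_model(), g, panel$plan,
                          inhibitors = panel$inhibitors)
  spec <- toy_spec(seed = 17, noise = list(cv = 0.05, n_replicates = 2))
  pseudo <- make_pseudo_experiments(toy_model(), g, panel$plan, spec,
                                    inhibitors = panel$inhibitors)
  rep_ <- validate_readouts(truth, pseudo)
  td <- tidy(rep_)
  expect_equal(nrow(td), 4)
  expect_true(all(td$rho > 0.9))
})

test_that("calibration strengths are recovered from observed inhibitions", {
  res <- parameter_recovery_harness(toy_model(), f_true = c(0, 0.4, 0.7, 0.8))
  expect_true(all(res$monotone))
  expect_equal(res$recovered[res$f_true == 0], 0)
  expect_lt(max(res$abs_error), 0.005)
  # with 5% observation noise recovery stays within 0.05
  res_n <- parameter_recovery_harness(toy_model(), f_true = c(0.4, 0.7),
                                      seed = 3, noise_cv = 0.05)
  expect_lt(max(res_n$abs_error), 0.05)
})
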