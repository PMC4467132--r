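test_that("phospho ratios do moiety bookkeeping over forms and complexes", {
  # ERK split across free, phospho and a kinase complex
  m <- network_model(
    species = dplyr::bind_rows(
      species_decl("MEK", "basic", 50),
      species_decl("ERK", "basic", 50),
      species_decl("ERK_PP", "modified", 30, composition = "ERK"),
      species_decl("MEK_ERK", "complex", 20, composition = c("MEK", "ERK"))
    ),
    reversible = reversible_reaction("b", c("MEK", "ERK"), "MEK_ERK",
                                     1e-3, 1e-2),
    annotations = list(endpoints = list(
      ERK = list(active = "ERK_PP", moiety = "ERK")
    ))
  )
  sim <- simulate_model(m, t_end = 1,
                        state0 = c(MEK = 50, ERK = 50, ERK_PP = 30,
                                   MEK_ERK = 20))
  expect_equal(phospho_ratio(sim, "ERK", 0), 30 / 100)
  # all-phospho and no-phospho limits
  sim1 <- simulate_model(m, t_end = 1,
                         state0 = c(MEK = 0, ERK = 0, ERK_PP = 100,
                                    MEK_ERK = 0))
  expect_equal(phospho_ratio(sim1, "ERK", 0), 1)
  sim0 <- simulate_model(m, t_end = 1,
                         state0 = c(MEK = 0, ERK = 100, ERK_PP = 0,
                                    MEK_ERK = 0))
  expect_equal(phospho_ratio(sim0, "ERK", 0), 0)
  expect_error(phospho_ratio(sim, "AKT", 0), "endpoint annotation")
})

test_that("vehicle-only plans self-normalize to exactly 1", {
  plan <- treatment_plan(list(), mrna_readout_times = 14400)
  rt <- run_experiment(toy_model(), genotype_preset("physiologic"), plan)
  expect_true(all(rt$treatment == "vehicle"))
  expect_true(all(rt$value == 1))
  expect_false(any(rt$undefined))
})

test_that("calibrated CI1040 reproduces its readouts through the pipeline", {
  ci <- calibrated_inhibitor("CI1040", 0.80, "ERK")
  plan <- treatment_plan(list(list(label = "CI1040", inhibitors = "CI1040")))
  rt <- run_experiment(toy_model(), genotype_preset("physiologic"), plan,
                       inhibitors = list(CI1040 = ci))
  v <- function(ep, t) rt$value[rt$treatment == "CI1040" &
                                  rt$endpoint == ep & rt$time_s == t]
  # by construction of the calibration the 30-min readout is 20% of control
  expect_equal(v("ERKPP_ratio", 1800), 0.2, tolerance = 1e-3)
  # MEK inhibition barely touches the AKT arm
  expect_equal(v("AKTP_ratio", 1800), 1, tolerance = 0.05)
  # MYC falls faster than CCND1 at 4 h (kdeg asymmetry)
  expect_lt(v("MYC_mRNA", 14400), v("CCND1_mRNA", 14400))
  # CCND1 inhibition is stronger after 8 h than after 4 h
  expect_lt(v("CCND1_mRNA", 28800), v("CCND1_mRNA", 14400))
})

test_that("combinations are never less inhibitory than the strongest agent", {
  ci <- calibrated_inhibitor("CI1040", 0.80, "ERK")
  inh <- list(CI1040 = ci)
  plan <- treatment_plan(list(
    list(label = "CI1040", inhibitors = "CI1040"),
    list(label = "PI103", inhibitors = "PI103"),
    list(label = "combo", inhibitors = c("CI1040", "PI103"))
  ), mrna_readout_times = 14400)
  rt <- run_experiment(toy_model(), genotype_preset("physiologic"), plan,
                       inhibitors = inh)
  for (ep in c("MYC_mRNA", "CCND1_mRNA")) {
    singles <- rt$value[rt$treatment %in% c("CI1040", "PI103") &
                          rt$endpoint == ep]
    combo <- rt$value[rt$treatment == "combo" & rt$endpoint == ep]
    expect_lte(combo, min(singles) + 1e-6)
  }
})

test_that("Act D exposes first-order decay and rescues CCND1 under CI1040", {
  m <- toy_model()
  g <- genotype_preset("physiologic")
  ad <- simulate_actd(m, g, time_points = c(0, 7200, 21600))
  v <- function(ep, t) ad$value[ad$endpoint == ep & ad$time_s == t]
  expect_equal(v("MYC_mRNA", 0), 1)
  expect_equal(v("CCND1_mRNA", 0), 1)
  # pure exponential decay with the printed rates
  expect_equal(v("MYC_mRNA", 7200), exp(-2.7e-4 * 7200), tolerance = 1e-3)
  expect_equal(v("CCND1_mRNA", 21600), exp(-5.7e-6 * 21600),
               tolerance = 1e-3)
  expect_gt(v("CCND1_mRNA", 21600), 0.85) # "substantially stable"

  ci <- calibrated_inhibitor("CI1040", 0.80, "ERK")
  inh <- list(CI1040 = ci)
  both <- simulate_actd(m, g, 14400, co_inhibitors = "CI1040",
                        inhibitors = inh)
  alone <- simulate_actd(m, g, 14400)
  cc <- function(x) x$value[x$endpoint == "CCND1_mRNA"]
  # with the intermediary-gene flag on, Act D blocks the destabilization
  expect_equal(cc(both), cc(alone), tolerance = 1e-6)
  # with the flag off the destabilization would have acted
  noblock <- simulate_actd(m, g, 14400, co_inhibitors = "CI1040",
                           inhibitors = inh,
                           actd_blocks_destabilization = FALSE)
  expect_lt(cc(noblock), cc(alone) - 0.1)
})

test_that("readout tables normalize scale-invariantly and plot", {
  # uniform rescaling of ksynth for both genes leaves normalized readouts
  ci <- calibrated_inhibitor("CI1040", 0.80, "ERK")
  plan <- treatment_plan(list(list(label = "CI1040", inhibitors = "CI1040")),
                         mrna_readout_times = 14400)
  m2 <- toy_model()
  m2$promoter$genes$MYC$ksynth <- m2$promoter$genes$MYC$ksynth * 3
  m2$promoter$genes$CCND1$ksynth <- m2$promoter$genes$CCND1$ksynth * 3
  rt1 <- run_experiment(toy_model(), genotype_preset("physiologic"), plan,
                        inhibitors = list(CI1040 = ci))
  rt2 <- run_experiment(m2, genotype_preset("physiologic"), plan,
                        inhibitors = list(CI1040 = ci))
  expect_equal(rt1$value, rt2$value, tolerance = 1e-6)
  expect_s3_class(autoplot(rt1), "ggplot")
})
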