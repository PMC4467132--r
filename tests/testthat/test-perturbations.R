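test_that("genotype presets carry the published directives", {
  m <- toy_model()
  hct <- genotype_preset("HCT116")
  mh <- apply_genotype(m, hct)
  # PTEN scaled to 60% of its physiological value
  base <- toy_parameters()$conc
  expect_equal(mh$species$conc[mh$species$id == "PTEN"],
               0.6 * base[["PTEN"]])
  expect_equal(mh$species$conc[mh$species$id == "CDH1"], 0)
  expect_equal(mh$species$conc[mh$species$id == "TGFBR2"], 0)
  ht <- genotype_preset("HT29")
  mt <- apply_genotype(m, ht)
  expect_equal(mt$species$conc[mt$species$id == "ErbB2"],
               2 * base[["ErbB2"]])
  expect_equal(mt$species$conc[mt$species$id == "SMAD4"], 0)
  # null SMAD4: downstream SMAD complexes never form
  eq <- equilibrate(mt)
  expect_equal(eq[["pSMAD2_SMAD4"]], 0)
  expect_equal(eq[["SMAD4_TCF7L2"]], 0)
})

test_that("applying a genotype twice equals applying it once", {
  m <- toy_model()
  g <- genotype_preset("HCT116")
  m1 <- apply_genotype(m, g)
  m2 <- apply_genotype(m1, g)
  expect_identical(m1$species$conc, m2$species$conc)
  expect_identical(m1$catalytic$kcat, m2$catalytic$kcat)
})

test_that("constitutive activation zeroes inactivation and decouples upstream", {
  m <- toy_model()
  g <- genotype("kras_on", mutation("constitutive_activation", "KRAS"))
  mg <- apply_genotype(m, g)
  expect_equal(mg$catalytic$kcat[mg$catalytic$id == "kras_gap"], 0)
  # receptor-level inhibition leaves ERKPP unchanged under constitutive KRAS
  eq <- equilibrate(mg)
  mi <- apply_inhibitor(mg, inhibitor_spec("antiEGFR", "EGF_EGFR", f = 0.9))
  eqi <- equilibrate(mi, state = eq)
  expect_lt(abs(eqi[["ERK_PP"]] - eq[["ERK_PP"]]) / eq[["ERK_PP"]], 1e-6)
  # a species with no inactivation process cannot be constitutively activated
  expect_error(
    apply_genotype(m, genotype("bad", mutation("constitutive_activation",
                                               "TP53"))),
    "no active form|no inactivation"
  )
})

test_that("activity scaling is the identity at f = 0 and commutes", {
  m <- toy_model()
  m0 <- apply_inhibitor(m, inhibitor_spec("x", "MEK_PP", f = 0))
  expect_identical(m0$catalytic$kcat, m$catalytic$kcat)
  a <- inhibitor_spec("a", "MEK_PP", f = 0.5)
  b <- inhibitor_spec("b", "PI3K_a", f = 0.3)
  mab <- apply_inhibitor(apply_inhibitor(m, a), b)
  mba <- apply_inhibitor(apply_inhibitor(m, b), a)
  expect_identical(mab$catalytic$kcat, mba$catalytic$kcat)
  expect_error(apply_inhibitor(m, inhibitor_spec("z", "NOPE", f = 0.5)),
               "matches no")
  expect_error(inhibitor_spec("z", "MEK_PP", f = 1), "f must be")
})

test_that("a basic-protein target also scales enzymes containing it", {
  m <- toy_model()
  mg <- apply_inhibitor(m, inhibitor_spec("aza", "GSK3B", f = 0.5))
  # the destruction complex DC contains GSK3B: its catalysis is scaled
  expect_equal(mg$catalytic$kcat[mg$catalytic$id == "bcat_phosphorylation"],
               0.5 * m$catalytic$kcat[m$catalytic$id == "bcat_phosphorylation"])
})

test_that("competitive binding sequesters the target", {
  m <- toy_model()
  spec <- inhibitor_spec("seq", "MEK_PP", mechanism = "competitive_binding",
                         concentration = 200, Ki = 1)
  mi <- apply_inhibitor(m, spec)
  expect_true("seq_drug" %in% mi$species$id)
  eq0 <- toy_equilibrium()
  st <- initialize_state(mi)
  st[names(eq0)] <- eq0
  eqi <- equilibrate(mi, state = st)
  expect_lt(eqi[["ERK_PP"]], 0.5 * eq0[["ERK_PP"]])
})

test_that("dose-response of the normalized readout is monotone nonincreasing", {
  m <- toy_model()
  eq <- toy_equilibrium()
  ci <- inhibitor_preset("CI1040")
  control <- phospho_ratio(
    simulate_model(m, state0 = eq, t_end = 1800, n_out = 7), "ERK", 1800)
  vals <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.95), function(f) {
    s <- ci; s$f <- f
    mt <- apply_inhibitor(m, s)
    phospho_ratio(simulate_model(mt, state0 = eq, t_end = 1800, n_out = 7),
                  "ERK", 1800) / control
  }, numeric(1))
  expect_false(is.unsorted(rev(vals)))
  expect_equal(vals[1], 1)
})

test_that("calibration reproduces requested inhibition levels round-trip", {
  m <- toy_model()
  g <- genotype_preset("physiologic")
  # desired 0: strength 0
  s0 <- calibrate_inhibitor(m, g, inhibitor_preset("CI1040"), 0, "ERK")
  expect_equal(s0$f, 0)
  for (lvl in c(0.2, 0.8)) {
    sp <- calibrate_inhibitor(m, g, inhibitor_preset("CI1040"), lvl, "ERK")
    expect_lt(abs(attr(sp, "achieved_inhibition") - lvl), 1e-3)
  }
  for (lvl in c(0.4, 0.7)) {
    sp <- calibrate_inhibitor(m, g, inhibitor_preset("Perifosine_40nM"),
                              lvl, "AKT")
    expect_lt(abs(attr(sp, "achieved_inhibition") - lvl), 1e-3)
  }
  # a readout insensitive to the target is not bracketable
  expect_error(
    calibrate_inhibitor(m, g, inhibitor_spec("aza", "GSK3B", f = 0.1),
                        0.8, "ERK"),
    "cannot reach"
  )
})
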