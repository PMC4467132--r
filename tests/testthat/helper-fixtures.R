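# Fixtures are built in code; nothing is read from disk.

# one reversible binding reaction A + B <-> AB
binding_model <- function(A = 100, B = 100, kon = 1e-3, koff = 1e-2) {
  network_model(
    species = dplyr::bind_rows(
      species_decl("A", "basic", A),
      species_decl("B", "basic", B),
      species_decl("AB", "complex", 0, composition = c("A", "B"))
    ),
    reversible = reversible_reaction("bind", c("A", "B"), "AB", kon, koff)
  )
}

# closed-form bimolecular binding equilibrium
binding_equilibrium <- function(At, Bt, Kd) {
  s <- At + Bt + Kd
  (s - sqrt(s^2 - 4 * At * Bt)) / 2
}

# kinase/phosphatase futile cycle on substrate S
cycle_model <- function(E = 10, P = 10, S = 100, k_kin = 2e-4, k_pho = 2e-4) {
  network_model(
    species = dplyr::bind_rows(
      species_decl("E", "basic", E),
      species_decl("Ph", "basic", P),
      species_decl("S", "basic", S),
      species_decl("S_p", "modified", 0, composition = "S")
    ),
    catalytic = dplyr::bind_rows(
      catalytic_reaction("kin", "E", "S", "S_p", k_kin),
      catalytic_reaction("pho", "Ph", "S_p", "S", k_pho)
    )
  )
}

# toy network and derived objects are expensive enough to share across tests
.toy_cache <- new.env(parent = emptyenv())

toy_model <- function() {
  if (is.null(.toy_cache$model)) .toy_cache$model <- make_toy_mim()
  .toy_cache$model
}

toy_equilibrium <- function() {
  if (is.null(.toy_cache$eq)) .toy_cache$eq <- equilibrate(toy_model())
  .toy_cache$eq
}

calibrated_inhibitor <- function(name, level, readout) {
  key <- paste0("cal_", name)
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- calibrate_inhibitor(
      toy_model(), genotype_preset("physiologic"), inhibitor_preset(name),
      f_desired = level, readout = readout
    )
  }
  .toy_cache[[key]]
}

# brute-force joint-occupancy enumeration for a promoter: every site is
# empty or occupied by exactly one of its TFs, RNAP bound or not; bound
# states carry [RNAP]*k_RNAP times the product of bound-activator omegas,
# and a bound repressor excludes RNAP (weight 0 in the bound partition)
enumerate_p_rnap <- function(config, state) {
  site_states <- lapply(config$sites, function(site) {
    b <- site$bindings
    ws <- list(list(w = 1, act_omega = 1)) # empty site
    for (i in seq_len(nrow(b))) {
      ws[[length(ws) + 1L]] <- list(
        w = state[[b$species_id[i]]] / b$Kd[i],
        act_omega = if (b$mode[i] == "activator") b$omega[i] else 0
      )
    }
    ws
  })
  z_unbound <- 0
  z_bound <- 0
  k <- if (config$k_rnap_mode == "association") config$k_rnap else 1 / config$k_rnap
  grid <- expand.grid(lapply(site_states, seq_along))
  for (r in seq_len(nrow(grid))) {
    w <- 1; womega <- 1
    for (s in seq_along(site_states)) {
      st <- site_states[[s]][[grid[r, s]]]
      w <- w * st$w
      womega <- womega * st$act_omega
    }
    z_unbound <- z_unbound + w
    z_bound <- z_bound + w * womega * config$rnap * k
  }
  z_bound / (z_bound + z_unbound)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}

# dose-escalation combination series: every treatment moves both the MAPK
# and the AKT arm (and, through them, both mRNAs), so each endpoint sees a
# graded series of distinct levels - the informative design for checking
# that validation statistics recover the sim-to-experiment link
graded_panel <- function(strengths = c(0.30, 0.50, 0.65, 0.80, 0.90)) {
  inh <- list()
  treatments <- list()
  for (i in seq_along(strengths)) {
    ci <- inhibitor_spec(paste0("CI_", i), "MEK_PP", f = strengths[i],
                         mek_inhibitor = TRUE)
    pf <- inhibitor_spec(paste0("Peri_", i), "akt_activation",
                         f = strengths[i])
    inh[[ci$name]] <- ci
    inh[[pf$name]] <- pf
    treatments[[i]] <- list(label = paste0("combo_", i),
                            inhibitors = c(ci$name, pf$name))
  }
  list(inhibitors = inh,
       plan = treatment_plan(treatments, mrna_readout_times = 14400))
}
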