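#' Specification for the seeded toy network
#'
#' @param seed Integer seed recorded on the model and used by the
#'   pseudo-experiment noise generator.
#' @param pathways Character subset of `c("egf_mapk", "pi3k_akt", "wnt")`;
#'   the TGF-beta/SMAD arm and the general transcription-factor species are
#'   always included as promoter furniture.
#' @param include_feedback Include the ERK-to-receptor negative feedback.
#' @param noise List with `cv` (> 0, lognormal coefficient of variation) and
#'   `n_replicates` (>= 2, biological duplicates).
#' @return A `toy_spec` object.
#' @export
toy_spec <- function(seed = 101L,
                     pathways = c("egf_mapk", "pi3k_akt", "wnt"),
                     include_feedback = TRUE,
                     noise = list(cv = 0.10, n_replicates = 2L)) {
  if (length(pathways) == 0L) rlang::abort("no pathway enabled")
  pathways <- match.arg(pathways, several.ok = TRUE)
  stopifnot(noise$cv > 0, noise$n_replicates >= 2)
  structure(list(seed = as.integer(seed), pathways = pathways,
                 include_feedback = include_feedback, noise = noise),
            class = "toy_spec")
}

#' Ground-truth parameter manifest of the toy network
#'
#' All toy concentrations and rate constants live here (not inside the
#' generator logic) so that tests and documentation can reference the exact
#' fixture values. Concentrations are nM; binding constants give Kd =
#' koff/kon = 10 nM; catalytic constants are mass-action (1/(nM s)) and put
#' each phospho/dephospho cycle near mid-activation at physiologic
#' equilibrium, with relaxation times of minutes (so 30-min protein readouts
#' sit at the post-treatment steady state while 4-8 h mRNA readouts probe
#' the slow transcript pools).
#'
#' @return Nested list of parameter values.
#' @export
toy_parameters <- function() {
  list(
    conc = c(
      EGF = 100, EGFR = 100, ErbB2 = 60, KRAS = 120, GAP = 50, BRAF = 100,
      MEK = 120, ERK = 150, PP = 50, AP1 = 80,
      PI3K = 100, PIP2 = 400, PTEN = 50, AKT = 150,
      GSK3B = 80, Axin = 50, TNKS = 30, APC = 60, CTNNB1 = 120,
      TCF7L2 = 60, GRO = 40, CDH1 = 60,
      TGFB = 30, TGFBR2 = 60, SMAD2 = 80, SMAD3 = 80, SMAD4 = 80,
      TP53 = 40, E2F = 60, DP1 = 60, RB = 40
    ),
    kon = 1e-3, koff = 1e-2,           # binding, Kd = 10 nM
    kcat_act = 2e-4, kcat_deact = 2e-4, # phospho / dephospho cycles
    kcat_akt = 5e-5,                    # AKT recruitment (keeps pAKT mid-range)
    kcat_feedback = 5e-5,               # ERK -> receptor desensitization
    promoter = list(
      rnap = 30,
      k_rnap = 0.000280, # set so that physiologic P(RNAPbound) is near 0.5
      omega_weak = 2, omega_strong = 40,
      Kd = c(bCat_TCF7L2 = 30, GRO_TCF7L2 = 30,
             SMAD4_TCF7L2 = 40, pSMAD2_SMAD4 = 40, pSMAD3_SMAD4 = 40,
             AP1 = 120, AP1_p = 40,
             TP53 = 200,
             E2F_DP1 = 40, E2F_DP1_RB = 40)
    )
  )
}

#' Generate the seeded toy signaling network
#'
#' Builds a miniature three-pathway molecular interaction map wired into the
#' five-site MYC/CCND1 promoter: an EGF receptor layer (EGF:EGFR dimer, an
#' EGFR:ErbB2 heterodimer that drives PI3K), a
#' KRAS-BRAF-MEK-ERK cascade with double ERK phosphorylation,
#' phosphatase-mediated inactivation of every phospho-form and an optional
#' ERK-to-receptor negative feedback; a PI3K/PIP3/AKT arm opposed by PTEN;
#' and a WNT arm with the Axin:GSK3B:APC beta-Catenin destruction complex,
#' Tankyrase-controlled Axin turnover, E-Cadherin sequestration of
#' beta-Catenin, and TCF7L2 complexes feeding the promoter. The TGF-beta/
#' SMAD arm and the AP1/TP53/E2F-DP1/RB transcription-factor species are
#' always present. The generator is deterministic given the spec.
#'
#' @param spec A [toy_spec()].
#' @return A validated `network_model` with promoter configuration, endpoint
#'   annotations and a `manifest` recording the directed-process count.
#' @export
make_toy_mim <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  if (length(spec$pathways) == 0L) rlang::abort("no pathway enabled")
  pars <- toy_parameters()
  conc <- pars$conc
  egf <- "egf_mapk" %in% spec$pathways
  pi3k <- "pi3k_akt" %in% spec$pathways
  wnt <- "wnt" %in% spec$pathways
  receptors <- egf || pi3k

  sp <- list(); rev <- list(); cat_ <- list()
  add_sp <- function(...) sp[[length(sp) + 1L]] <<- species_decl(...)
  add_rev <- function(id, r, p) {
    rev[[length(rev) + 1L]] <<-
      reversible_reaction(id, r, p, pars$kon, pars$koff)
  }
  add_cat <- function(id, e, s, p, kcat) {
    cat_[[length(cat_) + 1L]] <<- catalytic_reaction(id, e, s, p, kcat)
  }
  ka <- pars$kcat_act; kd <- pars$kcat_deact

  add_sp("PP", "basic", conc[["PP"]])

  if (receptors) {
    add_sp("EGF", "basic", conc[["EGF"]])
    add_sp("EGFR", "basic", conc[["EGFR"]])
    add_sp("ErbB2", "basic", conc[["ErbB2"]])
    add_sp("EGF_EGFR", "complex", 0, composition = c("EGF", "EGFR"))
    add_sp("EGF_EGFR_ErbB2", "complex", 0,
           composition = c("EGF", "EGFR", "ErbB2"))
    add_rev("bind_egf", c("EGF", "EGFR"), "EGF_EGFR")
    add_rev("bind_erbb2", c("EGF_EGFR", "ErbB2"), "EGF_EGFR_ErbB2")
  }
  if (egf) {
    add_sp("KRAS", "basic", conc[["KRAS"]])
    add_sp("KRAS_GTP", "modified", 0, composition = "KRAS")
    add_sp("GAP", "basic", conc[["GAP"]])
    add_sp("BRAF", "basic", conc[["BRAF"]])
    add_sp("BRAF_p", "modified", 0, composition = "BRAF")
    add_sp("MEK", "basic", conc[["MEK"]])
    add_sp("MEK_PP", "modified", 0, composition = "MEK")
    add_sp("ERK", "basic", conc[["ERK"]])
    add_sp("ERK_P", "modified", 0, composition = "ERK")
    add_sp("ERK_PP", "modified", 0, composition = "ERK")
    add_sp("AP1", "basic", conc[["AP1"]])
    add_sp("AP1_p", "modified", 0, composition = "AP1")
    add_cat("kras_activation", "EGF_EGFR", "KRAS", "KRAS_GTP", ka)
    add_cat("kras_gap", "GAP", "KRAS_GTP", "KRAS", kd)
    add_cat("braf_activation", "KRAS_GTP", "BRAF", "BRAF_p", ka)
    add_cat("braf_dephos", "PP", "BRAF_p", "BRAF", kd)
    add_cat("mek_activation", "BRAF_p", "MEK", "MEK_PP", ka)
    add_cat("mek_dephos", "PP", "MEK_PP", "MEK", kd)
    add_cat("erk_phos1", "MEK_PP", "ERK", "ERK_P", ka)
    add_cat("erk_phos2", "MEK_PP", "ERK_P", "ERK_PP", ka)
    add_cat("erk_dephos2", "PP", "ERK_PP", "ERK_P", kd)
    add_cat("erk_dephos1", "PP", "ERK_P", "ERK", kd)
    add_cat("ap1_phos", "ERK_PP", "AP1", "AP1_p", ka)
    add_cat("ap1_dephos", "PP", "AP1_p", "AP1", kd)
    if (spec$include_feedback) {
      add_sp("EGF_EGFR_i", "modified", 0, composition = c("EGF", "EGFR"))
      add_cat("receptor_feedback", "ERK_PP", "EGF_EGFR", "EGF_EGFR_i",
              pars$kcat_feedback)
      add_cat("receptor_recovery", "PP", "EGF_EGFR_i", "EGF_EGFR", kd)
    }
  }
  if (pi3k) {
    add_sp("PI3K", "basic", conc[["PI3K"]])
    add_sp("PI3K_a", "modified", 0, composition = "PI3K")
    add_sp("PIP2", "basic", conc[["PIP2"]])
    add_sp("PIP3", "modified", 0, composition = "PIP2")
    add_sp("PTEN", "basic", conc[["PTEN"]])
    add_sp("AKT", "basic", conc[["AKT"]])
    add_sp("AKT_p", "modified", 0, composition = "AKT")
    add_cat("pi3k_activation", "EGF_EGFR_ErbB2", "PI3K", "PI3K_a", ka)
    add_cat("pi3k_inactivation", "PP", "PI3K_a", "PI3K", kd)
    add_cat("pip3_production", "PI3K_a", "PIP2", "PIP3", ka)
    add_cat("pip3_pten", "PTEN", "PIP3", "PIP2", kd)
    add_cat("akt_activation", "PIP3", "AKT", "AKT_p", pars$kcat_akt)
    add_cat("akt_dephos", "PP", "AKT_p", "AKT", kd)
  }
  if (wnt) {
    add_sp("GSK3B", "basic", conc[["GSK3B"]])
    add_sp("Axin", "basic", conc[["Axin"]])
    add_sp("Axin_i", "modified", 0, composition = "Axin")
    add_sp("TNKS", "basic", conc[["TNKS"]])
    add_sp("APC", "basic", conc[["APC"]])
    add_sp("Axin_GSK3B", "complex", 0, composition = c("Axin", "GSK3B"))
    add_sp("DC", "complex", 0, composition = c("Axin", "GSK3B", "APC"))
    add_sp("CTNNB1", "basic", conc[["CTNNB1"]])
    add_sp("CTNNB1_p", "modified", 0, composition = "CTNNB1")
    add_sp("TCF7L2", "basic", conc[["TCF7L2"]])
    add_sp("bCat_TCF7L2", "complex", 0, composition = c("CTNNB1", "TCF7L2"))
    add_sp("GRO", "basic", conc[["GRO"]])
    add_sp("GRO_TCF7L2", "complex", 0, composition = c("GRO", "TCF7L2"))
    add_sp("CDH1", "basic", conc[["CDH1"]])
    add_sp("CDH1_CTNNB1", "complex", 0, composition = c("CDH1", "CTNNB1"))
    add_rev("bind_axin_gsk3b", c("Axin", "GSK3B"), "Axin_GSK3B")
    add_rev("bind_dc", c("Axin_GSK3B", "APC"), "DC")
    add_rev("bind_bcat_tcf", c("CTNNB1", "TCF7L2"), "bCat_TCF7L2")
    add_rev("bind_gro_tcf", c("GRO", "TCF7L2"), "GRO_TCF7L2")
    add_rev("bind_cdh1_bcat", c("CDH1", "CTNNB1"), "CDH1_CTNNB1")
    add_cat("bcat_phosphorylation", "DC", "CTNNB1", "CTNNB1_p", ka)
    add_cat("bcat_dephos", "PP", "CTNNB1_p", "CTNNB1", kd)
    add_cat("axin_degradation", "TNKS", "Axin", "Axin_i", ka)
    add_cat("axin_recovery", "PP", "Axin_i", "Axin", kd)
    if (pi3k) {
      add_sp("GSK3B_p", "modified", 0, composition = "GSK3B")
      add_cat("gsk3b_inhibition", "AKT_p", "GSK3B", "GSK3B_p",
              pars$kcat_feedback)
      add_cat("gsk3b_recovery", "PP", "GSK3B_p", "GSK3B", kd)
    }
  }
  # TGF-beta/SMAD arm and general TF species (always present)
  add_sp("TGFB", "basic", conc[["TGFB"]])
  add_sp("TGFBR2", "basic", conc[["TGFBR2"]])
  add_sp("TGFB_TGFBR2", "complex", 0, composition = c("TGFB", "TGFBR2"))
  add_sp("SMAD2", "basic", conc[["SMAD2"]])
  add_sp("SMAD2_p", "modified", 0, composition = "SMAD2")
  add_sp("SMAD3", "basic", conc[["SMAD3"]])
  add_sp("SMAD3_p", "modified", 0, composition = "SMAD3")
  add_sp("SMAD4", "basic", conc[["SMAD4"]])
  add_sp("pSMAD2_SMAD4", "complex", 0, composition = c("SMAD2", "SMAD4"))
  add_sp("pSMAD3_SMAD4", "complex", 0, composition = c("SMAD3", "SMAD4"))
  add_rev("bind_tgfb", c("TGFB", "TGFBR2"), "TGFB_TGFBR2")
  add_rev("bind_psmad2_smad4", c("SMAD2_p", "SMAD4"), "pSMAD2_SMAD4")
  add_rev("bind_psmad3_smad4", c("SMAD3_p", "SMAD4"), "pSMAD3_SMAD4")
  add_cat("smad2_phos", "TGFB_TGFBR2", "SMAD2", "SMAD2_p", ka)
  add_cat("smad2_dephos", "PP", "SMAD2_p", "SMAD2", kd)
  add_cat("smad3_phos", "TGFB_TGFBR2", "SMAD3", "SMAD3_p", ka)
  add_cat("smad3_dephos", "PP", "SMAD3_p", "SMAD3", kd)
  if (wnt) {
    add_sp("SMAD4_TCF7L2", "complex", 0, composition = c("SMAD4", "TCF7L2"))
    add_rev("bind_smad4_tcf", c("SMAD4", "TCF7L2"), "SMAD4_TCF7L2")
  }
  if (!egf) add_sp("AP1", "basic", conc[["AP1"]])
  add_sp("TP53", "basic", conc[["TP53"]])
  add_sp("E2F", "basic", conc[["E2F"]])
  add_sp("DP1", "basic", conc[["DP1"]])
  add_sp("E2F_DP1", "complex", 0, composition = c("E2F", "DP1"))
  add_sp("RB", "basic", conc[["RB"]])
  add_sp("E2F_DP1_RB", "complex", 0, composition = c("E2F", "DP1", "RB"))
  add_rev("bind_e2f_dp1", c("E2F", "DP1"), "E2F_DP1")
  add_rev("bind_e2f_rb", c("E2F_DP1", "RB"), "E2F_DP1_RB")
  add_sp("MYC_mRNA", "mRNA", 0)
  add_sp("CCND1_mRNA", "mRNA", 0)

  species <- dplyr::bind_rows(sp)

  # promoter wiring restricted to species the enabled pathways create
  pp <- pars$promoter
  kds <- pp$Kd
  present <- species$id
  bind_if <- function(id, mode, omega = NA_real_) {
    if (!id %in% present) return(NULL)
    tf_binding(id, kds[[id]], mode, omega)
  }
  site_rows <- function(...) {
    rows <- Filter(Negate(is.null), list(...))
    if (length(rows)) dplyr::bind_rows(rows) else tf_binding("none", 1, "activator", 1)[0, ]
  }
  sites <- list(
    tfbs_config("TFBS_TCF7L2", site_rows(
      bind_if("bCat_TCF7L2", "activator", pp$omega_strong),
      bind_if("GRO_TCF7L2", "repressor"))),
    tfbs_config("TFBS_SMAD4", site_rows(
      bind_if("SMAD4_TCF7L2", "activator", pp$omega_weak),
      bind_if("pSMAD2_SMAD4", "repressor"),
      bind_if("pSMAD3_SMAD4", "repressor"))),
    tfbs_config("TFBS_AP1", site_rows(
      bind_if("AP1", "activator", pp$omega_weak),
      bind_if("AP1_p", "activator", pp$omega_strong))),
    tfbs_config("TFBS_TP53", site_rows(bind_if("TP53", "repressor"))),
    tfbs_config("TFBS_E2F-DP1", site_rows(
      bind_if("E2F_DP1", "activator", pp$omega_weak),
      bind_if("E2F_DP1_RB", "repressor")))
  )
  promoter <- promoter_config(sites = sites, rnap = pp$rnap,
                              k_rnap = pp$k_rnap)

  annotations <- list(
    endpoints = list(
      ERK = list(active = "ERK_PP", moiety = "ERK"),
      AKT = list(active = "AKT_p", moiety = "AKT")
    ),
    active_forms = list(
      KRAS = "KRAS_GTP", BRAF = "BRAF_p", PI3K = "PI3K_a",
      CTNNB1 = "CTNNB1", ERK = "ERK_PP", AKT = "AKT_p", GSK3B = "GSK3B"
    )
  )

  m <- network_model(species, dplyr::bind_rows(rev), dplyr::bind_rows(cat_),
                     annotations = annotations, promoter = promoter)
  m$seed <- spec$seed
  m$manifest <- list(
    n_species = nrow(m$species),
    n_reversible = nrow(m$reversible),
    n_catalytic = nrow(m$catalytic),
    n_processes = n_rate_processes(m),
    pathways = spec$pathways,
    include_feedback = spec$include_feedback
  )
  m
}

# run code under a temporary RNG state seeded from `seed`
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate pseudo-experimental readout tables
#'
#' Runs [run_experiment()] for the ground truth, then multiplies every
#' readout by multiplicative lognormal noise with median 1 and the requested
#' coefficient of variation, emitting `n_replicates` rows per treatment x
#' endpoint x time - a stand-in for wet biological duplicates. Seeded and
#' bit-reproducible given `(spec$seed, spec)`.
#'
#' @param model A `network_model` (typically [make_toy_mim()]).
#' @param genotype A [genotype()].
#' @param plan A [treatment_plan()].
#' @param spec A [toy_spec()] supplying `noise$cv`, `noise$n_replicates` and
#'   the seed.
#' @param inhibitors Optional named [inhibitor_spec()] overrides.
#' @param settings A [solver_settings()].
#' @return Tibble with columns `treatment`, `endpoint`, `time_s`,
#'   `replicate`, `value`.
#' @export
make_pseudo_experiments <- function(model, genotype, plan, spec,
                                    inhibitors = NULL,
                                    settings = solver_settings()) {
  truth <- run_experiment(model, genotype, plan, inhibitors = inhibitors,
                          settings = settings)
  cv <- spec$noise$cv
  n_rep <- spec$noise$n_replicates
  sdlog <- sqrt(log(1 + cv^2))
  with_rng_seed(spec$seed, {
    truth |>
      dplyr::filter(!.data$undefined) |>
      dplyr::select(-"undefined") |>
      tidyr::crossing(replicate = seq_len(n_rep)) |>
      dplyr::mutate(value = .data$value *
                      stats::rlnorm(dplyr::n(), meanlog = 0, sdlog = sdlog))
  })
}

#' Inhibitor-calibration recovery harness
#'
#' For each true activity-scaling strength, measures the resulting readout
#' inhibition on the model (noiselessly, or with lognormal noise of the
#' given cv), hands that observed level to [calibrate_inhibitor()], and
#' reports the absolute error of the recovered strength. A non-monotone
#' observed dose-response is flagged.
#'
#' @param model A `network_model`.
#' @param f_true Numeric vector of true strengths in `[0, 1)`.
#' @param seed Integer seed (used only when `noise_cv > 0`).
#' @param spec Inhibitor whose target is exercised (default the bundled MEK
#'   inhibitor).
#' @param readout Endpoint moiety (default `"ERK"`).
#' @param genotype Background genotype (default physiologic).
#' @param readout_time Seconds (default 1800).
#' @param noise_cv Lognormal cv applied to the observed readout (0 = none).
#' @param settings A [solver_settings()].
#' @return Tibble: `f_true`, `observed_inhibition`, `recovered`,
#'   `abs_error`, `monotone`.
#' @export
parameter_recovery_harness <- function(model, f_true, seed = 1L,
                                       spec = inhibitor_preset("CI1040"),
                                       readout = "ERK",
                                       genotype = genotype_preset("physiologic"),
                                       readout_time = 1800, noise_cv = 0,
                                       settings = solver_settings()) {
  stopifnot(all(f_true >= 0), all(f_true < 1))
  m <- apply_genotype(model, genotype)
  eq <- equilibrate(m, settings = settings)
  control <- phospho_ratio(
    simulate_model(m, state0 = eq, t_end = readout_time, settings = settings,
                   times = c(0, readout_time / 2, readout_time)),
    readout, readout_time)
  observed <- vapply(f_true, function(f) {
    r <- inhibited_readout(m, eq, spec, f, readout, readout_time, settings,
                           control)
    1 - r
  }, numeric(1))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    observed <- with_rng_seed(seed, {
      1 - (1 - observed) * stats::rlnorm(length(observed), 0, sdlog)
    })
    observed <- pmin(pmax(observed, 0), 1 - 1e-9)
  }
  monotone <- !is.unsorted(observed[order(f_true)], strictly = FALSE)
  recovered <- vapply(seq_along(f_true), function(i) {
    if (observed[i] <= 0) return(0)
    calibrate_inhibitor(model, genotype, spec, f_desired = observed[i],
                        readout = readout, readout_time = readout_time,
                        settings = settings)$f
  }, numeric(1))
  tibble::tibble(
    f_true = f_true, observed_inhibition = observed, recovered = recovered,
    abs_error = abs(recovered - f_true), monotone = monotone
  )
}
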