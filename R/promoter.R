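#' Declare a transcription-factor binding at a promoter site
#'
#' @param species_id Id of the network species acting as this TF form.
#' @param Kd Dissociation constant for TF-site binding (nM, > 0).
#' @param mode `"activator"` or `"repressor"`.
#' @param omega Activation weight (dimensionless, >= 1); the fold increase of
#'   the RNAP-binding weight contributed by the bound activator. Activators
#'   only.
#' @return One-row tibble for a site's binding table.
#' @export
tf_binding <- function(species_id, Kd, mode = c("activator", "repressor"),
                       omega = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(Kd > 0)
  if (mode == "activator") {
    if (is.na(omega) || omega < 1) {
      rlang::abort(paste0("activator '", species_id, "' needs omega >= 1"))
    }
  } else if (!is.na(omega)) {
    rlang::abort(paste0("repressor '", species_id, "' must not carry omega"))
  }
  tibble::tibble(species_id = species_id, Kd = as.numeric(Kd),
                 mode = mode, omega = as.numeric(omega))
}

#' The five promoter binding-site names
#' @return Character vector of the canonical site names.
#' @export
tfbs_site_names <- function() {
  c("TFBS_TCF7L2", "TFBS_SMAD4", "TFBS_AP1", "TFBS_TP53", "TFBS_E2F-DP1")
}

#' Configure one transcription-factor binding site
#'
#' @param site_name One of [tfbs_site_names()].
#' @param bindings Tibble of [tf_binding()] rows (possibly empty).
#' @return A `tfbs_config` list.
#' @export
tfbs_config <- function(site_name, bindings) {
  site_name <- match.arg(site_name, tfbs_site_names())
  structure(list(site_name = site_name,
                 bindings = tibble::as_tibble(bindings)),
            class = "tfbs_config")
}

#' Default five-site promoter wiring
#'
#' The model promoter shared by MYC and CCND1 carries five binding sites.
#' The default wiring assigns: TCF7L2 site - beta-Catenin:TCF7L2 (`x1`) and
#' pY654-beta-Catenin:TCF7L2 (`x1p`) as activators, GROUCHO:TCF7L2 (`y1`) as
#' repressor; SMAD4 site - SMAD4:TCF7L2 (`x2`) activator, pSMAD2:SMAD4
#' (`y2`) and pSMAD3:SMAD4 (`y3`) repressors; AP1 site - AP1 (`x3`) and pAP1
#' (`x3p`) activators (no repressor); TP53 site - TP53 (`y4`) repressor;
#' E2F-DP1 site - E2F:DP1 (`x4`) activator, E2F:DP1:RB (`y5`) repressor.
#'
#' @param Kd Default TF-site dissociation constant (nM) used for every
#'   binding unless overridden downstream.
#' @param omega Default activation weight for activators.
#' @param species Named list overriding the default species ids for the
#'   eleven TF forms (names `x1, x1p, x2, x3, x3p, x4, y1, y2, y3, y4, y5`).
#' @return List of five `tfbs_config` objects.
#' @export
default_promoter_sites <- function(Kd = 50, omega = 10, species = list()) {
  ids <- utils::modifyList(list(
    x1 = "bCat_TCF7L2", x1p = "pbCat_TCF7L2", x2 = "SMAD4_TCF7L2",
    x3 = "AP1", x3p = "AP1_p", x4 = "E2F_DP1",
    y1 = "GRO_TCF7L2", y2 = "pSMAD2_SMAD4", y3 = "pSMAD3_SMAD4",
    y4 = "TP53", y5 = "E2F_DP1_RB"
  ), species)
  act <- function(s) tf_binding(s, Kd, "activator", omega)
  rep_ <- function(s) tf_binding(s, Kd, "repressor")
  list(
    tfbs_config("TFBS_TCF7L2",
                dplyr::bind_rows(act(ids$x1), act(ids$x1p), rep_(ids$y1))),
    tfbs_config("TFBS_SMAD4",
                dplyr::bind_rows(act(ids$x2), rep_(ids$y2), rep_(ids$y3))),
    tfbs_config("TFBS_AP1", dplyr::bind_rows(act(ids$x3), act(ids$x3p))),
    tfbs_config("TFBS_TP53", rep_(ids$y4)),
    tfbs_config("TFBS_E2F-DP1", dplyr::bind_rows(act(ids$x4), rep_(ids$y5)))
  )
}

#' Configure the shared MYC/CCND1 model promoter
#'
#' MYC and CCND1 share one promoter architecture and one synthesis rate; they
#' differ only in mRNA degradation rate. Defaults follow the model constants:
#' `ksynth = 5e-5`/s for both genes, `kdeg = 2.7e-4`/s (MYC, half-life about
#' 43 min) and `5.7e-6`/s (CCND1, half-life about 34 h).
#'
#' @param sites List of five `tfbs_config`s, one per site name (see
#'   [default_promoter_sites()]).
#' @param rnap RNA-polymerase-II concentration `[RNAP]` (nM).
#' @param k_rnap RNAP binding constant; with the default
#'   `k_rnap_mode = "association"` it multiplies (units 1/nM), with
#'   `"inverse_kd"` it divides (units nM).
#' @param k_rnap_mode `"association"` or `"inverse_kd"`.
#' @param genes Named list, one entry per gene:
#'   `list(ksynth =, kdeg =, mrna_species =)`.
#' @return A `promoter_config` object.
#' @export
promoter_config <- function(sites = default_promoter_sites(),
                            rnap = 30, k_rnap = 1 / 30,
                            k_rnap_mode = c("association", "inverse_kd"),
                            genes = list(
                              MYC = list(ksynth = 5e-5, kdeg = 2.7e-4,
                                         mrna_species = "MYC_mRNA"),
                              CCND1 = list(ksynth = 5e-5, kdeg = 5.7e-6,
                                           mrna_species = "CCND1_mRNA")
                            )) {
  k_rnap_mode <- match.arg(k_rnap_mode)
  nm <- vapply(sites, function(s) s$site_name, character(1))
  if (!setequal(nm, tfbs_site_names()) || anyDuplicated(nm)) {
    rlang::abort("promoter needs each of the five TFBS exactly once")
  }
  stopifnot(rnap > 0, k_rnap > 0)
  for (g in names(genes)) {
    stopifnot(genes[[g]]$ksynth >= 0, genes[[g]]$kdeg > 0)
  }
  structure(list(sites = sites[order(match(nm, tfbs_site_names()))],
                 rnap = rnap, k_rnap = k_rnap, k_rnap_mode = k_rnap_mode,
                 genes = genes),
            class = "promoter_config")
}

#' Regulation factor of a single binding site
#'
#' Thermodynamic-occupancy factor for one site with competing activators and
#' repressors (single occupancy per site):
#' `F = (1 + sum_a omega_a [a]/Kd_a) / (1 + sum_a [a]/Kd_a + sum_r [r]/Kd_r)`.
#' An empty site (all TF concentrations zero) contributes `F = 1`; a
#' saturating repressor drives `F` to 0; a saturating activator drives `F`
#' toward its `omega`.
#'
#' @param site A `tfbs_config`.
#' @param state Named numeric vector of species concentrations (nM); every
#'   bound species must be present and non-negative.
#' @return Dimensionless factor `F >= 0`.
#' @export
site_regulation_factor <- function(site, state) {
  b <- site$bindings
  if (nrow(b) == 0L) return(1)
  miss <- setdiff(b$species_id, names(state))
  if (length(miss)) {
    rlang::abort(paste0("site ", site$site_name,
                        ": species absent from state: ",
                        paste(miss, collapse = ", ")))
  }
  conc <- state[b$species_id]
  if (any(conc < 0)) {
    rlang::abort(paste0("site ", site$site_name,
                        ": negative concentration for ",
                        paste(b$species_id[conc < 0], collapse = ", ")))
  }
  x <- conc / b$Kd
  is_act <- b$mode == "activator"
  num <- 1 + sum(b$omega[is_act] * x[is_act])
  den <- 1 + sum(x)
  num / den
}

#' Promoter-level regulation factor
#'
#' Under the independence-of-sites assumption the promoter regulation factor
#' is the product of the five site factors,
#' `F_reg = F_TCF7L2 * F_SMAD4 * F_AP1 * F_TP53 * F_E2F-DP1`.
#'
#' @param config A `promoter_config`.
#' @param state Named species concentration vector (nM).
#' @return Dimensionless `F_reg >= 0`.
#' @export
promoter_regulation_factor <- function(config, state) {
  prod(vapply(config$sites, site_regulation_factor, numeric(1), state = state))
}

#' Probability that RNA polymerase is bound at the promoter
#'
#' `P = z / (1 + z)` with `z = [RNAP] * k_RNAP * F_reg` (or
#' `z = [RNAP] / k_RNAP * F_reg` when the binding constant is configured as a
#' dissociation constant). `P` is in `[0, 1]` and monotone nondecreasing in
#' `[RNAP]`, `k_RNAP` (association mode) and `F_reg`.
#'
#' @param F_reg Promoter regulation factor (>= 0).
#' @param config A `promoter_config`.
#' @return Probability in `[0, 1]`.
#' @export
p_rnap_bound <- function(F_reg, config) {
  stopifnot(F_reg >= 0)
  k <- if (config$k_rnap_mode == "association") config$k_rnap else 1 / config$k_rnap
  z <- config$rnap * k * F_reg
  z / (1 + z)
}

#' Instantaneous mRNA production/degradation rate
#'
#' `d(mRNA)/dt = ksynth * P(RNAPbound) - kdeg * mRNA`, a linear ODE whose
#' steady state is `ksynth * P / kdeg`.
#'
#' @param gene Gene name (must exist in `config$genes`).
#' @param P Probability of RNAP binding, in `[0, 1]`.
#' @param mrna_level Current mRNA level (>= 0, model units).
#' @param config A `promoter_config`.
#' @param kdeg_effective Optional override of the gene's degradation rate
#'   (1/s), e.g. from [ccnd1_kdeg_modifier()].
#' @return d(mRNA)/dt in model units per second.
#' @export
mrna_rate <- function(gene, P, mrna_level, config, kdeg_effective = NULL) {
  stopifnot(P >= 0, P <= 1, mrna_level >= 0)
  g <- config$genes[[gene]]
  if (is.null(g)) rlang::abort(paste0("unknown gene: ", gene))
  kdeg <- kdeg_effective %||% g$kdeg
  g$ksynth * P - kdeg * mrna_level
}

#' mRNA half-life from a first-order degradation rate
#'
#' @param kdeg Degradation rate constant (1/s, > 0).
#' @return Half-life `ln(2)/kdeg` in hours.
#' @export
#' @examples
#' mrna_half_life(2.7e-4) # MYC: about 0.71 h, well under 2 h
#' mrna_half_life(5.7e-6) # CCND1: about 34 h
mrna_half_life <- function(kdeg) {
  if (kdeg <= 0) rlang::abort("kdeg must be > 0")
  log(2) / kdeg / 3600
}

#' CCND1 mRNA destabilization under MEK inhibition
#'
#' MEK inhibition destabilizes CCND1 mRNA in inverse proportion to the
#' residual degree of ERK phosphorylation:
#' `kdeg_effective = kdeg_control * (ERKPP_control / ERKPP_treated)`.
#' With no inhibitor effect (ratio 1) the rate is unchanged; near-total ERK
#' inhibition is guarded by a floor on the treated ERKPP level (default
#' `1e-6` of control), at which the ratio is capped with a warning.
#'
#' @param kdeg_control Baseline CCND1 degradation rate (1/s).
#' @param erkpp_control Doubly phosphorylated ERK level in the untreated
#'   condition (nM, > 0).
#' @param erkpp_treated Doubly phosphorylated ERK level under the MEK
#'   inhibitor (nM, >= 0).
#' @param floor_frac Fraction of `erkpp_control` used as the floor for
#'   `erkpp_treated`.
#' @return Effective degradation rate (1/s).
#' @export
ccnd1_kdeg_modifier <- function(kdeg_control, erkpp_control, erkpp_treated,
                                floor_frac = 1e-6) {
  stopifnot(kdeg_control > 0, erkpp_control > 0, erkpp_treated >= 0)
  floor_ <- floor_frac * erkpp_control
  if (erkpp_treated <= floor_) {
    rlang::warn(paste0("ERKPP under treatment at or below the guard floor (",
                       format(floor_), " nM): ratio capped; ",
                       "near-total ERK inhibition"))
    erkpp_treated <- floor_
  }
  kdeg_control * (erkpp_control / erkpp_treated)
}
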