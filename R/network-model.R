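#' Declare a species for a kinetic network model
#'
#' A species is a node of the reaction network: an unbound basic protein, a
#' post-translationally modified form, a multi-protein complex, a drug
#' (inhibitor) molecule, or an mRNA. Every non-mRNA species carries a
#' *composition*: the multiset of basic-protein identifiers it contains
#' (a basic protein contains itself, a phospho-form contains its basic
#' protein, a complex contains the union of its parts). Compositions are what
#' make moiety bookkeeping and moiety-balance validation possible.
#'
#' @param id Unique species identifier (character scalar).
#' @param role One of `"basic"`, `"modified"`, `"complex"`, `"inhibitor"`,
#'   `"mRNA"`.
#' @param conc Initial concentration in nM (non-negative).
#' @param composition Character vector of basic-protein ids contained in this
#'   species, with multiplicity (e.g. `c("A", "A", "B")` for an A2B complex).
#'   Defaults to `id` itself for `basic` and `inhibitor` roles and to empty
#'   for `mRNA`.
#' @param name Free-text display name; defaults to `id`.
#'
#' @return A one-row tibble suitable for binding into a species sheet.
#' @export
#' @examples
#' species_decl("ERK", "basic", 150)
#' species_decl("ERK_PP", "modified", 0, composition = "ERK")
species_decl <- function(id, role, conc,
                         composition = NULL, name = id) {
  stopifnot(is.character(id), length(id) == 1L)
  role <- match.arg(role, c("basic", "modified", "complex", "inhibitor", "mRNA"))
  if (is.null(composition)) {
    composition <- if (role %in% c("basic", "inhibitor")) id else character(0)
  }
  tibble::tibble(
    id = id, name = name, role = role,
    composition = list(as.character(composition)),
    conc = as.numeric(conc)
  )
}

#' Declare a reversible (binding/unbinding) reaction
#'
#' Mass-action reversible reaction with forward rate constant `kon`
#' (1/s if unimolecular, 1/(nM s) if bimolecular) and reverse rate constant
#' `koff` (same convention on the product side). At most two reactants and
#' two products are allowed.
#'
#' @param id Unique reaction identifier.
#' @param reactants,products Character vectors of species ids (length 1-2).
#' @param kon,koff Non-negative rate constants.
#' @return A one-row tibble for the reversible-reaction sheet.
#' @export
reversible_reaction <- function(id, reactants, products, kon, koff) {
  stopifnot(length(reactants) %in% 1:2, length(products) %in% 1:2,
            kon >= 0, koff >= 0)
  tibble::tibble(
    id = id,
    reactants = list(as.character(reactants)),
    products = list(as.character(products)),
    kon = as.numeric(kon), koff = as.numeric(koff)
  )
}

#' Declare a catalytic reaction
#'
#' An enzyme converts a substrate into a product of identical composition
#' (catalysis changes form, never creates or destroys moieties). The rate law
#' is either mass action, `v = kcat [E] [S]` with `kcat` in 1/(nM s), or
#' Michaelis-Menten, `v = kcat [E] [S] / (Km + [S])` with `kcat` in 1/s and
#' `Km` in nM.
#'
#' @param id Unique reaction identifier.
#' @param enzyme,substrate,product Species ids.
#' @param kcat Catalytic rate constant (non-negative).
#' @param law `"mass_action"` (default) or `"michaelis_menten"`.
#' @param Km Michaelis constant in nM; required (> 0) for
#'   `"michaelis_menten"`, ignored otherwise.
#' @return A one-row tibble for the catalytic-reaction sheet.
#' @export
catalytic_reaction <- function(id, enzyme, substrate, product, kcat,
                               law = c("mass_action", "michaelis_menten"),
                               Km = NA_real_) {
  law <- match.arg(law)
  stopifnot(kcat >= 0)
  if (law == "michaelis_menten" && (is.na(Km) || Km <= 0)) {
    rlang::abort(paste0("catalytic reaction '", id,
                        "': michaelis_menten law requires Km > 0"))
  }
  tibble::tibble(
    id = id, enzyme = enzyme, substrate = substrate, product = product,
    law = law, kcat = as.numeric(kcat), Km = as.numeric(Km)
  )
}

#' Assemble a kinetic network model
#'
#' Bundles the species sheet and the two reaction sheets into a validated
#' `network_model` object, the simulatable unit of the package. Annotations
#' carry semantic metadata the readout layer needs (which species are the
#' phosphorylated ERK/AKT forms, which moiety each endpoint tracks, the
#' active form of each signaling protein for constitutive-activation
#' mutations). An optional promoter configuration (see [promoter_config()])
#' couples mRNA species to the transcription-rate function.
#'
#' @param species Tibble of species rows (see [species_decl()]).
#' @param reversible Tibble of reversible reactions, or `NULL`.
#' @param catalytic Tibble of catalytic reactions, or `NULL`.
#' @param annotations Named list. Recognized entries:
#'   `active_forms` (named list: moiety id -> active-form species ids),
#'   `endpoints` (named list: endpoint name -> list(active =, moiety =)).
#' @param promoter A [promoter_config()] or `NULL`.
#' @param validate Run [validate_network_model()] (default `TRUE`).
#'
#' @return An object of class `network_model`.
#' @export
#' @examples
#' m <- network_model(
#'   species = dplyr::bind_rows(
#'     species_decl("A", "basic", 100),
#'     species_decl("B", "basic", 50),
#'     species_decl("AB", "complex", 0, composition = c("A", "B"))
#'   ),
#'   reversible = reversible_reaction("bind", c("A", "B"), "AB", 1e-3, 1e-2)
#' )
#' moiety_totals(m)
network_model <- function(species, reversible = NULL, catalytic = NULL,
                          annotations = list(), promoter = NULL,
                          validate = TRUE) {
  empty_rev <- tibble::tibble(
    id = character(0), reactants = list(), products = list(),
    kon = numeric(0), koff = numeric(0)
  )
  empty_cat <- tibble::tibble(
    id = character(0), enzyme = character(0), substrate = character(0),
    product = character(0), law = character(0), kcat = numeric(0),
    Km = numeric(0)
  )
  m <- structure(
    list(
      species = tibble::as_tibble(species),
      reversible = if (is.null(reversible)) empty_rev else tibble::as_tibble(reversible),
      catalytic = if (is.null(catalytic)) empty_cat else tibble::as_tibble(catalytic),
      annotations = annotations,
      promoter = promoter,
      # baseline initial concentrations: genotype directives scale relative
      # to these so that applying a genotype twice equals applying it once
      baseline_conc = stats::setNames(as.numeric(species$conc), species$id)
    ),
    class = "network_model"
  )
  if (validate) validate_network_model(m)
  m
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model>\n")
  cat("  species:   ", nrow(x$species),
      " (", paste0(utils::head(x$species$id, 6), collapse = ", "),
      if (nrow(x$species) > 6) ", ..." else "", ")\n", sep = "")
  cat("  reversible:", nrow(x$reversible), "\n")
  cat("  catalytic: ", nrow(x$catalytic), "\n")
  cat("  directed rate processes:", n_rate_processes(x), "\n")
  if (!is.null(x$promoter)) {
    cat("  promoter:  ", length(x$promoter$genes), "gene(s):",
        paste(names(x$promoter$genes), collapse = ", "), "\n")
  }
  invisible(x)
}

multiset_key <- function(x) paste(sort(x), collapse = "+")

#' Validate a network model
#'
#' Checks the structural invariants: unique species ids; valid roles;
#' non-negative initial concentrations; non-empty compositions for every role
#' except mRNA; every reaction referencing only declared species; at most two
#' reactants/products per reversible reaction; non-negative rate constants;
#' `Km > 0` for Michaelis-Menten laws; and moiety balance (the multiset union
#' of reactant compositions equals that of product compositions for
#' reversible reactions; substrate and product compositions are identical for
#' catalytic reactions, whose enzyme is unchanged).
#'
#' @param model A `network_model`.
#' @return The model, invisibly; aborts with an informative error otherwise.
#' @export
validate_network_model <- function(model) {
  sp <- model$species
  if (anyDuplicated(sp$id)) {
    rlang::abort(paste0("duplicate species ids: ",
                        paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))
  }
  bad_role <- setdiff(unique(sp$role),
                      c("basic", "modified", "complex", "inhibitor", "mRNA"))
  if (length(bad_role)) {
    rlang::abort(paste0("unknown species role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (any(sp$conc < 0)) {
    rlang::abort(paste0("negative initial concentration for: ",
                        paste(sp$id[sp$conc < 0], collapse = ", ")))
  }
  empty_comp <- sp$role != "mRNA" & lengths(sp$composition) == 0L
  if (any(empty_comp)) {
    rlang::abort(paste0("empty composition for non-mRNA species: ",
                        paste(sp$id[empty_comp], collapse = ", ")))
  }
  known <- sp$id
  comp_of <- stats::setNames(sp$composition, sp$id)

  rev <- model$reversible
  if (nrow(rev)) {
    if (any(lengths(rev$reactants) > 2L | lengths(rev$products) > 2L |
            lengths(rev$reactants) < 1L | lengths(rev$products) < 1L)) {
      rlang::abort("reversible reactions must have 1-2 reactants and 1-2 products")
    }
    refs <- unique(c(unlist(rev$reactants), unlist(rev$products)))
    miss <- setdiff(refs, known)
    if (length(miss)) {
      rlang::abort(paste0("reversible reactions reference unknown species: ",
                          paste(miss, collapse = ", ")))
    }
    if (any(rev$kon < 0 | rev$koff < 0)) {
      rlang::abort("kon/koff must be non-negative")
    }
    unbal <- purrr::map2_lgl(rev$reactants, rev$products, function(r, p) {
      multiset_key(unlist(comp_of[r])) != multiset_key(unlist(comp_of[p]))
    })
    if (any(unbal)) {
      rlang::abort(paste0("moiety balance violated in reversible reaction(s): ",
                          paste(rev$id[unbal], collapse = ", ")))
    }
  }

  cat_ <- model$catalytic
  if (nrow(cat_)) {
    refs <- unique(c(cat_$enzyme, cat_$substrate, cat_$product))
    miss <- setdiff(refs, known)
    if (length(miss)) {
      rlang::abort(paste0("catalytic reactions reference unknown species: ",
                          paste(miss, collapse = ", ")))
    }
    if (any(cat_$kcat < 0)) rlang::abort("kcat must be non-negative")
    mm <- cat_$law == "michaelis_menten"
    if (any(mm & (is.na(cat_$Km) | cat_$Km <= 0))) {
      rlang::abort(paste0("Km must be > 0 for michaelis_menten reaction(s): ",
                          paste(cat_$id[mm & (is.na(cat_$Km) | cat_$Km <= 0)],
                                collapse = ", ")))
    }
    unbal <- purrr::map2_lgl(cat_$substrate, cat_$product, function(s, p) {
      multiset_key(unlist(comp_of[s])) != multiset_key(unlist(comp_of[p]))
    })
    if (any(unbal)) {
      rlang::abort(paste0("moiety balance violated in catalytic reaction(s): ",
                          paste(cat_$id[unbal], collapse = ", ")))
    }
  }
  invisible(model)
}

#' Expand a model into its directed rate processes
#'
#' Every reversible reaction contributes two directed processes (forward and
#' reverse) and every catalytic reaction one, so a model with R reversible
#' and C catalytic reactions has 2R + C directed rate processes.
#'
#' @param model A `network_model`.
#' @return Tibble with columns `process_id`, `reaction_id`, `direction`
#'   (one of `"forward"`, `"reverse"`, `"catalytic"`).
#' @export
expand_rate_processes <- function(model) {
  rev <- model$reversible
  cat_ <- model$catalytic
  dplyr::bind_rows(
    if (nrow(rev)) tibble::tibble(
      process_id = paste0(rep(rev$id, each = 2), c("_fwd", "_rev")),
      reaction_id = rep(rev$id, each = 2),
      direction = rep(c("forward", "reverse"), nrow(rev))
    ),
    if (nrow(cat_)) tibble::tibble(
      process_id = paste0(cat_$id, "_cat"),
      reaction_id = cat_$id,
      direction = "catalytic"
    )
  ) %||% tibble::tibble(process_id = character(0),
                        reaction_id = character(0),
                        direction = character(0))
}

#' Number of directed rate processes in a model
#'
#' @param model A `network_model`.
#' @return Integer: `2 * nrow(reversible) + nrow(catalytic)`.
#' @export
n_rate_processes <- function(model) {
  2L * nrow(model$reversible) + nrow(model$catalytic)
}

#' Total concentration of each basic-protein moiety
#'
#' For each basic protein, sums the concentration of every species whose
#' composition contains it, counting multiplicity. In a closed model (no
#' synthesis or degradation) these totals are conserved along any simulated
#' trajectory.
#'
#' @param model A `network_model`.
#' @param state Optional named concentration vector (nM); defaults to the
#'   model's initial concentrations.
#' @return Named numeric vector of totals (nM), one per basic moiety.
#' @export
moiety_totals <- function(model, state = NULL) {
  sp <- model$species
  if (is.null(state)) state <- stats::setNames(sp$conc, sp$id)
  moieties <- sort(unique(unlist(sp$composition)))
  # multiplicity matrix: species x moiety
  counts <- vapply(moieties, function(m) {
    vapply(sp$composition, function(cmp) sum(cmp == m), numeric(1))
  }, numeric(nrow(sp)))
  counts <- matrix(counts, nrow = nrow(sp),
                   dimnames = list(sp$id, moieties))
  totals <- as.numeric(crossprod(counts, state[sp$id]))
  stats::setNames(totals, moieties)
}
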