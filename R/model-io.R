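#' Read a kinetic network model from disk
#'
#' Two formats are supported. The native tabular format is a pair of CSV
#' sheets, `<path>_species.csv` (columns `id, name, role, composition, conc`,
#' compositions `;`-separated) and `<path>_reactions.csv` (columns
#' `id, type, reactants, products, enzyme, substrate, product, law, kon,
#' koff, kcat, Km`); `path` is the common stem. The SBML format is a single
#' Level 3 file with explicit MathML kinetic laws; species roles and
#' compositions are carried in an annotation element and default to
#' basic/self-composition when absent, so plain mass-action SBML from other
#' tools also loads. Units are taken to be nM and seconds.
#'
#' @param path File stem (native) or file path (SBML).
#' @param format `"native_table"` or `"sbml"`.
#' @return A validated [network_model()].
#' @export
read_network_model <- function(path, format = c("native_table", "sbml")) {
  format <- match.arg(format)
  switch(format,
         native_table = read_native_model(path),
         sbml = read_sbml_model(path))
}

#' Write a kinetic network model to disk
#'
#' Inverse of [read_network_model()]; the written file(s) round-trip species
#' ids, roles, compositions, initial concentrations and all rate constants.
#' SBML output carries one explicit kinetic-law expression per reaction
#' (reversible mass action, mass-action catalysis, or Michaelis-Menten with
#' the `Km + S` denominator), so any SBML-aware simulator can integrate it.
#'
#' @param model A validated `network_model`.
#' @param path File stem (native) or file path (SBML).
#' @inheritParams read_network_model
#' @return `path`, invisibly.
#' @export
write_network_model <- function(model, path,
                                format = c("native_table", "sbml")) {
  format <- match.arg(format)
  validate_network_model(model)
  switch(format,
         native_table = write_native_model(model, path),
         sbml = write_sbml_model(model, path))
  invisible(path)
}

# ---- native tabular format ------------------------------------------------

native_paths <- function(path) {
  list(species = paste0(path, "_species.csv"),
       reactions = paste0(path, "_reactions.csv"))
}

write_native_model <- function(model, path) {
  p <- native_paths(path)
  sp <- model$species
  readr::write_csv(tibble::tibble(
    id = sp$id, name = sp$name, role = sp$role,
    composition = vapply(sp$composition, paste, character(1), collapse = ";"),
    conc = sp$conc
  ), p$species)
  rev <- model$reversible
  cat_ <- model$catalytic
  rx <- dplyr::bind_rows(
    if (nrow(rev)) tibble::tibble(
      id = rev$id, type = "reversible",
      reactants = vapply(rev$reactants, paste, character(1), collapse = ";"),
      products = vapply(rev$products, paste, character(1), collapse = ";"),
      enzyme = NA_character_, substrate = NA_character_,
      product = NA_character_, law = NA_character_,
      kon = rev$kon, koff = rev$koff, kcat = NA_real_, Km = NA_real_
    ),
    if (nrow(cat_)) tibble::tibble(
      id = cat_$id, type = "catalytic",
      reactants = NA_character_, products = NA_character_,
      enzyme = cat_$enzyme, substrate = cat_$substrate,
      product = cat_$product, law = cat_$law,
      kon = NA_real_, koff = NA_real_, kcat = cat_$kcat, Km = cat_$Km
    )
  )
  if (is.null(rx) || ncol(rx) == 0L) {
    rx <- tibble::tibble(id = character(0), type = character(0),
                         reactants = character(0), products = character(0),
                         enzyme = character(0), substrate = character(0),
                         product = character(0), law = character(0),
                         kon = numeric(0), koff = numeric(0),
                         kcat = numeric(0), Km = numeric(0))
  }
  readr::write_csv(rx, p$reactions)
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

read_native_model <- function(path) {
  p <- native_paths(path)
  for (f in unlist(p)) {
    if (!file.exists(f)) rlang::abort(paste0("native model file not found: ", f))
  }
  sp_raw <- readr::read_csv(p$species, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character(),
                                                    conc = readr::col_double()))
  need <- c("id", "name", "role", "composition", "conc")
  miss <- setdiff(need, names(sp_raw))
  if (length(miss)) {
    rlang::abort(paste0("species sheet missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  species <- tibble::tibble(
    id = sp_raw$id, name = sp_raw$name, role = sp_raw$role,
    composition = lapply(sp_raw$composition, split_tokens),
    conc = sp_raw$conc
  )
  rx <- readr::read_csv(p$reactions, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character(),
                                                kon = readr::col_double(),
                                                koff = readr::col_double(),
                                                kcat = readr::col_double(),
                                                Km = readr::col_double()))
  bad <- which(!rx$type %in% c("reversible", "catalytic"))
  if (length(bad)) {
    rlang::abort(paste0("reaction sheet: unknown type in record(s): ",
                        paste(rx$id[bad], collapse = ", ")))
  }
  rev <- rx[rx$type == "reversible", , drop = FALSE]
  cat_ <- rx[rx$type == "catalytic", , drop = FALSE]
  reversible <- if (nrow(rev)) tibble::tibble(
    id = rev$id,
    reactants = lapply(rev$reactants, split_tokens),
    products = lapply(rev$products, split_tokens),
    kon = rev$kon, koff = rev$koff
  )
  catalytic <- if (nrow(cat_)) tibble::tibble(
    id = cat_$id, enzyme = cat_$enzyme, substrate = cat_$substrate,
    product = cat_$product,
    law = ifelse(is.na(cat_$law), "mass_action", cat_$law),
    kcat = cat_$kcat, Km = cat_$Km
  )
  network_model(species, reversible, catalytic)
}

# ---- SBML Level 3 ---------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
MIMDYN_NS <- "https://mimdyn.invalid/sbml-annotations"

mathml_ci <- function(parent, ids) {
  for (id in ids) xml2::xml_add_child(parent, "ci", id)
}

# <apply><times/> k, species... </apply>
mathml_times <- function(parent, k, species) {
  a <- xml2::xml_add_child(parent, "apply")
  xml2::xml_add_child(a, "times")
  mathml_ci(a, c(k, species))
  a
}

write_sbml_model <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "mimdyn_model")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      spatialDimensions = "3", constant = "true")
  losp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    row <- model$species[i, ]
    spn <- xml2::xml_add_child(
      losp, "species", id = row$id, name = row$name, compartment = "cell",
      initialConcentration = format(row$conc, digits = 17),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
    ann <- xml2::xml_add_child(spn, "annotation")
    xml2::xml_add_child(ann, "mimdynInfo",
                        "xmlns" = MIMDYN_NS,
                        role = row$role,
                        composition = paste(row$composition[[1]], collapse = ";"))
  }
  lorx <- xml2::xml_add_child(mdl, "listOfReactions")

  add_species_refs <- function(parent, tag, ids) {
    lst <- xml2::xml_add_child(parent, tag)
    tab <- table(ids)
    for (id in names(tab)) {
      xml2::xml_add_child(lst, "speciesReference", species = id,
                          stoichiometry = as.character(as.integer(tab[[id]])),
                          constant = "true")
    }
  }

  for (i in seq_len(nrow(model$reversible))) {
    row <- model$reversible[i, ]
    rxn <- xml2::xml_add_child(lorx, "reaction", id = row$id,
                               reversible = "true")
    add_species_refs(rxn, "listOfReactants", row$reactants[[1]])
    add_species_refs(rxn, "listOfProducts", row$products[[1]])
    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "minus")
    mathml_times(ap, "kon", row$reactants[[1]])
    mathml_times(ap, "koff", row$products[[1]])
    lop <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lop, "localParameter", id = "kon",
                        value = format(row$kon, digits = 17))
    xml2::xml_add_child(lop, "localParameter", id = "koff",
                        value = format(row$koff, digits = 17))
  }

  for (i in seq_len(nrow(model$catalytic))) {
    row <- model$catalytic[i, ]
    rxn <- xml2::xml_add_child(lorx, "reaction", id = row$id,
                               reversible = "false")
    add_species_refs(rxn, "listOfReactants", row$substrate)
    add_species_refs(rxn, "listOfProducts", row$product)
    lom <- xml2::xml_add_child(rxn, "listOfModifiers")
    xml2::xml_add_child(lom, "modifierSpeciesReference", species = row$enzyme)
    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    if (row$law == "mass_action") {
      mathml_times(math, "kcat", c(row$enzyme, row$substrate))
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "divide")
      mathml_times(ap, "kcat", c(row$enzyme, row$substrate))
      denom <- xml2::xml_add_child(ap, "apply")
      xml2::xml_add_child(denom, "plus")
      mathml_ci(denom, c("Km", row$substrate))
    }
    lop <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lop, "localParameter", id = "kcat",
                        value = format(row$kcat, digits = 17))
    if (row$law == "michaelis_menten") {
      xml2::xml_add_child(lop, "localParameter", id = "Km",
                          value = format(row$Km, digits = 17))
    }
  }
  xml2::write_xml(doc, path)
}

local_params <- function(rxn) {
  lp <- xml2::xml_find_all(rxn, ".//localParameter")
  stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                  xml2::xml_attr(lp, "id"))
}

refs_with_stoich <- function(rxn, tag) {
  refs <- xml2::xml_find_all(rxn, paste0("./", tag, "/speciesReference"))
  ids <- xml2::xml_attr(refs, "species")
  st <- xml2::xml_attr(refs, "stoichiometry")
  st <- ifelse(is.na(st), 1L, as.integer(as.numeric(st)))
  rep(ids, times = st)
}

read_sbml_model <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("SBML file not found: ", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    rlang::abort(paste0("SBML parse failure in '", path, "': ",
                        conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0 &&
      length(xml2::xml_find_all(doc, ".//model")) == 0) {
    rlang::abort(paste0("SBML parse failure: no <model> element in ", path))
  }
  species <- purrr::map_dfr(sp_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    conc <- as.numeric(xml2::xml_attr(nd, "initialConcentration"))
    if (is.na(conc)) conc <- 0
    info <- xml2::xml_find_first(nd, ".//mimdynInfo")
    if (inherits(info, "xml_node")) {
      role <- xml2::xml_attr(info, "role")
      comp <- split_tokens(xml2::xml_attr(info, "composition"))
    } else {
      role <- "basic"
      comp <- id
    }
    nm <- xml2::xml_attr(nd, "name")
    tibble::tibble(id = id, name = ifelse(is.na(nm), id, nm), role = role,
                   composition = list(comp), conc = conc)
  })
  if (nrow(species) == 0L) {
    species <- tibble::tibble(id = character(0), name = character(0),
                              role = character(0), composition = list(),
                              conc = numeric(0))
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rev_rows <- list(); cat_rows <- list()
  for (nd in rx_nodes) {
    id <- xml2::xml_attr(nd, "id")
    pars <- local_params(nd)
    reactants <- refs_with_stoich(nd, "listOfReactants")
    products <- refs_with_stoich(nd, "listOfProducts")
    modifiers <- xml2::xml_attr(
      xml2::xml_find_all(nd, "./listOfModifiers/modifierSpeciesReference"),
      "species")
    if (identical(xml2::xml_attr(nd, "reversible"), "true")) {
      if (!all(c("kon", "koff") %in% names(pars))) {
        rlang::abort(paste0("SBML reaction '", id,
                            "': reversible reaction lacks kon/koff local parameters"))
      }
      rev_rows[[length(rev_rows) + 1L]] <-
        reversible_reaction(id, reactants, products, pars[["kon"]], pars[["koff"]])
    } else {
      if (length(modifiers) != 1L || !"kcat" %in% names(pars)) {
        rlang::abort(paste0("SBML reaction '", id,
                            "': catalytic reaction needs one modifier and a kcat"))
      }
      law <- if ("Km" %in% names(pars)) "michaelis_menten" else "mass_action"
      cat_rows[[length(cat_rows) + 1L]] <-
        catalytic_reaction(id, modifiers, reactants[1], products[1],
                           pars[["kcat"]], law,
                           Km = if (law == "michaelis_menten") pars[["Km"]] else NA_real_)
    }
  }
  network_model(species,
                if (length(rev_rows)) dplyr::bind_rows(rev_rows),
                if (length(cat_rows)) dplyr::bind_rows(cat_rows))
}
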