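#' Define a treatment plan
#'
#' A plan lists treatments (each a label plus the inhibitor presets it
#' combines; the reserved inhibitor name `"ActD"` denotes the
#' pan-transcriptional inhibitor, which zeroes mRNA synthesis), the protein
#' readout time (default 30 min - phospho changes are fast) and the mRNA
#' readout times (defaults 4 h and 8 h - transcript pools respond slowly).
#' A vehicle control is always simulated.
#'
#' @param treatments List of `list(label =, inhibitors = c(...))` entries.
#' @param protein_readout_time Seconds (default 1800).
#' @param mrna_readout_times Seconds (default `c(14400, 28800)`).
#' @return A `treatment_plan` object.
#' @export
treatment_plan <- function(treatments,
                           protein_readout_time = 1800,
                           mrna_readout_times = c(14400, 28800)) {
  stopifnot(protein_readout_time > 0, all(mrna_readout_times > 0))
  for (tr in treatments) {
    stopifnot(is.character(tr$label), length(tr$label) == 1L)
  }
  labels <- vapply(treatments, `[[`, character(1), "label")
  if (anyDuplicated(labels)) rlang::abort("duplicate treatment labels")
  structure(list(treatments = treatments,
                 protein_readout_time = protein_readout_time,
                 mrna_readout_times = sort(mrna_readout_times)),
            class = "treatment_plan")
}

endpoint_annotation <- function(model, moiety) {
  ep <- model$annotations$endpoints[[moiety]]
  if (is.null(ep)) {
    rlang::abort(paste0("moiety '", moiety,
                        "' has no endpoint annotation on the model"))
  }
  ep
}

#' Phosphorylated fraction of a moiety
#'
#' Ratio of the summed active (phosphorylated) forms to the moiety's total
#' pool across all forms and complexes (counting multiplicity), at a
#' requested time of a simulation - the model analog of a
#' phospho/total-protein western-blot ratio.
#'
#' @param result A `mim_simulation`, or a named state vector.
#' @param moiety Endpoint name annotated on the model (e.g. `"ERK"`,
#'   `"AKT"`).
#' @param time Time (s); ignored when `result` is a state vector.
#' @return Fraction in `[0, 1]`.
#' @export
phospho_ratio <- function(result, moiety, time = NULL) {
  if (inherits(result, "mim_simulation")) {
    model <- result$model
    state <- state_at(result, time %||% max(result$times))
  } else {
    rlang::abort("phospho_ratio needs a mim_simulation")
  }
  ep <- endpoint_annotation(model, moiety)
  total <- moiety_totals(model, state)[[ep$moiety]]
  if (total <= 0) return(NA_real_)
  sum(state[ep$active]) / total
}

resolve_inhibitors <- function(names_, inhibitors) {
  lapply(names_, function(nm) {
    if (!is.null(inhibitors[[nm]])) return(inhibitors[[nm]])
    inhibitor_preset(nm)
  })
}

mrna_level <- function(sim, species, time) {
  unname(state_at(sim, time)[species])
}

new_readout_table <- function(df) {
  structure(df, class = c("readout_table", class(tibble::tibble())))
}

#' Run a virtual inhibitor experiment
#'
#' The pipeline mirrors the wet protocol: apply the genotype, initialize
#' (total pools on unbound basic proteins), equilibrate to the
#' quasi-stationary pre-treatment baseline, then for each treatment apply
#' its inhibitors and simulate forward, extracting phospho-protein ratios at
#' the protein readout time and mRNA levels at each mRNA readout time, all
#' divided by the vehicle control at the same time. Treatments containing a
#' MEK inhibitor automatically engage the CCND1 mRNA destabilization
#' modifier (Eq d); when the treatment also contains `"ActD"` and
#' `actd_blocks_destabilization` is `TRUE` (the default, reflecting the
#' rescue observation that the destabilization runs through the
#' transcription of an intermediary gene) the modifier stays off.
#'
#' @param model A `network_model` with promoter and endpoint annotations.
#' @param genotype A [genotype()].
#' @param plan A [treatment_plan()].
#' @param inhibitors Optional named list of [inhibitor_spec()]s overriding
#'   the bundled presets for the names used in the plan.
#' @param settings A [solver_settings()].
#' @param actd_blocks_destabilization See above.
#' @return A `readout_table` tibble with columns `treatment`, `endpoint`,
#'   `time_s`, `value` (vehicle control rows are exactly 1) and `undefined`
#'   (flagging endpoints whose control value was 0).
#' @export
run_experiment <- function(model, genotype, plan, inhibitors = NULL,
                           settings = solver_settings(),
                           actd_blocks_destabilization = TRUE) {
  stopifnot(inherits(plan, "treatment_plan"))
  m <- apply_genotype(model, genotype)
  eq <- equilibrate(m, settings = settings)
  t_all <- sort(unique(c(plan$protein_readout_time, plan$mrna_readout_times)))
  grid <- sort(unique(c(0, t_all, seq(0, max(t_all), length.out = 61))))

  genes <- m$promoter$genes
  protein_eps <- list(ERKPP_ratio = "ERK", AKTP_ratio = "AKT")

  extract <- function(sim) {
    rows <- list()
    for (ep in names(protein_eps)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        endpoint = ep, time_s = plan$protein_readout_time,
        raw = phospho_ratio(sim, protein_eps[[ep]],
                            plan$protein_readout_time))
    }
    for (g in names(genes)) {
      for (tt in plan$mrna_readout_times) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          endpoint = paste0(g, "_mRNA"), time_s = tt,
          raw = mrna_level(sim, genes[[g]]$mrna_species, tt))
      }
    }
    dplyr::bind_rows(rows)
  }

  control_sim <- simulate_model(m, state0 = eq, t_end = max(t_all),
                                settings = settings, times = grid,
                                metadata = list(treatment = "vehicle"))
  control <- extract(control_sim)

  erk_active <- m$annotations$endpoints$ERK$active
  run_one <- function(label, inh_names) {
    specs <- resolve_inhibitors(setdiff(inh_names, "ActD"), inhibitors)
    mt <- m
    for (sp in specs) mt <- apply_inhibitor(mt, sp)
    actd <- "ActD" %in% inh_names
    if (actd) mt$transcription_off <- TRUE
    mek <- any(vapply(specs, function(s) isTRUE(s$mek_inhibitor), logical(1)))
    if (mek && !(actd && actd_blocks_destabilization) &&
        !is.null(erk_active)) {
      mt$ccnd1_modifier <- list(enabled = TRUE,
                                erkpp_control = sum(eq[erk_active]),
                                floor_frac = 1e-6)
    }
    st <- initialize_state(mt)
    st[names(eq)] <- eq
    sim <- simulate_model(mt, state0 = st, t_end = max(t_all),
                          settings = settings, times = grid,
                          metadata = list(treatment = label))
    extract(sim) |>
      dplyr::mutate(treatment = label, .before = 1)
  }

  treated <- purrr::map_dfr(plan$treatments,
                            function(tr) run_one(tr$label, tr$inhibitors))
  out <- dplyr::bind_rows(
    control |> dplyr::mutate(treatment = "vehicle", .before = 1),
    treated
  ) |>
    dplyr::left_join(control |> dplyr::rename(control_raw = "raw"),
                     by = c("endpoint", "time_s")) |>
    dplyr::mutate(
      undefined = .data$control_raw == 0 | is.na(.data$control_raw),
      value = dplyr::if_else(.data$undefined, NA_real_,
                             .data$raw / .data$control_raw)
    ) |>
    dplyr::select("treatment", "endpoint", "time_s", "value", "undefined")
  if (any(out$undefined)) {
    rlang::warn(paste0("endpoint(s) with zero control value flagged undefined: ",
                       paste(unique(out$endpoint[out$undefined]),
                             collapse = ", ")))
  }
  new_readout_table(out)
}

#' Actinomycin-D mRNA stability experiment
#'
#' Blocks de novo transcription (`ksynth = 0` for both genes) from `t = 0`
#' at the equilibrated baseline and reports the mRNA remaining at each
#' requested time, normalized to `t = 0` - exposing first-order degradation
#' kinetics (`exp(-kdeg t)` in the absence of any modifier). A MEK inhibitor
#' can be co-applied; with `actd_blocks_destabilization = TRUE` (default)
#' the CCND1 destabilization stays off under Act D, reproducing the rescue
#' of CI1040-induced CCND1 decay.
#'
#' @param model A `network_model` with promoter.
#' @param genotype A [genotype()].
#' @param time_points Times (s) at which to report remaining mRNA.
#' @param co_inhibitors Optional character vector of inhibitor preset names
#'   co-applied with Act D.
#' @param inhibitors Optional named list of [inhibitor_spec()] overrides.
#' @param actd_blocks_destabilization See [run_experiment()].
#' @param settings A [solver_settings()].
#' @return A `readout_table` tibble (`treatment`, `endpoint`, `time_s`,
#'   `value` = fraction of the t = 0 level).
#' @export
simulate_actd <- function(model, genotype, time_points,
                          co_inhibitors = character(0), inhibitors = NULL,
                          actd_blocks_destabilization = TRUE,
                          settings = solver_settings()) {
  stopifnot(all(time_points >= 0))
  m <- apply_genotype(model, genotype)
  eq <- equilibrate(m, settings = settings)
  specs <- resolve_inhibitors(co_inhibitors, inhibitors)
  mt <- m
  for (sp in specs) mt <- apply_inhibitor(mt, sp)
  mt$transcription_off <- TRUE
  mek <- any(vapply(specs, function(s) isTRUE(s$mek_inhibitor), logical(1)))
  erk_active <- m$annotations$endpoints$ERK$active
  if (mek && !actd_blocks_destabilization && !is.null(erk_active)) {
    mt$ccnd1_modifier <- list(enabled = TRUE,
                              erkpp_control = sum(eq[erk_active]),
                              floor_frac = 1e-6)
  }
  st <- initialize_state(mt)
  st[names(eq)] <- eq
  t_end <- max(time_points, 1)
  grid <- sort(unique(c(0, time_points, seq(0, t_end, length.out = 61))))
  sim <- simulate_model(mt, state0 = st, t_end = t_end, settings = settings,
                        times = grid)
  label <- paste(c("ActD", vapply(specs, `[[`, character(1), "name")),
                 collapse = "+")
  genes <- m$promoter$genes
  rows <- purrr::map_dfr(names(genes), function(g) {
    base <- mrna_level(sim, genes[[g]]$mrna_species, 0)
    purrr::map_dfr(time_points, function(tt) {
      tibble::tibble(
        treatment = label, endpoint = paste0(g, "_mRNA"), time_s = tt,
        value = if (base > 0) mrna_level(sim, genes[[g]]$mrna_species, tt) / base
                else NA_real_,
        undefined = base <= 0
      )
    })
  })
  new_readout_table(rows)
}

#' Plot a readout table
#'
#' Bar chart of normalized readouts by treatment, faceted by endpoint (and
#' time when several mRNA times are present), mirroring the usual
#' treated-over-control histogram layout.
#'
#' @param object A `readout_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.readout_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      panel = paste0(.data$endpoint, " @ ",
                                     round(.data$time_s / 3600, 1), " h"))
  ggplot2::ggplot(df, ggplot2::aes(.data$treatment, .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized readout (vehicle = 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
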