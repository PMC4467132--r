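#' A single mutation/alteration directive
#'
#' Four modes mirror how driver alterations are introduced into the model:
#' `constitutive_activation` prevents dephosphorylation/inactivation of the
#' target's active form (its inactivating rate constants are zeroed, so the
#' downstream pathway switches on independently of upstream input); `null`
#' zeroes the target moiety's total pool (absence of a functional protein);
#' `partial_loss` scales the pool by `fraction`; `overexpression` scales it
#' by `fold`.
#'
#' @param mode One of `"constitutive_activation"`, `"null"`,
#'   `"partial_loss"`, `"overexpression"`.
#' @param target Species (moiety) id.
#' @param fraction Residual fraction in `(0, 1)` for `partial_loss`.
#' @param fold Expression fold `> 1` for `overexpression`.
#' @return One-row tibble for a genotype's directive table.
#' @export
mutation <- function(mode = c("constitutive_activation", "null",
                              "partial_loss", "overexpression"),
                     target, fraction = NA_real_, fold = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "partial_loss" && (is.na(fraction) || fraction <= 0 || fraction >= 1)) {
    rlang::abort("partial_loss requires fraction in (0, 1)")
  }
  if (mode == "overexpression" && (is.na(fold) || fold <= 1)) {
    rlang::abort("overexpression requires fold > 1")
  }
  tibble::tibble(mode = mode, target = target,
                 fraction = as.numeric(fraction), fold = as.numeric(fold))
}

#' A named set of mutation directives
#'
#' @param name Genotype label.
#' @param directives Tibble of [mutation()] rows (empty for the physiologic
#'   condition).
#' @return A `genotype` object.
#' @export
genotype <- function(name, directives = NULL) {
  if (is.null(directives)) {
    directives <- mutation("null", "x")[0, ]
  }
  structure(list(name = name, directives = tibble::as_tibble(directives)),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype> ", x$name, ": ", nrow(x$directives), " directive(s)\n",
      sep = "")
  invisible(x)
}

#' Bundled cell-line genotype presets
#'
#' `physiologic` is the unmutated baseline. `HCT116` carries constitutive
#' activation of KRAS, beta-Catenin (CTNNB1) and PI3K, partial loss of PTEN
#' to 60% of its physiological level, and null E-Cadherin (CDH1) and TGF-beta
#' receptor II (TGFBR2). `HT29` carries constitutive activation of BRAF and
#' PI3K, null APC and SMAD4, and 2-fold ErbB2 overexpression.
#'
#' @param name `"physiologic"`, `"HCT116"` or `"HT29"`.
#' @return A [genotype()].
#' @export
genotype_preset <- function(name = c("physiologic", "HCT116", "HT29")) {
  name <- match.arg(name)
  switch(
    name,
    physiologic = genotype("physiologic"),
    HCT116 = genotype("HCT116", dplyr::bind_rows(
      mutation("constitutive_activation", "KRAS"),
      mutation("constitutive_activation", "CTNNB1"),
      mutation("constitutive_activation", "PI3K"),
      mutation("partial_loss", "PTEN", fraction = 0.6),
      mutation("null", "CDH1"),
      mutation("null", "TGFBR2")
    )),
    HT29 = genotype("HT29", dplyr::bind_rows(
      mutation("constitutive_activation", "BRAF"),
      mutation("constitutive_activation", "PI3K"),
      mutation("null", "APC"),
      mutation("null", "SMAD4"),
      mutation("overexpression", "ErbB2", fold = 2)
    ))
  )
}

# catalytic reactions that inactivate the target's active form:
# substrate is an annotated active form of the moiety, product is not
inactivation_reactions <- function(model, target) {
  active <- model$annotations$active_forms[[target]]
  if (is.null(active)) {
    rlang::abort(paste0("constitutive_activation(", target,
                        "): no active form annotated for this moiety"))
  }
  hits <- model$catalytic$substrate %in% active &
    !model$catalytic$product %in% active
  model$catalytic$id[hits]
}

#' Apply a genotype to a model
#'
#' Returns a new model with the directives applied: constitutive activation
#' zeroes the rate constants of every catalytic process that inactivates the
#' target's active form (annotated in `annotations$active_forms`); null,
#' partial loss and overexpression rescale the target basic species' initial
#' concentration relative to the model's baseline, so the transformation is
#' idempotent. The returned model re-validates.
#'
#' @param model A `network_model`.
#' @param genotype A [genotype()].
#' @return The transformed `network_model` (with `$genotype` set).
#' @export
apply_genotype <- function(model, genotype) {
  stopifnot(inherits(genotype, "genotype"))
  d <- genotype$directives
  unknown <- setdiff(d$target, model$species$id)
  if (length(unknown)) {
    rlang::abort(paste0("genotype '", genotype$name,
                        "' references unknown species: ",
                        paste(unknown, collapse = ", ")))
  }
  for (i in seq_len(nrow(d))) {
    target <- d$target[i]
    base <- model$baseline_conc[[target]]
    j <- match(target, model$species$id)
    switch(
      d$mode[i],
      null = { model$species$conc[j] <- 0 },
      partial_loss = { model$species$conc[j] <- base * d$fraction[i] },
      overexpression = { model$species$conc[j] <- base * d$fold[i] },
      constitutive_activation = {
        rx <- inactivation_reactions(model, target)
        if (length(rx) == 0L) {
          rlang::abort(paste0("constitutive_activation(", target,
                              "): no inactivation process found in the model"))
        }
        model$catalytic$kcat[model$catalytic$id %in% rx] <- 0
      }
    )
  }
  model$genotype <- genotype$name
  validate_network_model(model)
  model
}

#' Specify a virtual inhibitor
#'
#' Two mechanisms: `activity_scaling` multiplies the target's catalytic rate
#' constants by `1 - f` (the simplest implementation of a stated inhibition
#' level), and `competitive_binding` adds an inhibitor species plus a
#' reversible reaction sequestering the target. The target may be a species
#' id (all catalysis by that enzyme is scaled; a basic-protein target also
#' matches enzymes containing it, e.g. a kinase buried in a complex) or a
#' catalytic-process id (only that process is scaled - used when a drug
#' blocks an activation step, such as an AKT-recruitment inhibitor).
#'
#' @param name Inhibitor label.
#' @param target Species id or catalytic-reaction id.
#' @param mechanism `"activity_scaling"` or `"competitive_binding"`.
#' @param f Inhibition fraction in `[0, 1)` (activity scaling).
#' @param concentration,Ki Inhibitor concentration and dissociation constant
#'   (nM), for competitive binding.
#' @param mek_inhibitor Flag marking MEK inhibitors; treatments containing
#'   one engage the CCND1 mRNA destabilization modifier
#'   ([ccnd1_kdeg_modifier()]).
#' @return An `inhibitor_spec` object.
#' @export
inhibitor_spec <- function(name, target,
                           mechanism = c("activity_scaling",
                                         "competitive_binding"),
                           f = NA_real_, concentration = NA_real_,
                           Ki = NA_real_, mek_inhibitor = FALSE) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "activity_scaling") {
    if (is.na(f) || f < 0 || f >= 1) {
      rlang::abort(paste0("inhibitor '", name, "': f must be in [0, 1)"))
    }
  } else if (is.na(concentration) || is.na(Ki) || concentration < 0 || Ki <= 0) {
    rlang::abort(paste0("inhibitor '", name,
                        "': competitive_binding needs concentration >= 0 and Ki > 0"))
  }
  structure(list(name = name, target = target, mechanism = mechanism,
                 f = f, concentration = concentration, Ki = Ki,
                 mek_inhibitor = mek_inhibitor),
            class = "inhibitor_spec")
}

#' @export
print.inhibitor_spec <- function(x, ...) {
  cat("<inhibitor_spec> ", x$name, " -> ", x$target, " (", x$mechanism,
      if (x$mechanism == "activity_scaling") paste0(", f = ", signif(x$f, 4)),
      ")\n", sep = "")
  invisible(x)
}

#' Bundled virtual-inhibitor presets
#'
#' The preset `f` values for CI1040 (MEK inhibitor, 80%) and Perifosine (AKT
#' inhibitor, 40% at 20 nM and 70% at 40 nM) are the stated inhibition
#' levels of the corresponding wet treatments; [calibrate_inhibitor()] turns
#' a stated level into the activity-scaling strength that reproduces it on
#' the measured readout. PI103 (PI3K), XAV939 (Tankyrase; raises Axin and so
#' the beta-Catenin destruction complex) and Azakenpaullone (GSK3-beta)
#' carry documented default strengths, their wet levels not being printed.
#'
#' @param name One of `"CI1040"`, `"Perifosine_20nM"`, `"Perifosine_40nM"`,
#'   `"PI103"`, `"XAV939"`, `"Azakenpaullone"`.
#' @return An [inhibitor_spec()].
#' @export
inhibitor_preset <- function(name = c("CI1040", "Perifosine_20nM",
                                      "Perifosine_40nM", "PI103", "XAV939",
                                      "Azakenpaullone")) {
  name <- match.arg(name)
  switch(
    name,
    CI1040 = inhibitor_spec("CI1040", "MEK_PP", f = 0.80,
                            mek_inhibitor = TRUE),
    Perifosine_20nM = inhibitor_spec("Perifosine_20nM", "akt_activation",
                                     f = 0.40),
    Perifosine_40nM = inhibitor_spec("Perifosine_40nM", "akt_activation",
                                     f = 0.70),
    PI103 = inhibitor_spec("PI103", "PI3K_a", f = 0.75),
    XAV939 = inhibitor_spec("XAV939", "TNKS", f = 0.80),
    Azakenpaullone = inhibitor_spec("Azakenpaullone", "GSK3B", f = 0.50)
  )
}

scaled_reactions <- function(model, target) {
  cat_ <- model$catalytic
  if (target %in% cat_$id) return(target)
  hits <- cat_$enzyme == target
  sp <- model$species
  j <- match(target, sp$id)
  if (!is.na(j) && sp$role[j] == "basic") {
    # basic-protein target also matches enzymes containing the moiety
    contains <- vapply(cat_$enzyme, function(e) {
      target %in% sp$composition[[match(e, sp$id)]]
    }, logical(1))
    hits <- hits | contains
  }
  cat_$id[hits]
}

#' Apply a virtual inhibitor to a model
#'
#' `activity_scaling` multiplies the matched catalytic rate constants by
#' `1 - f` (so `f = 0` is the identity and inhibitors on distinct targets
#' commute); `competitive_binding` adds the inhibitor species and a
#' sequestering reversible reaction with `koff/kon = Ki`.
#'
#' @param model A `network_model`.
#' @param spec An [inhibitor_spec()].
#' @return The transformed `network_model`.
#' @export
apply_inhibitor <- function(model, spec) {
  stopifnot(inherits(spec, "inhibitor_spec"))
  if (spec$mechanism == "activity_scaling") {
    rx <- scaled_reactions(model, spec$target)
    if (length(rx) == 0L) {
      rlang::abort(paste0("inhibitor '", spec$name, "': target '",
                          spec$target,
                          "' matches no catalytic process or enzyme"))
    }
    sel <- model$catalytic$id %in% rx
    model$catalytic$kcat[sel] <- model$catalytic$kcat[sel] * (1 - spec$f)
  } else {
    if (!spec$target %in% model$species$id) {
      rlang::abort(paste0("inhibitor '", spec$name, "': unknown target '",
                          spec$target, "'"))
    }
    inh_id <- paste0(spec$name, "_drug")
    cpx_id <- paste0(spec$target, "_", inh_id)
    tcomp <- model$species$composition[[match(spec$target, model$species$id)]]
    kon <- 1e-3
    model$species <- dplyr::bind_rows(
      model$species,
      species_decl(inh_id, "inhibitor", spec$concentration),
      species_decl(cpx_id, "complex", 0, composition = c(tcomp, inh_id))
    )
    model$baseline_conc <- c(model$baseline_conc,
                             stats::setNames(c(spec$concentration, 0),
                                             c(inh_id, cpx_id)))
    model$reversible <- dplyr::bind_rows(
      model$reversible,
      reversible_reaction(paste0("bind_", inh_id),
                          c(spec$target, inh_id), cpx_id,
                          kon = kon, koff = kon * spec$Ki)
    )
  }
  model$inhibitors <- c(model$inhibitors, list(spec))
  validate_network_model(model)
  model
}

# normalized readout under an activity-scaling strength s for spec's target;
# shared by calibration and the recovery harness
inhibited_readout <- function(model, eq_state, spec, strength, readout,
                              readout_time, settings, control_value) {
  s2 <- spec
  s2$f <- strength
  mt <- apply_inhibitor(model, s2)
  sim <- simulate_model(mt, state0 = eq_state, t_end = readout_time,
                        settings = settings,
                        times = c(0, readout_time / 2, readout_time))
  phospho_ratio(sim, readout, readout_time) / control_value
}

#' Calibrate an inhibitor strength to a desired readout inhibition
#'
#' Finds the activity-scaling strength such that the normalized phospho
#' readout at `readout_time` equals `1 - f_desired`, by bisection on the
#' bracketed monotone interval. The pipeline matches the virtual experiment:
#' apply genotype, initialize, equilibrate, apply the inhibitor at a trial
#' strength, simulate to `readout_time`, normalize to the vehicle control.
#'
#' @param model A `network_model`.
#' @param genotype A [genotype()] (the calibration background).
#' @param spec An [inhibitor_spec()] with `activity_scaling` mechanism; its
#'   `f` is ignored and replaced by the calibrated strength.
#' @param f_desired Target fractional inhibition of the readout, in `[0, 1)`.
#' @param readout Endpoint moiety for [phospho_ratio()], e.g. `"ERK"` or
#'   `"AKT"`.
#' @param readout_time Readout time (s), default 1800 (30 min).
#' @param settings A [solver_settings()].
#' @param tol Absolute tolerance on the achieved inhibition (default 1e-4,
#'   comfortably inside the 1e-3 contract).
#' @return The [inhibitor_spec()] with `f` set to the calibrated strength
#'   and attribute `achieved_inhibition`.
#' @export
calibrate_inhibitor <- function(model, genotype, spec, f_desired,
                                readout, readout_time = 1800,
                                settings = solver_settings(), tol = 1e-4) {
  stopifnot(f_desired >= 0, f_desired < 1,
            spec$mechanism == "activity_scaling")
  if (f_desired == 0) {
    spec$f <- 0
    attr(spec, "achieved_inhibition") <- 0
    return(spec)
  }
  m <- apply_genotype(model, genotype)
  eq <- equilibrate(m, settings = settings)
  control <- phospho_ratio(
    simulate_model(m, state0 = eq, t_end = readout_time, settings = settings,
                   times = c(0, readout_time / 2, readout_time)),
    readout, readout_time)
  if (control <= 0) {
    rlang::abort(paste0("calibration: control readout for ", readout,
                        " is zero"))
  }
  g <- function(s) 1 - inhibited_readout(m, eq, spec, s, readout,
                                         readout_time, settings, control)
  s_hi <- 1 - 1e-9
  if (g(s_hi) < f_desired) {
    rlang::abort(paste0("calibration: readout ", readout,
                        " cannot reach ", f_desired * 100,
                        "% inhibition (insensitive to '", spec$target, "')"))
  }
  root <- stats::uniroot(function(s) g(s) - f_desired,
                         lower = 0, upper = s_hi,
                         tol = 1e-12, maxiter = 200)
  spec$f <- root$root
  achieved <- g(root$root)
  if (abs(achieved - f_desired) > tol) {
    # fall back to a fine bisection if uniroot's interpolation stalled
    lo <- 0; hi <- s_hi
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (g(mid) < f_desired) lo <- mid else hi <- mid
      if (abs(g(mid) - f_desired) <= tol / 2) break
    }
    spec$f <- (lo + hi) / 2
    achieved <- g(spec$f)
  }
  attr(spec, "achieved_inhibition") <- achieved
  spec
}
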