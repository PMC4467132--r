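#' Solver settings for equilibration and simulation
#'
#' @param rel_tol,abs_tol Relative and absolute (nM) integration tolerances
#'   passed to the stiff solver.
#' @param t_max_equilibration Hard cap (s) on the equilibration horizon.
#' @param equilibration_tol Quasi-stationarity threshold on the scaled
#'   derivative norm `max_i |dx_i/dt| / (abs_tol + |x_i|)` (1/s).
#' @param max_step Maximum internal step size (s); `Inf` leaves the solver
#'   free.
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-8,
                            t_max_equilibration = 1e7,
                            equilibration_tol = 1e-8,
                            max_step = Inf) {
  stopifnot(rel_tol > 0, abs_tol > 0, t_max_equilibration > 0,
            equilibration_tol > 0, max_step > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 t_max_equilibration = t_max_equilibration,
                 equilibration_tol = equilibration_tol,
                 max_step = max_step),
            class = "solver_settings")
}

# Precompile a model into index vectors and a stoichiometry matrix so the
# ODE right-hand side is a handful of vectorized operations per call.
compile_network <- function(model) {
  ids <- model$species$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)

  uni_k <- numeric(0); uni_i <- integer(0)
  bi_k <- numeric(0); bi_i1 <- integer(0); bi_i2 <- integer(0)
  mm_k <- numeric(0); mm_e <- integer(0); mm_s <- integer(0); mm_Km <- numeric(0)
  cols <- list()

  stoich_col <- function(minus, plus) {
    col <- numeric(n)
    for (i in minus) col[i] <- col[i] - 1
    for (i in plus) col[i] <- col[i] + 1
    col
  }
  # column order must mirror the order rates are concatenated in the rhs:
  # all unimolecular, then bimolecular, then Michaelis-Menten
  uni_cols <- list(); bi_cols <- list(); mm_cols <- list()

  add_mass <- function(k, r_idx, p_idx) {
    if (length(r_idx) == 1L) {
      uni_k <<- c(uni_k, k); uni_i <<- c(uni_i, r_idx)
      uni_cols[[length(uni_cols) + 1L]] <<- stoich_col(r_idx, p_idx)
    } else {
      bi_k <<- c(bi_k, k); bi_i1 <<- c(bi_i1, r_idx[1]); bi_i2 <<- c(bi_i2, r_idx[2])
      bi_cols[[length(bi_cols) + 1L]] <<- stoich_col(r_idx, p_idx)
    }
  }

  rev <- model$reversible
  for (i in seq_len(nrow(rev))) {
    r <- idx[rev$reactants[[i]]]
    p <- idx[rev$products[[i]]]
    add_mass(rev$kon[i], r, p)
    add_mass(rev$koff[i], p, r)
  }
  cat_ <- model$catalytic
  for (i in seq_len(nrow(cat_))) {
    e <- idx[[cat_$enzyme[i]]]
    s <- idx[[cat_$substrate[i]]]
    p <- idx[[cat_$product[i]]]
    if (cat_$law[i] == "mass_action") {
      # enzyme-substrate product law: v = kcat [E][S]
      bi_k <- c(bi_k, cat_$kcat[i]); bi_i1 <- c(bi_i1, e); bi_i2 <- c(bi_i2, s)
      bi_cols[[length(bi_cols) + 1L]] <- stoich_col(s, p)
    } else {
      mm_k <- c(mm_k, cat_$kcat[i]); mm_e <- c(mm_e, e); mm_s <- c(mm_s, s)
      mm_Km <- c(mm_Km, cat_$Km[i])
      mm_cols[[length(mm_cols) + 1L]] <- stoich_col(s, p)
    }
  }
  all_cols <- c(uni_cols, bi_cols, mm_cols)
  S <- if (length(all_cols)) do.call(cbind, all_cols) else matrix(0, n, 0)

  # promoter coupling
  trans <- NULL
  if (!is.null(model$promoter)) {
    pc <- model$promoter
    site_parts <- lapply(pc$sites, function(site) {
      b <- site$bindings
      miss <- setdiff(b$species_id, ids)
      if (length(miss)) {
        rlang::abort(paste0("promoter site ", site$site_name,
                            " references species absent from the model: ",
                            paste(miss, collapse = ", ")))
      }
      list(i = idx[b$species_id], Kd = b$Kd,
           act = b$mode == "activator", omega = b$omega)
    })
    k <- if (pc$k_rnap_mode == "association") pc$k_rnap else 1 / pc$k_rnap
    genes <- lapply(names(pc$genes), function(g) {
      gg <- pc$genes[[g]]
      if (!gg$mrna_species %in% ids) {
        rlang::abort(paste0("gene ", g, ": mRNA species '", gg$mrna_species,
                            "' absent from the model"))
      }
      list(gene = g, i = idx[[gg$mrna_species]],
           ksynth = gg$ksynth, kdeg = gg$kdeg)
    })
    mod <- model$ccnd1_modifier %||%
      list(enabled = FALSE, erkpp_control = NA_real_, floor_frac = 1e-6)
    erk_idx <- integer(0)
    if (isTRUE(mod$enabled)) {
      erk_ids <- model$annotations$endpoints$ERK$active %||%
        model$annotations$active_forms$ERK
      if (is.null(erk_ids)) {
        rlang::abort("CCND1 destabilization needs an ERK endpoint annotation")
      }
      erk_idx <- idx[erk_ids]
    }
    trans <- list(sites = site_parts, rnap_k = pc$rnap * k, genes = genes,
                  off = isTRUE(model$transcription_off),
                  modifier = mod, erk_idx = erk_idx)
  }

  freg_fast <- function(y) {
    f <- 1
    for (sp in trans$sites) {
      x <- y[sp$i] / sp$Kd
      f <- f * (1 + sum(sp$omega[sp$act] * x[sp$act])) / (1 + sum(x))
    }
    f
  }

  rhs <- function(t, y, parms) {
    v <- c(uni_k * y[uni_i],
           bi_k * y[bi_i1] * y[bi_i2],
           mm_k * y[mm_e] * y[mm_s] / (mm_Km + y[mm_s]))
    dy <- as.numeric(S %*% v)
    if (!is.null(trans)) {
      yc <- pmax(y, 0)
      z <- trans$rnap_k * freg_fast(yc)
      P <- z / (1 + z)
      for (g in trans$genes) {
        ks <- if (trans$off) 0 else g$ksynth
        kd <- g$kdeg
        if (g$gene == "CCND1" && isTRUE(trans$modifier$enabled)) {
          floor_ <- trans$modifier$floor_frac * trans$modifier$erkpp_control
          erk_now <- max(sum(yc[trans$erk_idx]), floor_)
          kd <- kd * trans$modifier$erkpp_control / erk_now
        }
        dy[g$i] <- dy[g$i] + ks * P - kd * y[g$i]
      }
    }
    list(dy)
  }

  list(ids = ids, idx = idx, rhs = rhs, trans = trans)
}

#' Right-hand-side function of a model's ODE system
#'
#' Returns `f(state)` giving d(state)/dt (nM/s) at the supplied named state
#' vector. Reversible reactions contribute
#' `v = kon * prod(reactants) - koff * prod(products)`; mass-action catalysis
#' contributes `v = kcat [E][S]`; Michaelis-Menten catalysis
#' `v = kcat [E][S]/(Km + [S])`. If the model carries a promoter
#' configuration, each gene's mRNA additionally obeys
#' `ksynth * P(RNAPbound) - kdeg * mRNA`, with the CCND1 degradation rate
#' rescaled by the ERK-phosphorylation ratio when the MEK-inhibition modifier
#' is engaged.
#'
#' @param model A validated `network_model`.
#' @return A function mapping a named state vector to a named derivative
#'   vector.
#' @export
build_rhs <- function(model) {
  cn <- compile_network(model)
  function(state) {
    y <- state[cn$ids]
    stats::setNames(cn$rhs(0, y, NULL)[[1]], cn$ids)
  }
}

#' Initial state of a model under a genotype
#'
#' Assigns each basic protein's total pool entirely to its unbound basic
#' species; modified forms and complexes start at zero; mRNAs and inhibitor
#' species start at their declared concentrations. Genotype directives are
#' applied before any integration (nulls zeroed, partial losses and
#' overexpression scaled); rate-constant directives (constitutive
#' activation) also act through [apply_genotype()].
#'
#' @param model A `network_model`.
#' @param genotype Optional [genotype()]; if supplied, the model is passed
#'   through [apply_genotype()] first.
#' @return Named numeric state vector (nM).
#' @export
initialize_state <- function(model, genotype = NULL) {
  if (!is.null(genotype)) model <- apply_genotype(model, genotype)
  sp <- model$species
  conc <- ifelse(sp$role %in% c("modified", "complex"), 0, sp$conc)
  stats::setNames(as.numeric(conc), sp$id)
}

scaled_deriv_norm <- function(dy, y, abs_tol) {
  if (!length(dy)) return(0)
  max(abs(dy) / (abs_tol + abs(y)))
}

#' Bring a model to quasi-stationary equilibrium
#'
#' Integrates the system (stiff solver, expanding time chunks) until the
#' scaled derivative norm `max_i |dx_i/dt| / (abs_tol + |x_i|)` drops below
#' `settings$equilibration_tol`, which redistributes each basic protein among
#' all its forms and complexes. By default mRNA species equilibrate too;
#' `freeze_mrna = TRUE` holds them fixed (their derivatives are excluded from
#' the norm as well). If the cap `t_max_equilibration` is reached without
#' convergence the state is returned with a warning and
#' `attr(, "converged") = FALSE`; a norm that grows over the final stretch
#' raises a non-convergence error.
#'
#' @param model A `network_model`.
#' @param state Optional starting state; defaults to
#'   [initialize_state()] of the model.
#' @param settings A [solver_settings()].
#' @param freeze_mrna Hold mRNA species constant during equilibration.
#' @return Named state vector with attributes `converged` (logical) and
#'   `t_equilibration` (s).
#' @export
equilibrate <- function(model, state = NULL, settings = solver_settings(),
                        freeze_mrna = FALSE) {
  cn <- compile_network(model)
  if (is.null(state)) state <- initialize_state(model)
  y <- state[cn$ids]
  if (any(!is.finite(y))) rlang::abort("non-finite starting state")
  mrna_i <- which(model$species$role == "mRNA")
  deriv <- function(yy) {
    d <- cn$rhs(0, yy, NULL)[[1]]
    if (freeze_mrna) d[mrna_i] <- 0
    d
  }
  rhs_frozen <- function(t, yy, parms) list(deriv(yy))

  tol <- settings$equilibration_tol
  t_now <- 0
  chunk <- 100
  norm_prev <- Inf
  repeat {
    norm <- scaled_deriv_norm(deriv(y), y, settings$abs_tol)
    if (norm < tol) {
      out <- stats::setNames(pmax(as.numeric(y), 0), cn$ids)
      attr(out, "converged") <- TRUE
      attr(out, "t_equilibration") <- t_now
      return(out)
    }
    if (t_now >= settings$t_max_equilibration) {
      if (norm > norm_prev * 1.01) {
        rlang::abort(paste0("equilibration diverging: derivative norm ",
                            format(norm), " still growing at t_max = ",
                            format(settings$t_max_equilibration), " s"))
      }
      rlang::warn(paste0("equilibration hit t_max without reaching the ",
                         "quasi-stationarity threshold (norm = ",
                         format(norm), ")"))
      out <- stats::setNames(pmax(as.numeric(y), 0), cn$ids)
      attr(out, "converged") <- FALSE
      attr(out, "t_equilibration") <- t_now
      return(out)
    }
    norm_prev <- norm
    chunk <- min(chunk, settings$t_max_equilibration - t_now)
    sol <- deSolve::lsoda(y = y, times = c(0, chunk), func = rhs_frozen,
                          parms = NULL, rtol = settings$rel_tol,
                          atol = settings$abs_tol,
                          hmax = if (is.finite(settings$max_step))
                            settings$max_step else NULL)
    y <- sol[nrow(sol), -1]
    t_now <- t_now + chunk
    chunk <- chunk * 4
  }
}

#' Simulate a time course
#'
#' Integrates the model from `state0` to `t_end` with a stiff solver and
#' returns a `mim_simulation` object holding the trajectory on an output grid
#' that includes `t_end`. Small negative underflow is clipped to zero in the
#' returned concentrations only.
#'
#' @param model A `network_model`.
#' @param state0 Named starting state; defaults to [initialize_state()].
#' @param t_end Simulation horizon (s, > 0).
#' @param settings A [solver_settings()].
#' @param times Optional explicit output grid (s); must start at 0.
#' @param n_out Number of output points when `times` is not given.
#' @param metadata Free-form list recorded on the result (genotype,
#'   treatment labels, ...).
#' @return A `mim_simulation`: list with `times`, `conc` (time x species
#'   matrix, nM), `species`, `metadata`.
#' @export
simulate_model <- function(model, state0 = NULL, t_end,
                           settings = solver_settings(), times = NULL,
                           n_out = 101, metadata = list()) {
  cn <- compile_network(model)
  if (is.null(state0)) state0 <- initialize_state(model)
  y0 <- state0[cn$ids]
  if (any(is.na(y0))) {
    rlang::abort(paste0("state0 missing species: ",
                        paste(cn$ids[is.na(y0)], collapse = ", ")))
  }
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = n_out)
  }
  if (times[1] != 0) rlang::abort("output grid must start at t = 0")
  sol <- deSolve::lsoda(y = y0, times = times, func = cn$rhs, parms = NULL,
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        hmax = if (is.finite(settings$max_step))
                          settings$max_step else NULL)
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort(paste0("ODE solver failed near t = ",
                        format(sol[nrow(sol), 1]), " s"))
  }
  conc <- pmax(unname(sol[, -1, drop = FALSE]), 0)
  colnames(conc) <- cn$ids
  structure(list(times = sol[, 1], conc = conc, species = cn$ids,
                 model = model, metadata = metadata),
            class = "mim_simulation")
}

#' @export
print.mim_simulation <- function(x, ...) {
  cat("<mim_simulation> ", length(x$times), " time points, ",
      length(x$species), " species, t_end = ", max(x$times), " s\n", sep = "")
  invisible(x)
}

#' State vector at a requested time of a simulation
#'
#' @param sim A `mim_simulation`.
#' @param time Time (s); must lie on the output grid (nearest point within
#'   solver resolution is used, and an error is raised beyond the horizon).
#' @return Named concentration vector (nM).
#' @export
state_at <- function(sim, time) {
  if (time > max(sim$times) + 1e-9) {
    rlang::abort(paste0("time ", time, " s beyond simulation horizon"))
  }
  i <- which.min(abs(sim$times - time))
  stats::setNames(sim$conc[i, ], sim$species)
}

#' Tidy a simulation into a long tibble
#'
#' @param x A `mim_simulation`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `species`, `concentration`.
#' @export
tidy.mim_simulation <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$conc)) |>
    dplyr::mutate(time = x$times, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "species",
                        values_to = "concentration")
}

#' Plot simulated trajectories
#'
#' @param object A `mim_simulation`.
#' @param species Optional character vector restricting the plotted species.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mim_simulation <- function(object, species = NULL, ...) {
  df <- tidy.mim_simulation(object)
  if (!is.null(species)) df <- dplyr::filter(df, .data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 60, .data$concentration,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (nM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
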