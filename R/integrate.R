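#' Integrate the model ODE system
#'
#' Stiff integration (deSolve, `lsoda`, compiled right-hand side) of the
#' mass balances under a feeding regime. The absolute tolerance defaults
#' to 1e-4 and all variables obey a nonnegativity contract: the rate laws
#' vanish at zero concentration, so negative values can only arise as
#' numerical overshoot, which is clipped to zero and counted (attribute
#' `n_clipped` of the trajectory).
#'
#' For a feast/famine regime the square-wave dilution rate (`D_feed`
#' during `[0, TF)`, 0 during `[TF, TC)`, repeated; `t = 0` is a cycle
#' start) is handled by piecewise integration, so the solver never steps
#' across a discontinuity.
#'
#' @param state0 initial `state_vector`.
#' @param alloc a `proteome_allocation`.
#' @param regime a `feed_regime`.
#' @param params a `kinetic_params`.
#' @param t_span integration horizon, h.
#' @param atol,rtol solver tolerances.
#' @param n_grid output points (per feast and famine leg for
#'   feast/famine; total for a chemostat).
#' @param clamp state ids held fixed (batch reference solve).
#' @return an object of class `trajectory`: list with `times` (h),
#'   `states` (matrix time x state), `fluxes` (time x reaction), `extras`
#'   (load, EC, q_O2, q_CO2), `converged`, `n_cycles_run`.
#' @export
integrate_model <- function(state0, alloc, regime, params = default_params(),
                            t_span, atol = 1e-4, rtol = 1e-6,
                            n_grid = NULL, clamp = character()) {
  state0 <- as_state_vector(state0)
  validate_allocation(alloc)
  if (regime$mode == "chemostat") {
    if (is.null(n_grid)) n_grid <- 101
    grid <- seq(0, t_span, length.out = max(2, n_grid))
    out <- ode_leg(state0, alloc, params, D = regime$D_avg,
                   glc_feed = regime$glc_feed, times = grid,
                   atol = atol, rtol = rtol, clamp = clamp)
    tr <- make_trajectory(out$times, out$states, out$extras,
                          n_cycles = NA_integer_,
                          n_clipped = out$n_clipped)
    attr(tr, "root_hit") <- isTRUE(out$root_hit)
    return(tr)
  }
  # feast/famine: integrate whole cycles
  tc <- regime$TC / 3600
  n_cycles <- max(1L, ceiling(t_span / tc - 1e-9))
  pieces <- vector("list", 2L * n_cycles)
  st <- state0
  t0 <- 0
  for (cy in seq_len(n_cycles)) {
    legs <- ff_cycle_legs(st, alloc, regime, params, atol, rtol, n_grid)
    legs$feast$times <- legs$feast$times + t0
    legs$famine$times <- legs$famine$times + t0
    pieces[[2L * cy - 1L]] <- legs$feast
    pieces[[2L * cy]] <- legs$famine
    st <- as_state_vector(legs$famine$states[nrow(legs$famine$states), ])
    t0 <- t0 + tc
  }
  times <- do.call(c, lapply(pieces, `[[`, "times"))
  states <- do.call(rbind, lapply(pieces, `[[`, "states"))
  extras <- do.call(rbind, lapply(pieces, `[[`, "extras"))
  keep <- !duplicated(times)
  ncl <- sum(vapply(pieces, function(p) p$n_clipped %||% 0L, numeric(1)))
  tr <- make_trajectory(times[keep], states[keep, , drop = FALSE],
                        extras[keep, , drop = FALSE], n_cycles = n_cycles,
                        n_clipped = ncl)
  attr(tr, "root_hit") <- any(vapply(pieces, function(p)
    isTRUE(p$root_hit), logical(1)))
  tr
}

# integrate one feast/famine cycle from a cycle-start state; t from 0
ff_cycle_legs <- function(state0, alloc, regime, params, atol, rtol,
                          n_grid = NULL) {
  tf <- regime$TF / 3600
  tc <- regime$TC / 3600
  n_feast <- if (is.null(n_grid)) 41 else n_grid
  n_famine <- if (is.null(n_grid)) 141 else n_grid
  feast <- ode_leg(state0, alloc, params, D = regime$D_feed,
                   glc_feed = regime$glc_feed,
                   times = seq(0, tf, length.out = n_feast),
                   atol = atol, rtol = rtol, use_root = FALSE)
  st <- as_state_vector(feast$states[nrow(feast$states), ])
  famine <- if (tc > tf + 1e-12) {
    # famine grid densified toward the feed stop, where residual
    # substrate decays fastest (improves cycle quadrature)
    ode_leg(st, alloc, params, D = 0, glc_feed = regime$glc_feed,
            times = tf + (tc - tf) * seq(0, 1, length.out = n_famine)^1.7,
            atol = atol, rtol = rtol, use_root = FALSE)
  } else {
    list(times = tc, states = matrix(st, nrow = 1,
                                     dimnames = list(NULL, STATE_IDS)),
         extras = extras_at(st, alloc, params))
  }
  list(feast = feast, famine = famine)
}

# one constant-D integration leg through the compiled RHS
ode_leg <- function(state0, alloc, params, D, glc_feed, times,
                    atol, rtol, clamp = character(), use_root = TRUE) {
  clamp_glc <- as.numeric("Glc_ex" %in% clamp)
  clamp_tre <- as.numeric("Tre" %in% clamp)
  if (length(atol) == 1) {
    # per-variable absolute tolerances: extracellular concentrations and
    # biomass live on much smaller scales than the intracellular pools,
    # and the residual-substrate objective is read from Glc_ex
    atol <- stats::setNames(rep(atol, length(STATE_IDS)), STATE_IDS)
    atol[c("Glc_ex", "EtOH", "Glyc")] <-
      pmin(atol[c("Glc_ex", "EtOH", "Glyc")], 1e-7)
    atol["X"] <- min(atol[["X"]], 1e-8)
  }
  pv <- param_vector(alloc, params,
                     regime_vector(D, glc_feed,
                                   clamp_glc, state0[["Glc_ex"]],
                                   clamp_tre, state0[["Tre"]]))
  # Under continuous feeding the ATP-collapse state is absorbing, so a
  # root on ATP terminates integration as soon as the trajectory falls
  # into it (see src/model_rhs.c). The root is not used for
  # feast/famine legs: a strong feast pulse can push ATP through a deep
  # transient dip from which the famine phase recovers.
  out <- if (use_root) {
    suppressWarnings(
      deSolve::ode(y = unclass(state0)[STATE_IDS], times = times,
                   func = "protalloc_derivs", parms = pv,
                   dllname = "protalloc", initfunc = "protalloc_init",
                   rootfunc = "protalloc_root", nroot = 1L,
                   nout = 15L, outnames = EXTRA_IDS,
                   method = "lsoda", atol = atol, rtol = rtol,
                   maxsteps = 20000))
  } else {
    suppressWarnings(
      deSolve::ode(y = unclass(state0)[STATE_IDS], times = times,
                   func = "protalloc_derivs", parms = pv,
                   dllname = "protalloc", initfunc = "protalloc_init",
                   nout = 15L, outnames = EXTRA_IDS,
                   method = "lsoda", atol = atol, rtol = rtol,
                   maxsteps = 20000))
  }
  root_hit <- use_root && !is.null(attr(out, "troot")) &&
    length(attr(out, "troot")) > 0
  if (attr(out, "istate")[1] < 0 && !root_hit)
    warning("integration stopped early at t = ", max(out[, 1]))
  states <- out[, 1 + seq_along(STATE_IDS), drop = FALSE]
  colnames(states) <- STATE_IDS
  n_clipped <- sum(states < -atol)
  states[states < 0] <- 0
  extras <- out[, 1 + length(STATE_IDS) + seq_along(EXTRA_IDS),
                drop = FALSE]
  colnames(extras) <- EXTRA_IDS
  list(times = out[, 1], states = states, extras = extras,
       n_clipped = n_clipped, root_hit = root_hit)
}

EXTRA_IDS <- c(REACTION_IDS, "load", "EC", "q_O2", "q_CO2")

extras_at <- function(state, alloc, params) {
  v <- compute_rates(state, alloc, params)
  g <- gas_rates(v, params)
  m <- matrix(c(unclass(v), respiration_rates(state, alloc$phi[["Resp"]],
                                              params)[["load"]],
                energy_charge(state), g[["q_O2"]], g[["q_CO2"]]),
              nrow = 1, dimnames = list(NULL, EXTRA_IDS))
  m
}

make_trajectory <- function(times, states, extras, n_cycles,
                            converged = NA, n_clipped = 0L) {
  structure(list(times = times,
                 states = states,
                 fluxes = extras[, REACTION_IDS, drop = FALSE],
                 extras = extras[, c("load", "EC", "q_O2", "q_CO2"),
                                 drop = FALSE],
                 converged = converged,
                 n_cycles_run = n_cycles,
                 n_clipped = n_clipped),
            class = "trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$times), " points over ",
      signif(diff(range(x$times)), 4), " h",
      if (!is.na(x$n_cycles_run)) paste0(" (", x$n_cycles_run, " cycles)"),
      "\n", sep = "")
  if (!is.na(x$converged)) cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' Export a trajectory, state or flux vector as tidy data
#'
#' @param x a `trajectory`, `state_vector` or `flux_distribution`.
#' @return a data.frame with columns id, value, units (states/fluxes) or
#'   a long data.frame over time (trajectory).
#' @export
as_tidy_table <- function(x) {
  if (inherits(x, "state_vector")) {
    units <- ifelse(names(x) %in% INTRACELLULAR_IDS, "umol/g_X",
                    ifelse(names(x) == "X", "Cmol/L", "mmol/L"))
    return(data.frame(id = names(x), value = as.numeric(x), units = units))
  }
  if (inherits(x, "flux_distribution")) {
    units <- ifelse(names(x) == "Grwt", "1/h", "mol/Cmol_X/h")
    return(data.frame(id = names(x), value = as.numeric(x), units = units))
  }
  if (inherits(x, "trajectory")) {
    df <- data.frame(time_h = x$times, x$states, x$fluxes, x$extras,
                     check.names = FALSE)
    return(df)
  }
  stop("unsupported object")
}
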