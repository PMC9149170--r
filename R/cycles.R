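#' Simulate a feast/famine regime to a balanced cycle
#'
#' Integrates repeated feeding cycles until the state at cycle start
#' repeats within a relative tolerance (`tol_cycle`, per component with an
#' absolute floor), which defines a *balanced* (periodic) solution. The
#' run is declared `unbalanced` when `max_cycles` is exhausted or the
#' culture washes out; pools that drift monotonically across cycles (e.g.
#' FBP under a glycolytic imbalance) simply never satisfy the repetition
#' criterion.
#'
#' @param alloc a `proteome_allocation`.
#' @param regime a feast/famine `feed_regime` (a degenerate regime with
#'   `TF = TC` is allowed and reproduces the chemostat).
#' @param params a `kinetic_params`.
#' @param state0 optional cycle-start state; defaults to the chemostat
#'   steady state at `D_avg` (the paper's initialization), or a generic
#'   state if that is infeasible.
#' @param max_cycles maximum number of cycles (default 200).
#' @param tol_cycle relative repetition tolerance (default 1e-3).
#' @param atol,rtol solver tolerances.
#' @return a `trajectory` over the converged cycle (times from cycle
#'   start, h) with `converged = TRUE`, or an unconverged trajectory of
#'   the last cycle with `converged = FALSE`.
#' @export
simulate_to_stable_cycle <- function(alloc, regime,
                                     params = default_params(),
                                     state0 = NULL, max_cycles = 200,
                                     tol_cycle = 1e-3,
                                     atol = 1e-4, rtol = 1e-6) {
  stopifnot(regime$mode == "feast_famine")
  if (is.null(state0)) {
    ss <- find_steady_state(alloc, regime$D_avg, params,
                            glc_feed = regime$glc_feed)
    state0 <- if (ss$feasible) ss$state else
      default_state(Glc_ex = 0.1, X = 0.05)
  }
  st <- as_state_vector(state0)
  last <- NULL
  n_run <- 0L
  # excluded from the repetition criterion: extracellular products (no
  # feedback on the dynamics, washout timescale 1/D_avg is hundreds of
  # cycles) and AMP (slaved to ATP/ADP by the fast adenylate kinase, so
  # its repetition error is solver noise)
  conv_ids <- setdiff(STATE_IDS, c("EtOH", "Glyc", "AMP"))
  # every simulated cycle counts against max_cycles, including the ones
  # consumed by finite-difference Jacobians of the shooting step
  cycle_map <- function(x) {
    legs <- ff_cycle_legs(as_state_vector(pmax(x, 0)), alloc, regime,
                          params, atol, rtol)
    n_run <<- n_run + 1L
    collapsed <- isTRUE(legs$feast$root_hit) ||
      isTRUE(legs$famine$root_hit)
    list(end = as_state_vector(legs$famine$states[
           nrow(legs$famine$states), ]),
         legs = legs, collapsed = collapsed)
  }
  # relaxation cycles interleaved with shooting (Newton on the cycle-map
  # fixed point), which removes the slow biomass/adenylate modes that
  # plain cycle-to-cycle relaxation decays through only algebraically
  relax_block <- 8L
  n_attempts <- 0L
  while (n_run < max_cycles) {
    converged <- FALSE
    for (k in seq_len(min(relax_block, max_cycles - n_run))) {
      cm <- cycle_map(st)
      end <- cm$end
      last <- cm$legs
      if (end[["X"]] < 1e-6 || cm$collapsed)
        return(assemble_cycle(cm$legs, n_run, converged = FALSE))
      rel <- max(abs(end[conv_ids] - st[conv_ids]) /
                 pmax(abs(st[conv_ids]), 0.05))
      st <- end
      if (rel < tol_cycle) { converged <- TRUE; break }
    }
    if (converged) return(assemble_cycle(last, n_run, converged = TRUE))
    if (n_run >= max_cycles) break
    if (n_attempts >= 1L) next
    n_attempts <- n_attempts + 1L
    # Shooting step in the reduced space: the dynamics conserve the
    # adenylate, NAD(H) and total-phosphate moieties, so the cycle map
    # has a continuum of fixed points along those directions. Newton
    # therefore solves for the free pools only, with AMP, NAD and Pi
    # derived from the conserved totals of the incoming state.
    axp0 <- st[["ATP"]] + st[["ADP"]] + st[["AMP"]]
    nad0 <- st[["NAD"]] + st[["NADH"]]
    ptot0 <- st[["Pi"]] + st[["G6P"]] + 2 * st[["FBP"]] +
      3 * st[["ATP"]] + 2 * st[["ADP"]] + st[["AMP"]]
    free_ids <- c("Glc_ex", "G6P", "FBP", "PYR", "ATP", "ADP", "NADH",
                  "Tre", "X")
    expand <- function(x) {
      x <- pmax(x, 0)
      names(x) <- free_ids
      amp <- axp0 - x[["ATP"]] - x[["ADP"]]
      nad <- nad0 - x[["NADH"]]
      pi_ <- ptot0 - (x[["G6P"]] + 2 * x[["FBP"]] + 3 * x[["ATP"]] +
                      2 * x[["ADP"]] + max(amp, 0))
      full <- st
      full[free_ids] <- x
      full["AMP"] <- amp
      full["NAD"] <- nad
      full["Pi"] <- pi_
      full
    }
    fit <- try(minpack.lm::nls.lm(
      par = unclass(st)[free_ids],
      fn = function(x) {
        full <- expand(x)
        if (any(full < 0)) return(rep(10, length(free_ids)))
        e <- cycle_map(full)$end
        (unclass(e)[free_ids] - unclass(full)[free_ids]) /
          pmax(abs(unclass(full)[free_ids]), 0.05)
      },
      lower = rep(0, length(free_ids)),
      control = minpack.lm::nls.lm.control(maxiter = 4, ftol = 1e-12,
                                           ptol = 1e-10)),
      silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cand <- expand(fit$par)
      if (all(cand >= 0)) {
        cand <- as_state_vector(cand)
        cm <- cycle_map(cand)
        if (cm$end[["X"]] >= 1e-6) {
          rel <- max(abs(cm$end[conv_ids] - cand[conv_ids]) /
                     pmax(abs(cand[conv_ids]), 0.05))
          if (rel < tol_cycle)
            return(assemble_cycle(cm$legs, n_run, converged = TRUE))
          base_rel <- max(abs(cycle_map(st)$end[conv_ids] - st[conv_ids]) /
                          pmax(abs(st[conv_ids]), 0.05))
          if (rel < base_rel) st <- cm$end
        }
      }
    }
  }
  assemble_cycle(last, max_cycles, converged = FALSE)
}

assemble_cycle <- function(legs, n_cycles, converged) {
  times <- c(legs$feast$times, legs$famine$times)
  states <- rbind(legs$feast$states, legs$famine$states)
  extras <- rbind(legs$feast$extras, legs$famine$extras)
  keep <- !duplicated(times)
  make_trajectory(times[keep], states[keep, , drop = FALSE],
                  extras[keep, , drop = FALSE], n_cycles = n_cycles,
                  converged = converged)
}

#' Time-weighted average substrate concentration
#'
#' The objective used to rank proteomes under dynamic feeding:
#' `int_0^TC c_s(t) * t dt / int_0^TC t dt`, computed by trapezoidal
#' quadrature on the solver grid. Late residual substrate is penalized
#' more than substrate present right after the feed, selecting for fast
#' consumption.
#'
#' @param traj a `trajectory` covering exactly one cycle, times measured
#'   from the cycle start.
#' @return time-weighted substrate concentration, mmol/L.
#' @export
time_weighted_substrate <- function(traj) {
  if (is.null(traj) || length(traj$times) < 2)
    stop("empty or degenerate trajectory")
  t <- traj$times
  cs <- traj$states[, "Glc_ex"]
  trapz(t, cs * t) / trapz(t, t)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Enzyme saturation statistics over a trajectory
#'
#' Per-reaction max, min and time-weighted mean of `v / Vmax` over a
#' cycle (or a single-point steady state). The two respiratory reactions
#' share one sector; their saturation is the electron-transport load
#' divided by the shared capacity `phi_Resp * kcat_Resp`. Maintenance has
#' no sector, and reactions with `Vmax = 0` are reported as `NA`
#' (undefined), not 0.
#'
#' @param traj a `trajectory` (balanced cycle) or a `steady_state`.
#' @param alloc the `proteome_allocation` used to generate it.
#' @param params a `kinetic_params`.
#' @return data.frame: reaction, max, min, mean saturation in `[0, 1]`.
#' @export
saturation_stats <- function(traj, alloc, params = default_params()) {
  if (inherits(traj, "steady_state")) {
    stopifnot(traj$feasible)
    v1 <- traj$fluxes
    load <- respiration_rates(traj$state, alloc$phi[["Resp"]],
                              params)[["load"]]
    fluxes <- matrix(v1, nrow = 1, dimnames = list(NULL, REACTION_IDS))
    loads <- load
    times <- 0
  } else {
    fluxes <- traj$fluxes
    loads <- traj$extras[, "load"]
    times <- traj$times
  }
  vmax <- alloc$phi[SECTOR_IDS] * params$kcat[SECTOR_IDS]
  sat_one <- function(values) {
    if (length(times) < 2) {
      c(max = max(values), min = min(values), mean = mean(values))
    } else {
      c(max = max(values), min = min(values),
        mean = trapz(times, values) / diff(range(times)))
    }
  }
  rows <- lapply(c(SECTOR_IDS), function(sec) {
    if (sec == "Resp") {
      if (vmax[["Resp"]] <= 0) return(c(max = NA, min = NA, mean = NA))
      return(sat_one(pmin(loads / vmax[["Resp"]], 1)))
    }
    if (vmax[[sec]] <= 0) return(c(max = NA, min = NA, mean = NA))
    sat_one(pmin(fluxes[, sec] / vmax[[sec]], 1))
  })
  out <- data.frame(reaction = SECTOR_IDS, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Glucose closure of a balanced cycle
#'
#' Glucose fed over one cycle versus glucose consumed plus residual
#' change, as a relative imbalance (should be ~0 for a balanced cycle).
#'
#' @param traj a balanced one-cycle `trajectory`.
#' @param regime the `feed_regime`.
#' @return relative imbalance (dimensionless).
#' @export
cycle_glucose_closure <- function(traj, regime) {
  t <- traj$times
  # evaluate the feed integral on the feast leg only: D(t) is the square
  # wave's left limit D_feed on [0, TF] and 0 afterwards, so quadrature
  # must not interpolate across the switch-off
  feast <- t * 3600 <= regime$TF + 1e-9
  tf_h <- regime$TF / 3600
  fed <- trapz(t[feast],
               regime$D_feed * (regime$glc_feed -
                                traj$states[feast, "Glc_ex"]))
  consumed <- trapz(t, traj$fluxes[, "Upt"] * traj$states[, "X"] * 1000)
  dres <- traj$states[nrow(traj$states), "Glc_ex"] - traj$states[1, "Glc_ex"]
  (fed - consumed - dres) / max(fed, 1e-12)
}
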