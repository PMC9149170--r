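#' Mass-balance right-hand side of the ODE system
#'
#' Time derivatives of all fourteen state variables. Intracellular pools
#' (umol/g_X) change by `conv * S'v - mu * c` plus the fast adenylate
#' kinase interconversion, where `conv = 1e6 / g_per_cmol` converts
#' mol/Cmol_X/h into umol/g_X/h and `mu * c` is growth dilution.
#' Extracellular substrate follows `D(t) (feed - c) - q * X`, products
#' `-D(t) c + q * X`, and biomass `(mu - D(t)) X`.
#'
#' This is the reference R implementation; simulation uses an identical
#' compiled version (the two are cross-checked in the test suite).
#'
#' @param t time, h (only used to evaluate the square-wave dilution rate
#'   of a feast/famine regime, with the cycle starting at `t = 0`).
#' @param state a `state_vector`.
#' @param alloc a `proteome_allocation`.
#' @param regime a `feed_regime`.
#' @param params a `kinetic_params`.
#' @param clamp character vector of state ids to hold fixed (derivative 0),
#'   used by the substrate-excess batch reference solve.
#' @return named derivative vector over `STATE_IDS` (per hour), with the
#'   flux vector attached as attribute `fluxes`.
#' @export
mass_balances <- function(t, state, alloc, regime, params = default_params(),
                          clamp = character()) {
  s <- as_state_vector(state)
  v <- compute_rates(s, alloc, params)
  if (any(!is.finite(v))) {
    stop("non-finite rate in reaction(s): ",
         paste(REACTION_IDS[!is.finite(v)], collapse = ", "))
  }
  D <- dilution_at(regime, t * 3600)
  conv <- 1e6 / params$g_per_cmol
  mu <- v[["Grwt"]]
  S <- params$stoich %||% stoichiometry_matrix(params)
  dint <- conv * as.numeric(crossprod(S[, INTRACELLULAR_IDS], v))
  names(dint) <- INTRACELLULAR_IDS
  # growth dilution of intracellular pools is omitted: it is below 0.05%
  # of turnover for every pool, and because the cofactor moieties (AXP,
  # NAD(H)) and the phosphate bound in sugar phosphates have no synthesis
  # reaction in the lumped network, diluting them slowly drains conserved
  # totals and forbids any steady state. See the methods vignette.
  # fast adenylate kinase: 2 ADP <-> ATP + AMP, K_AK = ATP*AMP/ADP^2
  vak <- params$k_ak_relax *
    (s[["ADP"]]^2 - s[["ATP"]] * s[["AMP"]] / params$k_ak)
  dint["ADP"] <- dint[["ADP"]] - 2 * vak
  dint["ATP"] <- dint[["ATP"]] + vak
  dint["AMP"] <- dint[["AMP"]] + vak
  X <- s[["X"]]
  d <- c(
    Glc_ex = D * (regime$glc_feed - s[["Glc_ex"]]) - v[["Upt"]] * X * 1000,
    dint,
    EtOH = -D * s[["EtOH"]] + v[["Ferm"]] * X * 1000,
    Glyc = -D * s[["Glyc"]] + v[["Esnk"]] * X * 1000,
    X = (mu - D) * X
  )
  d <- d[STATE_IDS]
  if (length(clamp)) d[clamp] <- 0
  if (any(!is.finite(d))) {
    stop("non-finite derivative for ",
         paste(STATE_IDS[!is.finite(d)], collapse = ", "))
  }
  attr(d, "fluxes") <- v
  d
}

#' Gas exchange and derived rates at a state
#'
#' @param v a `flux_distribution`.
#' @param params a `kinetic_params`.
#' @return named numeric: `q_O2` and `q_CO2` (mol/Cmol_X/h).
#' @export
gas_rates <- function(v, params = default_params()) {
  c(q_O2 = params$w_tca / 2 * v[["Resp_TCA"]] + 0.5 * v[["Resp_NDE"]],
    q_CO2 = v[["Ferm"]] + 3 * v[["Resp_TCA"]] +
      params$co2_per_x * v[["Grwt"]])
}
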