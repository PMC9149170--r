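#' Phenotype record of a steady state or balanced cycle
#'
#' Collects the physiological rates a sweep reports per condition:
#' specific substrate uptake, ethanol excretion, oxygen uptake, growth
#' rate, biomass yield, plus the allocation's overcapacity. For a
#' balanced cycle all rates are time-weighted means.
#'
#' @param x a `steady_state` or a balanced one-cycle `trajectory`.
#' @param alloc the `proteome_allocation`.
#' @param params a `kinetic_params`.
#' @param regime the `feed_regime` (used for cycle averaging).
#' @return a one-row data.frame: q_s, q_EtOH, q_O2, q_CO2, mu, Y_XS,
#'   EC_mean, overcapacity.
#' @export
phenotype_record <- function(x, alloc, params = default_params(),
                             regime = NULL) {
  if (inherits(x, "steady_state")) {
    stopifnot(x$feasible)
    v <- x$fluxes
    g <- gas_rates(v, params)
    q_s <- v[["Upt"]]; q_e <- v[["Ferm"]]; mu <- v[["Grwt"]]
    q_o2 <- g[["q_O2"]]; q_co2 <- g[["q_CO2"]]
    ec <- energy_charge(x$state)
  } else {
    t <- x$times
    span <- diff(range(t))
    avg <- function(y) trapz(t, y) / span
    q_s <- avg(x$fluxes[, "Upt"]); q_e <- avg(x$fluxes[, "Ferm"])
    mu <- avg(x$fluxes[, "Grwt"])
    q_o2 <- avg(x$extras[, "q_O2"]); q_co2 <- avg(x$extras[, "q_CO2"])
    ec <- avg(x$extras[, "EC"])
  }
  data.frame(q_s = unname(q_s), q_EtOH = unname(q_e),
             q_O2 = unname(q_o2), q_CO2 = unname(q_co2),
             mu = unname(mu),
             Y_XS = unname(if (q_s > 0) mu / (6 * q_s) else NA_real_),
             EC_mean = unname(ec),
             overcapacity = overcapacity_fraction(alloc))
}

#' Proteome-specific ATP yields of fermentation and respiration
#'
#' ATP production rate of each catabolic route divided by the protein
#' mass of the sectors carrying it, in mol ATP per g protein per hour
#' (protein mass = sector fraction x 0.5 g protein/g_X x g_X/Cmol_X).
#' The fermentative route comprises the glycolytic sectors (Upt, UGlc,
#' LGlc) prorated by the carbon fraction routed to fermentation, plus the
#' fermentation sector; its ATP is the prorated net glycolytic
#' substrate-level phosphorylation. Respiration is the Resp sector alone;
#' its ATP is the TCA substrate-level plus chain phosphorylation. A
#' pathway with zero sector mass yields `NA` (undefined), not 0.
#'
#' @param fluxes a `flux_distribution` from a steady state.
#' @param alloc the `proteome_allocation`.
#' @param params a `kinetic_params`.
#' @param include_shared prorate the shared upstream glycolytic sectors
#'   into the fermentative route (default TRUE)?
#' @return named numeric: `fermentation`, `respiration`
#'   (mol ATP/g protein/h).
#' @export
atp_yield_per_protein <- function(fluxes, alloc,
                                  params = default_params(),
                                  include_shared = TRUE) {
  v <- fluxes
  phi <- alloc$phi
  g_prot_per_cmol <- params$protein_g_per_gx * params$g_per_cmol
  # carbon routing of pyruvate
  pyr_dest <- c(ferm = v[["Ferm"]], tca = v[["Resp_TCA"]],
                grwt = params$pyr_per_x * v[["Grwt"]])
  rho_ferm <- if (sum(pyr_dest) > 0) pyr_dest[["ferm"]] / sum(pyr_dest) else 0
  # net glycolytic substrate-level ATP
  atp_glyc <- 2 * v[["LGlc"]] - v[["Upt"]] - v[["UGlc"]]
  atp_ferm <- rho_ferm * atp_glyc
  mass_ferm <- phi[["Ferm"]] +
    if (include_shared) rho_ferm * (phi[["Upt"]] + phi[["UGlc"]] +
                                    phi[["LGlc"]]) else 0
  atp_resp <- params$a_tca * v[["Resp_TCA"]] +
    params$po_ratio * v[["Resp_NDE"]]
  mass_resp <- phi[["Resp"]]
  yield <- function(atp, mass) {
    if (mass <= 0) return(NA_real_)
    atp / (mass * g_prot_per_cmol)
  }
  c(fermentation = yield(atp_ferm, mass_ferm),
    respiration = yield(atp_resp, mass_resp))
}

#' Per-sector fold changes between two allocations
#'
#' Ratio `b / a` per sector; a sector with zero baseline is reported as
#' `NA` (no fold change computable).
#'
#' @param alloc_a baseline `proteome_allocation`.
#' @param alloc_b comparison `proteome_allocation`.
#' @return named numeric over sectors.
#' @export
sector_fold_changes <- function(alloc_a, alloc_b) {
  a <- alloc_a$phi
  b <- alloc_b$phi
  ifelse(a > 0, b / a, NA_real_)
}

#' Table of per-reaction saturation over a condition pair
#'
#' Convenience wrapper binding chemostat and feast/famine saturation
#' statistics into one comparison table.
#'
#' @param ff_stats data.frame from [saturation_stats()] on the balanced
#'   cycle.
#' @param ss_stats data.frame from [saturation_stats()] on the chemostat
#'   steady state.
#' @return merged data.frame with columns max_ff, min_ff, mean_ff,
#'   chemostat.
#' @export
saturation_table <- function(ff_stats, ss_stats) {
  out <- data.frame(reaction = ff_stats$reaction,
                    max_ff = ff_stats$max, min_ff = ff_stats$min,
                    mean_ff = ff_stats$mean,
                    chemostat = ss_stats$mean[match(ff_stats$reaction,
                                                    ss_stats$reaction)])
  out
}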