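#' Sector-scaled reaction rates
#'
#' Evaluates all eleven lumped reaction rates at a state. Each sector-bound
#' rate is `v_i = phi_i * kcat_i * f_i(c)`, where `f_i` is a dimensionless
#' saturation function in `[0, 1]` built from generalized Michaelis-Menten
#' terms in the reaction's substrates and cofactors, with one allosteric
#' term where the source kinetics require it (FBP activation of the
#' fermentative branch, G6P activation of trehalose synthesis) and
#' sigmoidal substrate dependence of the pyruvate decarboxylase branch.
#' The two respiratory reactions share the `Resp` sector through a common
#' electron-transport capacity (see [respiration_rates()]); maintenance is
#' a fixed, sector-free ATP drain saturating in ATP.
#'
#' @param state a `state_vector`.
#' @param alloc a `proteome_allocation`.
#' @param params a `kinetic_params`.
#' @return a named numeric vector of class `flux_distribution` over
#'   `REACTION_IDS` (mol/Cmol_X/h; `Grwt` in 1/h).
#' @export
compute_rates <- function(state, alloc, params = default_params()) {
  if (any(is.na(state))) stop("state contains NaN/NA")
  if (any(params$km <= 0)) stop("affinity constants must be > 0")
  s <- as_state_vector(state)
  phi <- alloc$phi
  k <- params$kcat
  f <- saturation_functions(s, params)
  v <- stats::setNames(numeric(length(REACTION_IDS)), REACTION_IDS)
  for (r in c("Upt", "UGlc", "LGlc", "Ferm", "Esnk", "TrSn", "TrDg")) {
    v[r] <- phi[[r]] * k[[r]] * f[[r]]
  }
  resp <- respiration_rates(s, phi[["Resp"]], params)
  v["Resp_TCA"] <- resp[["v_TCA"]]
  v["Resp_NDE"] <- resp[["v_NDE"]]
  # a fully drained adenylate pool means no phosphorylation potential:
  # energy charge 0 (the compiled implementation does the same)
  ec <- if (s[["ATP"]] + s[["ADP"]] + s[["AMP"]] > 0) energy_charge(s) else 0
  v["Grwt"] <- growth_rate(ec, phi[["Grwt"]], k[["Grwt"]],
                           params) * f[["Grwt_precursor"]]
  v["Mnt"] <- params$maintenance_rate *
    s[["ATP"]] / (s[["ATP"]] + params$km_atp_mnt)
  class(v) <- c("flux_distribution", "numeric")
  v
}

# dimensionless saturation terms, all in [0,1]
saturation_functions <- function(s, p) {
  km <- p$km; ka <- p$ka; h <- p$hill
  mm <- function(x, k) x / (x + k)
  hill <- function(x, k, n) x^n / (x^n + k^n)
  ki <- p$ki
  list(
    Upt  = mm(s[["Glc_ex"]], km[["glc_upt"]]) * mm(s[["ATP"]], km[["atp_upt"]]) *
           ki[["g6p_upt"]] / (ki[["g6p_upt"]] + s[["G6P"]]),
    # AMP activation: adenylate (PFK-type) control tying carbon influx
    # to the energy state
    UGlc = mm(s[["G6P"]], km[["g6p_uglc"]]) * mm(s[["ATP"]], km[["atp_uglc"]]) *
           mm(s[["AMP"]], ka[["amp_uglc"]]),
    # the pyruvate term is back-pressure of the lumped reversible segment:
    # negligible at physiological pools, throttles production when
    # pyruvate accumulates so the overflow gate (FBP) can open
    LGlc = mm(s[["FBP"]], km[["fbp_lglc"]]) * mm(s[["NAD"]], km[["nad_lglc"]]) *
           mm(s[["Pi"]], km[["pi_lglc"]]) * mm(s[["ADP"]], km[["adp_lglc"]]) *
           ki[["pyr_lglc"]] / (ki[["pyr_lglc"]] + s[["PYR"]]),
    Ferm = hill(s[["PYR"]], km[["pyr_ferm"]], h[["pyr_ferm"]]) *
           mm(s[["NADH"]], km[["nadh_ferm"]]) *
           hill(s[["FBP"]], ka[["fbp_ferm"]], h[["fbp_ferm"]]),
    Esnk = mm(s[["FBP"]], km[["fbp_esnk"]]) * mm(s[["NADH"]], km[["nadh_esnk"]]),
    # oxidative phosphorylation requires inorganic phosphate; the Pi term
    # also enforces the nonnegativity contract (rate -> 0 as Pi -> 0)
    TCA  = mm(s[["PYR"]], km[["pyr_tca"]]) * mm(s[["ADP"]], km[["adp_tca"]]) *
           mm(s[["Pi"]], km[["pi_resp"]]),
    NDE  = mm(s[["NADH"]], km[["nadh_nde"]]) * mm(s[["ADP"]], km[["adp_nde"]]) *
           mm(s[["Pi"]], km[["pi_resp"]]),
    TrSn = hill(s[["G6P"]], ka[["g6p_trsn"]], h[["g6p_trsn"]]) *
           mm(s[["ATP"]], km[["atp_trsn"]]),
    TrDg = mm(s[["Tre"]], km[["tre_trdg"]]) * mm(s[["ATP"]], km[["atp_trdg"]]),
    # precursor availability terms of the growth reaction (narrow Km so
    # they only act to shut growth down when a precursor pool empties)
    Grwt_precursor = mm(s[["G6P"]], km[["g6p_grwt"]]) *
                     mm(s[["PYR"]], km[["pyr_grwt"]])
  )
}

#' Growth rate from the energy charge
#'
#' The growth flux is `phi_Grwt * kcat_Grwt * sigma(EC)` with a logistic
#' sigmoid `sigma(ec) = 1 / (1 + exp(-(ec - ec_mid) / ec_slope))`. With the
#' defaults (midpoint 0.8, scale 0.05) the response is steepest between
#' energy charges of 0.7 and 0.9, the range observed for growing cells.
#'
#' @param ec energy charge in `[0, 1]`.
#' @param phi_grwt growth sector fraction.
#' @param kcat_grwt growth sector specific activity (1/h at phi = 1).
#' @param params a `kinetic_params` (supplies the sigmoid constants).
#' @return specific growth flux, 1/h.
#' @export
growth_rate <- function(ec, phi_grwt, kcat_grwt,
                        params = default_params()) {
  stopifnot(ec >= 0, ec <= 1)
  gs <- params$growth_sigmoid
  sigma <- 1 / (1 + exp(-(ec - gs[["ec_mid"]]) / gs[["ec_slope"]]))
  phi_grwt * kcat_grwt * sigma
}

#' Respiratory rates under the shared electron-transport capacity
#'
#' Pyruvate oxidation (`v_TCA`, Michaelis-Menten in PYR and ADP) and
#' external NADH dehydrogenase (`v_NDE`, Michaelis-Menten in NADH and ADP)
#' both feed the electron-transport chain and are bounded by the single
#' respiration sector: if the combined load `w_TCA * v_TCA + v_NDE`
#' (electron pairs) exceeds `phi_Resp * kcat_Resp`, both rates are scaled
#' by the common factor that makes the load bind exactly.
#'
#' @param state a `state_vector`.
#' @param phi_resp respiration sector fraction.
#' @param params a `kinetic_params`.
#' @return named numeric: `v_TCA`, `v_NDE` (mol/Cmol_X/h) and the
#'   realized electron-pair `load`.
#' @export
respiration_rates <- function(state, phi_resp, params = default_params()) {
  s <- as_state_vector(state)
  f <- saturation_functions(s, params)
  cap <- phi_resp * params$kcat[["Resp"]]
  # unconstrained rates: each branch alone could draw the full capacity
  v_tca <- cap / params$w_tca * f$TCA
  v_nde <- cap * f$NDE
  load <- params$w_tca * v_tca + v_nde
  if (load > cap && load > 0) {
    sc <- cap / load
    v_tca <- v_tca * sc
    v_nde <- v_nde * sc
    load <- cap
  }
  c(v_TCA = v_tca, v_NDE = v_nde, load = load)
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Specific rates (mol/Cmol_X/h; Grwt in 1/h)\n")
  print(signif(unclass(x), 4))
  invisible(x)
}
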