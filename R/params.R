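#' Kinetic parameter set
#'
#' Constructs the full parameter set of the proteome-dependent kinetic
#' model: maximum specific pathway activities per unit proteome fraction
#' (`kcat`, mol/Cmol_X/h at phi = 1, where a full proteome corresponds to
#' 500 mg protein per g_X), saturation and allosteric constants of the
#' lumped rate laws, the growth sigmoid acting on the adenylate energy
#' charge, respiratory and growth stoichiometry, maintenance, and unit
#' conversion constants.
#'
#' Every value can be overridden through `...` (by name), so an external
#' parameterization can be dropped in without code changes.
#'
#' Units: extracellular concentrations mmol/L, intracellular pools
#' umol/g_X, fluxes mol/Cmol_X/h, biomass Cmol/L.
#'
#' @param ... named overrides of any default entry.
#' @return An object of class `kinetic_params` (a validated named list).
#' @export
default_params <- function(...) {
  p <- list(
    # maximum specific activities per sector, mol/Cmol_X/h at phi = 1.
    # Calibrated against the batch flux/proteome reference shipped with the
    # package (see estimate_kcats and the methods vignette); kcat_Resp is in
    # electron-pair (NADH-equivalent) load units shared by the two
    # respiratory reactions; kcat_Grwt is in Cmol_X/Cmol_X/h (= 1/h).
    kcat = c(Upt = 8.5641, UGlc = 13.9181, LGlc = 15.4213, Ferm = 35.9512,
             Esnk = 31.7798, Resp = 7.4559, TrSn = 6.6592, TrDg = 1.9142,
             Grwt = 1.3831),

    # saturation / affinity constants (km), inhibition (ki) unused by the
    # default rate laws, activation (ka); intracellular in umol/g_X,
    # km_glc in mmol/L
    km = c(glc_upt = 1.0, atp_upt = 0.3,
           g6p_uglc = 1.0, atp_uglc = 0.3,
           fbp_lglc = 0.5, nad_lglc = 0.3, pi_lglc = 1.0, adp_lglc = 0.3,
           pyr_ferm = 6.0, nadh_ferm = 0.05,
           fbp_esnk = 2.0, nadh_esnk = 0.3,
           pyr_tca = 1.0, adp_tca = 0.2,
           nadh_nde = 0.3, adp_nde = 0.2,
           pi_resp = 0.5,
           atp_trsn = 0.5,
           tre_trdg = 3.0, atp_trdg = 0.3,
           g6p_grwt = 0.02, pyr_grwt = 0.02,
           atp_mnt = 0.1),
    ka = c(fbp_ferm = 0.3, g6p_trsn = 3.0,
           # AMP activation of the upper-glycolysis lump: the adenylate
           # control of phosphofructokinase that couples carbon influx to
           # the cell's energy state (throttles glycolysis under energy
           # surplus, opens it when ATP is drawn down)
           amp_uglc = 0.01),
    # G6P-proxy inhibition of the uptake/hexokinase lump (stands in for
    # trehalose-6-phosphate inhibition of hexokinase, the brake that
    # protects glycolysis from the substrate-accelerated "turbo" collapse)
    ki = c(g6p_upt = 12,
           # mass-action back-pressure of the lumped (reversible in vivo)
           # lower-glycolysis segment: only bites when pyruvate
           # accumulates far above its physiological range, throttling
           # production so that the FBP pool (and with it the
           # fermentative gate) rises instead
           pyr_lglc = 50),
    # Hill coefficients of the sigmoidal terms (pyruvate decarboxylase
    # branch and trehalose-6-P synthase)
    hill = c(pyr_ferm = 2, fbp_ferm = 2, g6p_trsn = 2),

    # growth sigmoid on energy charge: midpoint and logistic scale chosen
    # so the response is steepest between EC 0.7 and 0.9
    growth_sigmoid = c(ec_mid = 0.8, ec_slope = 0.05),

    # maintenance ATP hydrolysis, mol ATP/Cmol_X/h (growth independent)
    maintenance_rate = 0.0155,
    km_atp_mnt = 0.1,

    # respiration stoichiometry: w_tca electron-pair carriers (4 NADH +
    # 1 FADH2) per pyruvate fully oxidized; po_ratio mol ATP per
    # electron pair delivered to the chain
    po_ratio = 1.0,
    w_tca = 5,

    # growth reaction drains per Cmol biomass formed; nadh_per_x and
    # co2_per_x are derived so carbon and degree of reduction close exactly
    g6p_per_x = 0.12,
    pyr_per_x = 0.12,
    atp_per_x = 3.22,
    dor_x = 4.2,

    # adenylate kinase equilibrium (ATP*AMP/ADP^2) and relaxation constant
    k_ak = 1.0,
    k_ak_relax = 3e5,

    # conversions
    g_per_cmol = 26.4,          # g dry weight per Cmol biomass
    protein_g_per_gx = 0.5,     # g protein per g dry weight at phi = 1

    # mitochondrial constraint: maximum respiration sector fraction
    resp_cap = 0.12,
    cap_enabled = TRUE,

    # conserved moiety totals used by the default initial state
    axp_total = 4.79,
    nad_total = 3.0
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm)
    if (is.null(names(dots[[nm]])) || is.null(names(p[[nm]]))) {
      p[[nm]] <- dots[[nm]]
    } else {
      repl <- dots[[nm]]
      bad <- setdiff(names(repl), names(p[[nm]]))
      if (length(bad)) stop("unknown entries in ", nm, ": ",
                            paste(bad, collapse = ", "))
      p[[nm]][names(repl)] <- repl
    }
  }
  p <- derive_params(p)
  validate_params(p)
  p
}

# fill in derived stoichiometric coefficients
derive_params <- function(p) {
  # carbon closure: 6*g6p + 3*pyr = 1 (biomass Cmol) + co2
  p$co2_per_x <- 6 * p$g6p_per_x + 3 * p$pyr_per_x - 1
  # electron closure: 24*g6p + 10*pyr + 2*nadh_consumed = dor_x
  p$nadh_per_x <- (p$dor_x - 24 * p$g6p_per_x - 10 * p$pyr_per_x) / 2
  # ATP formed per pyruvate through the TCA lump (1 substrate level +
  # chain phosphorylation of its w_tca carriers)
  p$a_tca <- 1 + p$w_tca * p$po_ratio
  class(p) <- "kinetic_params"
  # cache the stoichiometric matrix: it is queried on every right-hand
  # side evaluation of the reference R implementation
  p$stoich <- stoichiometry_matrix(p)
  p
}

#' Validate a kinetic parameter set
#'
#' @param p a `kinetic_params` object.
#' @return `p`, invisibly; signals an error on violation.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (!identical(names(p$kcat), SECTOR_IDS))
    stop("kcat must be named by the nine sector ids")
  if (any(!is.finite(p$kcat)) || any(p$kcat <= 0))
    stop("all kcat must be finite and > 0")
  if (any(!is.finite(p$km)) || any(p$km <= 0))
    stop("all affinity constants must be finite and > 0")
  if (any(p$ka <= 0)) stop("activation constants must be > 0")
  if (any(p$ki <= 0)) stop("inhibition constants must be > 0")
  if (p$maintenance_rate <= 0) stop("maintenance_rate must be > 0")
  if (p$co2_per_x < 0)
    stop("growth precursor drains provide less than 1 Cmol carbon")
  if (p$po_ratio <= 0 || p$w_tca <= 0) stop("respiratory stoichiometry > 0")
  if (p$resp_cap <= 0 || p$resp_cap > 1) stop("resp_cap must be in (0,1]")
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameter set (proteome-dependent yeast model)\n")
  cat("  kcat [mol/Cmol_X/h at phi=1]:\n")
  print(round(x$kcat, 4))
  cat("  maintenance:", x$maintenance_rate, "mol ATP/Cmol_X/h",
      " P/O:", x$po_ratio, " w_TCA:", x$w_tca, "\n")
  cat("  growth drains per Cmol_X: G6P", x$g6p_per_x, " PYR", x$pyr_per_x,
      " ATP", x$atp_per_x, "\n")
  cat("  respiration sector cap:",
      if (isTRUE(x$cap_enabled)) x$resp_cap else "disabled", "\n")
  invisible(x)
}

# ---- flat numeric vector passed to the compiled RHS --------------------

# Layout shared with src/model_rhs.c; order matters. The regime block is
# appended by the integrator.
param_vector <- function(alloc, params, regime_block) {
  p <- params
  c(unname(alloc$phi),                                   # 1:9
    unname(p$kcat),                                      # 10:18
    unname(p$growth_sigmoid),                            # 19:20
    unname(p$km[c("glc_upt", "atp_upt", "g6p_uglc", "atp_uglc",
                  "fbp_lglc", "nad_lglc", "pi_lglc", "adp_lglc",
                  "pyr_ferm", "nadh_ferm", "fbp_esnk", "nadh_esnk",
                  "pyr_tca", "adp_tca", "nadh_nde", "adp_nde",
                  "pi_resp",
                  "atp_trsn", "tre_trdg", "atp_trdg",
                  "g6p_grwt", "pyr_grwt")]),             # 21:42
    unname(p$ka[c("fbp_ferm", "g6p_trsn", "amp_uglc")]), # 43:45
    unname(p$ki[c("g6p_upt", "pyr_lglc")]),              # 46:47
    unname(p$hill[c("pyr_ferm", "fbp_ferm", "g6p_trsn")]), # 48:50
    p$maintenance_rate, p$km_atp_mnt,                    # 50:51
    p$po_ratio, p$w_tca, p$a_tca,                        # 52:54
    p$g6p_per_x, p$pyr_per_x, p$atp_per_x,
    p$nadh_per_x, p$co2_per_x,                           # 55:59
    p$g_per_cmol, p$k_ak, p$k_ak_relax,                  # 60:62
    regime_block)                                        # 63:68
}

# regime block layout: D, glc_feed, clamp_glc, glc_clamp, clamp_tre,
# tre_clamp (D constant per integration leg; feast/famine is integrated
# piecewise at the R level so the RHS never sees a discontinuity)
regime_vector <- function(D, glc_feed, clamp_glc = 0, glc_clamp = 0,
                          clamp_tre = 0, tre_clamp = 0) {
  c(D, glc_feed, clamp_glc, glc_clamp, clamp_tre, tre_clamp)
}
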