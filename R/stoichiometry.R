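#' Stoichiometric matrix of the lumped network
#'
#' Returns the signed stoichiometric matrix (reactions x species) of the
#' eleven lumped reactions. Species comprise the ten intracellular pools
#' plus the exchanged species `Glc_ex`, `EtOH`, `Glyc`, `CO2`, `O2` and
#' biomass `X`, so the matrix supports exact elemental-closure checks;
#' the ODE right-hand side uses the intracellular columns only.
#'
#' Lumps (C3 basis for lower glycolysis and the glycerol sink):
#' \describe{
#'   \item{Upt}{Glc_ex + ATP -> G6P + ADP (transport + hexokinase)}
#'   \item{UGlc}{G6P + ATP -> FBP + ADP}
#'   \item{LGlc}{1/2 FBP + Pi + NAD + 2 ADP -> PYR + NADH + 2 ATP}
#'   \item{Ferm}{PYR + NADH -> EtOH + CO2 + NAD}
#'   \item{Esnk}{1/2 FBP + NADH -> Glyc + NAD + Pi}
#'   \item{Resp_TCA}{PYR + a ADP + a Pi + w/2 O2 -> 3 CO2 + a ATP, with
#'     a = 1 + w * P/O; the w mitochondrial electron pairs per pyruvate are
#'     generated and oxidized inside the lump}
#'   \item{Resp_NDE}{NADH + P/O ADP + P/O Pi + 1/2 O2 -> NAD + P/O ATP}
#'   \item{TrSn}{2 G6P + ATP -> Tre + ADP + 3 Pi}
#'   \item{TrDg}{Tre + 2 ATP -> 2 G6P + 2 ADP}
#'   \item{Grwt}{g6p_per_x G6P + pyr_per_x PYR + atp_per_x ATP +
#'     nadh_per_x NADH -> 1 X + co2_per_x CO2 (+ ADP, Pi, NAD back);
#'     the PPP NADPH drain is folded into the G6P coefficient}
#'   \item{Mnt}{ATP -> ADP + Pi}
#' }
#'
#' @param params a `kinetic_params` object.
#' @return numeric matrix, rownames `REACTION_IDS`, colnames species.
#' @export
stoichiometry_matrix <- function(params = default_params()) {
  p <- params
  species <- c(INTRACELLULAR_IDS, "Glc_ex", "EtOH", "Glyc", "CO2", "O2", "X")
  S <- matrix(0, nrow = length(REACTION_IDS), ncol = length(species),
              dimnames = list(REACTION_IDS, species))
  a <- p$a_tca
  po <- p$po_ratio
  S["Upt", c("Glc_ex", "ATP", "G6P", "ADP")] <- c(-1, -1, 1, 1)
  S["UGlc", c("G6P", "ATP", "FBP", "ADP")] <- c(-1, -1, 1, 1)
  S["LGlc", c("FBP", "Pi", "NAD", "ADP", "PYR", "NADH", "ATP")] <-
    c(-0.5, -1, -1, -2, 1, 1, 2)
  S["Ferm", c("PYR", "NADH", "EtOH", "CO2", "NAD")] <- c(-1, -1, 1, 1, 1)
  S["Esnk", c("FBP", "NADH", "Glyc", "NAD", "Pi")] <- c(-0.5, -1, 1, 1, 1)
  S["Resp_TCA", c("PYR", "ADP", "Pi", "O2", "CO2", "ATP")] <-
    c(-1, -a, -a, -p$w_tca / 2, 3, a)
  S["Resp_NDE", c("NADH", "ADP", "Pi", "O2", "NAD", "ATP")] <-
    c(-1, -po, -po, -0.5, 1, po)
  S["TrSn", c("G6P", "ATP", "Tre", "ADP", "Pi")] <- c(-2, -1, 1, 1, 3)
  S["TrDg", c("Tre", "ATP", "G6P", "ADP")] <- c(-1, -2, 2, 2)
  S["Grwt", c("G6P", "PYR", "ATP", "NADH", "ADP", "Pi", "NAD", "X", "CO2")] <-
    c(-p$g6p_per_x, -p$pyr_per_x, -p$atp_per_x, -p$nadh_per_x,
      p$atp_per_x, p$atp_per_x + p$g6p_per_x, p$nadh_per_x, 1, p$co2_per_x)
  S["Mnt", c("ATP", "ADP", "Pi")] <- c(-1, 1, 1)
  S
}

#' Elemental composition vectors
#'
#' Carbon atoms, degree of reduction (electrons available for transfer to
#' O2, with gamma(NADH) - gamma(NAD) = 2 and gamma(O2) = -4) and total
#' phosphorus per species, used for closure checks of the stoichiometry:
#' each vector must lie in the left null space of
#' [stoichiometry_matrix()].
#'
#' @param params a `kinetic_params`.
#' @return a list with numeric vectors `carbon`, `dor`, `phosphorus`
#'   named by species.
#' @export
elemental_vectors <- function(params = default_params()) {
  species <- colnames(stoichiometry_matrix(params))
  z <- stats::setNames(numeric(length(species)), species)
  carbon <- z; dor <- z; phos <- z
  carbon[c("G6P", "FBP", "PYR", "Tre", "Glc_ex", "EtOH", "Glyc",
           "CO2", "X")] <- c(6, 6, 3, 12, 6, 2, 3, 1, 1)
  dor[c("G6P", "FBP", "PYR", "Tre", "Glc_ex", "EtOH", "Glyc",
        "NADH", "O2", "X")] <- c(24, 24, 10, 48, 24, 12, 14, 2, -4,
                                 params$dor_x)
  phos[c("G6P", "FBP", "ATP", "ADP", "AMP", "Pi")] <- c(1, 2, 3, 2, 1, 1)
  list(carbon = carbon, dor = dor, phosphorus = phos)
}
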