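#' Sector, reaction and state identifiers
#'
#' The model divides the catalytically active proteome into nine sectors,
#' each bounding the Vmax of one lumped pathway: glucose uptake (`Upt`,
#' transport plus hexokinase), upper glycolysis (`UGlc`), lower glycolysis
#' (`LGlc`, per C3 unit), fermentation to ethanol (`Ferm`), the glycerol
#' electron sink (`Esnk`), respiration (`Resp`, a single sector shared by
#' pyruvate oxidation and external NADH dehydrogenase through the common
#' electron-transport chain), trehalose synthesis (`TrSn`) and degradation
#' (`TrDg`), and growth (`Grwt`). Maintenance (`Mnt`) carries no sector.
#'
#' @format Character vectors of canonical identifiers.
#' @name identifiers
NULL

#' @rdname identifiers
#' @export
SECTOR_IDS <- c("Upt", "UGlc", "LGlc", "Ferm", "Esnk", "Resp",
                "TrSn", "TrDg", "Grwt")

#' @rdname identifiers
#' @export
REACTION_IDS <- c("Upt", "UGlc", "LGlc", "Ferm", "Esnk", "Resp_TCA",
                  "Resp_NDE", "TrSn", "TrDg", "Grwt", "Mnt")

#' @rdname identifiers
#' @export
STATE_IDS <- c("Glc_ex", "G6P", "FBP", "PYR", "ATP", "ADP", "AMP",
               "NAD", "NADH", "Pi", "Tre", "EtOH", "Glyc", "X")

# sector that bounds each reaction; NA for maintenance
REACTION_SECTOR <- c(Upt = "Upt", UGlc = "UGlc", LGlc = "LGlc",
                     Ferm = "Ferm", Esnk = "Esnk", Resp_TCA = "Resp",
                     Resp_NDE = "Resp", TrSn = "TrSn", TrDg = "TrDg",
                     Grwt = "Grwt", Mnt = NA_character_)

# intracellular pools (umol/g_X) subject to growth dilution
INTRACELLULAR_IDS <- c("G6P", "FBP", "PYR", "ATP", "ADP", "AMP",
                       "NAD", "NADH", "Pi", "Tre")
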