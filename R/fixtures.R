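#' Fixture specification for synthetic protein tables
#'
#' @param n_proteins total number of proteins to generate.
#' @param sector_targets named numeric, target mass fraction per sector
#'   (must sum to <= 1; the remainder becomes unannotated mass).
#' @param noise_cv coefficient of variation of per-protein abundance
#'   noise (0 = exact round trip).
#' @param rng_seed integer seed; all fixtures are deterministic given it.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 200,
                         sector_targets = batch_allocation()$phi,
                         noise_cv = 0, rng_seed = 1) {
  bad <- setdiff(names(sector_targets), SECTOR_IDS)
  if (length(bad)) stop("unknown sectors: ", paste(bad, collapse = ", "))
  if (sum(sector_targets) > 1 + 1e-9)
    stop("sector mass targets sum to more than 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(n_proteins = n_proteins,
                 sector_targets = sector_targets,
                 noise_cv = noise_cv, rng_seed = rng_seed),
            class = "fixture_spec")
}

# annotation vocabulary that exercises the shipped mapping rules
FIXTURE_VOCAB <- list(
  Upt  = list(names = c("Hexokinase %d", "Hexose transporter HXT%d",
                        "Glucokinase GLK1"),
              label = "Metabolism; Central Carbon Metabolism"),
  UGlc = list(names = c("Phosphofructokinase subunit %d",
                        "Phosphoglucose isomerase PGI1"),
              label = "Metabolism; Central Carbon Metabolism"),
  LGlc = list(names = c("Glyceraldehyde-3-phosphate dehydrogenase TDH%d",
                        "Enolase ENO%d", "Pyruvate kinase CDC19",
                        "Phosphoglycerate kinase PGK1"),
              label = "Metabolism; Central Carbon Metabolism"),
  Ferm = list(names = c("Pyruvate decarboxylase PDC%d",
                        "Alcohol dehydrogenase ADH%d"),
              label = "Metabolism; Central Carbon Metabolism"),
  Esnk = list(names = c("Glycerol-3-phosphate dehydrogenase GPD%d",
                        "Glycerol-3-phosphatase GPP%d"),
              label = "Metabolism; Central Carbon Metabolism"),
  Resp = list(names = c("Cytochrome c oxidase subunit %d",
                        "ATP synthase subunit %d", "Protein MIT%d"),
              label = "Metabolism; Energy Metabolism"),
  TrSn = list(names = c("Trehalose-phosphate synthase TPS1",
                        "Trehalose synthesis regulator TPS%d"),
              label = "Metabolism; Central Carbon Metabolism"),
  TrDg = list(names = c("Neutral trehalase NTH1", "Acid trehalase ATH1"),
              label = "Metabolism; Central Carbon Metabolism"),
  Grwt = list(names = c("Ribosomal protein L%d", "Ribosomal protein S%d",
                        "Translation factor TEF%d",
                        "Amino-acid biosynthesis protein %d"),
              label = "Genetic Information Processing")
)

#' Generate a synthetic protein table
#'
#' Builds a (protein, mass fraction, annotation) table whose annotations
#' are drawn from a vocabulary matching the shipped sector-mapping rules,
#' such that [map_to_sectors()] recovers the target sector masses exactly
#' at `noise_cv = 0` and within the noise level otherwise. Synthetic
#' stand-in for a measured batch proteome; it reproduces sector mass
#' structure, not real protein identities.
#'
#' @param spec a `fixture_spec`.
#' @return a data.frame with columns `protein`, `mass_fraction`, `label`.
#' @export
make_protein_table <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed)
  tg <- spec$sector_targets[spec$sector_targets > 0]
  sectors <- names(tg)
  n_per <- round(spec$n_proteins * tg / sum(tg))
  n_per[n_per < 1] <- 1
  rows <- list()
  for (sec in sectors) {
    n <- n_per[[sec]]
    voc <- FIXTURE_VOCAB[[sec]]
    fmt <- voc$names[1 + (seq_len(n) - 1L) %% length(voc$names)]
    nm <- vapply(seq_len(n), function(i)
      if (grepl("%d", fmt[i], fixed = TRUE)) sprintf(fmt[i], i)
      else fmt[i], character(1))
    nm <- make.unique(nm, sep = " copy ")
    w <- stats::runif(n, 0.5, 1.5)
    mass <- tg[[sec]] * w / sum(w)
    if (spec$noise_cv > 0)
      mass <- pmax(0, mass * (1 + spec$noise_cv * stats::rnorm(n)))
    rows[[sec]] <- data.frame(protein = nm, mass_fraction = mass,
                              label = voc$label)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # unannotated remainder as proteins of unknown function, computed
  # after the noise so the table always sums to exactly 1 and the
  # annotated sector masses stay unbiased
  rest <- 1 - sum(out$mass_fraction)
  if (rest < 0) {
    out$mass_fraction <- out$mass_fraction / sum(out$mass_fraction)
    rest <- 0
  }
  if (sum(spec$sector_targets) < 1 - 1e-12 && rest > 1e-12) {
    n <- max(1L, round(0.1 * spec$n_proteins))
    w <- stats::runif(n, 0.5, 1.5)
    out <- rbind(out, data.frame(
      protein = sprintf("Uncharacterized protein YXX%03d", seq_len(n)),
      mass_fraction = rest * w / sum(w),
      label = "Unknown function"))
  }
  out
}

#' Build a calibration flux target from the model itself
#'
#' In-silico truth for parameter-recovery tests: the nine sector rates
#' realized by `(alloc, params)` at the calibration reference condition —
#' the substrate-excess batch state, whose growth flux is the maximum
#' growth rate (`condition = "batch"`, the default used by
#' [estimate_kcats()]) — or at the chemostat steady state at dilution
#' rate `D` (`condition = "chemostat"`).
#'
#' @param params a `kinetic_params` (the "true" parameters).
#' @param alloc the batch `proteome_allocation`.
#' @param D nominal growth/dilution rate, 1/h (> 0).
#' @param condition reference condition, see above.
#' @param growth_weight weight passed to [calibration_target()].
#' @return a `calibration_target`.
#' @export
make_flux_target <- function(params, alloc, D,
                             condition = c("batch", "chemostat"),
                             growth_weight = 10) {
  condition <- match.arg(condition)
  if (!is.finite(D) || D <= 0) stop("D must be > 0")
  if (condition == "batch") {
    v <- calibration_fluxes(alloc, params)
    # in-silico truth: the growth-attainment goal is the generating
    # model's own simulated maximum growth rate, so the target is
    # exactly self-consistent and recovery is well-posed
    mu_t <- find_batch_state(alloc, params)$mu_max
    return(calibration_target(v, alloc, growth_weight = growth_weight,
                              mu_target = mu_t))
  }
  {
    ss <- find_steady_state(alloc, D, params)
    if (!ss$feasible) stop("model infeasible at D = ", D, ": ",
                           ss$diagnostic)
    f <- ss$fluxes
    v <- c(Upt = f[["Upt"]], UGlc = f[["UGlc"]], LGlc = f[["LGlc"]],
           Ferm = f[["Ferm"]], Esnk = f[["Esnk"]], Resp = f[["Resp_TCA"]],
           TrSn = f[["TrSn"]], TrDg = f[["TrDg"]], Grwt = f[["Grwt"]])
  }
  if (any(!is.finite(v))) stop("model produced non-finite target fluxes")
  calibration_target(v, alloc, growth_weight = growth_weight)
}
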