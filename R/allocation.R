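#' Proteome allocation across the nine model sectors
#'
#' An allocation assigns each sector a fraction phi of the total catalytic
#' proteome (1.0 = 500 mg protein per g_X). Fractions must be nonnegative
#' and sum to at most one; the remainder `1 - sum(phi)` is the unallocated
#' (overcapacity) fraction. When the mitochondrial cap is enabled the
#' respiration sector may not exceed `resp_cap` (default 12%), reflecting
#' the maximum oxygen consumption capacity observed after long-term
#' adaptation.
#'
#' @param phi named numeric vector over the nine sector ids (any order;
#'   missing sectors default to 0).
#' @param resp_cap maximum respiration sector fraction.
#' @param cap_enabled enforce the respiration cap?
#' @return An object of class `proteome_allocation`.
#' @export
proteome_allocation <- function(phi, resp_cap = 0.12, cap_enabled = TRUE) {
  full <- stats::setNames(numeric(length(SECTOR_IDS)), SECTOR_IDS)
  if (is.null(names(phi)) && length(phi) == length(SECTOR_IDS)) {
    names(phi) <- SECTOR_IDS
  }
  bad <- setdiff(names(phi), SECTOR_IDS)
  if (length(bad)) stop("unknown sector ids: ", paste(bad, collapse = ", "))
  full[names(phi)] <- phi
  obj <- structure(list(phi = full, resp_cap = resp_cap,
                        cap_enabled = cap_enabled),
                   class = "proteome_allocation")
  validate_allocation(obj)
  obj
}

#' Validate a proteome allocation
#'
#' Checks nonnegativity, the total-proteome bound and (when enabled) the
#' respiration cap.
#'
#' @param alloc a `proteome_allocation`.
#' @param tol numerical slack on the constraints.
#' @return `alloc`, invisibly.
#' @export
validate_allocation <- function(alloc, tol = 1e-9) {
  stopifnot(inherits(alloc, "proteome_allocation"))
  phi <- alloc$phi
  if (any(!is.finite(phi))) stop("non-finite sector fraction")
  if (any(phi < -tol)) stop("negative sector fraction")
  if (sum(phi) > 1 + tol)
    stop("sector fractions sum to more than the total proteome (",
         signif(sum(phi), 6), ")")
  if (isTRUE(alloc$cap_enabled) && phi[["Resp"]] > alloc$resp_cap + tol)
    stop("respiration sector ", signif(phi[["Resp"]], 4),
         " exceeds the mitochondrial cap ", alloc$resp_cap)
  invisible(alloc)
}

#' Unallocated proteome fraction
#'
#' @param alloc a `proteome_allocation`.
#' @return `1 - sum(phi)`, the overcapacity fraction.
#' @export
overcapacity_fraction <- function(alloc) {
  1 - sum(alloc$phi)
}

#' Replace sector fractions of an allocation
#'
#' @param alloc a `proteome_allocation`.
#' @param ... named sector = value pairs.
#' @return the modified, revalidated allocation.
#' @export
set_sectors <- function(alloc, ...) {
  repl <- unlist(list(...))
  bad <- setdiff(names(repl), SECTOR_IDS)
  if (length(bad)) stop("unknown sector ids: ", paste(bad, collapse = ", "))
  alloc$phi[names(repl)] <- repl
  validate_allocation(alloc)
  alloc
}

#' @export
print.proteome_allocation <- function(x, ...) {
  cat("Proteome allocation (fraction of 500 mg protein/g_X)\n")
  print(round(x$phi, 4))
  cat("  allocated:", signif(sum(x$phi), 4),
      "  overcapacity:", signif(overcapacity_fraction(x), 4), "\n")
  invisible(x)
}

#' Reference batch proteome allocation
#'
#' A plausible sector decomposition of a glucose-excess (batch) proteome of
#' S. cerevisiae, used as default calibration input and sweep seed. It is a
#' synthetic stand-in assembled from the well-known mass structure of the
#' fermenting yeast proteome (glycolytic plus fermentative enzymes roughly
#' 25-30% of protein mass, ribosomes/translation around 40%, mitochondria
#' under 10% under glucose repression), not a redistribution of any
#' published dataset.
#'
#' @return a `proteome_allocation`.
#' @export
batch_allocation <- function() {
  proteome_allocation(c(
    Upt = 0.070, UGlc = 0.055, LGlc = 0.115, Ferm = 0.065,
    Esnk = 0.012, Resp = 0.080, TrSn = 0.003, TrDg = 0.003,
    Grwt = 0.420))
}
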