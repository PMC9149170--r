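#' Model state vector
#'
#' Builds and validates the 14-component state: extracellular glucose,
#' ethanol and glycerol (mmol/L), biomass (Cmol/L), and the intracellular
#' pools G6P, FBP, PYR, ATP, ADP, AMP, NAD, NADH, Pi and trehalose
#' (umol/g_X).
#'
#' @param ... named overrides of the default initial values.
#' @return a named numeric vector of class `state_vector`.
#' @export
default_state <- function(...) {
  s <- c(Glc_ex = 0.1, G6P = 2, FBP = 2, PYR = 1,
         ATP = 3.5, ADP = 1.0, AMP = 0.29,
         NAD = 2.5, NADH = 0.5, Pi = 25, Tre = 10,
         EtOH = 0, Glyc = 0, X = 0.10)
  dots <- unlist(list(...))
  bad <- setdiff(names(dots), STATE_IDS)
  if (length(bad)) stop("unknown state ids: ", paste(bad, collapse = ", "))
  s[names(dots)] <- dots
  class(s) <- c("state_vector", "numeric")
  validate_state(s)
  s
}

#' Coerce a named numeric vector to a state vector
#' @param x named numeric over the 14 state ids.
#' @return a `state_vector`.
#' @export
as_state_vector <- function(x) {
  if (inherits(x, "state_vector")) return(x)
  if (is.null(names(x)) && length(x) == length(STATE_IDS))
    names(x) <- STATE_IDS
  stopifnot(all(STATE_IDS %in% names(x)))
  s <- x[STATE_IDS]
  class(s) <- c("state_vector", "numeric")
  s
}

#' Validate a state vector
#' @param s a `state_vector`.
#' @param tol slack on nonnegativity.
#' @return `s`, invisibly.
#' @export
validate_state <- function(s, tol = 1e-9) {
  stopifnot(all(STATE_IDS %in% names(s)))
  if (any(!is.finite(s))) stop("non-finite state entry")
  if (any(s < -tol)) stop("negative state entry: ",
                          paste(names(s)[s < -tol], collapse = ", "))
  invisible(s)
}

#' Adenylate energy charge
#'
#' Atkinson's energy charge EC = (ATP + ADP/2) / (ATP + ADP + AMP), a 0-1
#' index of the phosphorylation state of the adenylate pool. Growth in the
#' model responds sigmoidally to EC.
#'
#' @param state a `state_vector` (or named vector with ATP, ADP, AMP).
#' @return EC, dimensionless in `[0, 1]`.
#' @export
energy_charge <- function(state) {
  tot <- state[["ATP"]] + state[["ADP"]] + state[["AMP"]]
  if (!is.finite(tot) || tot <= 0)
    stop("adenylate total must be positive")
  (state[["ATP"]] + 0.5 * state[["ADP"]]) / tot
}

#' @export
print.state_vector <- function(x, ...) {
  cat("Model state (mmol/L extracellular, umol/g_X intracellular, Cmol/L biomass)\n")
  print(round(unclass(x), 4))
  cat("  energy charge:", round(energy_charge(x), 4), "\n")
  invisible(x)
}
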