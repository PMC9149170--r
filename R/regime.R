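#' Feeding regime
#'
#' Describes how the bioreactor is fed: either a chemostat with constant
#' dilution rate `D_avg`, or a periodic feast/famine regime in which a
#' square-wave dilution rate `D_feed` is applied during the first `TF`
#' seconds of every `TC`-second cycle and zero during the rest, so the
#' cycle-average dilution rate is `D_feed * TF / TC`.
#'
#' The reference dynamic condition is `TC = 400 s`, `TF = 20 s`,
#' `D_feed = 2/h`, giving an average dilution rate of 0.1/h.
#'
#' @param mode `"chemostat"` or `"feast_famine"`.
#' @param D_avg average dilution rate, 1/h.
#' @param TC cycle length, s (feast/famine only).
#' @param TF feed length, s (feast/famine only).
#' @param D_feed dilution rate during feeding, 1/h; defaults to
#'   `D_avg * TC / TF` so the average constraint holds.
#' @param glc_feed feed glucose concentration, mmol/L.
#' @return an object of class `feed_regime`.
#' @export
feed_regime <- function(mode = c("chemostat", "feast_famine"),
                        D_avg = 0.1, TC = NULL, TF = NULL, D_feed = NULL,
                        glc_feed = 41.7) {
  mode <- match.arg(mode)
  if (!is.finite(D_avg) || D_avg < 0) stop("D_avg must be >= 0")
  if (mode == "feast_famine" && D_avg <= 0)
    stop("feast_famine needs D_avg > 0")
  if (glc_feed <= 0) stop("glc_feed must be > 0")
  if (mode == "feast_famine") {
    if (is.null(TC) || is.null(TF)) stop("feast_famine needs TC and TF")
    if (!(TF > 0 && TF <= TC)) stop("need 0 < TF <= TC")
    if (is.null(D_feed)) D_feed <- D_avg * TC / TF
    if (abs(D_feed * TF / TC - D_avg) > 1e-9 * max(1, D_avg))
      stop("D_feed * TF / TC must equal D_avg")
  } else {
    TC <- TF <- D_feed <- NA_real_
  }
  structure(list(mode = mode, D_avg = D_avg, TC = TC, TF = TF,
                 D_feed = D_feed, glc_feed = glc_feed),
            class = "feed_regime")
}

#' The reference feast/famine regime
#'
#' 400 s cycles fed for the first 20 s at D = 2/h (average D = 0.1/h).
#'
#' @param glc_feed feed glucose concentration, mmol/L.
#' @return a `feed_regime`.
#' @export
reference_ff_regime <- function(glc_feed = 41.7) {
  feed_regime("feast_famine", D_avg = 0.1, TC = 400, TF = 20,
              D_feed = 2, glc_feed = glc_feed)
}

#' Dilution rate at a time point
#'
#' @param regime a `feed_regime`.
#' @param t time from cycle start, seconds.
#' @return D(t), 1/h.
#' @export
dilution_at <- function(regime, t) {
  if (regime$mode == "chemostat") return(rep(regime$D_avg, length(t)))
  phase <- t %% regime$TC
  ifelse(phase < regime$TF, regime$D_feed, 0)
}

#' @export
print.feed_regime <- function(x, ...) {
  if (x$mode == "chemostat") {
    cat("Chemostat, D =", x$D_avg, "/h, feed glucose", x$glc_feed, "mmol/L\n")
  } else {
    cat("Feast/famine: TC =", x$TC, "s, TF =", x$TF, "s, D_feed =",
        x$D_feed, "/h (avg D =", x$D_avg, "/h), feed glucose",
        x$glc_feed, "mmol/L\n")
  }
  invisible(x)
}
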