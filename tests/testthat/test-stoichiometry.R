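test_that("carbon, electron and phosphorus vectors annihilate the stoichiometry", {
  p <- test_params()
  S <- stoichiometry_matrix(p)
  ev <- elemental_vectors(p)
  expect_lt(max(abs(S %*% ev$carbon)), 1e-12)
  expect_lt(max(abs(S %*% ev$dor)), 1e-12)
  expect_lt(max(abs(S %*% ev$phosphorus)), 1e-12)
})

test_that("zero fluxes give a zero derivative vector", {
  p <- test_params()
  zero <- proteome_allocation(stats::setNames(rep(0, 9), SECTOR_IDS))
  # no ATP: even maintenance is silent; D = 0: no exchange
  s <- default_state(ATP = 0, ADP = 0, AMP = 0, Glc_ex = 0)
  reg <- feed_regime("chemostat", D_avg = 0)
  d <- mass_balances(0, s, zero, reg, p)
  expect_equal(max(abs(unclass(d)[STATE_IDS])), 0)
})

test_that("elemental closure holds for random states with exchange terms", {
  p <- test_params()
  S <- stoichiometry_matrix(p)
  ev <- elemental_vectors(p)
  reg <- feed_regime("chemostat", D_avg = 0.17)
  conv <- 1e6 / p$g_per_cmol
  ext <- c("Glc_ex", "EtOH", "Glyc", "CO2", "O2", "X")
  set.seed(21)
  for (i in 1:100) {
    al <- proteome_allocation(stats::setNames(runif(9, 0, 0.1), SECTOR_IDS))
    s <- random_state()
    d <- mass_balances(0, s, al, reg, p)
    v <- attr(d, "fluxes")
    # carbon entering the intracellular pools must equal carbon supplied
    # by the reactions' external species (uptake minus CO2, products,
    # biomass), by the left-null-space property
    intra_c <- sum(ev$carbon[INTRACELLULAR_IDS] *
                   as.numeric(crossprod(S[, INTRACELLULAR_IDS], v)))
    ext_c <- sum(vapply(REACTION_IDS, function(r)
      sum(S[r, ext] * ev$carbon[ext]) * v[[r]], numeric(1)))
    expect_lt(abs(intra_c + ext_c), 1e-9)
  }
})

test_that("compiled and reference right-hand sides agree", {
  p <- test_params()
  al <- batch_allocation()
  reg <- feed_regime("chemostat", D_avg = 0.13, glc_feed = 41.7)
  rfun <- function(t, y, parms) {
    d <- mass_balances(t, as_state_vector(pmax(y, 0)), al, reg, p)
    list(unclass(d)[STATE_IDS])
  }
  pv <- protalloc:::param_vector(al, p,
                                 protalloc:::regime_vector(0.13, 41.7))
  set.seed(7)
  for (i in 1:10) {
    s <- random_state()
    tt <- c(0, 1e-5)
    oR <- deSolve::ode(unclass(s)[STATE_IDS], tt, rfun, NULL,
                       method = "lsoda", atol = 1e-10, rtol = 1e-10)
    oC <- deSolve::ode(unclass(s)[STATE_IDS], tt,
                       func = "protalloc_derivs", parms = pv,
                       dllname = "protalloc",
                       initfunc = "protalloc_init", nout = 15,
                       method = "lsoda", atol = 1e-10, rtol = 1e-10)
    rel <- max(abs(oR[2, 2:15] - oC[2, 2:15]) /
               pmax(abs(oR[2, 2:15]), 1e-6))
    expect_lt(rel, 1e-8)
  }
})

test_that("a NaN-producing parameterization is reported, not propagated", {
  p <- test_params()
  al <- batch_allocation()
  reg <- feed_regime("chemostat", D_avg = 0.1)
  s <- default_state()
  s["NADH"] <- NA
  expect_error(mass_balances(0, s, al, reg, p))
})
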