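test_that("closed-system integration conserves the AXP and NAD moieties", {
  p <- test_params()
  al <- batch_allocation()
  reg <- feed_regime("chemostat", D_avg = 0, glc_feed = 41.7)
  set.seed(31)
  for (i in 1:5) {
    s <- random_state()
    tr <- integrate_model(s, al, reg, p, t_span = 0.5, n_grid = 21)
    axp <- rowSums(tr$states[, c("ATP", "ADP", "AMP")])
    nad <- rowSums(tr$states[, c("NAD", "NADH")])
    expect_lt(max(abs(axp - axp[1])), 2e-3)
    expect_lt(max(abs(nad - nad[1])), 2e-3)
  }
})

test_that("the feast/famine square wave integrates to the average dilution rate", {
  reg <- reference_ff_regime()
  # piecewise-exact quadrature: midpoints of a grid aligned with TF
  brk <- sort(unique(c(seq(0, reg$TC, length.out = 4001), reg$TF)))
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  got <- sum(dilution_at(reg, mid) * diff(brk)) / reg$TC
  expect_equal(got, reg$D_avg, tolerance = 1e-12)
  expect_equal(reg$D_feed * reg$TF / reg$TC, reg$D_avg, tolerance = 1e-12)
})

test_that("a chemostat steady state is a fixed point of the integrator", {
  ss <- test_ss01()
  expect_true(ss$feasible)
  p <- test_params()
  reg <- feed_regime("chemostat", D_avg = 0.1)
  tr <- integrate_model(ss$state, batch_allocation(), reg, p,
                        t_span = 5, n_grid = 11)
  drift <- abs(tr$states[nrow(tr$states), ] - unclass(ss$state)[STATE_IDS])
  rel <- drift / pmax(abs(unclass(ss$state)[STATE_IDS]), 1e-3)
  expect_lt(max(rel), 10 * 1e-3)
})

test_that("trajectories have increasing times and nonnegative states", {
  p <- test_params()
  al <- batch_allocation()
  tr <- integrate_model(default_state(Glc_ex = 2, X = 0.05), al,
                        reference_ff_regime(), p, t_span = 0.3)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$states >= 0))
  expect_equal(colnames(tr$fluxes), REACTION_IDS)
})
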