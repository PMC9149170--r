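test_that("zero allocation gives exactly zero sector-bound rates", {
  p <- test_params()
  zero <- proteome_allocation(stats::setNames(rep(0, 9), SECTOR_IDS))
  v <- compute_rates(default_state(), zero, p)
  sector_bound <- setdiff(REACTION_IDS, "Mnt")
  expect_identical(unname(unclass(v)[sector_bound]), rep(0, 10))
  # maintenance is sector-free and keeps running
  expect_gt(v[["Mnt"]], 0)
})

test_that("rate equals phi * kcat at full saturation", {
  p <- default_params(kcat = c(Upt = 5, UGlc = 1, LGlc = 1, Ferm = 1,
                               Esnk = 1, Resp = 1, TrSn = 1, TrDg = 1,
                               Grwt = 1))
  al <- set_sectors(batch_allocation(), Upt = 0.1)
  s <- default_state(Glc_ex = 1e8, ATP = 1e8, G6P = 0)
  v <- compute_rates(s, al, p)
  expect_equal(unname(v[["Upt"]]), 0.5, tolerance = 1e-6)
})

test_that("all sector-bound rates are linear in the allocation", {
  p <- test_params()
  al <- batch_allocation()
  al2 <- al
  al2$phi <- al$phi / 2   # keep within caps; compare half vs full
  sector_bound <- setdiff(REACTION_IDS, "Mnt")
  set.seed(11)
  for (i in 1:100) {
    s <- random_state()
    v1 <- unclass(compute_rates(s, al, p))[sector_bound]
    v2 <- unclass(compute_rates(s, al2, p))[sector_bound]
    expect_equal(unname(v1), unname(2 * v2), tolerance = 1e-12)
  }
})

test_that("saturation functions lie in [0, 1] on random states", {
  p <- test_params()
  set.seed(12)
  for (i in 1:10000) {
    s <- default_state(Glc_ex = runif(1, 0, 1e3), G6P = runif(1, 0, 1e3),
                       FBP = runif(1, 0, 1e3), PYR = runif(1, 0, 1e4),
                       ATP = runif(1, 0, 10), ADP = runif(1, 0, 10),
                       AMP = runif(1, 0, 10), NAD = runif(1, 0, 5),
                       NADH = runif(1, 0, 5), Pi = runif(1, 0, 100),
                       Tre = runif(1, 0, 200))
    f <- unlist(protalloc:::saturation_functions(s, p))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("uptake is non-decreasing in extracellular glucose", {
  p <- test_params()
  al <- batch_allocation()
  grid <- c(0, 10^seq(-4, 2, length.out = 40))
  v <- vapply(grid, function(g)
    compute_rates(default_state(Glc_ex = g), al, p)[["Upt"]], numeric(1))
  expect_true(all(diff(v) >= -1e-15))
})

test_that("energy charge follows Atkinson's definition", {
  expect_equal(energy_charge(default_state(ATP = 1, ADP = 0, AMP = 0)), 1)
  expect_equal(energy_charge(default_state(ATP = 1e-12, ADP = 1e-12,
                                           AMP = 1)), 0,
               tolerance = 1e-9)
  for (x in c(0.3, 1, 4)) {
    expect_equal(energy_charge(default_state(ATP = x, ADP = x, AMP = x)),
                 0.5)
  }
  s <- default_state()
  s[c("ATP", "ADP", "AMP")] <- 0
  expect_error(energy_charge(s), "positive")
})

test_that("growth sigmoid has midpoint, ceiling and sensitivity band", {
  p <- test_params()
  mid <- p$growth_sigmoid[["ec_mid"]]
  expect_equal(growth_rate(mid, 0.4, 2, p), 0.5 * 0.4 * 2,
               tolerance = 1e-12)
  # sigma(1) = 1 / (1 + exp(-(1 - 0.8)/0.05)) = 0.98201...
  expect_equal(growth_rate(1, 0.4, 2, p), 0.4 * 2 / (1 + exp(-4)),
               tolerance = 1e-12)
  expect_gte(growth_rate(1, 0.4, 2, p), 0.95 * 0.4 * 2)
  # numerically: strictly increasing, steepest inside EC [0.7, 0.9], and
  # still responsive (>= 5% of max slope) at both band edges
  ec <- seq(0, 1, by = 0.001)
  sig <- vapply(ec, function(e) growth_rate(e, 1, 1, p), numeric(1))
  expect_true(all(diff(sig) > 0))
  slope <- diff(sig) / diff(ec)
  ec_mid_grid <- (ec[-1] + ec[-length(ec)]) / 2
  argmax <- ec_mid_grid[which.max(slope)]
  expect_true(argmax >= 0.7 && argmax <= 0.9)
  s_at <- function(x) slope[which.min(abs(ec_mid_grid - x))]
  expect_gte(s_at(0.7), 0.05 * max(slope))
  expect_gte(s_at(0.9), 0.05 * max(slope))
  expect_error(growth_rate(1.2, 0.4, 2, p))
})

test_that("respiratory branches share one electron-transport capacity", {
  p <- test_params()
  expect_equal(unname(respiration_rates(default_state(), 0, p)),
               c(0, 0, 0))
  # far-from-saturation state: the cap is inactive and rates equal the
  # unconstrained Michaelis-Menten forms
  s <- default_state(PYR = 0.01, NADH = 0.002, ADP = 0.01, Pi = 25)
  f <- protalloc:::saturation_functions(s, p)
  cap <- 0.1 * p$kcat[["Resp"]]
  r <- respiration_rates(s, 0.1, p)
  expect_equal(unname(r[["v_TCA"]]), unname(cap / p$w_tca * f$TCA),
               tolerance = 1e-12)
  expect_equal(unname(r[["v_NDE"]]), unname(cap * f$NDE),
               tolerance = 1e-12)
  expect_lt(r[["load"]], cap)
  # saturating state: unconstrained load is ~2x the cap, so both rates
  # are scaled by the same factor and the load binds exactly
  s2 <- default_state(PYR = 1e6, NADH = 1e6, ADP = 1e6, Pi = 1e6)
  r2 <- respiration_rates(s2, 0.1, p)
  expect_equal(unname(p$w_tca * r2[["v_TCA"]] + r2[["v_NDE"]]),
               unname(cap), tolerance = 1e-9)
  # the two branches keep their unconstrained ratio (their saturation
  # terms differ in the seventh digit at these concentrations)
  expect_equal(unname(r2[["v_TCA"]] / (cap / p$w_tca)),
               unname(r2[["v_NDE"]] / cap), tolerance = 1e-5)
})

test_that("invalid states and constants are rejected", {
  p <- test_params()
  al <- batch_allocation()
  s <- default_state()
  s["ATP"] <- NaN
  expect_error(compute_rates(s, al, p), "NaN")
  p2 <- p
  p2$km["glc_upt"] <- -1
  expect_error(compute_rates(default_state(), al, p2))
})
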