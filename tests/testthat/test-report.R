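test_that("sector fold changes behave as ratios", {
  a <- batch_allocation()
  expect_equal(unname(sector_fold_changes(a, a)),
               rep(1, 9))
  b <- a
  b$phi <- a$phi * 2
  # global rescaling of both allocations leaves ratios unchanged
  a2 <- a; a2$phi <- a$phi * 0.3
  b2 <- b; b2$phi <- b$phi * 0.3
  expect_equal(sector_fold_changes(a, b), sector_fold_changes(a2, b2))
  # zero baseline is undefined, not zero or infinite
  a0 <- set_sectors(a, TrSn = 0)
  fc <- sector_fold_changes(a0, b)
  expect_true(is.na(fc[["TrSn"]]))
  expect_false(anyNA(fc[setdiff(SECTOR_IDS, "TrSn")]))
})

test_that("ATP yields are intensive and handle degenerate pathways", {
  p <- test_params()
  ss <- test_ss01()
  al <- batch_allocation()
  y1 <- atp_yield_per_protein(ss$fluxes, al, p)
  expect_true(all(is.finite(y1)))
  # doubling all fluxes and all sector sizes leaves yields unchanged
  v2 <- ss$fluxes * 2
  class(v2) <- class(ss$fluxes)
  al2 <- al; al2$phi <- al$phi * 2
  al2$cap_enabled <- FALSE
  y2 <- atp_yield_per_protein(v2, al2, p)
  expect_equal(y1, y2, tolerance = 1e-12)
  # no fermentative flux -> zero fermentation yield
  v0 <- ss$fluxes
  v0["Ferm"] <- 0
  v0["LGlc"] <- (v0[["Upt"]] + v0[["UGlc"]]) / 2  # zero net SLP
  y0 <- atp_yield_per_protein(v0, al, p)
  expect_equal(unname(y0[["fermentation"]]), 0)
  # zero sector mass -> undefined
  al_no_resp <- set_sectors(al, Resp = 0)
  y3 <- atp_yield_per_protein(ss$fluxes, al_no_resp, p)
  expect_true(is.na(y3[["respiration"]]))
})

test_that("biomass yield is consistent between rate and carbon balance", {
  p <- test_params()
  ss <- test_ss01()
  v <- ss$fluxes
  y_rate <- v[["Grwt"]] / (6 * v[["Upt"]])
  g <- gas_rates(v, p)
  carbon_out <- g[["q_CO2"]] + 2 * v[["Ferm"]] + 3 * v[["Esnk"]] +
    12 * (v[["TrSn"]] - v[["TrDg"]])
  y_carbon <- 1 - carbon_out / (6 * v[["Upt"]])
  expect_equal(unname(y_rate), unname(y_carbon), tolerance = 0.01)
})

test_that("phenotype records carry consistent rates", {
  p <- test_params()
  ss <- test_ss01()
  al <- batch_allocation()
  ph <- phenotype_record(ss, al, p)
  expect_equal(ph$mu, 0.1, tolerance = 1e-6)
  expect_lte(ph$mu, 0.1 * 1.001)
  expect_gte(ph$Y_XS, 0)
  expect_equal(ph$overcapacity, overcapacity_fraction(al))
})
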