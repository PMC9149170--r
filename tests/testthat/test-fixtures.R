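test_that("noise-free protein tables round-trip exactly through mapping", {
  spec <- fixture_spec(n_proteins = 120, noise_cv = 0, rng_seed = 4)
  tab <- make_protein_table(spec)
  al <- map_to_sectors(tab)
  tg <- spec$sector_targets
  expect_equal(unname(al$phi[names(tg)]), unname(tg), tolerance = 1e-12)
  expect_equal(attr(al, "unassigned_mass"), 1 - sum(tg),
               tolerance = 1e-12)
  expect_equal(overcapacity_fraction(al), 1 - sum(tg), tolerance = 1e-12)
})

test_that("one protein per sector gives a nine-row table", {
  tg <- stats::setNames(rep(1 / 9, 9), SECTOR_IDS)
  spec <- fixture_spec(n_proteins = 9, sector_targets = tg, rng_seed = 1)
  tab <- make_protein_table(spec)
  expect_equal(nrow(tab), 9)
})

test_that("fixtures are deterministic given the seed", {
  a <- make_protein_table(fixture_spec(rng_seed = 7, noise_cv = 0.1))
  b <- make_protein_table(fixture_spec(rng_seed = 7, noise_cv = 0.1))
  expect_identical(a, b)
  c_ <- make_protein_table(fixture_spec(rng_seed = 8, noise_cv = 0.1))
  expect_false(identical(a$mass_fraction, c_$mass_fraction))
})

test_that("noisy round trips are unbiased within 1%", {
  tg <- batch_allocation()$phi
  rec <- matrix(0, nrow = 1000, ncol = 9,
                dimnames = list(NULL, SECTOR_IDS))
  for (r in 1:1000) {
    tab <- make_protein_table(fixture_spec(n_proteins = 60,
                                           sector_targets = tg,
                                           noise_cv = 0.1, rng_seed = r))
    rec[r, ] <- map_to_sectors(tab)$phi[SECTOR_IDS]
  }
  mean_rec <- colMeans(rec)
  keep <- tg > 0
  expect_true(all(abs(mean_rec[keep] / tg[keep] - 1) < 0.01))
})

test_that("flux targets come from the model and reject invalid rates", {
  p <- test_params()
  al <- batch_allocation()
  expect_error(make_flux_target(p, al, 0), "D must be")
  tgt <- make_flux_target(p, al, 0.4)
  expect_s3_class(tgt, "calibration_target")
  expect_length(tgt$fluxes, 9)
  expect_true(all(is.finite(tgt$fluxes)))
  # shipped preset: nine named rates
  preset <- experimental_flux_preset()
  expect_identical(names(preset), SECTOR_IDS)
  expect_equal(unname(preset[["Grwt"]]), 0.4)
})
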