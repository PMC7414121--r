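test_that("synthetic DEM has an incised channel and a sloped floodplain", {
  spec <- domain_spec(n_rows = 20, n_cols = 10, valley_slope = 1e-4,
                      channel_incision = 1, microtopography_sd = 0.1, seed = 7)
  dom <- make_dem(spec)
  cc <- dom$channel_col
  # channel cells sit well below both lateral neighbours
  expect_true(all(dom$bed[, cc] <= dom$bed[, cc - 1] - 0.5))
  expect_true(all(dom$bed[, cc] <= dom$bed[, cc + 1] - 0.5))
  expect_identical(unname(table(dom$kind)[["1"]]), 20L)

  # noise-free plane decreases strictly downstream by slope * cell_size
  flat <- make_dem(domain_spec(n_rows = 20, n_cols = 10, valley_slope = 1e-4,
                               microtopography_sd = 0))
  drops <- diff(flat$bed[, 2])
  expect_equal(drops, rep(-1e-4 * 90, 19))
})

test_that("DEM generation honours the seed contract", {
  spec <- domain_spec(n_rows = 12, n_cols = 8, seed = 42)
  expect_identical(make_dem(spec), make_dem(spec))
  other <- make_dem(domain_spec(n_rows = 12, n_cols = 8, seed = 43))
  expect_false(identical(make_dem(spec)$bed, other$bed))
})

test_that("invalid domain specs are rejected with the field named", {
  expect_error(domain_spec(n_rows = 1), "n_rows")
  expect_error(domain_spec(channel_incision = -1), "channel_incision")
  expect_error(domain_spec(cell_size = 0), "cell_size")
})

test_that("hydrograph applies base flow, droughts and floods as specified", {
  # constant series without events or noise
  cst <- make_hydrograph(hydrograph_spec(n_years = 2, base_flow = 5,
                                         seasonal_amplitude = 0,
                                         flood_years = integer(0),
                                         drought_years = integer(0),
                                         daily_noise_cv = 0))
  expect_equal(nrow(cst), 730L)
  expect_true(all(cst$flow_m3s == 5))

  # drought multiplier scales a whole year's mean
  hg <- make_hydrograph(hydrograph_spec(n_years = 4, flood_years = integer(0),
                                        drought_years = 3,
                                        drought_multiplier = 0.2,
                                        daily_noise_cv = 0.1, seed = 5))
  m3 <- mean(hg$flow_m3s[hg$water_year == 3])
  m2 <- mean(hg$flow_m3s[hg$water_year == 2])
  expect_equal(m3 / m2, 0.2, tolerance = 0.05)

  # flood pulse drives the annual maximum
  fl <- make_hydrograph(hydrograph_spec(n_years = 6, flood_years = 5,
                                        flood_magnitude = 100,
                                        drought_years = integer(0),
                                        daily_noise_cv = 0))
  expect_gte(max(fl$flow_m3s[fl$water_year == 5]), 100)
  expect_true(all(fl$flow_m3s >= 0))

  expect_error(hydrograph_spec(base_flow = -1), "base_flow")
  expect_error(hydrograph_spec(flood_years = 3, drought_years = 3),
               "disjoint")
})

test_that("initial vegetation is a banded mosaic partitioned into patches", {
  dom <- make_dem(domain_spec(n_rows = 20, n_cols = 17, seed = 11))
  veg <- make_initial_vegetation(dom, min_cells = 20, max_cells = 840)
  cls <- vegetation_classes()
  # partition: every cell in exactly one patch, patch areas sum to the domain
  expect_false(anyNA(veg$patch))
  expect_equal(sum(veg$patches$n_cells), 20 * 17)
  expect_setequal(unique(as.integer(veg$patch)), veg$patches$patch_id)
  # cells adjacent to the channel are Common Reed
  cc <- dom$channel_col
  expect_true(all(veg$veg[, c(cc - 1, cc, cc + 1)] == cls[["CommonReed"]]))
  # banding order away from the channel
  expect_true(all(veg$veg[, cc + 3] == cls[["MixedMarsh"]]))
  expect_true(all(veg$veg[, cc + 6] == cls[["RRG_good"]]))
  # patch sizes within bounds
  counts <- table(as.integer(veg$patch))
  expect_true(all(counts >= 20 & counts <= 840))
  expect_equal(as.integer(counts[as.character(veg$patches$patch_id)]),
               veg$patches$n_cells)
  # patches are internally single-class
  for (p in veg$patches$patch_id)
    expect_length(unique(veg$veg[veg$patch == p]), 1)

  expect_error(make_initial_vegetation(dom, band_widths = c(
    CommonReed = 5000, MixedMarsh = 5000, RRG_good = 5000)), "band_widths")
})

test_that("pseudo-observations reproduce truth at zero noise and by seed", {
  stack <- array(runif(4 * 3 * 20), c(4, 3, 20))
  obs0 <- make_pseudo_observations(stack, noise_sd = 0, gauge = c(2, 2))
  expect_equal(obs0$observed_m, stack[2, 2, ])
  o1 <- make_pseudo_observations(stack, noise_sd = 0.02, seed = 9,
                                 gauge = c(2, 2))
  o2 <- make_pseudo_observations(stack, noise_sd = 0.02, seed = 9,
                                 gauge = c(2, 2))
  expect_identical(o1, o2)
  expect_false(all(o1$observed_m == o1$truth_m))
  expect_error(make_pseudo_observations(stack, noise_sd = -1, gauge = c(1, 1)),
               "noise_sd")
})
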