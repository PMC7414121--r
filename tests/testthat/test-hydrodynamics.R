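test_that("link discharge reproduces the Manning formula and its symmetries", {
  # hand evaluation: A = 10 m2, R = 1 m, n = 0.05, dz = 0.1 m over 1000 m
  # -> Q = (10 * 1 / 0.05) * sqrt(1e-4) = 2 m3/s
  q <- link_discharge(z_k = 0.1, z_i = 0, bed_k = 0, bed_i = 0, n_link = 0.05,
                      cell_size = 1000, width = 100, hydraulic_radius = 1)
  expect_equal(q, 2)

  # zero head difference carries no flow
  expect_identical(link_discharge(0.4, 0.4, 0, 0, 0.05, 90), 0)

  # antisymmetry over random states
  set.seed(101)
  for (i in 1:50) {
    bk <- runif(1, -1, 1); bi <- runif(1, -1, 1)
    zk <- max(bk, bi) + runif(1, 0, 1); zi <- max(bk, bi) + runif(1, 0, 1)
    n <- runif(1, 0.02, 0.15)
    q1 <- link_discharge(zk, zi, bk, bi, n, 90)
    q2 <- link_discharge(zi, zk, bi, bk, n, 90)
    expect_equal(q1, -q2)
  }
  expect_error(link_discharge(1, 0, 0, 0, n_link = 0, cell_size = 90),
               "n_link")
})

test_that("adaptive time step respects its bounds and is monotone in depth", {
  cfg <- solver_config(dt_min = 1, dt_max = 5)
  expect_identical(adaptive_dt(matrix(0, 3, 3), 90, cfg), 5)
  set.seed(7)
  for (i in 1:20) {
    h <- matrix(runif(9, 0, 2), 3, 3)
    dt1 <- adaptive_dt(h, 90, cfg)
    dt2 <- adaptive_dt(2 * h, 90, cfg)
    expect_lte(dt2, dt1)
    expect_gte(dt1, cfg$dt_min); expect_lte(dt1, cfg$dt_max)
  }
})

test_that("a closed basin conserves volume through long integrations", {
  set.seed(3)
  bed <- matrix(runif(25, 0, 0.5), 5, 5)
  dom <- grid_domain(bed, cell_size = 30)
  z0 <- bed + matrix(runif(25, 0, 0.8), 5, 5)
  v0 <- sum(cell_volumes(dom, z0))
  # ~2000 sub-steps at the CFL-adaptive dt
  res <- hydro_step(dom, uniform_n(dom), z0, seconds = 20000,
                    ds_mode = "closed")
  expect_lt(abs(res$volume - v0) / v0, 1e-3)
  expect_equal(res$inflow_volume, 0)
  expect_equal(res$outflow_volume, 0)
})

test_that("a two-cell flat basin equilibrates to a level pool", {
  dom <- flat_basin(1, 2, cell_size = 10)
  res <- hydro_step(dom, uniform_n(dom), matrix(c(1, 0), 1, 2),
                    seconds = 86400, ds_mode = "closed")
  expect_equal(as.vector(res$z), c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(res$volume, 1 * 10^2)
})

test_that("drainage of a uniformly wetted slope is monotone", {
  dom <- sloped_plane(5, 5, slope = 2e-4)
  z0 <- matrix(0.3, 5, 5)  # uniform stage above the whole sloped bed
  run <- run_hydrodynamics(dom, uniform_n(dom), inflow = rep(0, 5),
                           downstream = "free", z0 = z0)
  for (d in 1:5) {
    zd <- run$depth[, , d] + dom$bed
    expect_true(all(zd <= z0 + 1e-9))
  }
  # stages keep falling day on day
  expect_true(all(run$depth[, , 5] <= run$depth[, , 1] + 1e-9))
})

test_that("steady flow on a plane reproduces Manning normal depth", {
  S <- 2e-4; nman <- 0.05; Q <- 20; nr <- 15; nc <- 5
  dom <- sloped_plane(nr, nc, S)
  q_unit <- Q / (nc * dom$cell_size)
  h_n <- (nman * q_unit / sqrt(S))^(3 / 5)
  run <- run_hydrodynamics(dom, uniform_n(dom, nman), inflow = rep(Q, 60),
                           downstream = rep(dom$bed[nr, 1] + h_n, 60),
                           config = solver_config(dt_max = 60))
  h_mid <- mean(run$depth[8, , 60])
  expect_equal(h_mid, h_n, tolerance = 0.05)
})

test_that("daily runs keep exact mass-balance books", {
  dom <- make_dem(domain_spec(n_rows = 10, n_cols = 8, seed = 2))
  hg <- make_hydrograph(hydrograph_spec(n_years = 1, daily_noise_cv = 0.1,
                                        flood_years = integer(0),
                                        drought_years = integer(0), seed = 2))
  run <- run_hydrodynamics(dom, veg_n(dom), hg$flow_m3s[1:90],
                           config = solver_config(dt_max = 60))
  mb <- run$mass_balance
  expect_lt(abs(sum(mb$residual_m3)) / sum(mb$inflow_m3), 1e-3)
  # daily identity: inflow - outflow = change in storage
  expect_lt(max(abs(mb$residual_m3)), 1e-6 * max(mb$storage_m3))
  # depths never negative
  expect_gte(min(run$depth), 0)
})

test_that("zero inflow on a dry domain stays dry", {
  dom <- make_dem(domain_spec(n_rows = 8, n_cols = 6, seed = 4))
  run <- run_hydrodynamics(dom, veg_n(dom), rep(0, 10))
  expect_true(all(run$depth == 0))
})

test_that("identical inputs give bit-identical runs", {
  dom <- make_dem(domain_spec(n_rows = 8, n_cols = 6, seed = 4))
  hg <- rep(c(5, 20, 8), length.out = 30)
  r1 <- run_hydrodynamics(dom, veg_n(dom), hg)
  r2 <- run_hydrodynamics(dom, veg_n(dom), hg)
  expect_identical(r1, r2)
})

test_that("stage forcing is accepted upstream", {
  dom <- sloped_plane(6, 4, 1e-4)
  stage <- data.frame(stage_m = rep(dom$bed[1, 1] + 0.4, 20))
  run <- run_hydrodynamics(dom, uniform_n(dom), stage, downstream = "free")
  expect_gt(max(run$depth[1, , 20]), 0.3)
  expect_gt(sum(run$mass_balance$inflow_m3), 0)
})

test_that("invalid roughness is rejected", {
  dom <- flat_basin(3, 3)
  n <- uniform_n(dom); n[2, 2] <- 0
  expect_error(run_hydrodynamics(dom, n, rep(1, 3)), "roughness")
})
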