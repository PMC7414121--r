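test_that("map agreement identities hold", {
  m <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
  rep_same <- map_agreement(m, m)
  expect_equal(rep_same$overall_accuracy, 100)
  expect_equal(rep_same$kappa, 1)
  # constant prediction against a 50/50 observation: accuracy 50 %, kappa 0
  pred <- matrix(1L, 2, 10)
  obs <- matrix(rep(c(1L, 2L), 10), 2, 10)
  r <- map_agreement(pred, obs)
  expect_equal(r$overall_accuracy, 50)
  expect_equal(r$kappa, 0)
})

test_that("map agreement matches a brute-force tally on random maps", {
  set.seed(13)
  for (i in 1:5) {
    pred <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
    obs <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
    r <- map_agreement(pred, obs)
    expect_equal(r$overall_accuracy, 100 * mean(pred == obs))
    # brute-force kappa from the marginals
    po <- mean(pred == obs)
    pe <- sum(vapply(1:4, function(k) mean(pred == k) * mean(obs == k),
                     numeric(1)))
    expect_equal(r$kappa, (po - pe) / (1 - pe))
    expect_equal(sum(r$confusion), 100)
  }
})

test_that("map agreement respects masks and rejects legend mismatches", {
  pred <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  obs <- matrix(c(1L, 2L, 2L, 2L), 2, 2)
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  r <- map_agreement(pred, obs, mask = mask)
  expect_equal(r$n, 3)
  expect_equal(r$overall_accuracy, 100)
  expect_error(map_agreement(pred, obs, levels = 1L), "legend")
  expect_error(map_agreement(pred, matrix(1L, 3, 3)), "size")
})

test_that("series skill identities hold and match direct formulas", {
  obs <- c(1, 3, 2, 5, 4, 6, 2, 3, 5, 1)
  perfect <- series_skill(obs, obs)
  expect_equal(perfect$percent_bias, 0)
  expect_equal(perfect$nse, 1)
  expect_equal(perfect$rsr, 0)
  # the mean predictor: NSE 0, RSR 1 exactly (population SD convention)
  meanpred <- series_skill(rep(mean(obs), 10), obs)
  expect_equal(meanpred$nse, 0)
  expect_equal(meanpred$rsr, 1)
  # random pair against hand-evaluated formulas; RSR = sqrt(1 - NSE)
  set.seed(19)
  mod <- obs + rnorm(10, 0, 0.5)
  sk <- series_skill(mod, obs)
  expect_equal(sk$percent_bias, 100 * sum(obs - mod) / sum(obs))
  expect_equal(sk$nse, 1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2))
  expect_equal(sk$rsr, sqrt(mean((obs - mod)^2)) /
                 sqrt(mean((obs - mean(obs))^2)))
  expect_equal(sk$rsr, sqrt(1 - sk$nse))
  expect_error(series_skill(1:5, rep(2, 5)), "variance")
})

test_that("degraded fraction counts invaded terrestrial plus poor RRG", {
  cls <- vegetation_classes()
  states <- data.frame(patch_id = 1:5,
                       class = unname(cls[c("CommonReed", "Terrestrial",
                                            "Terrestrial", "RRG_poor",
                                            "RRG_good")]),
                       memory = c(NA, cls[["MixedMarsh"]], NA, NA, NA),
                       n_cells = c(10, 30, 20, 15, 25))
  # wetland area excludes the originally terrestrial patch (20 cells):
  # degraded = invaded 30 + poor 15 over 80
  expect_equal(degraded_fraction(states), 100 * 45 / 80)
  expect_equal(degraded_fraction(states, include_original_terrestrial = TRUE),
               45)
  healthy <- data.frame(patch_id = 1, class = cls[["CommonReed"]],
                        memory = NA_integer_, n_cells = 50)
  expect_equal(degraded_fraction(healthy), 0)
  # half the wetland invaded
  half <- data.frame(patch_id = 1:2, class = unname(cls[c("Terrestrial",
                                                          "MixedMarsh")]),
                     memory = c(cls[["MixedMarsh"]], NA), n_cells = c(40, 40))
  expect_equal(degraded_fraction(half), 50)
})

test_that("degradation duration is the longest qualifying run", {
  expect_equal(degradation_duration(c(5, 10, 5), level = 25), 0)
  expect_equal(degradation_duration(c(10, 30, 30, 30, 10), level = 25), 3)
  set.seed(29)
  for (i in 1:10) {
    x <- runif(30, 0, 60)
    runs <- rle(x >= 25)
    want <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    expect_equal(degradation_duration(x, 25), want)
  }
})
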