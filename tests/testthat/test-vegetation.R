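cls <- vegetation_classes()

run_years <- function(states, mii_seq, rules = transition_rules()) {
  trace <- integer(length(mii_seq))
  for (y in seq_along(mii_seq)) {
    states <- update_patch(states, mii_seq[y], rules)
    trace[y] <- states$class
  }
  list(states = states, trace = trace)
}

test_that("non-woody patches transition to terrestrial on the 3rd dry year", {
  r <- run_years(one_patch("CommonReed"), c(10, 10, 10))
  expect_equal(r$trace, c(cls[["CommonReed"]], cls[["CommonReed"]],
                          cls[["Terrestrial"]]))
  expect_equal(r$states$memory, cls[["CommonReed"]])
  expect_equal(r$states$below, 3L)
  # an above-threshold year resets the counter: consecutive means consecutive
  r2 <- run_years(one_patch("MixedMarsh"), c(10, 10, 90, 10, 10, 10))
  expect_equal(r2$trace[5], cls[["MixedMarsh"]])
  expect_equal(r2$trace[6], cls[["Terrestrial"]])
})

test_that("RRG degrades to intermediate on the 3rd and poor on the 7th dry year", {
  r <- run_years(one_patch("RRG_good"), rep(0, 8))
  expect_equal(r$trace, unname(c(cls["RRG_good"], cls["RRG_good"],
                                 cls["RRG_intermediate"], cls["RRG_intermediate"],
                                 cls["RRG_intermediate"], cls["RRG_intermediate"],
                                 cls["RRG_poor"], cls["RRG_poor"])))
})

test_that("wet years leave healthy classes unchanged and reset counters", {
  st <- one_patch("CommonReed")
  st$below <- 2L
  out <- update_patch(st, 55, transition_rules())  # at threshold = not below
  expect_equal(out$class, cls[["CommonReed"]])
  expect_equal(out$below, 0L)
  expect_equal(out$above, 1L)
  # exactly one counter nonzero after any update
  expect_true(xor(out$below > 0, out$above > 0))
})

test_that("recovery restores remembered classes and steps RRG up one level", {
  # invaded terrestrial reverts after one above-threshold year
  r <- run_years(one_patch("CommonReed"), c(0, 0, 0, 90))
  expect_equal(r$trace[4], cls[["CommonReed"]])
  expect_true(is.na(r$states$memory))
  # RRG: poor -> intermediate -> good stepwise
  r2 <- run_years(one_patch("RRG_good"), c(rep(0, 7), 90, 90))
  expect_equal(r2$trace[7:9], unname(c(cls["RRG_poor"], cls["RRG_intermediate"],
                                       cls["RRG_good"])))
  # one-shot option jumps straight back to good
  rules1 <- transition_rules(rrg_one_shot_recovery = TRUE)
  r3 <- run_years(one_patch("RRG_good"), c(rep(0, 7), 90), rules1)
  expect_equal(r3$trace[8], cls[["RRG_good"]])
})

test_that("originally terrestrial patches never transition", {
  r <- run_years(one_patch("Terrestrial"), c(90, 90, 0, 0, 0, 90))
  expect_true(all(r$trace == cls[["Terrestrial"]]))
})

test_that("update_all matches a hand-run of the rule table and logs moves", {
  patches <- data.frame(patch_id = 1:4,
                        class0 = unname(cls[c("CommonReed", "MixedMarsh",
                                              "RRG_good", "Terrestrial")]),
                        n_cells = c(10, 20, 30, 40))
  states <- initial_patch_states(patches)
  rules <- transition_rules()
  # year of plenty: nothing moves
  res <- update_all(states, rep(100, 4), rules)
  expect_equal(res$states$class, states$class)
  expect_equal(nrow(res$log), 0)
  # permanent drought from healthy start: by year 3 non-woody are terrestrial,
  # by year 7 RRG is poor
  st <- states
  logs <- list()
  for (y in 1:7) {
    r <- update_all(st, rep(0, 4), rules)
    st <- r$states
    if (nrow(r$log)) logs[[length(logs) + 1]] <- cbind(year = y, r$log)
    if (y == 3)
      expect_equal(st$class[1:2], unname(rep(cls["Terrestrial"], 2)))
  }
  expect_equal(st$class[3], cls[["RRG_poor"]])
  # replay of the transition log reproduces the final state
  log <- do.call(rbind, logs)
  expect_equal(replay_log(states, log), st$class)
  expect_error(update_all(states, rep(50, 3), rules), "one MII")
})

test_that("roughness feedback maps classes locally and idempotently", {
  dom <- make_dem(domain_spec(n_rows = 20, n_cols = 17, seed = 11))
  veg <- make_initial_vegetation(dom)
  tab <- default_roughness()
  n0 <- roughness_feedback(dom, veg$patch, veg$patches$class0, tab)
  expect_true(all(n0[dom$kind == 1L] == tab[["channel"]]))
  expect_true(all(n0 > 0))
  # no transitions: map unchanged
  expect_identical(roughness_feedback(dom, veg$patch, veg$patches$class0, tab),
                   n0)
  # flip one patch: exactly that patch's floodplain cells change
  cls2 <- veg$patches$class0
  p <- veg$patches$patch_id[veg$patches$class0 == cls[["CommonReed"]]][1]
  cls2[p] <- cls[["Terrestrial"]]
  n1 <- roughness_feedback(dom, veg$patch, cls2, tab)
  changed <- which(n1 != n0)
  expect_true(all(veg$patch[changed] == p))
  expect_true(all(n1[changed] == tab[["Terrestrial"]]))
  # missing class entry is a configuration error
  expect_error(roughness_feedback(dom, veg$patch, veg$patches$class0,
                                  tab[-1]), "class")
})

test_that("the rule engine over MII arrays matches year-by-year updates", {
  set.seed(17)
  npatch <- 6
  states0 <- initial_patch_states(data.frame(
    patch_id = 1:npatch,
    class0 = unname(cls[c("CommonReed", "MixedMarsh", "RRG_good",
                          "CommonReed", "Terrestrial", "RRG_good")]),
    n_cells = rep(25, npatch)))
  arr <- array(runif(npatch * 8 * 6, 0, 100), c(npatch, 8, 6),
               dimnames = list(NULL, NULL, names(cls)))
  out <- run_rules(arr, states0, transition_rules())
  # independent replay through update_all
  st <- states0
  for (y in 1:8) {
    eff <- ifelse(st$class == cls[["Terrestrial"]],
                  ifelse(is.na(st$memory), cls[["MixedMarsh"]], st$memory),
                  st$class)
    mii <- arr[cbind(1:npatch, y, eff)]
    st <- update_all(st, mii, transition_rules())$states
    expect_equal(out$classes[, y], st$class)
  }
  expect_equal(replay_log(states0, out$log), out$states$class)
  # class areas always partition the total area
  for (y in 1:8)
    expect_equal(sum(class_extent(out$classes[, y], states0$n_cells)),
                 sum(states0$n_cells))
})

test_that("threshold calibration scores candidates and recovers a single one", {
  set.seed(23)
  arr <- array(runif(5 * 6 * 6, 0, 100), c(5, 6, 6),
               dimnames = list(NULL, NULL, names(cls)))
  states0 <- initial_patch_states(data.frame(
    patch_id = 1:5, class0 = unname(cls[c(1, 1, 2, 4, 4)]),
    n_cells = rep(10, 5)))
  truth <- run_rules(arr, states0, transition_rules())
  ref <- list(`4` = truth$classes[, 4], `6` = truth$classes[, 6])
  # single candidate: returned unchanged with its score
  one <- calibrate_thresholds(arr, states0,
                              list(CommonReed = 55, MixedMarsh = 20, RRG = 55),
                              ref)
  expect_equal(unname(one$rules$mii_threshold), c(55, 20, 55))
  expect_equal(one$best$overall_accuracy, 100)
  expect_true(all(one$scores$overall_accuracy >= 0 &
                  one$scores$overall_accuracy <= 100))
  expect_error(calibrate_thresholds(arr, states0,
                                    list(CommonReed = numeric(0),
                                         MixedMarsh = 20, RRG = 55), ref),
               "candidates")
})
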