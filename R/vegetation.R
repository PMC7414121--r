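#' Vegetation transition rule set
#'
#' Annual patch-level rules driven by the Minimum Inundation Index (MII):
#'
#' * a non-woody wetland patch (Common Reed, Mixed Marsh/Water Couch) whose
#'   MII stays below its class threshold for `years_to_terrestrial`
#'   consecutive water years transitions to the terrestrial association,
#'   remembering its wetland class;
#' * a good-condition River Red Gum patch degrades to intermediate condition
#'   on the `years_good_to_intermediate`-th consecutive below-threshold year
#'   ("more than two years"), and any River Red Gum patch reaches poor
#'   condition on the `years_to_poor`-th ("more than six years");
#' * recovery: a terrestrially invaded patch reverts to its remembered class
#'   after `years_to_recover` consecutive years with MII at or above that
#'   class's threshold; River Red Gum condition improves one level per
#'   above-threshold year (or straight to good if `rrg_one_shot_recovery`).
#'
#' "Below threshold" is the strict comparison `MII < threshold`. Transitions
#' are single-step: a patch changes at most one class/condition level per
#' water year. Counters are never reset by a transition, only by a year on
#' the other side of the threshold.
#'
#' @param mii_threshold named percentages: `CommonReed`, `MixedMarsh`, `RRG`
#'   (shared by all River Red Gum condition bands); defaults 55/20/55
#' @param years_to_terrestrial consecutive below-threshold years before
#'   terrestrial invasion (default 3)
#' @param years_good_to_intermediate consecutive below-threshold years at
#'   which good RRG degrades (default 3, i.e. "more than two")
#' @param years_to_poor consecutive below-threshold years at which RRG reaches
#'   poor condition (default 7, i.e. "more than six")
#' @param years_to_recover consecutive above-threshold years before an invaded
#'   patch reverts to its remembered class (default 1)
#' @param rrg_one_shot_recovery if `TRUE`, poor RRG recovers directly to good
#'   after one above-threshold year instead of stepping through intermediate
#' @return object of class `transition_rules`
#' @export
transition_rules <- function(mii_threshold = c(CommonReed = 55, MixedMarsh = 20,
                                               RRG = 55),
                             years_to_terrestrial = 3L,
                             years_good_to_intermediate = 3L,
                             years_to_poor = 7L,
                             years_to_recover = 1L,
                             rrg_one_shot_recovery = FALSE) {
  need <- c("CommonReed", "MixedMarsh", "RRG")
  if (!all(need %in% names(mii_threshold)))
    stop("`mii_threshold` must name CommonReed, MixedMarsh and RRG",
         call. = FALSE)
  if (any(mii_threshold < 0 | mii_threshold > 100))
    stop("thresholds must lie in [0, 100]", call. = FALSE)
  stopifnot(years_to_terrestrial >= 1, years_good_to_intermediate >= 1,
            years_to_poor >= 1, years_to_recover >= 1)
  structure(list(mii_threshold = mii_threshold[need],
                 years_to_terrestrial = as.integer(years_to_terrestrial),
                 years_good_to_intermediate = as.integer(years_good_to_intermediate),
                 years_to_poor = as.integer(years_to_poor),
                 years_to_recover = as.integer(years_to_recover),
                 rrg_one_shot_recovery = isTRUE(rrg_one_shot_recovery)),
            class = "transition_rules")
}

CLS <- c(CommonReed = 1L, MixedMarsh = 2L, Terrestrial = 3L,
         RRG_good = 4L, RRG_intermediate = 5L, RRG_poor = 6L)
cls_name <- function(code) names(CLS)[code]
is_rrg <- function(code) code >= 4L
is_nonwoody <- function(code) code <= 2L

#' Initial patch states
#'
#' @param patches data.frame with columns `patch_id`, `class0` (integer codes,
#'   see [vegetation_classes()]) and `n_cells`, as produced by
#'   [make_initial_vegetation()]
#' @return data.frame of per-patch state: class, consecutive below/above
#'   threshold year counters, and the remembered pre-invasion class (`NA`
#'   unless the patch is invaded terrestrial)
#' @export
initial_patch_states <- function(patches) {
  stopifnot(all(c("patch_id", "class0", "n_cells") %in% names(patches)))
  data.frame(patch_id = patches$patch_id,
             class = as.integer(patches$class0),
             below = 0L, above = 0L, memory = NA_integer_,
             n_cells = patches$n_cells)
}

# class whose water requirement / threshold governs a patch this year:
# invaded terrestrial patches are judged against their remembered class;
# originally terrestrial patches (no memory) against Mixed Marsh.
effective_class <- function(class, memory) {
  eff <- class
  terr <- class == CLS[["Terrestrial"]]
  eff[terr] <- ifelse(is.na(memory[terr]), CLS[["MixedMarsh"]], memory[terr])
  eff
}

threshold_for <- function(eff_class, rules) {
  thr <- rules$mii_threshold
  unname(ifelse(eff_class == CLS[["CommonReed"]], thr[["CommonReed"]],
         ifelse(eff_class == CLS[["MixedMarsh"]], thr[["MixedMarsh"]],
                thr[["RRG"]])))
}

#' Update one patch state for a water year
#'
#' @param state single-row data.frame as in [initial_patch_states()]
#' @param mii this water year's MII for the patch, percent
#' @param rules a [transition_rules()]
#' @return the updated single-row state
#' @export
update_patch <- function(state, mii, rules) {
  res <- update_all(state, mii, rules)
  res$states
}

#' Update all patch states for a water year
#'
#' Independent per-patch updates; see [transition_rules()] for the rule table.
#'
#' @param states patch-state data.frame
#' @param mii numeric vector, one MII (percent) per patch
#' @param rules a [transition_rules()]
#' @return list with updated `states` and a transition `log` data.frame
#'   (`patch_id`, `from`, `to`)
#' @export
update_all <- function(states, mii, rules) {
  if (length(mii) != nrow(states))
    stop("need exactly one MII value per patch", call. = FALSE)
  if (anyNA(mii)) stop("missing MII values", call. = FALSE)
  stopifnot(all(mii >= 0 & mii <= 100))
  eff <- effective_class(states$class, states$memory)
  thr <- threshold_for(eff, rules)
  below_year <- mii < thr
  old <- states$class

  states$below <- ifelse(below_year, states$below + 1L, 0L)
  states$above <- ifelse(below_year, 0L, states$above + 1L)

  cl <- states$class
  new <- cl
  # degradation
  hit_terr <- below_year & is_nonwoody(cl) &
    states$below >= rules$years_to_terrestrial
  new[hit_terr] <- CLS[["Terrestrial"]]
  states$memory[hit_terr] <- cl[hit_terr]
  new[below_year & cl == CLS[["RRG_good"]] &
        states$below >= rules$years_good_to_intermediate] <- CLS[["RRG_intermediate"]]
  new[below_year & cl == CLS[["RRG_intermediate"]] &
        states$below >= rules$years_to_poor] <- CLS[["RRG_poor"]]
  # recovery
  recov <- !below_year & cl == CLS[["Terrestrial"]] & !is.na(states$memory) &
    states$above >= rules$years_to_recover
  new[recov] <- states$memory[recov]
  states$memory[recov] <- NA_integer_
  new[!below_year & cl == CLS[["RRG_intermediate"]]] <- CLS[["RRG_good"]]
  new[!below_year & cl == CLS[["RRG_poor"]]] <-
    if (rules$rrg_one_shot_recovery) CLS[["RRG_good"]] else CLS[["RRG_intermediate"]]

  states$class <- as.integer(new)
  changed <- new != old
  log <- data.frame(patch_id = states$patch_id[changed],
                    from = cls_name(old[changed]), to = cls_name(new[changed]))
  list(states = states, log = log)
}

#' Run the transition rule engine over precomputed MII series
#'
#' Applies [update_all()] water year by water year using a per-class MII
#' array, so each patch is always judged against the requirement of its
#' current (effective) class. Used directly by threshold calibration, where
#' the hydrodynamics (and hence the MII array) are held fixed.
#'
#' @param mii_arr array `[n_patches, n_years, n_classes]` from [mii_by_class()]
#' @param states0 initial patch states
#' @param rules a [transition_rules()]
#' @return list: `classes` matrix `[n_patches, n_years]` of end-of-year class
#'   codes, `mii` matrix of the MII values used, final `states`, transition
#'   `log` (with a `year` column)
#' @export
run_rules <- function(mii_arr, states0, rules) {
  npatch <- dim(mii_arr)[1]; nyears <- dim(mii_arr)[2]
  stopifnot(npatch == nrow(states0))
  states <- states0
  classes <- matrix(NA_integer_, npatch, nyears)
  mii_used <- matrix(NA_real_, npatch, nyears)
  logs <- list()
  cls_names <- names(CLS)
  for (y in seq_len(nyears)) {
    eff <- effective_class(states$class, states$memory)
    mii <- mii_arr[cbind(seq_len(npatch), y, match(cls_names[eff],
                                                   dimnames(mii_arr)[[3]]))]
    res <- update_all(states, mii, rules)
    states <- res$states
    classes[, y] <- states$class
    mii_used[, y] <- mii
    if (nrow(res$log) > 0) logs[[length(logs) + 1L]] <- cbind(year = y, res$log)
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(year = integer(), patch_id = integer(),
               from = character(), to = character())
  list(classes = classes, mii = mii_used, states = states, log = log)
}

#' Replay a transition log
#'
#' Reconstructs final patch classes from initial classes and a transition log;
#' the log is a complete account of state evolution.
#'
#' @param states0 initial patch states
#' @param log transition log from [run_rules()] or [run_coupled()]
#' @return integer vector of final class codes per patch
#' @export
replay_log <- function(states0, log) {
  cls <- states0$class
  if (nrow(log) > 0) {
    log <- log[order(log$year), , drop = FALSE]
    for (i in seq_len(nrow(log))) {
      p <- match(log$patch_id[i], states0$patch_id)
      stopifnot(cls_name(cls[p]) == log$from[i])
      cls[p] <- CLS[[log$to[i]]]
    }
  }
  cls
}

#' Default Manning roughness per vegetation class
#'
#' Literature-range roughness for vegetated floodplain substrates and the
#' channel; exposed so calibrated values can be substituted.
#'
#' @return named numeric vector (s m^-1/3) with one entry per vegetation
#'   class plus `channel`
#' @export
default_roughness <- function() {
  c(CommonReed = 0.12, MixedMarsh = 0.08, Terrestrial = 0.04,
    RRG_good = 0.12, RRG_intermediate = 0.09, RRG_poor = 0.06,
    channel = 0.035)
}

#' Map patch classes to a cell roughness grid (vegetation feedback)
#'
#' Each cell takes the Manning roughness of its patch's current class;
#' channel cells take the channel roughness. Applied at water-year boundaries
#' in [run_coupled()], this is the feedback of vegetation change on the flow.
#'
#' @param domain a `grid_domain`
#' @param patch integer patch-id matrix
#' @param class_per_patch integer class codes indexed by patch id
#' @param table named roughness lookup as in [default_roughness()]
#' @return Manning-n matrix
#' @export
roughness_feedback <- function(domain, patch, class_per_patch,
                               table = default_roughness()) {
  need <- c(names(CLS), "channel")
  if (!all(cls_name(unique(class_per_patch)) %in% names(table)) ||
      !("channel" %in% names(table)))
    stop("roughness table is missing a class entry", call. = FALSE)
  n <- matrix(table[cls_name(class_per_patch[as.integer(patch)])],
              domain$n_rows, domain$n_cols)
  n[domain$kind == 1L] <- table[["channel"]]
  n
}

#' Per-class areas from patch states
#'
#' @param classes integer class codes per patch
#' @param n_cells cells per patch
#' @return named integer vector of cell counts per vegetation class
#' @export
class_extent <- function(classes, n_cells) {
  out <- vapply(CLS, function(code) sum(n_cells[classes == code]), numeric(1))
  names(out) <- names(CLS)
  out
}

#' Coupled flow--vegetation simulation
#'
#' The annual loop: run the storage-cell hydrodynamics for one June--May water
#' year under the current roughness map, summarise per-patch inundation as
#' MII, apply the transition rules, update the roughness from the new classes
#' (unless `feedback = FALSE`), and carry the water surface into the next
#' year.
#'
#' @param domain a `grid_domain`
#' @param inflow daily inflow data.frame (`flow_m3s`), whole water years
#' @param veg a list from [make_initial_vegetation()] (or compatible:
#'   `patch` matrix + `patches` data.frame)
#' @param rules a [transition_rules()]
#' @param requirements named list of [water_requirement()]s per class
#' @param roughness_table named vector as in [default_roughness()]
#' @param config a [solver_config()]
#' @param downstream downstream boundary treatment (see [run_hydrodynamics()])
#' @param feedback update roughness from vegetation annually (`TRUE`) or keep
#'   the initial-condition roughness throughout (`FALSE`)
#' @return list: `classes` `[n_patches, n_years]`, `mii` `[n_patches,
#'   n_years]`, `extent` `[n_classes, n_years]` cell counts, `degraded_pct`
#'   per year, transition `log`, final `states`, `mii_arr` (per-class MII),
#'   and `mass_balance`
#' @export
run_coupled <- function(domain, inflow, veg, rules = transition_rules(),
                        requirements = default_requirements(),
                        roughness_table = default_roughness(),
                        config = solver_config(dt_max = 60, loss_mm_day = 4),
                        downstream = "free", feedback = TRUE) {
  series <- if (is.data.frame(inflow)) inflow$flow_m3s else as.numeric(inflow)
  nyears <- n_complete_years(length(series))
  stopifnot(nyears >= 1)
  states <- initial_patch_states(veg$patches)
  npatch <- nrow(states)
  classes <- matrix(NA_integer_, npatch, nyears)
  mii_used <- matrix(NA_real_, npatch, nyears)
  mii_arr <- array(NA_real_, c(npatch, nyears, length(CLS)),
                   dimnames = list(NULL, NULL, names(CLS)))
  extent <- matrix(NA_real_, length(CLS), nyears,
                   dimnames = list(names(CLS), NULL))
  degraded <- numeric(nyears)
  logs <- list()
  mb <- list()
  z <- domain$bed
  n_map <- roughness_feedback(domain, veg$patch, states$class, roughness_table)
  for (y in seq_len(nyears)) {
    days <- ((y - 1L) * 365L + 1L):(y * 365L)
    hyd <- tryCatch(
      run_hydrodynamics(domain, n_map, series[days], downstream = downstream,
                        z0 = z, config = config),
      error = function(e) stop(sprintf("water year %d: %s", y,
                                       conditionMessage(e)), call. = FALSE))
    z <- hyd$z_final
    mb[[y]] <- cbind(water_year = y, hyd$mass_balance)
    arr <- mii_by_class(hyd$depth, veg$patch, requirements)
    mii_arr[, y, ] <- arr[, 1, names(CLS)]
    eff <- effective_class(states$class, states$memory)
    mii <- arr[cbind(seq_len(npatch), 1L, match(cls_name(eff),
                                                dimnames(arr)[[3]]))]
    res <- update_all(states, mii, rules)
    states <- res$states
    classes[, y] <- states$class
    mii_used[, y] <- mii
    extent[, y] <- class_extent(states$class, states$n_cells)
    degraded[y] <- degraded_fraction(states)
    if (nrow(res$log) > 0) logs[[length(logs) + 1L]] <- cbind(year = y, res$log)
    if (feedback)
      n_map <- roughness_feedback(domain, veg$patch, states$class,
                                  roughness_table)
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(year = integer(), patch_id = integer(),
               from = character(), to = character())
  list(classes = classes, mii = mii_used, mii_arr = mii_arr, extent = extent,
       degraded_pct = degraded, log = log, states = states,
       mass_balance = do.call(rbind, mb))
}

#' Calibrate MII transition thresholds against reference maps
#'
#' Exhaustive search over candidate threshold combinations. Each candidate
#' rule set is run through the transition engine on a fixed per-class MII
#' array (hydrodynamics frozen at the initial-condition roughness) and scored
#' by the mean area-weighted overall accuracy of the predicted patch classes
#' against the reference classes at the check years. Ties are broken in
#' favour of lower thresholds.
#'
#' @param mii_arr array from [mii_by_class()] (all simulated years)
#' @param states0 initial patch states
#' @param candidates named list of candidate threshold vectors:
#'   `CommonReed`, `MixedMarsh`, `RRG` (percent)
#' @param reference named list: one integer class-code vector per check year,
#'   names are the year indices into `mii_arr`
#' @param rules_base rule set providing the non-threshold parameters
#' @return list: `rules` (best rule set), `best` (its score row) and `scores`
#'   (full table: thresholds + mean overall accuracy, percent)
#' @export
calibrate_thresholds <- function(mii_arr, states0, candidates, reference,
                                 rules_base = transition_rules()) {
  need <- c("CommonReed", "MixedMarsh", "RRG")
  if (!all(need %in% names(candidates)) ||
      any(vapply(candidates[need], length, 1L) == 0))
    stop("candidates must provide non-empty CommonReed, MixedMarsh and RRG grids",
         call. = FALSE)
  if (length(reference) == 0) stop("need at least one reference map",
                                   call. = FALSE)
  check_years <- as.integer(names(reference))
  stopifnot(all(check_years >= 1), all(check_years <= dim(mii_arr)[2]))
  grid <- expand.grid(CommonReed = sort(candidates$CommonReed),
                      MixedMarsh = sort(candidates$MixedMarsh),
                      RRG = sort(candidates$RRG))
  area <- states0$n_cells
  total <- sum(area)
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rules <- rules_base
    rules$mii_threshold <- c(CommonReed = grid$CommonReed[i],
                             MixedMarsh = grid$MixedMarsh[i],
                             RRG = grid$RRG[i])
    sim <- run_rules(mii_arr, states0, rules)
    acc <- vapply(seq_along(check_years), function(j) {
      100 * sum(area[sim$classes[, check_years[j]] == reference[[j]]]) / total
    }, numeric(1))
    score[i] <- mean(acc)
  }
  grid$overall_accuracy <- score
  best_i <- which.max(score)  # expand.grid order => lowest thresholds win ties
  rules <- rules_base
  rules$mii_threshold <- c(CommonReed = grid$CommonReed[best_i],
                           MixedMarsh = grid$MixedMarsh[best_i],
                           RRG = grid$RRG[best_i])
  list(rules = rules, best = grid[best_i, ], scores = grid)
}
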