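#' Climate-change scenario specification
#'
#' A scenario is the base inflow series scaled by a proportionality factor.
#' The defaults mirror end-of-century runoff projections of -20 % (median)
#' with an upper limit of +20 % and a lower limit of -60 %: factors 1.0
#' (Current), 0.8 (Median), 1.2 (Upper) and 0.4 (Lower), i.e.
#' `factor = 1 + deltaR`.
#'
#' @param name scenario label
#' @param flow_factor positive flow multiplier
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(name, flow_factor) {
  if (!is.numeric(flow_factor) || flow_factor <= 0)
    stop("`flow_factor` must be > 0", call. = FALSE)
  structure(list(name = name, flow_factor = flow_factor),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @return `default_scenarios()`: list of the four standard scenarios.
#' @export
default_scenarios <- function() {
  list(scenario_spec("Current", 1.0), scenario_spec("Median", 0.8),
       scenario_spec("Upper", 1.2), scenario_spec("Lower", 0.4))
}

#' Scale a discharge series
#'
#' Multiplies every discharge value by a proportionality factor; dates are
#' unchanged.
#'
#' @param series data.frame with a `flow_m3s` column (e.g. from
#'   [make_hydrograph()]) or a numeric vector
#' @param factor positive multiplier
#' @return the scaled series, same shape as the input
#' @export
scale_discharge <- function(series, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("`factor` must be a single positive number", call. = FALSE)
  if (is.data.frame(series)) {
    stopifnot("flow_m3s" %in% names(series))
    series$flow_m3s <- series$flow_m3s * factor
    series
  } else {
    series * factor
  }
}

#' Fit a power-law rating curve
#'
#' Converts stage records to discharge before scenario scaling when the model
#' is stage-forced: fits `Q = a * (stage - h0)^b` by log-log least squares
#' (`h0` given, default 0).
#'
#' @param stage,discharge paired positive observations
#' @param h0 stage datum offset
#' @return function mapping stage to discharge, with coefficients in
#'   `attr(, "coef")`
#' @export
rating_curve <- function(stage, discharge, h0 = 0) {
  ok <- stage > h0 & discharge > 0
  if (sum(ok) < 2) stop("need at least two usable stage-discharge pairs",
                        call. = FALSE)
  fit <- stats::lm(log(discharge[ok]) ~ log(stage[ok] - h0))
  a <- exp(stats::coef(fit)[[1]]); b <- stats::coef(fit)[[2]]
  f <- function(s) ifelse(s > h0, a * (s - h0)^b, 0)
  attr(f, "coef") <- c(a = a, b = b, h0 = h0)
  f
}

#' Run the coupled model under multiple inflow scenarios
#'
#' One [run_coupled()] per scenario, sharing the domain, initial vegetation
#' and rules. A failing scenario is reported in the result without aborting
#' its siblings.
#'
#' @param specs list of [scenario_spec()]s (default: Current/Median/Upper/
#'   Lower)
#' @param domain,inflow,veg,rules,requirements,roughness_table,config,downstream,feedback
#'   passed to [run_coupled()]; `inflow` is the unscaled (Current) series
#' @return list with `runs` (named per-scenario [run_coupled()] outputs, or a
#'   condition object on failure) and `comparison`: data.frame of scenario,
#'   flow factor, water year, degraded percent and per-class cell counts
#' @export
run_scenarios <- function(specs = default_scenarios(), domain, inflow, veg,
                          rules = transition_rules(),
                          requirements = default_requirements(),
                          roughness_table = default_roughness(),
                          config = solver_config(dt_max = 60, loss_mm_day = 4),
                          downstream = "free", feedback = TRUE) {
  names(specs) <- vapply(specs, `[[`, "", "name")
  runs <- lapply(specs, function(sp) {
    tryCatch(run_coupled(domain, scale_discharge(inflow, sp$flow_factor), veg,
                         rules = rules, requirements = requirements,
                         roughness_table = roughness_table, config = config,
                         downstream = downstream, feedback = feedback),
             error = function(e) e)
  })
  rows <- list()
  for (nm in names(runs)) {
    r <- runs[[nm]]
    if (inherits(r, "error")) next
    ny <- length(r$degraded_pct)
    rows[[nm]] <- data.frame(scenario = nm,
                             flow_factor = specs[[nm]]$flow_factor,
                             water_year = seq_len(ny),
                             degraded_pct = r$degraded_pct,
                             t(r$extent))
  }
  list(runs = runs,
       comparison = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                    else NULL)
}
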