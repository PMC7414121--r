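#' Minimum water requirement of a vegetation association
#'
#' A requirement is met by a cell in a water year when its depth is at or
#' above `min_depth` for at least `min_duration` of the year (days need not be
#' consecutive: the depth--duration curve is an exceedance curve).
#'
#' @param min_depth metres (>= 0)
#' @param min_duration fraction of the water year in (0, 1]
#' @return object of class `water_requirement`
#' @export
water_requirement <- function(min_depth, min_duration) {
  stopifnot(min_depth >= 0, min_duration > 0, min_duration <= 1)
  structure(list(min_depth = min_depth, min_duration = min_duration),
            class = "water_requirement")
}

#' Default minimum water requirements per vegetation class
#'
#' Common Reed requires about four months (33 % of the year) of inundation at
#' or above 0.02 m; Mixed Marsh/Water Couch and River Red Gum cope with three
#' months (25 %). Terrestrial patches that were invaded carry the requirement
#' of their remembered wetland class; originally terrestrial patches are
#' assigned the Mixed Marsh requirement for completeness (they never
#' transition).
#'
#' @return named list of [water_requirement()]s, one per vegetation class
#' @export
default_requirements <- function() {
  rrg <- water_requirement(0.02, 0.25)
  list(CommonReed = water_requirement(0.02, 0.33),
       MixedMarsh = water_requirement(0.02, 0.25),
       Terrestrial = water_requirement(0.02, 0.25),
       RRG_good = rrg, RRG_intermediate = rrg, RRG_poor = rrg)
}

#' Depth--duration (exceedance) curve for one cell-year
#'
#' For a full water year of daily depths, the fraction of the year during
#' which the depth is at or above each level.
#'
#' @param depths numeric vector of 365 daily depths (m)
#' @return object of class `ddf_curve`; evaluate with [duration_fraction()]
#' @export
depth_duration_curve <- function(depths) {
  if (length(depths) != 365L)
    stop(sprintf("need a complete 365-day water year, got %d days",
                 length(depths)), call. = FALSE)
  if (anyNA(depths)) stop("depth series contains missing days", call. = FALSE)
  structure(list(sorted = sort(depths), n = length(depths)),
            class = "ddf_curve")
}

#' @rdname depth_duration_curve
#' @param curve a `ddf_curve`
#' @param depth level(s) to evaluate (m)
#' @return fraction of the year with depth at or above `depth`
#' @export
duration_fraction <- function(curve, depth) {
  stopifnot(inherits(curve, "ddf_curve"))
  vapply(depth, function(d) {
    # count of sorted values >= d
    (curve$n - findInterval(d, curve$sorted, left.open = TRUE)) / curve$n
  }, numeric(1))
}

#' Does a cell-year meet a minimum water requirement?
#'
#' `TRUE` iff the fraction of the water year with depth at or above
#' `min_depth` is at or above `min_duration` (both comparisons are `>=`).
#'
#' @param curve a [depth_duration_curve()]
#' @param requirement a [water_requirement()]
#' @return logical
#' @export
cell_compliance <- function(curve, requirement) {
  stopifnot(inherits(requirement, "water_requirement"))
  duration_fraction(curve, requirement$min_depth) >= requirement$min_duration
}

#' Minimum Inundation Index of a patch
#'
#' The percentage of a patch's cells whose annual inundation meets the
#' minimum water requirement: `MII = 100 * compliant / total`.
#'
#' @param compliance logical vector, one entry per patch cell
#' @return MII in percent, in `[0, 100]`
#' @export
compute_mii <- function(compliance) {
  if (length(compliance) == 0) stop("empty patch", call. = FALSE)
  if (anyNA(compliance)) stop("missing compliance values", call. = FALSE)
  100 * sum(compliance) / length(compliance)
}

# per-cell compliance matrix [cells, years] for one requirement
compliance_by_year <- function(depth_stack, requirement) {
  d <- dim(depth_stack)
  nyears <- n_complete_years(d[3])
  ncell <- d[1] * d[2]
  flat <- matrix(depth_stack, ncell, d[3])
  out <- matrix(NA, ncell, nyears)
  for (y in seq_len(nyears)) {
    days <- ((y - 1L) * 365L + 1L):(y * 365L)
    wet <- rowSums(flat[, days, drop = FALSE] >= requirement$min_depth) / 365
    out[, y] <- wet >= requirement$min_duration
  }
  out
}

#' Per-patch MII under every class requirement
#'
#' Computes, for each patch and water year, the MII that the patch would have
#' under the requirement of each vegetation class. Needed because a patch's
#' effective requirement follows its (changing) class.
#'
#' @param depth_stack array `[rows, cols, days]`; days must span whole water
#'   years (a partial trailing year is dropped with a warning)
#' @param patch integer patch-id matrix (partition of the grid)
#' @param requirements named list of [water_requirement()]s per class
#' @return array `[n_patches, n_years, n_classes]` of MII percentages, with
#'   dimnames on patches and classes
#' @export
mii_by_class <- function(depth_stack, patch, requirements = default_requirements()) {
  d <- dim(depth_stack)
  stopifnot(length(d) == 3, all(dim(patch) == d[1:2]))
  if (d[3] %% 365L != 0L)
    warning(sprintf("dropping partial trailing water year (%d spare days)",
                    d[3] %% 365L))
  nyears <- n_complete_years(d[3])
  pid <- as.integer(patch)
  npatch <- max(pid)
  classes <- names(requirements)
  # distinct requirements shared by several classes are computed once
  key <- vapply(requirements, function(r)
    paste(r$min_depth, r$min_duration), character(1))
  out <- array(NA_real_, c(npatch, nyears, length(classes)),
               dimnames = list(NULL, NULL, classes))
  patch_n <- tabulate(pid, npatch)
  for (k in unique(key)) {
    req <- requirements[[match(k, key)]]
    comp <- compliance_by_year(depth_stack, req)
    mii <- 100 * rowsum(comp + 0, pid) / patch_n
    for (cl in classes[key == k]) out[, , cl] <- mii
  }
  out
}

#' MII time series for the current patch classes
#'
#' One MII per patch per water year, computed against the requirement of the
#' patch's current class (constant classes; the coupled simulation in
#' [run_coupled()] re-evaluates classes annually).
#'
#' @param depth_stack array `[rows, cols, days]`
#' @param patch integer patch-id matrix
#' @param classes integer vector of class codes per patch (see
#'   [vegetation_classes()])
#' @param requirements named list of requirements per class
#' @return matrix `[n_patches, n_years]` of MII percentages
#' @export
mii_timeseries <- function(depth_stack, patch, classes,
                           requirements = default_requirements()) {
  arr <- mii_by_class(depth_stack, patch, requirements)
  cls_names <- names(vegetation_classes())[classes]
  out <- matrix(NA_real_, dim(arr)[1], dim(arr)[2])
  for (p in seq_len(dim(arr)[1])) out[p, ] <- arr[p, , cls_names[p]]
  out
}
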