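#' @title Synthetic study inputs
#'
#' @description
#' Generators for self-contained synthetic inputs that emulate the structure
#' of a dryland floodplain wetland study site: a gently sloped valley with an
#' incised channel, multi-year daily inflow hydrographs containing drought and
#' flood blocks, a banded initial vegetation mosaic partitioned into patches,
#' and pseudo-observations at a virtual gauge. All generators are pure
#' functions of their spec (including the seed): repeated calls are
#' bit-identical.
#'
#' @name synthetic
NULL

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Specify a synthetic valley domain
#'
#' @param n_rows,n_cols grid dimensions (rows run down-valley; row 1 is the
#'   upstream boundary, the last row the downstream boundary)
#' @param cell_size cell edge length in metres (default 90 m)
#' @param valley_slope down-valley bed gradient (m/m)
#' @param channel_col column index of the incised channel (default: centre)
#' @param channel_incision depth of the channel bed below the adjacent
#'   floodplain, metres; also used as the bank-full depth
#' @param channel_width channel section width, metres
#' @param microtopography_sd standard deviation of uncorrelated Gaussian
#'   floodplain microtopography, metres
#' @param seed integer RNG seed
#' @return an object of class `domain_spec`
#' @export
domain_spec <- function(n_rows = 20L, n_cols = 20L, cell_size = 90,
                        valley_slope = 2e-4, channel_col = NULL,
                        channel_incision = 1, channel_width = 20,
                        microtopography_sd = 0.05, seed = 1L) {
  if (!is.numeric(n_rows) || n_rows < 2) stop_field("n_rows", "must be >= 2")
  if (!is.numeric(n_cols) || n_cols < 2) stop_field("n_cols", "must be >= 2")
  if (cell_size <= 0) stop_field("cell_size", "must be > 0")
  if (channel_incision <= 0) stop_field("channel_incision", "must be > 0")
  if (channel_width <= 0) stop_field("channel_width", "must be > 0")
  if (microtopography_sd < 0) stop_field("microtopography_sd", "must be >= 0")
  if (is.null(channel_col)) channel_col <- as.integer(ceiling(n_cols / 2))
  if (channel_col < 1 || channel_col > n_cols)
    stop_field("channel_col", "outside the grid")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, valley_slope = valley_slope,
                 channel_col = as.integer(channel_col),
                 channel_incision = channel_incision,
                 channel_width = channel_width,
                 microtopography_sd = microtopography_sd,
                 seed = as.integer(seed)),
            class = "domain_spec")
}

#' Build a synthetic DEM and grid domain
#'
#' The floodplain is a plane sloping down-valley at `valley_slope`, with
#' uncorrelated Gaussian microtopography; the channel column is incised
#' `channel_incision` metres below the (noise-free) adjacent floodplain and
#' carries a rectangular section. The upstream inflow cell is the channel cell
#' in row 1; the whole last row is the downstream boundary.
#'
#' @param spec a [domain_spec()]
#' @return an object of class `grid_domain`: bed elevation matrix, cell-kind
#'   matrix (`0` floodplain, `1` channel), channel geometry and boundary cells.
#' @export
make_dem <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  plane <- -spec$valley_slope * spec$cell_size * (seq_len(nr) - 1L)
  bed <- matrix(plane, nr, nc)
  if (spec$microtopography_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(nr * nc, 0, spec$microtopography_sd), nr, nc))
    noise[, spec$channel_col] <- 0  # keep the channel profile monotone
    bed <- bed + noise
  }
  kind <- matrix(0L, nr, nc)
  kind[, spec$channel_col] <- 1L
  bed[, spec$channel_col] <- plane - spec$channel_incision
  structure(list(n_rows = nr, n_cols = nc, cell_size = spec$cell_size,
                 bed = bed, kind = kind,
                 channel_width = spec$channel_width,
                 bankfull_depth = spec$channel_incision,
                 channel_col = spec$channel_col,
                 inflow_cells = cbind(row = 1L, col = spec$channel_col),
                 spec = spec),
            class = "grid_domain")
}

#' Specify a synthetic multi-year daily hydrograph
#'
#' Emulates a semi-arid flow regime: a perennial base flow, a winter--spring
#' seasonal high-flow pulse every year, large flood pulses in designated flood
#' years, and a multiplicative flow reduction in drought years. The default
#' 22-year series mirrors a record with two major floods (years 10 and 20)
#' bracketing a 9-year drought (years 11--19).
#'
#' @param n_years number of 365-day water years
#' @param start_year calendar label of the first water year
#' @param base_flow perennial base flow, m3/s
#' @param seasonal_amplitude peak of the ordinary seasonal pulse, m3/s
#' @param seasonal_duration days of the seasonal pulse (half-sine), from the
#'   start of the water year
#' @param flood_years water-year indices receiving an extra flood pulse
#' @param flood_magnitude peak of the flood pulse, m3/s
#' @param flood_duration days of the flood pulse (half-sine)
#' @param drought_years water-year indices scaled down by `drought_multiplier`
#' @param drought_multiplier flow multiplier in (0, 1] for drought years
#' @param daily_noise_cv coefficient of variation of multiplicative daily noise
#' @param seed integer RNG seed
#' @return an object of class `hydrograph_spec`
#' @export
hydrograph_spec <- function(n_years = 22L, start_year = 1991L, base_flow = 2,
                            seasonal_amplitude = 20, seasonal_duration = 180L,
                            flood_years = c(10L, 20L), flood_magnitude = 80,
                            flood_duration = 150L, drought_years = 11:19,
                            drought_multiplier = 0.25, daily_noise_cv = 0.1,
                            seed = 1L) {
  if (base_flow < 0) stop_field("base_flow", "must be >= 0")
  if (seasonal_amplitude < 0) stop_field("seasonal_amplitude", "must be >= 0")
  if (flood_magnitude < 0) stop_field("flood_magnitude", "must be >= 0")
  if (drought_multiplier <= 0 || drought_multiplier > 1)
    stop_field("drought_multiplier", "must be in (0, 1]")
  if (daily_noise_cv < 0) stop_field("daily_noise_cv", "must be >= 0")
  if (length(intersect(flood_years, drought_years)) > 0)
    stop_field("flood_years", "flood and drought year sets must be disjoint")
  if (n_years < 1) stop_field("n_years", "must be >= 1")
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 base_flow = base_flow,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_duration = as.integer(seasonal_duration),
                 flood_years = as.integer(flood_years),
                 flood_magnitude = flood_magnitude,
                 flood_duration = as.integer(flood_duration),
                 drought_years = as.integer(drought_years),
                 drought_multiplier = drought_multiplier,
                 daily_noise_cv = daily_noise_cv, seed = as.integer(seed)),
            class = "hydrograph_spec")
}

#' Generate the daily discharge series for a hydrograph spec
#'
#' @param spec a [hydrograph_spec()]
#' @return a `data.frame` with columns `date`, `flow_m3s`, `water_year`
#'   (365 rows per water year); non-negative everywhere.
#' @export
make_hydrograph <- function(spec) {
  stopifnot(inherits(spec, "hydrograph_spec"))
  ny <- spec$n_years
  doy <- rep(seq_len(365L), ny)
  wy <- water_year_index(365L * ny)
  half_sine <- function(day, dur, amp) {
    ifelse(day <= dur, amp * sin(pi * day / dur), 0)
  }
  flow <- spec$base_flow +
    half_sine(doy, spec$seasonal_duration, spec$seasonal_amplitude)
  in_flood <- wy %in% spec$flood_years
  flow[in_flood] <- flow[in_flood] +
    half_sine(doy[in_flood], spec$flood_duration, spec$flood_magnitude)
  if (spec$daily_noise_cv > 0) {
    noise <- with_seed(spec$seed, rnorm(length(flow), 1, spec$daily_noise_cv))
    flow <- flow * pmax(noise, 0)
  }
  in_drought <- wy %in% spec$drought_years
  flow[in_drought] <- flow[in_drought] * spec$drought_multiplier
  data.frame(date = water_year_dates(spec$start_year, ny),
             flow_m3s = pmax(flow, 0), water_year = wy)
}

#' Vegetation classes
#'
#' Integer-coded vegetation classes: two non-woody wetland associations
#' (Common Reed, Mixed Marsh/Water Couch), a terrestrial (chenopod)
#' association, and River Red Gum woodland in three condition bands
#' (good: <40 % apparent canopy mortality, intermediate: 40--80 %,
#' poor: >80 %).
#'
#' @return named integer vector mapping class names to codes.
#' @export
vegetation_classes <- function() {
  c(CommonReed = 1L, MixedMarsh = 2L, Terrestrial = 3L,
    RRG_good = 4L, RRG_intermediate = 5L, RRG_poor = 6L)
}

#' Build a banded initial vegetation mosaic and its patch partition
#'
#' Classes are assigned by lateral distance to the channel, reproducing the
#' typical dryland-wetland gradient: Common Reed fringes the channel, Mixed
#' Marsh/Water Couch lies beyond it, River Red Gum occupies the outer, less
#' frequently inundated band, and any remaining area is (original) terrestrial
#' vegetation. Each band is split down-valley into contiguous rectangular
#' patches with cell counts within `[min_cells, max_cells]`.
#'
#' @param domain a [make_dem()] grid domain
#' @param band_widths named numeric vector of lateral band widths in metres,
#'   in order `CommonReed`, `MixedMarsh`, `RRG_good`
#' @param min_cells,max_cells patch size bounds in cells
#' @return a list with `veg`: integer class matrix; `patch`: integer patch-id
#'   matrix (a partition of the grid); `patches`: data.frame of patch id,
#'   initial class and cell count.
#' @export
make_initial_vegetation <- function(domain,
                                    band_widths = c(CommonReed = 180,
                                                    MixedMarsh = 270,
                                                    RRG_good = 270),
                                    min_cells = 20L, max_cells = 840L) {
  stopifnot(inherits(domain, "grid_domain"))
  need <- c("CommonReed", "MixedMarsh", "RRG_good")
  if (!all(need %in% names(band_widths)))
    stop_field("band_widths", "must name CommonReed, MixedMarsh and RRG_good")
  bw <- band_widths[need]
  if (any(bw < 0)) stop_field("band_widths", "must be >= 0")
  nr <- domain$n_rows; nc <- domain$n_cols
  dist <- abs(col(matrix(0, nr, nc)) - domain$channel_col) * domain$cell_size
  max_dist <- max(dist)
  if (sum(bw) > max_dist + domain$cell_size)
    stop_field("band_widths", "bands exceed the lateral extent of the domain")
  cls <- matrix(vegetation_classes()[["Terrestrial"]], nr, nc)
  edges <- cumsum(bw)
  cls[dist < edges[3]] <- vegetation_classes()[["RRG_good"]]
  cls[dist < edges[2]] <- vegetation_classes()[["MixedMarsh"]]
  cls[dist < edges[1]] <- vegetation_classes()[["CommonReed"]]

  # patches: contiguous row-blocks within each (band, valley side) strip
  side <- sign(col(cls) - domain$channel_col)
  patch <- matrix(NA_integer_, nr, nc)
  pid <- 0L
  info <- list()
  for (cl in unique(as.integer(cls))) {
    for (s in c(-1, 0, 1)) {
      sel_cols <- which(cls[1, ] == cl & side[1, ] == s)
      if (length(sel_cols) == 0) next
      cells_per_row <- length(sel_cols)
      k <- max(1L, ceiling(min_cells / cells_per_row))
      starts <- seq(1L, nr, by = k)
      # merge a trailing short block into the previous patch
      if (length(starts) > 1 && (nr - starts[length(starts)] + 1L) * cells_per_row < min_cells)
        starts <- starts[-length(starts)]
      for (st in starts) {
        en <- if (st == starts[length(starts)]) nr else min(st + k - 1L, nr)
        pid <- pid + 1L
        patch[st:en, sel_cols] <- pid
        info[[pid]] <- data.frame(patch_id = pid, class0 = cl,
                                  n_cells = (en - st + 1L) * cells_per_row)
      }
    }
  }
  patches <- do.call(rbind, info)
  if (any(patches$n_cells > max_cells))
    stop_field("max_cells", "band strips produce patches larger than max_cells")
  stopifnot(!anyNA(patch))
  list(veg = cls, patch = patch, patches = patches)
}

#' Pseudo-observations at a virtual gauge
#'
#' Extracts the depth series at a gauge cell from a simulated depth stack and
#' adds Gaussian observation noise, for exercising skill metrics without real
#' gauge records.
#'
#' @param depth_stack array `[rows, cols, days]` of daily depths (m)
#' @param gauge `c(row, col)` of the virtual gauge; default: channel cell at
#'   mid-domain when `domain` is given
#' @param noise_sd observation noise standard deviation, metres
#' @param seed integer RNG seed
#' @param domain optional grid domain used to place the default gauge
#' @return data.frame with columns `day`, `truth_m`, `observed_m`
#' @export
make_pseudo_observations <- function(depth_stack, noise_sd = 0, seed = 1L,
                                     gauge = NULL, domain = NULL) {
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  d <- dim(depth_stack)
  stopifnot(length(d) == 3)
  if (is.null(gauge)) {
    if (is.null(domain)) stop_field("gauge", "supply `gauge` or `domain`")
    gauge <- c(as.integer(ceiling(domain$n_rows / 2)), domain$channel_col)
  }
  truth <- depth_stack[gauge[1], gauge[2], ]
  obs <- if (noise_sd > 0) {
    truth + with_seed(seed, rnorm(length(truth), 0, noise_sd))
  } else truth
  data.frame(day = seq_len(d[3]), truth_m = truth, observed_m = obs)
}
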