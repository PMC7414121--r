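#' Solver configuration for the storage-cell model
#'
#' @param dt_min,dt_max bounds on the numerical sub-step, seconds. The solver
#'   adapts the step to the CFL condition within these bounds; defaults are the
#'   1--5 s range appropriate for fine channel networks. On coarse (90 m)
#'   synthetic grids the CFL condition itself permits tens of seconds, so
#'   multi-year runs may raise `dt_max`.
#' @param cfl_limit Courant number limit (<= 1) on celerity `sqrt(g h)`
#' @param dry_depth wetting/drying cutoff, metres: cells shallower than this
#'   carry no outgoing flux
#' @param loss_mm_day daily open-water loss (evapotranspiration plus
#'   infiltration), mm/day, removed from wetted cells at the end of each day.
#'   Default 0 (pure routing); the coupled vegetation loop uses 4 mm/day, a
#'   typical dryland open-water loss rate
#' @return an object of class `solver_config`
#' @export
solver_config <- function(dt_min = 1, dt_max = 5, cfl_limit = 0.7,
                          dry_depth = 0.001, loss_mm_day = 0) {
  stopifnot(dt_min > 0, dt_min <= dt_max, cfl_limit > 0, cfl_limit <= 1,
            dry_depth >= 0, loss_mm_day >= 0)
  structure(list(dt_min = dt_min, dt_max = dt_max, cfl_limit = cfl_limit,
                 dry_depth = dry_depth, loss_mm_day = loss_mm_day),
            class = "solver_config")
}

#' Construct a grid domain from explicit components
#'
#' Lower-level companion to [make_dem()] for assembling arbitrary domains
#' (test basins, supplied DEMs). Row 1 is the upstream boundary; the last row
#' is the downstream boundary.
#'
#' @param bed bed-elevation matrix (m)
#' @param kind integer matrix, `0` floodplain / `1` channel (default: all
#'   floodplain)
#' @param cell_size cell edge length (m)
#' @param channel_width,bankfull_depth rectangular channel section shared by
#'   all channel cells (m)
#' @param inflow_cells two-column matrix (`row`, `col`) of upstream forcing
#'   cells; default: every cell of row 1
#' @return an object of class `grid_domain`
#' @export
grid_domain <- function(bed, kind = NULL, cell_size = 90,
                        channel_width = 20, bankfull_depth = 1,
                        inflow_cells = NULL) {
  stopifnot(is.matrix(bed), nrow(bed) >= 1, ncol(bed) >= 1)
  if (any(!is.finite(bed))) stop("bed elevations must be finite", call. = FALSE)
  if (cell_size <= 0) stop("`cell_size` must be > 0", call. = FALSE)
  if (is.null(kind)) kind <- matrix(0L, nrow(bed), ncol(bed))
  storage.mode(kind) <- "integer"
  stopifnot(all(dim(kind) == dim(bed)), all(kind %in% c(0L, 1L)))
  if (any(kind == 1L) && channel_width <= 0)
    stop("channel cells need `channel_width` > 0", call. = FALSE)
  if (is.null(inflow_cells))
    inflow_cells <- cbind(row = 1L, col = seq_len(ncol(bed)))
  structure(list(n_rows = nrow(bed), n_cols = ncol(bed),
                 cell_size = cell_size, bed = bed, kind = kind,
                 channel_width = channel_width,
                 bankfull_depth = bankfull_depth,
                 channel_col = NA_integer_, inflow_cells = inflow_cells),
            class = "grid_domain")
}

#' Manning link discharge
#'
#' Discharge across the link between two storage cells, from Manning's
#' formula `Q = A R^(2/3) / n * S^(1/2)` with the water-surface slope
#' `S = |z_k - z_i| / dx` and the sign of the head difference (positive into
#' cell `i` when `z_k > z_i`). Conveyance geometry uses the upwind depth above
#' the link sill (the higher of the two bed elevations) and wide-rectangular
#' geometry (`R = h`) unless an explicit rectangular section is given.
#'
#' @param z_k,z_i water-surface elevations of the donor-side and receiver-side
#'   cells (m)
#' @param bed_k,bed_i bed elevations (m)
#' @param n_link Manning roughness of the link (s m^-1/3)
#' @param cell_size centroid distance `x_k - x_i` (m)
#' @param width flow width (m); defaults to `cell_size` (floodplain link)
#' @param hydraulic_radius optional override of R (m); default upwind depth
#' @param dry_depth depths below this carry no flow
#' @return signed discharge in m3/s, positive into cell `i`
#' @export
link_discharge <- function(z_k, z_i, bed_k, bed_i, n_link, cell_size,
                           width = cell_size, hydraulic_radius = NULL,
                           dry_depth = 0.001) {
  if (n_link <= 0) stop("`n_link` must be > 0", call. = FALSE)
  dz <- z_k - z_i
  if (dz == 0) return(0)
  sill <- max(bed_k, bed_i)
  h <- max(z_k, z_i) - sill
  if (h < dry_depth) return(0)
  A <- width * h
  R <- if (is.null(hydraulic_radius)) h else hydraulic_radius
  sign(dz) * A * R^(2 / 3) / n_link * sqrt(abs(dz) / cell_size)
}

#' CFL-adaptive time step
#'
#' Largest sub-step (clamped to `[dt_min, dt_max]`) for which the Courant
#' number `sqrt(g h) dt / cell_size` stays below `cfl_limit` in every wet
#' cell.
#'
#' @param depth matrix (or vector) of current water depths, metres
#' @param cell_size cell edge length, metres
#' @param config a [solver_config()]
#' @return sub-step in seconds
#' @export
adaptive_dt <- function(depth, cell_size, config = solver_config()) {
  hmax <- max(depth, 0)
  if (hmax < config$dry_depth) return(config$dt_max)
  dt <- config$cfl_limit * cell_size / sqrt(9.80665 * hmax)
  min(max(dt, config$dt_min), config$dt_max)
}

check_roughness <- function(domain, roughness) {
  stopifnot(is.matrix(roughness),
            nrow(roughness) == domain$n_rows, ncol(roughness) == domain$n_cols)
  if (any(!is.finite(roughness)) || any(roughness <= 0))
    stop("roughness must be positive and finite everywhere", call. = FALSE)
  roughness
}

up_cells_idx0 <- function(domain) {
  ic <- domain$inflow_cells
  as.integer((ic[, "col"] - 1L) * domain$n_rows + (ic[, "row"] - 1L))
}

#' Advance the hydraulic state by a fixed interval
#'
#' Low-level single-interval driver used for solver verification (closed-basin
#' conservation, level-pool equilibrium). Boundary handling: `ds_mode`
#' `"closed"` (no flow anywhere), `"free"` (last row drains to bed) or
#' `"stage"` (last row held at `ds_value`); upstream forcing is a constant
#' discharge (m3/s) or stage (m) over the interval.
#'
#' @param domain a `grid_domain`
#' @param roughness Manning-n matrix
#' @param z water-surface elevation matrix (initial state)
#' @param seconds interval length
#' @param inflow upstream forcing value (discharge m3/s unless
#'   `up_mode = "stage"`)
#' @param up_mode `"discharge"` or `"stage"`
#' @param ds_mode `"closed"`, `"free"` or `"stage"`
#' @param ds_value downstream stage when `ds_mode = "stage"`
#' @param config a [solver_config()]
#' @return list with updated `z`, total `volume`, and cumulative
#'   `inflow_volume` / `outflow_volume` (m3)
#' @export
hydro_step <- function(domain, roughness, z, seconds, inflow = 0,
                       up_mode = c("discharge", "stage"),
                       ds_mode = c("closed", "free", "stage"), ds_value = 0,
                       config = solver_config()) {
  up_mode <- match.arg(up_mode)
  ds_mode <- match.arg(ds_mode)
  check_roughness(domain, roughness)
  cpp_advance(domain$bed, domain$kind, roughness, domain$cell_size,
              domain$channel_width, domain$bankfull_depth, z, seconds,
              match(up_mode, c("discharge", "stage")) - 1L, inflow,
              up_cells_idx0(domain),
              match(ds_mode, c("closed", "free", "stage")) - 1L, ds_value,
              config$dt_min, config$dt_max, config$cfl_limit,
              config$dry_depth)
}

#' Run the storage-cell model over a daily forcing series
#'
#' Routes a daily inflow series over the domain, recording a daily depth grid
#' and a daily mass balance. Internally the model sub-steps each day at the
#' CFL-adaptive step.
#'
#' @param domain a `grid_domain`
#' @param roughness Manning-n matrix
#' @param inflow daily upstream forcing: numeric vector or a data.frame with a
#'   `flow_m3s` column (discharge mode) or `stage_m` column (stage mode)
#' @param downstream `"free"` (drain to bed), `"closed"`, or a numeric vector
#'   of daily downstream stages applied along the whole last row
#' @param z0 optional initial water-surface elevation matrix (default: dry)
#' @param config a [solver_config()]
#' @param record_depth keep the daily depth stack (set `FALSE` to save memory)
#' @return list with `depth` (array rows x cols x days, m), `mass_balance`
#'   (data.frame: day, inflow_m3, outflow_m3, storage_m3, residual_m3) and
#'   `z_final`
#' @export
run_hydrodynamics <- function(domain, roughness, inflow, downstream = "free",
                              z0 = NULL, config = solver_config(),
                              record_depth = TRUE) {
  check_roughness(domain, roughness)
  up_mode <- 0L
  if (is.data.frame(inflow)) {
    if ("flow_m3s" %in% names(inflow)) {
      series <- inflow$flow_m3s
    } else if ("stage_m" %in% names(inflow)) {
      series <- inflow$stage_m; up_mode <- 1L
    } else stop("inflow data.frame needs a `flow_m3s` or `stage_m` column",
                call. = FALSE)
  } else series <- as.numeric(inflow)
  if (anyNA(series)) stop("inflow series contains missing values", call. = FALSE)
  nd <- length(series)
  if (is.numeric(downstream)) {
    stopifnot(length(downstream) == nd)
    ds_mode <- 2L; ds_series <- as.numeric(downstream)
  } else {
    ds_mode <- match(match.arg(downstream, c("closed", "free")),
                     c("closed", "free")) - 1L
    ds_series <- numeric(nd)
  }
  if (is.null(z0)) z0 <- domain$bed
  res <- cpp_run_daily(domain$bed, domain$kind, roughness, domain$cell_size,
                       domain$channel_width, domain$bankfull_depth, z0,
                       up_mode, series, up_cells_idx0(domain),
                       ds_mode, ds_series,
                       config$dt_min, config$dt_max, config$cfl_limit,
                       config$dry_depth, config$loss_mm_day / 1000,
                       record_depth)
  storage0 <- cell_volumes(domain, z0)
  mb <- data.frame(day = seq_len(nd),
                   inflow_m3 = res$inflow_volume,
                   outflow_m3 = res$outflow_volume,
                   loss_m3 = res$loss_volume,
                   storage_m3 = res$storage_volume)
  prev <- c(sum(storage0), mb$storage_m3[-nd])
  mb$residual_m3 <- mb$inflow_m3 - mb$outflow_m3 - mb$loss_m3 -
    (mb$storage_m3 - prev)
  out <- list(mass_balance = mb, z_final = res$z_final)
  if (record_depth) out$depth <- res$depth
  out
}

#' Per-cell stored water volume at a given stage
#'
#' @param domain a `grid_domain`
#' @param z water-surface elevation matrix
#' @return matrix of volumes (m3)
#' @export
cell_volumes <- function(domain, z) {
  h <- pmax(z - domain$bed, 0)
  v <- h * domain$cell_size^2
  ch <- domain$kind == 1L
  hc <- pmin(h[ch], domain$bankfull_depth)
  v[ch] <- hc * domain$channel_width * domain$cell_size +
    pmax(h[ch] - domain$bankfull_depth, 0) * domain$cell_size^2
  v
}
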