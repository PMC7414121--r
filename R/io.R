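#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, row 1 = north (top). Round-trips are lossless at the written
#' precision (`%.10g`).
#'
#' @param path file path
#' @param grid numeric or integer matrix (row 1 = north)
#' @param cell_size cell edge length, metres
#' @param xll,yll lower-left corner coordinates
#' @param nodata NODATA code
#' @return `read_ascii_grid()`: a list with `grid` (matrix, `NA` for nodata)
#'   and the header fields.
#' @export
write_ascii_grid <- function(grid, path, cell_size = 90, xll = 0, yll = 0,
                             nodata = -9999) {
  stopifnot(is.matrix(grid))
  g <- grid
  g[is.na(g)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(g)), sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cell_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(g, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 7) stop(sprintf("%s: truncated ASCII grid", path),
                              call. = FALSE)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys) || anyNA(vals))
    stop(sprintf("%s: malformed header (line %d)", path,
                 which(!(keys %in% need) | is.na(vals))[1]), call. = FALSE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- lines[-(1:6)]
  if (length(body) != nr)
    stop(sprintf("%s: expected %d data rows, found %d", path, nr,
                 length(body)), call. = FALSE)
  g <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]])
    if (length(row) != nc || anyNA(row))
      stop(sprintf("%s: malformed data row (line %d)", path, i + 6),
           call. = FALSE)
    g[i, ] <- row
  }
  g[g == vals[["nodata_value"]]] <- NA
  list(grid = g, cell_size = vals[["cellsize"]], xll = vals[["xllcorner"]],
       yll = vals[["yllcorner"]], nodata = vals[["nodata_value"]])
}

#' Read and write daily series CSV (`date,value`)
#'
#' Dates are ISO-8601. `read_series()` verifies the series is strictly daily
#' over the synthetic 365-day calendar (leap days absent) or the true
#' calendar, and reports any missing dates.
#'
#' @param series data.frame with `date` and one value column
#' @param path file path
#' @param calendar `"noleap"` (365-day years, Feb 29 absent) or `"true"`
#' @return `read_series()`: data.frame with columns `date` (Date) and `value`.
#' @export
write_series <- function(series, path) {
  stopifnot(is.data.frame(series), "date" %in% names(series))
  value_col <- setdiff(names(series), c("date", "water_year"))[1]
  out <- data.frame(date = as.character(series$date),
                    value = series[[value_col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, calendar = c("noleap", "true")) {
  calendar <- match.arg(calendar)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "value") %in% names(df)))
    stop(sprintf("%s: need columns date,value", path), call. = FALSE)
  d <- as.Date(df$date)
  if (anyNA(d)) stop(sprintf("%s: unparseable date on line %d", path,
                             which(is.na(d))[1] + 1L), call. = FALSE)
  full <- seq(d[1], d[length(d)], by = "day")
  if (calendar == "noleap") full <- full[format(full, "%m-%d") != "02-29"]
  gaps <- setdiff(as.character(full), as.character(d))
  if (length(gaps) > 0)
    stop(sprintf("%s: series has gaps at %s", path,
                 paste(utils::head(gaps, 5), collapse = ", ")), call. = FALSE)
  data.frame(date = d, value = as.numeric(df$value))
}

#' Read and write integer-code legends
#'
#' Sidecar legend mapping raster codes to class names, as `code,name` CSV.
#'
#' @param legend named integer vector (names are class names)
#' @param path file path
#' @return `read_legend()`: named integer vector.
#' @export
write_legend <- function(legend, path) {
  write.csv(data.frame(code = unname(legend), name = names(legend)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_legend
#' @export
read_legend <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(df)))
    stop(sprintf("%s: need columns code,name", path), call. = FALSE)
  if (anyDuplicated(df$code) || anyDuplicated(df$name))
    stop(sprintf("%s: duplicate legend codes or names", path), call. = FALSE)
  structure(as.integer(df$code), names = df$name)
}

#' Write and read a gridded depth stack as long-format CSV
#'
#' Text serialisation of a `[rows, cols, days]` array with columns
#' `day,row,col,value`; dry cells (value 0) are omitted to keep files small.
#'
#' @param stack numeric array `[rows, cols, days]`
#' @param path file path
#' @return `read_depth_stack()`: the array.
#' @export
write_depth_stack <- function(stack, path) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  idx <- which(stack != 0, arr.ind = TRUE)
  df <- data.frame(day = idx[, 3], row = idx[, 1], col = idx[, 2],
                   value = stack[idx])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims %d %d %d", d[1], d[2], d[3]), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_depth_stack
#' @export
read_depth_stack <- function(path) {
  first <- readLines(path, n = 1)
  dims <- as.integer(strsplit(sub("^# dims ", "", first), " ")[[1]])
  if (length(dims) != 3 || anyNA(dims))
    stop(sprintf("%s: missing dims header", path), call. = FALSE)
  df <- read.csv(path, skip = 1)
  arr <- array(0, dims)
  arr[cbind(df$row, df$col, df$day)] <- df$value
  arr
}
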