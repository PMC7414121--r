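# Small domains and forcing series shared across tests; all built in code.

flat_basin <- function(nr, nc, cell_size = 30) {
  grid_domain(matrix(0, nr, nc), cell_size = cell_size)
}

sloped_plane <- function(nr, nc, slope, cell_size = 90) {
  grid_domain(matrix(-slope * cell_size * (0:(nr - 1)), nr, nc),
              cell_size = cell_size)
}

uniform_n <- function(domain, n = 0.05) {
  matrix(n, domain$n_rows, domain$n_cols)
}

veg_n <- function(domain, n_fp = 0.06, n_ch = 0.035) {
  m <- matrix(n_fp, domain$n_rows, domain$n_cols)
  m[domain$kind == 1L] <- n_ch
  m
}

# depth series with an exact number of wet days >= `depth`
wet_days_series <- function(n_wet, depth = 0.05, n_days = 365L) {
  c(rep(depth, n_wet), rep(0, n_days - n_wet))
}

# one-patch state row
one_patch <- function(class_name, n_cells = 10L) {
  initial_patch_states(data.frame(patch_id = 1L,
                                  class0 = vegetation_classes()[[class_name]],
                                  n_cells = n_cells))
}
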