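# In-code fixtures: small deterministic landscapes used across the suite.

# Regular rows x cols lattice; occupancy/forested/rate recycled over cells.
make_grid_landscape <- function(rows, cols, spacing = 4927, r = 0.4,
                                occupancy = 0, forested = TRUE,
                                class_code = 4, market_price = NULL) {
  n <- rows * cols
  cells <- data.frame(
    cell_id = seq_len(n),
    x_m = (rep(seq_len(cols), each = rows) - 1) * spacing,
    y_m = (rep(seq_len(rows), times = cols) - 1) * spacing,
    forested = rep_len(forested, n),
    max_spread_rate = rep_len(r, n),
    productivity_class = rep_len(class_code, n),
    occupancy_pct = rep_len(occupancy, n)
  )
  if (!is.null(market_price)) cells$market_price <- market_price
  landscape(cells, spacing_m = spacing)
}

# Two cells a fixed distance apart, cell 1 optionally invaded and mature.
make_two_cell <- function(distance = 4927, occ1 = 50, r = 0.4,
                          colonized1 = -3L) {
  cells <- data.frame(
    cell_id = 1:2, x_m = c(0, distance), y_m = 0, forested = TRUE,
    max_spread_rate = r, productivity_class = 4,
    occupancy_pct = c(occ1, 0)
  )
  ls <- landscape(cells)
  ls$cells$colonized_year[1] <- colonized1
  build_neighbor_index(ls, cutoff_m = distance * 2)
}

# Deterministic discrete logistic map x_{t+1} = x + r x (1 - x/K).
logistic_map <- function(x0, r, steps, K = 100) {
  out <- numeric(steps + 1)
  out[1] <- x0
  for (t in seq_len(steps)) {
    out[t + 1] <- out[t] + r * out[t] * (1 - out[t] / K)
  }
  out
}

# Shared paper_like test landscape (built once per test run).
paper_like_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synth_preset("paper_like", rows = 45, cols = 44,
                           seed = 20090715)
      ls <- seed_initial_invasion(generate_landscape(spec), spec)
      cache <<- build_neighbor_index(ls, 30000)
    }
    cache
  }
})
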