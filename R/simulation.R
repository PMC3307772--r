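#' Deterministic seed derivation
#'
#' Folds a root seed with stream keys (replicate index, year, ...) through a
#' Lehmer-style recurrence so every source of randomness in a run flows from
#' one root seed, replicate streams are independent of execution order, and
#' derived seeds stay below 2^31.
#'
#' @param root integer root seed.
#' @param ... integer keys identifying the substream.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.double(root) %% m
  for (k in c(...)) {
    s <- (s * 16807 + as.double(k) %% m + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

#' Simulation run configuration
#'
#' @param years horizon in years (>= 1); default 20 (the assumed harvest
#'   cycle).
#' @param replicates Monte Carlo replicates (>= 1); default 240.
#' @param seed root seed; all replicate and per-year streams derive from it.
#' @param policy a \code{\link{control_policy}}; default NC.
#' @param kernel a \code{\link{kernel_params}}.
#' @param costs a \code{\link{cost_params}}.
#' @param x_colonize occupancy (percent) assigned at colonization.
#' @param cutoff_m dispersal cutoff radius (m) if the landscape's neighbor
#'   index must be built.
#' @param snapshot_years years at which per-cell occupancy snapshots are kept
#'   (default 5/10/15/20); NULL disables snapshots.
#' @param keep_ledger keep each replicate's per-cell \code{cost_ledger}
#'   (memory heavy; default FALSE keeps yearly totals only).
#' @return A \code{run_config} list.
#' @export
run_config <- function(years = 20, replicates = 240, seed = 1L,
                       policy = control_policy("NC"),
                       kernel = kernel_params(),
                       costs = cost_params(),
                       x_colonize = 0.1, cutoff_m = 30000,
                       snapshot_years = c(5, 10, 15, 20),
                       keep_ledger = FALSE) {
  stopifnot(years >= 1, replicates >= 1)
  structure(list(years = as.integer(years),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), policy = policy, kernel = kernel,
                 costs = costs, x_colonize = x_colonize, cutoff_m = cutoff_m,
                 snapshot_years = snapshot_years, keep_ledger = keep_ledger),
            class = "run_config")
}

#' Run a single stochastic replicate
#'
#' Year 0 is the supplied landscape state: damage is accrued on it and the
#' control rule applied (undiscounted). Each subsequent year runs
#' spread -> damage accrual (on the post-spread, pre-control occupancy) ->
#' control decision with search/control accrual. Deterministic given
#' \code{seed}.
#'
#' @param x a landscape (neighbor index built on demand).
#' @param config a \code{\link{run_config}}.
#' @param seed integer seed for this replicate (defaults to the config root).
#' @param W optional precomputed \code{\link{kernel_matrix}}.
#' @return A \code{trajectory}: data.frame(year, invaded_ha, damage, search,
#'   control, total, discount_factor, pv_total, cum_pv_total) with attributes
#'   \code{ledger} (if requested) and \code{snapshots} (named list of
#'   occupancy vectors).
#' @export
run_replicate <- function(x, config, seed = config$seed, W = NULL) {
  stopifnot(inherits(x, "tallow_landscape"), inherits(config, "run_config"))
  if (is.null(x$nbr)) x <- build_neighbor_index(x, config$cutoff_m)
  if (is.null(W)) W <- kernel_matrix(x, config$kernel)
  cl <- x$cells
  n <- nrow(cl)
  yrs <- 0:config$years
  ledger <- cost_ledger(n, yrs)
  invaded <- numeric(length(yrs))
  snaps <- list()

  state <- spread_state(x)
  for (ti in seq_along(yrs)) {
    yr <- yrs[ti]
    if (yr > 0) {
      set.seed(derive_seed(seed, 7L, yr))
      state <- step_year(state, x, config$kernel, W = W,
                         x_colonize = config$x_colonize)
    }
    ledger$damage[, ti] <- damage_cost(state$occupancy, cl$productivity_kg,
                                       cl$market_price, cl$area_ha)
    ac <- apply_control(state, x, config$policy, config$costs)
    state <- ac$state
    ledger$search[, ti] <- ac$search
    ledger$control[, ti] <- ac$control
    invaded[ti] <- invaded_area_ha(state$occupancy, cl$area_ha)
    if (!is.null(config$snapshot_years) && yr %in% config$snapshot_years) {
      snaps[[as.character(yr)]] <- state$occupancy
    }
  }
  out <- ledger_totals(ledger, config$costs$discount_rate)
  out <- cbind(data.frame(year = out$year, invaded_ha = invaded),
               out[, setdiff(names(out), "year")])
  class(out) <- c("tallow_trajectory", "data.frame")
  if (config$keep_ledger) attr(out, "ledger") <- ledger
  if (length(snaps)) attr(out, "snapshots") <- snaps
  out
}

#' Monte Carlo simulation over replicates
#'
#' Replicate seeds derive deterministically from the config root seed, so two
#' runs with the same root reproduce each other and threshold sweeps can use
#' common random numbers.
#'
#' @param x a landscape.
#' @param config a \code{\link{run_config}}.
#' @param W optional precomputed \code{\link{kernel_matrix}}.
#' @return list of class \code{tallow_mc}: \code{summary} (per-year mean and
#'   SE of invaded area and cumulative discounted cost), \code{totals}
#'   (per-component discounted totals: mean, se), \code{trajectories} (list of
#'   per-replicate trajectories), \code{config}.
#' @export
run_monte_carlo <- function(x, config, W = NULL) {
  stopifnot(inherits(x, "tallow_landscape"), inherits(config, "run_config"))
  if (is.null(x$nbr)) x <- build_neighbor_index(x, config$cutoff_m)
  if (is.null(W)) W <- kernel_matrix(x, config$kernel)
  trajs <- lapply(seq_len(config$replicates), function(r) {
    run_replicate(x, config, seed = derive_seed(config$seed, 11L, r), W = W)
  })
  rate <- config$costs$discount_rate
  inv <- sapply(trajs, `[[`, "invaded_ha")
  cum <- sapply(trajs, `[[`, "cum_pv_total")
  if (is.null(dim(inv))) { inv <- matrix(inv, nrow = 1); cum <- matrix(cum, nrow = 1) }
  nrep <- config$replicates
  rowse <- function(m) if (nrep > 1) apply(m, 1, stats::sd) / sqrt(nrep) else 0 * m[, 1]
  summ <- data.frame(
    year = trajs[[1]]$year,
    invaded_ha_mean = rowMeans(inv), invaded_ha_se = rowse(inv),
    cum_pv_total_mean = rowMeans(cum), cum_pv_total_se = rowse(cum)
  )
  comp_pv <- function(col) vapply(trajs, function(tr) {
    sum(tr[[col]] * tr$discount_factor)
  }, numeric(1))
  comp <- lapply(c(damage = "damage", search = "search", control = "control",
                   total = "total"), comp_pv)
  totals <- data.frame(
    component = names(comp),
    mean = vapply(comp, mean, numeric(1)),
    se = vapply(comp, function(v) {
      if (nrep > 1) stats::sd(v) / sqrt(nrep) else 0
    }, numeric(1)),
    row.names = NULL
  )
  structure(list(summary = summ, totals = totals, trajectories = trajs,
                 config = config),
            class = "tallow_mc")
}

#' @export
print.tallow_mc <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "tallow_mc: %d replicates x %d years, policy %s\n",
    x$config$replicates, x$config$years, x$config$policy$name))
  cat(sprintf("  final invaded area: %.0f +/- %.0f ha\n",
              last$invaded_ha_mean, last$invaded_ha_se))
  cat(sprintf("  expected total cost (rho = %.2f): $%.0f +/- %.0f\n",
              x$config$costs$discount_rate, last$cum_pv_total_mean,
              last$cum_pv_total_se))
  invisible(x)
}

#' Control-threshold sweep with common random numbers
#'
#' Runs one Monte Carlo experiment per threshold, re-using the same replicate
#' seeds across thresholds (common random numbers) so policy comparisons are
#' not confounded by sampling noise. The reported optimum breaks ties toward
#' the larger threshold (less intervention).
#'
#' @param x a landscape.
#' @param config a \code{\link{run_config}} (its policy is replaced per
#'   threshold).
#' @param thresholds numeric vector of percent thresholds (>= 2 values).
#' @return data.frame of class \code{tallow_sweep}: theta, total/damage/
#'   search/control discounted means, total_se, n_reps; attribute
#'   \code{argmin} = the cost-minimizing theta.
#' @export
threshold_sweep <- function(x, config, thresholds) {
  if (length(thresholds) < 2L) stop("need at least 2 thresholds")
  if (is.null(x$nbr)) x <- build_neighbor_index(x, config$cutoff_m)
  W <- kernel_matrix(x, config$kernel)
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$policy <- control_policy("custom", threshold = th)
    mc <- run_monte_carlo(x, cfg, W = W)
    tt <- mc$totals
    data.frame(theta = th,
               total = tt$mean[tt$component == "total"],
               total_se = tt$se[tt$component == "total"],
               damage = tt$mean[tt$component == "damage"],
               search = tt$mean[tt$component == "search"],
               control = tt$mean[tt$component == "control"],
               n_reps = cfg$replicates)
  })
  out <- do.call(rbind, rows)
  best <- out$theta[out$total <= min(out$total)]
  attr(out, "argmin") <- max(best)  # tie toward less intervention
  class(out) <- c("tallow_sweep", "data.frame")
  out
}
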