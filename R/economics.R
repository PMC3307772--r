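#' Fit the exponential control-cost curve to quoted brackets
#'
#' Per-hectare treatment cost is modeled as \eqn{a e^{b x}} in the percent
#' invaded x. The coefficients are not published; they are recovered by
#' log-linear least squares on the quoted bracket endpoints
#' (percent, $/ha) — by default the Superior Forestry brackets
#' (1, 111), (25, 210), (60, 457), (100, 1446).
#'
#' @param brackets data.frame with columns \code{percent} and
#'   \code{cost_per_ha}; at least 3 points.
#' @return list(a, b, log_rmse): the fitted coefficients and the in-sample
#'   RMSE on the log scale.
#' @export
fit_control_curve <- function(brackets = timber_tables()$control_brackets) {
  if (nrow(brackets) < 2L) stop("need at least 2 calibration points")
  fit <- stats::lm(log(cost_per_ha) ~ percent, data = brackets)
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  if (is.na(b)) b <- 0
  list(a = a, b = b,
       log_rmse = sqrt(mean(stats::residuals(fit)^2)))
}

#' Economic parameters
#'
#' All constants of the cost model: the discount rate, the harvest cycle
#' bounding the accounting horizon, the full-plot search anchor, and the
#' exponential control-cost coefficients (fit from the embedded brackets
#' unless supplied).
#'
#' @param discount_rate annual discount rate in (0, 1); default 0.05. The
#'   sensitivity set used in reporting is {0.01, 0.03, 0.05, 0.07, 0.09}.
#' @param harvest_cycle horizon T in years (>= 1); default 20.
#' @param search_max cost of sweeping a whole plot to find a trace invasion;
#'   default $48,000 (19.77 $/ha on a 2,428 ha cell).
#' @param search_kink occupancy (percent) below which the full sweep cost
#'   applies; default 1.
#' @param search_form how search cost decays above the kink:
#'   \code{"inverse"} (default, cost = search_max * kink / occupancy),
#'   \code{"linear"}, or \code{"exponential"} (both calibrated to match the
#'   inverse form's endpoints at the kink and at 100%).
#' @param search_floor lower bound on a search bill; default $0.
#' @param control_a,control_b override the fitted Eq.-5 coefficients.
#' @param brackets calibration points for \code{\link{fit_control_curve}}.
#' @return A \code{cost_params} list (includes fitted \code{control_a},
#'   \code{control_b}).
#' @export
cost_params <- function(discount_rate = 0.05, harvest_cycle = 20,
                        search_max = 48000, search_kink = 1,
                        search_form = c("inverse", "linear", "exponential"),
                        search_floor = 0,
                        control_a = NULL, control_b = NULL,
                        brackets = timber_tables()$control_brackets) {
  search_form <- match.arg(search_form)
  if (discount_rate <= 0 || discount_rate >= 1) {
    stop("discount_rate must be in (0, 1)")
  }
  if (harvest_cycle < 1) stop("harvest_cycle must be >= 1")
  if (is.null(control_a) || is.null(control_b)) {
    fit <- fit_control_curve(brackets)
    if (is.null(control_a)) control_a <- fit$a
    if (is.null(control_b)) control_b <- fit$b
  }
  if (control_a <= 0) stop("control_a must be > 0")
  if (control_b < 0) stop("control_b must be >= 0")
  structure(list(discount_rate = discount_rate,
                 harvest_cycle = as.integer(harvest_cycle),
                 search_max = search_max, search_kink = search_kink,
                 search_form = search_form, search_floor = search_floor,
                 control_a = control_a, control_b = control_b),
            class = "cost_params")
}

#' Annual timber damage cost of an invaded cell
#'
#' Lost production value: invaded hectares times annual productivity times
#' market price (stand replacement makes losses proportional to occupied
#' area).
#'
#' @param occupancy_pct percent of the cell occupied, in [0, 100].
#' @param productivity_kg annual productivity V (kg/ha/yr).
#' @param market_price timber price P ($/kg).
#' @param area_ha cell area (ha); default 2,428.
#' @return Damage in $/yr. Vectorized.
#' @export
damage_cost <- function(occupancy_pct, productivity_kg, market_price,
                        area_ha = 2428) {
  if (any(occupancy_pct < 0 | occupancy_pct > 100)) {
    stop("occupancy_pct must be in [0, 100]")
  }
  occupancy_pct / 100 * area_ha * productivity_kg * market_price
}

#' Search cost for delineating an invasion in one cell
#'
#' Finding a trace invasion requires sweeping the whole plot
#' (\code{search_max}); a larger invasion is easier to find, so the bill
#' decreases with occupancy above the kink. The default decay is inverse
#' proportional (continuous at the kink and strictly decreasing); linear and
#' exponential alternatives are selectable because the functional form is a
#' modeling choice, not an observed quantity.
#'
#' @param occupancy_pct percent occupied (> 0; uninvaded cells are never
#'   searched in-model).
#' @param params a \code{\link{cost_params}} object.
#' @return Search cost in $ per cell-search. Vectorized.
#' @export
search_cost <- function(occupancy_pct, params = cost_params()) {
  if (any(occupancy_pct <= 0)) stop("occupancy_pct must be > 0 for a search")
  smax <- params$search_max; kink <- params$search_kink
  s <- switch(params$search_form,
    inverse = ifelse(occupancy_pct <= kink, smax,
                     smax * kink / occupancy_pct),
    linear = ifelse(occupancy_pct <= kink, smax,
                    smax * (1 - (1 - kink / 100) *
                              (occupancy_pct - kink) / (100 - kink))),
    exponential = {
      lambda <- log(100 / kink) / (100 - kink)
      ifelse(occupancy_pct <= kink, smax,
             smax * exp(-lambda * (occupancy_pct - kink)))
    }
  )
  pmax(s, params$search_floor)
}

#' Control (treatment) cost for one cell
#'
#' Per-hectare unit cost \eqn{a e^{b x}} at percent occupancy x, charged on
#' the invaded hectares only (the bracket quotes are $/ha of treated land).
#'
#' @param occupancy_pct percent occupied (> 0).
#' @param params a \code{\link{cost_params}} (supplies a, b).
#' @param area_ha cell area in ha; default 2,428.
#' @return Treatment cost in $. Vectorized.
#' @export
control_cost <- function(occupancy_pct, params = cost_params(),
                         area_ha = 2428) {
  if (any(occupancy_pct <= 0)) stop("occupancy_pct must be > 0 for control")
  unit <- params$control_a * exp(params$control_b * occupancy_pct)
  unit * occupancy_pct / 100 * area_ha
}

#' Present value of a nominal cost stream
#'
#' \eqn{\sum_t c_t / (1+\rho)^t} with t = 0 at the start of the stream
#' (first-year costs undiscounted).
#'
#' @param nominal numeric vector of nominal costs, ordered by year.
#' @param rate discount rate in [0, 1).
#' @param t integer years of each entry; default \code{0, 1, ...}.
#' @return Present value in $.
#' @export
present_value <- function(nominal, rate, t = seq_along(nominal) - 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  sum(nominal / (1 + rate)^t)
}

#' Per-cell, per-year cost ledger
#'
#' Three n_cells x n_years matrices of nominal dollars (damage, search,
#' control) plus the year labels. Discounting is applied on read so a single
#' simulated ledger can be summarized under any rate.
#'
#' @param n_cells number of cells.
#' @param years integer vector of year labels (typically 0:T).
#' @return A \code{cost_ledger}.
#' @export
cost_ledger <- function(n_cells, years) {
  z <- matrix(0, n_cells, length(years))
  structure(list(damage = z, search = z, control = z,
                 years = as.integer(years)),
            class = "cost_ledger")
}

#' Yearly totals and present values from a ledger
#'
#' @param ledger a \code{\link{cost_ledger}}.
#' @param rate discount rate.
#' @return data.frame(year, damage, search, control, total,
#'   discount_factor, pv_total, cum_pv_total) — nominal component totals per
#'   year, the per-year discount factor, the discounted yearly total, and its
#'   running sum.
#' @export
ledger_totals <- function(ledger, rate) {
  yr <- ledger$years
  dmg <- colSums(ledger$damage)
  srch <- colSums(ledger$search)
  ctrl <- colSums(ledger$control)
  tot <- dmg + srch + ctrl
  df <- 1 / (1 + rate)^yr
  data.frame(year = yr, damage = dmg, search = srch, control = ctrl,
             total = tot, discount_factor = df, pv_total = tot * df,
             cum_pv_total = cumsum(tot * df))
}

#' Discounted expected total cost over replicate ledgers
#'
#' @param ledgers list of \code{\link{cost_ledger}} objects (one per
#'   replicate) or of yearly-total data.frames from
#'   \code{\link{ledger_totals}}.
#' @param rate discount rate.
#' @return list(mean, se, per_replicate): Monte Carlo mean and standard error
#'   of the discounted total cost, plus the per-replicate values.
#' @export
expected_total_cost <- function(ledgers, rate) {
  pv <- vapply(ledgers, function(l) {
    if (inherits(l, "cost_ledger")) l <- ledger_totals(l, rate)
    sum(l$total * 1 / (1 + rate)^l$year)
  }, numeric(1))
  list(mean = mean(pv),
       se = if (length(pv) > 1) stats::sd(pv) / sqrt(length(pv)) else 0,
       per_replicate = pv)
}

#' Export a ledger as tidy CSV
#'
#' One row per (cell, year): cell_id, year, damage, search, control,
#' discount_factor.
#'
#' @param ledger a \code{\link{cost_ledger}}.
#' @param cell_id cell ids (rows of the ledger matrices).
#' @param rate discount rate used for the discount_factor column.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ledger <- function(ledger, cell_id, rate, path) {
  yrs <- ledger$years
  out <- data.frame(
    cell_id = rep(cell_id, times = length(yrs)),
    year = rep(yrs, each = length(cell_id)),
    damage = as.vector(ledger$damage),
    search = as.vector(ledger$search),
    control = as.vector(ledger$control),
    discount_factor = rep(1 / (1 + rate)^yrs, each = length(cell_id))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
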