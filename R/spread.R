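#' Lognormal dispersal kernel parameters
#'
#' The propagule travel distance is radially lognormal: \eqn{\ln d \sim
#' N(\mu, \sigma^2)} with d in meters. \code{exp(mu)} is the median dispersal
#' distance; the default 1,200 m median matches the invasion velocity of
#' roughly 1,200 m/yr the full-scale model projects along the Gulf front.
#' \code{local_fraction} is the share of a mature source's annual recruitment
#' increment retained within the source cell (cells are ~5 km wide, so most
#' seed rain is local).
#'
#' @param mu log-distance location (log meters); default \code{log(1200)}.
#' @param sigma log-distance scale (> 0); default 1.
#' @param local_fraction retained share in [0, 1]; default 0.9.
#' @return A \code{kernel_params} list.
#' @export
kernel_params <- function(mu = log(1200), sigma = 1, local_fraction = 0.9) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (local_fraction < 0 || local_fraction > 1) {
    stop("local_fraction must be in [0, 1]")
  }
  structure(list(mu = mu, sigma = sigma, local_fraction = local_fraction),
            class = "kernel_params")
}

#' Kernel mass landing in a distant cell footprint
#'
#' Fraction of a source's dispersed recruitment that lands within a target
#' cell of side \code{cell_side_m} at center-to-center distance
#' \code{distance_m}: the radial lognormal density at d, spread uniformly over
#' the annulus of radius d, integrated over the cell footprint (point
#' approximation \eqn{f(d) / (2\pi d) \times A}). Masses over a global tiling
#' plus truncation loss sum to (at most) 1; it is also the probability that a
#' propagule volume of the two-dimensional dispersal distribution falls in
#' the cell, used for probabilistic colonization.
#'
#' @param distance_m center-to-center distance in meters (> 0; self-dispersal
#'   is handled by \code{local_fraction}, not the kernel).
#' @param cell_side_m side of the (square) target cell in meters.
#' @param params a \code{\link{kernel_params}} object.
#' @return Dimensionless mass in [0, 1]. Vectorized over \code{distance_m}.
#' @export
kernel_cell_mass <- function(distance_m, cell_side_m, params) {
  if (any(distance_m <= 0)) stop("distance_m must be > 0")
  dens <- stats::dlnorm(distance_m, meanlog = params$mu, sdlog = params$sigma)
  pmin(dens / (2 * pi * distance_m) * cell_side_m^2, 1)
}

#' Sparse dispersal operator for a landscape
#'
#' Precomputes the n-by-n sparse matrix W with \code{W[i, j]} = kernel mass
#' from source cell j landing in recipient cell i, over the pairs in the
#' landscape's neighbor index. Non-forested recipients absorb mass (their
#' rows are zeroed): the kernel is normalized over space, and mass landing on
#' non-forest is lost rather than redistributed.
#'
#' @param x a landscape with a built neighbor index.
#' @param params a \code{\link{kernel_params}} object.
#' @return A \code{Matrix::dgCMatrix}.
#' @export
kernel_matrix <- function(x, params) {
  stopifnot(inherits(x, "tallow_landscape"))
  if (is.null(x$nbr)) stop("neighbor index not built; call build_neighbor_index()")
  n <- nrow(x$cells)
  side <- sqrt(x$cells$area_ha * 1e4)  # recipient footprint
  keep <- x$cells$forested[x$nbr$i]
  i <- x$nbr$i[keep]; j <- x$nbr$j[keep]; d <- x$nbr$d[keep]
  m <- kernel_cell_mass(d, side[i], params)
  Matrix::sparseMatrix(i = i, j = j, x = m, dims = c(n, n))
}

#' Invasion state of a landscape
#'
#' @param x a \code{tallow_landscape} providing the initial occupancy and
#'   colonization years, or NULL to build from vectors.
#' @param year integer simulation year of this state (default 0).
#' @param occupancy,colonized_year used when \code{x} is NULL.
#' @return Object of class \code{spread_state}: list(year, occupancy,
#'   colonized_year).
#' @export
spread_state <- function(x = NULL, year = 0L, occupancy = NULL,
                         colonized_year = NULL) {
  if (!is.null(x)) {
    stopifnot(inherits(x, "tallow_landscape"))
    occupancy <- x$cells$occupancy_pct
    colonized_year <- x$cells$colonized_year
  }
  stopifnot(length(occupancy) == length(colonized_year))
  if (any(occupancy < 0 | occupancy > 100)) {
    stop("occupancy must be within [0, 100]")
  }
  structure(list(year = as.integer(year), occupancy = as.numeric(occupancy),
                 colonized_year = as.integer(colonized_year)),
            class = "spread_state")
}

#' Logistic within-cell growth increment
#'
#' Annual increment \eqn{r x (1 - x/K)} on the percent-occupancy scale.
#'
#' @param x current occupancy (percent), in [0, K].
#' @param r maximum spread rate (per year, >= 0).
#' @param K carrying capacity (percent), default 100.
#' @return The increment (percent); never negative for valid inputs.
#'   Vectorized.
#' @export
logistic_increment <- function(x, r, K = 100) {
  if (any(x < 0 | x > K)) stop("x must be within [0, K]")
  if (any(r < 0)) stop("r must be >= 0")
  r * x * (1 - x / K)
}

#' Advance the invasion one year
#'
#' Synchronous annual update from the year-t state to year t+1:
#' \enumerate{
#'   \item every invaded forested cell grows by its logistic increment;
#'   \item a mature source (colonized at least 3 years before the new year)
#'     retains \code{local_fraction} of its increment and exports the rest
#'     through the dispersal operator; immature or empty cells export
#'     nothing;
#'   \item already-invaded recipients receive incoming mass
#'     deterministically;
#'   \item each uninvaded forested recipient is colonized with probability
#'     \eqn{1 - \prod_j (1 - p_{ij})} over mature sources j, where
#'     \eqn{p_{ij}} is the kernel mass received from source j (its exported
#'     increment times the kernel cell mass — the volume of the 2-D dispersal
#'     distribution over the recipient footprint — clamped to [0, 1]); on
#'     colonization its occupancy is set to \code{x_colonize} and its
#'     colonization year to the new year;
#'   \item occupancies are clamped to [0, K]; non-forested cells stay 0.
#' }
#' Uses the current R RNG stream for the colonization draws; the caller (see
#' \code{\link{run_replicate}}) seeds a deterministic per-year substream so
#' results are reproducible and independent of cell order. The input state is
#' not modified.
#'
#' @param state a \code{\link{spread_state}}.
#' @param x a landscape (with a neighbor index if \code{W} is NULL).
#' @param params a \code{\link{kernel_params}}.
#' @param W optional precomputed \code{\link{kernel_matrix}} (reused across
#'   years/replicates for speed).
#' @param x_colonize occupancy (percent) assigned at colonization;
#'   default 0.1.
#' @param K carrying capacity (percent), default 100.
#' @return The year t+1 \code{spread_state}.
#' @export
step_year <- function(state, x, params, W = NULL, x_colonize = 0.1, K = 100) {
  stopifnot(inherits(state, "spread_state"), inherits(x, "tallow_landscape"))
  cl <- x$cells
  n <- nrow(cl)
  stopifnot(length(state$occupancy) == n)
  if (is.null(W)) W <- kernel_matrix(x, params)
  new_year <- state$year + 1L
  occ <- state$occupancy
  col_yr <- state$colonized_year

  inc <- numeric(n)
  live <- cl$forested & occ > 0
  inc[live] <- logistic_increment(occ[live], cl$max_spread_rate[live], K)

  # sources: invaded, forested, and old enough to produce seed in new_year
  mature <- live & !is.na(col_yr) & (new_year - col_yr >= 3L)

  retained <- ifelse(mature, params$local_fraction * inc, inc)
  export <- numeric(n)
  export[mature] <- (1 - params$local_fraction) * inc[mature]
  incoming <- as.numeric(W %*% export)

  occ_new <- occ
  occ_new[live] <- occ[live] + retained[live] + incoming[live]

  # probabilistic colonization of empty forested cells
  empty <- cl$forested & occ == 0
  col_new <- col_yr
  sources <- which(mature & export > 0)
  if (any(empty) && length(sources)) {
    Ws <- W[, sources, drop = FALSE]
    # scale each source column by its exported increment: p_ij is the mass
    # received, not the bare kernel volume
    Ws@x <- Ws@x * rep(export[sources], diff(Ws@p))
    Ws@x <- log1p(-pmin(Ws@x, 1))
    p <- 1 - exp(Matrix::rowSums(Ws))
    p <- pmin(pmax(p, 0), 1)
    u <- stats::runif(n)  # fixed-length draw: independent of invasion pattern
    hit <- empty & (u < p)
    occ_new[hit] <- x_colonize
    col_new[hit] <- new_year
  }
  occ_new <- pmin(pmax(occ_new, 0), K)
  occ_new[!cl$forested] <- 0
  spread_state(year = new_year, occupancy = occ_new,
               colonized_year = col_new)
}
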