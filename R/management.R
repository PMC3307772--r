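#' Threshold-based control policy
#'
#' A cell is treated in a given year when its occupancy strictly exceeds the
#' threshold theta ("control beginning as soon as the percentage invaded
#' exceeded" it): NC = no control; LC theta = 60; MC theta = 25; HC theta = 0
#' (immediate control of any positive occupancy).
#'
#' @param name one of "NC", "LC", "MC", "HC", or "custom".
#' @param threshold percent occupancy in [0, 100); ignored for the named
#'   policies, required for "custom". NULL means never control.
#' @return A \code{control_policy} list(name, threshold).
#' @export
control_policy <- function(name = c("NC", "LC", "MC", "HC", "custom"),
                           threshold = NULL) {
  name <- match.arg(name)
  theta <- switch(name, NC = NULL, LC = 60, MC = 25, HC = 0,
                  custom = threshold)
  if (name == "custom") {
    if (is.null(theta)) stop("custom policy requires a threshold")
    if (theta < 0 || theta >= 100) stop("threshold must be in [0, 100)")
  }
  structure(list(name = name, threshold = theta), class = "control_policy")
}

#' Apply one year's control decision
#'
#' Every forested cell whose occupancy strictly exceeds the policy threshold
#' is searched and treated: its search and control costs are charged on the
#' pre-treatment occupancy, its occupancy is reduced to zero, and its
#' maturation clock is reset (a controlled cell can be re-invaded later and
#' then waits out the full 3-year delay again). Detection and treatment are
#' assumed perfect. NC returns the state unchanged with zero costs.
#'
#' @param state a \code{\link{spread_state}}.
#' @param x the landscape (supplies per-cell areas).
#' @param policy a \code{\link{control_policy}}.
#' @param params a \code{\link{cost_params}}.
#' @return list(state, treated, search, control): the post-control state, the
#'   row indices treated, and per-cell nominal search/control cost vectors
#'   (zero except at treated cells).
#' @export
apply_control <- function(state, x, policy, params = cost_params()) {
  stopifnot(inherits(state, "spread_state"),
            inherits(x, "tallow_landscape"),
            inherits(policy, "control_policy"))
  n <- length(state$occupancy)
  search <- numeric(n); control <- numeric(n)
  if (is.null(policy$threshold)) {
    return(list(state = state, treated = integer(0),
                search = search, control = control))
  }
  hit <- which(state$occupancy > policy$threshold)
  if (length(hit)) {
    occ <- state$occupancy[hit]
    area <- x$cells$area_ha[hit]
    search[hit] <- search_cost(occ, params)
    control[hit] <- control_cost(occ, params, area_ha = area)
    state$occupancy[hit] <- 0
    state$colonized_year[hit] <- NA_integer_
  }
  list(state = state, treated = hit, search = search, control = control)
}
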