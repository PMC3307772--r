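#' Embedded timber productivity and price tables
#'
#' Constants used throughout the damage-cost calculations: the seven-class
#' timber productivity lookup (kg/ha/yr), the five-class harvest-share and
#' stumpage-price table used to form the weighted market price, the control
#' cost brackets quoted by Superior Forestry Service, and unit conversions.
#'
#' @return A list of class \code{timber_tables} with elements
#'   \code{productivity} (named numeric, class codes "1".."7"),
#'   \code{timber_classes} (data.frame: class, share_pct, stumpage_price),
#'   \code{control_brackets} (data.frame: percent, cost_per_ha),
#'   \code{kg_per_short_ton}, \code{m3_per_short_ton}, \code{ha_per_acre}.
#' @export
timber_tables <- function() {
  tt <- list(
    # annual timber productivity V_i (kg/ha/yr) by site productivity class
    productivity = c(
      "1" = 5536.98, "2" = 4102.30, "3" = 2981.45, "4" = 2152.03,
      "5" = 1412.27, "6" = 739.76, "7" = 201.75
    ),
    # harvest volume shares (%) and stumpage prices ($/kg) by timber class
    timber_classes = data.frame(
      class = c("pine_sawtimber", "pine_chip_n_saw", "pine_pulpwood",
                "mixed_hardwood_sawtimber", "mixed_hardwood_pulpwood"),
      share_pct = c(34.63, 18.02, 25.51, 9.58, 12.26),
      stumpage_price = c(0.0405, 0.0245, 0.0077, 0.0223, 0.0065),
      stringsAsFactors = FALSE
    ),
    # per-hectare control cost brackets ($/ha at % invaded), Superior Forestry
    control_brackets = data.frame(
      percent = c(1, 25, 60, 100),
      cost_per_ha = c(111, 210, 457, 1446)
    ),
    kg_per_short_ton = 907.18,
    m3_per_short_ton = 3.02,
    ha_per_acre = 0.40468564224
  )
  class(tt) <- "timber_tables"
  tt
}

#' Look up annual timber productivity by class code
#'
#' @param class_code integer vector of productivity class codes, each in 1..7.
#' @param tables a \code{\link{timber_tables}} object.
#' @return Numeric vector of productivity values (kg/ha/yr).
#' @export
productivity_lookup <- function(class_code, tables = timber_tables()) {
  if (length(class_code) == 0L) return(numeric(0))
  bad <- !(class_code %in% 1:7) | is.na(class_code)
  if (any(bad)) {
    stop("productivity_class must be an integer in 1..7; got: ",
         paste(unique(class_code[bad]), collapse = ", "))
  }
  unname(tables$productivity[as.character(class_code)])
}

#' Weighted market price of standing timber
#'
#' The single market price \eqn{P} ($/kg) applied to timber losses: the
#' harvest-share weighted average of the five timber-class stumpage prices.
#'
#' @param tables a \code{\link{timber_tables}} object.
#' @param digits decimals for the canonical rounded constant (default 4).
#' @return Weighted price in $/kg.
#' @export
weighted_market_price <- function(tables = timber_tables(), digits = 4) {
  tc <- tables$timber_classes
  s <- sum(tc$share_pct)
  if (abs(s - 100) > 0.01) {
    stop("harvest shares must sum to 100 (±0.01); got ", s)
  }
  round(sum(tc$share_pct / 100 * tc$stumpage_price), digits)
}

#' Search cost rate per hectare from a per-acre quote
#'
#' @param dollars_per_acre quoted rate in $/acre.
#' @param tables a \code{\link{timber_tables}} object (for the acre/ha factor).
#' @return Rate in $/ha.
#' @export
search_rate_per_ha <- function(dollars_per_acre, tables = timber_tables()) {
  dollars_per_acre / tables$ha_per_acre
}
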