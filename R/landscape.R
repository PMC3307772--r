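#' Area of a square lattice cell in hectares
#'
#' @param side_m side length of the square cell in meters.
#' @param nearest if TRUE, round to the nearest hectare (the canonical
#'   reporting convention for the 4,927 m FIA-grid cell).
#' @return Area in hectares.
#' @examples
#' cell_area_ha(4927)        # 2428
#' cell_area_ha(100)         # 1
#' @export
cell_area_ha <- function(side_m, nearest = TRUE) {
  if (any(!is.finite(side_m)) || any(side_m <= 0)) {
    stop("side_m must be positive and finite")
  }
  a <- side_m^2 / 1e4
  if (nearest) round(a) else a
}

.landscape_required_cols <- c("cell_id", "x_m", "y_m", "forested",
                              "max_spread_rate", "productivity_class",
                              "occupancy_pct")

#' Construct a landscape from a cell table
#'
#' A landscape is an ordered collection of square forestland cells on a
#' projected planar grid, each carrying habitat (maximum spread rate),
#' timber (productivity class, market price) and invasion state (percent
#' occupancy, colonization year).
#'
#' @param cells data.frame with columns \code{cell_id, x_m, y_m, forested,
#'   max_spread_rate, productivity_class, occupancy_pct} and optionally
#'   \code{market_price}, \code{area_ha}, \code{colonized_year}.
#' @param spacing_m lattice spacing in meters (default 4,927: the FIA grid).
#' @param tables a \code{\link{timber_tables}} object used to fill
#'   \code{productivity_kg} from the class code and to default
#'   \code{market_price} to the weighted average price.
#' @return Object of class \code{tallow_landscape}.
#' @export
landscape <- function(cells, spacing_m = 4927, tables = timber_tables()) {
  stopifnot(is.data.frame(cells))
  missing_cols <- setdiff(.landscape_required_cols, names(cells))
  if (length(missing_cols)) {
    stop("landscape table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  cells$cell_id <- as.integer(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) stop("cell_id values must be unique")
  cells$forested <- as.logical(cells$forested)
  cells$productivity_class <- as.integer(cells$productivity_class)
  for (cc in c("x_m", "y_m", "max_spread_rate", "occupancy_pct",
               "market_price", "area_ha")) {
    if (!is.null(cells[[cc]])) cells[[cc]] <- as.numeric(cells[[cc]])
  }
  cells$occupancy_pct[is.na(cells$occupancy_pct)] <- 0
  bad_occ <- cells$occupancy_pct < 0 | cells$occupancy_pct > 100
  if (any(bad_occ)) {
    stop("occupancy_pct outside [0, 100] for cell_id: ",
         paste(cells$cell_id[bad_occ], collapse = ", "))
  }
  if (any(cells$max_spread_rate < 0)) {
    stop("max_spread_rate must be >= 0")
  }
  if (any(!cells$forested & cells$occupancy_pct > 0)) {
    stop("non-forested cells must have occupancy_pct = 0; offending cell_id: ",
         paste(cells$cell_id[!cells$forested & cells$occupancy_pct > 0],
               collapse = ", "))
  }
  cells$productivity_kg <- productivity_lookup(cells$productivity_class,
                                               tables)
  if (is.null(cells$market_price)) {
    cells$market_price <- weighted_market_price(tables)
  }
  if (is.null(cells$area_ha)) {
    cells$area_ha <- cell_area_ha(spacing_m)
  }
  if (any(cells$area_ha <= 0)) stop("area_ha must be positive")
  if (is.null(cells$colonized_year)) {
    cells$colonized_year <- NA_integer_
  }
  # invaded cells with no recorded colonization year are assumed mature
  # (the observed initial population reproduces immediately)
  idx <- cells$occupancy_pct > 0 & is.na(cells$colonized_year)
  cells$colonized_year[idx] <- -3L
  cells$colonized_year <- as.integer(cells$colonized_year)
  structure(
    list(cells = cells, spacing_m = spacing_m, nbr = NULL, cutoff_m = NULL),
    class = "tallow_landscape"
  )
}

#' @export
print.tallow_landscape <- function(x, ...) {
  n <- nrow(x$cells)
  inv <- sum(x$cells$occupancy_pct > 0)
  cat(sprintf(
    "tallow_landscape: %d cells (%.0f m spacing), %d forested, %d invaded\n",
    n, x$spacing_m, sum(x$cells$forested), inv))
  cat(sprintf("  invaded area: %.1f ha (%.3f%% of total)\n",
              invaded_area_ha(x),
              100 * invaded_area_ha(x) / sum(x$cells$area_ha)))
  if (!is.null(x$nbr)) {
    cat(sprintf("  neighbor index: cutoff %.0f m, %d directed pairs\n",
                x$cutoff_m, length(x$nbr$i)))
  }
  invisible(x)
}

#' Total invaded area of a landscape or occupancy vector
#'
#' @param x a \code{tallow_landscape}, or a numeric occupancy vector (percent)
#'   if \code{area_ha} is supplied.
#' @param area_ha per-cell areas (ha), required when \code{x} is numeric.
#' @return Invaded hectares.
#' @export
invaded_area_ha <- function(x, area_ha = NULL) {
  if (inherits(x, "tallow_landscape")) {
    sum(x$cells$occupancy_pct / 100 * x$cells$area_ha)
  } else {
    sum(x / 100 * area_ha)
  }
}

#' Read a landscape from CSV or GeoJSON
#'
#' CSV is the canonical format (exact column names
#' \code{cell_id, x_m, y_m, forested, max_spread_rate, productivity_class,
#' occupancy_pct}, optional \code{market_price, area_ha, colonized_year}).
#' GeoJSON input is a FeatureCollection whose feature properties mirror the
#' CSV columns.
#'
#' @param path file path; format detected from the extension
#'   (\code{.geojson}/\code{.json} vs anything else = CSV).
#' @param spacing_m lattice spacing in meters.
#' @param tables a \code{\link{timber_tables}} object.
#' @return A \code{tallow_landscape}.
#' @export
load_landscape <- function(path, spacing_m = 4927, tables = timber_tables()) {
  if (!file.exists(path)) stop("landscape file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("GeoJSON file has no features: ", path)
    rows <- lapply(gj$features, function(f) as.data.frame(f$properties))
    cells <- do.call(rbind, rows)
  } else {
    cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  landscape(cells, spacing_m = spacing_m, tables = tables)
}

#' Write a landscape to CSV
#'
#' Writes all cell columns so that \code{load_landscape(write_landscape(x))}
#' round-trips exactly (productivity_kg is recomputed from the class code on
#' load and therefore not written).
#'
#' @param x a \code{tallow_landscape}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "tallow_landscape"))
  cols <- c(.landscape_required_cols, "market_price", "area_ha",
            "colonized_year")
  out <- x$cells[, cols]
  # %.17g round-trips doubles exactly through the text format
  for (cc in names(out)) {
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a landscape as GeoJSON square polygons
#'
#' Derived output: each cell becomes a square Polygon centered on
#' (\code{x_m}, \code{y_m}) with side \code{spacing_m}; properties mirror the
#' CSV columns. Coordinates stay in the projected meter system.
#'
#' @param x a \code{tallow_landscape}.
#' @param path output path; if NULL the GeoJSON list is returned instead.
#' @param occupancy optional occupancy vector overriding the stored one
#'   (used for per-year snapshot maps).
#' @return \code{path} invisibly, or the GeoJSON structure if path is NULL.
#' @export
write_landscape_geojson <- function(x, path = NULL, occupancy = NULL) {
  stopifnot(inherits(x, "tallow_landscape"))
  cl <- x$cells
  if (!is.null(occupancy)) cl$occupancy_pct <- occupancy
  h <- x$spacing_m / 2
  feats <- lapply(seq_len(nrow(cl)), function(i) {
    cx <- cl$x_m[i]; cy <- cl$y_m[i]
    ring <- list(c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h),
                 c(cx - h, cy + h), c(cx - h, cy - h))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = as.list(cl[i, c(.landscape_required_cols, "market_price",
                                   "area_ha")])
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  if (is.null(path)) return(gj)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the within-cutoff neighbor index
#'
#' Computes, for every cell, the set of other cells whose centers lie within
#' \code{cutoff_m} (Euclidean, projected meters), with center-to-center
#' distances, sorted by distance. The index feeds the dispersal operator;
#' beyond ~30 km the lognormal kernel mass per cell is negligible at default
#' parameters.
#'
#' @param x a \code{tallow_landscape}.
#' @param cutoff_m cutoff radius in meters (> 0), default 30,000.
#' @param block block size for the pairwise-distance computation (memory
#'   control on large landscapes).
#' @return The landscape with its neighbor index populated.
#' @export
build_neighbor_index <- function(x, cutoff_m = 30000, block = 512L) {
  stopifnot(inherits(x, "tallow_landscape"))
  if (!is.finite(cutoff_m) || cutoff_m <= 0) stop("cutoff_m must be > 0")
  xs <- x$cells$x_m; ys <- x$cells$y_m
  n <- length(xs)
  ii <- list(); jj <- list(); dd <- list(); k <- 0L
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    dx <- outer(xs[start:end], xs, "-")
    dy <- outer(ys[start:end], ys, "-")
    d <- sqrt(dx * dx + dy * dy)
    hit <- which(d <= cutoff_m & d > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      k <- k + 1L
      ii[[k]] <- hit[, 1L] + (start - 1L)
      jj[[k]] <- hit[, 2L]
      dd[[k]] <- d[hit]
    }
  }
  i <- unlist(ii); j <- unlist(jj); d <- unlist(dd)
  if (is.null(i)) { i <- integer(0); j <- integer(0); d <- numeric(0) }
  ord <- order(i, d, j)
  x$nbr <- list(i = i[ord], j = j[ord], d = d[ord])
  x$cutoff_m <- cutoff_m
  x
}

#' Neighbors of one cell
#'
#' @param x a landscape with a built neighbor index.
#' @param cell_id the focal cell id.
#' @return data.frame(cell_id, distance_m), sorted by distance.
#' @export
neighbors <- function(x, cell_id) {
  stopifnot(inherits(x, "tallow_landscape"))
  if (is.null(x$nbr)) stop("neighbor index not built; call build_neighbor_index()")
  row <- match(cell_id, x$cells$cell_id)
  if (is.na(row)) stop("unknown cell_id: ", cell_id)
  sel <- x$nbr$i == row
  data.frame(cell_id = x$cells$cell_id[x$nbr$j[sel]],
             distance_m = x$nbr$d[sel])
}
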