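# Landscape data model and CSV readers/writers.
#
# Coordinate convention (used everywhere in the package and stated in every
# file header): 0-based, x = column, y = row, origin top-left. Cells are
# ordered row-major by (y, x); cell_index() maps coordinates to that order.

#' Map 0-based cell coordinates to the canonical cell index
#'
#' Cells are stored row-major in (y, x) order, so ascending index equals
#' ascending (y, x) lexicographic order; the deterministic tie-break of
#' [evaluate_rule()] relies on this.
#'
#' @param x,y 0-based column / row coordinates.
#' @param width Grid width in cells.
#' @return 1-based integer index into the cell table.
#' @export
cell_index <- function(x, y, width) as.integer(y) * as.integer(width) + as.integer(x) + 1L

#' @rdname cell_index
#' @param i 1-based cell index.
#' @export
cell_x <- function(i, width) (as.integer(i) - 1L) %% as.integer(width)

#' @rdname cell_index
#' @export
cell_y <- function(i, width) (as.integer(i) - 1L) %/% as.integer(width)

#' Construct a landscape object
#'
#' Bundles the gridded environment (zones, soil quality, water-body mask), the
#' per-zone per-year baseline yield table (kg maize per cell per year, the
#' precomputed product of drought conditions), water-source records with
#' active year ranges, and the annual target household-count series that the
#' simulator is calibrated against.
#'
#' @param cells `data.frame(x, y, zone, quality, water_body)`; one row per
#'   grid cell, `quality` in `[0, 1]`, `water_body` logical or 0/1.
#' @param yields `data.frame(zone, year, baseline_yield)` covering every zone
#'   for every year of the span; yields are non-negative.
#' @param water `data.frame(x, y, start_year, end_year)` of water sources
#'   (inclusive activity range). May have zero rows.
#' @param target `data.frame(year, households)` covering every year of the
#'   span.
#' @param start_year,end_year Inclusive simulation span (calendar years).
#' @return An object of class `emd_landscape`.
#' @export
landscape <- function(cells, yields, water, target, start_year, end_year) {
  cells$water_body <- as.logical(cells$water_body)
  cells <- cells[order(cells$y, cells$x), , drop = FALSE]
  rownames(cells) <- NULL
  yields <- yields[order(yields$zone, yields$year), , drop = FALSE]
  rownames(yields) <- NULL
  target <- target[order(target$year), , drop = FALSE]
  rownames(target) <- NULL
  l <- structure(list(
    width = max(cells$x) + 1L, height = max(cells$y) + 1L,
    start_year = as.integer(start_year), end_year = as.integer(end_year),
    cells = cells, yields = yields, water = water, target = target
  ), class = "emd_landscape")
  validate_landscape(l)
  l
}

validate_landscape <- function(l) {
  n <- l$width * l$height
  cl <- l$cells
  if (nrow(cl) != n) stop("cells: expected ", n, " rows for a ", l$width, "x", l$height, " grid, got ", nrow(cl))
  idx <- cell_index(cl$x, cl$y, l$width)
  if (anyDuplicated(idx)) stop("cells: duplicated (x, y) coordinate at row ", anyDuplicated(idx))
  if (any(cl$quality < 0 | cl$quality > 1)) {
    stop("cells: quality outside [0, 1] at row ", which(cl$quality < 0 | cl$quality > 1)[1])
  }
  years <- l$start_year:l$end_year
  zones <- sort(unique(cl$zone))
  key <- paste(l$yields$zone, l$yields$year)
  need <- as.vector(outer(zones, years, paste))
  miss <- setdiff(need, key)
  if (length(miss) > 0) stop("yields: missing (zone, year) entries within the span, first: (", miss[1], ")")
  if (any(l$yields$baseline_yield < 0)) stop("yields: negative baseline_yield at row ", which(l$yields$baseline_yield < 0)[1])
  if (nrow(l$water) > 0) {
    w <- l$water
    if (any(w$start_year > w$end_year)) stop("water: start_year > end_year at row ", which(w$start_year > w$end_year)[1])
    bad <- w$x < 0 | w$x >= l$width | w$y < 0 | w$y >= l$height
    if (any(bad)) stop("water: coordinates outside the grid at row ", which(bad)[1])
  }
  tmiss <- setdiff(years, l$target$year)
  if (length(tmiss) > 0) stop("target: missing year ", tmiss[1], " within the span")
  invisible(l)
}

#' @export
print.emd_landscape <- function(x, ...) {
  cat("<emd_landscape> ", x$width, "x", x$height, " cells, ",
      length(unique(x$cells$zone)), " zones, span ", x$start_year, "-", x$end_year,
      ", ", nrow(x$water), " water sources\n", sep = "")
  invisible(x)
}

# Internal fast-access view: atomic vectors in canonical cell order plus the
# yield matrix (zones x years). Built once per simulation.
landscape_arrays <- function(l) {
  cl <- l$cells
  years <- l$start_year:l$end_year
  zones <- sort(unique(cl$zone))
  ym <- matrix(NA_real_, nrow = length(zones), ncol = length(years),
               dimnames = list(zones, years))
  ym[cbind(match(l$yields$zone, zones), match(l$yields$year, years))] <- l$yields$baseline_yield
  list(
    width = l$width, height = l$height, n = l$width * l$height,
    xs = cl$x, ys = cl$y,
    zone_id = cl$zone, zone = match(cl$zone, zones),
    quality = cl$quality, water_body = cl$water_body,
    yield_mat = ym, years = years, zones = zones,
    water = l$water,
    target = l$target$households[match(years, l$target$year)]
  )
}

#' Cells available for farming
#'
#' A cell is available when it carries no farm, no dwelling, and is not part
#' of a water body. The result is the exact set satisfying those three
#' conditions; it may be empty.
#'
#' @param landscape An [landscape()] object.
#' @param occupancy List with logical vector `farms` and integer vector
#'   `dwellings` (counts), both of length `width * height` in canonical cell
#'   order.
#' @param year Calendar year (reserved; availability is currently
#'   year-independent).
#' @return Ascending integer vector of available cell indices.
#' @export
available_plots <- function(landscape, occupancy, year = NULL) {
  wb <- landscape$cells$water_body
  which(!occupancy$farms & occupancy$dwellings == 0L & !wb)
}

landscape_files <- c(cells = "cells.csv", yields = "yields.csv",
                     water = "water.csv", target = "target.csv")

coord_header <- "# coordinates: 0-based, x=column, y=row, origin top-left"

read_env_csv <- function(path, columns) {
  if (!file.exists(path)) stop("missing environment file: ", path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(columns, names(d))
  if (length(miss) > 0) stop(basename(path), ": missing column '", miss[1], "'")
  d[, columns, drop = FALSE]
}

#' Read a landscape from its environment file set
#'
#' Expects `cells.csv` (`x,y,zone,quality,water_body`), `yields.csv`
#' (`zone,year,baseline_yield`), `water.csv` (`x,y,start_year,end_year`) and
#' `target.csv` (`year,households`) in `dir`; UTF-8, comma-separated, header
#' row mandatory, `#` comment lines ignored. The simulation span is the year
#' range of `target.csv`. All landscape invariants are checked and violations
#' reported with the offending file and row.
#'
#' @param dir Directory containing the four files.
#' @return An [landscape()] object.
#' @export
read_landscape <- function(dir) {
  cells <- read_env_csv(file.path(dir, "cells.csv"), c("x", "y", "zone", "quality", "water_body"))
  yields <- read_env_csv(file.path(dir, "yields.csv"), c("zone", "year", "baseline_yield"))
  water <- read_env_csv(file.path(dir, "water.csv"), c("x", "y", "start_year", "end_year"))
  target <- read_env_csv(file.path(dir, "target.csv"), c("year", "households"))
  span <- range(target$year)
  gaps <- setdiff(span[1]:span[2], target$year)
  if (length(gaps) > 0) stop("target.csv: missing year ", gaps[1], " inside the target span")
  landscape(cells, yields, water, target, span[1], span[2])
}

# Canonical numeric formatting: up to 15 significant digits, no scientific
# notation. Valid files are defined to carry literals of <= 15 significant
# digits, so read/write round-trips byte-for-byte.
fmt_num <- function(x) {
  if (is.logical(x)) return(as.character(as.integer(x)))
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

write_env_csv <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(coord_header, paste(names(d), collapse = ",")), con)
  if (nrow(d) > 0) {
    cols <- lapply(d, fmt_num)
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
}

#' Write a landscape as its environment file set
#'
#' Inverse of [read_landscape()]: writes the four documented CSV files in
#' canonical formatting, so `write_landscape(read_landscape(dir))` reproduces
#' valid input files byte-for-byte.
#'
#' @param landscape An [landscape()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_env_csv(landscape$cells, file.path(dir, "cells.csv"))
  write_env_csv(landscape$yields, file.path(dir, "yields.csv"))
  write_env_csv(landscape$water, file.path(dir, "water.csv"))
  write_env_csv(landscape$target, file.path(dir, "target.csv"))
  invisible(dir)
}
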