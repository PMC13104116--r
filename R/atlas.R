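#' Tile a cortical sheet into rectangular regions
#'
#' Builds a parcellation of a rectangular cortical sheet into `K` contiguous
#' rectangular regions, standing in for an atlas alignment of the imaging
#' field of view. Regions tile the sheet exactly: every in-sheet position
#' maps to one and only one region.
#'
#' The sheet is cut into `floor(sqrt(K))` horizontal bands and each band is
#' split into equal-width columns, with the K regions distributed across
#' bands as evenly as possible. Region ids are `0 ... K-1`, named
#' `"R01" ... "RK"` by default.
#'
#' @param K Number of regions (>= 2). Default 19, the number of cortical
#'   regions that persist across recording days in a mesoscale field of view.
#' @param width,height Sheet extent in micrometres.
#' @param names Optional character vector of `K` region names.
#' @param seed Unused for the deterministic rectangular tiling; accepted so
#'   all generators share a calling convention.
#' @return An object of class `region_map`: a list with `width`, `height`,
#'   `n_regions`, and `rects`, a data frame with one row per region
#'   (`id`, `name`, `x0`, `x1`, `y0`, `y1`).
#' @examples
#' atlas <- make_atlas(K = 19, width = 4000, height = 3000)
#' region_lookup(atlas, x = c(10, 3990), y = c(10, 2990))
#' @export
make_atlas <- function(K = 19L, width = 4000, height = 3000, names = NULL,
                       seed = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L)
    stop("K must be an integer >= 2")
  if (width <= 0 || height <= 0)
    stop("sheet dimensions must be positive")
  n_rows <- max(1L, floor(sqrt(K)))
  # regions must be at least 1 micrometre wide/tall to be usable
  max_cols <- floor(width)
  if (floor(height) < n_rows || ceiling(K / n_rows) > max_cols)
    stop(sprintf(
      "K = %d regions cannot tile a %g x %g um sheet with regions >= 1 um",
      K, width, height))
  per_row <- rep(K %/% n_rows, n_rows)
  extra <- K %% n_rows
  if (extra > 0) per_row[seq_len(extra)] <- per_row[seq_len(extra)] + 1L
  row_edges <- seq(0, height, length.out = n_rows + 1L)
  rects <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
    col_edges <- seq(0, width, length.out = per_row[r] + 1L)
    data.frame(
      x0 = col_edges[-length(col_edges)], x1 = col_edges[-1L],
      y0 = row_edges[r], y1 = row_edges[r + 1L])
  }))
  rects$id <- seq_len(K) - 1L
  if (is.null(names)) names <- sprintf("R%02d", seq_len(K))
  if (length(names) != K) stop("names must have length K")
  rects$name <- names
  rects <- rects[, c("id", "name", "x0", "x1", "y0", "y1")]
  structure(
    list(width = width, height = height, n_regions = K, rects = rects),
    class = "region_map")
}

#' Map positions to region ids
#'
#' @param map A `region_map` from [make_atlas()].
#' @param x,y Numeric vectors of positions (micrometres), recycled to a
#'   common length.
#' @return Integer vector of 0-based region ids; `NA` for positions outside
#'   the sheet (background).
#' @export
region_lookup <- function(map, x, y) {
  stopifnot(inherits(map, "region_map"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- rep(NA_integer_, n)
  r <- map$rects
  for (i in seq_len(nrow(r))) {
    # half-open cells, closed on the far sheet edge, so the tiling is exact
    in_x <- x >= r$x0[i] & (x < r$x1[i] | (r$x1[i] == map$width & x <= r$x1[i]))
    in_y <- y >= r$y0[i] & (y < r$y1[i] | (r$y1[i] == map$height & y <= r$y1[i]))
    hit <- in_x & in_y & is.na(out)
    out[hit] <- r$id[i]
  }
  out
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d regions on a %g x %g um sheet\n",
              x$n_regions, x$width, x$height))
  invisible(x)
}

#' Region areas in square micrometres
#' @param map A `region_map`.
#' @return Named numeric vector of areas, one per region.
#' @export
region_areas <- function(map) {
  stopifnot(inherits(map, "region_map"))
  a <- (map$rects$x1 - map$rects$x0) * (map$rects$y1 - map$rects$y0)
  stats::setNames(a, map$rects$name)
}
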