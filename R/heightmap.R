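#' Gridded surface height map
#'
#' The basic container of the package: a rectangular grid of surface heights
#' in micrometres, with lateral sample spacings `dx`, `dy` (micrometres), a
#' grid origin, and free-form provenance metadata. Non-measured points
#' (voids) are stored as `NA`.
#'
#' The grid convention is row-major: `heights[i, j]` is the sample at
#' `x = x0 + (j - 1) * dx`, `y = y0 + (i - 1) * dy`, so y increases with the
#' row index and x with the column index. All coordinates and heights are in
#' micrometres.
#'
#' @param heights numeric matrix (ny rows by nx columns) of heights, um.
#'   `NA`/`NaN` entries mark voids (non-measured points).
#' @param dx,dy lateral sample spacing, um; must be positive.
#' @param x0,y0 coordinates of the `heights[1, 1]` sample, um.
#' @param meta named list of free-form provenance (instrument, specimen ID,
#'   tooth ID, sample position, generator settings, ...).
#'
#' @return An object of class `height_map`.
#' @examples
#' hm <- height_map(matrix(rnorm(64), 8, 8), dx = 0.44, dy = 0.44)
#' dim(hm$heights)
#' @export
height_map <- function(heights, dx, dy, x0 = 0, y0 = 0, meta = list()) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("`heights` must be a numeric matrix", call. = FALSE)
  heights[is.nan(heights)] <- NA_real_
  if (nrow(heights) < 2L || ncol(heights) < 2L)
    stop("height map must be at least 2 x 2", call. = FALSE)
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop("`dx` must be a single positive number", call. = FALSE)
  if (!is.numeric(dy) || length(dy) != 1L || !is.finite(dy) || dy <= 0)
    stop("`dy` must be a single positive number", call. = FALSE)
  if (all(is.na(heights)))
    stop("height map has no measured points", call. = FALSE)
  if (any(is.infinite(heights)))
    stop("heights must be finite", call. = FALSE)
  structure(
    list(heights = unname(heights), dx = as.numeric(dx), dy = as.numeric(dy),
         x0 = as.numeric(x0), y0 = as.numeric(y0), meta = meta),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  nv <- sum(is.na(x$heights))
  cat(sprintf(
    "<height_map> %d x %d samples, dx = %g um, dy = %g um (%.1f x %.1f um)\n",
    ncol(x$heights), nrow(x$heights), x$dx, x$dy,
    ncol(x$heights) * x$dx, nrow(x$heights) * x$dy))
  z <- x$heights[!is.na(x$heights)]
  cat(sprintf("  heights: [%.4g, %.4g] um, %d void(s)\n", min(z), max(z), nv))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname height_map
#' @param x object to test.
#' @export
is_height_map <- function(x) inherits(x, "height_map")

#' Number of void (non-measured) samples in a height map
#' @param map a [height_map()].
#' @return integer count of `NA` samples.
#' @export
n_voids <- function(map) sum(is.na(map$heights))

# x/y coordinate vectors of the grid (um)
grid_x <- function(map) map$x0 + (seq_len(ncol(map$heights)) - 1) * map$dx
grid_y <- function(map) map$y0 + (seq_len(nrow(map$heights)) - 1) * map$dy

#' Scale-limited roughness surface
#'
#' A [height_map()] that has passed through the preprocessing chain: voids
#' restored, form removed and band-limited by the areal filter, with mean
#' exactly zero. Carries an ordered `provenance` list recording each applied
#' step and its settings.
#'
#' @param map a void-free [height_map()]; its mean is subtracted.
#' @param provenance ordered list of applied steps (named lists with a
#'   `step` element and settings).
#' @return An object of classes `roughness_surface`, `height_map`.
#' @export
roughness_surface <- function(map, provenance = list()) {
  stopifnot(is_height_map(map))
  if (n_voids(map) > 0L)
    stop("roughness surface may not contain voids; run restore_voids() first",
         call. = FALSE)
  map$heights <- map$heights - mean(map$heights)
  map$provenance <- provenance
  class(map) <- c("roughness_surface", "height_map")
  map
}

#' @export
print.roughness_surface <- function(x, ...) {
  NextMethod()
  steps <- vapply(x$provenance, function(s) s$step, character(1))
  if (length(steps)) cat("  provenance:", paste(steps, collapse = " -> "), "\n")
  invisible(x)
}
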