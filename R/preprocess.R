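#' Restore non-measured points by harmonic interpolation
#'
#' Fills voids with the solution of the discrete Laplace equation using the
#' surrounding measured heights as boundary values (the classic "restore bad
#' data" operation of surface-metrology software). Measured heights are
#' unchanged; filled values obey the discrete maximum principle, i.e. they
#' lie within the range of the heights bounding each void region.
#'
#' @param map a [height_map()].
#' @return a void-free [height_map()]; `meta$restored_points` records the
#'   number of filled samples.
#' @export
restore_voids <- function(map) {
  stopifnot(is_height_map(map))
  h <- map$heights
  void <- is.na(h)
  nv <- sum(void)
  if (nv == 0L) {
    map$meta$restored_points <- 0L
    return(map)
  }
  if (nv >= 0.5 * length(h))
    stop("data-quality error: ", nv, " voids is >= 50% of ", length(h),
         " samples", call. = FALSE)
  nr <- nrow(h); nc <- ncol(h)
  idx <- matrix(0L, nr, nc)
  idx[void] <- seq_len(nv)  # unknown numbering

  vi <- which(void, arr.ind = TRUE)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(nv)
  deg <- numeric(nv)
  for (s in c("up", "down", "left", "right")) {
    di <- switch(s, up = -1L, down = 1L, left = 0L, right = 0L)
    dj <- switch(s, up = 0L, down = 0L, left = -1L, right = 1L)
    ni <- vi[, 1] + di; nj <- vi[, 2] + dj
    inb <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    w <- which(inb)
    nk <- cbind(ni[w], nj[w])
    nb_void <- void[nk]
    deg[w] <- deg[w] + 1
    # void neighbour: off-diagonal -1; measured neighbour: goes to RHS
    wv <- w[nb_void]
    if (length(wv)) {
      trip_i <- c(trip_i, wv)
      trip_j <- c(trip_j, idx[nk[nb_void, , drop = FALSE]])
      trip_x <- c(trip_x, rep(-1, length(wv)))
    }
    wm <- w[!nb_void]
    if (length(wm)) rhs[wm] <- rhs[wm] + h[nk[!nb_void, , drop = FALSE]]
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(nv), trip_i),
                            j = c(seq_len(nv), trip_j),
                            x = c(deg, trip_x), dims = c(nv, nv))
  sol <- as.numeric(Matrix::solve(A, rhs))
  h[void] <- sol
  map$heights <- h
  map$meta$restored_points <- nv
  map
}

#' Remove single-point spikes
#'
#' Automated surrogate for the manual editing of measurement spikes: any
#' sample whose absolute deviation from its local 3x3 median exceeds
#' `k` times the global median absolute deviation of the heights
#' (consistency-scaled MAD, a spike-robust scale of the surface relief) is
#' converted to a void, to be filled later by [restore_voids()].
#'
#' @param map a [height_map()].
#' @param k positive spike threshold in MAD units; default 10. `Inf`
#'   disables despiking.
#' @return the map with spikes voided; `meta$despiked_points` records how
#'   many were removed.
#' @export
despike <- function(map, k = 10) {
  stopifnot(is_height_map(map))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("parameter error: despike threshold k must be positive",
         call. = FALSE)
  if (is.infinite(k)) {
    map$meta$despiked_points <- 0L
    return(map)
  }
  med <- median3x3_cpp(map$heights)
  dev <- abs(map$heights - med)
  s <- stats::mad(map$heights, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- stats::sd(map$heights, na.rm = TRUE)
  spike <- !is.na(dev) & is.finite(s) & s > 0 & dev > k * s
  map$heights[spike] <- NA_real_
  map$meta$despiked_points <- sum(spike)
  map
}

#' Remove gross form with a low-order polynomial
#'
#' Fits a least-squares bivariate polynomial of total degree `order` (1 =
#' plane levelling, 2 = quadratic form removal) to the full grid and
#' subtracts it. Coordinates are centred and scaled to \[-1, 1\] before
#' fitting for numerical conditioning; the residual is orthogonal to every
#' retained monomial.
#'
#' @param map a void-free [height_map()].
#' @param order total polynomial degree, 1 or 2 (default 2).
#' @return the form-removed [height_map()]; fitted coefficients (in the
#'   scaled frame) in `meta$form_coefficients`.
#' @export
remove_form <- function(map, order = 2) {
  stopifnot(is_height_map(map))
  if (n_voids(map) > 0L)
    stop("sequencing error: voids present; run restore_voids() before ",
         "remove_form()", call. = FALSE)
  if (!order %in% c(1, 2))
    stop("parameter error: order must be 1 or 2", call. = FALSE)
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  x <- grid_x(map); y <- grid_y(map)
  xs <- (x - mean(x)) / max(abs(x - mean(x)))
  ys <- (y - mean(y)) / max(abs(y - mean(y)))
  X <- rep(xs, each = nr)
  Y <- rep(ys, times = nc)
  basis <- if (order == 1) cbind(1, X, Y)
           else cbind(1, X, Y, X^2, X * Y, Y^2)
  z <- as.vector(map$heights)
  fit <- stats::lm.fit(basis, z)
  map$heights <- matrix(fit$residuals, nr, nc)
  cf <- fit$coefficients
  names(cf) <- if (order == 1) c("1", "x", "y")
               else c("1", "x", "y", "x2", "xy", "y2")
  map$meta$form_coefficients <- cf
  map$meta$form_order <- order
  map
}

# amplitude transmission of the low-pass (waviness) branch at wavelength
# lambda for cutoff (nesting index) lc, both in the same units
filter_transmission_lowpass <- function(lambda, lc, type = c("spline",
                                                             "gaussian")) {
  type <- match.arg(type)
  if (type == "spline") {
    1 / (1 + (lc / lambda)^4)
  } else {
    alpha <- sqrt(log(2) / pi)
    exp(-pi * (alpha * lc / lambda)^2)
  }
}

#' Amplitude transmission of the roughness (high-pass) branch
#'
#' The fraction of a sinusoid's amplitude retained in the roughness surface
#' at spatial wavelength `lambda`, for a filter with nesting index
#' `nesting_index`. Both filter realizations transmit exactly 50% at
#' `lambda = nesting_index`.
#'
#' @param lambda spatial wavelength, mm (or any unit matching
#'   `nesting_index`).
#' @param nesting_index filter cutoff, same unit as `lambda`.
#' @param type `"spline"` (default) or `"gaussian"` characteristic.
#' @return transmission in \[0, 1\].
#' @export
filter_transmission <- function(lambda, nesting_index,
                                type = c("spline", "gaussian")) {
  1 - filter_transmission_lowpass(lambda, nesting_index, match.arg(type))
}

#' Scale-limit a surface with an areal high-pass filter
#'
#' Separates waviness from roughness with an areal filter realized in the
#' frequency domain on a mirror-extended (reflective boundary) grid. The
#' `"spline"` characteristic has low-pass amplitude transmission
#' `1 / (1 + (lc/lambda)^4)`; the `"gaussian"` characteristic follows the
#' ISO 16610-61 areal Gaussian, `exp(-pi (alpha lc / lambda)^2)` with
#' `alpha = sqrt(ln 2 / pi)`. Both pass exactly 50% of a sinusoid's
#' amplitude at the nesting index. The roughness surface is the input minus
#' the waviness, mean-subtracted.
#'
#' @param map a void-free, form-removed [height_map()].
#' @param nesting_index cutoff wavelength in mm; default 0.025 mm.
#' @param type filter characteristic, `"spline"` (default) or `"gaussian"`.
#' @param crop optional edge crop width in um applied after filtering to
#'   discard end effects (e.g. `nesting_index/2`); default 0 (no crop).
#' @return a [roughness_surface()] with provenance recording the settings.
#' @export
spline_highpass <- function(map, nesting_index = 0.025,
                            type = c("spline", "gaussian"), crop = 0) {
  stopifnot(is_height_map(map))
  type <- match.arg(type)
  if (n_voids(map) > 0L)
    stop("sequencing error: voids present", call. = FALSE)
  lc_um <- nesting_index * 1000  # nesting index given in mm, grid in um
  if (lc_um <= max(map$dx, map$dy))
    stop("parameter error: nesting index ", nesting_index,
         " mm must exceed the grid spacing", call. = FALSE)
  z <- map$heights
  nr <- nrow(z); nc <- ncol(z)
  # mirror extension: reflective boundaries, period 2nr x 2nc
  ze <- rbind(cbind(z, z[, nc:1]), cbind(z[nr:1, ], z[nr:1, nc:1]))
  fy <- c(0:(nr - 1), -(nr:1)) / (2 * nr * map$dy)
  fx <- c(0:(nc - 1), -(nc:1)) / (2 * nc * map$dx)
  f2 <- outer(fy^2, fx^2, `+`)  # squared radial spatial frequency
  H <- if (type == "spline") {
    1 / (1 + (lc_um^2 * f2)^2)
  } else {
    alpha <- sqrt(log(2) / pi)
    exp(-pi * alpha^2 * lc_um^2 * f2)
  }
  wav <- Re(stats::fft(stats::fft(ze) * H, inverse = TRUE)) / length(ze)
  rough <- z - wav[seq_len(nr), seq_len(nc)]
  out <- map
  out$heights <- rough
  crop_px_x <- floor(crop / map$dx)
  crop_px_y <- floor(crop / map$dy)
  if (crop_px_x > 0 || crop_px_y > 0) {
    ri <- (1 + crop_px_y):(nr - crop_px_y)
    ci <- (1 + crop_px_x):(nc - crop_px_x)
    if (length(ri) < 2L || length(ci) < 2L)
      stop("parameter error: crop removes the whole field", call. = FALSE)
    out$heights <- out$heights[ri, ci]
    out$x0 <- out$x0 + crop_px_x * out$dx
    out$y0 <- out$y0 + crop_px_y * out$dy
  }
  prov <- c(map$meta$provenance %||% list(),
            list(list(step = "spline_highpass", nesting_index_mm = nesting_index,
                      type = type, boundary = "mirror", crop_um = crop)))
  roughness_surface(out, provenance = prov)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: [despike()], [restore_voids()], [remove_form()] and
#' [spline_highpass()], producing the scale-limited roughness surface on
#' which the ISO parameters are computed. Each step and its settings are
#' recorded in the result's `provenance`.
#'
#' @param map a raw [height_map()].
#' @param config a [pipeline_config()] or list with elements `despike_k`,
#'   `form_order`, `nesting_index_mm`, `filter_type`, `crop_um`.
#' @return a [roughness_surface()] with 4-step provenance.
#' @export
standard_chain <- function(map, config = pipeline_config()) {
  cfg <- config$preprocess %||% config
  k <- cfg$despike_k %||% 10
  ord <- cfg$form_order %||% 2
  lc <- cfg$nesting_index_mm %||% 0.025
  type <- cfg$filter_type %||% "spline"
  crop <- cfg$crop_um %||% 0

  m1 <- despike(map, k = k)
  m2 <- restore_voids(m1)
  m3 <- remove_form(m2, order = ord)
  out <- spline_highpass(m3, nesting_index = lc, type = type, crop = crop)
  out$provenance <- list(
    list(step = "despike", k = k, removed = m1$meta$despiked_points),
    list(step = "restore_voids", restored = m2$meta$restored_points),
    list(step = "remove_form", order = ord),
    list(step = "spline_highpass", nesting_index_mm = lc, type = type,
         boundary = "mirror", crop_um = crop))
  out
}
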