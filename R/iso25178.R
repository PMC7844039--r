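#' Height (moment and extreme) parameters
#'
#' Sq (RMS height), Sa (mean absolute height), Ssk (skewness), Sku
#' (kurtosis), Sp (maximum peak height), Sv (maximum pit depth) and
#' Sz (= Sp + Sv), computed as area-weighted grid sums over a mean-zero
#' surface.
#'
#' @param surf a mean-zero [roughness_surface()] (or any height map; the
#'   mean is removed by the preprocessing chain, not here).
#' @return named list with elements Sq, Sa, Ssk, Sku, Sp, Sv, Sz (um except
#'   Ssk/Sku, dimensionless).
#' @export
height_parameters <- function(surf) {
  z <- as.vector(surf$heights)
  Sq <- sqrt(mean(z^2))
  Sa <- mean(abs(z))
  Sp <- max(z)
  Sv <- -min(z)
  if (Sq == 0) {
    warning("constant surface: Ssk and Sku undefined")
    return(list(Sq = 0, Sa = 0, Ssk = NaN, Sku = NaN, Sp = 0, Sv = 0, Sz = 0))
  }
  list(Sq = Sq, Sa = Sa,
       Ssk = mean(z^3) / Sq^3, Sku = mean(z^4) / Sq^4,
       Sp = Sp, Sv = Sv, Sz = Sp + Sv)
}

#' Areal material ratio (Abbott-Firestone) curve
#'
#' The height `c(p)` below which the areal material ratio is `p` percent:
#' the fraction of the surface at or above `c(p)` equals `p/100`. Evaluated
#' by linear interpolation between the descending order statistics of the
#' heights, on a dense uniform grid of `n` material ratios spanning
#' \[0, 100\]%, so that `c(0) = Sp` and `c(100) = -Sv` exactly.
#'
#' @param surf a mean-zero surface.
#' @param n number of grid points (>= 1000).
#' @return object of class `material_ratio_curve`: list with `p` (%),
#'   `c` (um, non-increasing).
#' @export
material_ratio_curve <- function(surf, n = 1001L) {
  stopifnot(n >= 1000L)
  z <- sort(as.vector(surf$heights), decreasing = TRUE)
  N <- length(z)
  ps <- (seq_len(N) - 1) / (N - 1) * 100
  pg <- seq(0, 100, length.out = n)
  cg <- stats::approx(ps, z, xout = pg, rule = 2)$y
  structure(list(p = pg, c = cg), class = "material_ratio_curve")
}

# trapezoid integral of curve values cg over p in [0, r] (r in %, on or off
# the grid); returns integral in um * %
trapz_to <- function(pg, cg, r) {
  if (r <= pg[1]) return(0)
  i <- findInterval(r, pg)
  full <- if (i >= 2) sum(diff(pg[1:i]) * (cg[1:(i - 1)] + cg[2:i]) / 2) else 0
  if (r > pg[i]) {
    cr <- stats::approx(pg, cg, xout = r)$y
    full <- full + (r - pg[i]) * (cg[i] + cr) / 2
  }
  full
}

#' Void and material volume parameters
#'
#' Vmp (peak material volume), Vmc (core material volume), Vvc (core void
#' volume) and Vvv (valley/dale void volume), in um^3/um^2, from the areal
#' material ratio curve: `Vm(r) = (1/100) * integral_0^r (c(u) - c(r)) du`
#' and `Vv(r) = (1/100) * integral_r^100 (c(r) - c(u)) du`, with
#' `Vmp = Vm(p)`, `Vmc = Vm(q) - Vm(p)`, `Vvv = Vv(q)`,
#' `Vvc = Vv(p) - Vv(q)`.
#'
#' @param curve a [material_ratio_curve()].
#' @param p,q material-ratio thresholds in percent, defaults 10 and 80.
#' @return named list Vmp, Vmc, Vvc, Vvv (um^3/um^2).
#' @export
volume_parameters <- function(curve, p = 10, q = 80) {
  if (!(p > 0 && q < 100 && p < q))
    stop("parameter error: need 0 < p < q < 100", call. = FALSE)
  pg <- curve$p; cg <- curve$c
  total <- trapz_to(pg, cg, 100)
  cr <- function(r) stats::approx(pg, cg, xout = r)$y
  Vm <- function(r) (trapz_to(pg, cg, r) - r * cr(r)) / 100
  Vv <- function(r) ((cr(r) * (100 - r)) - (total - trapz_to(pg, cg, r))) / 100
  list(Vmp = max(0, Vm(p)), Vmc = max(0, Vm(q) - Vm(p)),
       Vvc = max(0, Vv(p) - Vv(q)), Vvv = max(0, Vv(q)))
}

#' Core roughness parameters from the material ratio curve
#'
#' Finds the 40%-width secant of minimum slope magnitude along the
#' Abbott-Firestone curve, fits the equivalent straight line to the curve
#' over that window by least squares, and derives Sk (core depth, the line's
#' drop from 0 to 100% material ratio), Smr1/Smr2 (material ratios where the
#' curve crosses the line's values at 0 and 100%), and Spk/Svk (heights of
#' triangles area-equivalent to the peak region above Smr1 and the dale
#' region below Smr2). A piecewise-constant (two-level) curve makes the
#' minimum-slope window non-unique; the tie is broken at the smallest
#' starting ratio with a warning.
#'
#' @param curve a [material_ratio_curve()].
#' @return named list Sk, Spk, Svk (um), Smr1, Smr2 (%).
#' @export
core_parameters <- function(curve) {
  pg <- curve$p; cg <- curve$c
  n <- length(pg)
  step <- pg[2] - pg[1]
  w <- round(40 / step)  # window of exactly 40% material ratio
  i0 <- seq_len(n - w)
  slopes <- (cg[i0 + w] - cg[i0]) / 40   # <= 0, closest to 0 is flattest
  best <- max(slopes)
  hits <- which(slopes >= best - 1e-12 * max(1, abs(best)))
  if (length(hits) > 1L && (max(hits) - min(hits)) > 1L)
    warning("degenerate material ratio curve: minimum-slope secant not ",
            "unique; using smallest starting ratio")
  i <- min(hits)
  win <- i:(i + w)
  fit <- stats::lm.fit(cbind(1, pg[win]), cg[win])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  y0 <- a            # line at p = 0
  y100 <- a + 100 * b
  Sk <- y0 - y100

  # first ratio where the curve falls to the line's p=0 level
  below <- which(cg <= y0)
  if (!length(below)) {
    Smr1 <- 100
  } else if (below[1] == 1L) {
    Smr1 <- 0
  } else {
    j <- below[1]
    Smr1 <- pg[j - 1] + (cg[j - 1] - y0) / (cg[j - 1] - cg[j]) * step
  }
  # last ratio where the curve is still above the line's p=100 level
  above <- which(cg >= y100)
  if (!length(above)) {
    Smr2 <- 0
  } else if (above[length(above)] == n) {
    Smr2 <- 100
  } else {
    j <- above[length(above)]
    Smr2 <- pg[j] + (cg[j] - y100) / (cg[j] - cg[j + 1]) * step
  }

  Spk <- if (Smr1 <= step / 2) 0 else {
    A1 <- (trapz_to(pg, cg, Smr1) - Smr1 * y0) / 100  # um
    max(0, 2 * A1 * 100 / Smr1)
  }
  Svk <- if (Smr2 >= 100 - step / 2) 0 else {
    tail_int <- trapz_to(pg, cg, 100) - trapz_to(pg, cg, Smr2)
    A2 <- (y100 * (100 - Smr2) - tail_int) / 100       # um
    max(0, 2 * A2 * 100 / (100 - Smr2))
  }
  list(Sk = unname(Sk), Spk = unname(Spk), Svk = unname(Svk),
       Smr1 = unname(Smr1), Smr2 = unname(Smr2))
}

# centered (fftshift-ed) normalized areal autocorrelation and its lag axes
areal_acf <- function(surf) {
  z <- surf$heights - mean(surf$heights)
  nr <- nrow(z); nc <- ncol(z)
  F <- stats::fft(z)
  R <- Re(stats::fft(Mod(F)^2, inverse = TRUE)) / length(z)
  R <- R / R[1, 1]
  # reorder so lag 0 sits at (cy, cx)
  iy <- c((floor(nr / 2) + 1):nr, 1:floor(nr / 2))
  ix <- c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))
  Rc <- R[iy, ix]
  list(R = Rc,
       tx = (seq_len(nc) - (ceiling(nc / 2) + 1)) * surf$dx,
       ty = (seq_len(nr) - (ceiling(nr / 2) + 1)) * surf$dy)
}

#' Spatial parameters: autocorrelation length and texture aspect ratio
#'
#' Computes the normalized areal autocorrelation function (ACF) by FFT
#' (circular lags), then scans rays from the zero lag outward: the distance
#' at which the ACF first decays to the threshold `s` is found per direction
#' with bilinear interpolation on the lag grid and linear interpolation
#' along the ray. Sal is the minimum such distance over all directions
#' (fastest decay); Str is Sal divided by the maximum distance to the
#' boundary of the central non-decayed region (slowest decay, capped at the
#' half-size lag window when a ray never decays).
#'
#' @param surf a mean-zero surface.
#' @param s ACF decay threshold, default 0.2 (the conventional value).
#' @param n_theta number of ray directions, default 360.
#' @return named list Sal (um), Str (dimensionless in \[0,1\]); both `NA`
#'   with a warning when the ACF never decays below `s` inside the lag
#'   window.
#' @export
spatial_parameters <- function(surf, s = 0.2, n_theta = 360L) {
  ac <- areal_acf(surf)
  sal_str_from_acf(ac, s = s, n_theta = n_theta,
                   dx = surf$dx, dy = surf$dy)
}

# shared geometric search on an ACF lag grid (used by engine and exposed so
# a directly-computed ACF can be analysed identically)
sal_str_from_acf <- function(ac, s, n_theta, dx, dy) {
  R <- ac$R; tx <- ac$tx; ty <- ac$ty
  hx <- min(max(tx), -min(tx)); hy <- min(max(ty), -min(ty))
  rstep <- min(dx, dy) / 4
  interp <- function(x, y) {
    jx <- findInterval(x, tx, all.inside = TRUE)
    jy <- findInterval(y, ty, all.inside = TRUE)
    ux <- (x - tx[jx]) / (tx[jx + 1] - tx[jx])
    uy <- (y - ty[jy]) / (ty[jy + 1] - ty[jy])
    R[cbind(jy, jx)] * (1 - ux) * (1 - uy) +
      R[cbind(jy, jx + 1)] * ux * (1 - uy) +
      R[cbind(jy + 1, jx)] * (1 - ux) * uy +
      R[cbind(jy + 1, jx + 1)] * ux * uy
  }
  thetas <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  crossing <- rep(NA_real_, n_theta)
  rcap <- rep(NA_real_, n_theta)
  for (t in seq_len(n_theta)) {
    ct <- cos(thetas[t]); st <- sin(thetas[t])
    # per-direction cap: stay inside the rectangular lag window
    rcap[t] <- min(if (abs(ct) > 1e-12) hx / abs(ct) else Inf,
                   if (abs(st) > 1e-12) hy / abs(st) else Inf)
    rs <- seq(0, rcap[t], by = rstep)
    vals <- interp(rs * ct, rs * st)
    below <- which(vals <= s)
    if (length(below)) {
      j <- below[1]
      crossing[t] <- if (j == 1L) 0 else
        rs[j - 1] + (vals[j - 1] - s) / (vals[j - 1] - vals[j]) * rstep
    }
  }
  if (all(is.na(crossing))) {
    warning("autocorrelation never decays below ", s,
            " within the lag window; Sal/Str undefined")
    return(list(Sal = NA_real_, Str = NA_real_))
  }
  Sal <- min(crossing, na.rm = TRUE)
  longest <- max(ifelse(is.na(crossing), rcap, crossing))
  list(Sal = Sal, Str = Sal / longest)
}

# central-difference gradients (one-sided at edges), um/um
surface_gradients <- function(surf) {
  z <- surf$heights
  nr <- nrow(z); nc <- ncol(z)
  zx <- (z[, c(2:nc, nc)] - z[, c(1, 1:(nc - 1))]) /
    ((col(z)[, c(2:nc, nc)] - col(z)[, c(1, 1:(nc - 1))]) * surf$dx)
  zy <- (z[c(2:nr, nr), ] - z[c(1, 1:(nr - 1)), ]) /
    ((row(z)[c(2:nr, nr), ] - row(z)[c(1, 1:(nr - 1)), ]) * surf$dy)
  list(zx = zx, zy = zy)
}

#' Hybrid parameters: RMS gradient and developed area ratio
#'
#' Sdq is the root-mean-square surface slope; Sdr is the developed
#' interfacial area ratio in percent, `100 * mean(sqrt(1 + zx^2 + zy^2) - 1)`.
#' Gradients use central differences (one-sided at the grid edges).
#'
#' @param surf a surface.
#' @return named list Sdq (dimensionless), Sdr (%).
#' @export
hybrid_parameters <- function(surf) {
  g <- surface_gradients(surf)
  s2 <- g$zx^2 + g$zy^2
  list(Sdq = sqrt(mean(s2)), Sdr = 100 * mean(sqrt(1 + s2) - 1))
}

#' Feature parameters: summit density, curvature and five-point height
#'
#' Summits are strict 8-neighbour local maxima of the interior grid that
#' survive Wolf-style pruning: a summit is discarded when its topographic
#' prominence (height above the key saddle connecting it to a higher
#' summit) is below `pruning`% of Sz. Sds is the density of surviving
#' summits per unit evaluation area; Ssc is their mean curvature
#' `-(zxx + zyy)/2` from central second differences; S5z is the mean height
#' of the five highest surviving summits plus the mean depth of the five
#' deepest surviving dales (dales found symmetrically on the inverted
#' surface).
#'
#' @param surf a mean-zero surface.
#' @param pruning prominence threshold as a percentage of Sz, default 5.
#' @return named list Sds (1/um^2), Ssc (1/um), S5z (um), plus attribute
#'   `warnings` when fewer than five summits or dales exist.
#' @export
feature_parameters <- function(surf, pruning = 5) {
  z <- surf$heights
  warns <- character(0)
  Sz <- max(z) - min(z)
  if (Sz == 0) {
    warning("flat surface: no summits; Ssc undefined")
    return(list(Sds = 0, Ssc = NaN, S5z = 0))
  }
  thr <- pruning / 100 * Sz
  area <- nrow(z) * surf$dy * ncol(z) * surf$dx

  peaks <- prominence_cpp(z)
  keep <- peaks$prominence >= thr
  pr <- peaks$row[keep]; pc <- peaks$col[keep]; ph <- peaks$height[keep]

  dales <- prominence_cpp(-z)
  dkeep <- dales$prominence >= thr
  dh <- dales$height[dkeep]  # heights of -z at dales = depths

  Sds <- length(ph) / area
  Ssc <- if (length(ph)) {
    zxx <- (z[cbind(pr, pc + 1L)] - 2 * z[cbind(pr, pc)] +
              z[cbind(pr, pc - 1L)]) / surf$dx^2
    zyy <- (z[cbind(pr + 1L, pc)] - 2 * z[cbind(pr, pc)] +
              z[cbind(pr - 1L, pc)]) / surf$dy^2
    mean(-(zxx + zyy) / 2)
  } else NaN
  if (length(ph) < 5L || length(dh) < 5L) {
    warns <- c(warns, sprintf(
      "S5z computed over %d summit(s) and %d dale(s)", length(ph),
      length(dh)))
  }
  top <- if (length(ph)) mean(sort(ph, decreasing = TRUE)[seq_len(min(5L,
              length(ph)))]) else 0
  bot <- if (length(dh)) mean(sort(dh, decreasing = TRUE)[seq_len(min(5L,
              length(dh)))]) else 0
  out <- list(Sds = Sds, Ssc = Ssc, S5z = top + bot)
  if (length(warns)) attr(out, "warnings") <- warns
  out
}

#' Compute all 23 ISO 25178-2 texture parameters
#'
#' Assembles the height, material-ratio (volume and core), spatial, hybrid
#' and feature parameters into a single named record in the package's
#' canonical column order (see [iso_parameter_names()]). Per-parameter
#' warnings (undefined Ssk/Sku on a constant surface, undecayed ACF, sparse
#' summits) are collected in the `warnings` attribute.
#'
#' @param surf a [roughness_surface()] (mean-zero, void-free).
#' @param s ACF decay threshold for Sal/Str, default 0.2.
#' @param p,q material-ratio thresholds for the volume parameters (%).
#' @param pruning summit prominence threshold, % of Sz.
#' @return one-row data frame with the 23 parameters and a `warnings`
#'   attribute (character vector, possibly empty).
#' @export
compute_all <- function(surf, s = 0.2, p = 10, q = 80, pruning = 5) {
  warns <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  hp <- wcollect(height_parameters(surf))
  curve <- material_ratio_curve(surf)
  vp <- wcollect(volume_parameters(curve, p = p, q = q))
  cp <- wcollect(core_parameters(curve))
  sp <- wcollect(spatial_parameters(surf, s = s))
  yp <- wcollect(hybrid_parameters(surf))
  fp <- wcollect(feature_parameters(surf, pruning = pruning))
  warns <- c(warns, attr(fp, "warnings"))
  rec <- c(hp, vp, cp, sp, yp, fp)
  rec <- rec[iso_parameter_names()]
  out <- as.data.frame(rec)
  attr(out, "warnings") <- warns
  out
}
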