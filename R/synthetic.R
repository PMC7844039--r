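#' Deterministic analytic oracle surfaces
#'
#' Closed-form surfaces with known texture parameters, used as fixtures and
#' oracles throughout the package: flat planes, tilted planes, quadratic
#' bowls, sinusoids, checkerboards, egg-box gratings, sums of Gaussian
#' bumps, and i.i.d. uniform noise. The exact generating formula and its
#' parameters are recorded in the map's `meta`.
#'
#' @param kind one of `"flat"`, `"plane"`, `"quadratic"`, `"sinusoid"`,
#'   `"checkerboard"`, `"eggbox"`, `"bumps"`, `"uniform_noise"`.
#' @param params named list of kind-specific parameters:
#'   \describe{
#'     \item{plane}{`slope_x`, `slope_y`, `offset` (um per um, um)}
#'     \item{quadratic}{`c0, cx, cy, cxx, cxy, cyy`}
#'     \item{sinusoid}{`amplitude` (um), `wavelength` (um), `axis`
#'       (`"x"` or `"y"`), `phase` (radians)}
#'     \item{checkerboard}{`height` (um), `period` (samples per half-cell)}
#'     \item{eggbox}{`amplitude`, `wavelength`}
#'     \item{bumps}{`bumps`: data frame or list of `(x, y, h, sigma)`;
#'       each adds `h * exp(-((X-x)^2 + (Y-y)^2) / (2 sigma^2))`}
#'     \item{uniform_noise}{`a` (heights i.i.d. uniform on \[-a, a\]),
#'       `seed`}
#'   }
#' @param nx,ny grid size; @param dx,dy spacing, um.
#' @return a [height_map()].
#' @export
analytic_surface <- function(kind, params = list(), nx = 64L, ny = 64L,
                             dx = 0.44, dy = 0.44) {
  kind <- match.arg(kind, c("flat", "plane", "quadratic", "sinusoid",
                            "checkerboard", "eggbox", "bumps",
                            "uniform_noise"))
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dy
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)
  p <- params
  z <- switch(kind,
    flat = matrix(0, ny, nx),
    plane = (p$slope_x %||% 0) * X + (p$slope_y %||% 0) * Y +
      (p$offset %||% 0),
    quadratic = (p$c0 %||% 0) + (p$cx %||% 0) * X + (p$cy %||% 0) * Y +
      (p$cxx %||% 0) * X^2 + (p$cxy %||% 0) * X * Y + (p$cyy %||% 0) * Y^2,
    sinusoid = {
      A <- p$amplitude %||% 1; lam <- p$wavelength %||% 10
      ph <- p$phase %||% 0
      if ((p$axis %||% "x") == "x") A * sin(2 * pi * X / lam + ph)
      else A * sin(2 * pi * Y / lam + ph)
    },
    checkerboard = {
      h <- p$height %||% 0.3; per <- p$period %||% 1L
      h * (2 * ((floor(col(X) / per) + floor(row(X) / per)) %% 2) - 1)
    },
    eggbox = {
      A <- p$amplitude %||% 1; lam <- p$wavelength %||% 10
      A * sin(2 * pi * X / lam) * sin(2 * pi * Y / lam)
    },
    bumps = {
      z0 <- matrix(0, ny, nx)
      bl <- p$bumps
      if (is.data.frame(bl)) bl <- split(bl, seq_len(nrow(bl)))
      for (b in bl)
        z0 <- z0 + b$h * exp(-((X - b$x)^2 + (Y - b$y)^2) / (2 * b$sigma^2))
      z0
    },
    uniform_noise = {
      set.seed(p$seed %||% 1L)
      a <- p$a %||% 0.5
      matrix(stats::runif(nx * ny, -a, a), ny, nx)
    })
  if (kind %in% c("sinusoid", "eggbox")) {
    lam <- p$wavelength %||% 10
    if (abs(nx * dx / lam - round(nx * dx / lam)) > 1e-9)
      warning("non-integer number of periods across the field; ",
              "edge bias in moment parameters")
  }
  height_map(z, dx = dx, dy = dy,
             meta = list(generator = kind, params = p))
}

#' Stationary Gaussian random field with Gaussian autocorrelation
#'
#' Spectral (FFT) synthesis of a periodic, stationary Gaussian field whose
#' autocovariance is `sq^2 * exp(-r^2 / corr_len^2)` (so the normalized ACF
#' is e^-1 at lag `corr_len`), scaled so the expected RMS height equals
#' `sq`. Deterministic for a given seed.
#'
#' @param nx,ny grid size; @param dx,dy spacing, um.
#' @param sq target expected RMS height, um.
#' @param corr_len correlation length, um (must be >= dx).
#' @param seed explicit RNG seed.
#' @return a [height_map()] with generator settings in `meta`.
#' @export
gaussian_random_field <- function(nx, ny, dx, dy, sq, corr_len, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (corr_len < dx) stop("corr_len must be >= dx", call. = FALSE)
  if (corr_len > min(nx * dx, ny * dy) / 4)
    warning("corr_len exceeds a quarter of the field; ",
            "Sal may be undefined on this surface")
  # circular (torus) lag distances
  rx <- pmin(0:(nx - 1), nx - (0:(nx - 1))) * dx
  ry <- pmin(0:(ny - 1), ny - (0:(ny - 1))) * dy
  acf <- exp(-outer(ry^2, rx^2, `+`) / corr_len^2)
  S <- pmax(Re(stats::fft(acf)), 0)
  H <- sqrt(S)
  set.seed(seed)
  e <- matrix(stats::rnorm(nx * ny), ny, nx)
  z <- Re(stats::fft(stats::fft(e) * H, inverse = TRUE)) / (nx * ny)
  height_map(z * sq, dx = dx, dy = dy,
             meta = list(generator = "gaussian_random_field", sq = sq,
                         corr_len = corr_len, seed = seed))
}

# perpendicular-clamped distance from every grid node to a segment
segment_distance <- function(X, Y, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((X - ax) * vx + (Y - ay) * vy) / L2, 0), 1)
  sqrt((X - (ax + t * vx))^2 + (Y - (ay + t * vy))^2)
}

#' Add elongate scratch features to a surface
#'
#' Subtracts Poisson-placed line-segment grooves with Gaussian cross
#' sections (wear removes material, so features are always subtractive).
#' Orientations are drawn from a wrapped-normal approximation to a
#' von Mises distribution around 0 (the x axis); concentration 0 gives
#' isotropic orientations.
#'
#' @param map a [height_map()].
#' @param density expected scratches per um^2.
#' @param depth groove depth, um.
#' @param width full groove width, um (Gaussian sigma = width / 2);
#'   must be >= dx.
#' @param length_um scratch length, um (default 40).
#' @param orientation_conc orientation concentration >= 0.
#' @param seed explicit RNG seed.
#' @return the scratched map; `meta$n_scratches` records the count.
#' @export
add_scratches <- function(map, density, depth, width, length_um = 40,
                          orientation_conc = 0, seed) {
  stopifnot(is_height_map(map), depth > 0 || density == 0)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (density == 0) {
    map$meta$n_scratches <- 0L
    return(map)
  }
  if (width < map$dx) stop("width must be >= dx", call. = FALSE)
  x <- grid_x(map); y <- grid_y(map)
  wx <- max(x) - min(x); wy <- max(y) - min(y)
  area <- (wx + map$dx) * (wy + map$dy)
  set.seed(seed)
  n <- stats::rpois(1, density * area)
  X <- matrix(x, nrow(map$heights), ncol(map$heights), byrow = TRUE)
  Y <- matrix(y, nrow(map$heights), ncol(map$heights))
  sig <- width / 2
  for (i in seq_len(n)) {
    cx <- stats::runif(1, min(x), max(x))
    cy <- stats::runif(1, min(y), max(y))
    th <- if (orientation_conc == 0) stats::runif(1, 0, pi) else
      stats::rnorm(1, 0, 1 / sqrt(orientation_conc)) %% pi
    hx <- length_um / 2 * cos(th); hy <- length_um / 2 * sin(th)
    d <- segment_distance(X, Y, cx - hx, cy - hy, cx + hx, cy + hy)
    map$heights <- map$heights - depth * exp(-d^2 / (2 * sig^2))
  }
  map$meta$n_scratches <- n
  map
}

#' Add discrete pit features to a surface
#'
#' Subtracts Poisson-placed circular Gaussian depressions (subtractive
#' only, like [add_scratches()]). Pitting a one-sided amount of material
#' drives the height-distribution skew negative.
#'
#' @param map a [height_map()].
#' @param density expected pits per um^2.
#' @param depth pit depth, um.
#' @param radius pit radius (Gaussian sigma), um; must be >= dx.
#' @param seed explicit RNG seed.
#' @return the pitted map; `meta$n_pits` records the count.
#' @export
add_pits <- function(map, density, depth, radius, seed) {
  stopifnot(is_height_map(map), depth > 0 || density == 0)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (density == 0) {
    map$meta$n_pits <- 0L
    return(map)
  }
  if (radius < map$dx) stop("radius must be >= dx", call. = FALSE)
  x <- grid_x(map); y <- grid_y(map)
  area <- (max(x) - min(x) + map$dx) * (max(y) - min(y) + map$dy)
  set.seed(seed)
  n <- stats::rpois(1, density * area)
  X <- matrix(x, nrow(map$heights), ncol(map$heights), byrow = TRUE)
  Y <- matrix(y, nrow(map$heights), ncol(map$heights))
  for (i in seq_len(n)) {
    cx <- stats::runif(1, min(x), max(x))
    cy <- stats::runif(1, min(y), max(y))
    r2 <- (X - cx)^2 + (Y - cy)^2
    map$heights <- map$heights - depth * exp(-r2 / (2 * radius^2))
  }
  map$meta$n_pits <- n
  map
}

#' Default diet-level to texture mapping
#'
#' Texture-generation parameters per ordinal diet level 1-4, monotone by
#' construction in background roughness and feature depths so that
#' "rougher with higher elasmobranch proportion" holds in the generated
#' cohorts. Units: um for sq and depths, um for lengths, features per um^2
#' for densities.
#'
#' @return data frame with one row per diet level.
#' @export
default_texture_map <- function() {
  data.frame(
    diet_level = 1:4,
    base_sq = c(0.15, 0.22, 0.30, 0.40),
    corr_len = c(2, 2, 2, 2),
    scratch_density = c(6e-4, 8e-4, 1.0e-3, 1.2e-3),
    scratch_depth = c(0.30, 0.45, 0.60, 0.80),
    pit_density = c(3e-4, 4.5e-4, 6e-4, 8e-4),
    pit_depth = c(0.30, 0.50, 0.70, 0.90))
}

#' Cohort design for the synthetic wear-surface generator
#'
#' Describes a study cohort: specimen groups with diet levels and teeth
#' counts (defaulting to the sampling design of [study_design()]: 6
#' aquarium teeth, 3 wild specimens x 6 teeth, 8 within-tooth repeats, 6
#' teeth of an unknown specimen), the diet-level texture map, and the
#' field-of-view geometry (default 332 x 252 samples at 0.44 um, the
#' instrument field the generator emulates).
#'
#' @param specimens data frame with `group`, `n`, `diet_level`, `role`;
#'   `diet_level` of the unknown specimen is used for generation but its
#'   truth-table diet rank is `NA`.
#' @param texture_map data frame as [default_texture_map()]; must be
#'   monotone in `base_sq`, `scratch_depth` and `pit_depth`.
#' @param nx,ny,dx,dy field geometry.
#' @param seed cohort seed.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(specimens = NULL,
                          texture_map = default_texture_map(),
                          nx = 332L, ny = 252L, dx = 0.44, dy = 0.44,
                          seed = 1L) {
  if (is.null(specimens)) {
    sd0 <- study_design()
    specimens <- data.frame(group = sd0$group, n = sd0$n,
                            diet_level = ifelse(is.na(sd0$diet_rank), 1L,
                                                sd0$diet_rank),
                            role = sd0$role)
    specimens$diet_rank <- sd0$diet_rank
  }
  if (!"diet_rank" %in% names(specimens))
    specimens$diet_rank <- specimens$diet_level
  tm <- texture_map[order(texture_map$diet_level), ]
  if (any(tm$base_sq <= 0) || any(tm$scratch_density < 0) ||
      any(tm$pit_density < 0))
    stop("texture map: densities must be >= 0 and base_sq > 0",
         call. = FALSE)
  if (is.unsorted(tm$base_sq) || is.unsorted(tm$scratch_depth) ||
      is.unsorted(tm$pit_depth))
    stop("texture map must be monotone in diet level for base_sq and ",
         "feature depths", call. = FALSE)
  structure(list(specimens = specimens, texture_map = tm,
                 nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, dy = dy, seed = seed),
            class = "cohort_design")
}

# one synthetic wear surface: GRF background + scratches + pits
synthesize_surface <- function(tm_row, nx, ny, dx, dy, seed) {
  m <- gaussian_random_field(nx, ny, dx, dy, sq = tm_row$base_sq,
                             corr_len = tm_row$corr_len, seed = seed)
  m <- add_scratches(m, density = tm_row$scratch_density,
                     depth = tm_row$scratch_depth, width = 1.5,
                     orientation_conc = 2, seed = seed + 1L)
  add_pits(m, density = tm_row$pit_density, depth = tm_row$pit_depth,
           radius = 1.2, seed = seed + 2L)
}

#' Generate a synthetic cohort of wear surfaces with its truth table
#'
#' For each tooth of each specimen, generates a Gaussian-random-field
#' background plus scratch and pit features drawn from the specimen's
#' diet-level texture map. Within-tooth repeat groups are generated as
#' disjoint crops of a single double-size parent surface (so their
#' between-sample variance is smaller than between-tooth variance by
#' construction). Every generating parameter and the diet rank are
#' recorded in the truth table, which is the oracle for downstream tests.
#'
#' @param design a [cohort_design()].
#' @return list with `surfaces` (named list of [height_map()]s) and
#'   `truth` (data frame: group, sample_id, diet_rank, role, generating
#'   parameters, per-surface seed).
#' @export
make_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  seeds <- sample.int(2^31 - 10L, 4L * sum(design$specimens$n))
  si <- 0L
  surfaces <- list()
  truth <- list()
  for (r in seq_len(nrow(design$specimens))) {
    sp <- design$specimens[r, ]
    tm <- design$texture_map[design$texture_map$diet_level ==
                               sp$diet_level, ]
    if (!nrow(tm)) stop("no texture map row for diet level ", sp$diet_level,
                        call. = FALSE)
    if (sp$role == "within_tooth") {
      # disjoint crops of one parent field
      tiles_x <- ceiling(sp$n / 2); tiles_y <- 2L
      si <- si + 1L
      parent <- synthesize_surface(tm, design$nx * tiles_x,
                                   design$ny * tiles_y, design$dx,
                                   design$dy, seeds[si])
      for (t in seq_len(sp$n)) {
        ti <- (t - 1L) %% tiles_x
        tj <- (t - 1L) %/% tiles_x
        rows <- tj * design$ny + seq_len(design$ny)
        cols <- ti * design$nx + seq_len(design$nx)
        m <- height_map(parent$heights[rows, cols], design$dx, design$dy,
                        meta = list(generator = "within_tooth_crop",
                                    parent_seed = seeds[si]))
        id <- sprintf("%s_%d", sp$group, t)
        surfaces[[id]] <- m
        truth[[id]] <- data.frame(group = sp$group, sample_id = id,
                                  diet_rank = sp$diet_rank, role = sp$role,
                                  seed = seeds[si], tm)
      }
    } else {
      for (t in seq_len(sp$n)) {
        si <- si + 1L
        m <- synthesize_surface(tm, design$nx, design$ny, design$dx,
                                design$dy, seeds[si])
        id <- sprintf("%s_%d", sp$group, t)
        surfaces[[id]] <- m
        truth[[id]] <- data.frame(group = sp$group, sample_id = id,
                                  diet_rank = sp$diet_rank, role = sp$role,
                                  seed = seeds[si], tm)
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(surfaces = surfaces, truth = truth)
}

#' Simulate a texture-parameter table directly
#'
#' Draws per-record parameter values from independent normal distributions
#' around plausible baseline magnitudes, optionally shifting designated
#' parameters by a per-diet-level step (in within-group SD units). This is
#' the fast, table-level companion of [make_cohort()]: it produces the
#' statistical structure the discrimination pipeline assumes (known
#' differing parameters, ordinal group effects) without synthesizing
#' surfaces, and is the workhorse of the null-calibration and power
#' checks.
#'
#' @param groups character vector of group labels.
#' @param n integer vector of per-group record counts (recycled).
#' @param effect_parameters parameters receiving a group effect.
#' @param effect_size per-diet-level shift in SD units: a group of diet
#'   rank r is shifted by `(r - 1) * effect_size` SDs on each designated
#'   parameter; default 0 (null table).
#' @param diet_ranks integer vector of diet ranks per group (default
#'   `seq_along(groups)`); drives both the designed shift and the
#'   `diet_rank` column.
#' @param seed RNG seed.
#' @return a [specimen_table()].
#' @export
simulate_parameter_table <- function(groups = c("1", "2", "3", "4"),
                                     n = 6L, effect_parameters = character(0),
                                     effect_size = 0,
                                     diet_ranks = seq_along(groups),
                                     seed = 1L) {
  pn <- iso_parameter_names()
  base <- c(Sq = 0.30, Ssk = -0.30, Sku = 3.2, Sp = 1.0, Sv = 1.1,
            Sz = 2.1, Sds = 0.020, Str = 0.60, Sal = 5.0, Sdq = 0.15,
            Ssc = 0.050, Sdr = 1.2, Vmp = 0.015, Vmc = 0.25, Vvc = 0.35,
            Vvv = 0.040, Spk = 0.30, Sk = 0.70, Svk = 0.40, Smr1 = 10,
            Smr2 = 88, S5z = 1.5, Sa = 0.24)
  sds <- 0.15 * abs(base)
  n <- rep_len(n, length(groups))
  set.seed(seed)
  rows <- lapply(seq_along(groups), function(i) {
    rec <- as.data.frame(lapply(pn, function(pm) {
      mu <- base[[pm]]
      if (pm %in% effect_parameters)
        mu <- mu + (diet_ranks[i] - 1) * effect_size * sds[[pm]]
      stats::rnorm(n[i], mu, sds[[pm]])
    }))
    names(rec) <- pn
    cbind(data.frame(specimen_id = groups[i],
                     sample_id = sprintf("%s_%d", groups[i], seq_len(n[i])),
                     group = groups[i],
                     diet_rank = diet_ranks[i],
                     total_length = NA_real_), rec)
  })
  specimen_table(do.call(rbind, rows))
}
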