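test_that("height parameters match sinusoid and checkerboard closed forms", {
  s <- sinusoid_surf(A = 1, lam = 10)  # 64 samples per period, 10 periods
  hp <- height_parameters(s)
  expect_equal(hp$Sq, 1 / sqrt(2), tolerance = 0.005)
  expect_equal(hp$Sa, 2 / pi, tolerance = 0.005)
  expect_equal(hp$Ssk, 0, tolerance = 1e-10)
  expect_equal(hp$Sku, 1.5, tolerance = 0.005)

  cb <- checkerboard_surf(h = 0.3)
  hc <- height_parameters(cb)
  expect_equal(hc$Sq, 0.3, tolerance = 1e-12)
  expect_equal(hc$Sa, 0.3, tolerance = 1e-12)
  expect_equal(hc$Ssk, 0, tolerance = 1e-12)
  expect_equal(hc$Sku, 1, tolerance = 1e-12)
  expect_equal(hc$Sz, 0.6, tolerance = 1e-12)

  flat <- rough(analytic_surface("flat", nx = 16, ny = 16))
  expect_warning(hf <- height_parameters(flat), "constant")
  expect_true(is.nan(hf$Ssk) && is.nan(hf$Sku))
  expect_identical(hf$Sq, 0)
})

test_that("material ratio curve: step curve for checkerboard, straight line for uniform heights, c(0) = Sp", {
  cb <- checkerboard_surf(h = 0.3)
  cv <- material_ratio_curve(cb)
  expect_true(all(diff(cv$c) <= 1e-12))
  expect_true(all(abs(cv$c[cv$p < 49] - 0.3) < 1e-9))
  expect_true(all(abs(cv$c[cv$p > 51] + 0.3) < 1e-9))

  u <- uniform_surf(a = 0.5)
  cu <- material_ratio_curve(u)
  a <- max(abs(u$heights))
  expect_lt(max(abs(cu$c - a * (1 - cu$p / 50))), 2 * 2 * a / length(u$heights) + 0.01)

  g <- grf_surf(32, 32, seed = 4)
  expect_equal(material_ratio_curve(g)$c[1], height_parameters(g)$Sp)
  expect_equal(material_ratio_curve(g)$c[1001], -height_parameters(g)$Sv)
})

test_that("volume parameters: checkerboard step integrals, flat zeros, p >= q rejected", {
  cb <- checkerboard_surf(h = 0.3)
  vp <- volume_parameters(material_ratio_curve(cb))
  expect_equal(vp$Vmp, 0, tolerance = 0.01 * 0.3)
  expect_equal(vp$Vvv, 0, tolerance = 0.01 * 0.3)
  expect_equal(vp$Vmc, 0.3, tolerance = 0.01)
  expect_equal(vp$Vvc, 0.3, tolerance = 0.01)

  # near-flat surface: tiny symmetric ripple, volumes all ~0
  r <- rough(analytic_surface("sinusoid",
                              list(amplitude = 1e-9, wavelength = 8),
                              64, 64, 0.5, 0.5))
  vf <- volume_parameters(material_ratio_curve(r))
  expect_true(all(unlist(vf) >= 0 & unlist(vf) < 1e-8))
  expect_error(volume_parameters(material_ratio_curve(cb), p = 80, q = 10),
               "parameter error")
})

test_that("core parameters: straight Abbott curve gives Sk = 2a, Spk = Svk = 0, Smr1 = 0, Smr2 = 100", {
  u <- uniform_surf(a = 0.5, seed = 6)
  cp <- core_parameters(material_ratio_curve(u))
  expect_equal(cp$Sk, 1.0, tolerance = 0.02)
  expect_lt(cp$Spk, 0.02)
  expect_lt(cp$Svk, 0.02)
  expect_lt(cp$Smr1, 2)
  expect_gt(cp$Smr2, 98)
})

test_that("Gaussian surface has Sk about 2.5 Sq; core parameters are shift-invariant; two-level curve warns", {
  ratios <- vapply(1:3, function(sd) {
    g <- grf_surf(256, 256, sq = 1, corr_len = 3, seed = sd)
    core_parameters(material_ratio_curve(g))$Sk / height_parameters(g)$Sq
  }, numeric(1))
  expect_equal(mean(ratios), 2.5, tolerance = 0.1)

  g <- grf_surf(32, 32, seed = 8)
  cp1 <- core_parameters(material_ratio_curve(g))
  g2 <- g
  g2$heights <- g$heights + 3.7  # monotone shift, bypassing the constructor
  cp2 <- core_parameters(material_ratio_curve(g2))
  expect_equal(cp1[c("Sk", "Spk", "Svk", "Smr1", "Smr2")],
               cp2[c("Sk", "Spk", "Svk", "Smr1", "Smr2")], tolerance = 1e-9)

  cb <- checkerboard_surf(0.3)
  expect_warning(core_parameters(material_ratio_curve(cb)), "degenerate")
})

test_that("Sal matches the Gaussian-ACF closed form and white noise decorrelates within 1.5 grid steps", {
  tau <- 5
  sals <- vapply(1:10, function(sd) {
    g <- grf_surf(256, 256, sq = 1, corr_len = tau, seed = sd, dx = 0.5,
                  dy = 0.5)
    spatial_parameters(g)$Sal
  }, numeric(1))
  expect_equal(mean(sals), tau * sqrt(log(5)), tolerance = 0.10)

  w <- uniform_surf(a = 0.5, nx = 128, ny = 128, seed = 3)
  expect_lte(spatial_parameters(w)$Sal, 1.5 * 0.5)
})

test_that("Str is near zero for 1-D grooves and Sal/Str are undefined-flagged when the ACF never decays", {
  gro <- rough(analytic_surface("sinusoid",
                                list(amplitude = 1, wavelength = 4,
                                     axis = "x"), 128, 128, 0.5, 0.5))
  # constant along y: perfect anisotropy
  expect_lte(spatial_parameters(gro)$Str, 0.05)

  # an ACF that stays above the threshold everywhere flags Sal/Str undefined
  ac <- list(R = matrix(0.9, 17, 17),
             tx = (-8:8) * 0.5, ty = (-8:8) * 0.5)
  expect_warning(sp <- dmta:::sal_str_from_acf(ac, s = 0.2, n_theta = 90,
                                               dx = 0.5, dy = 0.5),
                 "never decays")
  expect_true(is.na(sp$Sal) && is.na(sp$Str))
})

test_that("hybrid parameters: zero on levelled planes, sqrt(2)-1 ratio on unit slopes, sinusoid closed form", {
  pl <- rough(analytic_surface("plane", list(slope_x = 0.3, slope_y = 0.1),
                               32, 32, 0.5, 0.5))
  lev <- remove_form(pl, 1)
  hy0 <- hybrid_parameters(lev)
  expect_lt(hy0$Sdq, 1e-9)
  expect_lt(hy0$Sdr, 1e-9)

  tilt <- analytic_surface("plane", list(slope_x = 1), 64, 64, 0.5, 0.5)
  hy <- hybrid_parameters(tilt)
  expect_equal(hy$Sdq, 1, tolerance = 1e-12)
  expect_equal(hy$Sdr, 100 * (sqrt(2) - 1), tolerance = 1e-12)

  s <- sinusoid_surf(A = 1, lam = 10)
  expect_equal(hybrid_parameters(s)$Sdq, sqrt(2) * pi / 10, tolerance = 0.01)
})

test_that("feature parameters: single bump, egg-box density, flat surface", {
  b <- rough(analytic_surface("bumps",
                              list(bumps = data.frame(x = 16, y = 16, h = 1,
                                                      sigma = 3)),
                              64, 64, 0.5, 0.5))
  fp <- feature_parameters(b)
  expect_equal(fp$Sds * (64 * 0.5)^2, 1, tolerance = 1e-12)
  expect_equal(fp$Ssc, 1 / 9, tolerance = 0.05)

  e <- rough(analytic_surface("eggbox", list(amplitude = 1, wavelength = 8),
                              128, 128, 0.5, 0.5))
  fe <- feature_parameters(e)
  expect_equal(fe$Sds, 2 / 64, tolerance = 0.05)

  flat <- rough(analytic_surface("flat", nx = 16, ny = 16))
  expect_warning(ff <- feature_parameters(flat), "flat")
  expect_identical(ff$Sds, 0)
  expect_true(is.nan(ff$Ssc))
  expect_identical(ff$S5z, 0)
})

test_that("compute_all returns the 23 parameters in canonical order and Sz = Sp + Sv on random fields", {
  g <- grf_surf(48, 48, seed = 10)
  rec <- compute_all(g)
  expect_identical(names(rec), iso_parameter_names())
  expect_identical(ncol(rec), 23L)
  for (sd in 1:25) {
    gg <- grf_surf(16, 16, seed = sd)
    hp <- height_parameters(gg)
    expect_equal(hp$Sz, hp$Sp + hp$Sv, tolerance = 1e-12)
  }
})

test_that("scaling homogeneity: doubling heights doubles length/volume parameters, leaves dimensionless ones", {
  g <- grf_surf(32, 32, sq = 0.4, corr_len = 2, seed = 13)
  g2 <- g
  g2$heights <- 2 * g$heights
  a <- suppressWarnings(compute_all(g))
  b <- suppressWarnings(compute_all(g2))
  linear <- c("Sq", "Sa", "Sp", "Sv", "Sz", "S5z", "Sk", "Spk", "Svk",
              "Vmp", "Vmc", "Vvc", "Vvv")
  for (pm in linear)
    expect_equal(b[[pm]], 2 * a[[pm]], tolerance = 1e-9,
                 label = paste("2x", pm))
  invariant <- c("Ssk", "Sku", "Str", "Smr1", "Smr2", "Sal")
  for (pm in invariant)
    expect_equal(b[[pm]], a[[pm]], tolerance = 1e-6,
                 label = paste("invariant", pm))
  # gradients double
  expect_equal(b$Sdq, 2 * a$Sdq, tolerance = 1e-9)
  # halving
  g3 <- g; g3$heights <- 0.5 * g$heights
  c3 <- suppressWarnings(compute_all(g3))
  expect_equal(c3$Sq, 0.5 * a$Sq, tolerance = 1e-12)
  expect_equal(c3$Sku, a$Sku, tolerance = 1e-9)
})

test_that("cyclic translation of a periodic surface changes no parameter", {
  e <- rough(analytic_surface("eggbox", list(amplitude = 0.5,
                                             wavelength = 8),
                              64, 64, 0.5, 0.5))
  sh <- e
  sh$heights <- e$heights[c(17:64, 1:16), c(33:64, 1:32)]
  a <- suppressWarnings(compute_all(e))
  b <- suppressWarnings(compute_all(sh))
  for (pm in setdiff(iso_parameter_names(), c("Sds", "Ssc", "S5z")))
    expect_equal(b[[pm]], a[[pm]], tolerance = 1e-9, label = pm)
  # feature counts may differ by edge rows entering/leaving the interior
  expect_equal(b$Sds, a$Sds, tolerance = 0.15)
})

test_that("parameter record invariants hold on random Gaussian fields", {
  for (sd in 1:60) {
    g <- grf_surf(16, 16, sq = runif(1, 0.1, 2), corr_len = runif(1, 1, 2),
                  seed = sd)
    r <- suppressWarnings(compute_all(g))
    expect_gte(r$Sq, r$Sa)
    expect_gte(r$Sku, r$Ssk^2 + 1)
    expect_true(r$Smr1 >= 0 && r$Smr1 <= r$Smr2 && r$Smr2 <= 100)
    expect_true(all(c(r$Vmp, r$Vmc, r$Vvc, r$Vvv) >= 0))
    expect_gte(r$Sdr, 0)
    if (!is.na(r$Str)) expect_true(r$Str >= 0 && r$Str <= 1)
    cv <- material_ratio_curve(g)
    expect_true(all(diff(cv$c) <= 1e-12))
  }
})
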