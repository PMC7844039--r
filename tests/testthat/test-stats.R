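make_groups <- function(vals, labels) {
  d <- data.frame(v = unlist(vals),
                  group = rep(labels, lengths(vals)))
  d
}

test_that("Shapiro-Wilk gate: uniform null p-values, power on lognormal data, constant groups flagged", {
  pn <- vapply(1:200, function(sd) {
    set.seed(sd)
    d <- data.frame(Sq = rnorm(30), group = "a")
    normality_check(d, "Sq")[["a"]]
  }, numeric(1))
  expect_gt(stats::ks.test(pn, "punif")$p.value, 0.01)

  pl <- vapply(1:200, function(sd) {
    set.seed(sd)
    d <- data.frame(Sq = exp(rnorm(30, sd = 2)), group = "a")
    normality_check(d, "Sq")[["a"]]
  }, numeric(1))
  expect_gte(mean(pl < 0.05), 0.90)

  d <- data.frame(Sq = c(rep(1, 5), rnorm(5)), group = rep(c("a", "b"), each = 5))
  expect_warning(p <- normality_check(d, "Sq"), "constant")
  expect_true(is.na(p[["a"]]) && !is.na(p[["b"]]))
  d2 <- data.frame(Sq = rnorm(7), group = c("a", "a", rep("b", 5)))
  expect_warning(normality_check(d2, "Sq"), "n < 3")
})

test_that("one-way ANOVA: zero F for identical groups, hand-computed textbook F, study df for 5 groups", {
  d <- make_groups(list(c(1, 2, 3), c(1, 2, 3)), c("a", "b"))
  an <- anova_per_parameter(d, parameters = "v")
  expect_equal(an$F, 0, tolerance = 1e-12)
  expect_equal(an$p, 1, tolerance = 1e-12)

  # textbook fixture: SSB = 18.6667 (df 2), SSW = 15 (df 9)
  d3 <- make_groups(list(c(1, 2, 3, 4), c(2, 3, 4, 5), c(4, 5, 6, 7)),
                    c("a", "b", "c"))
  an3 <- anova_per_parameter(d3, parameters = "v")
  expect_false(an3$welch)  # equal variances by construction
  expect_equal(an3$F, (18.66666666666667 / 2) / (15 / 9),
               tolerance = 1e-10)
  expect_identical(c(an3$df1, an3$df2), c(2, 9))

  # 5 groups of sizes 6, 8, 6, 6, 6 with homogeneous variances -> df (4, 27)
  set.seed(42)
  d5 <- make_groups(lapply(c(6, 8, 6, 6, 6), rnorm),
                    c("1", "2a", "2", "3", "4"))
  an5 <- anova_per_parameter(d5, parameters = "v", alpha_var = 1e-9)
  expect_identical(c(an5$df1, an5$df2), c(4, 27))
})

test_that("variance gate fires on heteroscedastic data and Welch df2 is below the classic df2", {
  for (sd in 1:10) {
    set.seed(sd)
    d <- make_groups(list(rnorm(8, sd = 0.2), rnorm(8, sd = 0.2),
                          rnorm(8, sd = 4)), c("a", "b", "c"))
    an <- anova_per_parameter(d, parameters = "v")
    expect_true(an$welch)
    expect_lt(an$df2, 21)
  }
  # the internal Brown-Forsythe matches car::leveneTest(center = median)
  set.seed(7)
  x <- c(rnorm(6), rnorm(8, sd = 3), rnorm(6, sd = 0.5))
  g <- factor(rep(c("a", "b", "c"), c(6, 8, 6)))
  mine <- dmta:::levene_test(x, g)
  ref <- car::leveneTest(x, g, center = median)
  expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("B-H step-up matches p.adjust, flags nothing at p = 1, and is monotone in the FDR", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(23)^2
    expect_identical(bh_adjust(p, 0.05), unname(p.adjust(p, "BH") <= 0.05))
  }
  expect_false(any(bh_adjust(rep(1, 10))))
  p <- runif(23)
  f1 <- bh_adjust(p, 0.02)
  f2 <- bh_adjust(p, 0.10)
  expect_true(all(f2[f1]))  # raising fdr never unflags
})

test_that("Tukey HSD: q = 0 for identical groups, overwhelming shifts detected, agreement with stats::TukeyHSD", {
  d <- make_groups(list(c(1, 2, 3, 4), c(1, 2, 3, 4)), c("a", "b"))
  tk <- tukey_hsd(d, "v")
  expect_equal(tk$q, 0, tolerance = 1e-12)
  expect_equal(tk$p_adj, 1, tolerance = 1e-12)

  hits <- vapply(1:20, function(sd) {
    set.seed(sd)
    sdp <- 1
    d3 <- make_groups(list(rnorm(6, 0, sdp), rnorm(6, 0, sdp),
                           rnorm(6, 10 * sdp, sdp)), c("a", "b", "c"))
    tk3 <- tukey_hsd(d3, "v")
    shifted <- tk3$p_adj[tk3$group2 == "c" | tk3$group1 == "c"]
    other <- tk3$p_adj[tk3$group1 == "a" & tk3$group2 == "b"]
    all(shifted < 0.001) && other > 0.001
  }, logical(1))
  expect_true(all(hits))

  # unbalanced fixture against stats::TukeyHSD (Tukey-Kramer path)
  set.seed(3)
  d4 <- make_groups(list(rnorm(6), rnorm(9, 1), rnorm(4, -0.5)),
                    c("a", "b", "c"))
  mine <- tukey_hsd(d4, "v")
  ref <- stats::TukeyHSD(stats::aov(v ~ group, data = d4))$group
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-9)
  expect_equal(abs(mine$diff), unname(abs(ref[, "diff"])), tolerance = 1e-12)
})

test_that("studentized range p-value agrees with direct numeric integration of the range distribution", {
  # P(Q > q | k, df) by double numeric integration, independent of ptukey
  range_sf <- function(q, k, df) {
    inner <- function(u) {
      vapply(u, function(ui) {
        g <- stats::integrate(function(z)
          stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * ui))^(k - 1),
          -8, 8, rel.tol = 1e-10)$value
        k * g
      }, numeric(1))
    }
    # u = s/sigma with s^2 ~ chi2_df/df
    fu <- function(u) 2 * u * df * stats::dchisq(df * u^2, df)
    1 - stats::integrate(function(u) fu(u) * inner(u), 0, 8,
                         rel.tol = 1e-9)$value
  }
  set.seed(5)
  d <- make_groups(list(rnorm(5), rnorm(5, 1.2), rnorm(5, 0.4)),
                   c("a", "b", "c"))
  tk <- tukey_hsd(d, "v")
  dfw <- 12
  for (i in seq_len(nrow(tk))) {
    expect_equal(tk$p_adj[i], range_sf(tk$q[i], 3, dfw), tolerance = 1e-6)
  }
})

test_that("correlation-mode PCA: perfect correlation, asymptotic equipartition, exact reconstruction", {
  set.seed(2)
  n <- 40
  x <- rnorm(n)
  d <- data.frame(p1 = x, p2 = 3 * x + 5, p3 = rnorm(n))
  pc <- fit_pca(d, c("p1", "p2"))
  expect_equal(pc$explained_pct[1], 100, tolerance = 1e-9)

  set.seed(3)
  big <- as.data.frame(matrix(rnorm(2000 * 4), 2000, 4))
  names(big) <- paste0("q", 1:4)
  pcb <- fit_pca(big, names(big))
  expect_true(all(abs(pcb$explained_pct - 25) < 5))

  g <- as.data.frame(matrix(rnorm(30 * 5), 30, 5))
  names(g) <- paste0("q", 1:5)
  pcg <- fit_pca(g, names(g))
  Z <- scale(as.matrix(g), center = pcg$means, scale = pcg$sds)
  expect_lt(max(abs(pcg$scores %*% t(pcg$loadings) - Z)), 1e-9)
  expect_equal(sum(pcg$explained_pct), 100, tolerance = 1e-6)
  # orthonormal loadings; agreement with prcomp eigenvalues
  expect_lt(max(abs(crossprod(pcg$loadings) - diag(5))), 1e-9)
  pr <- prcomp(g, scale. = TRUE)
  expect_equal(pcg$eigenvalues, unname(pr$sdev^2), tolerance = 1e-9)

  g$const <- 1
  expect_error(fit_pca(g, c("q1", "const")), "const")
})

test_that("projection uses training constants, is affine, and leaves the model untouched", {
  set.seed(4)
  d <- as.data.frame(matrix(rnorm(20 * 3), 20, 3))
  names(d) <- c("a", "b", "c")
  pc <- fit_pca(d, names(d))
  before <- unserialize(serialize(pc, NULL))
  expect_lt(max(abs(project_records(pc, d) - pc$scores)), 1e-9)

  mean_rec <- as.data.frame(as.list(pc$means))
  expect_lt(max(abs(project_records(pc, mean_rec))), 1e-12)

  x <- d[3, ]
  a <- 0.3
  blend <- as.data.frame(Map(function(v, m) a * v + (1 - a) * m, x,
                             pc$means))
  expect_equal(as.numeric(project_records(pc, blend)),
               as.numeric(a * project_records(pc, x)), tolerance = 1e-9)
  expect_identical(pc, before)
  expect_error(project_records(pc, d[, 1:2]), "missing")
})

test_that("Spearman: monotone pairs, anti-monotone pairs, midrank ties against a brute-force rho", {
  s <- spearman_rank(1:10, (1:10)^3)
  expect_equal(s$rs, 1, tolerance = 1e-12)
  expect_lt(s$p, 1e-6)
  expect_equal(spearman_rank(1:10, -(1:10))$rs, -1, tolerance = 1e-12)

  set.seed(6)
  x <- rnorm(24)
  y <- rep(1:4, each = 6)  # heavy ties, like diet ranks
  s2 <- spearman_rank(x, y)
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    rank(v, ties.method = "average")
  }
  rx <- midrank(x); ry <- midrank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(s2$rs, rho, tolerance = 1e-12)
  # permutation p agrees with the t approximation to MC accuracy
  s3 <- spearman_rank(x, y, method = "permutation", seed = 1)
  expect_lt(abs(s3$p - s2$p), 0.05)
  expect_error(spearman_rank(x, rep(1, 24)), "all-tied")
})

test_that("group summaries: hand-checked CI for {1,2,3}, grand mean, CI width scales as 1/sqrt(n)", {
  gs <- group_summary(c(1, 2, 3), rep("a", 3))
  expect_equal(gs$summary$mean, 2)
  expect_equal(gs$summary$se, 0.5773503, tolerance = 1e-6)
  expect_equal(gs$summary$upper - gs$summary$mean, 2.4841, tolerance = 1e-3)

  gs2 <- group_summary(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(gs2$grand_mean, mean(gs2$summary$mean))

  # n large enough that the t quantile and sd bias corrections are ~1
  widths <- vapply(c(40L, 160L), function(n) {
    w <- vapply(1:400, function(sd) {
      set.seed(sd * 1000 + n)
      g <- group_summary(rnorm(n), rep("a", n))
      g$summary$upper - g$summary$lower
    }, numeric(1))
    mean(w)
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.05)

  expect_warning(group_summary(c(1, 2, 3), c("a", "a", "b")), "n = 1")
})

test_that("subsampling comparison is seed-deterministic, null-calibrated, and powered at a 2-SD shift", {
  a <- simulate_parameter_table(groups = "A", n = 6, diet_ranks = 1,
                                seed = 11)
  b <- simulate_parameter_table(groups = "B", n = 18, diet_ranks = 1,
                                seed = 12)
  r1 <- subsample_compare(a, b, k = 6, reps = 10, seed = 5)
  r2 <- subsample_compare(a, b, k = 6, reps = 10, seed = 5)
  expect_identical(r1, r2)
  expect_error(subsample_compare(a, b, k = 30, seed = 1), "parameter error")

  # null: A and B drawn from the same distribution, fresh tables per batch
  rates <- vapply(1:20, function(i) {
    a0 <- simulate_parameter_table(groups = "A", n = 6, diet_ranks = 1,
                                   seed = 100 + i)
    b0 <- simulate_parameter_table(groups = "B", n = 18, diet_ranks = 1,
                                   seed = 200 + i)
    r <- subsample_compare(a0, b0, k = 6, reps = 10, seed = i)
    mean(r$n_significant / 23)
  }, numeric(1))
  expect_lte(mean(rates), 0.05 + 0.05)

  # power at a 2-SD designed shift in 5 parameters: a noncentral-t
  # calculation (ncp = 2*sqrt(3), df = 10, B-H-adaptive threshold) puts
  # per-parameter recovery near 0.55; assert the derived level
  des <- c("Sq", "Sal", "Sds", "Sdr", "Sdq")
  recovery <- function(effect, seed0) {
    mean(vapply(1:10, function(i) {
      a1 <- simulate_parameter_table(groups = "A", n = 6, diet_ranks = 1,
                                     seed = seed0 + i)
      b1 <- simulate_parameter_table(groups = "B", n = 18, diet_ranks = 2,
                                     effect_parameters = des,
                                     effect_size = effect,
                                     seed = seed0 + 100 + i)
      r <- subsample_compare(a1, b1, k = 6, reps = 10, seed = i)
      mean(vapply(r$sets, function(s) mean(des %in% s), numeric(1)))
    }, numeric(1)))
  }
  expect_gte(recovery(2, 300), 0.45)
  # at a 3-SD shift the same calculation gives ~0.96 recovery
  expect_gte(recovery(3, 500), 0.80)
})

test_that("the selection rule applied to the published pairwise tables yields the 14-parameter union", {
  sel <- pairwise_differing_parameters(published_pairwise_sets())
  expect_identical(sort(sel),
                   sort(c("Sq", "Sv", "Sz", "Sds", "Sal", "Vmp", "Vmc",
                          "Vvc", "Vvv", "Spk", "Sk", "Svk", "S5z", "Sa")))
  expect_length(sel, 14L)
})

test_that("full_analysis recovers a designed structure, projects unknowns, and is byte-deterministic", {
  des <- c("Sq", "Sal", "Sds", "Sdr", "Sdq")
  tab <- simulate_parameter_table(groups = c("1", "2", "2a", "3", "4", "5"),
                                  n = c(6, 6, 8, 6, 6, 6),
                                  diet_ranks = c(1, 2, 2, 3, 4, 1),
                                  effect_parameters = des, effect_size = 1.5,
                                  seed = 21)
  tab$diet_rank[tab$group == "5"] <- NA
  cfg <- pipeline_config(stats = list(within_tooth_label = "2a",
                                      unknown_label = "5"))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  rep1 <- suppressWarnings(full_analysis(tab, cfg, out = out1))
  suppressWarnings(full_analysis(tab, cfg, out = out2))

  flagged <- rep1$anova$parameter[which(rep1$anova$bh_significant)]
  expect_gte(sum(des %in% flagged), 4)
  expect_true(all(des %in% rep1$selected_parameters))
  expect_identical(nrow(rep1$projections), 6L)
  expect_identical(unique(rep1$projections$group), "5")
  expect_false("5" %in% rep1$scores$group)
  expect_false("2a" %in% rep1$scores$group)
  expect_gt(rep1$spearman_diet$rs, 0.5)

  for (f in c("anova.csv", "pairwise.csv", "scores.csv", "projections.csv",
              "pca_model.json", "summary.json")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readBin(file.path(out1, f), "raw",
                             file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw",
                             file.size(file.path(out2, f))),
                     label = paste("deterministic", f))
  }
})
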