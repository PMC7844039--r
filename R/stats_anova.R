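#' Per-group Shapiro-Wilk normality check
#'
#' Advisory check that each group's values for one parameter are compatible
#' with a normal distribution; the downstream pipeline stays parametric
#' regardless (the study design assumes approximate normality of texture
#' parameters), so these p-values are reported, not acted on.
#'
#' @param table a [specimen_table()] (or data frame with a `group` column).
#' @param parameter ISO symbol of the column to test.
#' @param group_field grouping column name, default `"group"`.
#' @return named numeric vector of per-group p-values; groups with n < 3 or
#'   zero variance are `NA` with a warning.
#' @export
normality_check <- function(table, parameter, group_field = "group") {
  g <- as.character(table[[group_field]])
  x <- table[[parameter]]
  vapply(split(x, g), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L) {
      warning("group with n < 3 skipped in normality check")
      return(NA_real_)
    }
    if (stats::sd(v) == 0) {
      warning("constant group: Shapiro-Wilk undefined")
      return(NA_real_)
    }
    stats::shapiro.test(v)$p.value
  }, numeric(1))
}

# Brown-Forsythe (median-centered Levene) via classic one-way ANOVA of
# absolute deviations from group medians; center = "mean" gives the
# mean-centered original.
levene_test <- function(x, g, center = c("median", "mean")) {
  center <- match.arg(center)
  g <- factor(g)
  ctr <- tapply(x, g, if (center == "median") stats::median else mean)
  d <- abs(x - ctr[g])
  if (stats::sd(d) == 0) return(list(statistic = 0, p.value = 1))
  ft <- stats::oneway.test(d ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = ft$p.value)
}

#' Variance-gated one-way ANOVA for every texture parameter
#'
#' For each parameter: Bartlett's test and a Brown-Forsythe Levene test are
#' run on the group variances; if either rejects homogeneity at
#' `alpha_var`, Welch's ANOVA (Satterthwaite denominator df) is used,
#' otherwise the classic one-way ANOVA. A Benjamini-Hochberg column flags
#' the parameters surviving FDR control across the family of tests.
#'
#' @param table a [specimen_table()].
#' @param group_field grouping column, default `"group"`.
#' @param alpha_var homogeneity-gate level, default 0.05.
#' @param fdr false discovery rate for the B-H column, default 0.05.
#' @param parameters columns to test; default all 23 ISO parameters.
#' @param levene_center `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @return data frame with one row per parameter: `parameter`, `F`, `df1`,
#'   `df2` (fractional for Welch), `p`, `welch` (logical),
#'   `bartlett_p`, `levene_p`, `bh_significant`.
#' @export
anova_per_parameter <- function(table, group_field = "group",
                                alpha_var = 0.05, fdr = 0.05,
                                parameters = iso_parameter_names(),
                                levene_center = "median") {
  g <- factor(as.character(table[[group_field]]))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  rows <- lapply(parameters, function(pm) {
    x <- table[[pm]]
    if (all(tapply(x, g, stats::sd) == 0)) {
      warning("degenerate parameter ", pm, ": zero within-group variance")
      return(data.frame(parameter = pm, F = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p = NA_real_, welch = NA,
                        bartlett_p = NA_real_, levene_p = NA_real_))
    }
    bt <- stats::bartlett.test(x, g)$p.value
    lv <- levene_test(x, g, center = levene_center)$p.value
    welch <- isTRUE(bt < alpha_var) || isTRUE(lv < alpha_var)
    ft <- stats::oneway.test(x ~ g, var.equal = !welch)
    data.frame(parameter = pm, F = unname(ft$statistic),
               df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
               p = ft$p.value, welch = welch,
               bartlett_p = bt, levene_p = lv)
  })
  out <- do.call(rbind, rows)
  out$bh_significant <- bh_adjust(out$p, fdr = fdr)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up significance flags
#'
#' The standard step-up procedure: sort the m p-values ascending, find the
#' largest k with `p(k) <= k * fdr / m`, and flag those k smallest
#' p-values. Flags are monotone in `fdr`. `NA` p-values are never flagged
#' and do not count towards m.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param fdr target false discovery rate, default 0.05.
#' @return logical vector of the same length.
#' @export
bh_adjust <- function(pvalues, fdr = 0.05) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  flags <- rep(FALSE, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (!m) return(flags)
  p <- pvalues[ok]
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * fdr / m)
  if (length(k)) flags[ok[o[seq_len(max(k))]]] <- TRUE
  flags
}

#' Tukey HSD pairwise comparisons for one parameter
#'
#' Tukey-Kramer studentized-range tests of all group pairs (exact for
#' balanced designs, Kramer-adjusted standard errors for unequal n), using
#' the pooled within-group variance of a classic one-way fit. Applied after
#' either ANOVA path; a warning notes when the variance gate had fired,
#' since the pooled-variance assumption is then questionable.
#'
#' @param table a [specimen_table()].
#' @param parameter ISO symbol of the column to test.
#' @param group_field grouping column, default `"group"`.
#' @param alpha pairwise significance level, default 0.05.
#' @param warn_heteroscedastic warn when Bartlett rejects homogeneity.
#' @return data frame of class `pairwise_result`: `group1`, `group2`,
#'   `diff` (mean difference), `q` (studentized range statistic),
#'   `p_adj`, `significant`.
#' @export
tukey_hsd <- function(table, parameter, group_field = "group", alpha = 0.05,
                      warn_heteroscedastic = TRUE) {
  g <- factor(as.character(table[[group_field]]))
  x <- table[[parameter]]
  ns <- tapply(x, g, length)
  if (any(ns < 2L)) {
    warning("singleton group(s) excluded from pairwise tests: ",
            paste(names(ns)[ns < 2L], collapse = ", "))
    keep <- g %in% names(ns)[ns >= 2L]
    x <- x[keep]; g <- droplevels(g[keep])
    ns <- tapply(x, g, length)
  }
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups with n >= 2", call. = FALSE)
  means <- tapply(x, g, mean)
  dfw <- length(x) - k
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  s2 <- ssw / dfw
  if (s2 <= 0) stop("pooled within-group variance is zero", call. = FALSE)
  if (warn_heteroscedastic && k >= 2L) {
    bt <- stats::bartlett.test(x, g)$p.value
    if (isTRUE(bt < 0.05))
      warning("unequal group variances (Bartlett p = ",
              signif(bt, 3), "); Tukey HSD assumes a pooled variance")
  }
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    n1 <- ns[pr[1]]; n2 <- ns[pr[2]]
    d <- means[pr[2]] - means[pr[1]]
    se <- sqrt(s2 / 2 * (1 / n1 + 1 / n2))  # Tukey-Kramer
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], diff = unname(d),
               q = unname(q), p_adj = unname(p))
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_adj < alpha
  out$parameter <- parameter
  rownames(out) <- NULL
  class(out) <- c("pairwise_result", "data.frame")
  out
}

#' Tie-corrected Spearman rank correlation
#'
#' Spearman's rho via Pearson correlation of midranks (so ties in either
#' variable are handled), with a t-approximation p-value
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df) by default, or a
#' permutation p-value with an explicit seed.
#'
#' @param scores numeric vector (e.g. PC1 scores).
#' @param covariate ordinal or continuous covariate (diet rank, length);
#'   ties allowed. Pairs with `NA` in either vector are dropped.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed RNG seed for the permutation method.
#' @return list with `rs`, `p`, `n`, `method`.
#' @export
spearman_rank <- function(scores, covariate, method = c("t", "permutation"),
                          n_perm = 9999L, seed = 1L) {
  method <- match.arg(method)
  ok <- !is.na(scores) & !is.na(covariate)
  x <- scores[ok]; y <- covariate[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  if (length(unique(y)) < 2L || length(unique(x)) < 2L)
    stop("all-tied variable: Spearman correlation undefined", call. = FALSE)
  rs <- stats::cor(rank(x), rank(y))
  if (method == "t") {
    if (abs(rs) >= 1) {
      p <- 0
    } else {
      tstat <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    rx <- rank(x)
    set.seed(seed)
    null <- replicate(n_perm, stats::cor(rx, rank(sample(y))))
    p <- (1 + sum(abs(null) >= abs(rs) - 1e-12)) / (n_perm + 1)
  }
  list(rs = rs, p = p, n = n, method = method)
}

#' Per-group mean, standard error and 95% confidence interval
#'
#' @param scores numeric vector.
#' @param groups group labels, same length.
#' @param conf confidence level, default 0.95 (t-based intervals).
#' @return list with `summary` (data frame: group, n, mean, se, lower,
#'   upper) and `grand_mean` (mean over all records).
#' @export
group_summary <- function(scores, groups, conf = 0.95) {
  g <- factor(as.character(groups))
  rows <- lapply(levels(g), function(lv) {
    v <- scores[g == lv]
    n <- length(v)
    m <- mean(v)
    if (n < 2L) {
      warning("group ", lv, " has n = 1: no confidence interval")
      return(data.frame(group = lv, n = n, mean = m, se = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    }
    se <- stats::sd(v) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    data.frame(group = lv, n = n, mean = m, se = se,
               lower = m - tq * se, upper = m + tq * se)
  })
  list(summary = do.call(rbind, rows), grand_mean = mean(scores))
}
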