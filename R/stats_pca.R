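#' Principal components analysis on correlations
#'
#' Standardizes each selected parameter to zero mean and unit standard
#' deviation over the training records, eigendecomposes the correlation
#' matrix, and stores the standardization constants so new records
#' (e.g. a specimen of unknown diet) can be projected into the same space
#' with [project_records()]. Components are ordered by decreasing
#' eigenvalue; each loading column is signed so its largest-magnitude entry
#' is positive (a deterministic convention -- published figures may show
#' either sign).
#'
#' @param table a [specimen_table()] (training records only).
#' @param parameters character vector of parameter columns to use.
#' @return object of class `dmta_pca`: list with `parameters`, `means`,
#'   `sds`, `loadings` (parameter x component), `eigenvalues`,
#'   `explained_pct`, `scores` (training-record x component).
#' @export
fit_pca <- function(table, parameters) {
  miss <- setdiff(parameters, names(table))
  if (length(miss))
    stop("missing parameter column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(as.data.frame(table)[, parameters, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 records", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant parameter(s): ",
         paste(parameters[sdv == 0], collapse = ", "), call. = FALSE)
  Z <- scale(X, center = mu, scale = sdv)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  V <- eg$vectors
  # sign convention: largest |loading| entry of each component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- parameters
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  ev <- pmax(eg$values, 0)
  structure(list(
    parameters = parameters, means = mu, sds = sdv, loadings = V,
    eigenvalues = ev, explained_pct = ev / sum(ev) * 100,
    scores = Z %*% V), class = "dmta_pca")
}

#' @export
print.dmta_pca <- function(x, ...) {
  cat(sprintf("<dmta_pca> %d parameters, %d training records\n",
              length(x$parameters), nrow(x$scores)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$explained_pct[1], x$explained_pct[2]))
  invisible(x)
}

#' Project new records into a fitted PCA
#'
#' Standardizes the new records with the model's training means and
#' standard deviations (never the new data's own), then multiplies by the
#' training loadings. The fitted model is not modified.
#'
#' @param model a [fit_pca()] model.
#' @param records data frame containing all model parameters.
#' @return matrix of component scores (records x components).
#' @export
project_records <- function(model, records) {
  stopifnot(inherits(model, "dmta_pca"))
  miss <- setdiff(model$parameters, names(records))
  if (length(miss))
    stop("records missing model parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(as.data.frame(records)[, model$parameters, drop = FALSE])
  Z <- scale(X, center = model$means, scale = model$sds)
  Z %*% model$loadings
}

#' @export
predict.dmta_pca <- function(object, newdata, ...) {
  project_records(object, newdata)
}

#' Subsampling comparison of two cohorts
#'
#' Repeatedly draws `k` records without replacement from `tableB`, compares
#' them with all of `tableA` by the variance-gated ANOVA + Benjamini-
#' Hochberg pipeline ([anova_per_parameter()]), and collects the set of
#' flagged parameters per repetition. This mirrors comparing a fixed
#' cohort of shed aquarium teeth with random draws of wild teeth.
#'
#' @param tableA,tableB [specimen_table()]s (or data frames with the ISO
#'   parameter columns).
#' @param k subsample size from `tableB`, default 6.
#' @param reps repetitions, default 10.
#' @param seed RNG seed (explicit; same seed gives identical output).
#' @param fdr false discovery rate, default 0.05.
#' @param parameters columns to test; default all 23.
#' @return list with `sets` (per-rep character vectors of flagged
#'   parameters), `counts` (named counts per parameter across reps),
#'   `n_significant` (per-rep set sizes).
#' @export
subsample_compare <- function(tableA, tableB, k = 6L, reps = 10L, seed,
                              fdr = 0.05,
                              parameters = iso_parameter_names()) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (k > nrow(tableB))
    stop("parameter error: k = ", k, " exceeds |tableB| = ", nrow(tableB),
         call. = FALSE)
  set.seed(seed)
  A <- as.data.frame(tableA)[, parameters, drop = FALSE]
  B <- as.data.frame(tableB)[, parameters, drop = FALSE]
  sets <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sample(nrow(B), k)
    d <- rbind(cbind(A, .grp = "A"), cbind(B[idx, , drop = FALSE],
                                           .grp = "B"))
    an <- anova_per_parameter(d, group_field = ".grp", fdr = fdr,
                              parameters = parameters)
    sets[[r]] <- an$parameter[which(an$bh_significant)]
  }
  counts <- table(factor(unlist(sets), levels = parameters))
  list(sets = sets, counts = counts,
       n_significant = vapply(sets, length, integer(1)))
}

#' Parameters exhibiting any significant pairwise difference
#'
#' The PCA parameter-selection rule of the discrimination pipeline: the
#' union, over parameters, of those with at least one significant Tukey
#' HSD pair. Can also be applied to pre-encoded published pairwise tables
#' (a list of per-pair character vectors).
#'
#' @param pairwise either a list of [tukey_hsd()] results or a list of
#'   character vectors of differing parameters per group pair.
#' @return sorted character vector of parameter symbols.
#' @export
pairwise_differing_parameters <- function(pairwise) {
  syms <- unlist(lapply(pairwise, function(el) {
    if (is.data.frame(el)) unique(el$parameter[el$significant]) else el
  }))
  sort(unique(syms))
}

#' Full dietary-discrimination analysis of a specimen table
#'
#' The complete statistics stage: per-parameter variance-gated ANOVA with
#' a Benjamini-Hochberg column; Tukey HSD pairwise matrices; selection of
#' the parameters with significant pairwise differences; correlation-mode
#' PCA of those parameters over the training specimens (optionally
#' excluding a within-tooth repeat group and always excluding the unknown
#' specimen); projection of the unknown specimen's records; Spearman rank
#' correlations of PC1 scores against diet rank and body length; and
#' per-group PC1 summaries.
#'
#' @param table a [specimen_table()].
#' @param config a [pipeline_config()] or list; honored stats settings:
#'   `group_field`, `fdr`, `alpha_var`, `within_tooth_label`,
#'   `unknown_label`, `include_within_tooth_in_anova`, `pca_parameters`
#'   (NULL = the Tukey-derived union).
#' @param out optional directory; when given, writes `anova.csv`,
#'   `pairwise.csv`, `scores.csv`, `projections.csv`, `pca_model.json`
#'   and `summary.json` there.
#' @return list of class `dmta_report`: `anova`, `pairwise` (named list of
#'   [tukey_hsd()] frames), `selected_parameters`, `pca`, `scores` (data
#'   frame with group labels), `projections` (or NULL), `spearman_diet`,
#'   `spearman_length`, `group_summary`, `pc1_anova`.
#' @export
full_analysis <- function(table, config = pipeline_config(), out = NULL) {
  cfg <- config$stats %||% config
  gf <- cfg$group_field %||% "group"
  fdr <- cfg$fdr %||% 0.05
  alpha_var <- cfg$alpha_var %||% 0.05
  wt <- cfg$within_tooth_label %||% NA_character_
  unk <- cfg$unknown_label %||% NA_character_
  incl_wt <- cfg$include_within_tooth_in_anova %||% TRUE

  tab <- as.data.frame(table)
  g <- as.character(tab[[gf]])
  known <- if (!is.na(unk)) tab[g != unk, , drop = FALSE] else tab
  anova_tab <- if (!incl_wt && !is.na(wt)) {
    known[as.character(known[[gf]]) != wt, , drop = FALSE]
  } else known

  an <- anova_per_parameter(anova_tab, group_field = gf,
                            alpha_var = alpha_var, fdr = fdr)
  pw <- lapply(iso_parameter_names(), function(pm)
    suppressWarnings(tukey_hsd(anova_tab, pm, group_field = gf)))
  names(pw) <- iso_parameter_names()
  sel <- cfg$pca_parameters %||% pairwise_differing_parameters(pw)
  if (length(sel) < 2L)
    stop("fewer than 2 parameters show pairwise differences; no PCA",
         call. = FALSE)

  # PCA training set: known-diet specimens, within-tooth repeats excluded
  train <- known
  if (!is.na(wt)) train <- train[as.character(train[[gf]]) != wt, ,
                                 drop = FALSE]
  pca <- fit_pca(train, sel)
  scores <- data.frame(sample_id = train$sample_id,
                       group = as.character(train[[gf]]),
                       pca$scores, check.names = FALSE)

  projections <- NULL
  if (!is.na(unk) && any(g == unk)) {
    urec <- tab[g == unk, , drop = FALSE]
    projections <- data.frame(sample_id = urec$sample_id, group = unk,
                              project_records(pca, urec),
                              check.names = FALSE)
  }

  sp_diet <- sp_len <- NULL
  if ("diet_rank" %in% names(train) && any(!is.na(train$diet_rank)))
    sp_diet <- spearman_rank(scores$PC1, train$diet_rank)
  if ("total_length" %in% names(train) && any(!is.na(train$total_length)))
    sp_len <- spearman_rank(scores$PC1, train$total_length)

  # ANOVA of PC1 scores across all groups with scores (projection included)
  all_scores <- rbind(scores[, c("sample_id", "group", "PC1")],
                      if (!is.null(projections))
                        projections[, c("sample_id", "group", "PC1")])
  pc1_an <- stats::oneway.test(PC1 ~ group, data = all_scores,
                               var.equal = TRUE)
  gs <- group_summary(all_scores$PC1, all_scores$group)

  rep <- structure(list(
    anova = an, pairwise = pw, selected_parameters = sel, pca = pca,
    scores = scores, projections = projections,
    spearman_diet = sp_diet, spearman_length = sp_len,
    group_summary = gs,
    pc1_anova = list(F = unname(pc1_an$statistic),
                     df1 = unname(pc1_an$parameter[1]),
                     df2 = unname(pc1_an$parameter[2]),
                     p = pc1_an$p.value)), class = "dmta_report")

  if (!is.null(out)) write_report(rep, out)
  rep
}

write_report <- function(rep, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$anova, file.path(out, "anova.csv"), row.names = FALSE)
  pwall <- do.call(rbind, rep$pairwise)
  utils::write.csv(pwall, file.path(out, "pairwise.csv"), row.names = FALSE)
  utils::write.csv(rep$scores, file.path(out, "scores.csv"),
                   row.names = FALSE)
  if (!is.null(rep$projections))
    utils::write.csv(rep$projections, file.path(out, "projections.csv"),
                     row.names = FALSE)
  model <- rep$pca
  jsonlite::write_json(list(
    parameters = model$parameters, means = unname(model$means),
    sds = unname(model$sds), loadings = unname(model$loadings),
    explained_pct = model$explained_pct), file.path(out, "pca_model.json"),
    digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(list(
    selected_parameters = rep$selected_parameters,
    spearman_diet = rep$spearman_diet, spearman_length = rep$spearman_length,
    pc1_anova = rep$pc1_anova,
    group_summary = rep$group_summary$summary,
    grand_mean = rep$group_summary$grand_mean),
    file.path(out, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(out)
}

#' @export
print.dmta_report <- function(x, ...) {
  nsig <- sum(x$anova$bh_significant, na.rm = TRUE)
  cat("<dmta_report>\n")
  cat(sprintf("  ANOVA: %d/%d parameters B-H significant: %s\n",
              nsig, nrow(x$anova),
              paste(x$anova$parameter[which(x$anova$bh_significant)],
                    collapse = ", ")))
  cat(sprintf("  PCA on %d pairwise-differing parameters; PC1 %.1f%%\n",
              length(x$selected_parameters), x$pca$explained_pct[1]))
  if (!is.null(x$spearman_diet))
    cat(sprintf("  PC1 vs diet rank: rs = %.4f, p = %.4g\n",
                x$spearman_diet$rs, x$spearman_diet$p))
  invisible(x)
}
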