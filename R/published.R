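#' Published ANOVA results for the sand tiger shark microwear dataset
#'
#' The per-parameter ANOVA table of the *Carcharias taurus*
#' dietary-discrimination study that this pipeline reproduces: F statistic,
#' p-value, degrees of freedom, whether the Welch path was taken
#' (fractional df2), and the Benjamini-Hochberg flag at FDR 0.05. Useful as
#' a worked input for [bh_adjust()] and for checking the pipeline's gate
#' logic without the deposited raw data.
#'
#' @return data frame with columns `parameter`, `F`, `p`, `df1`, `df2`,
#'   `welch`, `bh_significant`, in the canonical parameter order.
#' @export
published_anova_table <- function() {
  d <- data.frame(
    parameter = iso_parameter_names(),
    F = c(2.7789, 2.0122, 5.5796, 1.6849, 1.8052, 1.1382, 18.8940, 3.5685,
          8.8923, 7.1046, 3.8799, 7.3744, 2.0855, 2.5595, 2.4292, 3.1651,
          1.9043, 2.4630, 3.2954, 1.7856, 4.5516, 1.2853, 2.6142),
    p = c(0.0781, 0.1596, 0.0117, 0.1825, 0.1926, 0.3873, 0.0001, 0.0393,
          0.0001, 0.0037, 0.0289, 0.0030, 0.1505, 0.0918, 0.1042, 0.0569,
          0.1802, 0.1001, 0.0527, 0.1609, 0.0185, 0.3350, 0.0888),
    df1 = 4,
    df2 = c(11.558, 11.457, 10.413, 27, 12.021, 11.301, 27, 11.806, 27,
            11.855, 12.433, 12.069, 11.143, 12.24, 12.147, 11.334, 10.958,
            12.334, 10.96, 27, 11.841, 10.774, 11.902),
    welch = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
              TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              FALSE, TRUE, TRUE, TRUE),
    bh_significant = FALSE)
  d$bh_significant <- d$parameter %in% c("Sds", "Sal", "Sdq", "Sdr")
  d
}

#' Published Tukey HSD pairwise differences between specimens
#'
#' The parameters that differ significantly in each pairwise comparison of
#' the five specimen groups (aquarium sample 1, within-tooth repeats 2a,
#' wild specimens 2-4). Pairs with no differences are empty vectors. The
#' union across pairs -- the PCA parameter-selection rule of
#' [pairwise_differing_parameters()] -- contains 14 symbols.
#'
#' @return named list of character vectors, one per unordered group pair
#'   (`"1|2"`, `"1|2a"`, ...).
#' @export
published_pairwise_sets <- function() {
  big <- c("Sq", "Sv", "Sz", "Sds", "Sal", "Vmp", "Vmc", "Vvc", "Vvv",
           "Spk", "Sk", "Svk", "S5z", "Sa")
  list(
    "1|2a" = character(0),
    "1|2"  = c("Sds"),
    "1|3"  = c("Sds", "Sal"),
    "1|4"  = big,
    "2a|2" = character(0),
    "2a|3" = c("Sds", "Sal"),
    "2a|4" = c("Sq", "Sds", "Sal", "Vmp", "Vvv", "Spk", "Svk"),
    "2|3"  = character(0),
    "2|4"  = c("Sds"),
    "3|4"  = character(0))
}

#' Specimen design of the sand tiger shark study
#'
#' The sampling design emulated by the synthetic cohort generator: one
#' aquarium sample of six shed teeth (fish-only diet, diet rank 1), three
#' wild specimens of six teeth each with increasing relative proportion of
#' elasmobranch prey (ranks 2-4), eight repeat fields within a single tooth
#' of specimen 2 (group "2a"), and one specimen of unknown diet
#' (group "5") whose six teeth are projected into the fitted PCA.
#'
#' @return data frame with columns `group`, `n`, `diet_rank` (NA for the
#'   unknown), `total_length` (cm), `role`
#'   (`"cohort"`, `"within_tooth"`, `"unknown"`).
#' @export
study_design <- function() {
  data.frame(
    group = c("1", "2", "2a", "3", "4", "5"),
    n = c(6L, 6L, 8L, 6L, 6L, 6L),
    diet_rank = c(1L, 2L, 2L, 3L, 4L, NA),
    total_length = c(270, 190, 190, 240, 278, 335),
    role = c("cohort", "cohort", "within_tooth", "cohort", "cohort",
             "unknown"))
}
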