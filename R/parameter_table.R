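#' The 23 ISO 25178-2 texture parameters computed by the package
#'
#' Symbols in the package's canonical column order (the order used by the
#' dietary-discrimination ANOVA table and by [write_parameter_table()]).
#'
#' @return character vector of length 23.
#' @export
iso_parameter_names <- function() {
  c("Sq", "Ssk", "Sku", "Sp", "Sv", "Sz", "Sds", "Str", "Sal", "Sdq",
    "Ssc", "Sdr", "Vmp", "Vmc", "Vvc", "Vvv", "Spk", "Sk", "Svk",
    "Smr1", "Smr2", "S5z", "Sa")
}

SPECIMEN_ID_COLS <- c("specimen_id", "sample_id", "group", "diet_rank",
                      "total_length")

#' Construct a specimen table
#'
#' A data frame of one texture-parameter record per measured surface, tagged
#' with specimen/sample identifiers, a group label and optional ordinal diet
#' rank and body length (cm). This is the exchange object between the
#' parameter stage and the statistics stage.
#'
#' @param df data frame with columns `specimen_id`, `sample_id`, `group`,
#'   optionally `diet_rank` (positive integer or `NA`) and `total_length`
#'   (cm or `NA`), plus the 23 ISO parameter columns of
#'   [iso_parameter_names()]. Extra columns are preserved.
#' @return the validated data frame with class `specimen_table`.
#' @export
specimen_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"diet_rank" %in% names(df)) df$diet_rank <- NA_integer_
  if (!"total_length" %in% names(df)) df$total_length <- NA_real_
  miss <- setdiff(c("specimen_id", "sample_id", "group"), names(df))
  if (length(miss))
    stop("specimen table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pmiss <- setdiff(iso_parameter_names(), names(df))
  if (length(pmiss))
    stop("specimen table missing parameter column(s): ",
         paste(pmiss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("validation error: duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(as.character(df$group))))
    stop("validation error: empty group label", call. = FALSE)
  dr <- df$diet_rank[!is.na(df$diet_rank)]
  if (length(dr) && (any(dr != round(dr)) || any(dr < 1)))
    stop("validation error: diet_rank must be a positive integer",
         call. = FALSE)
  for (p in iso_parameter_names()) {
    if (!is.numeric(df[[p]]))
      stop("parse error: non-numeric parameter column ", p, call. = FALSE)
  }
  ord <- c(SPECIMEN_ID_COLS, iso_parameter_names())
  extra <- setdiff(names(df), ord)
  df <- df[, c(ord, extra), drop = FALSE]
  class(df) <- c("specimen_table", "data.frame")
  df
}

#' Read a CSV table of per-surface texture parameters
#'
#' Expects a header row naming the 23 ISO parameter columns by symbol
#' (`Sq`, `Ssk`, ..., `Sa`) plus `specimen_id`, `sample_id` and `group`
#' identifiers. Deposited tables with other column names can be adapted
#' with `column_map`.
#'
#' @param path CSV file.
#' @param column_map optional named character vector mapping file column
#'   names to the canonical names, e.g. `c(Specimen = "specimen_id")`.
#'   Values of `Smr1`/`Smr2` given as ratios in \[0, 1\] can be rescaled with
#'   `smr_as_ratio = TRUE`.
#' @param smr_as_ratio logical; if `TRUE`, `Smr1`/`Smr2` in the file are
#'   fractions and are multiplied by 100 on read.
#' @return a [specimen_table()].
#' @export
read_parameter_table <- function(path, column_map = NULL,
                                 smr_as_ratio = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (!nrow(raw) || !ncol(raw)) stop("parse error: empty table", call. = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  }
  for (p in intersect(iso_parameter_names(), names(raw))) {
    v <- raw[[p]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(is.na(conv) & !is.na(v) & v != "")
      if (length(bad))
        stop("parse error: non-numeric value in column ", p, ", row ", bad[1],
             call. = FALSE)
      raw[[p]] <- conv
    }
  }
  if ("diet_rank" %in% names(raw))
    raw$diet_rank <- suppressWarnings(as.integer(raw$diet_rank))
  if ("total_length" %in% names(raw))
    raw$total_length <- suppressWarnings(as.numeric(raw$total_length))
  for (idc in c("specimen_id", "sample_id", "group"))
    if (idc %in% names(raw)) raw[[idc]] <- as.character(raw[[idc]])
  if (smr_as_ratio) {
    raw$Smr1 <- raw$Smr1 * 100
    raw$Smr2 <- raw$Smr2 * 100
  }
  specimen_table(raw)
}

#' Write a specimen table to CSV
#'
#' Columns are written in a stable order: identifiers first, then the 23
#' ISO parameters in [iso_parameter_names()] order, then any extra columns.
#' Missing values (voids, unknown diet rank) are serialized as empty cells.
#'
#' @param table a [specimen_table()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(table, path) {
  table <- specimen_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
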