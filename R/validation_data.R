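## Validation dataset handling: age-expression parsing and CSV I/O for
## victim-perpetrator DDI case tables, plus the packaged 25-case table.

.ddi_required_cols <- c("victim", "perpetrator", "cyp", "age_text",
                        "observed_aucr_pediatric", "aucr_adult")
.ddi_optional_cols <- c("printed_pred_a", "printed_pred_b", "printed_pred_c",
                        "age_override_years")

.unit_years <- c(y = 1, m = 1 / 12, w = 1 / 52)

# Parse one "NUMBER [unit]" bound; returns list(value, unit or NA).
.parse_bound <- function(txt) {
  m <- regmatches(txt, regexec("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*([ymw])?\\s*$",
                               txt))[[1]]
  if (length(m) == 0) return(NULL)
  list(value = as.numeric(m[2]), unit = if (nzchar(m[3])) m[3] else NA_character_)
}

#' Parse a pediatric age expression
#'
#' Accepts a point age or an age range in years (`y`, the default),
#' months (`m`) or weeks (`w`): `"6"`, `"19 m"`, `"2-10"`,
#' `"2 w-7.8 y"`, `"10-108 m"`.  En/em dashes are treated as `"-"`.
#' Each bound carries its own unit; a bound without a unit inherits a
#' unit trailing the range end (so `"10-108 m"` is months for both
#' bounds), otherwise years.  Months convert at 12/year and weeks at
#' 52/year.  For ranges the canonical age is the midpoint of the bounds;
#' for points it is the value itself.
#'
#' @param text a single age string.
#' @return an object of class `age_spec`: list with `raw_text`,
#'   `low_years`, `high_years` and `point_years` (the canonical decimal
#'   age used for prediction).
#' @examples
#' parse_age("2-10")$point_years    # 6
#' parse_age("19 m")$point_years    # 19/12
#' @export
parse_age <- function(text) {
  if (length(text) != 1 || !is.character(text) || is.na(text)) {
    stop_parse("age text must be a single string")
  }
  norm <- gsub("–|—", "-", text)
  parts <- strsplit(norm, "-", fixed = TRUE)[[1]]
  if (!(length(parts) %in% 1:2) || any(!nzchar(trimws(parts)))) {
    stop_parse(sprintf("unparseable age expression: '%s'", text))
  }
  bounds <- lapply(parts, .parse_bound)
  if (any(vapply(bounds, is.null, logical(1)))) {
    stop_parse(sprintf("unparseable age expression: '%s'", text))
  }
  if (length(bounds) == 1) {
    u <- if (is.na(bounds[[1]]$unit)) "y" else bounds[[1]]$unit
    v <- bounds[[1]]$value * .unit_years[[u]]
    lo <- hi <- pt <- v
  } else {
    u2 <- if (is.na(bounds[[2]]$unit)) "y" else bounds[[2]]$unit
    # a unit trailing the range applies to an unitless first bound
    u1 <- if (is.na(bounds[[1]]$unit)) u2 else bounds[[1]]$unit
    lo <- bounds[[1]]$value * .unit_years[[u1]]
    hi <- bounds[[2]]$value * .unit_years[[u2]]
    if (lo > hi) {
      stop_parse(sprintf("age range lower bound exceeds upper: '%s'", text))
    }
    pt <- (lo + hi) / 2
  }
  structure(list(raw_text = text, low_years = lo, high_years = hi,
                 point_years = pt),
            class = "age_spec")
}

#' @export
print.age_spec <- function(x, ...) {
  cat(sprintf("age '%s': [%.4g, %.4g] y, canonical %.4g y\n",
              x$raw_text, x$low_years, x$high_years, x$point_years))
  invisible(x)
}

#' Read a DDI case table from CSV
#'
#' Expected columns: `victim`, `perpetrator`, `cyp`, `age_text`,
#' `observed_aucr_pediatric`, `aucr_adult`, and optionally
#' `printed_pred_a`, `printed_pred_b`, `printed_pred_c` (published
#' predictions) and `age_override_years` (a cohort mean age replacing
#' the range-midpoint canonical age).  Ages are parsed with
#' [parse_age()]; the returned table gains `age_low_years`,
#' `age_high_years` and `age_years` (the canonical age after any
#' override).  Schema violations are reported with their row number.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of class `ddi_cases`.
#' @export
read_ddi_cases <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(.ddi_required_cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) stop_schema("case table has no rows")
  for (col in setdiff(.ddi_optional_cols, names(df))) df[[col]] <- ""
  df <- df[c(.ddi_required_cols, .ddi_optional_cols)]

  num_or_na <- function(x) ifelse(nzchar(trimws(x)), suppressWarnings(as.numeric(x)), NA_real_)
  for (col in c("observed_aucr_pediatric", "aucr_adult",
                "printed_pred_a", "printed_pred_b", "printed_pred_c",
                "age_override_years")) {
    df[[col]] <- num_or_na(df[[col]])
  }

  age_lo <- age_hi <- age_pt <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    row_err <- function(msg) stop_schema(sprintf("row %d: %s", i, msg))
    for (col in c("victim", "perpetrator", "cyp", "age_text")) {
      if (!nzchar(trimws(df[[col]][i]))) row_err(sprintf("empty '%s'", col))
    }
    df$cyp[i] <- tryCatch(cyp_isoform(df$cyp[i]),
                          pedddi_error = function(e) row_err(conditionMessage(e)))
    a <- tryCatch(parse_age(df$age_text[i]),
                  pedddi_error = function(e) row_err(conditionMessage(e)))
    age_lo[i] <- a$low_years; age_hi[i] <- a$high_years
    age_pt[i] <- if (!is.na(df$age_override_years[i])) {
      if (df$age_override_years[i] < 0) row_err("negative age_override_years")
      df$age_override_years[i]
    } else a$point_years
    for (col in c("observed_aucr_pediatric", "aucr_adult")) {
      v <- df[[col]][i]
      if (is.na(v) || v <= 0) row_err(sprintf("'%s' must be a positive number", col))
    }
    for (col in c("printed_pred_a", "printed_pred_b", "printed_pred_c")) {
      v <- df[[col]][i]
      if (!is.na(v) && v <= 0) row_err(sprintf("'%s' must be positive when present", col))
    }
  }
  df$age_low_years <- age_lo
  df$age_high_years <- age_hi
  df$age_years <- age_pt
  class(df) <- c("ddi_cases", "data.frame")
  df
}

#' Write a DDI case table to CSV
#'
#' Writes the schema columns of [read_ddi_cases()] (derived age columns
#' are dropped); `write_ddi_cases()` then `read_ddi_cases()` round-trips
#' the content.  An empty table writes a header-only file.
#'
#' @param records a `ddi_cases` data.frame (or any data.frame with the
#'   schema columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ddi_cases <- function(records, path) {
  cols <- intersect(c(.ddi_required_cols, .ddi_optional_cols), names(records))
  missing <- setdiff(.ddi_required_cols, cols)
  if (length(missing) > 0 && nrow(records) > 0) {
    stop_schema(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0 && length(cols) == 0) {
    cols <- c(.ddi_required_cols, .ddi_optional_cols)
    records <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.csv(as.data.frame(records)[cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' The packaged 25-case pediatric DDI validation table
#'
#' Twenty-five victim-perpetrator cases with observed pediatric AUC
#' ratios, the corresponding adult AUC ratios, and the published
#' predictions of the three extrapolation approaches.  Drug names and
#' values are transcribed verbatim from the source table (including the
#' "Etopside" spelling).
#'
#' @return a `ddi_cases` data.frame with 25 rows (see
#'   [read_ddi_cases()] for columns).
#' @examples
#' tab <- load_validation_table()
#' table(tab$cyp)
#' @export
load_validation_table <- function() {
  path <- system.file("extdata", "ddi_validation_table.csv",
                      package = "pedddi")
  if (!nzchar(path) || !file.exists(path)) {
    stop_schema("packaged validation table not found; reinstall the package")
  }
  df <- read_ddi_cases(path)
  if (nrow(df) != 25) {
    stop_schema(sprintf("packaged validation table corrupt: %d rows, expected 25",
                        nrow(df)))
  }
  df
}
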