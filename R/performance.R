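## Prediction-performance metrics for predicted-vs-observed AUC ratios,
## and the evaluation of an extrapolation approach on a case table.

#' Fold error of a prediction
#'
#' `max(p/o, o/p)`: the symmetric, always-`>= 1` multiplicative error.
#'
#' @param predicted,observed positive numerics (vectorised).
#' @return numeric vector of fold errors.
#' @export
fold_error <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  pmax(predicted / observed, observed / predicted)
}

#' Geometric mean fold error (GMFE)
#'
#' `exp(mean(|ln(p/o)|))`: the geometric mean of the per-case fold
#' errors. 1 means perfect prediction; 2 means an average two-fold
#' error.  The standard accuracy summary for PK predictions, whose
#' errors are multiplicative and asymmetric.
#'
#' @param predicted,observed positive numeric vectors of equal length.
#' @return scalar GMFE `>= 1`.
#' @export
gmfe <- function(predicted, observed) {
  .check_pairs(predicted, observed, scalar_ok = FALSE)
  exp(mean(abs(log(predicted / observed))))
}

#' Mean absolute prediction error (MAPE, percent)
#'
#' `100 * mean(|p - o| / o)`.
#'
#' @param predicted,observed positive numeric vectors of equal length.
#' @return scalar percentage `>= 0`.
#' @export
mape <- function(predicted, observed) {
  .check_pairs(predicted, observed, scalar_ok = FALSE)
  100 * mean(abs(predicted - observed) / observed)
}

#' Two-fold (50-200%) acceptance criterion
#'
#' `TRUE` iff `0.5 <= p/o <= 2`, boundaries inclusive.
#'
#' @param predicted,observed positive numerics (vectorised).
#' @return logical vector.
#' @export
within_twofold <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  r <- predicted / observed
  r >= 0.5 & r <= 2
}

#' Guest acceptance limit for an observed AUC ratio
#'
#' Observation-dependent acceptance interval for DDI predictions that
#' tightens toward unity as the observed ratio approaches 1.  With
#' `R = max(obs, 1/obs)`, the limit is `L = (delta + 2 (R - 1)) / R`; a
#' prediction is acceptable iff `1/L <= p/o <= L`.  `delta = 1` gives
#' the strict variant (interval collapses to equality at `obs = 1`);
#' the default `delta = 1.25` builds in bioequivalence-type variability.
#'
#' @param observed positive observed AUC ratio(s).
#' @param delta limit parameter `>= 1`.
#' @return numeric limit(s) `L >= 1`.
#' @examples
#' guest_limit(1)     # 1.25
#' guest_limit(2)     # (1.25 + 2)/2
#' @export
guest_limit <- function(observed, delta = 1.25) {
  if (!is.numeric(observed) || any(!is.finite(observed)) || any(observed <= 0)) {
    stop_domain("observed must be finite and > 0")
  }
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) || delta < 1) {
    stop_domain("delta must be a single number >= 1")
  }
  R <- pmax(observed, 1 / observed)
  (delta + 2 * (R - 1)) / R
}

#' @rdname guest_limit
#' @param predicted positive predicted AUC ratio(s).
#' @return `within_guest()`: logical vector, `TRUE` iff the prediction
#'   falls inside the Guest interval of its observation.
#' @export
within_guest <- function(predicted, observed, delta = 1.25) {
  .check_pairs(predicted, observed)
  L <- guest_limit(observed, delta)
  r <- predicted / observed
  r >= 1 / L & r <= L
}

#' Ordinary least-squares calibration line
#'
#' Unweighted OLS regression of predicted on observed AUC ratios
#' (`predicted = intercept + slope * observed`); a slope near 1 and
#' intercept near 0 indicate a well-calibrated predictor.
#'
#' @param predicted,observed positive numeric vectors (`>= 2` pairs,
#'   non-degenerate observed variance).
#' @return named numeric vector `c(slope, intercept)`.
#' @export
ols_fit <- function(predicted, observed) {
  .check_pairs(predicted, observed, scalar_ok = FALSE)
  if (length(observed) < 2 || stats::var(observed) == 0) {
    stop_domain("ols_fit needs >= 2 pairs with non-degenerate observed values")
  }
  co <- stats::coef(stats::lm(predicted ~ observed))
  c(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Evaluate an extrapolation approach on a DDI case table
#'
#' Computes per-record predicted-vs-observed pairs and the full metric
#' panel for one approach.  In `mode = "recompute"` the predictions are
#' generated by [predict_pediatric_aucr()] from each record's adult AUC
#' ratio, CYP isoform and canonical age; in `mode = "printed"` the
#' table's published prediction column is used.  Whenever published
#' predictions are present, a reproducibility audit table compares the
#' recomputed predictions against them and flags rows where the
#' absolute difference exceeds 0.01 (i.e. beyond the published
#' two-decimal precision).
#'
#' @param records a `ddi_cases` table ([read_ddi_cases()],
#'   [load_validation_table()]).
#' @param approach `"A"`, `"B"` or `"C"`.
#' @param mode `"recompute"` (default) or `"printed"`.
#' @param adult_weight_kg,allometric_exponent passed to the predictor.
#' @param guest_delta Guest limit parameter (default 1.25).
#' @return an object of class `ddi_performance`: list with `approach`,
#'   `mode`, `n`, `gmfe`, `mape_percent`, `ols_slope`, `ols_intercept`,
#'   `n_outside_twofold`, `n_outside_guest`, `guest_delta`,
#'   `per_record` (victim, perpetrator, predicted, observed, ratio,
#'   bias, within_twofold, within_guest) and `audit` (recomputed vs
#'   published predictions with residuals and flags, or `NULL` when the
#'   table carries no published predictions).
#' @examples
#' tab <- load_validation_table()
#' evaluate_performance(tab, "C", mode = "printed")
#' @export
evaluate_performance <- function(records, approach = "C",
                                 mode = c("recompute", "printed"),
                                 adult_weight_kg = 70,
                                 allometric_exponent = 0.75,
                                 guest_delta = 1.25) {
  mode <- match.arg(mode)
  approach <- match.arg(toupper(approach), c("A", "B", "C"))
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_domain("records must be a non-empty case table")
  }
  printed_col <- paste0("printed_pred_", tolower(approach))

  recomputed <- vapply(seq_len(nrow(records)), function(i) {
    predict_pediatric_aucr(records$aucr_adult[i], records$cyp[i],
                           records$age_years[i], approach,
                           adult_weight_kg = adult_weight_kg,
                           allometric_exponent = allometric_exponent)$aucr_pediatric
  }, numeric(1))

  if (mode == "printed") {
    if (!printed_col %in% names(records) || anyNA(records[[printed_col]])) {
      stop_domain(sprintf(
        "mode 'printed' requires a complete '%s' column", printed_col))
    }
    predicted <- records[[printed_col]]
  } else {
    predicted <- recomputed
  }
  observed <- records$observed_aucr_pediatric

  per_record <- data.frame(
    victim = records$victim, perpetrator = records$perpetrator,
    predicted = predicted, observed = observed,
    ratio = predicted / observed, bias = predicted - observed,
    within_twofold = within_twofold(predicted, observed),
    within_guest = within_guest(predicted, observed, guest_delta),
    stringsAsFactors = FALSE)

  audit <- NULL
  if (printed_col %in% names(records) && !all(is.na(records[[printed_col]]))) {
    resid <- round_half_out(recomputed, 2) - records[[printed_col]]
    audit <- data.frame(
      victim = records$victim, perpetrator = records$perpetrator,
      cyp = records$cyp, age_years = records$age_years,
      recomputed = recomputed,
      recomputed_2dp = round_half_out(recomputed, 2),
      published = records[[printed_col]],
      residual = resid,
      flagged = !is.na(resid) & abs(resid) > 0.01 + 1e-9,
      stringsAsFactors = FALSE)
  }

  fit <- ols_fit(predicted, observed)
  structure(list(
    approach = approach, mode = mode, n = nrow(records),
    gmfe = gmfe(predicted, observed),
    mape_percent = mape(predicted, observed),
    ols_slope = fit[["slope"]], ols_intercept = fit[["intercept"]],
    n_outside_twofold = sum(!per_record$within_twofold),
    n_outside_guest = sum(!per_record$within_guest),
    guest_delta = guest_delta,
    per_record = per_record, audit = audit),
    class = "ddi_performance")
}

#' @export
print.ddi_performance <- function(x, ...) {
  cat(sprintf(
    "Approach %s (%s mode, n = %d): GMFE %.2f | MAPE %.2f%% | OLS slope %.4f, intercept %.4f\n",
    x$approach, x$mode, x$n, x$gmfe, x$mape_percent, x$ols_slope,
    x$ols_intercept))
  cat(sprintf(
    "  outside 50-200%% range: %d/%d | outside Guest limits (delta = %.2f): %d/%d\n",
    x$n_outside_twofold, x$n, x$guest_delta, x$n_outside_guest, x$n))
  if (!is.null(x$audit) && any(x$audit$flagged)) {
    f <- x$audit[x$audit$flagged, ]
    cat(sprintf(
      "  audit: %d record(s) where recomputed prediction differs from the published value by > 0.01:\n",
      nrow(f)))
    for (i in seq_len(nrow(f))) {
      cat(sprintf("    %s-%s (%s, age %.3g y): recomputed %.2f vs published %.2f\n",
                  f$victim[i], f$perpetrator[i], f$cyp[i], f$age_years[i],
                  f$recomputed_2dp[i], f$published[i]))
    }
  }
  invisible(x)
}

.check_pairs <- function(predicted, observed, scalar_ok = TRUE) {
  if (!is.numeric(predicted) || !is.numeric(observed) ||
      any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0)) {
    stop_domain("predicted and observed must be finite and > 0")
  }
  if (length(predicted) != length(observed)) {
    stop_domain("predicted and observed must have equal length")
  }
  if (!scalar_ok && length(predicted) == 0) {
    stop_domain("empty input")
  }
}
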