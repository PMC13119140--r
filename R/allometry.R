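## Body-size scaling: weight-for-age and the allometric clearance factor.

#' Pediatric body weight from age (Luscombe formula)
#'
#' `weight (kg) = 3 * age (years) + 7`, the linear weight-for-age
#' approximation used for children roughly 1-12 years old but applied
#' here across the whole pediatric range for consistency with the
#' extrapolation framework.
#'
#' @param age_years non-negative age(s) in decimal years.
#' @return numeric vector of weights in kg.
#' @examples
#' pediatric_weight(6)   # 25 kg
#' @export
pediatric_weight <- function(age_years) {
  if (length(age_years) == 0 || !is.numeric(age_years) ||
      any(!is.finite(age_years))) {
    stop_domain("age_years must be finite numeric")
  }
  if (any(age_years < 0)) stop_domain("age_years must be >= 0")
  3 * age_years + 7
}

#' Allometric body-size correction factor
#'
#' \eqn{W_{allometry} = (WT_{pediatric}/WT_{adult})^{exponent}}, the
#' factor by which total (body-size-dependent) clearance is scaled.  The
#' default exponent 0.75 is the classical allometric exponent for
#' metabolic clearance; the adult reference weight defaults to 70 kg.
#'
#' @param weight_pediatric_kg pediatric body weight(s), kg, > 0.
#' @param weight_adult_kg adult reference weight, kg, > 0 (default 70).
#' @param exponent allometric exponent (default 0.75).
#' @return dimensionless numeric factor(s); 1 when the weights are equal
#'   and below 1 for any child lighter than the adult reference.
#' @examples
#' w_allometry(pediatric_weight(6))   # (25/70)^0.75
#' @export
w_allometry <- function(weight_pediatric_kg, weight_adult_kg = 70,
                        exponent = 0.75) {
  if (!is.numeric(weight_pediatric_kg) || !is.numeric(weight_adult_kg) ||
      any(!is.finite(weight_pediatric_kg)) || any(!is.finite(weight_adult_kg))) {
    stop_domain("weights must be finite numeric")
  }
  if (any(weight_pediatric_kg <= 0) || any(weight_adult_kg <= 0)) {
    stop_domain("weights must be > 0")
  }
  (weight_pediatric_kg / weight_adult_kg)^exponent
}
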