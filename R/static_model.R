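## Static DDI model: adult-level equations and the adult-to-pediatric
## AUC-ratio extrapolation (Approaches A, B, C).

#' Adult AUC ratio under competitive/mechanistic inhibition
#'
#' Static-model AUC ratio for a victim drug co-administered with an
#' inhibitor: `1 / (1 - CR * IR)`, where `CR` is the fraction of the
#' victim's oral clearance through the affected CYP and `IR` the
#' time-integrated in vivo inhibition ratio of the perpetrator.
#'
#' @param cr clearance ratio, in `[0, 1]`.
#' @param ir inhibition ratio, in `[0, 1]` (0 = no inhibition, 1 =
#'   complete shutdown of the pathway).
#' @return AUC ratio >= 1.
#' @examples
#' adult_aucr_inhibition(0.5, 1)   # 2: half the clearance fully blocked
#' @export
adult_aucr_inhibition <- function(cr, ir) {
  .check_fraction(cr, "cr")
  .check_fraction(ir, "ir")
  if (any(cr * ir >= 1)) {
    stop_model_domain("cr * ir >= 1: complete inhibition of total clearance")
  }
  1 / (1 - cr * ir)
}

#' Adult AUC ratio under induction
#'
#' Static-model AUC ratio for a victim drug co-administered with an
#' inducer: `1 / (1 + CR * IC)`, where `IC` is the induction analogue of
#' the inhibition ratio.
#'
#' @param cr clearance ratio, in `[0, 1]`.
#' @param ic induction parameter, >= 0.
#' @return AUC ratio in `(0, 1]`.
#' @examples
#' adult_aucr_induction(0.5, 1)   # 2/3
#' @export
adult_aucr_induction <- function(cr, ic) {
  .check_fraction(cr, "cr")
  if (!is.numeric(ic) || any(!is.finite(ic)) || any(ic < 0)) {
    stop_domain("ic must be finite and >= 0")
  }
  1 / (1 + cr * ic)
}

#' Ontogeny/allometry-corrected clearance ratio
#'
#' Scales an adult clearance ratio to a pediatric one:
#' `CR_ped = Z * CR_adult / W`.  The ontogeny factor `Z` corrects the
#' pathway-specific clearance in the numerator; the allometric factor
#' `W` corrects total clearance in the denominator.  If the corrected
#' value exceeds 1 it is returned unclamped with a warning, since it is
#' then no longer interpretable as a clearance fraction.
#'
#' @param cr_adult adult clearance ratio, in `[0, 1]`.
#' @param z ontogeny factor `Z_ontogeny`, >= 0.
#' @param w allometric factor `W_allometry`, > 0.
#' @return corrected clearance ratio.
#' @examples
#' correct_cr(0.8, z_ontogeny("CYP3A4", 6), 1)
#' @export
correct_cr <- function(cr_adult, z, w) {
  .check_fraction(cr_adult, "cr_adult")
  .check_zw(z, w)
  out <- z * cr_adult / w
  if (any(out > 1)) {
    warning("corrected clearance ratio exceeds 1; no longer interpretable ",
            "as a fraction of total clearance", call. = FALSE)
  }
  out
}

#' Pediatric AUC ratio from an adult AUC ratio
#'
#' The core extrapolation identity
#' \deqn{AUCR_{ped} = \frac{1}{1 - \frac{Z}{W}\left(1 - \frac{1}{AUCR_{adult}}\right)}}
#' applied with the correction factors of the chosen approach.  The
#' inhibition (`AUCR > 1`) and induction (`AUCR < 1`) forms of the
#' static model are algebraically the same function, so a single
#' implementation serves both; `1 - 1/AUCR` simply changes sign.
#'
#' @param aucr_adult adult AUC ratio, > 0.
#' @param z ontogeny factor `Z_ontogeny`, >= 0 (1 for Approach A).
#' @param w allometric factor `W_allometry`, > 0 (1 for Approaches A, B).
#' @return pediatric AUC ratio, > 0.  With `z = w = 1` the input is
#'   returned unchanged (Approach A identity).
#' @examples
#' z <- z_ontogeny("CYP3A4", 6)
#' w <- w_allometry(pediatric_weight(6))
#' pediatric_aucr(1.49, z, w)
#' @export
pediatric_aucr <- function(aucr_adult, z = 1, w = 1) {
  if (!is.numeric(aucr_adult) || any(!is.finite(aucr_adult)) ||
      any(aucr_adult <= 0)) {
    stop_domain("aucr_adult must be finite and > 0")
  }
  .check_zw(z, w)
  term <- (z / w) * (1 - 1 / aucr_adult)
  if (any(term >= 1)) {
    stop_model_domain(
      "corrected interaction term >= 1: predicts non-positive clearance")
  }
  1 / (1 - term)
}

#' Back-calculate the adult AUC ratio from a pediatric prediction
#'
#' Algebraic inverse of [pediatric_aucr()]: returns the adult AUC ratio
#' that would produce the given pediatric AUC ratio under factors
#' `z`, `w`.  Used for round-trip checks and for reading an adult
#' equivalent off an observed pediatric ratio.
#'
#' @param aucr_pediatric pediatric AUC ratio, > 0.
#' @param z ontogeny factor, > 0 (not invertible at `z = 0`).
#' @param w allometric factor, > 0.
#' @return adult AUC ratio.
#' @export
invert_to_adult <- function(aucr_pediatric, z, w) {
  if (!is.numeric(aucr_pediatric) || any(!is.finite(aucr_pediatric)) ||
      any(aucr_pediatric <= 0)) {
    stop_domain("aucr_pediatric must be finite and > 0")
  }
  .check_zw(z, w)
  if (any(z == 0)) stop_domain("not invertible: z = 0 maps every adult AUCR to 1")
  term <- (w / z) * (1 - 1 / aucr_pediatric)
  if (any(term >= 1)) {
    stop_model_domain("inverse undefined: (w/z) * (1 - 1/AUCR) >= 1")
  }
  1 / (1 - term)
}

#' Correction factors for an extrapolation approach
#'
#' Dispatches the `(Z, W)` pair used by [pediatric_aucr()]:
#' * **A**: `Z = 1`, `W = 1` (direct translation);
#' * **B**: `Z` = ontogeny fraction at the given age, `W = 1`;
#' * **C**: `Z` as in B, `W` = allometric factor from the Luscombe
#'   weight (or a supplied pediatric weight) against the adult
#'   reference weight.
#'
#' @param approach `"A"`, `"B"` or `"C"`.
#' @param isoform CYP label (required for B and C).
#' @param age_years age in decimal years (required for B and C).
#' @param adult_weight_kg adult reference weight, default 70.
#' @param allometric_exponent default 0.75.
#' @param pediatric_weight_kg optional observed pediatric weight
#'   overriding the Luscombe formula (Approach C only).
#' @return a list with elements `z`, `w`, `approach`, and for B/C the
#'   inputs that produced them (`isoform`, `age_years`,
#'   `pediatric_weight_kg`, `weight_source`).
#' @export
correction_factors <- function(approach, isoform = NULL, age_years = NULL,
                               adult_weight_kg = 70,
                               allometric_exponent = 0.75,
                               pediatric_weight_kg = NULL) {
  approach <- match.arg(toupper(approach), c("A", "B", "C"))
  if (approach == "A") {
    return(list(z = 1, w = 1, approach = "A",
                isoform = NA_character_, age_years = NA_real_,
                pediatric_weight_kg = NA_real_, weight_source = "none"))
  }
  if (is.null(isoform) || is.null(age_years)) {
    stop_domain(sprintf("approach %s requires isoform and age_years", approach))
  }
  iso <- cyp_isoform(isoform)
  z <- z_ontogeny(iso, age_years)
  if (approach == "B") {
    return(list(z = z, w = 1, approach = "B",
                isoform = iso, age_years = age_years,
                pediatric_weight_kg = NA_real_, weight_source = "none"))
  }
  if (is.null(pediatric_weight_kg)) {
    wt <- pediatric_weight(age_years)
    src <- "luscombe_formula"
  } else {
    if (any(pediatric_weight_kg <= 0)) stop_domain("pediatric weight must be > 0")
    wt <- pediatric_weight_kg
    src <- "user_supplied"
  }
  list(z = z,
       w = w_allometry(wt, adult_weight_kg, allometric_exponent),
       approach = "C", isoform = iso, age_years = age_years,
       pediatric_weight_kg = wt, weight_source = src)
}

#' Predict a pediatric AUC ratio from an adult one
#'
#' Single-case front end: builds the approach's correction factors and
#' applies the pediatric extrapolation identity.  The result records the
#' factors and inputs for auditability.
#'
#' @inheritParams correction_factors
#' @param aucr_adult adult AUC ratio, > 0.
#' @return an object of class `ddi_prediction`: a list with
#'   `aucr_pediatric`, `aucr_adult`, `direction` (`"inhibition"`,
#'   `"induction"` or `"none"`), and the factor provenance
#'   (`approach`, `z`, `w`, `isoform`, `age_years`,
#'   `pediatric_weight_kg`, `weight_source`, `adult_weight_kg`,
#'   `allometric_exponent`).
#' @examples
#' p <- predict_pediatric_aucr(1.49, "CYP3A4", 6, approach = "C")
#' p$aucr_pediatric          # ~2.78
#' @export
predict_pediatric_aucr <- function(aucr_adult, isoform = NULL,
                                   age_years = NULL, approach = "C",
                                   adult_weight_kg = 70,
                                   allometric_exponent = 0.75,
                                   pediatric_weight_kg = NULL) {
  f <- correction_factors(approach, isoform, age_years,
                          adult_weight_kg, allometric_exponent,
                          pediatric_weight_kg)
  pred <- pediatric_aucr(aucr_adult, f$z, f$w)
  direction <- if (aucr_adult > 1) "inhibition"
               else if (aucr_adult < 1) "induction" else "none"
  structure(
    c(list(aucr_pediatric = pred, aucr_adult = aucr_adult,
           direction = direction,
           adult_weight_kg = adult_weight_kg,
           allometric_exponent = allometric_exponent),
      f),
    class = "ddi_prediction")
}

#' @export
print.ddi_prediction <- function(x, digits = 4, ...) {
  cat(sprintf("Pediatric DDI prediction (Approach %s, %s)\n",
              x$approach, x$direction))
  if (!is.na(x$age_years)) {
    cat(sprintf("  isoform %s, age %.4g y", x$isoform, x$age_years))
    if (!is.na(x$pediatric_weight_kg)) {
      cat(sprintf(", weight %.4g kg (%s)", x$pediatric_weight_kg,
                  x$weight_source))
    }
    cat("\n")
  }
  cat(sprintf("  Z_ontogeny = %.*g, W_allometry = %.*g\n",
              digits, x$z, digits, x$w))
  cat(sprintf("  adult AUCR %.*g -> pediatric AUCR %.*g (%.2f at 2 dp)\n",
              digits, x$aucr_adult, digits, x$aucr_pediatric,
              round_half_out(x$aucr_pediatric, 2)))
  invisible(x)
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_domain(sprintf("%s must be in [0, 1]", name))
  }
}

.check_zw <- function(z, w) {
  if (!is.numeric(z) || any(!is.finite(z)) || any(z < 0)) {
    stop_domain("z must be finite and >= 0")
  }
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop_domain("w must be finite and > 0")
  }
}
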