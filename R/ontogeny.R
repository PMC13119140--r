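## CYP ontogeny: fractional enzyme abundance/activity relative to adult,
## as Emax-type maturation functions of postnatal age.

# Maturation-function parameters, one row per supported isoform:
#   adult = asymptotic adult fraction, birth = fraction at age 0,
#   age50 = age (years) at half-maximal maturation, hill = Hill exponent.
# z(age) = (adult - birth) * age^hill / (age50^hill + age^hill) + birth
.ontogeny_params <- list(
  CYP1A2  = list(adult = 1.05,  birth = 0.08, age50 = 1.69,  hill = 1.1),
  CYP2B6  = list(adult = 1,     birth = 0.1,  age50 = 1,     hill = 1),
  CYP2C9  = list(adult = 1,     birth = 0.17, age50 = 0.016, hill = 0.53),
  CYP2C19 = list(adult = 1,     birth = 0.3,  age50 = 0.28,  hill = 2.44),
  CYP3A4  = list(adult = 1.061, birth = 0,    age50 = 0.66,  hill = 0.78)
)

#' Supported CYP isoforms
#'
#' The five cytochrome P450 isoforms for which an ontogeny (maturation)
#' function is available.  `"CYP3A4"` denotes the combined CYP3A4/5
#' function.
#'
#' @return character vector of the five canonical isoform labels.
#' @examples
#' cyp_isoforms()
#' @export
cyp_isoforms <- function() names(.ontogeny_params)

#' Parse and canonicalise a CYP isoform label
#'
#' Matching is case-insensitive; `"CYP3A4/5"` and `"CYP3A5"` are aliases
#' for the combined `"CYP3A4"` member.  Any other label is rejected.
#'
#' @param x character vector of isoform labels.
#' @return character vector of canonical labels (see [cyp_isoforms()]).
#' @examples
#' cyp_isoform(c("cyp3a4/5", "CYP2c19"))
#' @export
cyp_isoform <- function(x) {
  if (length(x) == 0 || !is.character(x)) {
    stop_unsupported_enzyme("isoform label must be a non-empty character vector")
  }
  up <- toupper(trimws(x))
  up[up %in% c("CYP3A4/5", "CYP3A5")] <- "CYP3A4"
  bad <- !(up %in% cyp_isoforms())
  if (any(bad)) {
    stop_unsupported_enzyme(sprintf(
      "unsupported CYP isoform(s): %s (no ontogeny function; supported: %s)",
      paste(unique(x[bad]), collapse = ", "),
      paste(cyp_isoforms(), collapse = ", ")))
  }
  up
}

#' Fractional CYP ontogeny at a given age
#'
#' Evaluates the isoform's maturation function: the enzyme's
#' abundance/activity at `age_years` as a fraction of the adult level.
#' Each function has the Emax form
#' \deqn{Z(Age) = (adult - birth)\frac{Age^{n}}{Age_{50}^{n} + Age^{n}} + birth}
#' with isoform-specific parameters; at birth it equals the birth
#' fraction (0.08, 0.1, 0.17, 0.3 and 0 for CYP1A2, CYP2B6, CYP2C9,
#' CYP2C19 and CYP3A4/5) and it approaches the adult asymptote (1.05, 1,
#' 1, 1 and 1.061) at large ages.
#'
#' @param isoform a CYP label accepted by [cyp_isoform()] (scalar).
#' @param age_years non-negative, finite age(s) in decimal years.
#'   Evaluating far beyond the pediatric range is allowed but ages above
#'   25 years trigger a warning.
#' @return numeric vector of ontogeny fractions \eqn{Z_{ontogeny}}, one
#'   per element of `age_years`.
#' @examples
#' z_ontogeny("CYP3A4", 6)
#' z_ontogeny("CYP2C19", 0)     # birth fraction 0.3
#' z_ontogeny("CYP1A2", c(0.5, 1, 2, 5, 12))
#' @export
z_ontogeny <- function(isoform, age_years) {
  iso <- cyp_isoform(isoform)
  if (length(iso) != 1) stop_domain("one isoform per call")
  if (length(age_years) == 0 || !is.numeric(age_years) ||
      any(!is.finite(age_years))) {
    stop_domain("age_years must be finite numeric")
  }
  if (any(age_years < 0)) stop_domain("age_years must be >= 0")
  if (any(age_years > 25)) {
    warning("age above 25 years: ontogeny functions are parameterised for ",
            "the pediatric range", call. = FALSE)
  }
  p <- .ontogeny_params[[iso]]
  a <- age_years^p$hill
  (p$adult - p$birth) * a / (p$age50^p$hill + a) + p$birth
}
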