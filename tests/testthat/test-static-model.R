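# Samples (aucr_adult, z, w) tuples inside the model's valid domain.
random_valid_tuples <- function(n, seed = 42) {
  set.seed(seed)
  a <- exp(runif(8 * n, log(0.05), log(20)))
  z <- runif(8 * n, 1e-6, 1.061)
  w <- runif(8 * n, 0.1, 1.5)
  keep <- (z / w) * (1 - 1 / a) < 1 - 1e-9
  idx <- which(keep)[seq_len(n)]
  data.frame(a = a[idx], z = z[idx], w = w[idx])
}

test_that("adult static equations reproduce their closed forms", {
  expect_equal(adult_aucr_inhibition(0.5, 1), 2)
  expect_equal(adult_aucr_inhibition(0, 0.9), 1)
  expect_error(adult_aucr_inhibition(1, 1), class = "pedddi_model_domain_error")
  expect_error(adult_aucr_inhibition(1.2, 0.5), class = "pedddi_domain_error")
  expect_equal(adult_aucr_induction(0.5, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(adult_aucr_induction(0, 5), 1)
  expect_equal(adult_aucr_induction(1, 0), 1)
  expect_error(adult_aucr_induction(0.5, -1), class = "pedddi_domain_error")
})

test_that("clearance-ratio correction scales by z/w and flags > 1", {
  expect_equal(correct_cr(0.8, 1, 1), 0.8)
  expect_equal(correct_cr(0.8, 0.9, 1), 0.72)
  expect_warning(out <- correct_cr(0.8, 0.9, 0.462), "exceeds 1")
  expect_equal(out, 0.72 / 0.462, tolerance = 1e-12)
  expect_error(correct_cr(0.8, 0.9, 0), class = "pedddi_domain_error")
})

test_that("pediatric extrapolation hits the published CYP3A4 values", {
  expect_equal(pediatric_aucr(1.49, 1, 1), 1.49)
  expect_equal(pediatric_aucr(1, 0.5, 0.7), 1)
  expect_equal(round_half_out(pediatric_aucr(1.49, 0.9001, 0.4620), 2), 2.78)
  expect_equal(round_half_out(pediatric_aucr(1.16, 0.9473, 0.6200), 2), 1.27)
  expect_error(pediatric_aucr(10, 2, 0.5), class = "pedddi_model_domain_error")
  expect_error(pediatric_aucr(-1, 1, 1), class = "pedddi_domain_error")
})

test_that("inhibition and induction forms are the same function", {
  tup <- random_valid_tuples(10000, seed = 402)
  f12 <- pediatric_aucr(tup$a, tup$z, tup$w)
  f14 <- 1 / (1 + (tup$z / tup$w) * (1 / tup$a - 1))  # induction form
  expect_equal(f12, f14, tolerance = 1e-12)
})

test_that("composing the adult equation with the extrapolation matches the corrected-CR identity", {
  set.seed(7)
  cr <- runif(500, 0.01, 0.99)
  ir <- runif(500, 0.01, 1)
  z <- runif(500, 0.05, 1.061)
  w <- runif(500, 0.3, 1.5)
  keep <- cr * ir < 1 - 1e-9 & (z / w) * cr * ir < 1 - 1e-9
  cr <- cr[keep]; ir <- ir[keep]; z <- z[keep]; w <- w[keep]
  via_model <- pediatric_aucr(adult_aucr_inhibition(cr, ir), z, w)
  direct <- 1 / (1 - (z / w) * cr * ir)
  expect_equal(via_model, direct, tolerance = 1e-10)
})

test_that("extrapolation preserves interaction direction and is monotone in z/w", {
  tup <- random_valid_tuples(2000, seed = 11)
  pred <- pediatric_aucr(tup$a, tup$z, tup$w)
  expect_true(all((pred > 1) == (tup$a > 1)))
  expect_true(all((pred < 1) == (tup$a < 1)))
  # monotone in the combined factor z/w, increasing for inhibition,
  # decreasing for induction
  ratios <- seq(0.1, 1.6, by = 0.05)
  inh <- pediatric_aucr(1.49, ratios, 1)
  ind <- pediatric_aucr(0.7, ratios, 1)
  expect_true(all(diff(inh) > 0))
  expect_true(all(diff(ind) < 0))
})

test_that("back-calculation inverts the forward extrapolation", {
  tup <- random_valid_tuples(2000, seed = 23)
  fwd <- pediatric_aucr(tup$a, tup$z, tup$w)
  expect_equal(invert_to_adult(fwd, tup$z, tup$w), tup$a, tolerance = 1e-9)
  expect_equal(invert_to_adult(1, 0.5, 0.7), 1)
  expect_equal(invert_to_adult(1.8, 1, 1), 1.8)
  expect_error(invert_to_adult(1.5, 0, 1), class = "pedddi_domain_error")
})

test_that("approach dispatch builds the documented correction factors", {
  fa <- correction_factors("A")
  expect_equal(c(fa$z, fa$w), c(1, 1))
  fb <- correction_factors("B", "CYP3A4", 6)
  expect_equal(fb$z, z_ontogeny("CYP3A4", 6))
  expect_equal(fb$w, 1)
  fc <- correction_factors("C", "cyp3a4/5", 6)
  expect_equal(fc$w, w_allometry(25, 70), tolerance = 1e-12)
  expect_identical(fc$weight_source, "luscombe_formula")
  fo <- correction_factors("C", "CYP3A4", 6, pediatric_weight_kg = 20)
  expect_identical(fo$weight_source, "user_supplied")
  expect_equal(fo$w, w_allometry(20, 70), tolerance = 1e-12)
  expect_error(correction_factors("B"), class = "pedddi_domain_error")
  expect_error(correction_factors("C", "CYP2D6", 6),
               class = "pedddi_unsupported_enzyme_error")
})

test_that("single-case prediction reproduces published rows and records provenance", {
  pa <- predict_pediatric_aucr(1.49, "CYP3A4", 6, "A")
  expect_equal(pa$aucr_pediatric, 1.49)
  pb <- predict_pediatric_aucr(1.49, "CYP3A4", 6, "B")
  expect_equal(round_half_out(pb$aucr_pediatric, 2), 1.42)
  pc <- predict_pediatric_aucr(1.15, "CYP3A4", 3, "C")
  expect_equal(round_half_out(pc$aucr_pediatric, 2), 1.47)
  expect_identical(pc$direction, "inhibition")
  expect_identical(predict_pediatric_aucr(0.8, "CYP3A4", 3, "C")$direction,
                   "induction")
  expect_identical(predict_pediatric_aucr(1, "CYP3A4", 3, "C")$direction,
                   "none")
  expect_equal(pc$z, z_ontogeny("CYP3A4", 3))
  expect_equal(pc$pediatric_weight_kg, 16)
})

test_that("ontogeny-plus-allometry is the most conservative approach for inhibition DDIs", {
  tab <- load_validation_table()
  rows <- tab[tab$cyp == "CYP3A4" & tab$aucr_adult > 1, ]
  for (i in seq_len(nrow(rows))) {
    b <- predict_pediatric_aucr(rows$aucr_adult[i], rows$cyp[i],
                                rows$age_years[i], "B")$aucr_pediatric
    c_ <- predict_pediatric_aucr(rows$aucr_adult[i], rows$cyp[i],
                                 rows$age_years[i], "C")$aucr_pediatric
    expect_gte(c_, b)
  }
})
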