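test_that("median-effect fits recover exact curves and obey the Dm definition", {
  doses <- c(0.25, 0.5, 1, 2, 4)
  tb <- data.frame(dose = doses, growth = me_growth(doses, m = 1, dm = 1))
  fit <- fit_median_effect(tb)
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$dm, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # fa at D = 2 on the m = 1, Dm = 1 curve is 2/3
  expect_equal(median_effect_fa(fit, 2), 2 / 3, tolerance = 1e-9)
  # D = Dm gives fa = 0.5 regardless of slope
  steep <- fit_median_effect(
    data.frame(dose = doses, growth = me_growth(doses, m = 3, dm = 0.7)))
  expect_equal(median_effect_fa(steep, steep$dm), 0.5, tolerance = 1e-9)
  expect_equal(steep$m, 3, tolerance = 1e-6)

  # glance exposes IC50 = Dm
  expect_equal(glance(steep)$ic50, steep$dm)

  # scale equivariance: dose rescaling moves Dm, not m
  fit10 <- fit_median_effect(
    data.frame(dose = doses * 10, growth = me_growth(doses, m = 1, dm = 1)))
  expect_equal(fit10$dm, 10, tolerance = 1e-9)
  expect_equal(fit10$m, fit$m, tolerance = 1e-9)

  # unusable inputs
  expect_error(fit_median_effect(data.frame(dose = doses, growth = 1.2)),
               "fittable")
  expect_error(
    fit_median_effect(data.frame(dose = c(1, 2), growth = c(0.6, 0.4))),
    "3 usable")
  expect_error(fit_median_effect(data.frame(dose = -1, growth = 0.5)),
               "positive")
})

test_that("Dm recovery stays within 10% under 1% multiplicative noise", {
  doses <- c(0.5, 1, 2.5, 5, 10, 25)
  true_growth <- me_growth(doses, m = 2, dm = 5)
  rel_err <- sapply(1:100, function(s) {
    withr::with_seed(s, {
      noisy <- true_growth * (1 + rnorm(length(doses), 0, 0.01))
    })
    # growth can drift above 1 at low doses; such points are dropped with a
    # warning by design
    fit <- suppressWarnings(
      fit_median_effect(data.frame(dose = doses, growth = noisy)))
    abs(fit$dm - 5) / 5
  })
  expect_lt(max(rel_err), 0.10)
})

test_that("combination index obeys the Chou-Talalay additivity algebra", {
  doses <- c(0.25, 0.5, 1, 2, 4, 8)
  fitA <- fit_median_effect(
    data.frame(dose = doses, growth = me_growth(doses, m = 1.5, dm = 2)))
  fitB <- fit_median_effect(
    data.frame(dose = doses, growth = me_growth(doses, m = 0.8, dm = 0.5)))

  # half of each Dx: exactly additive
  fa <- 0.6
  ci <- combination_index(fitA, fitB,
                          median_effect_dose(fitA, fa) / 2,
                          median_effect_dose(fitB, fa) / 2, fa)
  expect_equal(ci, 1, tolerance = 1e-9)

  # single agent at its own Dx is self-additive
  expect_equal(combination_index(fitA, fitB,
                                 median_effect_dose(fitA, fa), 0, fa),
               1, tolerance = 1e-9)

  # sham combination: a drug with itself at (d, d) and the observed effect
  # of 2d gives CI = 1
  d <- 0.8
  fa_2d <- median_effect_fa(fitA, 2 * d)
  expect_equal(combination_index(fitA, fitA, d, d, fa_2d), 1,
               tolerance = 1e-9)

  expect_error(combination_index(fitA, fitB, 1, 1, 1.2), "observed_fa")
  expect_error(combination_index(fitA, fitB, 0, 0, 0.5), "zero")
})

test_that("Loewe excess vanishes on sham combinations and flags built-in synergy", {
  doses <- c(0.25, 0.5, 1, 2, 4, 8)
  fitA <- fit_median_effect(
    data.frame(dose = doses, growth = me_growth(doses, m = 1.5, dm = 2)))
  fitB <- fit_median_effect(
    data.frame(dose = doses, growth = me_growth(doses, m = 0.8, dm = 0.5)))

  # sham: drug with itself at (d, d); observed growth = single agent at 2d
  d <- 0.8
  obs <- 1 - median_effect_fa(fitA, 2 * d)
  ex <- loewe_excess(fitA, fitA, d, d, obs)
  expect_equal(as.numeric(ex), 0, tolerance = 1e-6)

  # either dose zero: expectation equals the single-agent curve
  ex_b0 <- loewe_excess(fitA, fitB, 2, 0, 1 - median_effect_fa(fitA, 2))
  expect_equal(as.numeric(ex_b0), 0, tolerance = 1e-9)

  # observation 10 points below the additive expectation: excess = 10
  expected <- attr(loewe_excess(fitA, fitB, 1, 0.3, 0.5), "expected_growth")
  ex10 <- loewe_excess(fitA, fitB, 1, 0.3, expected - 0.10)
  expect_equal(as.numeric(ex10), 10, tolerance = 1e-6)
  # antisymmetry around the expectation
  ex_neg <- loewe_excess(fitA, fitB, 1, 0.3, expected + 0.10)
  expect_equal(as.numeric(ex_neg), -10, tolerance = 1e-6)

  # plate scoring returns the best synergy first
  plate <- data.frame(dose_a = c(1, 2), dose_b = c(0.3, 0.6),
                      growth = c(expected - 0.2, 0.9))
  sc <- score_combinations(plate, fitA, fitB)
  expect_equal(sc$dose_a[1], 1)
  expect_equal(sc$loewe_excess[1], 20, tolerance = 1e-6)
  expect_true(all(diff(sc$loewe_excess) <= 0))
})

test_that("cisplatin classification applies the 5 uM rule with censoring", {
  expect_equal(classify_cisplatin_response(6.33), "resistant")
  expect_equal(classify_cisplatin_response(0.23), "sensitive")
  expect_equal(classify_cisplatin_response(5.0), "resistant")  # boundary
  expect_equal(classify_cisplatin_response(">10"), "resistant")
  expect_equal(classify_cisplatin_response(c("0.43", "2.10")),
               c("sensitive", "sensitive"))
  expect_error(classify_cisplatin_response(-1), "positive")
  expect_error(classify_cisplatin_response(">2"), "censored|Censored")
})

test_that("the cell-line panel reproduces the printed mutation-by-response splits", {
  panel <- tnbc_panel()
  expect_equal(nrow(panel), 9)
  expect_equal(sum(panel$response == "sensitive"), 6)
  expect_equal(sum(panel$response == "resistant"), 3)
  # PIK3CA mutants: 2 of 6 sensitive lines, 1 of 3 resistant lines
  expect_equal(sum(panel$pik3ca_mutant & panel$response == "sensitive"), 2)
  expect_equal(sum(panel$pik3ca_mutant & panel$response == "resistant"), 1)
  # exactly one TP53 wild-type line among the nine
  expect_equal(sum(!panel$tp53_mutant), 1)
  expect_equal(panel$cell_line[!panel$tp53_mutant], "CAL-51")
})
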