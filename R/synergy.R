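#' Fit the median-effect (Chou-Talalay) dose-response model
#'
#' Fits `fa/fu = (D/Dm)^m` — fa the fraction affected (1 - growth relative to
#' untreated control), fu = 1 - fa — by least squares on the linearised form
#' `log(fa/fu) = m log D - m log Dm`. Dm, the median-effect dose, is the
#' IC50. Points with fa outside (0, 1) carry no information on this scale and
#' are dropped with a warning; the remainder are clipped to [0.005, 0.995]
#' before the log transform to avoid infinities.
#'
#' @param table Data frame with columns `dose` (> 0) and `growth` (fraction
#'   of untreated control), optionally `drug` and `replicate`.
#' @param drug Optional drug identifier to filter on.
#' @return A `median_effect_fit`: list with `m` (slope), `dm` (median-effect
#'   dose = IC50), `r_squared`, `n` (points used), `drug`.
#' @examples
#' tb <- data.frame(dose = c(0.25, 0.5, 1, 2, 4),
#'                  growth = 1 - 1 / (1 + (1 / c(0.25, 0.5, 1, 2, 4))))
#' fit_median_effect(tb)
#' @export
fit_median_effect <- function(table, drug = NULL) {
  table <- as_tibble(table)
  if (!is.null(drug)) {
    if ("drug" %in% names(table)) {
      table <- table |> filter(.data$drug == .env$drug)
    }
  }
  stopifnot(all(c("dose", "growth") %in% names(table)))
  if (any(table$dose <= 0)) abort("Doses must be positive.")
  fa <- 1 - table$growth
  usable <- fa > 0 & fa < 1
  if (!any(usable)) {
    abort("Effect out of fittable range: no dose with 0 < fa < 1.")
  }
  if (any(!usable)) {
    warn(sprintf("Dropping %d point(s) with fa outside (0, 1).", sum(!usable)))
  }
  d <- table$dose[usable]
  fa <- pmin(pmax(fa[usable], 0.005), 0.995)
  if (length(unique(d)) < 3) {
    abort("Need at least 3 usable dose levels to fit the median-effect model.")
  }
  y <- log(fa / (1 - fa))
  x <- log(d)
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  dm <- exp(-unname(coef(fit)[1]) / m)
  # computed directly: summary.lm() warns on noise-free (perfect-fit) curves
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(m = m, dm = dm, r_squared = r2, n = length(d),
         drug = drug %||% (if ("drug" %in% names(table)) table$drug[1] else NA_character_)),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> %s: m = %.3f, Dm (IC50) = %.4g, r^2 = %.4f (n = %d)\n",
              x$drug %||% "drug", x$m, x$dm, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.median_effect_fit <- function(x, ...) {
  tibble(term = c("m", "dm"), estimate = c(x$m, x$dm))
}

#' @export
glance.median_effect_fit <- function(x, ...) {
  tibble(m = x$m, dm = x$dm, ic50 = x$dm, r_squared = x$r_squared, n = x$n)
}

#' Fraction affected at a dose under a median-effect fit
#' @param fit A `median_effect_fit`.
#' @param dose Dose(s), same units as the fit.
#' @return Fraction affected fa in (0, 1); 0 at dose 0.
#' @export
median_effect_fa <- function(fit, dose) {
  ifelse(dose == 0, 0, 1 / (1 + (fit$dm / dose)^fit$m))
}

#' Dose producing a given effect under a median-effect fit
#' @param fit A `median_effect_fit`.
#' @param fa Fraction affected in (0, 1).
#' @return Dose Dx with `median_effect_fa(fit, Dx) == fa`.
#' @export
median_effect_dose <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) abort("`fa` must lie strictly in (0, 1).")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' `CI = dA / DxA + dB / DxB`, where Dx is the single-agent dose that would
#' produce the observed combined effect, obtained by inverting each drug's
#' median-effect curve (mutually exclusive form, the CalcuSyn default).
#' CI < 1 indicates synergy, CI = 1 additivity, CI > 1 antagonism. A zero
#' dose contributes nothing (single agents are self-additive).
#'
#' @param fit_a,fit_b `median_effect_fit` objects for the two drugs.
#' @param dose_a,dose_b Doses in the combination (>= 0, not both 0).
#' @param observed_fa Observed fraction affected of the combination, in
#'   (0, 1).
#' @return Numeric combination index (vectorised over doses/effects).
#' @export
combination_index <- function(fit_a, fit_b, dose_a, dose_b, observed_fa) {
  if (any(observed_fa <= 0 | observed_fa >= 1)) {
    abort("`observed_fa` must lie strictly in (0, 1).")
  }
  if (any(dose_a < 0 | dose_b < 0) || any(dose_a == 0 & dose_b == 0)) {
    abort("Doses must be >= 0 and not both zero.")
  }
  dxa <- median_effect_dose(fit_a, observed_fa)
  dxb <- median_effect_dose(fit_b, observed_fa)
  dose_a / dxa + dose_b / dxb
}

# Loewe-additive fraction affected of a dose pair: the fa* solving
# dA/DxA(fa*) + dB/DxB(fa*) = 1. The left side decreases monotonically in
# fa*, so a unique root exists in (0, 1) for positive doses.
loewe_fa <- function(fit_a, fit_b, dose_a, dose_b, tol = 1e-10) {
  if (dose_a == 0 && dose_b == 0) return(0)
  if (dose_b == 0) return(median_effect_fa(fit_a, dose_a))
  if (dose_a == 0) return(median_effect_fa(fit_b, dose_b))
  f <- function(fa) {
    dose_a / median_effect_dose(fit_a, fa) +
      dose_b / median_effect_dose(fit_b, fa) - 1
  }
  eps <- 1e-9
  lo <- f(eps); hi <- f(1 - eps)
  if (lo < 0) {
    warn("Dose pair below both curves' range; Loewe effect clamped to 0.")
    return(0)
  }
  if (hi > 0) {
    warn("Dose pair beyond both curves' range; Loewe effect clamped to 1.")
    return(1)
  }
  uniroot(f, c(eps, 1 - eps), tol = tol)$root
}

#' Loewe-additivity synergy excess
#'
#' Computes the growth expected under Loewe additivity for a combination dose
#' pair — the effect level at which the two drugs' dose-equivalents sum to
#' one — and returns the excess of that expectation over the observed growth,
#' in percentage points. Positive excess means the combination suppressed
#' growth more than additivity predicts (synergy).
#'
#' @param fit_a,fit_b `median_effect_fit` objects for the two drugs.
#' @param dose_a,dose_b Doses in the combination (>= 0).
#' @param observed_growth Observed growth fraction of the combination.
#' @return Numeric excess in percentage points, with the Loewe-expected
#'   growth attached as attribute `"expected_growth"`.
#' @export
loewe_excess <- function(fit_a, fit_b, dose_a, dose_b, observed_growth) {
  stopifnot(length(dose_a) == 1, length(dose_b) == 1,
            length(observed_growth) == 1)
  expected_growth <- 1 - loewe_fa(fit_a, fit_b, dose_a, dose_b)
  structure((expected_growth - observed_growth) * 100,
            expected_growth = expected_growth)
}

#' Score a combination plate against single-agent fits
#'
#' Maps every combination dose pair of a plate table to its Chou-Talalay
#' combination index and Loewe excess.
#'
#' @param plate Data frame with columns `dose_a`, `dose_b`, `growth`
#'   (replicates are averaged per dose pair first).
#' @param fit_a,fit_b Single-agent `median_effect_fit` objects.
#' @return Tibble per dose pair: `dose_a`, `dose_b`, `growth`,
#'   `combination_index`, `expected_growth`, `loewe_excess`, sorted by
#'   decreasing excess (the first row is the best Loewe synergy).
#' @export
score_combinations <- function(plate, fit_a, fit_b) {
  plate <- as_tibble(plate) |>
    summarise(growth = mean(.data$growth), .by = c("dose_a", "dose_b"))
  plate |>
    mutate(
      combination_index = pmap(
        list(.data$dose_a, .data$dose_b, .data$growth),
        function(da, db, gr) {
          fa <- 1 - gr
          if (fa <= 0 || fa >= 1) return(NA_real_)
          combination_index(fit_a, fit_b, da, db, fa)
        }
      ) |> unlist(),
      expected_growth = pmap(
        list(.data$dose_a, .data$dose_b),
        function(da, db) 1 - loewe_fa(fit_a, fit_b, da, db)
      ) |> unlist(),
      loewe_excess = (.data$expected_growth - .data$growth) * 100
    ) |>
    arrange(desc(.data$loewe_excess))
}

#' Classify cisplatin response from an IC50
#'
#' Applies the clinical benchmark used for this panel: a line is
#' cisplatin-sensitive if its IC50 is below 5 uM (the IC50 of the normal
#' breast epithelial line MCF10A, 5.25 uM, anchors the cutoff) and resistant
#' above; the boundary value 5 is classified resistant. Right-censored
#' values given as strings like `">10"` are resistant provided the censoring
#' bound is at least 5.
#'
#' @param ic50 Numeric IC50(s) in uM, or character with optional `">x"`
#'   censoring.
#' @return Character vector, `"sensitive"` or `"resistant"`.
#' @examples
#' classify_cisplatin_response(c(0.23, 6.33))
#' classify_cisplatin_response(">10")
#' @export
classify_cisplatin_response <- function(ic50) {
  vapply(ic50, function(x) {
    if (is.character(x) || is.factor(x)) {
      x <- trimws(as.character(x))
      if (startsWith(x, ">")) {
        bound <- suppressWarnings(as.numeric(sub("^>", "", x)))
        if (is.na(bound) || bound <= 0) abort(paste0("Unparseable IC50: ", x))
        if (bound < 5) {
          abort(paste0("Censored IC50 ", x,
                       " cannot be classified (bound below 5 uM)."))
        }
        return("resistant")
      }
      x <- suppressWarnings(as.numeric(x))
    }
    if (is.na(x) || x <= 0) abort("IC50 must be positive.")
    if (x < 5) "sensitive" else "resistant"
  }, character(1), USE.NAMES = FALSE)
}

#' TNBC cell-line sensitivity panel
#'
#' The printed drug-sensitivity panel for nine TNBC cell lines: cisplatin
#' IC50 (uM, `">10"` right-censored for MFM-223) and PIK3CA / TP53 mutation
#' status as annotated from the Cancer Cell Line Encyclopedia. Shipped as
#' plain text in `extdata`.
#'
#' @param classify Add `response` (via [classify_cisplatin_response()]) and
#'   logical `pik3ca_mutant`, `tp53_mutant` columns; default TRUE.
#' @return Tibble with one row per cell line.
#' @export
tnbc_panel <- function(classify = TRUE) {
  path <- system.file("extdata", "tnbc_panel.csv", package = "perturbnet")
  panel <- readr::read_csv(path, col_types = "cccc")
  if (classify) {
    panel <- panel |>
      mutate(
        response = classify_cisplatin_response(.data$cisplatin_ic50),
        pik3ca_mutant = .data$pik3ca_mutation != "WT",
        tp53_mutant = .data$tp53_mutation != "WT"
      )
  }
  panel
}

#' Dose-response curve with median-effect fit overlay
#' @param object A `median_effect_fit`.
#' @param table Optional data frame with `dose`, `growth` to show as points.
#' @param ... Unused.
#' @return A ggplot object, growth versus dose on a log axis.
#' @export
autoplot.median_effect_fit <- function(object, table = NULL, ...) {
  rng <- if (!is.null(table)) range(table$dose) else object$dm * c(1 / 16, 16)
  curve <- tibble(dose = exp(seq(log(rng[1]), log(rng[2]), length.out = 200))) |>
    mutate(growth = 1 - median_effect_fa(object, .data$dose))
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$dose, y = .data$growth)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "growth (fraction of control)",
                  title = sprintf("%s: m = %.2f, IC50 = %.3g",
                                  object$drug %||% "median-effect fit",
                                  object$m, object$dm)) +
    ggplot2::theme_minimal()
  if (!is.null(table)) {
    p <- p + ggplot2::geom_point(data = as_tibble(table), alpha = 0.6)
  }
  p
}
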