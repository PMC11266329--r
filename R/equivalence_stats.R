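## Equivalence analysis: quadrature-derived margin, paired two one-sided
## t tests (TOST), and the multiple-testing-corrected significance level.

#' Derive the equivalence margin from a quadrature uncertainty budget
#'
#' The attenuation-correction uncertainty is assumed independent of all
#' other PET uncertainties, so it adds in quadrature to the baseline PET-CT
#' SUV uncertainty. The margin is the largest attenuation-correction
#' uncertainty that raises the total by no more than `allowed_increase`:
#' `sqrt((delta_petct + allowed_increase)^2 - delta_petct^2)`. With the
#' default literature repeatability of 12% and a 0.5% allowed increase this
#' gives 3.5%.
#'
#' @param delta_petct baseline PET-CT SUV uncertainty (%; > 0).
#' @param allowed_increase tolerated increase in total uncertainty (%; > 0).
#' @return Margin (%).
#' @export
derive_margin <- function(delta_petct = 12, allowed_increase = 0.5) {
  if (delta_petct <= 0 || allowed_increase <= 0)
    stop("delta_petct and allowed_increase must be > 0", call. = FALSE)
  sqrt((delta_petct + allowed_increase)^2 - delta_petct^2)
}

#' Total uncertainty from two independent components
#'
#' `sqrt(a^2 + b^2)`; commutative and never below either component.
#'
#' @param delta_petct,delta_ac non-negative uncertainties (%).
#' @return Combined uncertainty (%).
#' @export
quadrature_total <- function(delta_petct, delta_ac) {
  if (delta_petct < 0 || delta_ac < 0)
    stop("uncertainties must be non-negative", call. = FALSE)
  sqrt(delta_petct^2 + delta_ac^2)
}

#' TOST p-value from summary statistics
#'
#' Two one-sided paired t tests against the interval `(-margin, +margin)`:
#' `t_low = (mean + margin) / se` and `t_high = (margin - mean) / se`, each
#' with `n - 1` degrees of freedom and an upper-tail p-value. The reported
#' p is the larger of the two (standard TOST convention); equivalence is
#' declared when it does not exceed the corrected significance level.
#'
#' @param mean_diff mean paired difference (%).
#' @param se_diff its standard error (%; > 0).
#' @param n number of pairs (>= 2).
#' @param margin equivalence margin (%; > 0).
#' @return p-value, with the two one-sided t statistics attached as
#'   attributes `t_low` and `t_high`. A degenerate `se_diff = 0` returns 0
#'   when `|mean_diff| < margin`, else 1, with a warning.
#' @export
tost_from_summary <- function(mean_diff, se_diff, n, margin) {
  if (n < 2) stop("TOST needs n >= 2", call. = FALSE)
  if (margin <= 0) stop("margin must be > 0", call. = FALSE)
  if (se_diff < 0) stop("se_diff must be >= 0", call. = FALSE)
  if (se_diff == 0) {
    warning("degenerate SE = 0; p-value set by whether |mean| < margin")
    return(if (abs(mean_diff) < margin) 0 else 1)
  }
  df <- n - 1
  t_low <- (mean_diff + margin) / se_diff
  t_high <- (margin - mean_diff) / se_diff
  p <- max(stats::pt(t_low, df, lower.tail = FALSE),
           stats::pt(t_high, df, lower.tail = FALSE))
  structure(p, t_low = t_low, t_high = t_high)
}

#' Paired TOST from per-patient differences
#'
#' Computes the mean and standard error (`sd / sqrt(n)`, sample sd with
#' `n - 1` denominator, matching the t test's degrees of freedom) of the
#' paired percent differences and delegates to [tost_from_summary()].
#'
#' @param diffs numeric vector of per-patient percent differences (n >= 2).
#' @param margin equivalence margin (%).
#' @param alpha_corrected significance level used for the equivalence call.
#' @param comparison label recorded in the result.
#' @return Object of class `equivalence_result`: `comparison`, `n`,
#'   `mean_diff`, `se_diff`, `margin`, `p_value`, `alpha_corrected`,
#'   `equivalent`.
#' @export
tost_paired <- function(diffs, margin, alpha_corrected = 0.05,
                        comparison = "") {
  n <- length(diffs)
  if (n < 2) stop("TOST needs at least two paired differences", call. = FALSE)
  m <- mean(diffs)
  se <- sd(diffs) / sqrt(n)
  p <- tost_from_summary(m, se, n, margin)
  structure(list(comparison = comparison, n = n, mean_diff = m, se_diff = se,
                 margin = margin, p_value = as.numeric(p),
                 alpha_corrected = alpha_corrected,
                 equivalent = as.numeric(p) <= alpha_corrected),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("<equivalence %s>  n=%d  mean %.2f%% +- %.2f%% (SE)  margin %.2f%%  p=%.3g  %s\n",
              x$comparison, x$n, x$mean_diff, x$se_diff, x$margin, x$p_value,
              if (x$equivalent) "EQUIVALENT" else "not equivalent"))
  invisible(x)
}

#' Multiple-testing-corrected significance level
#'
#' `base_alpha / (n_tests - 1)`, implemented exactly as the study's printed
#' arithmetic (note: plain Bonferroni would divide by `n_tests`). The
#' unrounded value is used for decisions; `reported` carries the 3-decimal
#' rounding used in text.
#'
#' @param n_tests number of tests (>= 2).
#' @param base_alpha base significance level (default 0.05).
#' @return Corrected alpha, with the rounded value as attribute `reported`.
#' @export
corrected_alpha <- function(n_tests = 8L, base_alpha = 0.05) {
  if (n_tests < 2) stop("n_tests must be >= 2", call. = FALSE)
  a <- base_alpha / (n_tests - 1)
  structure(a, reported = round(a, 3))
}
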