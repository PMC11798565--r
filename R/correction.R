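#' Misclassification profile for the prevalence correction
#'
#' Bundles the plug-in quantities the correction needs: the population
#' fractions of the confuser classes (healthy, MDD, BD), the rates at which
#' the classifier falsely calls each confuser class positive, and the
#' true-positive to false-negative ratio observed in external validation.
#' Classes outside \{healthy, MDD, BD\} contribute no expected false
#' positives, mirroring the correction formula.
#'
#' The default profile carries the published plug-in values: P_hc = 0.80,
#' r_hc = 0.031, P_mdd = 0.079, r_mdd = 0.554, P_bd = 0.004, r_bd = 0.594,
#' and TP:FN = 46:15.
#'
#' @param p_healthy,p_mdd,p_bd Population fractions of the confuser classes.
#' @param r_healthy,r_mdd,r_bd False-positive rates of the classifier on the
#'   confuser classes.
#' @param tp_fn_ratio True-positive : false-negative ratio (> 0); equals
#'   sensitivity / (1 - sensitivity).
#' @return A `misclassification_profile` object.
#' @export
#' @examples
#' misclassification_profile()
misclassification_profile <- function(p_healthy = 0.80, r_healthy = 0.031,
                                      p_mdd = 0.079, r_mdd = 0.554,
                                      p_bd = 0.004, r_bd = 0.594,
                                      tp_fn_ratio = 46 / 15) {
  p <- c(healthy = p_healthy, mdd = p_mdd, bd = p_bd)
  r <- c(healthy = r_healthy, mdd = r_mdd, bd = r_bd)
  if (any(p < 0) || any(p > 1) || sum(p) > 1 + 1e-9) {
    stop("confuser-class fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  if (any(r < 0) || any(r > 1)) {
    stop("false-positive rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(tp_fn_ratio) || tp_fn_ratio <= 0) {
    stop("tp_fn_ratio must be positive", call. = FALSE)
  }
  structure(list(p = p, r = r, tp_fn_ratio = tp_fn_ratio),
            class = "misclassification_profile")
}

#' @export
print.misclassification_profile <- function(x, ...) {
  cat("Misclassification profile\n")
  for (k in names(x$p)) {
    cat(sprintf("  %-8s P = %.3f, false-positive rate = %.3f\n",
                k, x$p[[k]], x$r[[k]]))
  }
  cat(sprintf("  TP:FN ratio = %.4f (sensitivity %.4f)\n",
              x$tp_fn_ratio, x$tp_fn_ratio / (1 + x$tp_fn_ratio)))
  invisible(x)
}

#' Read / write a misclassification profile (YAML)
#'
#' @param path File path.
#' @return `read_profile()` returns a `misclassification_profile`.
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  misclassification_profile(
    p_healthy = y$p_healthy, r_healthy = y$r_healthy,
    p_mdd = y$p_mdd, r_mdd = y$r_mdd,
    p_bd = y$p_bd, r_bd = y$r_bd,
    tp_fn_ratio = y$tp_fn_ratio
  )
}

#' @rdname read_profile
#' @param profile A `misclassification_profile`.
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(list(
    p_healthy = unname(profile$p["healthy"]), r_healthy = unname(profile$r["healthy"]),
    p_mdd = unname(profile$p["mdd"]), r_mdd = unname(profile$r["mdd"]),
    p_bd = unname(profile$p["bd"]), r_bd = unname(profile$r["bd"]),
    tp_fn_ratio = profile$tp_fn_ratio
  ), path)
  invisible(path)
}

#' Crude prevalence
#'
#' The proportion of sampled respondents the classifier calls positive,
#' before any misclassification correction.
#'
#' @param n_crude Number of classifier positives (0..n).
#' @param n Sample size (> 0).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' crude_prevalence(62, 750)  # 0.0827 -> 8.3%
crude_prevalence <- function(n_crude, n) {
  stopifnot(length(n) == 1, length(n_crude) == 1)
  if (n <= 0) stop("sample size n must be positive", call. = FALSE)
  if (n_crude < 0 || n_crude > n) {
    stop("n_crude must lie in [0, n]", call. = FALSE)
  }
  n_crude / n
}

#' Expected false positives from the confuser classes
#'
#' Evaluates N_fp = (P_hc r_hc + P_mdd r_mdd + P_bd r_bd) * n: the number of
#' classifier positives expected to be healthy, MDD or BD respondents
#' misclassified as cases. Component terms are kept unrounded; only the
#' summed total is rounded (half away from zero), which with the default
#' profile at n = 750 gives 53.2065 -> 53.
#'
#' @param profile A [misclassification_profile()].
#' @param n Sample size.
#' @return A tibble with per-class expected counts (`class`, `expected`) in
#'   attribute form plus columns `n_fp_real` (unrounded total) and `n_fp`
#'   (rounded total); see also [correct_prevalence()].
#' @export
#' @examples
#' expected_false_positives(misclassification_profile(), 750)
expected_false_positives <- function(profile, n) {
  stopifnot(inherits(profile, "misclassification_profile"), n > 0)
  components <- profile$p * profile$r * n
  total <- sum(components)
  tibble::tibble(
    n_fp_real = total,
    n_fp = as.integer(round_half_away(total)),
    components = list(tibble::tibble(class = names(components),
                                     expected = unname(components)))
  )
}

#' Back-calculate true-positive and false-negative counts
#'
#' Given the crude positive count and the expected false positives, the true
#' positives are N_tp = N_crude - N_fp (clamped at zero with a warning when
#' the expected false positives exceed the crude count, as can happen in
#' bootstrap resamples), and the false negatives follow from the external
#' TP:FN ratio p as N_fn = N_tp / p, rounded half away from zero.
#'
#' @param n_crude Crude positive count.
#' @param n_fp Expected false positives (integer or real).
#' @param tp_fn_ratio TP:FN ratio (> 0).
#' @return A tibble with `n_tp`, `n_fn_real`, `n_fn`.
#' @export
#' @examples
#' correct_counts(62, 53, 46 / 15)
correct_counts <- function(n_crude, n_fp, tp_fn_ratio = 46 / 15) {
  stopifnot(n_crude >= 0, n_fp >= 0)
  if (tp_fn_ratio <= 0) stop("tp_fn_ratio must be positive", call. = FALSE)
  n_tp <- n_crude - n_fp
  if (n_tp < 0) {
    warning("expected false positives exceed the crude count; ",
            "true positives clamped to 0", call. = FALSE)
    n_tp <- 0
  }
  n_fn_real <- n_tp / tp_fn_ratio
  tibble::tibble(
    n_tp = n_tp,
    n_fn_real = n_fn_real,
    n_fn = as.integer(round_half_away(n_fn_real))
  )
}

#' Misclassification-corrected prevalence estimate
#'
#' Runs the full correction on a crude positive count: expected false
#' positives are removed, expected false negatives restored, and the adjusted
#' prevalence P = (N_crude - N_fp + N_fn) / n reported alongside all
#' intermediate counts. This is the package's central computation; with the
#' default profile and the reference study's counts (62 positives of 750) it
#' reproduces the worked example 8.3% crude -> 1.6% adjusted.
#'
#' When expected false positives exceed the crude count the reported
#' (headline) adjusted count and prevalence are clamped to zero with a
#' warning; the unclamped values are kept in `n_adjusted_raw` and
#' `adjusted_prevalence_raw`. Simulation studies of the estimator should
#' average the raw value: truncation at zero makes the clamped estimator
#' upward-biased when the true prevalence is small relative to the
#' false-positive load.
#'
#' @param n_crude Crude positive count.
#' @param n Sample size.
#' @param profile A [misclassification_profile()].
#' @return A `prevalence_correction` object.
#' @export
#' @examples
#' correct_prevalence(62, 750)
correct_prevalence <- function(n_crude, n,
                               profile = misclassification_profile()) {
  crude <- crude_prevalence(n_crude, n)
  fp <- expected_false_positives(profile, n)
  cc <- correct_counts(n_crude, fp$n_fp, profile$tp_fn_ratio)
  n_adjusted_raw <- n_crude - fp$n_fp + cc$n_fn
  n_adjusted <- n_adjusted_raw
  clamped <- FALSE
  if (n_adjusted < 0 || n_adjusted > n) {
    warning("adjusted case count outside [0, n]; clamped", call. = FALSE)
    n_adjusted <- min(max(n_adjusted, 0), n)
    clamped <- TRUE
  }
  adj <- n_adjusted / n
  structure(list(
    n = n, n_crude = n_crude,
    n_fp_real = fp$n_fp_real, n_fp = fp$n_fp,
    fp_components = fp$components[[1]],
    n_tp = cc$n_tp, n_fn_real = cc$n_fn_real, n_fn = cc$n_fn,
    n_adjusted = n_adjusted,
    n_adjusted_raw = n_adjusted_raw,
    crude_prevalence = crude,
    adjusted_prevalence = adj,
    adjusted_prevalence_raw = n_adjusted_raw / n,
    clamped = clamped,
    profile = profile
  ), class = "prevalence_correction")
}

#' Adjusted prevalence from a correction result
#'
#' @param result A `prevalence_correction`.
#' @param n Sample size (defaults to the one stored in the result).
#' @return Fraction in \[0, 1\].
#' @export
adjusted_prevalence <- function(result, n = result$n) {
  stopifnot(inherits(result, "prevalence_correction"), n > 0)
  adj <- (result$n_crude - result$n_fp + result$n_fn) / n
  if (adj < 0 || adj > 1) {
    warning("adjusted prevalence outside [0, 1]; clamped", call. = FALSE)
    adj <- min(max(adj, 0), 1)
  }
  adj
}

#' Adjusted 2x2 confusion table
#'
#' Arranges the corrected counts as a 2x2 table of predicted status against
#' adjusted case status: predicted positives split into true positives and
#' false positives, predicted negatives into false negatives and true
#' negatives; cells are non-negative and sum to n.
#'
#' @param result A `prevalence_correction`.
#' @param n Sample size (defaults to the stored one).
#' @return A 2x2 integer matrix with dimnames `predicted` x `adjusted`.
#' @export
#' @examples
#' confusion_table(correct_prevalence(62, 750))
confusion_table <- function(result, n = result$n) {
  stopifnot(inherits(result, "prevalence_correction"))
  tn <- n - result$n_crude - result$n_fn
  m <- matrix(c(result$n_tp, result$n_fn, result$n_fp, tn), nrow = 2,
              dimnames = list(predicted = c("case", "non-case"),
                              adjusted = c("case", "non-case")))
  if (any(m < 0)) {
    warning("confusion table has a negative cell; counts are inconsistent ",
            "with n", call. = FALSE)
  }
  m
}

#' @export
print.prevalence_correction <- function(x, ...) {
  cat("Misclassification-corrected prevalence\n")
  cat(sprintf("  sample size          %d\n", as.integer(x$n)))
  cat(sprintf("  crude positives      %d  (crude prevalence %.1f%%)\n",
              as.integer(x$n_crude), 100 * x$crude_prevalence))
  cat(sprintf("  expected false pos.  %d  (unrounded %.4f)\n",
              x$n_fp, x$n_fp_real))
  cat(sprintf("  true positives       %d\n", as.integer(x$n_tp)))
  cat(sprintf("  expected false neg.  %d  (unrounded %.4f)\n",
              x$n_fn, x$n_fn_real))
  cat(sprintf("  adjusted cases       %d\n", as.integer(x$n_adjusted)))
  cat(sprintf("  adjusted prevalence  %.1f%%\n", 100 * x$adjusted_prevalence))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prevalence_correction <- function(x, ...) {
  tibble::tibble(
    quantity = c("n", "n_crude", "n_fp_real", "n_fp", "n_tp", "n_fn_real",
                 "n_fn", "n_adjusted", "crude_prevalence",
                 "adjusted_prevalence"),
    value = c(x$n, x$n_crude, x$n_fp_real, x$n_fp, x$n_tp, x$n_fn_real,
              x$n_fn, x$n_adjusted, x$crude_prevalence,
              x$adjusted_prevalence)
  )
}

#' @exportS3Method generics::glance
glance.prevalence_correction <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_crude = x$n_crude, n_fp = x$n_fp, n_tp = x$n_tp,
    n_fn = x$n_fn, n_adjusted = x$n_adjusted,
    crude_prevalence = x$crude_prevalence,
    adjusted_prevalence = x$adjusted_prevalence
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.prevalence_correction <- function(object, ...) {
  df <- tibble::tibble(
    stage = factor(c("crude", "- false positives", "+ false negatives"),
                   levels = c("crude", "- false positives",
                              "+ false negatives")),
    count = c(object$n_crude, object$n_crude - object$n_fp, object$n_adjusted)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(
      x = NULL, y = "case count",
      title = "Correction of the crude case count",
      subtitle = sprintf("crude %.1f%% -> adjusted %.1f%% (n = %d)",
                         100 * object$crude_prevalence,
                         100 * object$adjusted_prevalence,
                         as.integer(object$n))
    ) +
    ggplot2::theme_minimal()
}

#' Format a prevalence as a percentage string
#'
#' One-decimal percentage with halves rounded away from zero, matching the
#' conventional reporting format (0.082667 -> "8.3%").
#'
#' @param p Fraction in \[0, 1\].
#' @return Character string.
#' @export
format_prevalence <- function(p) {
  sprintf("%.1f%%", round_half_away(1000 * p) / 10)
}
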