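new_interval_estimate <- function(point, lower, upper, replicates, method,
                                  seed, boot_stats = NULL) {
  structure(list(
    point = point,
    lower = min(max(lower, 0), 1),
    upper = min(max(upper, 0), 1),
    replicates = as.integer(replicates),
    method = method,
    seed = seed,
    boot_stats = boot_stats
  ), class = "interval_estimate")
}

#' Bootstrap confidence interval for a prevalence
#'
#' Treats the sample as `n` binary case indicators of which `case_count` are
#' positive and resamples them with replacement `replicates` times (the
#' replicate positive count is therefore a Binomial(n, case_count/n) draw,
#' which is how the resampling is carried out). Two interval types are
#' available:
#'
#' * `normal`: point +/- 1.96 x SD of the replicate prevalences
#'   (normal-approximation bootstrap);
#' * `percentile`: the empirical 2.5 and 97.5 percentiles of the replicate
#'   prevalences.
#'
#' Bounds are clamped to \[0, 1\]. With 12 cases of 750 and 10,000 replicates
#' the normal interval is approximately 0.7%--2.5%.
#'
#' @param case_count Number of positive indicators (0..n).
#' @param n Sample size.
#' @param replicates Bootstrap replicates (default 10,000).
#' @param method `"normal"` or `"percentile"`.
#' @param seed Integer seed.
#' @return An `interval_estimate`.
#' @export
#' @examples
#' bootstrap_prevalence_ci(12, 750, seed = 1)
bootstrap_prevalence_ci <- function(case_count, n, replicates = 10000,
                                    method = c("normal", "percentile"),
                                    seed = NULL) {
  method <- match.arg(method)
  stopifnot(case_count >= 0, case_count <= n, n >= 1)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  p_hat <- case_count / n
  with_seed(seed, {
    boot_p <- stats::rbinom(replicates, n, p_hat) / n
    if (method == "normal") {
      sd_b <- stats::sd(boot_p)
      if (is.na(sd_b)) sd_b <- 0
      new_interval_estimate(p_hat, p_hat - 1.96 * sd_b, p_hat + 1.96 * sd_b,
                            replicates, "normal_boot", seed, boot_p)
    } else {
      q <- unname(stats::quantile(boot_p, c(0.025, 0.975), type = 7))
      new_interval_estimate(p_hat, q[1], q[2], replicates, "percentile_boot",
                            seed, boot_p)
    }
  })
}

#' Bootstrap confidence interval for the corrected prevalence
#'
#' Full-pipeline bootstrap: each replicate resamples respondents (rows) with
#' replacement, recomputes the crude positive count from their predicted
#' labels, and re-applies the entire misclassification correction. The
#' interval is then formed from the replicate adjusted prevalences with the
#' chosen method. Replicates in which expected false positives exceed the
#' resampled crude count clamp the true-positive count at zero (with the
#' usual warning suppressed inside the replicate loop).
#'
#' @param sample A participant table with a `predicted_label` column.
#' @param profile A [misclassification_profile()].
#' @param replicates Bootstrap replicates.
#' @param method `"normal"` or `"percentile"`.
#' @param seed Integer seed.
#' @return An `interval_estimate` whose point is the full-sample adjusted
#'   prevalence.
#' @export
bootstrap_corrected_ci <- function(sample,
                                   profile = misclassification_profile(),
                                   replicates = 10000,
                                   method = c("normal", "percentile"),
                                   seed = NULL) {
  method <- match.arg(method)
  stopifnot("predicted_label" %in% names(sample))
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  labels <- as.integer(sample$predicted_label)
  n <- length(labels)
  point_fit <- correct_prevalence(sum(labels), n, profile)
  adjust_count <- function(n_crude) {
    fp <- expected_false_positives(profile, n)
    cc <- suppressWarnings(correct_counts(n_crude, fp$n_fp,
                                          profile$tp_fn_ratio))
    min(max((n_crude - fp$n_fp + cc$n_fn) / n, 0), 1)
  }
  with_seed(seed, {
    boot_adj <- vapply(seq_len(replicates), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      adjust_count(sum(labels[idx]))
    }, numeric(1))
    point <- point_fit$adjusted_prevalence
    if (method == "normal") {
      sd_b <- stats::sd(boot_adj)
      if (is.na(sd_b)) sd_b <- 0
      new_interval_estimate(point, point - 1.96 * sd_b, point + 1.96 * sd_b,
                            replicates, "normal_boot_corrected", seed, boot_adj)
    } else {
      q <- unname(stats::quantile(boot_adj, c(0.025, 0.975), type = 7))
      new_interval_estimate(point, q[1], q[2], replicates,
                            "percentile_boot_corrected", seed, boot_adj)
    }
  })
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f (95%% CI %.4f-%.4f), %d replicates\n",
              x$method, x$point, x$lower, x$upper, x$replicates))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.interval_estimate <- function(x, ...) {
  tibble::tibble(point = x$point, lower = x$lower, upper = x$upper,
                 replicates = x$replicates, method = x$method)
}

#' @exportS3Method ggplot2::autoplot
autoplot.interval_estimate <- function(object, ...) {
  stopifnot(!is.null(object$boot_stats))
  df <- tibble::tibble(stat = object$boot_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = c(object$lower, object$point,
                                       object$upper),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(x = "bootstrap replicate prevalence", y = "replicates",
                  title = sprintf("Bootstrap distribution (%s)", object$method),
                  subtitle = sprintf("%.2f%% (95%% CI %.2f%%-%.2f%%)",
                                     100 * object$point, 100 * object$lower,
                                     100 * object$upper)) +
    ggplot2::theme_minimal()
}
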