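#' Study run configuration
#'
#' Bundles everything one replication of the survey study needs: the
#' demographic composition, the latent-class mix, the feature schema, the
#' misclassification profile, the classifier mode and the bootstrap settings.
#'
#' @param sample_n Quota-matched sample size (default 750, the reference
#'   design).
#' @param panel_n Size of the simulated web panel from which the sample is
#'   recruited; must comfortably exceed `sample_n` in every demographic cell.
#' @param mode `"oracle"` (rate-based classifier; isolates the correction) or
#'   `"trained"` (fit the MLP on a synthetic development set, then apply it).
#' @param mix A [population_mix()].
#' @param composition A composition table.
#' @param schema A [feature_schema()]; features are only generated in
#'   `"trained"` mode (the oracle needs none).
#' @param profile A [misclassification_profile()].
#' @param rates [oracle_rates()] for oracle mode.
#' @param dev_n_case,dev_n_control Development-set class sizes for trained
#'   mode (defaults 223 cases / 1776 controls, the reference development-set
#'   shape).
#' @param spec,control MLP architecture and training settings (trained mode).
#' @param replicates,ci_method Bootstrap settings.
#' @param seed Master seed; stage seeds are derived from it.
#' @param output_dir Optional directory; when set, intermediate tables and
#'   the report are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(sample_n = 750L,
                       panel_n = 20000L,
                       mode = c("oracle", "trained"),
                       mix = population_mix(),
                       composition = default_composition(),
                       schema = default_feature_schema(),
                       profile = misclassification_profile(),
                       rates = oracle_rates(),
                       dev_n_case = 223L,
                       dev_n_control = 1776L,
                       spec = mlp_spec(),
                       control = mlp_control(),
                       replicates = 10000L,
                       ci_method = "normal",
                       seed = 1L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  if (sample_n < 1) stop("sample_n must be >= 1", call. = FALSE)
  if (panel_n < sample_n) stop("panel_n must be >= sample_n", call. = FALSE)
  structure(list(
    sample_n = as.integer(sample_n), panel_n = as.integer(panel_n),
    mode = mode, mix = validate_mix(mix),
    composition = validate_composition(composition), schema = schema,
    profile = profile, rates = rates,
    dev_n_case = as.integer(dev_n_case),
    dev_n_control = as.integer(dev_n_control),
    spec = spec, control = control,
    replicates = as.integer(replicates), ci_method = ci_method,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognised keys: `sample_n`, `panel_n`, `mode`, `seed`, `replicates`,
#' `ci_method`, `p_sz` (schizophrenia share of the simulated mix),
#' `composition`, `schema`, `profile` (paths to CSV/YAML files, resolved
#' relative to the config file; defaults used when absent), `output_dir`.
#' Referenced files must exist.
#'
#' @param path Path to a YAML config file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    if (!file.exists(full)) stop("config references missing file: ", p,
                                 call. = FALSE)
    full
  }
  args <- list()
  for (k in c("sample_n", "panel_n", "mode", "seed", "replicates",
              "ci_method", "dev_n_case", "dev_n_control")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$p_sz)) args$mix <- population_mix(sz = y$p_sz)
  if (!is.null(y$composition)) args$composition <- read_composition(resolve(y$composition))
  if (!is.null(y$schema)) args$schema <- read_feature_schema(resolve(y$schema))
  if (!is.null(y$profile)) args$profile <- read_profile(resolve(y$profile))
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  do.call(run_config, args)
}

#' Run one full study replication
#'
#' Executes the study stages in pipeline order: simulate the panel, allocate
#' quotas and draw the quota-matched sample, classify it (oracle rates or a
#' freshly trained MLP on a synthetic development set), compute the crude
#' prevalence, apply the misclassification correction, and attach bootstrap
#' confidence intervals for the crude and adjusted estimates. All randomness
#' derives from the single master seed, so reports regenerate exactly.
#'
#' @param config A [run_config()].
#' @return A `study_report` with elements `correction`
#'   (a `prevalence_correction`), `crude_ci`, `adjusted_ci`, `corrected_ci`
#'   (interval estimates), `metrics` (trained mode only), `sample` (the
#'   classified sample tibble), and `seeds`.
#' @export
#' @examples
#' \donttest{
#' report <- run_study(run_config(panel_n = 5000, replicates = 500, seed = 7))
#' report$correction
#' }
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, 6))
  panel <- simulate_panel(config$mix, config$composition, config$panel_n,
                          seed = seeds[1])
  quota <- build_quota_table(config$composition, config$sample_n)
  sampled <- quota_sample(panel, quota, seed = seeds[2])

  metrics <- NULL
  if (config$mode == "oracle") {
    sampled <- oracle_classify(sampled, config$rates, seed = seeds[3])
  } else {
    dev <- tibble::tibble(
      id = seq_len(config$dev_n_case + config$dev_n_control),
      latent_class = factor(rep(c("sz", "healthy"),
                                c(config$dev_n_case, config$dev_n_control)),
                            levels = latent_classes())
    )
    dev <- generate_features(dev, config$schema, seed = seeds[4])
    dev_labels <- as.integer(dev$latent_class == "sz")
    fit <- train_mlp(dev, dev_labels, spec = config$spec,
                     control = config$control, seed = seeds[5])
    metrics <- classifier_metrics(mlp_forward(fit, dev), dev_labels,
                                  threshold = config$spec$threshold)
    sampled <- generate_features(sampled, config$schema, seed = seeds[6])
    sampled <- classify(fit, sampled)
  }

  n_crude <- sum(sampled$predicted_label)
  correction <- correct_prevalence(n_crude, config$sample_n, config$profile)
  crude_ci <- bootstrap_prevalence_ci(n_crude, config$sample_n,
                                      config$replicates, config$ci_method,
                                      seed = seeds[3] %% 1000000L + 1L)
  adjusted_ci <- bootstrap_prevalence_ci(correction$n_adjusted,
                                         config$sample_n, config$replicates,
                                         config$ci_method,
                                         seed = seeds[3] %% 1000000L + 2L)
  corrected_ci <- bootstrap_corrected_ci(sampled, config$profile,
                                         config$replicates, config$ci_method,
                                         seed = seeds[3] %% 1000000L + 3L)

  report <- structure(list(
    correction = correction,
    crude_ci = crude_ci,
    adjusted_ci = adjusted_ci,
    corrected_ci = corrected_ci,
    metrics = metrics,
    sample = sampled,
    seeds = seeds,
    config = config
  ), class = "study_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_survey(sampled, file.path(config$output_dir, "sample.csv"))
    write_composition(config$composition,
                      file.path(config$output_dir, "composition.csv"))
    render_report(report, "json", file.path(config$output_dir, "report.json"))
    render_report(report, "text", file.path(config$output_dir, "report.txt"))
  }
  report
}

report_as_list <- function(report) {
  cx <- report$correction
  out <- list(
    sample_n = as.integer(cx$n),
    mode = report$config$mode,
    seed = report$config$seed,
    correction = list(
      n_crude = as.integer(cx$n_crude),
      n_fp_real = cx$n_fp_real, n_fp = cx$n_fp,
      n_tp = as.integer(cx$n_tp),
      n_fn_real = cx$n_fn_real, n_fn = cx$n_fn,
      n_adjusted = as.integer(cx$n_adjusted),
      crude_prevalence = cx$crude_prevalence,
      adjusted_prevalence = cx$adjusted_prevalence
    ),
    confusion = {
      m <- suppressWarnings(confusion_table(cx))
      list(tp = m[1, 1], fp = m[1, 2], fn = m[2, 1], tn = m[2, 2])
    },
    crude_ci = unclass(tidy(report$crude_ci)),
    adjusted_ci = unclass(tidy(report$adjusted_ci)),
    corrected_ci = unclass(tidy(report$corrected_ci))
  )
  out$crude_ci <- lapply(as.list(tidy(report$crude_ci)), unname)
  out$adjusted_ci <- lapply(as.list(tidy(report$adjusted_ci)), unname)
  out$corrected_ci <- lapply(as.list(tidy(report$corrected_ci)), unname)
  if (!is.null(report$metrics)) {
    out$classifier_metrics <- as.list(glance(report$metrics))
  }
  out
}

#' Render a study report
#'
#' @param report A `study_report`.
#' @param format `"json"` (lossless, machine-readable; re-rendering the
#'   parsed JSON reproduces the bytes) or `"text"`.
#' @param path Optional file to write; the rendered string is returned
#'   invisibly either way.
#' @return The rendered report string, invisibly.
#' @export
render_report <- function(report, format = c("json", "text"), path = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    txt <- as.character(jsonlite::toJSON(report_as_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE))
  } else {
    txt <- paste(utils::capture.output({
      print(report$correction)
      cat("\nConfusion table (adjusted):\n")
      print(suppressWarnings(confusion_table(report$correction)))
      cat("\nIntervals:\n")
      print(report$crude_ci)
      print(report$adjusted_ci)
      print(report$corrected_ci)
      if (!is.null(report$metrics)) print(report$metrics)
    }), collapse = "\n")
  }
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
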