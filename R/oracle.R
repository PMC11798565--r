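#' Class-conditional positive-call rates for the oracle classifier
#'
#' The oracle classifier labels a respondent positive with a probability that
#' depends only on the latent diagnostic class. Defaults are the published
#' validation rates of the reference classifier: 3.1% of healthy individuals
#' falsely called positive (internal validation), 55.4% of MDD and 59.4% of
#' BD patients misclassified as schizophrenia (external validation), and a
#' schizophrenia sensitivity of 46/61 (about 0.754) — the exact external
#' true-positive fraction, kept in ratio form so the oracle is consistent
#' with the correction's TP:FN ratio of 46:15. The `other` class (e.g. OCD)
#' has no published misclassification rate and defaults to 0.
#'
#' @param healthy,mdd,bd,sz,other Positive-call probabilities in \[0, 1\].
#' @return A named numeric vector of class `oracle_rates`.
#' @export
#' @examples
#' oracle_rates()
oracle_rates <- function(healthy = 0.031, mdd = 0.554, bd = 0.594,
                         sz = 46 / 61, other = 0) {
  r <- c(healthy = healthy, mdd = mdd, bd = bd, sz = sz, other = other)
  if (any(r < 0) || any(r > 1)) {
    stop("oracle rates must lie in [0, 1]", call. = FALSE)
  }
  structure(r, class = c("oracle_rates", "numeric"))
}

#' Oracle classification by latent class
#'
#' Labels each row positive with probability `rates[latent_class]`,
#' independently across rows. This reproduces a classifier's validation error
#' structure (per-class sensitivity and false-positive rates) without any
#' trained weights, which isolates the downstream prevalence correction from
#' classifier fitting.
#'
#' @param table A participant table with a `latent_class` column.
#' @param rates An [oracle_rates()] vector.
#' @param seed Integer seed.
#' @return The table with `predicted_label` appended (integer 0/1).
#' @export
#' @examples
#' panel <- simulate_panel(population_mix(), panel_n = 100, seed = 1)
#' oracle_classify(panel, oracle_rates(), seed = 2)
oracle_classify <- function(table, rates = oracle_rates(), seed = NULL) {
  stopifnot("latent_class" %in% names(table))
  cls <- as.character(table$latent_class)
  missing <- setdiff(unique(cls), names(rates))
  if (length(missing) > 0) {
    stop("no oracle rate for class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(table)
  with_seed(seed, {
    out$predicted_label <- as.integer(
      stats::rbinom(nrow(out), 1L, unname(rates[cls])))
    out
  })
}
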