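#' Population mix over latent diagnostic classes
#'
#' The assumed composition of the general population over the five latent
#' classes. Defaults follow the published plug-in estimates used by the
#' correction: 80% of the population with no mental disorder, point
#' prevalence 7.9% for MDD and 0.4% for BD; the schizophrenia share is the
#' quantity under study and `other` closes the simplex.
#'
#' @param healthy,mdd,bd,sz Class fractions in \[0, 1\].
#' @param other Fraction for all remaining mental disorders; by default the
#'   remainder `1 - healthy - mdd - bd - sz`.
#' @return A named numeric vector of class `population_mix` (sums to 1).
#' @export
#' @examples
#' population_mix(sz = 0.016)
population_mix <- function(healthy = 0.80, mdd = 0.079, bd = 0.004,
                           sz = 0.016, other = NULL) {
  other <- other %||% (1 - healthy - mdd - bd - sz)
  mix <- c(healthy = healthy, mdd = mdd, bd = bd, sz = sz, other = other)
  if (any(mix < -1e-9) || any(mix > 1 + 1e-9)) {
    stop("population mix entries must lie in [0, 1]", call. = FALSE)
  }
  mix <- pmin(pmax(mix, 0), 1)
  if (abs(sum(mix) - 1) > 1e-9) {
    stop(sprintf("population mix must sum to 1 (got %.12f)", sum(mix)),
         call. = FALSE)
  }
  structure(mix, class = c("population_mix", "numeric"))
}

validate_mix <- function(mix) {
  if (inherits(mix, "population_mix")) return(mix)
  if (is.null(names(mix)) || !setequal(names(mix), latent_classes())) {
    stop("mix must be a population_mix() or a vector named ",
         paste(latent_classes(), collapse = ", "), call. = FALSE)
  }
  do.call(population_mix, as.list(mix[latent_classes()]))
}

#' Simulate a synthetic survey panel
#'
#' Draws a registry-style panel of potential respondents: each row gets a
#' demographic cell drawn from `composition` and a latent diagnostic class
#' drawn independently from `mix`. This emulates the pool of web-panel
#' monitors from which a quota-matched sample is recruited; no participation
#' or attrition behaviour is modelled.
#'
#' @param mix A [population_mix()].
#' @param composition A demographic composition table
#'   (default [default_composition()]).
#' @param panel_n Number of panelists to simulate.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A tibble with columns `id`, `age_group`, `gender`, `region`,
#'   `latent_class`.
#' @export
#' @examples
#' panel <- simulate_panel(population_mix(), panel_n = 500, seed = 1)
#' table(panel$latent_class)
simulate_panel <- function(mix, composition = default_composition(),
                           panel_n, seed = NULL) {
  mix <- validate_mix(mix)
  comp <- validate_composition(composition)
  stopifnot(panel_n >= 1)
  with_seed(seed, {
    cell_idx <- sample.int(nrow(comp), panel_n, replace = TRUE,
                           prob = comp$proportion)
    cls <- sample(latent_classes(), panel_n, replace = TRUE, prob = mix)
    tibble::tibble(
      id = seq_len(panel_n),
      age_group = comp$age_group[cell_idx],
      gender = comp$gender[cell_idx],
      region = comp$region[cell_idx],
      latent_class = factor(cls, levels = latent_classes())
    )
  })
}

#' Quota-sample a panel to match a demographic composition
#'
#' Recruits exactly `quota` respondents from each demographic cell, drawn
#' uniformly without replacement within the cell, mimicking recruitment that
#' stops once each cell's target is reached.
#'
#' @param panel A participant table (e.g. from [simulate_panel()]).
#' @param quota A quota table from [build_quota_table()].
#' @param seed Integer seed.
#' @return A tibble of sampled rows with exactly the quota count per cell,
#'   ordered by demographic cell.
#' @export
quota_sample <- function(panel, quota, seed = NULL) {
  stopifnot(all(c("age_group", "gender", "region") %in% names(panel)),
            "quota" %in% names(quota))
  panel <- as_cell_factors(tibble::as_tibble(panel))
  cells <- demographic_cells()
  key <- function(a, g, r) {
    (as.integer(a) - 1L) * 26L + (as.integer(g) - 1L) * 13L + as.integer(r)
  }
  panel_key <- key(panel$age_group, panel$gender, panel$region)
  quota_tbl <- as_cell_factors(tibble::as_tibble(quota))
  quota_key <- key(quota_tbl$age_group, quota_tbl$gender, quota_tbl$region)
  target <- integer(nrow(cells))
  target[quota_key] <- as.integer(quota_tbl$quota)
  if (sum(target) == 0) return(panel[0, , drop = FALSE])
  idx_by_cell <- split(seq_len(nrow(panel)), factor(panel_key, levels = seq_len(nrow(cells))))
  with_seed(seed, {
    picked <- lapply(which(target > 0L), function(k) {
      avail <- idx_by_cell[[k]]
      if (length(avail) < target[k]) {
        stop(sprintf(
          "panel has %d rows in cell %s/%s/%s but the quota requires %d",
          length(avail), cells$age_group[k], cells$gender[k], cells$region[k],
          target[k]), call. = FALSE)
      }
      avail[sample.int(length(avail), target[k])]
    })
    panel[unlist(picked), , drop = FALSE]
  })
}
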