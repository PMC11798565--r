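#' Demographic cell levels
#'
#' The survey design stratifies respondents over three items: five age groups
#' spanning ages 20--75, two genders, and the 13 geographical administrative
#' regions of Japan, giving 5 x 2 x 13 = 130 demographic cells.
#'
#' Age-group boundaries are a package default (conventional decade bins closed
#' at the 20--75 design range); any 5-level ordered factor can be substituted
#' by supplying your own composition table with matching levels.
#'
#' @return A named list with character vectors `age_group`, `gender`, `region`.
#' @export
#' @examples
#' lengths(demographic_levels())
demographic_levels <- function() {
  list(
    age_group = c("20-29", "30-39", "40-49", "50-59", "60-75"),
    gender = c("male", "female"),
    region = c(
      "Hokkaido", "Tohoku", "North Kanto", "Greater Tokyo", "Koshinetsu",
      "Hokuriku", "Tokai", "Kinki ex Keihanshin", "Keihanshin", "Chugoku",
      "Shikoku", "Kyushu ex Okinawa", "Okinawa"
    )
  )
}

#' All 130 demographic cells
#'
#' @return A tibble with one row per age_group x gender x region cell, in the
#'   canonical cell order (age group varying slowest, region fastest).
#' @export
#' @examples
#' nrow(demographic_cells())  # 130
demographic_cells <- function() {
  lv <- demographic_levels()
  tidyr::expand_grid(
    age_group = factor(lv$age_group, levels = lv$age_group, ordered = TRUE),
    gender = factor(lv$gender, levels = lv$gender),
    region = factor(lv$region, levels = lv$region)
  )
}

#' Synthetic default demographic composition
#'
#' A plausible — but entirely synthetic — stand-in for the national population
#' composition over the 130 age x gender x region cells. Region weights
#' roughly track the relative sizes of the 13 Japanese regions, age weights
#' reflect an ageing population, and genders split near-evenly; the three
#' margins are combined independently and normalised to sum to one. It is
#' **not** census data; supply your own table via [read_composition()] for any
#' real analysis.
#'
#' @return A tibble with columns `age_group`, `gender`, `region`, `proportion`
#'   (130 rows, proportions summing to 1).
#' @export
#' @examples
#' sum(default_composition()$proportion)
default_composition <- function() {
  lv <- demographic_levels()
  age_w <- c(0.16, 0.18, 0.21, 0.20, 0.25)
  gender_w <- c(0.49, 0.51)
  region_w <- c(
    0.041, 0.068, 0.053, 0.290, 0.041,
    0.023, 0.115, 0.046, 0.130, 0.057,
    0.029, 0.095, 0.012
  )
  cells <- demographic_cells()
  prop <- age_w[as.integer(cells$age_group)] *
    gender_w[as.integer(cells$gender)] *
    region_w[as.integer(cells$region)]
  cells$proportion <- prop / sum(prop)
  cells
}

#' Validate a demographic composition table
#'
#' Checks that all 130 cells are present exactly once and that proportions are
#' non-negative and sum to 1 within `tol`.
#'
#' @param composition A data frame with columns `age_group`, `gender`,
#'   `region`, `proportion`.
#' @param tol Tolerance on the proportion sum (default `1e-9`).
#' @return The composition, invisibly, as a tibble with canonical factor
#'   levels and cell order.
#' @export
validate_composition <- function(composition, tol = 1e-9) {
  required <- c("age_group", "gender", "region", "proportion")
  missing <- setdiff(required, names(composition))
  if (length(missing) > 0) {
    stop("composition is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  comp <- as_cell_factors(tibble::as_tibble(composition))
  if (anyNA(comp$age_group) || anyNA(comp$gender) || anyNA(comp$region)) {
    stop("composition contains demographic levels outside the design",
         call. = FALSE)
  }
  comp <- dplyr::arrange(comp, .data$age_group, .data$gender, .data$region)
  cells <- demographic_cells()
  if (nrow(comp) != nrow(cells) ||
      !identical(comp[c("age_group", "gender", "region")], cells)) {
    stop("composition must contain each of the 130 demographic cells exactly once",
         call. = FALSE)
  }
  if (any(comp$proportion < 0)) {
    stop("composition proportions must be non-negative", call. = FALSE)
  }
  if (abs(sum(comp$proportion) - 1) > tol) {
    stop(sprintf("composition proportions sum to %.12f, not 1",
                 sum(comp$proportion)), call. = FALSE)
  }
  invisible(comp)
}

# coerce cell columns to the canonical factor levels
as_cell_factors <- function(tbl) {
  lv <- demographic_levels()
  tbl$age_group <- factor(as.character(tbl$age_group), levels = lv$age_group,
                          ordered = TRUE)
  tbl$gender <- factor(as.character(tbl$gender), levels = lv$gender)
  tbl$region <- factor(as.character(tbl$region), levels = lv$region)
  tbl
}

#' Read / write a composition table
#'
#' CSV with columns `age_group`, `gender`, `region`, `proportion`; validated
#' on read.
#'
#' @param path File path.
#' @return `read_composition()` returns a validated composition tibble.
#' @export
read_composition <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  comp <- validate_composition(raw)
  comp
}

#' @rdname read_composition
#' @param composition A composition table.
#' @export
write_composition <- function(composition, path) {
  comp <- validate_composition(composition)
  readr::write_csv(comp, path)
  invisible(path)
}

#' Allocate integer quotas over demographic cells
#'
#' Converts target population proportions into integer recruitment quotas by
#' largest-remainder apportionment: each cell receives the floor of its
#' proportional share `total_n * proportion`, and the remaining units go to
#' the cells with the largest fractional remainders. Ties in the remainder are
#' broken by canonical cell order (age group, then gender, then region), so
#' the allocation is deterministic. Every quota therefore differs from the
#' exact share by less than one respondent, and quotas sum exactly to
#' `total_n`.
#'
#' @param composition A composition table (see [validate_composition()]).
#' @param total_n Total sample size (positive integer; the reference study
#'   design uses 750).
#' @return A tibble with columns `age_group`, `gender`, `region`, `proportion`,
#'   `quota`.
#' @export
#' @examples
#' q <- build_quota_table(default_composition(), 750)
#' sum(q$quota)
build_quota_table <- function(composition, total_n) {
  stopifnot(length(total_n) == 1, total_n >= 1, total_n == as.integer(total_n))
  comp <- validate_composition(composition)
  share <- total_n * comp$proportion
  base <- floor(share)
  remainder <- share - base
  leftover <- as.integer(round(total_n - sum(base)))
  quota <- as.integer(base)
  if (leftover > 0) {
    # order() is stable, so equal remainders fall back to cell order
    top <- order(remainder, decreasing = TRUE)[seq_len(leftover)]
    quota[top] <- quota[top] + 1L
  }
  comp$quota <- quota
  comp
}

#' Required sample size for a single population proportion
#'
#' Evaluates the classical single-proportion sample-size formula
#' n = Z^2 p (1 - p) / e^2 and returns its ceiling. With the reference design
#' inputs (Z = 1.96 for a 95% CI, assumed proportion p = 0.02, margin of error
#' e = 0.01) the formula gives 752.95, i.e. 753 respondents; the reference
#' study rounded its recruitment target to 750.
#'
#' @param z Normal quantile for the desired confidence level (e.g. 1.96).
#' @param p_assumed Assumed proportion, in (0, 1).
#' @param e Margin of error (> 0).
#' @return Integer sample size (ceiling of the formula).
#' @export
#' @examples
#' required_sample_size(1.96, 0.02, 0.01)
required_sample_size <- function(z, p_assumed, e) {
  stopifnot(z > 0, p_assumed > 0, p_assumed < 1, e > 0)
  as.integer(ceiling(z^2 * p_assumed * (1 - p_assumed) / e^2))
}
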