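test_that("population_mix validates the simplex", {
  mix <- population_mix(sz = 0.016)
  expect_equal(sum(mix), 1)
  expect_equal(unname(mix["other"]), 0.101)
  expect_error(population_mix(healthy = 0.9, mdd = 0.2, bd = 0, sz = 0),
               "\\[0, 1\\]")
  expect_error(population_mix(other = 0.5), "sum to 1")
})

test_that("simulated panels follow the latent-class mix", {
  # degenerate mix: everyone is a case
  all_sz <- simulate_panel(population_mix(0, 0, 0, 1, 0), panel_n = 50, seed = 1)
  expect_true(all(all_sz$latent_class == "sz"))

  # class counts within 4 binomial SDs of expectation at n = 100000
  mix <- population_mix(0.80, 0.079, 0.004, 0.016, 0.101)
  panel <- simulate_panel(mix, panel_n = 100000, seed = 7)
  counts <- table(panel$latent_class)[latent_classes()]
  for (k in latent_classes()) {
    expected <- 100000 * mix[[k]]
    sd_k <- sqrt(100000 * mix[[k]] * (1 - mix[[k]]))
    expect_lt(abs(counts[[k]] - expected), 4 * sd_k + 1)
  }

  # same seed gives identical tables
  expect_identical(simulate_panel(mix, panel_n = 1000, seed = 3),
                   simulate_panel(mix, panel_n = 1000, seed = 3))
})

test_that("latent-class frequencies pass a goodness-of-fit sweep across seeds", {
  mix <- population_mix(0.80, 0.079, 0.004, 0.016, 0.101)
  pvals <- vapply(1:20, function(s) {
    panel <- simulate_panel(mix, panel_n = 100000, seed = s)
    counts <- table(panel$latent_class)[latent_classes()]
    stats::chisq.test(as.numeric(counts), p = as.numeric(mix))$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("demographic cells follow the composition proportions", {
  comp <- default_composition()
  panel <- simulate_panel(population_mix(), comp, panel_n = 100000, seed = 5)
  obs <- panel |>
    dplyr::count(age_group, gender, region, .drop = FALSE) |>
    dplyr::arrange(age_group, gender, region)
  expect_gt(stats::chisq.test(obs$n, p = comp$proportion)$p.value, 0.001)
})

test_that("quota sampling returns exactly the quota per cell", {
  comp <- default_composition()
  quota <- build_quota_table(comp, 750)
  panel <- simulate_panel(population_mix(), comp, panel_n = 100000, seed = 2)
  sampled <- quota_sample(panel, quota, seed = 3)
  expect_equal(nrow(sampled), 750)
  got <- sampled |>
    dplyr::count(age_group, gender, region, .drop = FALSE) |>
    dplyr::arrange(age_group, gender, region)
  expect_equal(got$n, quota$quota)
  # sampled without replacement
  expect_equal(anyDuplicated(sampled$id), 0)
  # deterministic under the seed
  expect_identical(sampled, quota_sample(panel, quota, seed = 3))
})

test_that("quota sampling handles empty quotas and short cells", {
  comp <- default_composition()
  quota <- build_quota_table(comp, 750)
  quota$quota <- 0L
  panel <- simulate_panel(population_mix(), comp, panel_n = 1000, seed = 1)
  expect_equal(nrow(quota_sample(panel, quota)), 0)

  # a panel with no rows in a quota-bearing cell errors, naming the cell
  quota2 <- build_quota_table(one_cell_composition(1), 10)
  empty_cell_panel <- panel[panel$age_group != "20-29", ]
  expect_error(quota_sample(empty_cell_panel, quota2, seed = 1),
               "20-29/male/Hokkaido")
})

test_that("features separate classes as the schema dictates", {
  # continuous feature with a unit shift: empirical class means differ by
  # 1 within 4 standard errors
  schema <- feature_schema(list(list(
    name = "x", category = "psychiatric", type = "continuous",
    mean = c(healthy = 0, mdd = 0, bd = 0, sz = 1, other = 0), sd = 1
  )))
  n_per <- 2000
  tbl <- tibble::tibble(
    id = seq_len(2 * n_per),
    latent_class = factor(rep(c("sz", "healthy"), each = n_per),
                          levels = latent_classes())
  )
  tbl <- generate_features(tbl, schema, seed = 11)
  diff <- mean(tbl$x[tbl$latent_class == "sz"]) -
    mean(tbl$x[tbl$latent_class == "healthy"])
  se <- sqrt(2 / n_per)
  expect_lt(abs(diff - 1), 4 * se)

  # identical seed, identical features
  expect_identical(tbl, generate_features(tbl[1:2], schema, seed = 11))
})

test_that("default schema supports a separable case/control problem", {
  dev <- make_dev_set(seed = 21)
  df <- data.frame(y = as.integer(dev$latent_class == "sz"),
                   dev[setdiff(names(dev), c("id", "latent_class"))])
  # logistic benchmark on the generated features
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  expect_gte(auc_mann_whitney(stats::fitted(fit), df$y), 0.8)
})

test_that("null schema yields chance-level separability", {
  dev <- make_dev_set(2500, 2500, schema = null_feature_schema(), seed = 31)
  df <- data.frame(y = as.integer(dev$latent_class == "sz"),
                   dev[setdiff(names(dev), c("id", "latent_class"))])
  # fit on a random half, score the other: held-out AUC must sit near 0.5
  set.seed(99)
  tr <- sample.int(nrow(df), nrow(df) / 2)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df[tr, ],
                                     family = stats::binomial()))
  scores <- stats::predict(fit, newdata = df[-tr, ])
  expect_gt(auc_mann_whitney(scores, df$y[-tr]), 0.45)
  expect_lt(auc_mann_whitney(scores, df$y[-tr]), 0.55)
})

test_that("feature schemas round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  schema <- default_feature_schema()
  write_feature_schema(schema, path)
  back <- read_feature_schema(path)
  expect_equal(back$name, schema$name)
  expect_equal(back$type, schema$type)
  for (i in seq_len(nrow(schema))) {
    expect_equal(back$params[[i]], schema$params[[i]], tolerance = 1e-12)
  }
})

test_that("schemas referencing unknown classes or categories are rejected", {
  expect_error(feature_schema(list(list(
    name = "x", category = "psychiatric", type = "continuous",
    mean = c(healthy = 0, zombie = 1), sd = 1
  ))), "named for all")
  expect_error(feature_schema(list(list(
    name = "x", category = "astrology", type = "continuous",
    mean = c(healthy = 0, mdd = 0, bd = 0, sz = 0, other = 0), sd = 1
  ))), "category")
})
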