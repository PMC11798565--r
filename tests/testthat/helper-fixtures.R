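# shared fixtures, built in code at test time

# development-set-shaped cohort: n_case schizophrenia rows then n_control
# healthy rows, with features drawn from the given schema
make_dev_set <- function(n_case = 223, n_control = 1776,
                         schema = default_feature_schema(), seed = 1) {
  tbl <- tibble::tibble(
    id = seq_len(n_case + n_control),
    latent_class = factor(rep(c("sz", "healthy"), c(n_case, n_control)),
                          levels = latent_classes())
  )
  generate_features(tbl, schema, seed = seed)
}

# uniform composition over all 130 cells
uniform_composition <- function() {
  comp <- demographic_cells()
  comp$proportion <- rep(1 / nrow(comp), nrow(comp))
  comp
}

# composition placing all mass on a single cell
one_cell_composition <- function(row = 1) {
  comp <- demographic_cells()
  comp$proportion <- rep(0, nrow(comp))
  comp$proportion[row] <- 1
  comp
}

# independent AUC oracle: average over all positive-negative pairs,
# ties counting one half
auc_all_pairs <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
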