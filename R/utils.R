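#' Latent diagnostic classes
#'
#' The five latent classes of the cohort model: `healthy` (no mental
#' disorder), `mdd` (major depressive disorder), `bd` (bipolar disorder),
#' `sz` (schizophrenia, the target class), and `other` (any other mental
#' disorder, e.g. OCD). The correction deliberately ignores `other`: it
#' contributes neither expected false positives nor false negatives.
#'
#' @return Character vector of the five class labels.
#' @export
latent_classes <- function() c("healthy", "mdd", "bd", "sz", "other")

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is left untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# commercial rounding: halves go away from zero (round() rounds to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
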