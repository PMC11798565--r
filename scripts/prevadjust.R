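#!/usr/bin/env Rscript

# Thin command-line wrapper over the prevadjust package.
#
#   Rscript scripts/prevadjust.R run --config run.yaml
#   Rscript scripts/prevadjust.R correct --crude 62 --n 750 [--profile p.yaml]
#   Rscript scripts/prevadjust.R ci --cases 12 --n 750 [--reps 10000]
#                                  [--method normal|percentile] [--seed 1]

suppressPackageStartupMessages(library(prevadjust))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0) {
  stop("usage: prevadjust.R <run|correct|ci> [options]", call. = FALSE)
}
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}

if (cmd == "run") {
  cfg <- load_run_config(opt("--config", stop("--config required")))
  report <- run_study(cfg)
  cat(render_report(report, "text"), "\n")
} else if (cmd == "correct") {
  profile <- if (!is.null(opt("--profile"))) read_profile(opt("--profile"))
             else misclassification_profile()
  cx <- correct_prevalence(as.numeric(opt("--crude", stop("--crude required"))),
                           as.numeric(opt("--n", "750")), profile)
  print(cx)
  if (!is.null(opt("--json"))) {
    jsonlite::write_json(as.list(glance(cx)), opt("--json"),
                         auto_unbox = TRUE, digits = NA)
  }
} else if (cmd == "ci") {
  ci <- bootstrap_prevalence_ci(
    as.numeric(opt("--cases", stop("--cases required"))),
    as.numeric(opt("--n", "750")),
    replicates = as.integer(opt("--reps", "10000")),
    method = opt("--method", "normal"),
    seed = as.integer(opt("--seed", "1"))
  )
  print(ci)
} else {
  stop("unknown command: ", cmd, call. = FALSE)
}
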