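#!/usr/bin/env Rscript
# Thin command-line front end over the sofaoxi package.
#
#   Rscript scripts/sofa_oxi.R simulate  --config cfg.yaml --out cohort.csv
#   Rscript scripts/sofa_oxi.R score     --in cohort.csv --methods CONV,A,E --out scores.csv
#   Rscript scripts/sofa_oxi.R evaluate  --in cohort.csv --out report/
#   Rscript scripts/sofa_oxi.R reproduce --seed 7 --out report/
#
# Exit codes: 0 success, 2 validation failure, 3 statistical degeneracy.

suppressPackageStartupMessages(library(sofaoxi))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("subcommand required: simulate | score | evaluate | reproduce",
       call. = FALSE)
}
cmd <- args[1]
args <- args[-1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

# YAML config mirrors the generator/run parameters by name
load_config <- function(path, n, seed) {
  cfg <- default_config(n = n, seed = seed)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  cfg
}

fail <- function(code, e) {
  message("error: ", conditionMessage(e))
  quit(status = code, save = "no")
}

run <- function() {
  switch(cmd,
    simulate = {
      out <- get_arg("--out", "cohort.csv")
      cfg <- load_config(get_arg("--config"),
                         n = as.integer(get_arg("--n", "15000")),
                         seed = as.integer(get_arg("--seed", "20230925")))
      gc <- generate_cohort(cfg)
      write_cohort(gc$records, out)
      utils::write.csv(gc$truth, sub("\\.csv$", "_truth.csv", out),
                       row.names = FALSE)
      message("wrote ", out)
    },
    score = {
      cohort <- read_cohort(get_arg("--in", "cohort.csv"))
      methods <- strsplit(get_arg("--methods", "CONV,A,B,C,D,E,F"), ",")[[1]]
      scores <- score_cohort(cohort, methods)
      utils::write.csv(scores, get_arg("--out", "scores.csv"),
                       row.names = FALSE)
      message("scored ", nrow(cohort), " patients under ",
              length(methods), " methods")
    },
    evaluate = {
      methods <- strsplit(get_arg("--methods", "CONV,A,B,C,D,E,F"), ",")[[1]]
      run_pipeline(get_arg("--in", "cohort.csv"),
                   get_arg("--out", "report"),
                   methods = methods,
                   n_boot = as.integer(get_arg("--n-boot", "100")),
                   seed = as.integer(get_arg("--seed", "1")))
    },
    reproduce = {
      reproduce_analysis(seed = as.integer(get_arg("--seed", "1")),
                         out_dir = get_arg("--out", "report"),
                         n = as.integer(get_arg("--n", "15000")))
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
}

tryCatch(run(), error = function(e) {
  if (grepl("degenera", conditionMessage(e))) fail(3, e) else fail(2, e)
})
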