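#!/usr/bin/env Rscript
# Thin command-line wrapper over psyecon::run_pipeline(): simulate a
# cohort, score it, fit the behavioural tasks, run the compliance
# regressions and write all tables plus a run manifest.
#
#   Rscript scripts/pipeline.R --seed 1 --out runs/demo [--config cfg.json]
#                              [--alpha 0.05] [--quiet]
#
# The optional JSON config may override scalar generator settings:
# n_participants, n_incomplete, tweedie_power, and any field of the
# demographics/econ lists (e.g. {"n_participants": 500, "econ": {"lapse": 0}}).

suppressPackageStartupMessages({
  library(optparse)
  library(psyecon)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "JSON file with generator overrides"),
  make_option("--seed", type = "integer", default = 1L,
              help = "RNG seed [default %default]"),
  make_option("--out", type = "character", default = "pipeline_out",
              help = "output directory [default %default]"),
  make_option("--alpha", type = "double", default = 0.05,
              help = "significance threshold [default %default]"),
  make_option("--quiet", action = "store_true", default = FALSE,
              help = "suppress per-stage logging")
)))

cfg_args <- list()
if (!is.null(opts$config)) {
  ov <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  base <- cohort_config()
  for (nm in intersect(names(ov), c("n_participants", "n_incomplete",
                                    "tweedie_power")))
    cfg_args[[nm]] <- ov[[nm]]
  for (nm in intersect(names(ov), c("demographics", "econ"))) {
    merged <- base[[nm]]
    merged[names(ov[[nm]])] <- ov[[nm]]
    cfg_args[[nm]] <- merged
  }
}
config <- do.call(cohort_config, cfg_args)

manifest <- run_pipeline(config, seed = opts$seed, out_dir = opts$out,
                         alpha_level = opts$alpha, verbose = !opts$quiet)
cat(sprintf("run complete: %d files in %s (seed %d)\n",
            length(manifest$files), opts$out, manifest$seed))
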