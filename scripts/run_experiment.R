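#!/usr/bin/env Rscript
# Thin command-line wrapper over gammasynch::runExperiment().
#
# Usage:
#   Rscript scripts/run_experiment.R --out results/run1 [--seed 1]
#     [--config experiment.yaml] [--animals 5] [--channels 3] [--trials 50]
#
# A YAML config (fields matching experimentConfig() arguments) overrides
# the defaults; explicit flags override the config.

suppressPackageStartupMessages(library(gammasynch))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

opts <- list()
cfgPath <- getArg("--config")
if (!is.null(cfgPath)) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("--config requires the 'yaml' package")
  opts <- yaml::read_yaml(cfgPath)
}
if (!is.null(v <- getArg("--seed"))) opts$seed <- as.integer(v)
if (!is.null(v <- getArg("--animals"))) opts$nAnimals <- as.integer(v)
if (!is.null(v <- getArg("--channels"))) opts$channelsPerAnimal <- as.integer(v)
if (!is.null(v <- getArg("--trials"))) opts$nTrials <- as.integer(v)
out <- getArg("--out", "results/experiment")

config <- do.call(experimentConfig, opts)
res <- runExperiment(config, outDir = out)
cat("condition contrasts (per-animal design):\n")
print(res$contrasts, digits = 3)
cat("\noutputs written to ", out, "\n", sep = "")
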