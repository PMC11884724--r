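#!/usr/bin/env Rscript

# Thin command-line wrapper around ssrpop::run_pipeline():
#   Rscript scripts/run_pipeline.R --input genotypes.csv --dialect genalex \
#     --out results/ --seed 1 [--kmax 8 --runs 8 --burnin 30000 --reps 15000 \
#      --perm 999 --missing 0]

suppressPackageStartupMessages({
  library(optparse)
  library(ssrpop)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--input", type = "character", help = "genotype CSV"),
  make_option("--dialect", type = "character", default = "genalex",
              help = "genalex or long [default %default]"),
  make_option("--missing", type = "character", default = "0",
              help = "missing-allele code [default %default]"),
  make_option("--out", type = "character", default = "ssrpop-results",
              help = "output directory [default %default]"),
  make_option("--kmax", type = "integer", default = 8,
              help = "largest k in the admixture grid [default %default]"),
  make_option("--runs", type = "integer", default = 8,
              help = "admixture runs per k [default %default]"),
  make_option("--burnin", type = "integer", default = 30000),
  make_option("--reps", type = "integer", default = 15000),
  make_option("--perm", type = "integer", default = 999,
              help = "AMOVA permutations [default %default]"),
  make_option("--seed", type = "integer", default = 1)
)))

if (is.null(opts$input)) stop("--input is required")
g <- read_genotypes(opts$input, dialect = opts$dialect, missing = opts$missing)
run_pipeline(
  g, opts$out, amova_perm = opts$perm, k_range = seq_len(opts$kmax),
  runs_per_k = opts$runs, burnin = opts$burnin, reps = opts$reps,
  seed = opts$seed
)
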