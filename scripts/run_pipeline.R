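#!/usr/bin/env Rscript
# Thin command-line wrapper over occupex::run_all() / simulate_cohort().
#
#   Rscript scripts/run_pipeline.R --simulate --out results/run1 --seed 7
#   Rscript scripts/run_pipeline.R --participants p.csv --jobs j.csv \
#       --responses r.csv --coder-a a.csv --coder-b b.csv \
#       --out results/run1 --seed 7

suppressMessages({
  library(optparse)
  library(occupex)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--participants", type = "character", default = NULL),
  make_option("--jobs", type = "character", default = NULL),
  make_option("--responses", type = "character", default = NULL),
  make_option("--coder-a", dest = "coder_a", type = "character",
              default = NULL),
  make_option("--coder-b", dest = "coder_b", type = "character",
              default = NULL),
  make_option("--schema", type = "character", default = NULL),
  make_option("--simulate", action = "store_true", default = FALSE,
              help = "generate a synthetic cohort instead of reading files"),
  make_option("--out", type = "character", default = "results/run"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--permutations", type = "integer", default = 10000L))))

schema <- if (is.null(opts$schema)) default_schema() else
  read_schema(opts$schema)

if (opts$simulate) {
  sim <- simulate_cohort(sim_config(seed = opts$seed))
  simdir <- file.path(opts$out, "simulated_input")
  write_sim(sim, simdir)
  opts$participants <- file.path(simdir, "participants.csv")
  opts$jobs <- file.path(simdir, "jobs.csv")
  opts$responses <- file.path(simdir, "responses.csv")
  opts$coder_a <- file.path(simdir, "coder_a.csv")
  opts$coder_b <- file.path(simdir, "coder_b.csv")
  schema <- sim$config$schema
}

need <- c("participants", "jobs", "responses", "coder_a", "coder_b")
miss <- need[vapply(need, function(x) is.null(opts[[x]]), TRUE)]
if (length(miss))
  stop("missing required input(s): ", paste(miss, collapse = ", "),
       " (or pass --simulate)")

run_all(opts$participants, opts$jobs, opts$responses,
        utils::read.csv(opts$coder_a, stringsAsFactors = FALSE),
        utils::read.csv(opts$coder_b, stringsAsFactors = FALSE),
        schema = schema, out_dir = opts$out, seed = opts$seed,
        B = opts$permutations)
cat("pipeline outputs written to", opts$out, "\n")
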