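#!/usr/bin/env Rscript
# Thin shell interface over the glycoMRM package.
#
#   Rscript scripts/glycomrm.R simulate --seed INT --out DIR
#   Rscript scripts/glycomrm.R run-all  --seed INT --out DIR
#       [--abundance CSV --sample-sheet CSV --manifest CSV]
#       [--scope global|per_protein|per_site] [--qc-interval INT]
#       [--p-alpha NUM] [--fdr-alpha NUM] [--penalty lasso|none] [--verbose]

suppressPackageStartupMessages(library(glycoMRM))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L || !argv[1] %in% c("simulate", "run-all")) {
  stop("usage: glycomrm.R {simulate|run-all} --seed INT --out DIR [...]",
       call. = FALSE)
}
cmd <- argv[1]
argv <- argv[-1]
opt <- function(flag, default = NULL) {
  i <- match(flag, argv)
  if (is.na(i)) return(default)
  if (i == length(argv)) stop("missing value for ", flag, call. = FALSE)
  argv[i + 1L]
}
has <- function(flag) flag %in% argv

seed <- as.integer(opt("--seed"))
if (is.na(seed) || is.null(seed)) stop("--seed INT is required", call. = FALSE)
out <- opt("--out", "glycomrm_out")
verbose <- has("--verbose")
message("seed: ", seed)

if (cmd == "simulate") {
  sim <- simulate_cohort(sim_config(seed = seed))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(sim$raw, file.path(out, "raw_abundance.csv"),
                        seed = seed)
  write_sample_sheet(sim$sheet, file.path(out, "sample_sheet.csv"),
                     seed = seed)
  write_marker_manifest(sim$manifest, file.path(out, "manifest.csv"),
                        seed = seed)
  utils::write.csv(sim$truth$effects,
                   file.path(out, "ground_truth_effects.csv"),
                   row.names = FALSE)
  if (verbose) print(sim)
  message("wrote synthetic cohort to ", out)
} else {
  cfg <- pipeline_config(
    seed = seed, out_dir = out,
    abundance = opt("--abundance"),
    sample_sheet = opt("--sample-sheet"),
    manifest = opt("--manifest"),
    qc_interval = as.integer(opt("--qc-interval", "10")),
    p_alpha = as.numeric(opt("--p-alpha", "0.05")),
    fdr_alpha = as.numeric(opt("--fdr-alpha", "0.05")),
    scope = opt("--scope", "global"),
    penalty = opt("--penalty", "lasso")
  )
  run <- run_pipeline(cfg)
  if (verbose) print(run)
}
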