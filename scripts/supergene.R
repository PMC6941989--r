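#!/usr/bin/env Rscript

# Thin command-line wrapper over the package's two entry points.
#
#   Rscript scripts/supergene.R simulate --preset turnover --seed 7 --out prefix
#   Rscript scripts/supergene.R run --preset turnover --seed 1 --out dir
#   Rscript scripts/supergene.R run --vcf x.vcf --samples s.tsv \
#       --locus chr1:1200001-1300000 --seed 1 --out dir

suppressMessages({
  library(optparse)
  library(supergene)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "run"))
  stop("usage: supergene.R <simulate|run> [options]")
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--preset", type = "character", default = NULL),
  make_option("--vcf", type = "character", default = NULL),
  make_option("--samples", type = "character", default = NULL),
  make_option("--locus", type = "character", default = NULL,
              help = "chrom:start-end (1-based inclusive)"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "supergene_out"))),
  args = args[-1])

parse_locus <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("--locus must be chrom:start-end")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

if (cmd == "simulate") {
  if (is.null(opts$preset)) stop("simulate needs --preset")
  res <- simulate_supergene(scenario_preset(opts$preset, seed = opts$seed))
  paths <- write_sim_outputs(res, opts$out)
  message("wrote ", paste(paths, collapse = ", "))
} else {
  cfg <- if (!is.null(opts$preset))
    scan_config(preset = opts$preset, seed = opts$seed, out_dir = opts$out)
  else
    scan_config(vcf = opts$vcf, samples = opts$samples,
                locus = parse_locus(opts$locus), seed = opts$seed,
                out_dir = opts$out)
  report <- run_scan(cfg)
  print(report)
  message("report bundle written to ", opts$out)
}
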