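#!/usr/bin/env Rscript

# Step 2 -- synthetic exposure studies: generate the five case-study
# scenarios (three proliferative hepatotoxicants, two inactive controls)
# in the Open TG-GATEs design and write them as the tab-delimited
# matrix/design/annotation files the pipeline reads.
#
# The generator emulates: 5 replicate rats per group, control + three dose
# levels, the chemical-specific sacrifice times, ~30k-probe arrays, and
# injected log2(3) fold changes for the genes each study reported
# (e.g. Ccnd1 up at 300 mg/kg carbon tetrachloride, 24 h only).

suppressPackageStartupMessages(library(aopke))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (name in c("carbon_tetrachloride", "aflatoxin_b1", "thioacetamide",
               "diazepam", "simvastatin")) {
  sc <- preset_scenario(name, seed = seed)
  sim <- generate_scenario(sc)
  dir <- file.path(out, name)
  dir.create(dir, showWarnings = FALSE)
  write_scenario(sc, file.path(dir, "scenario.yaml"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  cat(sprintf("%-22s %5d probes x %2d samples, %d injected effects\n",
              name, nrow(sim$expression$values),
              ncol(sim$expression$values), nrow(sc$effects)))
}
cat("wrote simulated studies under ", out, "\n", sep = "")
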