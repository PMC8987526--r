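#!/usr/bin/env Rscript

# Step 4 -- Key-Event inference: overlay the gene-level calls from
# 03_diffexpr.R on the causal subnetwork and decide, per dose and
# sacrifice time, whether regenerative proliferation is inferred active.
#
# Expected verdict pattern (matching the five published case studies):
#   carbon tetrachloride  active at the high dose, 24 h only (Ccnd1)
#   aflatoxin B1          active at mid (Ccnd1) and high (Ccnd1 + Rb1);
#                         Lrp5/Vhl recorded as non-causal context
#   thioacetamide         active at the high dose at all four durations
#   diazepam              inactive everywhere (Myc alone cannot trigger)
#   simvastatin           inactive everywhere

suppressPackageStartupMessages(library(aopke))

indir <- "results/diffexpr"
out <- "results/ke_reports"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
stopifnot(dir.exists(indir))

g <- rp_network()
summary_rows <- list()

for (f in list.files(indir, pattern = "_gene_calls\\.tsv$")) {
  name <- sub("_gene_calls\\.tsv$", "", f)
  genes <- tibble::as_tibble(utils::read.delim(file.path(indir, f)))
  rep <- chemical_report(g, genes)
  cat("\n")
  print(rep)
  print(as.data.frame(rep$verdicts[, c("dose_level", "time_value",
                                       "ke_active", "triggering_nodes",
                                       "active_nonsufficient")]),
        row.names = FALSE)
  utils::write.table(rep$verdicts, file.path(out, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(chemical = rep$chemical, first_active = rep$first_active,
         verdicts = rep$verdicts),
    file.path(out, paste0(name, ".json")), auto_unbox = TRUE, digits = NA)
  summary_rows[[name]] <- data.frame(
    chemical = rep$chemical,
    ke_ever_active = any(rep$verdicts$ke_active),
    first_active = ifelse(is.na(rep$first_active), "-", rep$first_active))
}

cat("\n== chemical-level summary\n")
print(do.call(rbind, summary_rows), row.names = FALSE)
cat("\nwrote per-chemical reports under ", out, "\n", sep = "")
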