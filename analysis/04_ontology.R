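#!/usr/bin/env Rscript
# Functional profile of the swimbladder-enriched list: GO slim
# classification, hypergeometric and EASE term over-representation with BH
# FDR, and the transcriptional energy distribution.

suppressPackageStartupMessages(library(crosstx))

sim <- file.path("results", "sim")
enr <- file.path("results", "enrichment")
out <- file.path("results", "ontology")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ann <- parse_mapping_table(file.path(sim, "annotations.tsv"), "annotation")
mat <- read_expression_matrix(file.path(sim, "expression.tsv"))
sel <- read_tsv(file.path(enr, "enriched_swimbladder.tsv"))

slim <- classify_slim(sel$cluster_id, ann)
write_tsv(slim, file.path(out, "slim_classification.tsv"))

for (method in c("hypergeometric", "ease")) {
  te <- term_enrichment(sel$cluster_id, rownames(mat), ann, method = method)
  write_tsv(te, file.path(out, paste0("term_enrichment_", method, ".tsv")))
  hits <- te[te$q < 0.01, ]
  cat(sprintf("%-15s %d terms tested, %d with FDR < 0.01: %s\n", method,
              nrow(te), nrow(hits),
              paste(utils::head(hits$term, 5), collapse = ", ")))
}

ed <- energy_distribution(mat[, "swimbladder"], ann)
write_tsv(ed, file.path(out, "energy_distribution.tsv"))
top <- ed[order(-ed$rpkm_share), ][1:5, ]
cat("\nTop categories by transcriptional energy (share of summed RPKM):\n")
print(top, row.names = FALSE, digits = 3)
cat(sprintf("Unclassified genes: %.0f%% of the gene tally\n",
            100 * ed$gene_count_share[ed$category == "unclassified"]))
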