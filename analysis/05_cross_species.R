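#!/usr/bin/env Rscript
# Tissue relatedness across species: each tissue's projected enriched list
# is scored by preranked GSEA against specificity rankings of every
# target-species tissue, giving the NES/FDR relatedness matrix. A query
# tissue should peak on its matched target.

suppressPackageStartupMessages(library(crosstx))

sim <- file.path("results", "sim")
enr <- file.path("results", "enrichment")
out <- file.path("results", "cross_species")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

queries <- parse_gene_sets_gmt(file.path(enr, "projected_sets.gmt"))
target <- read_expression_matrix(file.path(sim, "target_expression.tsv"))

nm <- cross_species_matrix(queries, target, n_perm = 1000, seed = 1)
for (piece in c("nes", "p", "fdr"))
  write_expression_matrix(nm[[piece]],
                          file.path(out, paste0("matrix_", piece, ".tsv")))

print(nm)
diag_hit <- vapply(rownames(nm$nes), function(tis)
  names(which.max(nm$nes[tis, ])) == tis, logical(1))
cat(sprintf("\n%d of %d query tissues peak on their matched target tissue\n",
            sum(diag_hit), length(diag_hit)))
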