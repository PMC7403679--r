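#!/usr/bin/env Rscript
# Stage 4: rank genes by their peak sliding-window PBS on each branch and
# run ranked gene-set enrichment (gene-label permutation null) per branch.
# The designated planted GO term should enrich on the Waresley-like branch
# and not on the others.
#
# Reads:  results/data, results/pbs
# Writes: results/enrichment/{gene_scores_*.tsv, gsea_*.tsv}

library(nichescan)

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ps <- read_track("results/pbs/pbs_sliding.tsv")
genes <- read_gff_genes("results/data/genes.gff3")
collection <- read_gene_go("results/data/gene_go.tsv")
planted_term <- "GO:SYN0001"

branches <- c(gamlingay = 1, waresley = 2, wales = 3)
for (pop in names(branches)) {
  scores <- score_genes(ps, genes, branch = branches[[pop]])
  write_track(scores, file.path(out, sprintf("gene_scores_%s.tsv", pop)))
  ranked <- rank_genes(scores)
  g <- gsea(ranked, collection, n_perm = 1000, seed = 11)
  write_track(g, file.path(out, sprintf("gsea_%s.tsv", pop)))
  row <- g[g$go_id == planted_term, ]
  message(sprintf(
    "%s: %d genes ranked; planted term NES = %.2f, nominal p = %.3g, FDR q = %.3g (rank %d of %d terms)",
    pop, nrow(ranked), row$nes, row$p_nominal, row$q_fdr,
    which(g$go_id == planted_term), nrow(g)))
}
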