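#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Three populations of Nicrophorus vespilloides-like diploids: two focal
# woodland populations diverged at background F = 0.01 and a distant
# outgroup at F = 0.05, 12,000 SNPs on 2 x 600 kb contigs.  Twelve genes of
# the designated "oogenesis-like" GO term carry 3-SNP selected blocks
# (F_sel = 0.6) on the Waresley-like branch.  Also simulates 50 split-brood
# dyads per population with a +5-egg clutch elevation in the derived
# population and culling of surplus offspring on small carcasses.
#
# Writes: results/data/{genotypes.vcf, population_map.tsv, genes.gff3,
#         gene_go.tsv, broods.tsv}

library(nichescan)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gene_starts <- seq(0, by = 2000, length.out = 300)
set.seed(seed)
planted_genes <- sort(sample(300, 12))
planted <- data.frame(
  contig = 1L,
  pos = rep(gene_starts[planted_genes], each = 3) + c(200L, 500L, 800L),
  focal_population = "waresley", f_sel = 0.6)

sim <- sim_config(n_contigs = 2, contig_length = 6e5, n_snps = 12000,
                  planted_loci = planted, seed = seed)

freqs <- simulate_frequencies(sim)
gm <- simulate_genotypes(freqs, sim)
info <- simulate_info(nrow(freqs), sim)
ann <- generate_annotation(sim)

write_vcf(gm, info, file.path(out, "genotypes.vcf"))
write_population_map(gm$pop_map, file.path(out, "population_map.tsv"))
write_gff3(ann$genes, file.path(out, "genes.gff3"))
write_gene_go(ann$gene_go, file.path(out, "gene_go.tsv"))

broods <- simulate_broods(50, elevation_offset = 5, culling_on_small = TRUE,
                          seed = seed + 1L)
write_broods(broods, file.path(out, "broods.tsv"))

planted_ids <- ann$genes$gene_id[ann$genes$contig == 1][planted_genes]
writeLines(planted_ids, file.path(out, "planted_genes.txt"))

message(sprintf(
  "simulated %d SNPs x %d samples (%d planted), %d genes, %d dyads -> %s",
  nrow(freqs), ncol(gm$geno), sum(freqs$planted), nrow(ann$genes),
  nrow(broods) / 2, out))
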