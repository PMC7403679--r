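#!/usr/bin/env Rscript
# Stage 2: hard-filter the VCF and compute windowed population-genetic
# statistics: Hudson F_ST in 2-kb non-overlapping windows for the three
# population pairs, plus nucleotide diversity and Tajima's D per focal
# population.
#
# Reads:  results/data/ (stage 1)
# Writes: results/scan/{filter_report.tsv, fst_scan_*.tsv, diversity_*.tsv}

library(nichescan)

data_dir <- "results/data"
out <- "results/scan"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pop_map <- read_population_map(file.path(data_dir, "population_map.tsv"))
loaded <- read_vcf(file.path(data_dir, "genotypes.vcf"), pop_map)

flt <- hard_filter(loaded$info)
write.table(flt$report, file.path(out, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("hard filter: %d of %d records removed (QD %d, SOR %d, FS %d)",
                flt$report$n_removed, flt$report$n_records,
                flt$report$qd_violations, flt$report$sor_violations,
                flt$report$fs_violations))

gm <- subset_genotypes(loaded$gm, flt$keep)
counts <- allele_counts(gm)
contig_lengths <- tapply(gm$pos, gm$contig, max) + 1L
windows <- make_windows(contig_lengths, 2000)

pairs <- list(c("gamlingay", "waresley"), c("gamlingay", "wales"),
              c("waresley", "wales"))
for (pr in pairs) {
  tr <- window_fst(counts, pr[1], pr[2], windows)
  write_track(tr, file.path(out, sprintf("fst_scan_%s_vs_%s.tsv",
                                         pr[1], pr[2])))
  gw <- genomewide_fst(tr)
  message(sprintf("%s vs %s: weighted FST = %.4f, unweighted FST = %.4f",
                  pr[1], pr[2], gw[["weighted"]], gw[["unweighted"]]))
}

for (pop in c("gamlingay", "waresley")) {
  pi_t <- nucleotide_diversity(counts, pop, windows)
  td <- tajimas_d(counts, pop, windows)
  pi_t$S <- td$S
  pi_t$tajimas_d <- td$tajimas_d
  pi_t$defined <- td$defined
  write_track(pi_t, file.path(out, sprintf("diversity_%s.tsv", pop)))
  message(sprintf("%s: mean pi = %.5f per bp, mean Tajima's D = %.3f (%d windows)",
                  pop, mean(pi_t$pi), mean(pi_t$tajimas_d[pi_t$defined]),
                  sum(pi_t$defined)))
}
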