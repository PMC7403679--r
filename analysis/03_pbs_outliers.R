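#!/usr/bin/env Rscript
# Stage 3: polarise the divergence.  Combine the three pairwise F_ST scan
# tracks into per-branch population branch statistics, z-standardise the
# focal-pair F_ST, flag PBS > 0.05 outlier windows by branch class, and
# profile the top outlier gene with 500-bp/100-bp sliding windows.
#
# Reads:  results/data, results/scan
# Writes: results/pbs/{pbs_scan.tsv, zfst.tsv, outliers.tsv,
#         pbs_sliding.tsv, top_gene_profile.tsv}

library(nichescan)

scan_dir <- "results/scan"
out <- "results/pbs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

f12 <- read_track(file.path(scan_dir, "fst_scan_gamlingay_vs_waresley.tsv"))
f13 <- read_track(file.path(scan_dir, "fst_scan_gamlingay_vs_wales.tsv"))
f23 <- read_track(file.path(scan_dir, "fst_scan_waresley_vs_wales.tsv"))
attr(f12, "pops") <- c("gamlingay", "waresley")
attr(f13, "pops") <- c("gamlingay", "wales")
attr(f23, "pops") <- c("waresley", "wales")

pt <- pbs_scan(f12, f13, f23)
write_track(pt, file.path(out, "pbs_scan.tsv"))
mp <- mean_pbs(pt)
message(sprintf("mean PBS: Gamlingay = %.4f, Waresley = %.4f, Wales = %.4f",
                mp[["gamlingay"]], mp[["waresley"]], mp[["wales"]]))

z <- zfst(f12)
write_track(z, file.path(out, "zfst.tsv"))
v <- which(z$valid & !is.na(z$zfst))
top <- v[which.max(z$zfst[v])]
message(sprintf("top focal-pair window %s:%d-%d: FST = %.3f, zFST = %.2f, P = %.2e",
                z$contig[top], z$start[top], z$end[top], z$fst[top],
                z$zfst[top], z$p[top]))

outliers <- flag_outliers(pt, threshold = 0.05)
write_track(outliers, file.path(out, "outliers.tsv"))
message(sprintf("PBS > 0.05 outlier windows: %d (%s)", nrow(outliers),
                paste(sprintf("%s %d", names(table(outliers$class)),
                              table(outliers$class)), collapse = ", ")))

## sliding-window PBS for gene-level work (stage 4 reuses this track)
pop_map <- read_population_map("results/data/population_map.tsv")
loaded <- read_vcf("results/data/genotypes.vcf", pop_map)
flt <- hard_filter(loaded$info)
gm <- subset_genotypes(loaded$gm, flt$keep)
counts <- allele_counts(gm)
contig_lengths <- tapply(gm$pos, gm$contig, max) + 1L
sw <- make_windows(contig_lengths, 500, 100)
s12 <- window_fst(counts, "gamlingay", "waresley", sw, min_sites = 2L)
s13 <- window_fst(counts, "gamlingay", "wales", sw, min_sites = 2L)
s23 <- window_fst(counts, "waresley", "wales", sw, min_sites = 2L)
ps <- pbs_scan(s12, s13, s23)
write_track(ps, file.path(out, "pbs_sliding.tsv"))

## profile the gene under the strongest Waresley-branch outlier
genes <- read_gff_genes("results/data/genes.gff3")
if (any(outliers$class %in% c("focal2", "both"))) {
  w_out <- outliers[outliers$class %in% c("focal2", "both"), ]
  peak <- w_out[which.max(w_out$pbs2), ]
  g <- genes[genes$contig == peak$contig & genes$start < peak$end &
               genes$end > peak$start, ][1, ]
  prof <- gene_profile(g, ps, branch = 2, flank = 500)
  write_track(prof$profile, file.path(out, "top_gene_profile.tsv"))
  message(sprintf("top Waresley outlier gene %s: peak sliding-window PBS = %.3f at %s:%d-%d",
                  g$gene_id, prof$argmax$pbs, prof$argmax$contig,
                  prof$argmax$start, prof$argmax$end))
}
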