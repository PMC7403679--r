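#!/usr/bin/env Rscript
# Stage 5: phenotype analyses.  Clutch-size reaction norms from the
# split-brood dyads (elevation vs slope permutation contrasts), brood-size
# slopes (the culling signature), carcass-use efficiency, egg volumes, and
# guild relative abundance from the published trap totals.
#
# Reads:  results/data/broods.tsv, inst/extdata/guild_counts.tsv
# Writes: results/phenotype/{reaction_norms_*.tsv, contrasts.tsv,
#         guild_abundance.tsv}

library(nichescan)

out <- "results/phenotype"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

broods <- read_broods("results/data/broods.tsv")
contrasts <- list()
for (trait in c("clutch_size", "brood_size", "egg_volume", "efficiency")) {
  rn <- reaction_norms(broods, trait)
  write_track(rn, file.path(out, sprintf("reaction_norms_%s.tsv", trait)))
  for (cmp in c("elevation", "slope")) {
    pc <- permutation_contrast(rn, cmp, n_perm = 9999, seed = 7)
    contrasts[[paste(trait, cmp, sep = ".")]] <-
      data.frame(trait = trait, component = cmp, delta = pc$delta,
                 p = pc$p, n_perm = pc$n_perm, exhaustive = pc$exhaustive)
    message(sprintf("%s %s: delta (Gamlingay - Waresley) = %.3f, permutation p = %.4g",
                    trait, cmp, pc$delta, pc$p))
  }
}
write_track(do.call(rbind, contrasts), file.path(out, "contrasts.tsv"))

eff <- carcass_efficiency(broods$total_brood_mass, broods$carcass_mass)
message(sprintf("mean carcass-use efficiency: %.3f (boundary cases: %d)",
                mean(eff$efficiency), sum(eff$boundary)))

guild <- read.delim(system.file("extdata", "guild_counts.tsv",
                                package = "nichescan"))
ra <- relative_abundance(guild)
write_track(ra, file.path(out, "guild_abundance.tsv"))
ves <- ra[ra$species == "N_vespilloides", ]
message(sprintf("N. vespilloides relative abundance: Gamlingay %.1f%% (%d of %d), Waresley %.1f%% (%d of %d)",
                ves$percent[ves$woodland == "gamlingay"],
                ves$count[ves$woodland == "gamlingay"],
                ves$total[ves$woodland == "gamlingay"],
                ves$percent[ves$woodland == "waresley"],
                ves$count[ves$woodland == "waresley"],
                ves$total[ves$woodland == "waresley"]))
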