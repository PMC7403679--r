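---
title: "Polarising fine-scale divergence: windowed F_ST, PBS and ranked enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarising fine-scale divergence: windowed F_ST, PBS and ranked enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescan)
```

## The scientific setting

Two neighbouring populations of the burying beetle *Nicrophorus
vespilloides* can adapt their fecundity to the size of carrion locally
available: where competitors leave larger carcasses unused, selection can
favour females that lay more eggs per gram of carrion.  Detecting such
recent, fine-scale adaptation genomically is hard because overall
differentiation between neighbouring populations is tiny (genome-wide
F_ST of order 0.01), so the signal is a handful of modestly elevated
windows against a noisy background.  Two questions then matter:

1. **Which population moved?**  A pairwise F_ST peak says two populations
   differ, not which one diverged.  Adding a distant outgroup and
   computing **population branch statistics (PBS)** polarises each
   window's divergence onto one of the three branches.
2. **Is the divergence concentrated in functionally coherent genes?**
   Rather than thresholding outliers, a **ranked gene-set enrichment**
   over per-gene divergence scores asks whether, say, oogenesis-annotated
   genes sit unusually high in the genome-wide ranking.

`nichescan` implements this analysis end to end, together with the
phenotype side of the same study design: split-brood reaction norms of
clutch size against carcass size, carcass-use efficiency, egg volume, and
guild relative abundance.  A synthetic-data generator with known truth
stands in for the sequencing and breeding data, so every stage is testable
against oracles.

## Divergence statistics

**Per-site F_ST.**  The default estimator is Hudson's, computed from
per-population allele counts.  With sample frequencies $\hat p_1, \hat
p_2$ and allele totals $n_1, n_2$:

$$N = (\hat p_1-\hat p_2)^2-\frac{\hat p_1(1-\hat p_1)}{n_1-1}
      -\frac{\hat p_2(1-\hat p_2)}{n_2-1},\qquad
  D = \hat p_1(1-\hat p_2)+\hat p_2(1-\hat p_1).$$

Windowed F_ST is the *ratio of sums* $\sum N/\sum D$ over the sites in a
window ("weighted"), or the mean of per-site ratios over sites with $D>0$
("unweighted").  A Weir–Cockerham ANOVA variant on allele frequencies is
available (`estimator = "wc"`) so both conventions can be compared; output
is always labelled with the estimator used, since the source tools of
studies in this area often leave it ambiguous.  Hudson's is the default
because it is the standard substrate for PBS and is robust to unequal
sample sizes.

**Windows.**  The genome scan uses 2-kb non-overlapping windows; gene-level
work uses 500-bp windows sliding by 100 bp.  Windows are 0-based,
half-open internally; conversion to the 1-based conventions of VCF and
GFF3 happens only at the file boundary.  Windows with fewer usable sites
than `min_sites` (default 5 for 2-kb scan windows, 2 for 500-bp sliding
windows) are emitted but flagged invalid — tiny windows produce wild
ratios, and the defaults reflect the expected site densities rather than
any property of a particular run.

**PBS.**  Each pairwise F_ST is transformed to a branch length
$T = -\log(1-F_{ST})$, and the branch specific to population 1 of a
(1, 2, outgroup) triple is

$$PBS_1 = \tfrac12\,(T_{12} + T_{13} - T_{23}),$$

with rotations for the other two branches.  The three values satisfy
$PBS_i + PBS_j = T_{ij}$ exactly, which the test-suite asserts to 1e-12 on
a million random triples.  Numerical guards: F_ST is clamped to
$[0, 1-10^{-6}]$ before the log (negative estimates are sampling noise;
the cap keeps $T$ finite and is recorded in output), and natural log is
used throughout (base only rescales all branches jointly).

**zF_ST and outliers.**  Scan-window F_ST is standardised by the mean and
SD over valid windows; the attached tail probability is the one-sided
upper standard-normal tail.  This is a descriptive ranking device, not a
calibrated test — the z-values are not normal under the true null, and
the choice of a one-sided tail is a documented convention.  PBS outliers
use the scatterplot convention: windows exceeding a threshold (default
0.05) on either focal branch, classified `focal1` / `focal2` / `both`.

**Diversity summaries.**  Per-site diversity is the unbiased
heterozygosity $2\hat p(1-\hat p)\,n/(n-1)$; window $\pi$ divides the site
sum by the full window span (the all-sites convention, so invariant
positions count in the denominator).  Tajima's D uses the classical
constants; the per-window allele number is the modal called-allele total
among segregating sites, windows need at least 3 segregating sites and 4
alleles, and others are flagged undefined.

**Hard filter.**  Records are removed iff QD < 2.0 or SOR > 3.0 or
FS > 200 — the GATK-style hard-filter rule.  Missing annotations follow a
configurable policy (`pass` by default) and the filter report counts
violations per criterion, so a record violating two criteria appears in
both counts.

## Per-gene scores and ranked enrichment

Each gene's divergence score on a branch is the **maximum PBS among valid
sliding windows overlapping the gene body** (at least 1 bp of half-open
intersection).  Whether the original analyses used sliding or tiled 500-bp
windows is ambiguous; sliding is the default (it matches the sliding
profile convention) and tiled windows remain available through
`make_windows()`.  Ranking is by descending score with a lexicographic
gene-ID tie-break, so results are deterministic; unscored genes (no valid
overlapping window) are excluded and counted.

Enrichment uses the classic weighted Kolmogorov–Smirnov running sum: a hit
at rank $i$ adds $|s_i|^p / \sum_{hits}|s|^p$, a miss subtracts
$1/(N-n_{set})$; ES is the extremal deviation.  The null permutes gene
labels; with a fixed ranking this is equivalent to drawing random sets of
the same size, so null distributions are computed once per distinct set
size and shared across terms.  NES divides ES by the mean same-sign null
|ES|; the nominal p is the same-sign null tail; the FDR q is the
sign-stratified ratio of null to observed NES tail fractions, clipped to
[0, 1].  Defaults ($p = 1$, 1000 permutations, set-size bounds [10, 500])
follow the community baseline for ranked enrichment; all are arguments.
Depleted (negative-ES) terms are reported with their sign rather than
dropped.  GO structure is taken as given: the gene-to-term table is
assumed already propagated, and no ontology parsing is attempted.

Each branch is ranked and tested separately — divergence on one branch
never enters another branch's ranking — so cross-branch comparison of NES
for a term is qualitative (which branch enriches), not a formal test of
NES difference.

## Phenotype computations

- **Egg volume**: $V = \pi w^2 L / 6$ (prolate spheroid; mm³), which
  reduces to the sphere volume at $L = w$.
- **Carcass-use efficiency**: total brood mass at larval dispersal divided
  by carcass mass, with an empirical-logit transform; exact 0/1 values are
  shrunk by $\varepsilon = 1/(2 n_{obs})$ and flagged.
- **Reaction norms**: each dyad (paired sibling broods, one on a small and
  one on a large carcass) yields an *elevation* — the cross-treatment mean
  — and a *slope* — large minus small.  Elevation could equally be defined
  as the small-carcass intercept; the cross-treatment mean is used because
  it is orthogonal to the slope in this two-point design, and the
  decomposition is exactly invertible.  Incomplete dyads (breeding
  failures) are excluded and counted.
- **Permutation contrasts** replace the original study's GLMMs: the
  population difference in mean elevation (or slope) is tested by
  shuffling population labels across dyads, two-sided, with exhaustive
  enumeration whenever $\binom{n_A+n_B}{n_A}$ fits inside the permutation
  budget (the p-value is then exact and includes the observed
  assignment).  This is a deliberate methodological substitution, not a
  reproduction of the original test statistics: it tests exchangeability
  of dyad summaries, without random block effects.
- **Guild relative abundance**: species proportions of trap counts per
  woodland, reported to one decimal of a percent.  The bundled
  `guild_counts.tsv` holds the published season totals (1811 of 2219
  *N. vespilloides* in Gamlingay Wood; 1963 of 2096 in Waresley Wood),
  with the remaining congeners aggregated.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with known truth, at desk scale.

**Genotypes.**  Ancestral frequencies $p_0$ are drawn from a configurable
law; each population's frequency comes from the Balding–Nichols beta law
$\mathrm{Beta}\!\big(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\big)$, so
$E[p]=p_0$ and $\mathrm{Var}(p)=F\,p_0(1-p_0)$; $F=0$ copies $p_0$
exactly.  Diploid genotypes are independent Binomial(2, p) draws — hard
calls, a deliberate simplification of the low-coverage
genotype-likelihood setting of real data.  Defaults mirror the study
design: 40 + 40 diploids for the focal populations, 22 for the outgroup;
branch drift 0.01 for the two focal branches and 0.05 for the outgroup,
which places genome-wide weighted F_ST near the 0.01 order observed
between neighbouring woodlands.  "Planted" loci draw the focal
population's frequency with a larger $F_{sel}$, concentrating divergence
where the configuration says.  Synthetic QD/SOR/FS INFO fields make a
configurable fraction (default 5%) of records fail the hard filter so the
filter stage has work to do.

**Frequency laws.**  The default is Uniform(0.05, 0.95), which avoids
near-fixed sites that make F_ST estimators degenerate and keeps small
scans informative.  A log-uniform option (density $\propto 1/p$) mimics a
neutral site-frequency spectrum: integrating binomial sampling over
$1/p$ gives a sample SFS exactly $\propto 1/i$, so on such draws
Tajima's D is centred near zero — the property the test-suite checks with
wide bounds $(5\times 10^{-4}, 0.999)$.  Under the uniform default D is
strongly positive (common alleles are over-represented relative to
Watterson's expectation), which is expected and harmless for the
divergence statistics: sites are exchangeable draws, not a coalescent
sample, and no test pretends otherwise.

**Annotation.**  Genes tile each contig at fixed length and spacing
(defaults 1 kb / 1 kb), written as 1-based inclusive GFF3.  Every gene
gets 1–3 random GO terms; a designated term additionally collects every
gene overlapping a planted locus plus random decoys up to a configured
set size.

**Broods.**  Clutch size is Poisson with mean
`base + slope·[large carcass] + offset·[derived population]` — an
elevation shift with a shared slope, the signature under study.  Brood
size applies binomial offspring loss, plus an extra culling loss for the
derived population on small carcasses when enabled.  Egg length is normal
(1.9 ± 0.08 mm) and egg width shrinks mildly with clutch size (an
egg-size/egg-number trade-off); only a binomial "measurable" subset of
eggs (65%) carries measurements, mimicking eggs hidden in the soil.
Defaults (base clutch 15, carcass effect +5, offset +5, 10% baseline
loss, 25% culling) give clutch sizes and effect magnitudes in the range
of real broods.

**Determinism.**  One master seed governs a run; sub-streams use fixed
documented offsets (+0 frequencies, +1 genotypes, +2 INFO fields, +3
annotation), so modules are independently reproducible and identical
configurations produce byte-identical artifacts.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium (sites are independent,
so real scans have fewer effective windows and more correlated peaks),
sequencing error and genotype uncertainty, varying gene length and
density, GO term overlap structure, block effects and over-dispersion in
brood counts.  Conclusions from the synthetic experiments are about the
correctness and calibration of the statistics, not about the biology of
any real population.

## Study conditions used by the simulation experiments

Problem sizes were chosen once, as the smallest that leave the
statistics in their intended regime:

- **Planted-locus recovery**: 20,000 SNPs on 2 × 1 Mb, background
  F = 0.01, one planted SNP at $F_{sel} = 0.5$ on the derived focal
  branch, 100 seeds.  At these densities (~10 sites per 2-kb window) a
  *single* selected SNP contributes roughly $(F_{sel}+F)\,p_0(1-p_0)
  \approx 0.09$ to the window numerator against a denominator near 4, an
  expected focal-branch PBS excess of only ~0.03 — below the
  maximum-over-1000-windows noise floor at 80/80/44 sampled alleles.  The
  recovery experiment therefore shows exactly this: the planted window is
  *rarely the single top window* genome-wide, although it is essentially
  never the top window on the wrong focal branch.  Single-SNP selection
  signals at this drift scale are not reliably rank-one detectable in
  2-kb windows; multi-SNP selected blocks (below) are.
- **Enrichment power**: 6,000 SNPs on 1 × 600 kb, 300 genes, 40 GO terms;
  12 of the 15 genes of the designated term carry a 3-SNP selected block
  at $F_{sel} = 0.6$ on the derived branch; 1000 permutations; 100
  replicates.  This yields NES ≈ 2.2 on the focal branch with FDR q
  below 0.05, and a clear focal-versus-other-branch NES ordering — the
  qualitative pattern expected when divergence concentrates in one
  functional gene set on one branch.
- **Enrichment calibration**: the same genome with no planted loci; the
  fraction of terms at nominal p < 0.05, pooled over 25 seeds, sits at
  5% ± 2%.
- **Reaction norms**: 50 dyads per population, elevation offset +5 eggs;
  the elevation contrast reaches p < 0.01 while the slope contrast stays
  above 0.05 in ≥ 90% of seeds.  Super-uniformity of the permutation p
  under exchangeable nulls is checked over 500 seeds with a one-sided
  Kolmogorov–Smirnov bound at α = 0.01.

## Known limitations

- Genotypes are hard calls; the genotype-likelihood machinery appropriate
  to low-coverage data is out of scope, so absolute statistic values on
  real low-coverage VCFs inherit the usual hard-call biases.
- The zF_ST tail probability is a ranking convenience, not a calibrated
  p-value.
- The Weir–Cockerham option uses the allele-frequency (ANOVA) form
  without the genotypic heterozygosity term.
- Multi-allelic records are skipped on read (and counted), not split.
- FDR q-values for very small collections are coarse: with few terms the
  observed-tail denominator is grainy, and q = 0 simply means no null NES
  reached the observed one.
- Permutation contrasts ignore experimental blocks; with strong block
  structure the exchangeability assumption weakens.
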