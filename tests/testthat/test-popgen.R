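test_that("hard filter removes exactly the QD/SOR/FS violators", {
  info <- data.frame(QD = c(5, 1.9), SOR = c(1, 1), FS = c(10, 10))
  res <- hard_filter(info)
  expect_equal(res$keep, c(TRUE, FALSE))
  expect_equal(res$report$qd_violations, 1)

  # missing-value policy
  miss <- data.frame(QD = NA, SOR = 1, FS = 10)
  expect_true(hard_filter(miss, missing = "pass")$keep)
  expect_false(hard_filter(miss, missing = "fail")$keep)
})

test_that("six-record toy VCF filters as enumerated by hand", {
  path <- tempfile(fileext = ".vcf")
  toy <- write_toy_vcf(path)
  loaded <- read_vcf(path, toy$pop_map)
  res <- hard_filter(loaded$info)
  expect_equal(res$keep, toy$expected_keep)
  expect_equal(res$report$n_retained, 3)
  expect_equal(res$report$n_removed, 3)
  # record 6 violates two criteria, so per-criterion counts exceed removals
  expect_equal(res$report$qd_violations, 2)
  expect_equal(res$report$sor_violations, 1)
  expect_equal(res$report$fs_violations, 1)
  expect_gte(res$report$qd_violations + res$report$sor_violations +
               res$report$fs_violations, res$report$n_removed)
  unlink(path)
})

test_that("allele counts equal a per-sample loop oracle", {
  geno <- matrix(c(0L, 1L, 2L), nrow = 1)
  colnames(geno) <- c("a", "b", "c")
  gm1 <- genotype_matrix(geno, 1L, 0L, c(a = "p", b = "p", c = "p"))
  cnt1 <- allele_counts(gm1)
  expect_equal(unname(cnt1$count[1, "p"]), 3)
  expect_equal(unname(cnt1$total[1, "p"]), 6)

  set.seed(11)
  geno <- matrix(sample(c(0:2, NA), 200, replace = TRUE), nrow = 20)
  colnames(geno) <- sprintf("s%02d", 1:10)
  pops <- setNames(rep(c("x", "y"), each = 5), colnames(geno))
  gm <- genotype_matrix(geno, rep(1L, 20), 0:19, pops)
  cnt <- allele_counts(gm)
  for (snp in 1:20) {
    for (pop in c("x", "y")) {
      tot <- 0L; dose <- 0L
      for (s in names(pops)[pops == pop]) {
        g <- unname(gm$geno[snp, s])
        if (!is.na(g)) { tot <- tot + 2L; dose <- dose + g }
      }
      expect_identical(unname(cnt$count[snp, pop]), dose)
      expect_identical(unname(cnt$total[snp, pop]), tot)
    }
  }
  # all-missing population yields total 0
  geno_na <- matrix(NA_integer_, 1, 2, dimnames = list(NULL, c("a", "b")))
  cnt_na <- allele_counts(genotype_matrix(geno_na, 1L, 0L,
                                          c(a = "p", b = "p")))
  expect_equal(unname(cnt_na$total[1, "p"]), 0)
})

test_that("Hudson per-site components match hand-evaluated values", {
  # fixed difference, large samples: ratio tends to 1
  big <- hudson_site(1000, 1000, 0, 1000)
  expect_equal(big$den, 1)
  expect_equal(big$num / big$den, 1, tolerance = 1e-2)
  # identical frequencies, large n: numerator tends to 0
  eq <- hudson_site(500, 1000, 500, 1000)
  expect_equal(eq$num, 0, tolerance = 1e-3)
  # hand-evaluated: p1 = 0.2, p2 = 0.8, n1 = n2 = 10
  h <- hudson_site(2, 10, 8, 10)
  expect_equal(h$num, 0.36 - 2 * (0.2 * 0.8 / 9), tolerance = 1e-12)
  expect_equal(h$den, 0.68, tolerance = 1e-12)
  expect_equal(h$num / h$den, 0.4771241830065359, tolerance = 1e-10)
  # both fixed for the same allele: (0, 0)
  z <- hudson_site(10, 10, 10, 10)
  expect_equal(c(z$num, z$den), c(0, 0))
  # insufficient alleles: excluded
  low <- hudson_site(1, 2, 5, 10)
  expect_true(is.na(low$num) && is.na(low$den))
})

test_that("FST is invariant under a simultaneous allele-label swap", {
  set.seed(21)
  t1 <- 80; t2 <- 44
  c1 <- rbinom(50, t1, 0.3); c2 <- rbinom(50, t2, 0.5)
  a <- hudson_site(c1, t1, c2, t2)
  b <- hudson_site(t1 - c1, t1, t2 - c2, t2)
  expect_equal(a$num, b$num, tolerance = 1e-12)
  expect_equal(a$den, b$den, tolerance = 1e-12)
  w <- wc_site(c1, t1, c2, t2)
  ws <- wc_site(t1 - c1, t1, t2 - c2, t2)
  expect_equal(w$num / w$den, ws$num / ws$den, tolerance = 1e-12)
})

test_that("window construction tiles, slides and truncates as specified", {
  w1 <- make_windows(c(chr = 5000), 2000)
  expect_equal(w1$start, c(0, 2000, 4000))
  expect_equal(w1$end, c(2000, 4000, 5000))
  expect_equal(w1$partial, c(FALSE, FALSE, TRUE))

  w2 <- make_windows(c(chr = 1000), 500, 100)
  expect_equal(w2$start, seq(0, 500, by = 100))
  expect_true(all(!w2$partial))

  w3 <- make_windows(c(chr = 300), 500)
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$start, w3$end), c(0, 300))
  expect_true(w3$partial)
})

test_that("windowed FST agrees with direct arithmetic and mode definitions", {
  # two sites with components (0.1, 0.5) and (0.3, 0.5): both modes give 0.4
  counts <- list(contig = c(1, 1), pos = c(10, 20),
                 count = cbind(a = c(4, 4), b = c(4, 4)),
                 total = cbind(a = c(10, 10), b = c(10, 10)),
                 populations = c("a", "b"))
  win <- make_windows(c("1" = 100), 100)
  with_mocked_components <- function(num, den, mode) {
    tr <- nichescan:::aggregate_fst(num, den, counts$contig, counts$pos, win, 1L)
    if (mode == "weighted") tr$fst_weighted else tr$fst_unweighted
  }
  expect_equal(with_mocked_components(c(0.1, 0.3), c(0.5, 0.5), "weighted"), 0.4)
  expect_equal(with_mocked_components(c(0.1, 0.3), c(0.5, 0.5), "unweighted"), 0.4)
  # equal denominators no longer: modes diverge as defined
  expect_equal(with_mocked_components(c(0.1, 0.3), c(0.5, 1.0), "weighted"),
               0.4 / 1.5)
  expect_equal(with_mocked_components(c(0.1, 0.3), c(0.5, 1.0), "unweighted"),
               mean(c(0.2, 0.3)))

  # single-SNP window: weighted == unweighted == per-site ratio
  single <- nichescan:::aggregate_fst(0.2, 0.5, 1, 10,
                                      make_windows(c("1" = 100), 100), 1L)
  expect_equal(single$fst_weighted, 0.4)
  expect_equal(single$fst_unweighted, 0.4)

  # identical populations: valid windows are <= 0 and clamp to 0
  set.seed(5)
  geno <- matrix(rbinom(400 * 20, 2, 0.4), nrow = 400)
  colnames(geno) <- sprintf("s%02d", 1:20)
  pops <- setNames(rep(c("a", "b"), 10), colnames(geno))
  gm <- genotype_matrix(geno, rep(1L, 400), seq(0, 39900, by = 100), pops)
  tr <- window_fst(allele_counts(gm), "a", "b",
                   make_windows(c("1" = 40000), 2000))
  expect_lt(mean(tr$fst[tr$valid]), 0.02)
  expect_true(all(tr$fst_clamped >= 0))
})

test_that("windowed FST equals a brute-force per-site loop", {
  set.seed(33)
  cfg <- sim_config(n_contigs = 2, contig_length = 5e4, n_snps = 1500, seed = 12)
  fr <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(fr, cfg)
  cnt <- allele_counts(gm)
  win <- make_windows(c("1" = 5e4, "2" = 5e4), 2000)
  tr <- window_fst(cnt, "gamlingay", "wales", win, min_sites = 1L)
  for (i in sample(nrow(tr), 40)) {
    sel <- cnt$contig == tr$contig[i] & cnt$pos >= tr$start[i] &
      cnt$pos < tr$end[i]
    num <- 0; den <- 0; ratios <- c()
    for (j in which(sel)) {
      o <- oracle_hudson(cnt$count[j, "gamlingay"], cnt$total[j, "gamlingay"],
                         cnt$count[j, "wales"], cnt$total[j, "wales"])
      if (o["den", 1] == 0) o["num", 1] <- 0
      num <- num + o["num", 1]; den <- den + o["den", 1]
      if (o["den", 1] > 0) ratios <- c(ratios, o["num", 1] / o["den", 1])
    }
    if (den > 0) expect_equal(tr$fst_weighted[i], unname(num / den),
                              tolerance = 1e-12)
    if (length(ratios)) expect_equal(tr$fst_unweighted[i],
                                     unname(mean(ratios)), tolerance = 1e-12)
  }
})

test_that("nucleotide diversity follows the unbiased heterozygosity formula", {
  counts <- list(contig = 1, pos = 100,
                 count = cbind(p = 40), total = cbind(p = 80),
                 populations = "p")
  win <- make_windows(c("1" = 2000), 2000)
  pi_t <- nucleotide_diversity(counts, "p", win)
  expect_equal(pi_t$pi, (2 * 0.25 * 80 / 79) / 2000, tolerance = 1e-12)
  # monomorphic window
  counts$count <- cbind(p = 0)
  expect_equal(nucleotide_diversity(counts, "p", win)$pi, 0)
  # allele-label symmetry
  counts$count <- cbind(p = 10)
  a <- nucleotide_diversity(counts, "p", win)$pi
  counts$count <- cbind(p = 70)
  expect_equal(nucleotide_diversity(counts, "p", win)$pi, a)
})

test_that("Tajima's D matches a brute-force recomputation from haplotypes", {
  # 5 diploid samples (n = 10 alleles), 5 segregating singleton sites
  geno <- matrix(0L, nrow = 5, ncol = 5,
                 dimnames = list(NULL, sprintf("s%d", 1:5)))
  for (k in 1:5) geno[k, k] <- 1L
  gm <- genotype_matrix(geno, rep(1L, 5), seq(0L, 400L, by = 100L),
                        setNames(rep("p", 5), colnames(geno)))
  cnt <- allele_counts(gm)
  win <- make_windows(c("1" = 500), 500)
  got <- tajimas_d(cnt, "p", win)

  # oracle: explicit haplotype table (singleton alleles on distinct
  # haplotypes), all pairwise differences, all constants from scratch
  hap <- matrix(0L, nrow = 10, ncol = 5)
  for (k in 1:5) hap[2 * k - 1, k] <- 1L
  n <- 10; S <- 5
  pair_diffs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pair_diffs <- c(pair_diffs, sum(hap[i, ] != hap[j, ]))
  }
  pi_mean <- mean(pair_diffs)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  d_oracle <- (pi_mean - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))

  expect_true(got$defined)
  expect_equal(got$tajimas_d, d_oracle, tolerance = 1e-12)
  expect_lt(d_oracle, 0) # singletons only: deficit of pairwise diversity
})

test_that("Tajima's D is undefined without enough segregating sites", {
  counts <- list(contig = c(1, 1), pos = c(10, 20),
                 count = cbind(p = c(0, 10)), total = cbind(p = c(10, 10)),
                 populations = "p")
  win <- make_windows(c("1" = 100), 100)
  got <- tajimas_d(counts, "p", win)
  expect_false(got$defined)
  expect_true(is.na(got$tajimas_d))
})

test_that("Tajima's D is centred near zero under a neutral-like frequency law", {
  cfg <- sim_config(n_contigs = 1, contig_length = 6e5, n_snps = 20000,
                    ancestral_freq_law = list(kind = "loguniform",
                                              min = 5e-4, max = 0.999),
                    branch_drift = c(gamlingay = 0, waresley = 0, wales = 0),
                    sample_sizes = c(gamlingay = 40, waresley = 2, wales = 2),
                    seed = 3)
  fr <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(fr, cfg)
  cnt <- allele_counts(gm)
  td <- tajimas_d(cnt, "gamlingay", make_windows(c("1" = 6e5), 2000))
  expect_gte(sum(td$defined), 200)
  expect_lt(abs(mean(td$tajimas_d[td$defined])), 0.3)
})

test_that("mean weighted FST increases with branch drift", {
  means <- vapply(c(0.005, 0.01, 0.05, 0.1), function(f) {
    cfg <- sim_config(n_contigs = 1, contig_length = 2e5, n_snps = 2000,
                      branch_drift = c(gamlingay = f, waresley = f,
                                       wales = 0.05),
                      seed = 17)
    sc <- core_scan(cfg, make_windows(c("1" = 2e5), 2000))
    genomewide_fst(sc$fst[[1]])[["weighted"]]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
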