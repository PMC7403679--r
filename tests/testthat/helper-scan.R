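# Shared fixtures: in-memory scan chains over the synthetic generator, and
# small independent oracles used across test files.

# frequency -> genotype -> counts -> three pairwise FST tracks -> PBS track
core_scan <- function(config, windows, min_sites = 5L, mode = "weighted") {
  fr <- simulate_frequencies(config)
  gm <- simulate_genotypes(fr, config)
  cnt <- allele_counts(gm)
  f12 <- window_fst(cnt, "gamlingay", "waresley", windows,
                    mode = mode, min_sites = min_sites)
  f13 <- window_fst(cnt, "gamlingay", "wales", windows,
                    mode = mode, min_sites = min_sites)
  f23 <- window_fst(cnt, "waresley", "wales", windows,
                    mode = mode, min_sites = min_sites)
  list(freqs = fr, gm = gm, counts = cnt, fst = list(f12, f13, f23),
       pbs = pbs_scan(f12, f13, f23))
}

# Hudson per-site components, written out longhand (independent of the
# package's vectorised implementation).
oracle_hudson <- function(c1, t1, c2, t2) {
  p1 <- c1 / t1
  p2 <- c2 / t2
  rbind(num = (p1 - p2)^2 - p1 * (1 - p1) / (t1 - 1) - p2 * (1 - p2) / (t2 - 1),
        den = p1 * (1 - p2) + p2 * (1 - p1))
}

# GSEA running sum recomputed step by step with an explicit loop.
oracle_running_sum <- function(scores, hit, p) {
  n <- length(scores)
  nr <- sum(abs(scores[hit])^p)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (hit[i]) {
      acc + (if (nr > 0) abs(scores[i])^p / nr else 1 / sum(hit))
    } else {
      acc - 1 / (n - sum(hit))
    }
    run[i] <- acc
  }
  run
}

# A dyad-summary table built directly (bypassing the generator).
toy_summaries <- function(a_vals, b_vals, component = "elevation") {
  df <- data.frame(
    dyad_id = sprintf("d%02d", seq_len(length(a_vals) + length(b_vals))),
    population = rep(c("popA", "popB"), c(length(a_vals), length(b_vals)))
  )
  df[[component]] <- c(a_vals, b_vals)
  df
}

# Six-record toy VCF with known QD/SOR/FS violations, written to a file.
write_toy_vcf <- function(path) {
  geno <- matrix(c(0L, 1L, 2L), nrow = 6, ncol = 3, byrow = TRUE)
  colnames(geno) <- c("s1", "s2", "s3")
  pop_map <- c(s1 = "gamlingay", s2 = "gamlingay", s3 = "waresley")
  gm <- genotype_matrix(geno, rep(1L, 6), seq(0L, 500L, by = 100L), pop_map)
  info <- data.frame(
    QD = c(5, 25, 10, 1.5, 8, 1.0),   # records 4 and 6 violate QD < 2
    SOR = c(1, 0.5, 2.9, 1, 4.0, 1),  # record 5 violates SOR > 3
    FS = c(10, 0, 150, 20, 5, 300)    # record 6 also violates FS > 200
  )
  write_vcf(gm, info, path)
  list(pop_map = pop_map, info = info,
       expected_keep = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
}
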