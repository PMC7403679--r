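test_that("branch length transform and clamps behave as documented", {
  expect_equal(branch_length(0), 0)
  expect_equal(branch_length(0.11), -log(0.89), tolerance = 1e-12)
  expect_equal(branch_length(0.11), 0.1165338, tolerance = 1e-6)
  expect_equal(branch_length(-0.3), 0)       # negatives clamp to 0
  expect_equal(branch_length(1), -log(1e-6)) # cap at 1 - eps
  expect_equal(branch_length(5), -log(1e-6))
})

test_that("PBS decomposition matches hand evaluation and its identities", {
  z <- pbs(0, 0, 0)
  expect_equal(unlist(z), c(pbs1 = 0, pbs2 = 0, pbs3 = 0))

  t12 <- branch_length(0.11); t13 <- branch_length(0.20)
  t23 <- branch_length(0.05)
  got <- pbs(t12, t13, t23)
  expect_equal(got$pbs1, (0.1165338 + 0.2231436 - 0.0512933) / 2,
               tolerance = 1e-6)
  expect_equal(got$pbs1, 0.1441921, tolerance = 1e-6)

  # algebraic identities on random admissible triples
  set.seed(2)
  f <- matrix(runif(3000, 0, 0.999), ncol = 3)
  tt <- branch_length(f)
  p <- pbs(tt[, 1], tt[, 2], tt[, 3])
  expect_lt(max(abs(p$pbs1 + p$pbs2 - tt[, 1])), 1e-12)
  expect_lt(max(abs(p$pbs1 + p$pbs3 - tt[, 2])), 1e-12)
  expect_lt(max(abs(p$pbs2 + p$pbs3 - tt[, 3])), 1e-12)
  expect_lt(max(abs(p$pbs1 + p$pbs2 + p$pbs3 - rowSums(tt) / 2)), 1e-12)
})

test_that("PBS1 is monotone in its own pairwise distances", {
  grid <- seq(0.05, 0.3, by = 0.05)
  up12 <- vapply(grid, function(f) pbs(branch_length(f), branch_length(0.2),
                                       branch_length(0.1))$pbs1, numeric(1))
  expect_true(all(diff(up12) > 0))
  up13 <- vapply(grid, function(f) pbs(branch_length(0.2), branch_length(f),
                                       branch_length(0.1))$pbs1, numeric(1))
  expect_true(all(diff(up13) > 0))
  down23 <- vapply(grid, function(f) pbs(branch_length(0.2), branch_length(0.2),
                                         branch_length(f))$pbs1, numeric(1))
  expect_true(all(diff(down23) < 0))
})

test_that("pbs_scan rejects mismatched window sets and permutes with labels", {
  cfg <- sim_config(n_contigs = 1, contig_length = 1e5, n_snps = 1000, seed = 19)
  win <- make_windows(c("1" = 1e5), 2000)
  sc <- core_scan(cfg, win)
  bad <- sc$fst[[2]][-1, ]
  expect_error(pbs_scan(sc$fst[[1]], bad, sc$fst[[3]]), "identical window set")

  # swapping the two focal populations swaps pbs1 and pbs2
  cnt <- sc$counts
  f21 <- window_fst(cnt, "waresley", "gamlingay", win)
  f23 <- window_fst(cnt, "waresley", "wales", win)
  f13 <- window_fst(cnt, "gamlingay", "wales", win)
  swapped <- pbs_scan(f21, f23, f13)
  expect_equal(swapped$pbs1, sc$pbs$pbs2, tolerance = 1e-12)
  expect_equal(swapped$pbs2, sc$pbs$pbs1, tolerance = 1e-12)
  expect_equal(swapped$pbs3, sc$pbs$pbs3, tolerance = 1e-12)
})

test_that("equal branch drift gives statistically equal mean PBS on the focal branches", {
  m <- vapply(1:8, function(s) {
    cfg <- sim_config(n_contigs = 1, contig_length = 2e5, n_snps = 2000,
                      seed = 100 + s)
    sc <- core_scan(cfg, make_windows(c("1" = 2e5), 2000))
    mean_pbs(sc$pbs)[c("gamlingay", "waresley")]
  }, numeric(2))
  d <- m[1, ] - m[2, ]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("raising outgroup drift raises the outgroup's mean PBS", {
  m <- vapply(c(0.02, 0.05, 0.1), function(f) {
    cfg <- sim_config(n_contigs = 1, contig_length = 2e5, n_snps = 2000,
                      branch_drift = c(gamlingay = 0.01, waresley = 0.01,
                                       wales = f),
                      seed = 23)
    sc <- core_scan(cfg, make_windows(c("1" = 2e5), 2000))
    mean_pbs(sc$pbs)[["wales"]]
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("zFST standardises, ranks monotonically and de-standardises", {
  cfg <- sim_config(n_contigs = 1, contig_length = 2e5, n_snps = 2000, seed = 29)
  sc <- core_scan(cfg, make_windows(c("1" = 2e5), 2000))
  z <- zfst(sc$fst[[1]])
  v <- z$valid & !is.na(z$zfst)
  expect_equal(mean(z$zfst[v]), 0, tolerance = 1e-12)
  expect_equal(sd(z$zfst[v]), 1, tolerance = 1e-12)
  # one-sided normal upper tail
  expect_equal(stats::pnorm(1.959964, lower.tail = FALSE), 0.025,
               tolerance = 1e-6)
  expect_equal(z$p[v], pnorm(z$zfst[v], lower.tail = FALSE))
  # ranking by z equals ranking by raw FST
  expect_equal(order(z$zfst[v]), order(z$fst[v]))
  # de-standardisation recovers raw FST
  back <- z$zfst[v] * attr(z, "zfst_sd") + attr(z, "zfst_mean")
  expect_equal(back, z$fst[v], tolerance = 1e-12)
})

test_that("outlier flagging classifies threshold exceedances by branch", {
  win <- data.frame(contig = "1", start = c(0, 2000, 4000, 6000),
                    end = c(2000, 4000, 6000, 8000), partial = FALSE)
  tr <- win
  tr$fst12 <- tr$fst13 <- tr$fst23 <- 0.01
  tr$pbs1 <- c(0.01, 0.06, 0.01, 0.07)
  tr$pbs2 <- c(0.01, 0.01, 0.06, 0.07)
  tr$pbs3 <- 0
  tr$valid <- TRUE
  attr(tr, "pops") <- c("gamlingay", "waresley", "wales")
  class(tr) <- c("pbs_track", "data.frame")
  out <- flag_outliers(tr, threshold = 0.05)
  expect_equal(nrow(out), 3)
  expect_equal(out$class, c("focal1", "focal2", "both"))
  expect_equal(out$start, c(2000, 4000, 6000))
  # empty track
  expect_equal(nrow(flag_outliers(tr[0, ], 0.05)), 0)
})

test_that("a planted selected locus elevates its window on the focal branch only", {
  hits <- vapply(1:10, function(s) {
    planted <- data.frame(contig = 1L, pos = 100500L,
                          focal_population = "waresley", f_sel = 0.5)
    cfg <- sim_config(n_contigs = 1, contig_length = 2e5, n_snps = 2000,
                      planted_loci = planted, seed = 400 + s)
    sc <- core_scan(cfg, make_windows(c("1" = 2e5), 2000))
    pt <- sc$pbs
    i <- which(pt$start <= 100500 & 100500 < pt$end)
    v <- pt$valid
    c(rank_w = mean(pt$pbs2[v] <= pt$pbs2[i]),
      excess_g = pt$pbs1[i] - mean(pt$pbs1[v]))
  }, numeric(2))
  # focal branch: planted window sits high in the PBS distribution
  expect_gt(mean(hits["rank_w", ]), 0.85)
  # other focal branch: no systematic elevation
  expect_lt(mean(hits["excess_g", ]), 0.02)
})

test_that("gene profiles slice the sliding track and locate the peak", {
  win <- make_windows(c("1" = 3000), 500, 100)
  tr <- win
  tr$fst12 <- tr$fst13 <- tr$fst23 <- 0.01
  tr$pbs1 <- rep(0.01, nrow(tr))
  tr$pbs2 <- rep(0.01, nrow(tr))
  tr$pbs3 <- 0
  tr$valid <- TRUE
  class(tr) <- c("pbs_track", "data.frame")
  gene <- list(contig = "1", start = 1000, end = 2000)

  # constant track: flat profile, argmax = first overlapping window
  prof <- gene_profile(gene, tr, branch = 1)
  expect_equal(prof$argmax$start, min(prof$profile$start))
  expect_equal(prof$profile$start, seq(600, 1900, by = 100))

  # single elevated window inside the gene
  tr$pbs1[tr$start == 1400] <- 0.2
  prof2 <- gene_profile(gene, tr, branch = 1)
  expect_equal(prof2$argmax$start, 1400)
  expect_equal(prof2$argmax$pbs, 0.2)

  # flanks extend the slice
  prof3 <- gene_profile(gene, tr, branch = 1, flank = 500)
  expect_true(min(prof3$profile$start) < 600)
})

test_that("gene profile values equal per-site recomputation within each window", {
  cfg <- sim_config(n_contigs = 1, contig_length = 2e4, n_snps = 600, seed = 77)
  win <- make_windows(c("1" = 2e4), 500, 100)
  sc <- core_scan(cfg, win, min_sites = 2L)
  gene <- list(contig = "1", start = 5000, end = 7000)
  prof <- gene_profile(gene, sc$pbs, branch = 2)
  cnt <- sc$counts
  for (r in seq_len(nrow(prof$profile))) {
    row <- prof$profile[r, ]
    if (!row$valid || is.na(row$pbs)) next
    sel <- which(cnt$pos >= row$start & cnt$pos < row$end)
    wfst <- function(pa, pb) {
      num <- 0; den <- 0
      for (j in sel) {
        o <- oracle_hudson(cnt$count[j, pa], cnt$total[j, pa],
                           cnt$count[j, pb], cnt$total[j, pb])
        if (o["den", 1] == 0) o["num", 1] <- 0
        num <- num + o["num", 1]; den <- den + o["den", 1]
      }
      num / den
    }
    t12 <- branch_length(wfst("gamlingay", "waresley"))
    t13 <- branch_length(wfst("gamlingay", "wales"))
    t23 <- branch_length(wfst("waresley", "wales"))
    expect_equal(row$pbs, unname((t12 + t23 - t13) / 2), tolerance = 1e-12)
  }
})
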