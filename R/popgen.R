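#' Genotype matrix container
#'
#' Per-sample biallelic genotypes (alt-allele dosage 0/1/2, `NA` = missing)
#' with 0-based SNP coordinates and a sample-to-population map.  The
#' substrate of every population-genetic statistic in the package.
#'
#' @param geno SNP x sample integer matrix (values 0, 1, 2 or `NA`).
#' @param contig integer/character contig per SNP.
#' @param pos 0-based position per SNP (unique and sorted within contig).
#' @param pop_map named character vector, sample name -> population.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, contig, pos, pop_map) {
  stopifnot(is.matrix(geno), nrow(geno) == length(contig),
            length(contig) == length(pos))
  if (is.null(colnames(geno))) stop("geno must have sample column names")
  if (!setequal(colnames(geno), names(pop_map))) {
    stop("pop_map must name exactly the samples in geno")
  }
  pop_map <- pop_map[colnames(geno)]
  ord <- order(contig, pos)
  if (is.unsorted(ord)) {
    geno <- geno[ord, , drop = FALSE]; contig <- contig[ord]; pos <- pos[ord]
  }
  if (anyDuplicated(paste(contig, pos))) stop("duplicate SNP coordinates")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  structure(list(geno = geno, contig = contig, pos = pos, pop_map = pop_map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "SNPs x", ncol(x$geno), "samples;",
      length(unique(x$pop_map)), "populations\n")
  invisible(x)
}

#' Per-population allele counts
#'
#' For every SNP and population: the derived (alt) allele count summed over
#' non-missing samples, and the called-allele total (2 x non-missing
#' samples).  Sites where a population has no calls get total 0 and are
#' skipped by downstream estimators.
#'
#' @param gm a [genotype_matrix()].
#' @return list with `contig`, `pos`, `count` and `total` (SNP x population
#'   matrices), and `populations`.
#' @export
allele_counts <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$pop_map)
  count <- matrix(0L, nrow(gm$geno), length(pops), dimnames = list(NULL, pops))
  total <- count
  for (pop in pops) {
    sub <- gm$geno[, gm$pop_map == pop, drop = FALSE]
    count[, pop] <- as.integer(rowSums(sub, na.rm = TRUE))
    total[, pop] <- 2L * as.integer(rowSums(!is.na(sub)))
  }
  list(contig = gm$contig, pos = gm$pos, count = count, total = total,
       populations = pops)
}

#' GATK-style hard filter on VCF INFO annotations
#'
#' Removes a record iff QD < 2.0 OR SOR > 3.0 OR FS > 200.  Missing
#' annotations are treated according to `missing`: `"pass"` (the criterion
#' with the missing value cannot fire) or `"fail"` (a missing value fires
#' its criterion).
#'
#' @param info data.frame with numeric columns `QD`, `SOR`, `FS` (NA =
#'   missing/malformed, flagged upstream with a warning by the reader).
#' @param missing policy for missing values.
#' @param qd_min,sor_max,fs_max thresholds.
#' @return list with `keep` (logical vector) and `report` (data.frame of
#'   per-criterion violation counts among all records, plus totals; a record
#'   violating several criteria is counted under each, so criterion counts
#'   can sum to more than `n_removed`).
#' @export
hard_filter <- function(info, missing = c("pass", "fail"),
                        qd_min = 2.0, sor_max = 3.0, fs_max = 200) {
  missing <- match.arg(missing)
  stopifnot(all(c("QD", "SOR", "FS") %in% names(info)))
  miss_fires <- missing == "fail"
  v_qd <- ifelse(is.na(info$QD), miss_fires, info$QD < qd_min)
  v_sor <- ifelse(is.na(info$SOR), miss_fires, info$SOR > sor_max)
  v_fs <- ifelse(is.na(info$FS), miss_fires, info$FS > fs_max)
  remove <- v_qd | v_sor | v_fs
  report <- data.frame(
    n_records = length(remove),
    n_removed = sum(remove),
    n_retained = sum(!remove),
    qd_violations = sum(v_qd),
    sor_violations = sum(v_sor),
    fs_violations = sum(v_fs)
  )
  list(keep = !remove, report = report)
}

#' Hudson per-site F_ST components
#'
#' For two populations with sample allele frequencies `p_i = count_i /
#' total_i` and allele totals `n_i`, returns the per-site numerator
#' `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)` and
#' denominator `p1 (1 - p2) + p2 (1 - p1)`.  The ratio of window-summed
#' numerator to denominator is the windowed ("ratio of averages") Hudson
#' F_ST.  Sites fixed for the same allele in both populations contribute
#' (0, 0).  Sites where either total is below 2 (or below `min_alleles`)
#' contribute (NA, NA) and are excluded downstream.
#'
#' @param c1,t1,c2,t2 vectors of allele counts and totals for the two
#'   populations.
#' @param min_alleles minimum called alleles per population for a site to be
#'   used (default 4).
#' @return list with vectors `num` and `den`.
#' @export
hudson_site <- function(c1, t1, c2, t2, min_alleles = 4L) {
  usable <- t1 >= max(2L, min_alleles) & t2 >= max(2L, min_alleles)
  p1 <- c1 / t1
  p2 <- c2 / t2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (t1 - 1) - p2 * (1 - p2) / (t2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fixed_same <- den == 0
  num[fixed_same] <- 0
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  list(num = num, den = den)
}

#' Weir-Cockerham per-site F_ST components (allele-frequency form)
#'
#' ANOVA estimator on population allele frequencies for two populations
#' (r = 2): between-population mean square `MSP = sum n_i (p_i - pbar)^2 /
#' (r - 1)`, within-population mean square `MSG = sum n_i p_i (1 - p_i) /
#' sum (n_i - 1)`, and effective size `n_c = (sum n_i - sum n_i^2 / sum
#' n_i) / (r - 1)`.  Components are `num = MSP - MSG` and `den = MSP +
#' (n_c - 1) MSG`; theta is their windowed ratio.  This is the
#' allele-count form (no genotypic heterozygosity term), appropriate for
#' frequency data.
#'
#' @inheritParams hudson_site
#' @return list with vectors `num` and `den`.
#' @export
wc_site <- function(c1, t1, c2, t2, min_alleles = 4L) {
  usable <- t1 >= max(2L, min_alleles) & t2 >= max(2L, min_alleles)
  p1 <- c1 / t1
  p2 <- c2 / t2
  ntot <- t1 + t2
  pbar <- (c1 + c2) / ntot
  msp <- t1 * (p1 - pbar)^2 + t2 * (p2 - pbar)^2
  msg <- (t1 * p1 * (1 - p1) + t2 * p2 * (1 - p2)) / (ntot - 2)
  nc <- (ntot - (t1^2 + t2^2) / ntot)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  fixed_same <- pbar == 0 | pbar == 1
  num[fixed_same] <- 0
  den[fixed_same] <- 0
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  list(num = num, den = den)
}

#' Genomic window sets
#'
#' Builds half-open 0-based windows per contig: full windows start at
#' 0, slide, 2 slide, ... while `start <= length - size`; if the full
#' windows do not reach the contig end (as with non-overlapping tiling of a
#' length that is not a multiple of the window size, or `size > length`), a
#' terminal partial window is emitted and flagged.  `slide = size` gives the
#' non-overlapping scan mode.
#'
#' @param contig_lengths named vector of contig lengths (bp).
#' @param size window size (bp).
#' @param slide step between window starts (bp); defaults to `size`.
#' @return data.frame with `contig`, `start`, `end`, `partial`.
#' @export
make_windows <- function(contig_lengths, size, slide = size) {
  stopifnot(size >= 1, slide >= 1)
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- seq_along(contig_lengths)
  }
  out <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    starts <- if (len >= size) seq(0L, len - size, by = slide) else integer(0)
    w <- data.frame(contig = rep(ct, length(starts)), start = starts,
                    end = starts + size,
                    partial = rep(FALSE, length(starts)))
    covered <- if (nrow(w)) max(w$end) else 0L
    if (covered < len) {
      w <- rbind(w, data.frame(contig = ct, start = covered, end = len,
                               partial = TRUE))
    }
    w
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Map sites to windows; returns data.frame(site_idx, win_idx).  Handles
# overlapping (sliding) windows via IRanges.
site_window_hits <- function(contig, pos, windows) {
  hits <- lapply(unique(windows$contig), function(ct) {
    wi <- which(windows$contig == ct)
    si <- which(contig == ct)
    if (!length(wi) || !length(si)) return(NULL)
    ir_w <- IRanges::IRanges(start = windows$start[wi] + 1L, end = windows$end[wi])
    ir_s <- IRanges::IRanges(start = pos[si] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(ir_s, ir_w)
    data.frame(site_idx = si[S4Vectors::queryHits(ov)],
               win_idx = wi[S4Vectors::subjectHits(ov)])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(site_idx = integer(0), win_idx = integer(0)) else out
}

#' Windowed F_ST track
#'
#' Aggregates per-site F_ST components into windows.  Weighted mode is the
#' ratio of window-summed numerators to denominators ("ratio of averages");
#' unweighted mode is the mean of per-site ratios over sites with a positive
#' denominator.  Windows with fewer usable sites than `min_sites` are
#' emitted but flagged invalid.  Negative window values are retained in
#' `fst`; `fst_clamped` is floored at 0 for use as a branch-length input.
#'
#' @param counts output of [allele_counts()].
#' @param pop1,pop2 population names.
#' @param windows a [make_windows()] data.frame.
#' @param estimator `"hudson"` or `"wc"`.
#' @param mode `"weighted"` or `"unweighted"` (selects the `fst` column;
#'   both are always computed).
#' @param min_sites minimum usable sites per window.
#' @return `fst_track` data.frame: windows plus `n_sites`, `num_sum`,
#'   `den_sum`, `fst_weighted`, `fst_unweighted`, `fst`, `fst_clamped`,
#'   `valid`; attributes `estimator`, `mode`, `pops`.
#' @export
window_fst <- function(counts, pop1, pop2, windows,
                       estimator = c("hudson", "wc"),
                       mode = c("weighted", "unweighted"),
                       min_sites = 5L) {
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  stopifnot(pop1 %in% counts$populations, pop2 %in% counts$populations)
  site_fn <- if (estimator == "hudson") hudson_site else wc_site
  comp <- site_fn(counts$count[, pop1], counts$total[, pop1],
                  counts$count[, pop2], counts$total[, pop2])
  track <- aggregate_fst(comp$num, comp$den, counts$contig, counts$pos,
                         windows, min_sites)
  track$fst <- if (mode == "weighted") track$fst_weighted else track$fst_unweighted
  track$fst_clamped <- pmax(track$fst, 0)
  attr(track, "estimator") <- estimator
  attr(track, "mode") <- mode
  attr(track, "pops") <- c(pop1, pop2)
  class(track) <- c("fst_track", "data.frame")
  track
}

aggregate_fst <- function(num, den, contig, pos, windows, min_sites) {
  hits <- site_window_hits(contig, pos, windows)
  n_win <- nrow(windows)
  num_h <- num[hits$site_idx]
  den_h <- den[hits$site_idx]
  ok <- !is.na(den_h)
  pos_den <- ok & den_h > 0
  wfac <- factor(hits$win_idx, levels = seq_len(n_win))
  num_sum <- as.numeric(tapply(ifelse(ok, num_h, 0), wfac, sum, default = 0))
  den_sum <- as.numeric(tapply(ifelse(ok, den_h, 0), wfac, sum, default = 0))
  n_sites <- as.integer(tapply(pos_den, wfac, sum, default = 0))
  ratio <- ifelse(pos_den, num_h / den_h, NA_real_)
  unw <- as.numeric(tapply(ratio, wfac, mean, na.rm = TRUE, default = NA_real_))
  out <- windows
  out$n_sites <- n_sites
  out$num_sum <- num_sum
  out$den_sum <- den_sum
  out$fst_weighted <- ifelse(den_sum > 0, num_sum / den_sum, NA_real_)
  out$fst_unweighted <- ifelse(n_sites > 0, unw, NA_real_)
  out$valid <- n_sites >= min_sites
  out
}

#' Genome-wide F_ST summaries
#'
#' The genome-wide pair usually reported for a scan: the weighted value is
#' the ratio of genome-summed numerator to denominator; the unweighted value
#' is the mean of per-window (weighted) ratios over valid windows.
#'
#' @param track an `fst_track`.
#' @return named numeric vector `c(weighted, unweighted)`.
#' @export
genomewide_fst <- function(track) {
  v <- track$valid & !is.na(track$fst_weighted)
  c(weighted = sum(track$num_sum[v]) / sum(track$den_sum[v]),
    unweighted = mean(track$fst_weighted[v]))
}

#' Windowed nucleotide diversity
#'
#' Per site the unbiased heterozygosity `2 p (1 - p) n / (n - 1)` (the mean
#' pairwise difference at the site for `n` sampled alleles); window pi is
#' the site sum divided by the full window span in bp (all-sites
#' convention: invariant positions count in the denominator).
#'
#' @param counts output of [allele_counts()].
#' @param pop population name.
#' @param windows a [make_windows()] data.frame.
#' @return data.frame: windows plus `n_sites` (segregating sites used),
#'   `pi_sum` (summed per-site diversity) and `pi` (per bp).
#' @export
nucleotide_diversity <- function(counts, pop, windows) {
  stopifnot(pop %in% counts$populations)
  cnt <- counts$count[, pop]
  tot <- counts$total[, pop]
  usable <- tot >= 2
  p <- ifelse(usable, cnt / tot, NA_real_)
  site_pi <- ifelse(usable, 2 * p * (1 - p) * tot / (tot - 1), NA_real_)
  hits <- site_window_hits(counts$contig, counts$pos, windows)
  wfac <- factor(hits$win_idx, levels = seq_len(nrow(windows)))
  sp <- site_pi[hits$site_idx]
  seg <- !is.na(sp) & sp > 0
  out <- windows
  out$n_sites <- as.integer(tapply(seg, wfac, sum, default = 0))
  out$pi_sum <- as.numeric(tapply(ifelse(is.na(sp), 0, sp), wfac, sum, default = 0))
  out$pi <- out$pi_sum / (out$end - out$start)
  out
}

tajima_constants <- function(n) {
  # n = number of sampled alleles
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Classical standardized difference between the mean-pairwise-diversity and
#' segregating-sites estimators of theta:
#' `D = (pi_sum - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the usual
#' sample-size constants.  The allele number `n` per window is taken as the
#' most common called-allele total among its segregating sites (constant by
#' construction on complete-call data).  Windows with fewer than
#' `min_segsites` segregating sites, or with `n < 4`, are flagged undefined.
#'
#' @param counts output of [allele_counts()].
#' @param pop population name.
#' @param windows a [make_windows()] data.frame.
#' @param min_segsites minimum segregating sites per window (default 3).
#' @return data.frame: windows plus `S`, `pi_sum`, `n_alleles`, `tajimas_d`,
#'   `defined`.
#' @export
tajimas_d <- function(counts, pop, windows, min_segsites = 3L) {
  stopifnot(pop %in% counts$populations)
  cnt <- counts$count[, pop]
  tot <- counts$total[, pop]
  seg <- tot >= 2 & cnt > 0 & cnt < tot
  p <- ifelse(seg, cnt / tot, NA_real_)
  site_pi <- ifelse(seg, 2 * p * (1 - p) * tot / (tot - 1), 0)
  hits <- site_window_hits(counts$contig, counts$pos, windows)
  wfac <- factor(hits$win_idx, levels = seq_len(nrow(windows)))
  seg_h <- seg[hits$site_idx]
  out <- windows
  out$S <- as.integer(tapply(seg_h, wfac, sum, default = 0))
  out$pi_sum <- as.numeric(tapply(site_pi[hits$site_idx], wfac, sum, default = 0))
  mode_tot <- tapply(ifelse(seg_h, tot[hits$site_idx], NA), wfac, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    tx <- table(x)
    as.numeric(names(tx)[which.max(tx)])
  }, default = NA_real_)
  out$n_alleles <- as.numeric(mode_tot)
  d <- rep(NA_real_, nrow(out))
  ok <- out$S >= min_segsites & !is.na(out$n_alleles) & out$n_alleles >= 4
  for (i in which(ok)) {
    k <- tajima_constants(out$n_alleles[i])
    s <- out$S[i]
    d[i] <- (out$pi_sum[i] - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
  }
  out$tajimas_d <- d
  out$defined <- ok
  out
}
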