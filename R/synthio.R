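#' Simulation configuration for the three-population genome generator
#'
#' Builds and validates the configuration that drives the synthetic genome:
#' three populations (two focal woodland-like populations and one outgroup)
#' diverged from a shared ancestral allele-frequency pool by branch-specific
#' drift under the Balding-Nichols model, with an optional minority of
#' "planted" strongly divergent loci on one focal branch.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param n_snps total number of biallelic SNPs across the genome (planted
#'   loci are added on top if their positions are not already drawn).
#' @param ancestral_freq_law a list describing the law of the ancestral
#'   frequency p0: `list(kind = "uniform", min, max)` or
#'   `list(kind = "loguniform", min, max)` (density proportional to 1/p,
#'   mimicking a neutral site-frequency spectrum).
#' @param branch_drift named numeric vector mapping the three population
#'   names to their branch drift coefficient F in \[0, 1).
#' @param sample_sizes named integer vector of diploid sample sizes per
#'   population (same names as `branch_drift`).
#' @param planted_loci `NULL` or a data.frame with columns `contig` (1-based
#'   contig index), `pos` (0-based position), `focal_population` (name) and
#'   `f_sel` (drift coefficient of the selected locus on the focal branch,
#'   must exceed that population's background F).
#' @param gene_length,gene_spacing gene tiling parameters (bp) for the
#'   synthetic annotation.
#' @param n_go_terms number of GO terms in the synthetic gene-to-GO map.
#' @param planted_go_term identifier of the term that collects every gene
#'   overlapping a planted locus (plus decoys up to `go_set_size`).
#' @param go_set_size target member count of `planted_go_term`.
#' @param filter_fail_frac fraction of VCF records given INFO values that
#'   fail the QD/SOR/FS hard filter.
#' @param seed integer master seed; sub-streams use fixed documented offsets
#'   (frequencies +0, genotypes +1, INFO fields +2, annotation +3).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 2L,
                       contig_length = 1e6,
                       n_snps = 20000L,
                       ancestral_freq_law = list(kind = "uniform", min = 0.05, max = 0.95),
                       branch_drift = c(gamlingay = 0.01, waresley = 0.01, wales = 0.05),
                       sample_sizes = c(gamlingay = 40L, waresley = 40L, wales = 22L),
                       planted_loci = NULL,
                       gene_length = 1000L,
                       gene_spacing = 1000L,
                       n_go_terms = 40L,
                       planted_go_term = "GO:SYN0001",
                       go_set_size = 15L,
                       filter_fail_frac = 0.05,
                       seed = 1L) {
  stopifnot(n_contigs >= 1L, contig_length >= 1, n_snps >= 1L)
  if (!is.list(ancestral_freq_law) ||
      !ancestral_freq_law$kind %in% c("uniform", "loguniform")) {
    stop("ancestral_freq_law must be list(kind = 'uniform'|'loguniform', min, max)")
  }
  if (ancestral_freq_law$min <= 0 || ancestral_freq_law$max >= 1 ||
      ancestral_freq_law$min >= ancestral_freq_law$max) {
    stop("ancestral_freq_law bounds must satisfy 0 < min < max < 1")
  }
  pops <- names(branch_drift)
  if (length(pops) != 3L || is.null(pops) || anyDuplicated(pops)) {
    stop("branch_drift must name exactly three distinct populations")
  }
  if (any(branch_drift < 0) || any(branch_drift >= 1)) {
    stop("all branch drift coefficients must lie in [0, 1)")
  }
  if (!setequal(names(sample_sizes), pops)) {
    stop("sample_sizes must name the same populations as branch_drift")
  }
  if (any(sample_sizes < 2L)) stop("need at least 2 diploid samples per population")
  if (!is.null(planted_loci)) {
    planted_loci <- as.data.frame(planted_loci)
    stopifnot(all(c("contig", "pos", "focal_population", "f_sel") %in%
                    names(planted_loci)))
    if (any(planted_loci$contig < 1L) || any(planted_loci$contig > n_contigs) ||
        any(planted_loci$pos < 0) || any(planted_loci$pos >= contig_length)) {
      stop("planted loci must fall inside contig bounds")
    }
    if (!all(planted_loci$focal_population %in% pops)) {
      stop("planted focal_population must be one of the configured populations")
    }
    bg <- branch_drift[planted_loci$focal_population]
    if (any(planted_loci$f_sel <= bg)) {
      stop("planted f_sel must exceed the focal population's background F")
    }
    if (any(planted_loci$f_sel >= 1)) stop("f_sel must lie in [0, 1)")
  }
  if (gene_length + gene_spacing > contig_length) {
    stop("gene_length + gene_spacing must not exceed contig_length")
  }
  structure(list(
    n_contigs = as.integer(n_contigs), contig_length = as.integer(contig_length),
    n_snps = as.integer(n_snps), ancestral_freq_law = ancestral_freq_law,
    branch_drift = branch_drift, sample_sizes = sample_sizes,
    planted_loci = planted_loci, gene_length = as.integer(gene_length),
    gene_spacing = as.integer(gene_spacing), n_go_terms = as.integer(n_go_terms),
    planted_go_term = planted_go_term, go_set_size = as.integer(go_set_size),
    filter_fail_frac = filter_fail_frac, seed = as.integer(seed)
  ), class = "sim_config")
}

draw_ancestral <- function(law, n) {
  if (law$kind == "uniform") {
    stats::runif(n, law$min, law$max)
  } else {
    # density proportional to 1/p on (min, max): log-uniform
    exp(stats::runif(n, log(law$min), log(law$max)))
  }
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-SNP ancestral frequencies p0 and, for each population with drift
#' coefficient F, a derived frequency from
#' Beta(p0 (1 - F) / F, (1 - p0) (1 - F) / F), so that E\[p\] = p0 and
#' Var(p) = F p0 (1 - p0).  A branch with F = 0 copies p0 unchanged (the
#' zero-drift limit of the law; no division by zero is attempted).  Planted
#' loci are drawn with their `f_sel` on the focal branch only.
#'
#' @param config a [sim_config()].
#' @return a data.frame (one row per SNP, sorted by contig then position)
#'   with columns `contig`, `pos` (0-based), `p0`, `planted`, and one derived
#'   frequency column per population.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 0L)
  per_contig <- table(factor(sample.int(config$n_contigs, config$n_snps, replace = TRUE),
                             levels = seq_len(config$n_contigs)))
  rows <- lapply(seq_len(config$n_contigs), function(ct) {
    n_ct <- as.integer(per_contig[[ct]])
    pos <- sort(sample.int(config$contig_length, n_ct, replace = FALSE)) - 1L
    data.frame(contig = ct, pos = pos)
  })
  tab <- do.call(rbind, rows)
  tab$planted <- FALSE
  if (!is.null(config$planted_loci)) {
    pl <- config$planted_loci
    key <- paste(tab$contig, tab$pos)
    pkey <- paste(pl$contig, pl$pos)
    hit <- match(pkey, key)
    new <- which(is.na(hit))
    if (length(new)) {
      add <- data.frame(contig = pl$contig[new], pos = pl$pos[new], planted = TRUE)
      tab <- rbind(tab, add)
      tab <- tab[order(tab$contig, tab$pos), , drop = FALSE]
    }
    key <- paste(tab$contig, tab$pos)
    tab$planted[match(pkey, key)] <- TRUE
  }
  rownames(tab) <- NULL
  n <- nrow(tab)
  tab$p0 <- draw_ancestral(config$ancestral_freq_law, n)
  for (pop in names(config$branch_drift)) {
    f <- rep(config$branch_drift[[pop]], n)
    if (!is.null(config$planted_loci)) {
      pl <- config$planted_loci
      sel <- pl[pl$focal_population == pop, , drop = FALSE]
      if (nrow(sel)) {
        idx <- match(paste(sel$contig, sel$pos), paste(tab$contig, tab$pos))
        f[idx] <- sel$f_sel
      }
    }
    p <- tab$p0
    drift <- f > 0
    if (any(drift)) {
      a <- p[drift] * (1 - f[drift]) / f[drift]
      b <- (1 - p[drift]) * (1 - f[drift]) / f[drift]
      p[drift] <- stats::rbeta(sum(drift), a, b)
    }
    tab[[pop]] <- p
  }
  tab
}

#' Diploid genotypes from population allele frequencies
#'
#' Each sample's genotype at each SNP is an independent Binomial(2, p) draw
#' from its population's frequency (hard calls; sites are unlinked).
#'
#' @param freqs output of [simulate_frequencies()].
#' @param config the [sim_config()] used to generate `freqs`.
#' @return a `genotype_matrix`: list with `geno` (SNP x sample integer matrix
#'   of alt-allele dosages), `contig`, `pos` (0-based), and `pop_map` (named
#'   character vector sample -> population).
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pops <- names(config$sample_sizes)
  n_snp <- nrow(freqs)
  mats <- lapply(pops, function(pop) {
    ns <- config$sample_sizes[[pop]]
    matrix(stats::rbinom(n_snp * ns, 2L, rep(freqs[[pop]], times = ns)),
           nrow = n_snp, ncol = ns)
  })
  geno <- do.call(cbind, mats)
  samples <- unlist(lapply(pops, function(pop) {
    sprintf("%s_%02d", pop, seq_len(config$sample_sizes[[pop]]))
  }))
  colnames(geno) <- samples
  pop_map <- rep(pops, times = config$sample_sizes[pops])
  names(pop_map) <- samples
  genotype_matrix(geno, freqs$contig, freqs$pos, pop_map)
}

#' Synthetic INFO annotations for hard-filter testing
#'
#' Draws QD, SOR and FS values for each record so that a configurable
#' fraction fails exactly one of the GATK-style criteria
#' (QD < 2.0, SOR > 3.0, FS > 200); the rest pass all three comfortably.
#'
#' @param n_records number of records.
#' @param config a [sim_config()] (uses `filter_fail_frac` and seed offset +2).
#' @return data.frame with columns `QD`, `SOR`, `FS`.
#' @export
simulate_info <- function(n_records, config) {
  set.seed(config$seed + 2L)
  qd <- stats::runif(n_records, 5, 30)
  sor <- stats::runif(n_records, 0.3, 2.5)
  fs <- stats::runif(n_records, 0, 30)
  n_fail <- round(config$filter_fail_frac * n_records)
  if (n_fail > 0) {
    fail_idx <- sample.int(n_records, n_fail)
    which_crit <- sample.int(3L, n_fail, replace = TRUE)
    qd[fail_idx[which_crit == 1L]] <- stats::runif(sum(which_crit == 1L), 0, 1.99)
    sor[fail_idx[which_crit == 2L]] <- stats::runif(sum(which_crit == 2L), 3.01, 8)
    fs[fail_idx[which_crit == 3L]] <- stats::runif(sum(which_crit == 3L), 200.1, 400)
  }
  data.frame(QD = qd, SOR = sor, FS = fs)
}

#' Synthetic gene annotation and gene-to-GO map
#'
#' Tiles genes of fixed length at fixed spacing along every contig (1-based
#' inclusive GFF3 convention; internally converted to 0-based half-open by
#' the readers).  Every gene receives at least one GO term.  The designated
#' `planted_go_term` contains every gene that overlaps a planted locus, plus
#' randomly chosen decoy genes up to `go_set_size` members.
#'
#' @param config a [sim_config()] (seed offset +3).
#' @return list with `genes` (data.frame `gene_id`, `contig`, `start`, `end`,
#'   0-based half-open) and `gene_go` (data.frame `gene_id`, `go_id`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  period <- config$gene_length + config$gene_spacing
  starts0 <- seq(0L, config$contig_length - config$gene_length, by = period)
  genes <- do.call(rbind, lapply(seq_len(config$n_contigs), function(ct) {
    data.frame(
      gene_id = sprintf("gene_c%02d_%04d", ct, seq_along(starts0)),
      contig = ct, start = starts0, end = starts0 + config$gene_length
    )
  }))
  rownames(genes) <- NULL

  terms <- sprintf("GO:SYN%04d", seq_len(config$n_go_terms))
  if (!config$planted_go_term %in% terms) {
    terms <- c(config$planted_go_term, terms[-1L])
  }
  other <- setdiff(terms, config$planted_go_term)
  n_terms_per_gene <- sample(1:3, nrow(genes), replace = TRUE)
  gene_go <- data.frame(
    gene_id = rep(genes$gene_id, n_terms_per_gene),
    go_id = unlist(lapply(n_terms_per_gene, function(k) sample(other, k)))
  )

  planted_genes <- character(0)
  if (!is.null(config$planted_loci)) {
    pl <- config$planted_loci
    hit <- vapply(seq_len(nrow(pl)), function(i) {
      g <- genes[genes$contig == pl$contig[i] &
                   genes$start <= pl$pos[i] & pl$pos[i] < genes$end, , drop = FALSE]
      if (nrow(g) == 0L) {
        stop("planted locus at contig ", pl$contig[i], " pos ", pl$pos[i],
             " does not overlap any gene")
      }
      g$gene_id[1L]
    }, character(1))
    planted_genes <- unique(hit)
  }
  n_decoy <- max(0L, config$go_set_size - length(planted_genes))
  decoys <- sample(setdiff(genes$gene_id, planted_genes), n_decoy)
  members <- c(planted_genes, decoys)
  gene_go <- rbind(gene_go,
                   data.frame(gene_id = members,
                              go_id = config$planted_go_term))
  gene_go <- gene_go[order(gene_go$gene_id, gene_go$go_id), , drop = FALSE]
  gene_go <- unique(gene_go)
  rownames(gene_go) <- NULL
  list(genes = genes, gene_go = gene_go)
}

#' Split-brood dyad phenotypes
#'
#' Simulates paired sibling breeding records: each dyad has one arm bred on a
#' small carcass and one on a large carcass.  Clutch size is Poisson with
#' mean `base_clutch + carcass_effect * 1[large] + elevation_offset *
#' 1[population == derived]`, mirroring a reaction norm whose elevation (not
#' slope) differs between populations.  Brood size at dispersal is the clutch
#' minus binomial losses; when `culling_on_small` is set, the derived
#' population loses an extra culling fraction of offspring on small carcasses
#' only.  Egg length is normal; egg width shrinks mildly as the clutch grows
#' (an egg size / egg number trade-off).
#'
#' @param n_dyads_per_population dyads per population.
#' @param elevation_offset added mean clutch (eggs) for the derived population.
#' @param culling_on_small if `TRUE`, apply extra offspring loss to the
#'   derived population's small-carcass arms.
#' @param seed integer seed.
#' @param populations two population labels (ancestral first).
#' @param derived which population carries the elevation offset.
#' @param base_clutch mean small-carcass clutch in the ancestral population.
#' @param carcass_effect added mean clutch on a large carcass (reaction-norm
#'   slope, shared by both populations).
#' @param base_loss_rate baseline per-offspring loss probability.
#' @param cull_rate extra per-offspring loss for derived-population broods on
#'   small carcasses when `culling_on_small` is set.
#' @param measurable_rate probability an egg is fully visible and measurable.
#' @return data.frame, one row per dyad arm, with list columns `egg_l` and
#'   `egg_w` (mm, measurable eggs only).
#' @export
simulate_broods <- function(n_dyads_per_population = 50L,
                            elevation_offset = 5,
                            culling_on_small = FALSE,
                            seed = 1L,
                            populations = c("gamlingay", "waresley"),
                            derived = "waresley",
                            base_clutch = 15,
                            carcass_effect = 5,
                            base_loss_rate = 0.1,
                            cull_rate = 0.25,
                            measurable_rate = 0.65) {
  stopifnot(length(populations) == 2L, derived %in% populations)
  if (base_clutch + min(0, elevation_offset) < 0 ||
      base_clutch + carcass_effect + min(0, elevation_offset) < 0) {
    stop("clutch-size means must be non-negative")
  }
  set.seed(seed)
  arms <- expand.grid(dyad = seq_len(n_dyads_per_population),
                      population = populations,
                      carcass = c("small", "large"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  arms <- arms[order(arms$population, arms$dyad, arms$carcass), , drop = FALSE]
  arms$dyad_id <- sprintf("%s_d%03d", arms$population, arms$dyad)
  arms$block <- 1L + (arms$dyad %% 2L)
  n <- nrow(arms)
  large <- arms$carcass == "large"
  is_derived <- arms$population == derived
  arms$carcass_mass <- ifelse(large, stats::runif(n, 26, 31), stats::runif(n, 12, 17))
  mu <- base_clutch + carcass_effect * large + elevation_offset * is_derived
  arms$clutch_size <- stats::rpois(n, mu)
  loss <- stats::rbinom(n, arms$clutch_size, base_loss_rate)
  brood <- arms$clutch_size - loss
  if (culling_on_small) {
    cull_arm <- is_derived & !large
    extra <- stats::rbinom(n, brood, cull_rate * cull_arm)
    brood <- brood - extra
  }
  arms$brood_size <- brood
  larval_mass <- stats::rnorm(n, ifelse(large, 0.21, 0.18), 0.02)
  larval_mass <- pmax(larval_mass, 0.05)
  arms$total_brood_mass <- round(brood * larval_mass, 3)
  arms$n_eggs_measurable <- stats::rbinom(n, arms$clutch_size, measurable_rate)
  egg <- lapply(seq_len(n), function(i) {
    k <- arms$n_eggs_measurable[i]
    l <- stats::rnorm(k, 1.9, 0.08)
    w_mu <- 0.85 - 0.002 * (arms$clutch_size[i] - base_clutch)
    w <- stats::rnorm(k, w_mu, 0.05)
    w <- pmax(pmin(w, l), 0.01)
    list(l = pmax(l, 0.02), w = w)
  })
  arms$egg_l <- I(lapply(egg, `[[`, "l"))
  arms$egg_w <- I(lapply(egg, `[[`, "w"))
  arms$dyad <- NULL
  rownames(arms) <- NULL
  arms[, c("dyad_id", "population", "block", "carcass", "carcass_mass",
           "clutch_size", "brood_size", "total_brood_mass",
           "n_eggs_measurable", "egg_l", "egg_w")]
}
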