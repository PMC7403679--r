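#' Subset a genotype matrix by SNP
#'
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over SNPs.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, keep) {
  genotype_matrix(gm$geno[keep, , drop = FALSE], gm$contig[keep],
                  gm$pos[keep], gm$pop_map)
}

#' End-to-end pipeline configuration
#'
#' Bundles the synthetic-genome configuration (or input file paths), the
#' population roles, window/estimator settings and enrichment parameters.
#'
#' @param sim a [sim_config()] (synthetic mode), or `NULL` when `vcf`,
#'   `pop_map_file`, `gff`, `gene_go_file` point at existing inputs.
#' @param vcf,pop_map_file,gff,gene_go_file input paths (file mode).
#' @param focal1,focal2,outgroup population role assignment (exactly three
#'   distinct populations).
#' @param scan_size non-overlapping scan window size (bp, default 2000).
#' @param sliding_size,slide sliding-window size and step for gene scoring
#'   (bp, defaults 500 / 100).
#' @param estimator `"hudson"` or `"wc"`.
#' @param mode `"weighted"` or `"unweighted"` window F_ST.
#' @param min_sites_scan,min_sites_sliding per-window usable-site minima.
#' @param outlier_threshold PBS outlier threshold (default 0.05).
#' @param gsea_n_perm,gsea_min_size,gsea_max_size,gsea_weight GSEA settings.
#' @param out_dir artifact directory (created if needed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            vcf = NULL, pop_map_file = NULL, gff = NULL,
                            gene_go_file = NULL,
                            focal1 = "gamlingay", focal2 = "waresley",
                            outgroup = "wales",
                            scan_size = 2000L, sliding_size = 500L, slide = 100L,
                            estimator = "hudson", mode = "weighted",
                            min_sites_scan = 5L, min_sites_sliding = 2L,
                            outlier_threshold = 0.05,
                            gsea_n_perm = 1000L, gsea_min_size = 10L,
                            gsea_max_size = 500L, gsea_weight = 1,
                            out_dir = tempfile("nichescan_run_")) {
  roles <- c(focal1, focal2, outgroup)
  if (anyDuplicated(roles)) stop("focal1, focal2, outgroup must be distinct")
  if (is.null(sim) && (is.null(vcf) || is.null(pop_map_file) || is.null(gff) ||
                       is.null(gene_go_file))) {
    stop("either a sim_config or all four input paths are required")
  }
  if (!is.null(sim) && !setequal(roles, names(sim$branch_drift))) {
    stop("roles must name the three simulated populations")
  }
  stopifnot(scan_size > 0, sliding_size > 0, slide > 0, outlier_threshold > 0)
  structure(list(sim = sim, vcf = vcf, pop_map_file = pop_map_file, gff = gff,
                 gene_go_file = gene_go_file,
                 focal1 = focal1, focal2 = focal2, outgroup = outgroup,
                 scan_size = as.integer(scan_size),
                 sliding_size = as.integer(sliding_size),
                 slide = as.integer(slide),
                 estimator = estimator, mode = mode,
                 min_sites_scan = as.integer(min_sites_scan),
                 min_sites_sliding = as.integer(min_sites_sliding),
                 outlier_threshold = outlier_threshold,
                 gsea_n_perm = as.integer(gsea_n_perm),
                 gsea_min_size = as.integer(gsea_min_size),
                 gsea_max_size = as.integer(gsea_max_size),
                 gsea_weight = gsea_weight,
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the divergence-polarisation pipeline
#'
#' Executes the stages in dependency order: simulate (or load) genotypes and
#' annotation; hard-filter records; allele counts; pairwise windowed F_ST on
#' the non-overlapping scan windows (three pairs); PBS scan, zF_ST of the
#' focal pair, and outlier flagging; nucleotide diversity and Tajima's D per
#' focal population; sliding-window F_ST/PBS; per-gene scores, rankings and
#' GSEA for each branch.  All artifacts are written as TSV/VCF/GFF3 under
#' `config$out_dir` together with a manifest recording the config hash and
#' seed; a re-run with an identical config reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory stage results and the artifact
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[nichescan] ", ...)
  art <- list()
  path <- function(f) file.path(config$out_dir, f)
  hash <- config_hash(config)
  meta <- c(config_hash = hash)

  if (!is.null(config$sim)) {
    say("stage simulate: ", config$sim$n_snps, " SNPs, ",
        config$sim$n_contigs, " contig(s)")
    freqs <- simulate_frequencies(config$sim)
    gm <- simulate_genotypes(freqs, config$sim)
    info <- simulate_info(nrow(freqs), config$sim)
    ann <- generate_annotation(config$sim)
    write_vcf(gm, info, art$vcf <- path("genotypes.vcf"))
    write_population_map(gm$pop_map, art$pop_map <- path("population_map.tsv"))
    write_gff3(ann$genes, art$gff <- path("genes.gff3"))
    write_gene_go(ann$gene_go, art$gene_go <- path("gene_go.tsv"))
    genes <- ann$genes
    genes$contig <- paste0("contig", genes$contig)
    collection <- split(ann$gene_go$gene_id, ann$gene_go$go_id)
    gm$contig <- paste0("contig", gm$contig)
    contig_lengths <- stats::setNames(
      rep(config$sim$contig_length, config$sim$n_contigs),
      paste0("contig", seq_len(config$sim$n_contigs)))
  } else {
    say("stage load: ", config$vcf)
    pop_map <- read_population_map(config$pop_map_file)
    loaded <- read_vcf(config$vcf, pop_map)
    gm <- loaded$gm
    info <- loaded$info
    genes <- read_gff_genes(config$gff)
    collection <- read_gene_go(config$gene_go_file)
    contig_lengths <- tapply(gm$pos, gm$contig, max) + 1L
  }

  flt <- hard_filter(info)
  say("stage filter: removed ", flt$report$n_removed, " of ",
      flt$report$n_records, " records")
  utils::write.table(flt$report, art$filter_report <- path("filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- subset_genotypes(gm, flt$keep)
  counts <- allele_counts(gm)

  pair_tracks <- function(windows, min_sites) {
    pairs <- list(c(config$focal1, config$focal2),
                  c(config$focal1, config$outgroup),
                  c(config$focal2, config$outgroup))
    lapply(pairs, function(pr) {
      window_fst(counts, pr[1], pr[2], windows, estimator = config$estimator,
                 mode = config$mode, min_sites = min_sites)
    })
  }

  say("stage fst: ", config$scan_size, "-bp scan windows")
  scan_windows <- make_windows(contig_lengths, config$scan_size)
  scan_fst <- pair_tracks(scan_windows, config$min_sites_scan)
  for (i in seq_along(scan_fst)) {
    pr <- attr(scan_fst[[i]], "pops")
    f <- sprintf("fst_scan_%s_vs_%s.tsv", pr[1], pr[2])
    write_track(scan_fst[[i]], art[[paste0("fst_scan_", i)]] <- path(f), meta)
  }

  say("stage pbs: scan windows")
  pbs_track <- pbs_scan(scan_fst[[1]], scan_fst[[2]], scan_fst[[3]])
  write_track(pbs_track, art$pbs_scan <- path("pbs_scan.tsv"), meta)
  z <- zfst(scan_fst[[1]])
  write_track(z, art$zfst <- path("zfst_focal_pair.tsv"), meta)
  outliers <- flag_outliers(pbs_track, config$outlier_threshold)
  write_track(outliers, art$outliers <- path("pbs_outliers.tsv"), meta)

  say("stage diversity: pi and Tajima's D")
  div <- lapply(c(config$focal1, config$focal2), function(pop) {
    pi_t <- nucleotide_diversity(counts, pop, scan_windows)
    td <- tajimas_d(counts, pop, scan_windows)
    pi_t$tajimas_d <- td$tajimas_d
    pi_t$S <- td$S
    pi_t$defined <- td$defined
    write_track(pi_t, path(sprintf("diversity_%s.tsv", pop)), meta)
    pi_t
  })
  names(div) <- c(config$focal1, config$focal2)
  art$diversity <- path(sprintf("diversity_%s.tsv",
                                c(config$focal1, config$focal2)))

  say("stage gene scores: ", config$sliding_size, "/", config$slide,
      " sliding windows")
  slide_windows <- make_windows(contig_lengths, config$sliding_size,
                                config$slide)
  slide_fst <- pair_tracks(slide_windows, config$min_sites_sliding)
  pbs_slide <- pbs_scan(slide_fst[[1]], slide_fst[[2]], slide_fst[[3]])
  write_track(pbs_slide, art$pbs_sliding <- path("pbs_sliding.tsv"), meta)

  branches <- stats::setNames(1:3, c(config$focal1, config$focal2,
                                     config$outgroup))
  gsea_res <- list()
  ranked_all <- list()
  for (pop in names(branches)) {
    scores <- score_genes(pbs_slide, genes, branch = branches[[pop]])
    write_track(scores, path(sprintf("gene_scores_%s.tsv", pop)), meta)
    ranked <- rank_genes(scores)
    write_track(ranked, path(sprintf("gene_ranking_%s.tsv", pop)), meta)
    ranked_all[[pop]] <- ranked
    say("stage gsea: branch ", pop, " (", nrow(ranked), " ranked genes)")
    gsea_res[[pop]] <- gsea(ranked, collection, n_perm = config$gsea_n_perm,
                            seed = if (!is.null(config$sim))
                              config$sim$seed + 10L else 1L,
                            min_size = config$gsea_min_size,
                            max_size = config$gsea_max_size,
                            p = config$gsea_weight)
    write_track(gsea_res[[pop]], path(sprintf("gsea_%s.tsv", pop)), meta)
  }
  art$gene_scores <- path(sprintf("gene_scores_%s.tsv", names(branches)))
  art$gsea <- path(sprintf("gsea_%s.tsv", names(branches)))

  manifest <- data.frame(
    key = c("config_hash", "seed", "estimator", "mode", "scan_size",
            "sliding_size", "slide", "artifacts"),
    value = c(hash,
              if (!is.null(config$sim)) config$sim$seed else NA,
              config$estimator, config$mode, config$scan_size,
              config$sliding_size, config$slide,
              paste(sort(basename(unlist(art))), collapse = ","))
  )
  utils::write.table(manifest, path("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  art$manifest <- path("manifest.tsv")
  say("done: ", length(unlist(art)), " artifacts in ", config$out_dir)

  invisible(list(
    config = config, manifest = manifest, artifacts = art,
    filter_report = flt$report, counts = counts,
    scan_fst = scan_fst, pbs_scan = pbs_track, zfst = z, outliers = outliers,
    diversity = div, pbs_sliding = pbs_slide, rankings = ranked_all,
    gsea = gsea_res
  ))
}
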