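#' Write a genotype matrix as VCF v4.2
#'
#' Sorted biallelic records with GT fields and QD/SOR/FS INFO annotations.
#' Internal 0-based positions become 1-based VCF POS on output.
#'
#' @param gm a [genotype_matrix()].
#' @param info data.frame with `QD`, `SOR`, `FS` (one row per SNP), e.g.
#'   from [simulate_info()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, info, path) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(info) == nrow(gm$geno))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=nichescan",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant call quality by depth">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Strand odds ratio">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled Fisher strand p">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gm$geno)), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[gm$geno[ok] + 1L]
  info_str <- sprintf("QD=%.2f;SOR=%.3f;FS=%.3f", info$QD, info$SOR, info$FS)
  lines <- paste(
    paste0("contig", gm$contig), gm$pos + 1L, ".", "A", "T", ".", "PASS",
    info_str, "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read a biallelic VCF into a genotype matrix
#'
#' Parses with `vcfR`; multi-allelic records are skipped (and counted in a
#' warning); VCF 1-based POS becomes the internal 0-based position.
#' Malformed or absent QD/SOR/FS annotations become `NA` (the hard filter's
#' missing-value policy decides their fate).
#'
#' @param path VCF file.
#' @param pop_map named character vector sample -> population (e.g. from
#'   [read_population_map()]).
#' @return list with `gm` (a [genotype_matrix()]) and `info` (data.frame
#'   `QD`, `SOR`, `FS`).
#' @export
read_vcf <- function(path, pop_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  bi <- !grepl(",", alt) & !is.na(alt)
  if (any(!bi)) {
    warning(sum(!bi), " multi-allelic record(s) skipped")
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  contig <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v) - 1L
  num_info <- function(key) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    x
  }
  info <- data.frame(QD = num_info("QD"), SOR = num_info("SOR"),
                     FS = num_info("FS"))
  list(gm = genotype_matrix(dose, contig, pos, pop_map[colnames(dose)]),
       info = info)
}

#' Write / read a sample-to-population map
#'
#' Two-column TSV (`sample`, `population`).
#'
#' @param pop_map named character vector sample -> population.
#' @param path file path.
#' @return `write_population_map`: the path, invisibly.
#' @export
write_population_map <- function(pop_map, path) {
  utils::write.table(
    data.frame(sample = names(pop_map), population = unname(pop_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_map
#' @return `read_population_map`: named character vector.
#' @export
read_population_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$population, tab$sample)
}

#' Write genes as GFF3
#'
#' Internal 0-based half-open gene intervals become 1-based inclusive GFF3
#' records of type `gene`.
#'
#' @param genes data.frame `gene_id`, `contig`, `start`, `end`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(
    paste0("contig", genes$contig), "nichescan", "gene",
    genes$start + 1L, genes$end, ".", "+", ".",
    paste0("ID=", genes$gene_id),
    sep = "\t"
  ), con)
  invisible(path)
}

#' Read gene records from GFF3
#'
#' Uses `rtracklayer` when available (the robust path), otherwise a plain
#' 9-column read.  1-based inclusive GFF3 coordinates become 0-based
#' half-open intervals.
#'
#' @param path GFF3 file.
#' @return data.frame `gene_id`, `contig`, `start`, `end` (0-based
#'   half-open; `contig` keeps the file's seqid string).
#' @export
read_gff_genes <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr[gr$type == "gene"])
    data.frame(gene_id = df$ID,
               contig = as.character(df$seqnames),
               start = df$start - 1L, end = df$end,
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    tab <- tab[tab[[3]] == "gene", , drop = FALSE]
    data.frame(gene_id = sub("^.*ID=([^;]+).*$", "\\1", tab[[9]]),
               contig = tab[[1]], start = tab[[4]] - 1L, end = tab[[5]],
               stringsAsFactors = FALSE)
  }
}

#' Write / read a gene-to-GO two-column TSV
#'
#' @param gene_go data.frame `gene_id`, `go_id`.
#' @param path file path.
#' @return `write_gene_go`: the path, invisibly; `read_gene_go`: a named
#'   list GO term -> character vector of gene IDs.
#' @export
write_gene_go <- function(gene_go, path) {
  utils::write.table(gene_go[, c("gene_id", "go_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_go
#' @export
read_gene_go <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(tab$gene_id, tab$go_id)
}

#' Write / read a BED-like per-window track TSV
#'
#' Tab-separated with `# key=value` comment header lines carrying
#' provenance; round-trips losslessly through [read_track()].
#'
#' @param track a window track data.frame.
#' @param path file path.
#' @param meta named character vector written as `# key=value` comments.
#' @return `write_track`: the path, invisibly.
#' @export
write_track <- function(track, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  }
  df <- as.data.frame(track)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE,
                            nsmall = 0),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @return `read_track`: data.frame with attribute `meta`.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^# ", lines)
  meta <- sub("^# ", "", lines[is_meta])
  tab <- utils::read.delim(text = lines[!is_meta], stringsAsFactors = FALSE)
  attr(tab, "meta") <- meta
  tab
}

#' Write / read brood-dyad tables
#'
#' One row per dyad arm; per-egg length/width lists are serialised as
#' comma-joined millimetre values.
#'
#' @param broods data.frame from [simulate_broods()].
#' @param path file path.
#' @return `write_broods`: the path, invisibly; `read_broods`: the table
#'   with `egg_l`/`egg_w` restored as list columns.
#' @export
write_broods <- function(broods, path) {
  flat <- broods
  flat$egg_l <- vapply(broods$egg_l, function(x) paste(sprintf("%.4f", x),
                                                       collapse = ","), "")
  flat$egg_w <- vapply(broods$egg_w, function(x) paste(sprintf("%.4f", x),
                                                       collapse = ","), "")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_broods
#' @export
read_broods <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parse_num <- function(s) {
    lapply(strsplit(ifelse(is.na(s), "", s), ","), function(x) {
      as.numeric(x[nzchar(x)])
    })
  }
  tab$egg_l <- I(parse_num(tab$egg_l))
  tab$egg_w <- I(parse_num(tab$egg_w))
  tab
}
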