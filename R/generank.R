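#' Per-gene divergence scores from a sliding PBS track
#'
#' Assigns each gene the maximum PBS among valid sliding windows that
#' overlap its body by at least 1 bp (half-open interval intersection).
#' Genes with no valid overlapping window are flagged unscored (NA).
#'
#' @param track a sliding-window `pbs_track`.
#' @param genes data.frame with `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open).
#' @param branch branch column to score (1, 2 or 3).
#' @return `gene_score_table` data.frame: `gene_id`, `contig`, `start`,
#'   `end`, `score`, `n_windows`, `scored`.
#' @export
score_genes <- function(track, genes, branch = 1L) {
  col <- paste0("pbs", branch)
  stopifnot(col %in% names(track))
  known <- genes$contig %in% unique(track$contig)
  if (any(!known)) {
    warning(sum(!known), " gene(s) on contigs absent from the track are unscored")
  }
  tv <- track[track$valid & !is.na(track[[col]]), , drop = FALSE]
  score <- rep(NA_real_, nrow(genes))
  n_win <- integer(nrow(genes))
  for (ct in unique(genes$contig[known])) {
    gi <- which(genes$contig == ct)
    wi <- which(tv$contig == ct)
    if (!length(wi)) next
    ir_g <- IRanges::IRanges(start = genes$start[gi] + 1L, end = genes$end[gi])
    ir_w <- IRanges::IRanges(start = tv$start[wi] + 1L, end = tv$end[wi])
    ov <- IRanges::findOverlaps(ir_g, ir_w)
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov)
    vals <- tv[[col]][wi[S4Vectors::subjectHits(ov)]]
    mx <- tapply(vals, q, max)
    nn <- tapply(vals, q, length)
    idx <- gi[as.integer(names(mx))]
    score[idx] <- as.numeric(mx)
    n_win[idx] <- as.integer(nn)
  }
  out <- data.frame(gene_id = genes$gene_id, contig = genes$contig,
                    start = genes$start, end = genes$end,
                    score = score, n_windows = n_win,
                    scored = !is.na(score))
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Rank genes from most to least diverged
#'
#' Descending by score with a stable lexicographic tie-break on gene ID;
#' unscored genes are excluded (their count is kept as an attribute).
#'
#' @param table a `gene_score_table`.
#' @return data.frame `gene_id`, `score` in rank order; attribute
#'   `n_unscored`.
#' @export
rank_genes <- function(table) {
  scored <- table[table$scored, , drop = FALSE]
  ord <- order(-scored$score, scored$gene_id, method = "radix")
  out <- data.frame(gene_id = scored$gene_id[ord], score = scored$score[ord])
  rownames(out) <- NULL
  attr(out, "n_unscored") <- sum(!table$scored)
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running statistic over a ranked list: at each in-set gene
#' the sum increases by `|score|^p` normalised by the in-set `|score|^p`
#' total; at each out-of-set gene it decreases by `1 / (N - n_set)`.  ES is
#' the running sum's maximum signed deviation from zero; the leading edge is
#' the set members at or before the extremum (after it for negative ES).
#'
#' @param ranked data.frame `gene_id`, `score`, already in rank order (see
#'   [rank_genes()]).
#' @param gene_set character vector of gene IDs.
#' @param p weight exponent on `|score|` (0 = unweighted KS; default 1).
#' @return list with `es`, `running` (vector, one entry per ranked gene)
#'   and `leading_edge` (character vector of gene IDs).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  hit <- ranked$gene_id %in% gene_set
  n <- nrow(ranked)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene_set has empty intersection with the ranked list")
  if (n_hit == n) stop("gene_set covers the whole ranked list; misses undefined")
  w <- abs(ranked$score)^p
  nr <- sum(w[hit])
  inc <- numeric(n)
  if (nr > 0) {
    inc[hit] <- w[hit] / nr
  } else {
    inc[hit] <- 1 / n_hit # all-zero scores: fall back to unweighted steps
  }
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  i_star <- which.max(abs(running))
  es <- running[i_star]
  leading <- if (es >= 0) {
    ranked$gene_id[seq_len(i_star)][hit[seq_len(i_star)]]
  } else {
    idx <- seq(i_star + 1L, n)
    ranked$gene_id[idx][hit[idx]]
  }
  list(es = es, running = running, leading_edge = leading)
}

# Null ES values for a given set size under gene-label permutation.
# Permuting gene labels with scores fixed is equivalent to drawing a random
# set of the same size from the ranked list, so the null depends on the set
# size only and can be shared across same-size terms.
null_es <- function(ranked, size, n_perm, p = 1) {
  n <- nrow(ranked)
  w <- abs(ranked$score)^p
  vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, size)
    hit <- logical(n)
    hit[idx] <- TRUE
    nr <- sum(w[hit])
    inc <- numeric(n)
    if (nr > 0) inc[hit] <- w[hit] / nr else inc[hit] <- 1 / size
    inc[!hit] <- -1 / (n - size)
    running <- cumsum(inc)
    running[which.max(abs(running))]
  }, numeric(1))
}

#' Ranked gene-set enrichment analysis
#'
#' Cutoff-free enrichment of gene sets in a ranked list, with a gene-label
#' permutation null.  For each term: ES from [enrichment_score()];
#' NES = ES / mean(|null ES| of the same sign); nominal p = fraction of
#' same-sign null ES at least as extreme; FDR q by the sign-stratified
#' NES-comparison procedure (ratio of the null and observed tail fractions
#' at the term's NES, clipped to \[0, 1\]).  Because permuting gene labels
#' with a fixed ranking only randomises set membership, null distributions
#' are computed once per distinct set size and shared.
#'
#' @param ranked data.frame `gene_id`, `score` in rank order.
#' @param collection named list of character vectors (term -> gene IDs).
#' @param n_perm permutations per set size (default 1000; < 100 warns).
#' @param seed integer seed (one draw stream for the whole call).
#' @param min_size,max_size set-size bounds after intersecting with the
#'   ranked list; out-of-bounds terms are skipped and reported.
#' @param p weight exponent (default 1).
#' @param term_names optional named character vector term -> display name.
#' @return `gsea_result` data.frame: `go_id`, `go_name`, `size`, `es`,
#'   `nes`, `p_nominal`, `q_fdr`, ordered by decreasing NES; attribute
#'   `skipped` lists out-of-bounds terms.
#' @export
gsea <- function(ranked, collection, n_perm = 1000L, seed = 1L,
                 min_size = 10L, max_size = 500L, p = 1,
                 term_names = NULL) {
  if (n_perm < 100L) warning("n_perm < 100 gives unstable NES/FDR estimates")
  set.seed(seed)
  ids <- names(collection)
  sizes <- vapply(collection, function(g) sum(ranked$gene_id %in% g), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- ids[!keep]
  ids <- ids[keep]
  if (!length(ids)) stop("no term within the set-size bounds")
  es_obs <- vapply(ids, function(id) {
    enrichment_score(ranked, collection[[id]], p = p)$es
  }, numeric(1))
  term_size <- sizes[ids]
  nulls <- lapply(sort(unique(term_size)), function(s) null_es(ranked, s, n_perm, p))
  names(nulls) <- as.character(sort(unique(term_size)))

  nes <- p_nom <- rep(NA_real_, length(ids))
  null_nes_all <- list()
  for (i in seq_along(ids)) {
    nv <- nulls[[as.character(term_size[i])]]
    pos <- nv[nv >= 0]
    neg <- nv[nv < 0]
    m_pos <- if (length(pos)) mean(pos) else NA_real_
    m_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    e <- es_obs[i]
    if (e >= 0) {
      nes[i] <- e / m_pos
      p_nom[i] <- if (length(pos)) mean(pos >= e) else NA_real_
    } else {
      nes[i] <- -abs(e) / m_neg
      p_nom[i] <- if (length(neg)) mean(abs(neg) >= abs(e)) else NA_real_
    }
    null_nes_all[[i]] <- c(pos / m_pos, -abs(neg) / m_neg)
  }
  null_nes <- unlist(null_nes_all)
  q <- vapply(seq_along(ids), function(i) {
    v <- nes[i]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      null_frac <- mean(null_nes[null_nes >= 0] >= v)
      obs_frac <- mean(nes[nes >= 0] >= v)
    } else {
      null_frac <- mean(null_nes[null_nes < 0] <= v)
      obs_frac <- mean(nes[nes < 0] <= v)
    }
    if (is.na(obs_frac) || obs_frac == 0) return(NA_real_)
    min(1, null_frac / obs_frac)
  }, numeric(1))

  nm <- if (is.null(term_names)) rep(NA_character_, length(ids)) else
    unname(term_names[ids])
  out <- data.frame(go_id = ids, go_name = nm, size = unname(term_size),
                    es = unname(es_obs), nes = nes, p_nominal = p_nom,
                    q_fdr = q)
  out <- out[order(-out$nes), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("gsea_result", "data.frame")
  out
}
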