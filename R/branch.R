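#' Log branch length from F_ST
#'
#' `T = -log(1 - F_ST)`, the population-branch-statistic transform of a
#' pairwise F_ST.  Input is clamped to \[0, 1 - 1e-6\]: negative estimates
#' (sampling noise) give T = 0; values at or above the cap give the finite
#' ceiling `-log(1e-6)` rather than infinity.
#'
#' @param fst numeric vector of pairwise F_ST values.
#' @param eps clamp distance from 1.
#' @return numeric vector of branch lengths (>= 0).
#' @export
branch_length <- function(fst, eps = 1e-6) {
  f <- pmin(pmax(fst, 0), 1 - eps)
  -log(1 - f)
}

#' Population branch statistics for one window
#'
#' Given the three pairwise branch lengths `T12`, `T13`, `T23` of a
#' three-population tree, the branch specific to each population is
#' `PBS1 = (T12 + T13 - T23) / 2` and rotations.  The three values satisfy
#' `PBS1 + PBS2 = T12` (and rotations) exactly.
#'
#' @param t12,t13,t23 pairwise branch lengths (vectors).
#' @return list with `pbs1`, `pbs2`, `pbs3`.
#' @export
pbs <- function(t12, t13, t23) {
  list(pbs1 = (t12 + t13 - t23) / 2,
       pbs2 = (t12 + t23 - t13) / 2,
       pbs3 = (t13 + t23 - t12) / 2)
}

#' Genome-wide PBS scan from three F_ST tracks
#'
#' Combines three pairwise `fst_track`s computed on the *same* window set
#' into a per-window PBS track for the three branches.  F_ST values are
#' clamped (negatives to 0, cap at 1 - 1e-6) before the log transform; a
#' window's PBS is defined only where all three pairwise values are valid.
#'
#' @param f12 track for (pop1, pop2); `f13` for (pop1, pop3); `f23` for
#'   (pop2, pop3).  pop1/pop2 are the focal populations, pop3 the outgroup.
#' @return `pbs_track` data.frame: windows plus `fst12`, `fst13`, `fst23`,
#'   `pbs1`, `pbs2`, `pbs3`, `valid`; attribute `pops` names the branches.
#' @export
pbs_scan <- function(f12, f13, f23) {
  key <- function(tr) paste(tr$contig, tr$start, tr$end)
  if (!identical(key(f12), key(f13)) || !identical(key(f12), key(f23))) {
    stop("the three F_ST tracks must share an identical window set")
  }
  p12 <- attr(f12, "pops"); p13 <- attr(f13, "pops"); p23 <- attr(f23, "pops")
  if (is.null(p12) || is.null(p13) || is.null(p23)) {
    # tracks re-read from TSV lose their label attributes
    pops <- c("focal1", "focal2", "outgroup")
  } else {
    pops <- c(p12[1], p12[2], p13[2])
    if (!identical(p13[1], pops[1]) || !setequal(p23, pops[2:3])) {
      stop("track population labels are inconsistent with the (12, 13, 23) layout")
    }
  }
  out <- f12[, c("contig", "start", "end", "partial")]
  out$fst12 <- f12$fst
  out$fst13 <- f13$fst
  out$fst23 <- f23$fst
  valid <- f12$valid & f13$valid & f23$valid &
    !is.na(out$fst12) & !is.na(out$fst13) & !is.na(out$fst23)
  t12 <- branch_length(out$fst12)
  t13 <- branch_length(out$fst13)
  t23 <- branch_length(out$fst23)
  pb <- pbs(t12, t13, t23)
  out$pbs1 <- ifelse(valid, pb$pbs1, NA_real_)
  out$pbs2 <- ifelse(valid, pb$pbs2, NA_real_)
  out$pbs3 <- ifelse(valid, pb$pbs3, NA_real_)
  out$valid <- valid
  attr(out, "pops") <- pops
  class(out) <- c("pbs_track", "data.frame")
  out
}

#' Genome-wide mean PBS per branch
#'
#' @param track a `pbs_track`.
#' @return named numeric vector of per-branch means over valid windows.
#' @export
mean_pbs <- function(track) {
  v <- track$valid
  m <- c(mean(track$pbs1[v]), mean(track$pbs2[v]), mean(track$pbs3[v]))
  names(m) <- attr(track, "pops")
  m
}

#' z-standardised F_ST with tail probabilities
#'
#' Standardises window F_ST by the mean and standard deviation over valid
#' windows (`zfst` has mean 0, sd 1 over those windows by construction) and
#' attaches the one-sided upper-tail standard-normal probability.
#'
#' @param track an `fst_track`.
#' @return the track with added columns `zfst` and `p`; attributes
#'   `zfst_mean`, `zfst_sd` allow de-standardisation.
#' @export
zfst <- function(track) {
  v <- track$valid & !is.na(track$fst)
  mu <- mean(track$fst[v])
  sd_ <- stats::sd(track$fst[v])
  track$zfst <- ifelse(v, (track$fst - mu) / sd_, NA_real_)
  track$p <- stats::pnorm(track$zfst, lower.tail = FALSE)
  attr(track, "zfst_mean") <- mu
  attr(track, "zfst_sd") <- sd_
  track
}

#' Flag PBS outlier windows
#'
#' Windows whose PBS exceeds `threshold` on either focal branch, labelled by
#' class: `"focal1"` (first focal branch only), `"focal2"`, or `"both"` --
#' the three highlight classes of a two-focal-population PBS scatterplot.
#'
#' @param track a `pbs_track`.
#' @param threshold PBS outlier threshold (default 0.05).
#' @return data.frame of outlier windows with their PBS values and a
#'   `class` column.
#' @export
flag_outliers <- function(track, threshold = 0.05) {
  v <- track$valid
  o1 <- v & track$pbs1 > threshold
  o2 <- v & track$pbs2 > threshold
  sel <- o1 | o2
  out <- track[sel, c("contig", "start", "end", "pbs1", "pbs2", "pbs3"),
               drop = FALSE]
  out$class <- ifelse(o1[sel] & o2[sel], "both",
                      ifelse(o1[sel], "focal1", "focal2"))
  rownames(out) <- NULL
  out
}

#' Sliding-window PBS profile across a gene
#'
#' Extracts the ordered sliding-window PBS values overlapping a gene body
#' (plus an optional flank) for one branch, and reports the argmax window
#' (ties broken by smallest start coordinate).
#'
#' @param gene list or one-row data.frame with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param track a sliding-window `pbs_track`.
#' @param branch which branch column to profile (1, 2 or 3).
#' @param flank bp added on both sides of the gene body.
#' @return list with `profile` (ordered data.frame of overlapping windows)
#'   and `argmax` (one-row data.frame, or NULL if no valid window overlaps).
#' @export
gene_profile <- function(gene, track, branch = 1L, flank = 0L) {
  col <- paste0("pbs", branch)
  stopifnot(col %in% names(track))
  lo <- max(0L, gene$start - flank)
  hi <- gene$end + flank
  sel <- track$contig == gene$contig & track$start < hi & track$end > lo
  prof <- track[sel, c("contig", "start", "end", col, "valid"), drop = FALSE]
  prof <- prof[order(prof$start), , drop = FALSE]
  names(prof)[4] <- "pbs"
  rownames(prof) <- NULL
  cand <- which(prof$valid & !is.na(prof$pbs))
  argmax <- NULL
  if (length(cand)) {
    best <- cand[which.max(prof$pbs[cand])] # which.max: first max = smallest start
    argmax <- prof[best, , drop = FALSE]
  }
  list(profile = prof, argmax = argmax)
}
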