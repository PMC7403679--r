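#' Egg volume under the prolate-spheroid model
#'
#' `V = pi * w^2 * L / 6` for an egg of length `L` and width `w` (mm ->
#' mm^3).  At `L = w = d` this is the sphere volume `pi d^3 / 6`.
#'
#' @param l egg length (mm), `l >= w`.
#' @param w egg width (mm), `w >= 0`.
#' @return egg volume (mm^3), vectorised.
#' @export
egg_volume <- function(l, w) {
  if (any(w < 0, na.rm = TRUE) || any(l < w, na.rm = TRUE)) {
    stop("need L >= w >= 0")
  }
  pi * w^2 * l / 6
}

#' Carcass-use efficiency
#'
#' Total brood mass at larval dispersal divided by carcass mass, with an
#' empirical-logit transform.  Boundary values (E = 0 or E = 1) are shrunk
#' by `eps = 1 / (2 n_obs)` before the logit and flagged.
#'
#' @param total_brood_mass brood mass at dispersal (g, >= 0).
#' @param carcass_mass carcass mass (g, > 0).
#' @param n_obs observation count used for the boundary shrinkage (defaults
#'   to the input length).
#' @return data.frame with `efficiency`, `logit`, `boundary`.
#' @export
carcass_efficiency <- function(total_brood_mass, carcass_mass,
                               n_obs = length(total_brood_mass)) {
  if (any(carcass_mass <= 0, na.rm = TRUE)) stop("carcass_mass must be > 0")
  if (any(total_brood_mass < 0, na.rm = TRUE)) stop("brood mass must be >= 0")
  e <- total_brood_mass / carcass_mass
  boundary <- e <= 0 | e >= 1
  eps <- 1 / (2 * n_obs)
  e_adj <- e
  e_adj[e <= 0] <- eps
  e_adj[e >= 1] <- 1 - eps
  data.frame(efficiency = e,
             logit = log(e_adj / (1 - e_adj)),
             boundary = boundary)
}

arm_trait_value <- function(broods, trait) {
  switch(trait,
    clutch_size = broods$clutch_size,
    brood_size = broods$brood_size,
    egg_volume = vapply(seq_len(nrow(broods)), function(i) {
      l <- broods$egg_l[[i]]; w <- broods$egg_w[[i]]
      if (!length(l)) return(NA_real_)
      mean(egg_volume(l, w))
    }, numeric(1)),
    efficiency = carcass_efficiency(broods$total_brood_mass,
                                    broods$carcass_mass)$efficiency,
    stop("unknown trait: ", trait)
  )
}

#' Reaction-norm elevation and slope per dyad
#'
#' For each complete dyad (one small-carcass and one large-carcass arm) the
#' trait's reaction norm is summarised by its elevation -- the cross-
#' treatment mean `(small + large) / 2` -- and its slope `large - small`.
#' Dyads missing an arm, or with a missing trait value in either arm
#' (breeding failure), are excluded and counted.
#'
#' @param broods data.frame of dyad arms as from [simulate_broods()] (or a
#'   dyad TSV read by [read_broods()]).
#' @param trait one of `"clutch_size"`, `"brood_size"`, `"egg_volume"`,
#'   `"efficiency"`.
#' @return data.frame `dyad_id`, `population`, `trait`, `small`, `large`,
#'   `elevation`, `slope`; attribute `n_excluded`.
#' @export
reaction_norms <- function(broods,
                           trait = c("clutch_size", "brood_size",
                                     "egg_volume", "efficiency")) {
  trait <- match.arg(trait)
  broods$._value <- arm_trait_value(broods, trait)
  small <- broods[broods$carcass == "small", c("dyad_id", "population", "._value")]
  large <- broods[broods$carcass == "large", c("dyad_id", "._value")]
  names(small)[3] <- "small"
  names(large)[2] <- "large"
  m <- merge(small, large, by = "dyad_id")
  complete <- !is.na(m$small) & !is.na(m$large)
  n_dyads <- length(unique(broods$dyad_id))
  out <- m[complete, , drop = FALSE]
  out$trait <- trait
  out$elevation <- (out$small + out$large) / 2
  out$slope <- out$large - out$small
  out <- out[order(out$population, out$dyad_id),
             c("dyad_id", "population", "trait", "small", "large",
               "elevation", "slope")]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_dyads - nrow(out)
  out
}

#' Permutation contrast between two populations
#'
#' Two-sided permutation test of the difference in mean elevation (or
#' slope) between the two populations, shuffling population labels across
#' dyads.  When the number of distinct label assignments `choose(nA + nB,
#' nA)` is at most `n_perm`, the test enumerates all of them exhaustively
#' and the p-value is the exact fraction of assignments (including the
#' observed one) whose absolute difference is at least the observed; with
#' random shuffles the p-value uses the standard (1 + hits) / (1 + n_perm)
#' correction.
#'
#' @param summaries output of [reaction_norms()] (two populations).
#' @param component `"elevation"` or `"slope"`.
#' @param n_perm maximum permutations (default 9999).
#' @param seed integer seed (used only in random mode).
#' @return list with `delta` (mean A - mean B, populations in sorted label
#'   order), `p`, `n_perm`, `exhaustive`.
#' @export
permutation_contrast <- function(summaries, component = c("elevation", "slope"),
                                 n_perm = 9999L, seed = 1L) {
  component <- match.arg(component)
  pops <- sort(unique(summaries$population))
  if (length(pops) != 2L) stop("need exactly two populations")
  x <- summaries[[component]]
  is_a <- summaries$population == pops[1]
  n_a <- sum(is_a)
  n <- length(x)
  delta_obs <- mean(x[is_a]) - mean(x[!is_a])
  tol <- 1e-12
  n_comb <- choose(n, n_a)
  if (n_comb <= n_perm) {
    idx <- utils::combn(n, n_a)
    tot <- sum(x)
    d <- colSums(matrix(x[idx], nrow = n_a)) / n_a -
      (tot - colSums(matrix(x[idx], nrow = n_a))) / (n - n_a)
    p <- mean(abs(d) >= abs(delta_obs) - tol)
    list(delta = delta_obs, p = p, n_perm = n_comb, exhaustive = TRUE)
  } else {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      sh <- sample.int(n, n_a)
      d <- mean(x[sh]) - mean(x[-sh])
      if (abs(d) >= abs(delta_obs) - tol) hits <- hits + 1L
    }
    list(delta = delta_obs, p = (1 + hits) / (1 + n_perm),
         n_perm = n_perm, exhaustive = FALSE)
  }
}

#' Guild relative abundance per woodland
#'
#' Species proportions of trap counts within each woodland, with the
#' percentage rounded to one decimal for reporting.
#'
#' @param counts data.frame with `woodland`, `species`, `count`
#'   (non-negative integers; multiple rows per pair are summed).
#' @return data.frame `woodland`, `species`, `count`, `total`,
#'   `proportion`, `percent`.
#' @export
relative_abundance <- function(counts) {
  if (any(counts$count < 0)) stop("counts must be non-negative")
  agg <- stats::aggregate(count ~ woodland + species, data = counts, FUN = sum)
  totals <- stats::aggregate(count ~ woodland, data = agg, FUN = sum)
  names(totals)[2] <- "total"
  out <- merge(agg, totals, by = "woodland")
  out$proportion <- out$count / out$total
  out$percent <- round(100 * out$proportion, 1)
  out <- out[order(out$woodland, -out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
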