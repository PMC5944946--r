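#' Chao-1 richness estimator
#'
#' Estimates the number of OTUs expected in a sample from its singleton and
#' doubleton counts. The bias-corrected form is used by default,
#' \deqn{S_{chao1} = S_{obs} + \frac{F_1 (F_1 - 1)}{2 (F_2 + 1)},}
#' where `F1` and `F2` are the numbers of OTUs observed exactly once and
#' exactly twice in the sample; it stays defined when no doubletons occur.
#'
#' @param counts non-negative integer vector of per-OTU read counts for one
#'   sample.
#' @param bias_corrected use the `F2 + 1` denominator (default); `FALSE`
#'   gives the classic `F1^2 / (2 F2)` form (infinite when `F2 = 0` and
#'   `F1 > 0`).
#' @return The estimated richness (`>= S_obs`).
#' @examples
#' chao1(c(5, 1, 1, 2))  # 4 + 2*1/(2*2) = 4.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_counts(counts)
  if (sum(counts) == 0) stop("empty sample", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f1 == 0) {
    s_obs
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Simpson dominance index
#'
#' \eqn{D = \sum_i p_i^2} over relative abundances; ranges from `1/S` (all
#' taxa equally present) up to 1 (one taxon dominates the community).
#'
#' @inheritParams chao1
#' @return `D` in (0, 1].
#' @export
simpson <- function(counts) {
  counts <- check_counts(counts, integer = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("empty sample", call. = FALSE)
  sum((counts / tot)^2)
}

#' Shannon diversity (natural log)
#'
#' @inheritParams chao1
#' @return `H' = -sum p log p` in nats.
#' @export
shannon <- function(counts) {
  counts <- check_counts(counts, integer = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("empty sample", call. = FALSE)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Shannon equitability (Pielou evenness)
#'
#' `J = H' / H'_max` with `H'_max = log(S_obs)`: the observed Shannon
#' diversity relative to the maximum possible for the observed richness.
#' Undefined (returned as `NA` with a warning) when fewer than two OTUs are
#' observed.
#'
#' @inheritParams chao1
#' @return `J` in [0, 1], or `NA` if `S_obs <= 1`.
#' @export
equitability <- function(counts) {
  counts <- check_counts(counts, integer = FALSE)
  s_obs <- sum(counts > 0)
  if (s_obs <= 1) {
    warning("equitability undefined for S_obs <= 1", call. = FALSE)
    return(NA_real_)
  }
  shannon(counts) / log(s_obs)
}

check_counts <- function(counts, integer = TRUE) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (integer && any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be whole numbers", call. = FALSE)
  }
  counts
}

#' Per-sample alpha-diversity table
#'
#' Computes, for every sample of an OTU table: observed richness, Chao-1,
#' Simpson dominance, Shannon diversity, equitability, and the ratio of
#' observed to Chao-1-expected OTUs (sequencing-effort completeness).
#'
#' @param x an [otu_table()].
#' @return Data frame with one row per sample: `sample_id`, `date`,
#'   `molecule`, `s_obs`, `s_chao1`, `simpson_d`, `shannon_h`,
#'   `equitability_j`, `obs_over_expected`.
#' @export
diversity_table <- function(x) {
  res <- apply(x$counts, 1L, function(v) {
    c(s_obs = sum(v > 0), s_chao1 = chao1(v), simpson_d = simpson(v),
      shannon_h = shannon(v),
      equitability_j = if (sum(v > 0) > 1) equitability(v) else NA_real_)
  })
  out <- data.frame(sample_id = rownames(x$counts),
                    date = x$dates, molecule = x$molecule,
                    t(res), stringsAsFactors = FALSE, row.names = NULL)
  out$obs_over_expected <- out$s_obs / out$s_chao1
  out
}

#' Permutation comparison of a diversity index between two samples
#'
#' Tests whether two libraries differ in a diversity index beyond what
#' random allocation of their pooled reads would produce. The reads of both
#' samples are pooled and repeatedly re-split without replacement at the
#' original depths; the two-sided p-value is the add-one-smoothed fraction
#' of permutations whose index difference is at least as extreme as
#' observed: `p = (1 + #{|d_perm| >= |d_obs|}) / (n_perm + 1)`.
#'
#' @param a,b non-negative integer count vectors over the same OTU set.
#' @param index one of `"simpson"`, `"shannon"`, `"equitability"`,
#'   `"chao1"`, or a function of a count vector.
#' @param n_perm number of random permutation pairs (default 1000).
#' @param seed integer RNG seed.
#' @return List: `delta_obs` (index(a) - index(b)), `p_value`, `index`,
#'   `n_perm`.
#' @export
compare_diversity <- function(a, b, index = "simpson", n_perm = 1000L,
                              seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  a <- check_counts(a)
  b <- check_counts(b)
  if (length(a) != length(b)) {
    stop("samples must cover the same OTU set", call. = FALSE)
  }
  if (sum(a) == 0 || sum(b) == 0) stop("empty sample", call. = FALSE)
  f <- if (is.function(index)) index else
    switch(match.arg(index, c("simpson", "shannon", "equitability",
                              "chao1")),
           simpson = simpson, shannon = shannon,
           equitability = equitability, chao1 = chao1)
  idx_name <- if (is.function(index)) "custom" else index
  delta_obs <- f(a) - f(b)
  na <- sum(a)
  pool <- rep.int(seq_along(a), a + b)
  n_extreme <- with_local_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      take <- sample.int(length(pool), na)
      pa <- tabulate(pool[take], nbins = length(a))
      pb <- tabulate(pool[-take], nbins = length(a))
      if (abs(f(pa) - f(pb)) >= abs(delta_obs) - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(delta_obs = delta_obs,
       p_value = (1 + n_extreme) / (n_perm + 1),
       index = idx_name, n_perm = as.integer(n_perm))
}
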