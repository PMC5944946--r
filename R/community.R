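#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \deqn{d = \frac{\sum_i |x_i - y_i|}{\sum_i (x_i + y_i)}}
#' on counts or relative abundances; 0 for identical profiles, 1 for
#' disjoint supports. Community similarity is reported as
#' `100 * (1 - d)` percent.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return `d` in [0, 1].
#' @examples
#' bray_curtis(c(1, 2), c(2, 0))  # 3/5
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("negative abundances", call. = FALSE)
  den <- sum(x) + sum(y)
  if (den == 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(x - y)) / den
}

#' Bray-Curtis distance matrix of an OTU table
#'
#' @param x an [otu_table()], `rel_abundance` object, or samples x OTUs
#'   matrix.
#' @return A `dist` object.
#' @export
bray_curtis_matrix <- function(x) {
  vegan::vegdist(community_matrix(x), method = "bray")
}

community_matrix <- function(x) {
  if (inherits(x, "otu_table")) x$counts
  else if (inherits(x, "rel_abundance")) x$values
  else as.matrix(x)
}

community_meta <- function(x) {
  m <- community_matrix(x)
  if (inherits(x, "otu_table") || inherits(x, "rel_abundance")) {
    data.frame(sample_id = rownames(m), date = x$dates,
               molecule = x$molecule, stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = rownames(m), date = as.Date(NA),
               molecule = NA_character_, stringsAsFactors = FALSE)
  }
}

#' SIMPROF similarity-profile permutation test
#'
#' Tests whether a set of samples carries multivariate structure beyond
#' exchangeability. The observed profile is the ordered vector of pairwise
#' Bray-Curtis similarities; the null profile is built by permuting each
#' OTU's values independently across samples (which preserves every OTU's
#' marginal distribution but destroys co-occurrence structure). The test
#' statistic `pi` is the mean absolute deviation of the observed ordered
#' profile from the mean ordered profile of `n_expected` permutations; the
#' p-value compares `pi` with `n_test` further permuted profiles
#' (add-one smoothing).
#'
#' @param x samples x OTUs matrix, [otu_table()] or `rel_abundance`
#'   (at least 2 samples).
#' @param n_expected permutations used for the mean expected profile.
#' @param n_test permutations used for the null distribution of `pi`.
#' @param alpha significance level used for the `significant` flag.
#' @param seed integer RNG seed.
#' @return List: `pi` (statistic), `p_value`, `significant`, `n_samples`,
#'   plus the observed and mean expected ordered similarity profiles.
#' @export
simprof_test <- function(x, n_expected = 1000L, n_test = 999L,
                         alpha = 0.05, seed = 1L) {
  m <- community_matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  res <- with_local_seed(seed,
    cpp_simprof_core(m, as.integer(n_expected), as.integer(n_test)))
  p <- (1 + sum(res$pi_perm >= res$pi_obs - 1e-15)) / (n_test + 1)
  list(pi = res$pi_obs, p_value = p, significant = p <= alpha,
       n_samples = nrow(m),
       obs_profile = res$obs_profile, mean_profile = res$mean_profile)
}

#' Cluster samples on Bray-Curtis dissimilarity with SIMPROF pruning
#'
#' Group-average (UPGMA) agglomeration on the Bray-Curtis matrix, with the
#' SIMPROF test applied top-down: the root node is tested first, and each
#' child subtree is tested only while its parent showed significant
#' structure. Maximal subtrees whose test is non-significant form the
#' SIMPROF-homogeneous groups. Flat cluster labels are also produced at the
#' requested percent-similarity levels (cutting the tree at dissimilarity
#' `1 - s/100`).
#'
#' @param x samples x OTUs matrix, [otu_table()] or `rel_abundance` with at
#'   least 3 samples. Clustering on untransformed read counts or on
#'   relative abundances are both supported; pass the object you want.
#' @param cut_similarities percent-similarity levels at which flat labels
#'   are produced (default 25 and 40).
#' @param simprof run the SIMPROF test per node (default `TRUE`).
#' @param n_expected,n_test,alpha,seed passed to [simprof_test()].
#' @return A `community_clustering` object: list with `hclust`, `labels`
#'   (data frame of flat labels per cut), `simprof` (per-node data frame:
#'   node id, size, pi, p, significant, tested), `groups`
#'   (SIMPROF-homogeneous group label per sample, `NA` if simprof is off),
#'   and `meta` (sample_id, date, molecule).
#' @export
cluster_samples <- function(x, cut_similarities = c(25, 40),
                            simprof = TRUE, n_expected = 1000L,
                            n_test = 999L, alpha = 0.05, seed = 1L) {
  m <- community_matrix(x)
  if (nrow(m) < 3) stop("need at least 3 samples", call. = FALSE)
  d <- vegan::vegdist(m, method = "bray")
  hc <- stats::hclust(d, method = "average")
  labels <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
  for (s in cut_similarities) {
    labels[[paste0("cut", s)]] <-
      stats::cutree(hc, h = 1 - s / 100)[rownames(m)]
  }
  node_members <- hclust_node_members(hc)
  simprof_df <- data.frame(node = seq_len(nrow(hc$merge)),
                           n = vapply(node_members, length, integer(1)),
                           pi = NA_real_, p_value = NA_real_,
                           significant = FALSE, tested = FALSE)
  groups <- rep(NA_integer_, nrow(m))
  if (simprof) {
    ## top-down: children are examined only under a significant parent
    test_node <- function(node, seed_offset) {
      idx <- node_members[[node]]
      if (length(idx) < 3) return(invisible(NULL))
      res <- simprof_test(m[idx, , drop = FALSE], n_expected = n_expected,
                          n_test = n_test, alpha = alpha,
                          seed = seed + seed_offset)
      simprof_df$pi[node] <<- res$pi
      simprof_df$p_value[node] <<- res$p_value
      simprof_df$significant[node] <<- res$significant
      simprof_df$tested[node] <<- TRUE
      if (res$significant) {
        for (child in hc$merge[node, ]) {
          if (child > 0) test_node(child, seed_offset + node)
        }
      }
      invisible(NULL)
    }
    test_node(nrow(hc$merge), 0L)
    groups <- simprof_group_labels(hc, simprof_df, node_members)
  }
  structure(list(hclust = hc, labels = labels, simprof = simprof_df,
                 groups = groups, meta = community_meta(x),
                 cut_similarities = cut_similarities),
            class = "community_clustering")
}

#' @export
print.community_clustering <- function(x, ...) {
  cat(sprintf("community_clustering: %d samples (UPGMA on Bray-Curtis)\n",
              length(x$hclust$order)))
  for (s in x$cut_similarities) {
    cat(sprintf("  clusters at %g%% similarity: %d\n", s,
                length(unique(x$labels[[paste0("cut", s)]]))))
  }
  if (any(x$simprof$tested)) {
    cat(sprintf("  SIMPROF: %d node(s) tested, %d significant; %d groups\n",
                sum(x$simprof$tested), sum(x$simprof$significant),
                length(unique(x$groups))))
  }
  invisible(x)
}

## list of leaf index vectors per internal node of an hclust tree
hclust_node_members <- function(hc) {
  n_nodes <- nrow(hc$merge)
  members <- vector("list", n_nodes)
  for (node in seq_len(n_nodes)) {
    kids <- hc$merge[node, ]
    idx <- integer(0)
    for (k in kids) {
      idx <- c(idx, if (k < 0) -k else members[[k]])
    }
    members[[node]] <- idx
  }
  members
}

## SIMPROF-homogeneous groups: maximal subtrees whose root test is
## non-significant (descend only through significant nodes)
simprof_group_labels <- function(hc, simprof_df, node_members) {
  n <- length(hc$order)
  groups <- rep(NA_integer_, n)
  counter <- 0L
  assign_group <- function(node) {
    if (node < 0) {
      counter <<- counter + 1L
      groups[-node] <<- counter
      return(invisible(NULL))
    }
    if (simprof_df$tested[node] && simprof_df$significant[node]) {
      for (child in hc$merge[node, ]) assign_group(child)
    } else {
      counter <<- counter + 1L
      groups[node_members[[node]]] <<- counter
    }
    invisible(NULL)
  }
  assign_group(nrow(hc$merge))
  groups
}

#' rDNA/rRNA pair coupling in a dendrogram
#'
#' For each (date-matched) rDNA/rRNA library pair, reports whether the two
#' leaves form a cherry in the dendrogram (they merge with each other
#' before any other sample: the operational version of appearing "side by
#' side"), and whether they carry the same flat cluster label at a given
#' similarity cut.
#'
#' @param clustering a `community_clustering` from [cluster_samples()].
#' @param pairs data frame with columns `dna_sample` and `rna_sample`
#'   (e.g. `pair_libraries()$pairs`).
#' @param cut percent similarity of the co-clustering cut (default 40).
#' @return List: `n_pairs`, `n_adjacent`, `n_same_cluster`, and the
#'   per-pair logical data frame `detail`.
#' @export
pair_coupling <- function(clustering, pairs, cut = 40) {
  hc <- clustering$hclust
  ids <- clustering$labels$sample_id
  col <- paste0("cut", cut)
  if (!col %in% names(clustering$labels)) {
    stop("clustering has no labels at ", cut, "% similarity", call. = FALSE)
  }
  lab <- clustering$labels[[col]]
  i <- match(pairs$dna_sample, ids)
  j <- match(pairs$rna_sample, ids)
  if (any(is.na(i)) || any(is.na(j))) {
    stop("pair sample(s) absent from clustering", call. = FALSE)
  }
  ## a cherry is a merge row joining the two leaves directly
  cherry_rows <- hc$merge[hc$merge[, 1] < 0 & hc$merge[, 2] < 0, ,
                          drop = FALSE]
  cherry_key <- apply(-cherry_rows, 1L, function(r)
    paste(sort(r), collapse = "-"))
  pair_key <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "-"),
                     i, j)
  adjacent <- pair_key %in% cherry_key
  same <- lab[i] == lab[j]
  list(n_pairs = nrow(pairs),
       n_adjacent = sum(adjacent),
       n_same_cluster = sum(same),
       detail = data.frame(pairs, adjacent = adjacent,
                           same_cluster = same, stringsAsFactors = FALSE))
}

#' Agreement between community clusters and season groups
#'
#' Matches clusters to seasons by majority vote and reports the fraction of
#' samples whose cluster's majority season equals their own season label.
#'
#' @param labels cluster label per sample (vector), or a
#'   `community_clustering` plus `cut`.
#' @param seasons season label per sample, aligned with `labels` (for a
#'   `community_clustering`, named by sample id or ordered as its samples).
#' @param cut percent similarity cut used when `labels` is a
#'   `community_clustering` (default 25).
#' @return Fraction in [0, 1].
#' @export
season_agreement <- function(labels, seasons, cut = 25) {
  if (inherits(labels, "community_clustering")) {
    ids <- labels$labels$sample_id
    labels <- labels$labels[[paste0("cut", cut)]]
    if (!is.null(names(seasons))) seasons <- seasons[ids]
  }
  if (length(labels) != length(seasons) || any(is.na(seasons))) {
    stop("season label missing for some samples", call. = FALSE)
  }
  ok <- logical(length(labels))
  for (cl in unique(labels)) {
    in_cl <- labels == cl
    tab <- table(seasons[in_cl])
    majority <- names(tab)[which.max(tab)]
    ok[in_cl] <- seasons[in_cl] == majority
  }
  mean(ok)
}

#' Venn partition of OTU membership across three clusters
#'
#' An OTU belongs to a cluster if it has at least one read in at least one
#' sample of that cluster. Returns the seven Venn region counts and each
#' region's percent of the union (nearest-integer rounding).
#'
#' @param labels cluster label per sample (exactly 3 distinct values), or a
#'   `community_clustering` (labels at `cut` taken).
#' @param x the [otu_table()] the labels refer to.
#' @param cut percent similarity cut when `labels` is a clustering
#'   (default 25).
#' @return List: `regions` (named counts: `A`, `B`, `C`, `AB`, `AC`, `BC`,
#'   `ABC`), `pct_of_union` (rounded), `n_union`, `cluster_names`.
#' @export
venn_partition <- function(labels, x, cut = 25) {
  if (inherits(labels, "community_clustering")) {
    ids <- labels$labels$sample_id
    labels <- labels$labels[[paste0("cut", cut)]]
    x <- subset_otu_table(x, samples = ids)
  }
  m <- community_matrix(x)
  cl <- sort(unique(labels))
  if (length(cl) != 3) stop("exactly 3 clusters required", call. = FALSE)
  sets <- lapply(cl, function(g) {
    rowsel <- labels == g
    if (!any(rowsel)) stop("cluster with zero samples", call. = FALSE)
    colnames(m)[colSums(m[rowsel, , drop = FALSE]) > 0]
  })
  names(sets) <- c("A", "B", "C")
  inA <- colnames(m) %in% sets$A
  inB <- colnames(m) %in% sets$B
  inC <- colnames(m) %in% sets$C
  regions <- c(
    A = sum(inA & !inB & !inC), B = sum(!inA & inB & !inC),
    C = sum(!inA & !inB & inC), AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC), BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
  n_union <- sum(regions)
  list(regions = regions,
       pct_of_union = round(100 * regions / n_union),
       n_union = n_union, cluster_names = cl)
}

#' Kolmogorov-Smirnov comparison of per-group distributions
#'
#' Two-sample KS test on, e.g., per-taxonomic-group OTU counts or read
#' proportions from two surveys, asking whether the two distributions
#' differ.
#'
#' @param a,b numeric vectors (one value per group).
#' @return List: `D` (KS statistic), `p_value` (asymptotic two-sided).
#' @export
ks_compare_groups <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    stop("need at least one value per side", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p_value = unname(res$p.value))
}

#' Overlap between the rDNA and rRNA OTU inventories
#'
#' @param dna_otus,rna_otus character vectors of OTU ids detected in each
#'   dataset.
#' @return List: `n_union`, `n_shared`, `n_dna_only`, `n_rna_only`,
#'   `pct_shared` (= 100 * shared / union).
#' @export
dataset_overlap <- function(dna_otus, rna_otus) {
  dna_otus <- unique(as.character(dna_otus))
  rna_otus <- unique(as.character(rna_otus))
  shared <- intersect(dna_otus, rna_otus)
  un <- union(dna_otus, rna_otus)
  list(n_union = length(un), n_shared = length(shared),
       n_dna_only = length(setdiff(dna_otus, rna_otus)),
       n_rna_only = length(setdiff(rna_otus, dna_otus)),
       pct_shared = if (length(un)) 100 * length(shared) / length(un)
                    else NaN)
}
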