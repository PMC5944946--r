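test_that("Bray-Curtis matches hand values and the brute-force oracle", {
  expect_equal(bray_curtis(c(1, 2), c(2, 0)), 0.6)
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(5, 0, 0), c(0, 2, 7)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "unequal")
  set.seed(41)
  for (i in 1:100) {
    x <- rpois(sample(2:10, 1), 3)
    y <- rpois(length(x), 3)
    if (sum(x) + sum(y) == 0) x[1] <- 1
    expect_equal(bray_curtis(x, y), oracle_bray_curtis(x, y),
                 tolerance = 1e-12)
  }
  # and against vegan's implementation on a matrix
  m <- matrix(rpois(40, 5), 4, 10)
  d_pkg <- as.matrix(bray_curtis_matrix(m))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d_pkg[i, j], bray_curtis(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("identical samples collapse to one cluster at every level", {
  counts <- matrix(rep(c(5L, 3L, 2L), each = 3), 3,
                   dimnames = list(paste0("S", 1:3), paste0("o", 1:3)))
  x <- otu_table(counts, dates = as.Date("2014-01-01") + 1:3,
                 molecule = rep("rDNA", 3))
  cl <- cluster_samples(x, cut_similarities = c(25, 40, 90),
                        simprof = FALSE)
  expect_equal(length(unique(cl$labels$cut25)), 1)
  expect_equal(length(unique(cl$labels$cut90)), 1)
  expect_error(cluster_samples(x$counts[1:2, ]), "3 samples")
})

test_that("a duplicated sample merges at 100% similarity as a cherry", {
  set.seed(43)
  counts <- matrix(rpois(40, 4) + 1L, 4,
                   dimnames = list(paste0("S", 1:4), paste0("o", 1:10)))
  counts[2, ] <- counts[1, ]
  x <- otu_table(counts, dates = as.Date("2014-01-01") + 1:4,
                 molecule = rep("rDNA", 4))
  cl <- cluster_samples(x, simprof = FALSE)
  hc <- cl$hclust
  first <- hc$merge[1, ]
  expect_equal(sort(-first), c(1, 2))
  expect_equal(hc$height[1], 0)
})

test_that("SIMPROF returns pi = 0, p = 1 for identical samples", {
  counts <- matrix(rep(c(10L, 5L, 1L), each = 4), 4,
                   dimnames = list(paste0("S", 1:4), paste0("o", 1:3)))
  st <- simprof_test(counts, n_expected = 100, n_test = 99, seed = 1)
  expect_equal(st$pi, 0)
  expect_equal(st$p_value, 1)
  expect_false(st$significant)
})

test_that("SIMPROF type-I error stays near alpha on exchangeable nulls", {
  rej <- 0L
  n_rep <- 100
  for (i in 1:n_rep) {
    nl <- simulate_null(15, 50, 500, seed = 7000 + i)
    st <- simprof_test(nl$table, n_expected = 200, n_test = 199,
                       seed = 8000 + i)
    if (st$significant) rej <- rej + 1L
  }
  # alpha + 2 binomial SE
  expect_lte(rej / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("SIMPROF detects planted two-group structure", {
  set.seed(45)
  p1 <- runif(40); p2 <- runif(40)
  counts <- rbind(t(rmultinom(8, 1000, p1)), t(rmultinom(8, 1000, p2)))
  dimnames(counts) <- list(paste0("S", 1:16), paste0("o", 1:40))
  st <- simprof_test(counts, seed = 9)
  expect_lte(st$p_value, 0.05)
})

test_that("planted two-season communities split at the 25% cut", {
  # sample at the two guild peaks (mid-April and mid-December)
  dates <- sort(c(as.Date("2013-04-15") + 365 * (0:7),
                  as.Date("2013-12-16") + 365 * (0:7)))
  tr <- synthetic_truth(dates = dates, n_otus = 200,
                        depth_dna = 3000, depth_rna = 3000,
                        guild_peaks = c(spring = 105, winter = 350),
                        bloom = FALSE, seed = 12)
  sim <- simulate_community(tr)
  cl <- cluster_samples(sim$dna, simprof = FALSE)
  lab <- cl$labels$cut25
  expect_equal(length(unique(lab)), 2)
  expect_gte(season_agreement(
    cl, setNames(tr$date_season, rownames(sim$dna$counts)), cut = 25), 0.9)
})

test_that("pair coupling counts cherries and co-clustered pairs", {
  set.seed(47)
  base <- matrix(rpois(5 * 30, 5) + 1L, 5)
  counts <- rbind(base, base)  # rRNA copies = exact duplicates
  dimnames(counts) <- list(c(paste0("D", 1:5), paste0("R", 1:5)),
                           paste0("o", 1:30))
  dates <- as.Date("2014-01-01") + 10 * (1:5)
  x <- otu_table(counts, dates = rep(dates, 2),
                 molecule = rep(c("rDNA", "rRNA"), each = 5))
  cl <- cluster_samples(x, simprof = FALSE)
  pairs <- data.frame(dna_sample = paste0("D", 1:5),
                      rna_sample = paste0("R", 1:5))
  pc <- pair_coupling(cl, pairs, cut = 40)
  expect_equal(pc$n_adjacent, 5)
  expect_equal(pc$n_same_cluster, 5)
})

test_that("pairs planted in different guilds never co-cluster", {
  dates <- sort(c(as.Date("2013-04-15") + 365 * (0:4),
                  as.Date("2013-12-16") + 365 * (0:4)))
  tr <- synthetic_truth(dates = dates, n_otus = 150,
                        guild_peaks = c(spring = 105, winter = 350),
                        depth_dna = 2000, depth_rna = 2000,
                        bloom = FALSE, seed = 19)
  sim <- simulate_community(tr)
  # pair each spring rDNA sample with a winter rRNA sample
  springs <- rownames(sim$dna$counts)[tr$date_season == "spring"]
  winters <- rownames(sim$rna$counts)[tr$date_season == "winter"]
  k <- min(length(springs), length(winters))
  counts <- rbind(sim$dna$counts, sim$rna$counts)
  x <- otu_table(counts,
                 dates = c(sim$dna$dates, sim$rna$dates),
                 molecule = c(sim$dna$molecule, sim$rna$molecule))
  cl <- cluster_samples(x, cut_similarities = c(25), simprof = FALSE)
  pairs <- data.frame(dna_sample = springs[1:k], rna_sample = winters[1:k])
  pc <- pair_coupling(cl, pairs, cut = 25)
  expect_equal(pc$n_same_cluster, 0)
  # structural inequality on a moderate-divergence synthetic run
  tr2 <- synthetic_truth(n_otus = 150, n_dates = 12,
                         depth_dna = 2000, depth_rna = 2000,
                         copy_numbers = c(All = 1), activity_sd = 0.3,
                         bloom = FALSE, seed = 23)
  sim2 <- simulate_community(tr2)
  x2 <- otu_table(rbind(sim2$dna$counts, sim2$rna$counts),
                  dates = c(sim2$dna$dates, sim2$rna$dates),
                  molecule = c(sim2$dna$molecule, sim2$rna$molecule))
  cl2 <- cluster_samples(x2, simprof = FALSE)
  pr2 <- pair_libraries(sim2$manifest, sim2$dna, sim2$rna)$pairs
  pc2 <- pair_coupling(cl2, pr2, cut = 40)
  expect_lte(pc2$n_adjacent, pc2$n_same_cluster)
})

test_that("season agreement scores majority-vote concordance", {
  expect_equal(season_agreement(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  lab <- rep(1:2, each = 5)
  seas <- c(rep("a", 5), rep("b", 4), "a")
  expect_equal(season_agreement(lab, seas), 0.9)
})

test_that("Venn regions are exact and sum to the union", {
  # planted membership pattern with centre 199 of union 868
  sizes <- c(A = 100, B = 150, C = 150, AB = 80, AC = 90, BC = 99,
             ABC = 199)  # union 868
  member <- list(A = c("A", "AB", "AC", "ABC"),
                 B = c("B", "AB", "BC", "ABC"),
                 C = c("C", "AC", "BC", "ABC"))
  n <- sum(sizes)
  region_of <- rep(names(sizes), sizes)
  counts <- matrix(0L, 3, n,
                   dimnames = list(c("S1", "S2", "S3"),
                                   paste0("o", seq_len(n))))
  for (cl in 1:3) {
    counts[cl, region_of %in% member[[c("A", "B", "C")[cl]]]] <- 1L
  }
  x <- otu_table(counts, dates = as.Date("2014-01-01") + 1:3,
                 molecule = rep("rDNA", 3))
  vp <- venn_partition(labels = 1:3, x = x)
  expect_equal(vp$regions, sizes)
  expect_equal(vp$n_union, 868)
  expect_equal(sum(vp$regions), vp$n_union)
  # the paper-style centre share: 199 of 868 -> 23% after rounding
  expect_equal(unname(vp$pct_of_union["ABC"]),
               round(100 * 199 / sum(sizes)))
})

test_that("Venn edge cases and random partitions keep the sum invariant", {
  counts <- diag(3L) * 5L
  dimnames(counts) <- list(paste0("S", 1:3), paste0("o", 1:3))
  x <- otu_table(counts, dates = as.Date("2014-01-01") + 1:3,
                 molecule = rep("rDNA", 3))
  vp <- venn_partition(1:3, x)
  expect_equal(unname(vp$regions["ABC"]), 0)

  all3 <- otu_table(matrix(1L, 3, 4,
                           dimnames = list(paste0("S", 1:3),
                                           paste0("o", 1:4))),
                    dates = as.Date("2014-01-01") + 1:3,
                    molecule = rep("rDNA", 3))
  vp2 <- venn_partition(1:3, all3)
  expect_equal(unname(vp2$regions["ABC"]), 4)
  expect_equal(vp2$n_union, 4)

  set.seed(53)
  for (i in 1:20) {
    t <- random_table(6, 25, 60, seed = 100 + i)
    vp3 <- venn_partition(rep(1:3, each = 2), t)
    expect_equal(sum(vp3$regions), vp3$n_union)
    expect_equal(vp3$n_union, sum(otu_sums(t) > 0))
  }
  expect_error(venn_partition(c(1, 1, 2), x), "3 clusters")
})

test_that("KS statistic matches the ECDF-scan oracle", {
  res <- ks_compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$D, 0)
  expect_equal(res$p_value, 1)
  expect_equal(ks_compare_groups(c(1, 2, 3), c(1, 2, 3, 100))$D,
               oracle_ks_d(c(1, 2, 3), c(1, 2, 3, 100)), tolerance = 1e-9)
  expect_equal(ks_compare_groups(c(1, 2), c(10, 20, 30))$D, 1)
  set.seed(59)
  for (i in 1:100) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    expect_equal(ks_compare_groups(a, b)$D, oracle_ks_d(a, b),
                 tolerance = 1e-9)
  }
})

test_that("dataset overlap reproduces exact set arithmetic", {
  # counts as printed for the two Illumina inventories:
  # 696 rDNA OTUs of which 168 unique; 700 rRNA OTUs of which 172 unique
  shared <- paste0("s", 1:528)
  dna <- c(shared, paste0("d", 1:168))
  rna <- c(shared, paste0("r", 1:172))
  ov <- dataset_overlap(dna, rna)
  expect_equal(ov$n_union, 868)
  expect_equal(ov$n_shared, 528)
  expect_equal(ov$n_dna_only, 168)
  expect_equal(ov$n_rna_only, 172)
  expect_equal(ov$pct_shared, 100 * 528 / 868, tolerance = 1e-9)

  expect_equal(dataset_overlap(letters, letters)$pct_shared, 100)
  expect_equal(dataset_overlap(letters[1:5], letters[6:9])$pct_shared, 0)
  set.seed(61)
  for (i in 1:50) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    ov2 <- dataset_overlap(a, b)
    expect_equal(ov2$n_union,
                 ov2$n_shared + ov2$n_dna_only + ov2$n_rna_only)
  }
})
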