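# small in-code fixtures shared across test files

toy_counts <- function() {
  matrix(c(5L, 0L, 1L,
           2L, 3L, 0L),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("S1", "S2"), c("OTU1", "OTU2", "OTU3")))
}

toy_table <- function(molecule = c("rDNA", "rDNA")) {
  otu_table(toy_counts(), dates = c("2014-03-04", "2014-03-31"),
            molecule = molecule)
}

random_table <- function(n_samples, n_otus, depth, seed) {
  set.seed(seed)
  p <- runif(n_otus)
  counts <- t(rmultinom(n_samples, depth, p))
  dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                           paste0("OTU", seq_len(n_otus)))
  otu_table(counts, dates = as.Date("2013-01-01") + seq_len(n_samples),
            molecule = rep("rDNA", n_samples))
}

toy_taxonomy <- function(otu_ids, metazoa = character(0)) {
  data.frame(otu_id = otu_ids,
             supergroup = ifelse(otu_ids %in% metazoa, "Metazoa",
                                 "Alveolata"),
             group = "Dinophyceae",
             closest_relative = "Gyrodinium_spirale",
             pct_identity = 99,
             is_metazoa = otu_ids %in% metazoa,
             stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# brute-force independent index oracles (kept deliberately naive)
oracle_chao1 <- function(v) {
  s <- 0; f1 <- 0; f2 <- 0
  for (x in v) {
    if (x > 0) s <- s + 1
    if (x == 1) f1 <- f1 + 1
    if (x == 2) f2 <- f2 + 1
  }
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_simpson <- function(v) {
  tot <- 0
  for (x in v) tot <- tot + x
  d <- 0
  for (x in v) d <- d + (x / tot)^2
  d
}

oracle_equitability <- function(v) {
  tot <- 0; s <- 0
  for (x in v) { tot <- tot + x; if (x > 0) s <- s + 1 }
  h <- 0
  for (x in v) if (x > 0) h <- h - (x / tot) * log(x / tot)
  h / log(s)
}

oracle_bray_curtis <- function(x, y) {
  num <- 0; den <- 0
  for (k in seq_along(x)) {
    num <- num + abs(x[k] - y[k])
    den <- den + x[k] + y[k]
  }
  num / den
}

# two-sample KS statistic by explicit ECDF scan over all observed values
oracle_ks_d <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  dmax <- 0
  for (t in ts) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    dmax <- max(dmax, abs(fa - fb))
  }
  dmax
}
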