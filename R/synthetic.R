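#' Ground-truth parameters for a synthetic paired rDNA/rRNA time series
#'
#' Builds the parameter set ("truth") from which [simulate_community()]
#' draws paired rDNA/rRNA OTU tables. The generator emulates the
#' statistical structure of a multi-year coastal 18S survey:
#'
#' * each OTU belongs to one of three seasonal guilds (spring, summer,
#'   winter) and has a Gaussian seasonal bump in log biomass (peak
#'   day-of-year, width, amplitude) on top of a heavy-tailed baseline, plus
#'   AR(1) log-noise shared by the two molecules;
#' * each OTU carries the rDNA copy-number multiplier of its taxonomic
#'   group (dinoflagellates high), which inflates its rDNA — not rRNA —
#'   read share;
#' * rRNA weight is biomass times a per-date activity factor; one optional
#'   bloom taxon (a *Phaeocystis*-like haptophyte) has its activity rise
#'   `bloom_lead_days` ahead of its biomass and stay high through the
#'   bloom, so its rRNA signal crosses any abundance threshold before its
#'   rDNA signal does;
#' * reads are drawn multinomially at the configured library depths.
#'
#' OTU-level parameters are drawn under `param_seed`; the sampling run
#' (noise and reads) uses `seed`, so two runs differing only in `seed`
#' share identical expected values.
#'
#' @param n_dates,start,interval_days sampling calendar (defaults: 30
#'   roughly-monthly dates from late Feb 2013); alternatively pass `dates`
#'   directly.
#' @param dates optional explicit `Date` vector.
#' @param n_otus community richness (default 900).
#' @param depth_dna,depth_rna reads per library (defaults 20000 and 10000).
#' @param guild_peaks named day-of-year peaks of the three seasonal guilds.
#' @param guild_peak_sd sd (days) of OTU peaks around their guild peak.
#' @param width_range min/max seasonal bump width (days).
#' @param amp_range min/max seasonal log-amplitude.
#' @param base_sd sd of the lognormal baseline sizes (heavy tail: the top
#'   ~100 OTUs carry most reads).
#' @param noise_sd,noise_rho AR(1) log-biomass noise (shared by rDNA and
#'   rRNA of the same date).
#' @param activity_sd sd of the lognormal per-date activity factor applied
#'   to rRNA weights (0 = constant per-cell activity).
#' @param copy_numbers named vector of rDNA copy-number multipliers per
#'   taxonomic group; OTUs are assigned groups (and their supergroups) in
#'   proportion to `group_prob`.
#' @param group_prob group assignment probabilities (recycled/normalised).
#' @param bloom add the bloom taxon (default `TRUE`).
#' @param bloom_lead_days days by which the bloom taxon's activity leads
#'   its abundance (default 21).
#' @param bloom_peak_yday,bloom_width,bloom_amp bloom biomass bump (sharp
#'   spring bloom by default).
#' @param bloom_base_rel off-season relative abundance targeted for the
#'   bloom taxon (default 1e-5, i.e. 0.001%).
#' @param param_seed seed for OTU parameter draws.
#' @param seed seed for the sampling run.
#' @return A `synthetic_truth` object (list) with per-OTU parameter table
#'   `otus`, the calendar `dates`, `date_season` (guild nearest each
#'   date), depths, the bloom settings and both seeds.
#' @export
synthetic_truth <- function(n_dates = 30L, start = as.Date("2013-02-26"),
                            interval_days = 29L, dates = NULL,
                            n_otus = 900L,
                            depth_dna = 20000L, depth_rna = 10000L,
                            guild_peaks = c(spring = 105, summer = 210,
                                            winter = 350),
                            guild_peak_sd = 15,
                            width_range = c(20, 45),
                            amp_range = c(3.5, 6),
                            base_sd = 2,
                            noise_sd = 0.4, noise_rho = 0.6,
                            activity_sd = 0.5,
                            copy_numbers = c(Dinophyceae = 100,
                                             Syndiniales = 20,
                                             Ciliophora = 10,
                                             Bacillariophyta = 5,
                                             Haptophyta = 3,
                                             MAST = 2,
                                             Chlorophyta = 1,
                                             Fungi = 1),
                            group_prob = NULL,
                            bloom = TRUE, bloom_lead_days = 21,
                            bloom_peak_yday = 105, bloom_width = 12,
                            bloom_amp = 8, bloom_base_rel = 1e-5,
                            param_seed = 42L, seed = 1L) {
  if (is.null(dates)) {
    dates <- start + interval_days * (seq_len(n_dates) - 1L)
  }
  dates <- as.Date(dates)
  if (length(dates) < 2 || n_otus < 2) {
    stop("need at least 2 dates and 2 OTUs", call. = FALSE)
  }
  if (depth_dna <= 0 || depth_rna <= 0) stop("depths must be positive",
                                             call. = FALSE)
  if (bloom_lead_days < 0) stop("bloom lead must be >= 0", call. = FALSE)
  groups <- names(copy_numbers)
  if (is.null(group_prob)) group_prob <- rep(1, length(groups))
  group_prob <- group_prob / sum(group_prob)
  supergroup_of <- c(Dinophyceae = "Alveolata", Syndiniales = "Alveolata",
                     Ciliophora = "Alveolata",
                     Bacillariophyta = "Stramenopiles",
                     MAST = "Stramenopiles", Haptophyta = "Hacrobia",
                     Chlorophyta = "Archaeplastida", Fungi = "Opisthokonta")
  otus <- with_local_seed(param_seed, {
    guild <- sample(names(guild_peaks), n_otus, replace = TRUE)
    group <- sample(groups, n_otus, replace = TRUE, prob = group_prob)
    data.frame(
      otu_id = paste0("OTU", seq_len(n_otus)),
      guild = guild,
      group = group,
      supergroup = ifelse(group %in% names(supergroup_of),
                          supergroup_of[group], "unclassified"),
      copy_number = unname(copy_numbers[group]),
      peak_yday = (guild_peaks[guild] +
                     stats::rnorm(n_otus, 0, guild_peak_sd)) %% 365,
      width = stats::runif(n_otus, width_range[1], width_range[2]),
      amplitude = stats::runif(n_otus, amp_range[1], amp_range[2]),
      log_base = stats::rnorm(n_otus, 0, base_sd),
      lead_days = 0,
      stringsAsFactors = FALSE)
  })
  bloom_id <- NA_character_
  if (bloom) {
    bloom_id <- paste0("OTU", n_otus + 1L)
    otus <- rbind(otus, data.frame(
      otu_id = bloom_id, guild = "spring", group = "Haptophyta",
      supergroup = "Hacrobia",
      copy_number = unname(copy_numbers["Haptophyta"]),
      peak_yday = bloom_peak_yday, width = bloom_width,
      amplitude = bloom_amp, log_base = NA,  # scaled to bloom_base_rel
      lead_days = bloom_lead_days, stringsAsFactors = FALSE))
  }
  yd <- as.integer(format(dates, "%j"))
  season <- names(guild_peaks)[apply(
    vapply(guild_peaks, function(p) circ_yday_dist(yd, p), numeric(length(yd))),
    1L, which.min)]
  structure(list(otus = otus, dates = dates, date_season = season,
                 depth_dna = as.integer(depth_dna),
                 depth_rna = as.integer(depth_rna),
                 guild_peaks = guild_peaks,
                 noise_sd = noise_sd, noise_rho = noise_rho,
                 activity_sd = activity_sd,
                 bloom_otu = bloom_id, bloom_base_rel = bloom_base_rel,
                 param_seed = as.integer(param_seed),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

## circular distance in days between day-of-year vectors
circ_yday_dist <- function(a, b) {
  d <- abs(a - b) %% 365
  pmin(d, 365 - d)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d OTUs x %d dates (%s .. %s), depths %d/%d%s\n",
    nrow(x$otus), length(x$dates), min(x$dates), max(x$dates),
    x$depth_dna, x$depth_rna,
    if (is.na(x$bloom_otu)) "" else
      sprintf("; bloom taxon %s (lead %g d)", x$bloom_otu,
              x$otus$lead_days[x$otus$otu_id == x$bloom_otu])))
  invisible(x)
}

## deterministic log-weight of every OTU at arbitrary dates (no noise).
## With use_lead = TRUE an OTU's activity lead shifts the RISING edge of
## its seasonal bump `lead_days` earlier: activity climbs ahead of
## biomass, plateaus at the peak value, and decays together with biomass
## (ribosome build-up anticipates proliferation; senescence shuts both
## down).
truth_log_weight <- function(truth, dates, use_lead = FALSE) {
  yd <- as.numeric(format(as.Date(dates), "%j")) %% 365
  ot <- truth$otus
  out <- matrix(0, nrow = length(dates), ncol = nrow(ot),
                dimnames = list(as.character(dates), ot$otu_id))
  base <- ifelse(is.na(ot$log_base), 0, ot$log_base)  # bloom scaled later
  for (i in seq_len(nrow(ot))) {
    ## signed circular days until the peak (positive = before the peak)
    delta <- (ot$peak_yday[i] - yd + 182.5) %% 365 - 182.5
    d <- abs(delta)
    if (use_lead && ot$lead_days[i] > 0) {
      d <- ifelse(delta > 0, pmax(0, delta - ot$lead_days[i]), d)
    }
    out[, i] <- base[i] + ot$amplitude[i] * exp(-d^2 / (2 * ot$width[i]^2))
  }
  out
}

#' Simulate a paired rDNA/rRNA survey from a ground truth
#'
#' Draws the read tables the truth describes (see [synthetic_truth()]):
#' latent log biomass = seasonal bump + AR(1) noise (one realisation shared
#' by both molecules); rDNA sampling weight = copy number x biomass; rRNA
#' sampling weight = activity x biomass, where the bloom taxon's activity
#' profile rises `lead_days` ahead of its biomass (rising edge shifted
#' early, decay shared); multinomial reads at each library's depth.
#'
#' @param truth a `synthetic_truth`.
#' @return List: `dna` and `rna` ([otu_table()]s), `manifest` (data frame
#'   linking the paired libraries), `taxonomy` (data frame accepted by the
#'   taxonomy-dependent operations), `truth`, and the deterministic
#'   expected relative abundances `exp_dna_rel` / `exp_rna_rel`
#'   (noise-free, for parameter-recovery checks).
#' @export
simulate_community <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ot <- truth$otus
  n_d <- length(truth$dates)
  n_o <- nrow(ot)
  lw <- truth_log_weight(truth, truth$dates)
  log_c <- log(ot$copy_number)
  ## log weights per molecule; the bloom taxon's baseline is calibrated so
  ## that its off-season expected relative abundance is bloom_base_rel in
  ## BOTH libraries (the two normalising totals differ, because copy
  ## numbers inflate only rDNA), keeping the activity lead a pure time
  ## shift on the relative-abundance scale
  lw_dna <- sweep(lw, 2L, log_c, "+")
  lw_rna <- lw
  bloom_i <- which(ot$otu_id %in% truth$bloom_otu)
  if (length(bloom_i)) {
    others <- setdiff(seq_len(n_o), bloom_i)
    tot_dna <- mean(rowSums(exp(lw_dna[, others, drop = FALSE])))
    tot_rna <- mean(rowSums(exp(lw_rna[, others, drop = FALSE])))
    lw_dna[, bloom_i] <- lw[, bloom_i] +
      log(truth$bloom_base_rel * tot_dna)
    lw_rna[, bloom_i] <- truth_log_weight(
      truth, truth$dates, use_lead = TRUE)[, bloom_i] +
      log(truth$bloom_base_rel * tot_rna)
  }
  res <- with_local_seed(truth$seed, {
    ## AR(1) log-biomass noise, one series per OTU, shared by molecules
    eps <- matrix(0, n_d, n_o)
    if (truth$noise_sd > 0) {
      innov_sd <- truth$noise_sd * sqrt(1 - truth$noise_rho^2)
      eps[1, ] <- stats::rnorm(n_o, 0, truth$noise_sd)
      for (t in 2:n_d) {
        eps[t, ] <- truth$noise_rho * eps[t - 1, ] +
          stats::rnorm(n_o, 0, innov_sd)
      }
    }
    act <- matrix(0, n_d, n_o)
    if (truth$activity_sd > 0) {
      act[] <- stats::rnorm(n_d * n_o, 0, truth$activity_sd)
      act[, bloom_i] <- 0  # bloom taxon: deterministic shifted activity
    }
    w_dna <- exp(lw_dna + eps)
    w_rna <- exp(lw_rna + eps + act)
    dna_counts <- t(vapply(seq_len(n_d), function(t)
      as.integer(stats::rmultinom(1, truth$depth_dna, w_dna[t, ])),
      integer(n_o)))
    rna_counts <- t(vapply(seq_len(n_d), function(t)
      as.integer(stats::rmultinom(1, truth$depth_rna, w_rna[t, ])),
      integer(n_o)))
    list(dna = dna_counts, rna = rna_counts)
  })
  dimnames(res$dna) <- list(paste0("D", format(truth$dates, "%Y%m%d")),
                            ot$otu_id)
  dimnames(res$rna) <- list(paste0("R", format(truth$dates, "%Y%m%d")),
                            ot$otu_id)
  exp_dna <- exp(lw_dna)
  exp_rna <- exp(lw_rna)
  manifest <- data.frame(
    library_id = c(rownames(res$dna), rownames(res$rna)),
    date = rep(truth$dates, 2),
    molecule = rep(c("rDNA", "rRNA"), each = n_d),
    pair_id = rep(paste0("P", format(truth$dates, "%Y%m%d")), 2),
    stringsAsFactors = FALSE)
  taxonomy <- data.frame(
    otu_id = ot$otu_id, supergroup = ot$supergroup, group = ot$group,
    closest_relative = paste0(ot$group, "_sp"),
    pct_identity = 97, is_metazoa = FALSE, stringsAsFactors = FALSE)
  rownames(taxonomy) <- taxonomy$otu_id
  list(dna = otu_table(res$dna, dates = truth$dates,
                       molecule = rep("rDNA", n_d)),
       rna = otu_table(res$rna, dates = truth$dates,
                       molecule = rep("rRNA", n_d)),
       manifest = manifest, taxonomy = taxonomy, truth = truth,
       exp_dna_rel = exp_dna / rowSums(exp_dna),
       exp_rna_rel = exp_rna / rowSums(exp_rna))
}

#' Simulate an exchangeable null community
#'
#' Every sample is drawn i.i.d. from one shared multinomial: there is no
#' between-sample structure by construction. Used to calibrate the type-I
#' error of [simprof_test()] and of [compare_diversity()].
#'
#' @param n_samples,n_otus,depth table dimensions and library depth.
#' @param seed integer RNG seed (also draws the shared composition).
#' @return List: `table` (an [otu_table()], all samples labelled rDNA on
#'   consecutive dates) and `p` (the shared OTU proportions).
#' @export
simulate_null <- function(n_samples, n_otus, depth, seed = 1L) {
  if (n_samples < 1 || n_otus < 1 || depth < 1) {
    stop("all sizes must be >= 1", call. = FALSE)
  }
  res <- with_local_seed(seed, {
    p <- exp(stats::rnorm(n_otus, 0, 1))
    p <- p / sum(p)
    counts <- t(stats::rmultinom(n_samples, depth, p))
    list(p = p, counts = counts)
  })
  dimnames(res$counts) <- list(paste0("S", seq_len(n_samples)),
                               paste0("OTU", seq_len(n_otus)))
  list(table = otu_table(res$counts,
                         dates = as.Date("2013-01-01") +
                           seq_len(n_samples) - 1L,
                         molecule = rep("rDNA", n_samples)),
       p = res$p)
}

#' Simulate points with a known reduced-major-axis slope
#'
#' Draws `(x, y)` pairs from the symmetric errors-in-variables model for
#' which the RMA estimator is consistent: a latent value `t ~ N(0, sd_t^2)`
#' observed as `x = t + e_x` and `y = b + slope * t + e_y`, with
#' `sd(e_y) = |slope| * sd(e_x)` so that `sd(y)/sd(x) = |slope|` exactly in
#' expectation. Used for parameter-recovery validation of [rma_fit()].
#'
#' @param slope,intercept true RMA line.
#' @param n number of points.
#' @param sd_t latent spread (default 1).
#' @param sd_e error sd on `x` (default 0.35; implies Pearson r about 0.9).
#' @param seed integer RNG seed.
#' @return Data frame with columns `x` and `y`.
#' @export
simulate_rma_points <- function(slope, intercept = 0, n = 300L, sd_t = 1,
                                sd_e = 0.35, seed = 1L) {
  with_local_seed(seed, {
    t <- stats::rnorm(n, 0, sd_t)
    x <- t + stats::rnorm(n, 0, sd_e)
    y <- intercept + slope * t + stats::rnorm(n, 0, abs(slope) * sd_e)
    data.frame(x = x, y = y)
  })
}
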