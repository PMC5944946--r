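#' Signed rRNA:rDNA ratio
#'
#' The raw activity ratio `r = rrna_rel / rdna_rel` (relative abundance of
#' an OTU in the rRNA library over its relative abundance in the rDNA
#' library of the same date) is reported on a signed scale whose magnitude
#' is always at least 1: `+r` when `r >= 1` (more rRNA than rDNA signal:
#' relatively active) and `-1/r` when `r < 1` (e.g. -40 means the OTU has
#' 40 times more rDNA reads than rRNA reads: abundant but with low relative
#' activity). A value of exactly 1 is returned as `+1`. Dates where the OTU
#' occurs in only one of the two libraries are excluded (`NA`): the ratio
#' is undefined there.
#'
#' @param rdna_rel,rrna_rel relative read abundances (fractions in [0, 1]),
#'   vectorised.
#' @return Numeric vector with values in `(-Inf, -1] U [1, Inf)` or `NA`
#'   for excluded entries.
#' @examples
#' signed_ratio(0.020, 0.0005)  # -40
#' signed_ratio(0.001, 0.003)   # +3
#' @export
signed_ratio <- function(rdna_rel, rrna_rel) {
  if (any(rdna_rel < 0, na.rm = TRUE) || any(rrna_rel < 0, na.rm = TRUE)) {
    stop("relative abundances must be non-negative", call. = FALSE)
  }
  out <- rep(NA_real_, max(length(rdna_rel), length(rrna_rel)))
  rdna_rel <- rep_len(rdna_rel, length(out))
  rrna_rel <- rep_len(rrna_rel, length(out))
  ok <- !is.na(rdna_rel) & !is.na(rrna_rel) & rdna_rel > 0 & rrna_rel > 0
  r <- rrna_rel[ok] / rdna_rel[ok]
  out[ok] <- ifelse(r >= 1, r, -1 / r)
  out
}

#' Invert a signed ratio back to the raw ratio
#'
#' @param v signed ratio(s) from [signed_ratio()].
#' @return `r = rrna_rel / rdna_rel` (`v` if `v >= 1`, else `-1/v`).
#' @export
unsign_ratio <- function(v) {
  ifelse(is.na(v), NA_real_, ifelse(v >= 1, v, -1 / v))
}

#' Per-OTU, per-date activity ratio series
#'
#' Joins the paired rDNA and rRNA relative-abundance tables on sampling
#' date and computes, for every OTU at every paired date, the two relative
#' abundances, the signed rRNA:rDNA ratio, and the quadrant life-cycle
#' phase ([classify_quadrant()]).
#'
#' @param dna_rel,rna_rel `rel_abundance` objects (see
#'   [relative_abundance()]) for the rDNA and rRNA libraries; dates present
#'   in both are used.
#' @param otus optional subset of OTU ids (default: OTUs common to both
#'   tables).
#' @param rare_thresh,abundant_thresh passed to [classify_quadrant()].
#' @return A data frame of class `ratio_series`: `otu_id`, `date`,
#'   `rdna_rel`, `rrna_rel`, `signed_ratio`, `quadrant`.
#' @export
ratio_series <- function(dna_rel, rna_rel, otus = NULL,
                         rare_thresh = 1e-4, abundant_thresh = 1e-3) {
  dates <- as.Date(sort(intersect(dna_rel$dates, rna_rel$dates)),
                   origin = "1970-01-01")
  if (!length(dates)) stop("no shared dates", call. = FALSE)
  if (is.null(otus)) {
    otus <- intersect(colnames(dna_rel$values), colnames(rna_rel$values))
  }
  di <- match(dates, dna_rel$dates)
  ri <- match(dates, rna_rel$dates)
  d <- dna_rel$values[di, otus, drop = FALSE]
  r <- rna_rel$values[ri, otus, drop = FALSE]
  out <- data.frame(
    otu_id = rep(otus, each = length(dates)),
    date = as.Date(rep(dates, times = length(otus)),
                   origin = "1970-01-01"),
    rdna_rel = as.numeric(d), rrna_rel = as.numeric(r),
    stringsAsFactors = FALSE)
  out$signed_ratio <- signed_ratio(out$rdna_rel, out$rrna_rel)
  out$quadrant <- classify_quadrant(out$rdna_rel, out$rrna_rel,
                                    rare_thresh, abundant_thresh)
  class(out) <- c("ratio_series", "data.frame")
  out
}

#' Reduced major axis (RMA) regression of log rRNA on log rDNA abundance
#'
#' Fits the line minimising errors in both coordinates, appropriate when
#' neither axis is a controlled predictor: slope
#' `= sign(cor(x, y)) * sd(y) / sd(x)` and intercept
#' `b = mean(y) - slope * mean(x)`. On `(log10 rDNA, log10 rRNA)` relative
#' abundances a slope of 1 means rRNA signal tracks rDNA signal
#' proportionally; a group is called RNA-prevalent when its slope is
#' credibly above 1 and DNA-prevalent when credibly below, using a
#' bootstrap standard-error band `slope +/- z_mult * SE` around 1
#' (`z_mult = 2` approximates a 95% interval).
#'
#' @param x,y numeric vectors (log10 relative abundances); pairs with
#'   missing values are dropped. At least 3 points are required.
#' @param n_boot bootstrap replicates for the standard errors
#'   (default 1000).
#' @param seed integer RNG seed for the bootstrap.
#' @param z_mult width of the standard-error band used for the prevalence
#'   call (default 2).
#' @param group optional group label stored in the result.
#' @return An `rma_fit` object: list with `slope`, `intercept`, `n`,
#'   `slope_se`, `intercept_se`, `r` (Pearson correlation), `prevalence`
#'   (`"RNA-prevalent"`, `"DNA-prevalent"` or `"neutral"`), `group`.
#' @examples
#' f <- rma_fit(c(0, 1, 2), c(1, 3, 5))
#' c(f$slope, f$intercept)  # 2, 1
#' @export
rma_fit <- function(x, y, n_boot = 1000L, seed = 1L, z_mult = 2,
                    group = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  est <- function(x, y) {
    sdx <- stats::sd(x)
    if (sdx == 0) return(c(NA_real_, NA_real_))
    r <- suppressWarnings(stats::cor(x, y))
    s <- ifelse(is.na(r) || r >= 0, 1, -1) * stats::sd(y) / sdx
    c(s, mean(y) - s * mean(x))
  }
  fit <- est(x, y)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      est(x[idx], y[idx])
    }, numeric(2))
  })
  ses <- apply(boots, 1L, stats::sd, na.rm = TRUE)
  prevalence <- if (fit[1] - z_mult * ses[1] > 1) "RNA-prevalent"
                else if (fit[1] + z_mult * ses[1] < 1) "DNA-prevalent"
                else "neutral"
  structure(list(slope = fit[1], intercept = fit[2], n = n,
                 slope_se = ses[1], intercept_se = ses[2],
                 r = suppressWarnings(stats::cor(x, y)),
                 prevalence = prevalence, z_mult = z_mult, group = group),
            class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf(
    "rma_fit%s: slope %.3f +/- %.3f, b %.3f +/- %.3f (n = %d) -> %s\n",
    if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    x$slope, x$slope_se, x$intercept, x$intercept_se, x$n, x$prevalence))
  invisible(x)
}

#' Per-group RMA prevalence regressions
#'
#' Pools all (OTU, date) points of each higher taxonomic group across the
#' selected OTUs, takes `log10` of both relative abundances (dates where
#' the OTU is absent from either library are excluded), and fits
#' [rma_fit()] per group.
#'
#' @param series a `ratio_series` from [ratio_series()].
#' @param tax taxonomy data frame ([read_taxonomy()]); the `group` column
#'   defines the pooling.
#' @param min_points groups with fewer usable points are skipped
#'   (default 3).
#' @inheritParams rma_fit
#' @return Data frame with one row per group: `group`, `n`, `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `prevalence`.
#' @export
rma_by_group <- function(series, tax, min_points = 3L, n_boot = 1000L,
                         seed = 1L, z_mult = 2) {
  grp <- tax$group[match(series$otu_id, tax$otu_id)]
  usable <- series$rdna_rel > 0 & series$rrna_rel > 0 & !is.na(grp)
  rows <- list()
  for (g in sort(unique(grp[usable]))) {
    sel <- usable & grp == g
    if (sum(sel) < min_points) next
    fit <- rma_fit(log10(series$rdna_rel[sel]), log10(series$rrna_rel[sel]),
                   n_boot = n_boot, seed = seed, z_mult = z_mult, group = g)
    rows[[g]] <- data.frame(group = g, n = fit$n, slope = fit$slope,
                            slope_se = fit$slope_se,
                            intercept = fit$intercept,
                            intercept_se = fit$intercept_se,
                            prevalence = fit$prevalence,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(group = character(), n = integer(),
                      slope = numeric(), slope_se = numeric(),
                      intercept = numeric(), intercept_se = numeric(),
                      prevalence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Quadrant life-cycle phase of an OTU at one date
#'
#' Classifies an OTU by its relative abundance in the rDNA library
#' (presence/abundance axis) and rRNA library (activity axis). Cells are
#' "rare" below `rare_thresh` (default 0.01% as a fraction) and "abundant"
#' above `abundant_thresh` (default 0.1%); the same thresholds are applied
#' to rRNA to separate low-activity from active. The four corners are
#' `rare-low`, `rare-active`, `abundant-active` and `abundant-low`; any
#' point with either coordinate inside the intermediate band
#' `(rare_thresh, abundant_thresh]` is in `transition` between phases.
#'
#' Thresholds are on relative abundances, so the classification is
#' invariant to rescaling all counts of a sample.
#'
#' @param rdna_rel,rrna_rel relative abundances (vectorised).
#' @param rare_thresh,abundant_thresh fraction thresholds,
#'   `0 < rare_thresh <= abundant_thresh`.
#' @return Character vector of quadrant labels.
#' @examples
#' classify_quadrant(5e-5, 5e-5)  # rare-low
#' classify_quadrant(5e-3, 5e-3)  # abundant-active
#' classify_quadrant(5e-4, 5e-4)  # transition
#' @export
classify_quadrant <- function(rdna_rel, rrna_rel, rare_thresh = 1e-4,
                              abundant_thresh = 1e-3) {
  if (any(rdna_rel < 0, na.rm = TRUE) || any(rrna_rel < 0, na.rm = TRUE)) {
    stop("relative abundances must be non-negative", call. = FALSE)
  }
  if (rare_thresh <= 0 || rare_thresh > abundant_thresh) {
    stop("need 0 < rare_thresh <= abundant_thresh", call. = FALSE)
  }
  dna_state <- ifelse(rdna_rel <= rare_thresh, "rare",
                      ifelse(rdna_rel > abundant_thresh, "abundant", "mid"))
  rna_state <- ifelse(rrna_rel <= rare_thresh, "low",
                      ifelse(rrna_rel > abundant_thresh, "active", "mid"))
  out <- rep("transition", length(dna_state))
  out[dna_state == "rare" & rna_state == "low"] <- "rare-low"
  out[dna_state == "rare" & rna_state == "active"] <- "rare-active"
  out[dna_state == "abundant" & rna_state == "active"] <- "abundant-active"
  out[dna_state == "abundant" & rna_state == "low"] <- "abundant-low"
  out[is.na(rdna_rel) | is.na(rrna_rel)] <- NA_character_
  out
}

#' Phase timeline, bloom intervals and early warnings for one OTU
#'
#' Orders one OTU's ratio series by date, assigns the quadrant phase at
#' each date, and derives: bloom intervals (maximal runs of consecutive
#' `abundant-active` dates) and early-warning dates. A date raises an early
#' warning when the rRNA signal has crossed the abundant threshold while
#' the rDNA signal has not (`rare-active`, or `transition` with
#' `rrna_rel > abundant_thresh` and `rdna_rel <= abundant_thresh`) and a
#' bloom interval follows later in the series; the lead time to the next
#' bloom start is reported in days.
#'
#' @param series a `ratio_series` (or data frame with `otu_id`, `date`,
#'   `rdna_rel`, `rrna_rel`) holding at least 2 dates for `otu`.
#' @param otu the OTU id to extract; may be omitted if `series` holds a
#'   single OTU.
#' @param rare_thresh,abundant_thresh see [classify_quadrant()].
#' @return A `phase_timeline` object: list with `otu_id`, `timeline` (data
#'   frame: `date`, `rdna_rel`, `rrna_rel`, `quadrant`), `blooms` (data
#'   frame: `start`, `end`, `n_dates`, `senescence` — `TRUE` when the run
#'   ends by activity loss, i.e. the next observed state is
#'   `abundant-low`), and `warnings` (data frame: `date`, `next_bloom_start`,
#'   `lead_days`, `lead_dates` — sampling dates between warning and bloom
#'   start).
#' @export
phase_timeline <- function(series, otu = NULL, rare_thresh = 1e-4,
                           abundant_thresh = 1e-3) {
  df <- as.data.frame(series)
  if (!is.null(otu)) df <- df[df$otu_id == otu, , drop = FALSE]
  if (length(unique(df$otu_id)) != 1) {
    stop("series must be reduced to a single OTU", call. = FALSE)
  }
  if (nrow(df) < 2) stop("need at least 2 dates", call. = FALSE)
  df <- df[order(df$date), , drop = FALSE]
  quad <- classify_quadrant(df$rdna_rel, df$rrna_rel, rare_thresh,
                            abundant_thresh)
  timeline <- data.frame(date = df$date, rdna_rel = df$rdna_rel,
                         rrna_rel = df$rrna_rel, quadrant = quad,
                         stringsAsFactors = FALSE)
  in_bloom <- quad == "abundant-active"
  runs <- rle(in_bloom)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bloom_idx <- which(runs$values)
  blooms <- data.frame(start = as.Date(character()),
                       end = as.Date(character()),
                       n_dates = integer(), senescence = logical())
  for (b in bloom_idx) {
    after <- ends[b] + 1L
    blooms <- rbind(blooms, data.frame(
      start = df$date[starts[b]], end = df$date[ends[b]],
      n_dates = runs$lengths[b],
      senescence = after <= nrow(df) && quad[after] == "abundant-low"))
  }
  warn_flag <- quad == "rare-active" |
    (quad == "transition" & df$rrna_rel > abundant_thresh &
       df$rdna_rel <= abundant_thresh)
  warnings <- data.frame(date = as.Date(character()),
                         next_bloom_start = as.Date(character()),
                         lead_days = numeric(), lead_dates = integer())
  if (nrow(blooms) > 0) {
    for (w in which(warn_flag)) {
      nxt <- blooms$start[blooms$start > df$date[w]]
      if (!length(nxt)) next
      nb <- min(nxt)
      warnings <- rbind(warnings, data.frame(
        date = df$date[w], next_bloom_start = nb,
        lead_days = as.numeric(nb - df$date[w]),
        lead_dates = sum(df$date > df$date[w] & df$date <= nb)))
    }
  }
  structure(list(otu_id = df$otu_id[1], timeline = timeline,
                 blooms = blooms, warnings = warnings,
                 rare_thresh = rare_thresh,
                 abundant_thresh = abundant_thresh),
            class = "phase_timeline")
}

#' @export
print.phase_timeline <- function(x, ...) {
  cat(sprintf("phase_timeline for %s: %d dates, %d bloom(s), %d warning(s)\n",
              x$otu_id, nrow(x$timeline), nrow(x$blooms), nrow(x$warnings)))
  invisible(x)
}

#' Select the most abundant OTUs of the rDNA survey
#'
#' Ranks OTUs by their total reads (or total relative abundance) across all
#' samples and keeps the top `k` and/or those above a total-fraction floor.
#' Ties at the selection boundary break deterministically by OTU id.
#'
#' @param x an [otu_table()] or `rel_abundance` (typically the rDNA table).
#' @param k keep the `k` highest-ranked OTUs (`Inf` to disable).
#' @param min_total_frac additionally require the OTU's share of all reads
#'   to exceed this fraction (default 0, disabled).
#' @return List: `otus` (selected ids, by decreasing total), `share`
#'   (fraction of all reads carried by the selection), `totals` (named
#'   totals of the selected OTUs).
#' @export
top_abundant_otus <- function(x, k = 100L, min_total_frac = 0) {
  m <- community_matrix(x)
  tot <- colSums(m)
  ord <- order(-tot, colnames(m))
  tot <- tot[ord]
  sel <- seq_along(tot) <= k & tot / sum(tot) > min_total_frac
  list(otus = names(tot)[sel],
       share = sum(tot[sel]) / sum(tot),
       totals = tot[sel])
}
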