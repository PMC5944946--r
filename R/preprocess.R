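#' Remove dataset-wide singleton OTUs
#'
#' Drops every OTU whose total read count summed over all samples of the
#' table equals exactly one. Such "single singletons" are most likely
#' erroneous sequencing products and are removed before any downstream
#' analysis. The rule is applied per molecule dataset: filter the rDNA and
#' rRNA tables independently.
#'
#' @param x an [otu_table()].
#' @return The filtered [otu_table()]; all retained counts are unchanged.
#'   Warns if every OTU is a singleton (empty table returned).
#' @export
remove_dataset_singletons <- function(x) {
  tot <- otu_sums(x)
  keep <- tot != 1L
  if (!any(keep)) {
    warning("all OTUs are dataset singletons; empty table returned",
            call. = FALSE)
  }
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out
}

#' Remove metazoan OTUs
#'
#' 18S primers amplify metazoa as well; surveys of microbial eukaryotes
#' drop those OTUs using the taxonomy table.
#'
#' @param x an [otu_table()].
#' @param tax taxonomy data frame from [read_taxonomy()]; every OTU of `x`
#'   must be present.
#' @return The filtered [otu_table()].
#' @export
remove_metazoa <- function(x, tax) {
  ids <- colnames(x$counts)
  missing <- setdiff(ids, tax$otu_id)
  if (length(missing)) {
    stop("OTUs absent from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  flag <- tax$is_metazoa[match(ids, tax$otu_id)]
  out <- x
  out$counts <- x$counts[, !flag, drop = FALSE]
  out
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each library without replacement to a common depth so that
#' richness and diversity are comparable across libraries of unequal
#' sequencing effort. Deterministic given `seed`.
#'
#' @param x an [otu_table()].
#' @param depth target reads per sample; `"auto"` uses the minimum library
#'   size of `x`.
#' @param seed integer seed for the subsampling RNG.
#' @param drop_shallow if `TRUE`, samples shallower than `depth` are removed
#'   (with a message); if `FALSE` (default) such samples are an error.
#' @return The rarefied [otu_table()]; every retained row sums exactly to
#'   `depth`.
#' @export
rarefy <- function(x, depth = "auto", seed = 1L, drop_shallow = FALSE) {
  totals <- sample_sums(x)
  if (identical(depth, "auto")) depth <- min(totals)
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0) stop("depth must be positive", call. = FALSE)
  shallow <- totals < depth
  if (any(shallow)) {
    if (!drop_shallow) {
      stop("samples shallower than depth ", depth, ": ",
           paste(names(totals)[shallow], collapse = ", "),
           "; set drop_shallow = TRUE to remove them", call. = FALSE)
    }
    message("dropping ", sum(shallow), " sample(s) shallower than ", depth)
    x <- subset_otu_table(x, samples = !shallow)
  }
  out <- x
  out$counts <- with_local_seed(seed, {
    ## rrarefy warns when the table holds no singleton counts (its
    ## observed-counts heuristic); our validation already guarantees
    ## integer counts, so that warning is noise here
    m <- withCallingHandlers(
      vegan::rrarefy(x$counts, depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    storage.mode(m) <- "integer"
    m
  })
  dimnames(out$counts) <- dimnames(x$counts)
  out
}

## evaluate expr under a local RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Convert counts to per-sample relative abundances
#'
#' Divides every count by its library total, the scale on which the
#' rRNA:rDNA activity framework operates.
#'
#' @param x an [otu_table()].
#' @return A `rel_abundance` object: list with `values` (samples x OTUs
#'   matrix of fractions, each row summing to 1), `dates`, `molecule`.
#' @export
relative_abundance <- function(x) {
  totals <- sample_sums(x)
  if (any(totals == 0)) {
    stop("zero total reads in sample(s): ",
         paste(names(totals)[totals == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(values = x$counts / totals,
                 dates = x$dates, molecule = x$molecule),
            class = "rel_abundance")
}

#' @export
print.rel_abundance <- function(x, ...) {
  cat(sprintf("rel_abundance: %d samples x %d OTUs\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Run the standard filtering chain
#'
#' Convenience wrapper applying, in order: dataset-singleton removal,
#' metazoa removal, rarefaction, relative abundance. Returns the
#' intermediate tables plus a per-step report of what was removed.
#'
#' @inheritParams rarefy
#' @param x an [otu_table()].
#' @param tax taxonomy data frame ([read_taxonomy()]).
#' @return List with `table` (rarefied [otu_table()]), `rel`
#'   ([relative_abundance()] of it) and `report` (data frame: step, OTUs and
#'   samples retained).
#' @export
preprocess_table <- function(x, tax, depth = "auto", seed = 1L,
                             drop_shallow = FALSE) {
  steps <- list(input = x)
  steps$singletons_removed <- remove_dataset_singletons(x)
  steps$metazoa_removed <- remove_metazoa(steps$singletons_removed, tax)
  steps$rarefied <- rarefy(steps$metazoa_removed, depth = depth, seed = seed,
                           drop_shallow = drop_shallow)
  report <- data.frame(
    step = names(steps),
    n_samples = vapply(steps, function(t) nrow(t$counts), integer(1)),
    n_otus = vapply(steps, function(t) ncol(t$counts), integer(1)),
    total_reads = vapply(steps, function(t) sum(t$counts), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = steps$rarefied, rel = relative_abundance(steps$rarefied),
       report = report)
}
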