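#' Construct an OTU count table
#'
#' An `otu_table` holds a samples x OTUs matrix of non-negative integer read
#' counts together with per-sample metadata: the sampling date and the
#' molecule the library was built from (`"rDNA"` for the gene survey,
#' `"rRNA"` for the reverse-transcribed ribosomal RNA survey).
#'
#' @param counts integer matrix, samples in rows, OTUs in columns. Row and
#'   column names are used as sample and OTU identifiers.
#' @param dates sampling date of each sample (`Date` or something
#'   [as.Date()] accepts), one per row of `counts`.
#' @param molecule character vector, `"rDNA"` or `"rRNA"`, one per sample.
#'
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `dates` and `molecule`.
#'
#' @details Validation enforces: finite, non-negative, whole-number counts;
#'   unique sample and OTU identifiers; no duplicated (date, molecule) pair;
#'   and a positive total read count for every sample.
#'
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 2L, 3L, 0L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), c("OTU1", "OTU2", "OTU3")))
#' ot <- otu_table(m, dates = c("2014-03-04", "2014-03-31"),
#'                 molecule = c("rDNA", "rDNA"))
#' sample_sums(ot)
#' @export
otu_table <- function(counts, dates, molecule) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  }
  dates <- as.Date(dates)
  molecule <- as.character(molecule)
  obj <- structure(list(counts = counts, dates = dates, molecule = molecule),
                   class = "otu_table")
  validate_otu_table(obj)
}

validate_otu_table <- function(x) {
  counts <- x$counts
  if (!is.numeric(counts)) {
    stop("OTU counts must be numeric", call. = FALSE)
  }
  if (any(!is.finite(counts))) {
    stop("OTU counts must all be finite", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("OTU counts must be non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("OTU counts must be whole numbers", call. = FALSE)
  }
  storage.mode(x$counts) <- "integer"
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate OTU ids", call. = FALSE)
  }
  if (length(x$dates) != nrow(counts) || length(x$molecule) != nrow(counts)) {
    stop("'dates' and 'molecule' must have one entry per sample",
         call. = FALSE)
  }
  if (any(is.na(x$dates))) stop("unparseable sample dates", call. = FALSE)
  if (!all(x$molecule %in% c("rDNA", "rRNA"))) {
    stop("molecule labels must be 'rDNA' or 'rRNA'", call. = FALSE)
  }
  key <- paste(x$dates, x$molecule)
  if (anyDuplicated(key)) {
    stop("duplicate (date, molecule) pair: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (ncol(counts) > 0 && any(rowSums(counts) == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$molecule)),
                            as.integer(table(x$molecule))), collapse = ", ")))
  cat(sprintf("dates: %s .. %s; total reads: %s\n",
              min(x$dates), max(x$dates),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Per-sample and per-OTU read totals
#'
#' @param x an [otu_table()].
#' @return Named numeric vector of row (sample) or column (OTU) totals.
#' @export
sample_sums <- function(x) rowSums(x$counts)

#' @rdname sample_sums
#' @export
otu_sums <- function(x) colSums(x$counts)

#' Subset an OTU table
#'
#' @param x an [otu_table()].
#' @param samples,otus index vectors (logical, integer or names) selecting
#'   samples and/or OTUs; default keeps everything.
#' @return A validated [otu_table()].
#' @export
subset_otu_table <- function(x, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(x$counts))
  if (is.null(otus)) otus <- seq_len(ncol(x$counts))
  if (is.character(samples)) samples <- match(samples, rownames(x$counts))
  if (is.logical(samples)) samples <- which(samples)
  counts <- x$counts[samples, otus, drop = FALSE]
  otu_table(counts, dates = x$dates[samples], molecule = x$molecule[samples])
}

## ---- readers ----------------------------------------------------------

#' Read an OTU count table from disk
#'
#' Two dialects are supported. `"tsv"` expects a tab-delimited table whose
#' first three columns are `sample_id`, `date` and `molecule`, followed by
#' one integer column per OTU (the layout written by [write_otu_table()]).
#' `"mothur_shared"` expects the mothur `.shared` layout with leading
#' `label`, `Group` and `numOtus` columns; dates and molecule labels are not
#' part of that format and must then be supplied via `manifest`.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"mothur_shared"`.
#' @param manifest optional data frame as returned by [read_manifest()],
#'   used to attach dates/molecules to mothur `.shared` samples (matched on
#'   `library_id`). Required for `dialect = "mothur_shared"`.
#' @param transposed logical; for the `"tsv"` dialect only, set `TRUE` if
#'   the file stores OTUs as rows and samples as columns.
#' @return An [otu_table()]. Column order of the file is preserved.
#' @export
read_otu_table <- function(path, dialect = c("tsv", "mothur_shared"),
                           manifest = NULL, transposed = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      stop("malformed OTU table (", conditionMessage(e), "): ", path,
           call. = FALSE)
    })
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("malformed OTU table (empty or missing header): ", path,
         call. = FALSE)
  }
  if (dialect == "mothur_shared") {
    need <- c("label", "Group", "numOtus")
    if (!identical(tolower(names(raw)[1:3]), tolower(need))) {
      stop("malformed mothur shared header (expected label/Group/numOtus): ",
           path, call. = FALSE)
    }
    counts <- as.matrix(raw[, -(1:3), drop = FALSE])
    rownames(counts) <- as.character(raw[[2L]])
    if (any(raw[[3L]] != ncol(counts))) {
      stop("numOtus column disagrees with the number of OTU columns",
           call. = FALSE)
    }
    if (is.null(manifest)) {
      stop("a manifest is required to date mothur shared samples",
           call. = FALSE)
    }
    idx <- match(rownames(counts), manifest$library_id)
    if (any(is.na(idx))) {
      stop("samples absent from manifest: ",
           paste(rownames(counts)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    return(otu_table(check_integer_counts(counts, path),
                     dates = manifest$date[idx],
                     molecule = manifest$molecule[idx]))
  }
  if (transposed) {
    ids <- raw[[1L]]
    m <- t(as.matrix(raw[, -1L, drop = FALSE]))
    colnames(m) <- ids
    meta_cols <- c("date", "molecule")
    if (!all(meta_cols %in% colnames(m))) {
      stop("transposed TSV must carry 'date' and 'molecule' rows",
           call. = FALSE)
    }
    dates <- m[, "date"]
    molecule <- m[, "molecule"]
    counts <- m[, setdiff(colnames(m), meta_cols), drop = FALSE]
    storage.mode(counts) <- "double"
    return(otu_table(check_integer_counts(counts, path), dates, molecule))
  }
  need <- c("sample_id", "date", "molecule")
  if (!all(need %in% names(raw))) {
    stop("malformed OTU table header; need columns ",
         paste(need, collapse = ", "), ": ", path, call. = FALSE)
  }
  counts <- as.matrix(raw[, setdiff(names(raw), need), drop = FALSE])
  rownames(counts) <- as.character(raw$sample_id)
  otu_table(check_integer_counts(counts, path),
            dates = raw$date, molecule = raw$molecule)
}

check_integer_counts <- function(counts, path) {
  suppressWarnings(storage.mode(counts) <- "double")
  if (any(!is.finite(counts))) {
    stop("non-numeric or missing counts in ", path, call. = FALSE)
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 0)) {
    stop("counts must be non-negative integers in ", path, call. = FALSE)
  }
  counts
}

#' Write an OTU count table as tidy TSV
#'
#' Writes the layout [read_otu_table()]'s `"tsv"` dialect reads back:
#' columns `sample_id`, `date`, `molecule`, then one column per OTU.
#'
#' @param x an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$counts),
                   date = as.character(x$dates),
                   molecule = x$molecule,
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU taxonomy table
#'
#' Expects a TSV with columns `otu_id`, `supergroup`, `group`,
#' `closest_relative` and `pct_identity`. Supergroups outside the controlled
#' vocabulary (the eight eukaryote super-groups observed in coastal 18S
#' surveys, plus `"Metazoa"` and `"unclassified"`) are recoded to
#' `"unclassified"` with a warning. Metazoan OTUs are flagged so they can be
#' excluded from microbial analyses.
#'
#' @param path path to the taxonomy TSV.
#' @return A data frame (one row per OTU) with an extra logical column
#'   `is_metazoa`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tax <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("otu_id", "supergroup", "group", "closest_relative",
            "pct_identity")
  if (!all(need %in% names(tax))) {
    stop("taxonomy file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tax$otu_id)) {
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(tax$otu_id[duplicated(tax$otu_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(tax$pct_identity)) ||
      any(tax$pct_identity < 0 | tax$pct_identity > 100)) {
    stop("pct_identity must lie in [0, 100]", call. = FALSE)
  }
  known <- c(supergroup_vocabulary(), "Metazoa", "unclassified")
  bad <- !(tax$supergroup %in% known)
  if (any(bad)) {
    warning("unknown supergroup(s) recoded to 'unclassified': ",
            paste(unique(tax$supergroup[bad]), collapse = ", "),
            call. = FALSE)
    tax$supergroup[bad] <- "unclassified"
  }
  tax$is_metazoa <- tax$supergroup == "Metazoa"
  rownames(tax) <- tax$otu_id
  tax
}

#' Controlled supergroup vocabulary
#'
#' The eight eukaryotic super-groups recorded in the eastern English Channel
#' 18S surveys, in decreasing order of OTU richness.
#' @return Character vector.
#' @export
supergroup_vocabulary <- function() {
  c("Alveolata", "Stramenopiles", "Opisthokonta", "Hacrobia",
    "Archaeplastida", "Apusozoa", "Rhizaria", "Amoebozoa")
}

#' Read a sample manifest
#'
#' A manifest links each sequencing library to its sampling date and source
#' molecule, and joins the rDNA and rRNA libraries from the same date
#' through a shared `pair_id`.
#'
#' @param path TSV with columns `library_id`, `date`, `molecule`, `pair_id`.
#' @return A data frame with `date` parsed as `Date`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mf <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("library_id", "date", "molecule", "pair_id")
  if (!all(need %in% names(mf))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mf$date <- as.Date(mf$date)
  if (any(is.na(mf$date))) stop("unparseable manifest dates", call. = FALSE)
  key <- paste(mf$pair_id, mf$molecule)
  if (anyDuplicated(key)) {
    stop("pair_id maps to two libraries of the same molecule: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  for (mol in unique(mf$molecule)) {
    d <- mf$date[mf$molecule == mol]
    if (anyDuplicated(d)) {
      stop("duplicate dates within molecule ", mol, call. = FALSE)
    }
  }
  mf
}

#' Read an environmental-variable table
#'
#' @param path TSV with a `date` column followed by named environmental
#'   variables (attenuation coefficient, PAR, temperature, salinity, oxygen,
#'   pH, nutrients, POC/PON, SPM, chlorophyll a, N/P ...). Missing values
#'   are empty cells or `NA`; they are kept as `NA`, never imputed here.
#' @param check_nonnegative names of columns that must be >= 0 when present
#'   (concentrations); set `NULL` to skip.
#' @return A data frame with `date` parsed as `Date`.
#' @export
read_env_table <- function(path,
                           check_nonnegative = c("Kd", "PAR", "O2",
                                                 "NO3_NO2", "PO4", "SiOH4",
                                                 "POC", "PON", "SPM",
                                                 "Chl_a")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  env <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"date" %in% names(env)) {
    stop("environmental table needs a 'date' column", call. = FALSE)
  }
  env$date <- as.Date(env$date)
  vals <- env[setdiff(names(env), "date")]
  if (any(vapply(vals, function(v) any(is.infinite(v)), logical(1)))) {
    stop("environmental values must be finite or missing", call. = FALSE)
  }
  for (nm in intersect(check_nonnegative, names(env))) {
    if (any(env[[nm]] < 0, na.rm = TRUE)) {
      stop("negative values in concentration variable ", nm, call. = FALSE)
    }
  }
  env
}

#' Pair rDNA and rRNA libraries from the same date
#'
#' @param manifest data frame from [read_manifest()].
#' @param dna,rna [otu_table()]s holding the rDNA and rRNA libraries; sample
#'   ids must match manifest `library_id`s.
#' @return A list with `pairs` (data frame: `pair_id`, `date`,
#'   `dna_sample`, `rna_sample`) and `unpaired` (data frame of libraries
#'   whose mate is missing from the manifest or from the tables).
#' @export
pair_libraries <- function(manifest, dna, rna) {
  ids <- unique(manifest$pair_id)
  pairs <- list()
  unpaired <- list()
  for (pid in ids) {
    sub <- manifest[manifest$pair_id == pid, , drop = FALSE]
    d <- sub[sub$molecule == "rDNA", , drop = FALSE]
    r <- sub[sub$molecule == "rRNA", , drop = FALSE]
    d_ok <- nrow(d) == 1 && d$library_id %in% rownames(dna$counts)
    r_ok <- nrow(r) == 1 && r$library_id %in% rownames(rna$counts)
    if (d_ok && r_ok) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        pair_id = pid, date = d$date,
        dna_sample = d$library_id, rna_sample = r$library_id,
        stringsAsFactors = FALSE)
    } else {
      unpaired[[length(unpaired) + 1L]] <- sub
    }
  }
  list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(pair_id = character(), date = as.Date(character()),
                 dna_sample = character(), rna_sample = character(),
                 stringsAsFactors = FALSE),
    unpaired = if (length(unpaired)) do.call(rbind, unpaired) else
      manifest[0, , drop = FALSE]
  )
}
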