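#' Analysis configuration
#'
#' Bundles the tunable constants of the screening protocol: the CV cutoff used
#' to call a gene stably expressed, the number of top candidates carried into
#' RT-qPCR validation, and the sample quality-control thresholds.
#'
#' @param cv_cutoff CV (on the log2(x+1) scale) at or below which a gene is
#'   considered stably expressed. Default 0.3.
#' @param top_k Number of smallest-CV genes selected as candidate reference
#'   genes. Default 12.
#' @param min_alignment_rate Samples must have an alignment rate strictly
#'   greater than this fraction. Default 0.70.
#' @param min_replicates Minimum size of a biological replicate group after the
#'   alignment-rate and read-count filters. Default 2.
#' @param min_total_reads Samples with fewer total reads are excluded.
#'   Default 1e6.
#' @param normalization_method One of `"RC"`, `"FPKM"`, `"TPM"`, `"TMM"`,
#'   `"MOR"`.
#' @param rng_seed Integer seed used by simulation helpers.
#' @return A list of class `"AnalysisConfig"`.
#' @export
#' @examples
#' analysis_config(cv_cutoff = 0.25)
analysis_config <- function(cv_cutoff = 0.3, top_k = 12L,
                            min_alignment_rate = 0.70, min_replicates = 2L,
                            min_total_reads = 1e6,
                            normalization_method = "MOR", rng_seed = 1L) {
  stopifnot(is.numeric(cv_cutoff), length(cv_cutoff) == 1L, cv_cutoff > 0)
  stopifnot(top_k >= 1L)
  stopifnot(min_alignment_rate >= 0, min_alignment_rate <= 1)
  normalization_method <- match.arg(normalization_method, NORM_METHODS)
  structure(list(cv_cutoff = cv_cutoff, top_k = as.integer(top_k),
                 min_alignment_rate = min_alignment_rate,
                 min_replicates = as.integer(min_replicates),
                 min_total_reads = min_total_reads,
                 normalization_method = normalization_method,
                 rng_seed = as.integer(rng_seed)),
            class = "AnalysisConfig")
}

#' Construct a count matrix
#'
#' A `CountMatrix` holds raw (unnormalized) integer read counts, genes in rows
#' and samples in columns, plus optional per-gene effective lengths (bases)
#' needed for FPKM/TPM.
#'
#' @param counts Numeric matrix with unique rownames (gene ids) and colnames
#'   (sample ids); all entries must be non-negative integers.
#' @param lengths Optional numeric vector of positive gene lengths, either
#'   unnamed (aligned to `rownames(counts)`) or named by gene id.
#' @param allow_fractional Accept non-integer counts (e.g. multi-mapper
#'   weighted counting). Default `FALSE`.
#' @return An object of class `"CountMatrix"` with elements `counts` and
#'   `lengths`.
#' @export
count_matrix <- function(counts, lengths = NULL, allow_fractional = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (!allow_fractional && any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("non-integer count at gene '%s', sample '%s'; ",
                        "use allow_fractional = TRUE for weighted counts"),
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (!is.null(lengths)) {
    if (is.null(names(lengths))) {
      if (length(lengths) != nrow(counts))
        stop("lengths must align with the gene ids")
      names(lengths) <- rownames(counts)
    }
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths <= 0))
      stop("gene lengths must be positive and cover every gene")
  }
  structure(list(counts = counts, lengths = lengths), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$lengths)) "" else " (with gene lengths)"))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

# Coerce a plain matrix (or CountMatrix) to CountMatrix, inventing ids if absent.
as_count_matrix <- function(x, lengths = NULL, allow_fractional = FALSE) {
  if (inherits(x, "CountMatrix")) return(x)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  count_matrix(x, lengths = lengths, allow_fractional = allow_fractional)
}

# featureCounts annotation columns that are not samples
FC_ANNOT_COLS <- c("Chr", "Start", "End", "Strand", "Length")

#' Read a gene x sample count table
#'
#' Accepts either a plain delimited matrix (first column gene ids, remaining
#' columns numeric counts) or featureCounts output: leading `#` comment lines
#' are skipped and the `Chr`/`Start`/`End`/`Strand`/`Length` annotation columns
#' are recognized, with `Length` populating the gene lengths.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param length_column Name of the column holding per-gene effective lengths;
#'   default `"Length"` (the featureCounts convention).
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @param allow_fractional Accept non-integer counts. Default `FALSE`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, length_column = "Length", sep = NULL,
                        allow_fractional = FALSE) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"")
  if (ncol(df) < 2L) stop("count table needs a gene id column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1L, drop = FALSE]
  lengths <- NULL
  if (length_column %in% colnames(df)) {
    lengths <- as.numeric(df[[length_column]])
    names(lengths) <- ids
  }
  drop <- intersect(c(FC_ANNOT_COLS, length_column), colnames(df))
  df <- df[, setdiff(colnames(df), drop), drop = FALSE]
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn))
        stop(sprintf("non-numeric count at gene '%s', column '%s'",
                     ids[which(is.na(vn))[1L]], colnames(df)[j]))
      df[[j]] <- vn
    }
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  count_matrix(m, lengths = lengths, allow_fractional = allow_fractional)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 5L)
  first <- first[!startsWith(first, "#")][1L]
  if (is.na(first)) stop("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a delimited table
#'
#' Thin wrapper used by the command-line interface; writes a matrix or data
#' frame as TSV with an optional `# key=value` comment header.
#'
#' @param x Matrix or data frame.
#' @param path Output path.
#' @param comment Optional named character vector written as `# key=value`
#'   lines before the header.
#' @param sep Field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, comment = NULL, sep = "\t") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(sprintf("# %s=%s", names(comment), as.character(comment)), con)
  if (is.matrix(x)) x <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a Ct table
#'
#' Holds quantification-cycle (Ct/Cq) values from RT-qPCR, genes in rows and
#' samples in columns, with optional per-sample group labels (e.g. treatment)
#' and per-gene amplification factors E (default 2, i.e. perfect doubling).
#'
#' @param ct Numeric matrix of Ct values (finite and > 0; `NA` allowed for
#'   missing reactions) with gene rownames and sample colnames.
#' @param groups Optional character vector of per-sample labels, named by
#'   sample id or aligned to the columns.
#' @param efficiencies Per-gene amplification factor in (1, 3]; scalar or
#'   vector named by gene id. Default 2.
#' @return An object of class `"CtTable"`.
#' @export
ct_table <- function(ct, groups = NULL, efficiencies = 2) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(ct)) || anyDuplicated(colnames(ct)))
    stop("duplicate gene or sample id in Ct table")
  if (!is.numeric(ct)) stop("Ct values must be numeric")
  if (any(!is.na(ct) & (ct <= 0 | !is.finite(ct))))
    stop("Ct values must be finite and > 0")
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[colnames(ct)]
    if (length(groups) != ncol(ct) || anyNA(groups))
      stop("groups must label every sample")
    groups <- stats::setNames(as.character(groups), colnames(ct))
  }
  if (length(efficiencies) == 1L && is.null(names(efficiencies)))
    efficiencies <- stats::setNames(rep(efficiencies, nrow(ct)), rownames(ct))
  efficiencies <- efficiencies[rownames(ct)]
  if (anyNA(efficiencies) || any(efficiencies <= 1 | efficiencies > 3))
    stop("amplification efficiencies must lie in (1, 3] for every gene")
  structure(list(ct = ct, groups = groups,
                 efficiencies = stats::setNames(as.numeric(efficiencies), rownames(ct))),
            class = "CtTable")
}

#' @export
print.CtTable <- function(x, ...) {
  cat(sprintf("CtTable: %d genes x %d samples%s\n", nrow(x$ct), ncol(x$ct),
              if (is.null(x$groups)) ""
              else sprintf(" (%d groups)", length(unique(x$groups)))))
  invisible(x)
}

as_ct_table <- function(x, groups = NULL, efficiencies = 2) {
  if (inherits(x, "CtTable")) return(x)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  ct_table(x, groups = groups, efficiencies = efficiencies)
}

#' Read a Ct table
#'
#' Genes in rows, samples in columns. A row whose id is `group` (case
#' insensitive) is interpreted as per-sample group labels. Empty cells and
#' `NA` are recorded as missing.
#'
#' @inheritParams read_counts
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, sep = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  groups <- NULL
  grow <- which(tolower(ids) == "group")
  if (length(grow) == 1L) {
    groups <- stats::setNames(as.character(unlist(df[grow, ])), colnames(df))
    df <- df[-grow, , drop = FALSE]
    ids <- ids[-grow]
  }
  m <- as.matrix(as.data.frame(lapply(df, as.numeric), check.names = FALSE))
  rownames(m) <- ids
  ct_table(m, groups = groups)
}

#' Sequence sets
#'
#' A `SequenceSet` is a light container for nucleotide sequences with an
#' optional species tag per record, used for ortholog search, consensus
#' building and in-silico specificity scans. Sequences are stored uppercase
#' and must use IUPAC nucleotide codes only.
#'
#' @param ids Character vector of unique record ids.
#' @param sequences Character vector of non-empty nucleotide strings.
#' @param species Optional character vector of species tags (NA allowed).
#' @return An object of class `"SequenceSet"`.
#' @export
sequence_set <- function(ids, sequences, species = NULL) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) stop("ids and sequences must align")
  if (anyDuplicated(ids)) stop("duplicate sequence id")
  if (any(!nzchar(sequences))) stop("empty sequence record")
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", sequences)
  if (any(bad))
    stop("illegal (non-IUPAC) character in sequence: ", ids[which(bad)[1L]])
  if (is.null(species)) species <- rep(NA_character_, length(ids))
  structure(list(ids = ids, sequences = stats::setNames(sequences, ids),
                 species = stats::setNames(as.character(species), ids)),
            class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat(sprintf("SequenceSet: %d records (%d with species tags)\n",
              length(x$ids), sum(!is.na(x$species))))
  invisible(x)
}

#' @export
length.SequenceSet <- function(x) length(x$ids)

#' Read and write FASTA sequence sets
#'
#' `read_fasta()` parses a FASTA file into a [sequence_set()], uppercasing the
#' sequences. The species tag is taken from the header by splitting the first
#' whitespace-delimited token on `species_sep` and taking field
#' `species_field` (when present); the full token remains the record id.
#'
#' @param path FASTA file path.
#' @param species_sep Single character separating header fields; default `"|"`.
#' @param species_field 1-based index of the species field within the header
#'   token; default 2.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, species_sep = "|", species_field = 2L) {
  stopifnot(file.exists(path))
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("failed to parse FASTA: ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("no FASTA records in ", path)
  heads <- vapply(strsplit(names(x), "[ \t]"), `[[`, "", 1L)
  seqs <- toupper(as.character(x))
  if (any(!nzchar(seqs))) stop("empty FASTA record: ", heads[!nzchar(seqs)][1L])
  parts <- strsplit(heads, species_sep, fixed = TRUE)
  species <- vapply(parts, function(p)
    if (length(p) >= species_field) p[[species_field]] else NA_character_, "")
  sequence_set(heads, seqs, species)
}

#' @rdname read_fasta
#' @param set A [sequence_set()].
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(set, path, width = 70L) {
  stopifnot(inherits(set, "SequenceSet"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in set$ids) {
    writeLines(paste0(">", id), con)
    s <- set$sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Apply the sample quality-control filters
#'
#' Samples are filtered in a fixed, deterministic order: (1) alignment rate
#' must exceed `min_alignment_rate`; (2) total reads must reach
#' `min_total_reads`; (3) after those two filters, each biological replicate
#' group must retain at least `min_replicates` samples. The operation is
#' idempotent.
#'
#' @param meta Data frame with columns `sample_id`, `alignment_rate` (fraction
#'   in \[0,1\]), `total_reads`, `replicate_group`, and optionally `condition`.
#' @param cfg An [analysis_config()].
#' @param verbose Emit one message per exclusion decision.
#' @return A list with `kept` (character vector of retained sample ids, input
#'   order) and `excluded` (data frame of `sample_id`, `reason` with reasons
#'   `"alignment_rate"`, `"low_reads"`, `"replicates"`).
#' @export
filter_samples <- function(meta, cfg = analysis_config(), verbose = FALSE) {
  need <- c("sample_id", "alignment_rate", "total_reads", "replicate_group")
  if (!all(need %in% colnames(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(meta$alignment_rate < 0 | meta$alignment_rate > 1))
    stop("alignment_rate must be a fraction in [0, 1]")
  reason <- rep(NA_character_, nrow(meta))
  reason[meta$alignment_rate <= cfg$min_alignment_rate] <- "alignment_rate"
  ok <- is.na(reason)
  reason[ok & meta$total_reads < cfg$min_total_reads] <- "low_reads"
  ok <- is.na(reason)
  grp_n <- table(meta$replicate_group[ok])
  small <- names(grp_n)[grp_n < cfg$min_replicates]
  reason[ok & meta$replicate_group %in% small] <- "replicates"
  if (verbose) {
    for (i in which(!is.na(reason)))
      message(sprintf("excluding sample %s: %s", meta$sample_id[i], reason[i]))
  }
  list(kept = meta$sample_id[is.na(reason)],
       excluded = data.frame(sample_id = meta$sample_id[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}
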