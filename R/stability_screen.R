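#' Log2(x+1) transform of a normalized matrix
#'
#' All CV statistics in the screening protocol are computed on the
#' log2(value + 1) scale, which damps the influence of zeros and of very
#' highly expressed genes.
#'
#' @param m A `NormalizedMatrix` (values >= 0) from [normalize()].
#' @return The matrix with values `log2(x + 1)` and the `log2` flag set; the
#'   method tag gains a `+log2p1` marker.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "NormalizedMatrix"))
  if (m$log2) stop("matrix is already log2(x+1)-transformed")
  if (any(m$values < 0)) stop("log transform requires non-negative values")
  new_normalized_matrix(log2(m$values + 1),
                        paste0(m$method, "+log2p1"), log2 = TRUE)
}

#' Per-gene expression stability statistics
#'
#' Computes mean, sample standard deviation (n-1 denominator) and coefficient
#' of variation `cv = sd/mean` per gene across samples, on the log2(x+1)
#' scale. Genes whose transformed mean is zero (silent everywhere) get an
#' undefined CV (`NA`) and are flagged; they can never pass the stability
#' screen.
#'
#' @param m A log2(x+1)-transformed `NormalizedMatrix` (see [log_transform()]).
#'   Passing an untransformed matrix is an error: the protocol never computes
#'   CV on the linear scale.
#' @return Data frame with columns `gene_id`, `mean`, `sd`, `cv`,
#'   `n_samples`, `defined`.
#' @export
gene_cv_stats <- function(m) {
  stopifnot(inherits(m, "NormalizedMatrix"))
  if (!m$log2)
    stop("gene_cv_stats expects a log2(x+1)-transformed matrix; call log_transform() first")
  x <- m$values
  if (ncol(x) < 2L) stop("need at least two samples to compute CV")
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  data.frame(gene_id = rownames(x), mean = mu, sd = sdv, cv = cv,
             n_samples = ncol(x), defined = mu > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen stably expressed genes
#'
#' Returns the genes whose CV is defined and at most `cutoff` (inclusive).
#'
#' @param stats Data frame from [gene_cv_stats()].
#' @param cutoff CV cutoff, default 0.3.
#' @return Character vector of gene ids (input order), with attribute
#'   `n_screened`.
#' @export
screen_stable_genes <- function(stats, cutoff = 0.3) {
  stopifnot(is.numeric(cutoff), cutoff >= 0)
  keep <- !is.na(stats$cv) & stats$cv <= cutoff
  structure(stats$gene_id[keep], n_screened = sum(keep))
}

#' Select top-k candidate reference genes
#'
#' The `k` genes with the smallest defined CV, ascending; ties are broken by
#' smaller SD, then lexicographic gene id, so the selection is deterministic.
#'
#' @param stats Data frame from [gene_cv_stats()].
#' @param k Number of candidates, default 12.
#' @param exclude Optional gene ids to omit before selection.
#' @return Character vector of `k` gene ids in ascending-CV order.
#' @export
select_candidates <- function(stats, k = 12L, exclude = NULL) {
  s <- stats[!is.na(stats$cv), , drop = FALSE]
  if (!is.null(exclude)) s <- s[!s$gene_id %in% exclude, , drop = FALSE]
  if (nrow(s) < k)
    stop(sprintf("only %d genes with defined CV; cannot select %d", nrow(s), k))
  s <- s[order(s$cv, s$sd, s$gene_id), , drop = FALSE]
  s$gene_id[seq_len(k)]
}

#' Compare normalization methods by CV distributions
#'
#' Runs each normalization method, log2(x+1)-transforms, and summarizes (a)
#' per-sample lower/upper quartiles of the transformed values (the bar-plot
#' view of between-sample spread) and (b) the distribution of per-gene CVs
#' over all genes and over an optional designated gene set such as previously
#' reported reference genes.
#'
#' @param counts A [count_matrix()]; lengths are needed when FPKM/TPM are
#'   among `methods`.
#' @param gene_set Optional character vector of gene ids to summarize
#'   separately.
#' @param methods Methods to compare; default all five.
#' @param cutoff CV cutoff used only to report how many genes pass per method.
#' @return A list of class `"MethodComparisonSummary"`: per method, a list
#'   with `quartiles` (2 x samples matrix), `cv_all` and (when `gene_set` is
#'   given) `cv_set` (each: `median`, `mean`, `n_defined`), and `n_pass`.
#' @export
compare_normalizations <- function(counts, gene_set = NULL,
                                   methods = NORM_METHODS, cutoff = 0.3) {
  cm <- as_count_matrix(counts, allow_fractional = TRUE)
  out <- lapply(methods, function(meth) {
    lg <- log_transform(normalize(cm, meth))
    st <- gene_cv_stats(lg)
    q <- apply(lg$values, 2L, stats::quantile, probs = c(0.25, 0.75))
    rownames(q) <- c("lower", "upper")
    res <- list(quartiles = q, cv_all = cv_summary(st$cv),
                n_pass = length(screen_stable_genes(st, cutoff)))
    if (!is.null(gene_set)) {
      miss <- setdiff(gene_set, st$gene_id)
      if (length(miss)) stop("gene_set ids not in matrix: ",
                             paste(miss, collapse = ", "))
      res$cv_set <- cv_summary(st$cv[match(gene_set, st$gene_id)])
    }
    res
  })
  names(out) <- methods
  structure(out, class = "MethodComparisonSummary")
}

cv_summary <- function(cv) {
  ok <- !is.na(cv)
  list(median = stats::median(cv[ok]), mean = mean(cv[ok]),
       n_defined = sum(ok))
}

#' @export
print.MethodComparisonSummary <- function(x, ...) {
  cat("CV comparison across normalization methods\n")
  for (m in names(x)) {
    cat(sprintf("  %-4s median CV %.4f  mean CV %.4f  (pass: %d)", m,
                x[[m]]$cv_all$median, x[[m]]$cv_all$mean, x[[m]]$n_pass))
    if (!is.null(x[[m]]$cv_set))
      cat(sprintf("  | gene set: median %.4f mean %.4f",
                  x[[m]]$cv_set$median, x[[m]]$cv_set$mean))
    cat("\n")
  }
  invisible(x)
}

#' Evaluate a gene set on an independent dataset
#'
#' Restricts the CV statistics to a designated gene set (e.g. candidate
#' reference genes carried to a test dataset) and flags each gene as passing
#' or failing the CV cutoff. If the matrix is not yet log2(x+1)-transformed it
#' is transformed first, so CV is always computed on the log scale.
#'
#' @param m A `NormalizedMatrix`.
#' @param gene_ids Character vector of gene ids; all must be present.
#' @param cutoff CV cutoff, default 0.3.
#' @return Data frame of the per-gene statistics plus a logical `pass` column,
#'   in `gene_ids` order; empty input yields an empty data frame.
#' @export
evaluate_gene_set <- function(m, gene_ids, cutoff = 0.3) {
  stopifnot(inherits(m, "NormalizedMatrix"))
  if (!m$log2) m <- log_transform(m)
  stats <- gene_cv_stats(m)
  if (length(gene_ids) == 0L)
    return(cbind(stats[0, , drop = FALSE], pass = logical(0)))
  miss <- setdiff(gene_ids, stats$gene_id)
  if (length(miss))
    stop("gene ids absent from matrix: ", paste(miss, collapse = ", "))
  out <- stats[match(gene_ids, stats$gene_id), , drop = FALSE]
  out$pass <- !is.na(out$cv) & out$cv <= cutoff
  rownames(out) <- NULL
  out
}
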