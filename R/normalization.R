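NORM_METHODS <- c("RC", "FPKM", "TPM", "TMM", "MOR")

new_size_factors <- function(factors, method) {
  structure(factors, method = method, class = "SizeFactors")
}

#' @export
print.SizeFactors <- function(x, ...) {
  cat(sprintf("%s size factors:\n", attr(x, "method")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The between-sample scaling used by the median-of-ratios (MOR) method: a
#' pseudo-reference is formed per gene as the geometric mean of its counts
#' across samples, restricted to genes with a nonzero count in every sample;
#' the size factor of a sample is the median over those genes of the ratio of
#' its count to the pseudo-reference.
#'
#' @param counts A [count_matrix()] or numeric matrix of raw counts.
#' @return Named numeric vector of positive size factors (class
#'   `"SizeFactors"`, method `"MOR"`).
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors_median_of_ratios(m)
size_factors_median_of_ratios <- function(counts) {
  cm <- as_count_matrix(counts, allow_fractional = TRUE)
  x <- cm$counts
  if (ncol(x) < 2L) stop("median-of-ratios needs at least two samples")
  pos <- rowSums(x == 0) == 0L
  if (!any(pos))
    stop(paste("no gene has nonzero counts in every sample;",
               "filter to expressed genes before computing size factors"))
  ref <- exp(rowMeans(log(x[pos, , drop = FALSE])))
  f <- apply(x[pos, , drop = FALSE], 2L, function(col) stats::median(col / ref))
  new_size_factors(f, "MOR")
}

#' Trimmed mean of M-values (TMM) size factors
#'
#' Between-sample scaling from a doubly trimmed, precision-weighted mean of
#' per-gene log2 expression ratios (M values) against a reference sample. The
#' reference is the sample whose upper-quartile count fraction is closest to
#' the mean of those fractions. Per comparison, genes with nonzero counts in
#' both samples contribute M = log2((x/N)/(r/N_r)) and
#' A = 0.5 log2((x/N)(r/N_r)); the most extreme 30 percent of M ranks and 5
#' percent of A ranks are discarded from each tail, and the remaining M are
#' averaged with inverse approximate-variance weights. Factors are rescaled
#' to geometric mean 1.
#'
#' @param counts A [count_matrix()] or numeric matrix of raw counts.
#' @param ref_sample Optional sample id (or index) to use as reference.
#' @param logratio_trim,sum_trim Tail trim fractions for M and A ranks.
#' @return Named numeric vector of positive factors (class `"SizeFactors"`,
#'   method `"TMM"`), geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  cm <- as_count_matrix(counts, allow_fractional = TRUE)
  x <- cm$counts
  if (ncol(x) < 2L) stop("TMM needs at least two samples")
  N <- colSums(x)
  if (any(N <= 0)) stop("every sample must have a positive library size")
  if (is.null(ref_sample)) {
    uq <- apply(x, 2L, stats::quantile, probs = 0.75) / N
    ref_sample <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    ref_sample <- match(ref_sample, colnames(x))
    if (is.na(ref_sample)) stop("ref_sample not found among sample ids")
  }
  r <- x[, ref_sample]
  Nr <- N[ref_sample]
  logf <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair_logfactor(x[, j], N[j], r, Nr, logratio_trim, sum_trim)
  }, 0)
  f <- 2^logf
  f <- f / exp(mean(log(f)))
  new_size_factors(stats::setNames(f, colnames(x)), "TMM")
}

# Weighted trimmed log2 factor of one sample against the reference.
tmm_pair_logfactor <- function(xj, Nj, r, Nr, logratio_trim, sum_trim) {
  keep <- xj > 0 & r > 0
  xk <- xj[keep]; rk <- r[keep]
  if (length(xk) == 0L) {
    warning("no gene expressed in both sample and reference; TMM factor set to 1")
    return(0)
  }
  M <- log2((xk / Nj) / (rk / Nr))
  A <- 0.5 * log2((xk / Nj) * (rk / Nr))
  if (max(abs(M)) < 1e-6) return(0)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) {
    warning("TMM trim left no genes; factor set to 1")
    return(0)
  }
  w <- 1 / ((Nj - xk) / (Nj * xk) + (Nr - rk) / (Nr * rk))
  sum(M[keep2] * w[keep2]) / sum(w[keep2])
}

new_normalized_matrix <- function(values, method, log2 = FALSE) {
  structure(list(values = values, method = method, log2 = log2),
            class = "NormalizedMatrix")
}

#' Construct a normalized expression matrix
#'
#' Wraps an expression matrix with its normalization-method tag and a flag
#' saying whether values are already on the log2(x+1) scale. Mostly useful
#' for feeding externally normalized values into the CV screen.
#'
#' @param values Numeric matrix (genes x samples) with dimnames.
#' @param method Method tag, e.g. `"MOR"` or `"external"`.
#' @param log2 Whether `values` are already log2(x+1)-transformed.
#' @return An object of class `"NormalizedMatrix"`.
#' @export
normalized_matrix <- function(values, method = "external", log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite and numeric")
  new_normalized_matrix(values, method, log2)
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (%s%s): %d genes x %d samples\n", x$method,
              if (x$log2) ", log2(x+1)" else "", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (library_size * length)`.
#'
#' @param counts A [count_matrix()] with gene lengths.
#' @return A `NormalizedMatrix` with method `"FPKM"`.
#' @export
fpkm <- function(counts) {
  cm <- as_count_matrix(counts, allow_fractional = TRUE)
  if (is.null(cm$lengths))
    stop("FPKM requires per-gene effective lengths")
  N <- colSums(cm$counts)
  v <- cm$counts * 1e9 / outer(cm$lengths, N)
  new_normalized_matrix(v, "FPKM")
}

#' TPM normalization
#'
#' Transcripts per million: length-normalized rates `count/length` rescaled so
#' each sample column sums to one million. All-zero samples stay all zero (with
#' a warning).
#'
#' @param counts A [count_matrix()] with gene lengths.
#' @return A `NormalizedMatrix` with method `"TPM"`.
#' @export
tpm <- function(counts) {
  cm <- as_count_matrix(counts, allow_fractional = TRUE)
  if (is.null(cm$lengths))
    stop("TPM requires per-gene effective lengths")
  rate <- cm$counts / cm$lengths
  tot <- colSums(rate)
  if (any(tot == 0)) warning("all-zero sample(s); TPM column left at zero")
  tot[tot == 0] <- 1
  v <- sweep(rate, 2L, tot, "/") * 1e6
  new_normalized_matrix(v, "TPM")
}

#' Normalize a count matrix
#'
#' Dispatch over the five supported expression scales: `"RC"` returns the raw
#' counts unchanged; `"FPKM"` and `"TPM"` are within-sample length/depth
#' normalizations; `"TMM"` divides by `library size x TMM factor` and scales
#' per million (CPM on effective library sizes); `"MOR"` divides each sample
#' column by its median-of-ratios size factor.
#'
#' @param counts A [count_matrix()] (lengths required for FPKM/TPM).
#' @param method One of `"RC"`, `"FPKM"`, `"TPM"`, `"TMM"`, `"MOR"`.
#' @return A `NormalizedMatrix` carrying the method tag.
#' @export
normalize <- function(counts, method = c("RC", "FPKM", "TPM", "TMM", "MOR")) {
  if (length(method) != 1L || !method %in% NORM_METHODS)
    stop("unknown normalization method; valid: ", paste(NORM_METHODS, collapse = ", "))
  cm <- as_count_matrix(counts, allow_fractional = TRUE)
  switch(method,
    RC = new_normalized_matrix(cm$counts, "RC"),
    FPKM = fpkm(cm),
    TPM = tpm(cm),
    TMM = {
      f <- tmm_factors(cm)
      eff <- colSums(cm$counts) * as.numeric(f)
      new_normalized_matrix(sweep(cm$counts, 2L, eff, "/") * 1e6, "TMM")
    },
    MOR = {
      f <- size_factors_median_of_ratios(cm)
      new_normalized_matrix(sweep(cm$counts, 2L, as.numeric(f), "/"), "MOR")
    })
}
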