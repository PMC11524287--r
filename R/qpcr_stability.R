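#' Relative quantities from Ct values
#'
#' Transforms quantification cycles to relative quantities with the
#' highest-expression calibrator convention: per gene,
#' `q_i = E^(min(Ct) - Ct_i)` with amplification factor E (default 2), so the
#' sample with the lowest Ct has q = 1 and `log2(q) <= 0`.
#'
#' @param ct A [ct_table()] or numeric matrix of Ct values.
#' @return List with matrices `q` and `log_q` (log2 scale).
#' @export
relative_quantities <- function(ct) {
  tab <- as_ct_table(ct)
  x <- tab$ct
  E <- tab$efficiencies
  minct <- apply(x, 1L, min, na.rm = TRUE)
  log_q <- (minct - x) * log2(E)  # recycles E down columns gene-wise
  q <- 2^log_q
  list(q = q, log_q = log_q)
}

# Pairwise-complete SD of the per-sample difference of two rows.
pair_sd <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  stats::sd(a[ok] - b[ok])
}

#' Delta-Ct stability scores
#'
#' For every gene pair the standard deviation (n-1) of the per-sample Ct
#' difference is computed; a gene's score is the mean of those SDs over all
#' its partners. Lower scores mean more stable expression. Pairs sharing
#' fewer than two samples are skipped with a warning.
#'
#' @param ct A [ct_table()] or Ct matrix (>= 2 genes, >= 2 samples).
#' @return Named numeric vector of per-gene scores.
#' @export
delta_ct_stability <- function(ct) {
  x <- as_ct_table(ct)$ct
  G <- nrow(x)
  if (G < 2L || ncol(x) < 2L) stop("need at least 2 genes and 2 samples")
  S <- matrix(NA_real_, G, G)
  for (j in seq_len(G - 1L)) for (k in (j + 1L):G) {
    S[j, k] <- S[k, j] <- pair_sd(x[j, ], x[k, ])
  }
  if (anyNA(S[upper.tri(S)]))
    warning("some gene pairs share < 2 samples and were skipped")
  score <- vapply(seq_len(G), function(j) mean(S[j, -j], na.rm = TRUE), 0)
  if (any(!is.finite(score)))
    stop("gene with no valid pairing: ",
         paste(rownames(x)[!is.finite(score)], collapse = ", "))
  stats::setNames(score, rownames(x))
}

#' geNorm expression stability (M values)
#'
#' Works on log2 relative quantities. The pairwise variation of genes j and k
#' is the SD over samples of `log2(q_j/q_k)`; a gene's M value is the mean of
#' its pairwise variations. Genes are then excluded iteratively (largest M
#' first, M recomputed on the remaining set) down to the final most-stable
#' pair. Optionally reports geNorm's pairwise-variation statistic
#' `V_{n/n+1}`, the SD over samples of `log2(NF_n/NF_{n+1})` where `NF_n` is
#' the per-sample geometric mean of the n most stable genes' quantities.
#'
#' @param ct A [ct_table()] or Ct matrix (>= 2 genes).
#' @param compute_v Also compute `V_{n/n+1}` for n = 2..G-1. Default `TRUE`.
#' @return List with `M` (initial M value per gene), `exclusion_order`
#'   (ids in order of removal; the final two are the most stable pair,
#'   appended last), `ranking` (most stable first; the final pair shares
#'   ranks 1-2), and `V` (named vector, or `NULL`).
#' @export
genorm <- function(ct, compute_v = TRUE) {
  tab <- as_ct_table(ct)
  lq <- relative_quantities(tab)$log_q
  G <- nrow(lq)
  if (G < 2L) stop("geNorm needs at least two genes")
  m_values <- function(mat) {
    g <- nrow(mat)
    vapply(seq_len(g), function(j)
      mean(vapply(setdiff(seq_len(g), j), function(k)
        pair_sd(mat[j, ], mat[k, ]), 0)), 0)
  }
  M0 <- stats::setNames(m_values(lq), rownames(lq))
  excl <- character(0)
  cur <- lq
  while (nrow(cur) > 2L) {
    M <- m_values(cur)
    # ties: drop the lexicographically later id for determinism
    worst <- which(M == max(M))
    worst <- worst[order(rownames(cur)[worst], decreasing = TRUE)][1L]
    excl <- c(excl, rownames(cur)[worst])
    cur <- cur[-worst, , drop = FALSE]
  }
  # the stepwise procedure cannot split the final pair; order it by the
  # full-set M values (then id) so the ranking stays fully informative
  pair <- rownames(cur)[order(M0[rownames(cur)], rownames(cur))]
  exclusion_order <- c(excl, rev(pair))
  ranking <- rev(exclusion_order)
  V <- NULL
  if (compute_v && G >= 3L) {
    q <- 2^lq
    stable_first <- ranking
    nf <- function(n) {
      sub <- q[stable_first[seq_len(n)], , drop = FALSE]
      exp(colMeans(log(sub)))
    }
    ns <- 2:(G - 1L)
    V <- vapply(ns, function(n) stats::sd(log2(nf(n) / nf(n + 1L))), 0)
    names(V) <- sprintf("V%d/%d", ns, ns + 1L)
  }
  list(M = M0, exclusion_order = exclusion_order, ranking = ranking, V = V)
}

#' NormFinder stability scores
#'
#' Model-based variance decomposition on log2 relative quantities. In the
#' ungrouped mode each value is double-centered (sample effect = column mean,
#' gene effect = row mean of the column-centered values); a gene's raw
#' variability is the sample variance of its residuals, bias-adjusted by
#' subtracting the mean residual variance of the other genes divided by
#' (G - 1), floored at zero, and reported as an SD. In grouped mode the same
#' residual analysis is done within each group and combined with the absolute
#' inter-group deviation of the gene: score = mean |group effect| + mean
#' intra-group SD. Lower is more stable.
#'
#' @param ct A [ct_table()] or Ct matrix.
#' @param groups Optional per-sample labels; defaults to the table's groups.
#'   Each group must contain at least two samples.
#' @return Named numeric vector of per-gene stability scores.
#' @export
normfinder <- function(ct, groups = NULL) {
  tab <- as_ct_table(ct)
  if (is.null(groups)) groups <- tab$groups
  lq <- relative_quantities(tab)$log_q
  if (anyNA(lq)) {
    drop <- rownames(lq)[rowSums(is.na(lq)) > 0]
    warning("dropping genes with missing Ct from NormFinder: ",
            paste(drop, collapse = ", "))
    lq <- lq[setdiff(rownames(lq), drop), , drop = FALSE]
  }
  if (nrow(lq) < 3L) stop("NormFinder needs at least three complete genes")
  if (is.null(groups)) return(normfinder_scores(lq))
  groups <- as.character(groups)
  tab_n <- table(groups)
  if (any(tab_n < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab_n)[tab_n < 2L], collapse = ", "))
  G <- nrow(lq)
  gl <- unique(groups)
  intra <- sapply(gl, function(g)
    normfinder_scores(lq[, groups == g, drop = FALSE]))
  # inter-group effect: deviation of a gene's group mean (gene-centered)
  # from its overall mean across groups
  centered <- sweep(lq, 2L, colMeans(lq))
  gmeans <- sapply(gl, function(g)
    rowMeans(centered[, groups == g, drop = FALSE]))
  eff <- gmeans - rowMeans(gmeans)
  score <- rowMeans(abs(eff)) + rowMeans(intra)
  stats::setNames(score, rownames(lq))
}

# Ungrouped NormFinder: double-centering residual SD with bias adjustment.
normfinder_scores <- function(lq) {
  G <- nrow(lq)
  y <- sweep(lq, 2L, colMeans(lq))       # remove sample effect
  d <- sweep(y, 1L, rowMeans(y))         # remove gene effect
  v <- apply(d, 1L, stats::var)
  adj <- vapply(seq_len(G), function(j) mean(v[-j]) / (G - 1L), 0)
  stats::setNames(sqrt(pmax(v - adj, 0)), rownames(lq))
}

#' BestKeeper descriptive stability statistics
#'
#' Operates on raw Ct values. Per gene: SD (n-1) and percent CV
#' (`100 * SD / mean`) of its Ct values; the BestKeeper index is the
#' per-sample geometric mean of Ct over the genes with complete rows, and
#' each gene's `r` is the Pearson correlation of its Ct with the index.
#' Genes are ranked by ascending SD.
#'
#' @param ct A [ct_table()] or Ct matrix.
#' @return List with data frame `stats` (`gene_id`, `sd`, `cv_pct`, `r`,
#'   `in_index`), numeric `index` per sample, and `ranking` (gene ids by
#'   ascending SD).
#' @export
bestkeeper <- function(ct) {
  x <- as_ct_table(ct)$ct
  sdv <- apply(x, 1L, stats::sd, na.rm = TRUE)
  mu <- rowMeans(x, na.rm = TRUE)
  cv_pct <- 100 * sdv / mu
  complete <- rowSums(is.na(x)) == 0L
  if (!any(complete)) stop("no gene has complete Ct values; cannot form index")
  if (!all(complete))
    warning("genes with missing Ct excluded from the BestKeeper index: ",
            paste(rownames(x)[!complete], collapse = ", "))
  index <- exp(colMeans(log(x[complete, , drop = FALSE])))
  r <- vapply(seq_len(nrow(x)), function(j) {
    ok <- !is.na(x[j, ])
    if (stats::sd(index[ok]) == 0 || stats::sd(x[j, ok]) == 0) return(NA_real_)
    stats::cor(x[j, ok], index[ok])
  }, 0)
  stats <- data.frame(gene_id = rownames(x), sd = sdv, cv_pct = cv_pct, r = r,
                      in_index = complete, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(stats = stats, index = stats::setNames(index, colnames(x)),
       ranking = stats$gene_id[order(stats$sd, stats$gene_id)])
}

#' Geometric-mean comprehensive ranking
#'
#' Combines the four per-algorithm rank vectors into
#' `geomean_rank = (r_deltaCt * r_geNorm * r_NormFinder * r_BestKeeper)^(1/4)`
#' and orders genes ascending; ties are broken by the delta-Ct rank, then by
#' gene id.
#'
#' @param ranks A list with components `deltaCt`, `geNorm`, `NormFinder`,
#'   `BestKeeper`, each a numeric rank vector named by gene id (1 = most
#'   stable).
#' @return Data frame `gene_id`, the four ranks, `geomean_rank`,
#'   `final_rank`, ordered by `final_rank`.
#' @export
comprehensive_rank <- function(ranks) {
  need <- c("deltaCt", "geNorm", "NormFinder", "BestKeeper")
  miss <- setdiff(need, names(ranks))
  if (length(miss))
    stop("missing algorithm rank(s): ", paste(miss, collapse = ", "))
  ids <- names(ranks$deltaCt)
  for (a in need) {
    if (!setequal(names(ranks[[a]]), ids))
      stop("rank vectors must cover the same genes")
    ranks[[a]] <- ranks[[a]][ids]
  }
  gm <- (ranks$deltaCt * ranks$geNorm * ranks$NormFinder * ranks$BestKeeper)^(1 / 4)
  out <- data.frame(gene_id = ids, deltaCt = ranks$deltaCt,
                    geNorm = ranks$geNorm, NormFinder = ranks$NormFinder,
                    BestKeeper = ranks$BestKeeper, geomean_rank = gm,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$geomean_rank, out$deltaCt, out$gene_id), , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full four-algorithm stability report
#'
#' Runs delta-Ct, geNorm, NormFinder and BestKeeper on a Ct table, ranks
#' genes within each algorithm (1 = most stable) and combines the ranks by
#' their geometric mean.
#'
#' For the rank vectors: delta-Ct, NormFinder and BestKeeper rank by
#' ascending score/SD; geNorm ranks by its stepwise exclusion order, the
#' final most-stable pair sharing ranks 1 and 2 in id order.
#'
#' @param ct A [ct_table()] or Ct matrix.
#' @param groups Optional per-sample group labels for NormFinder.
#' @return A list of class `"StabilityReport"`: `table` (per-gene scores,
#'   ranks, `geomean_rank`, `final_rank`), `genorm` (full geNorm output) and
#'   `bestkeeper` (full BestKeeper output).
#' @export
qpcr_rank <- function(ct, groups = NULL) {
  tab <- as_ct_table(ct)
  dsc <- delta_ct_stability(tab)
  gn <- genorm(tab)
  nf <- normfinder(tab, groups = groups)
  bk <- bestkeeper(tab)
  ids <- rownames(tab$ct)
  rank_of <- function(score) rank(score, ties.method = "average")
  r_d <- stats::setNames(rank_of(dsc[ids]), ids)
  r_g <- stats::setNames(match(ids, gn$ranking), ids)
  nf_full <- stats::setNames(rep(NA_real_, length(ids)), ids)
  nf_full[names(nf)] <- nf
  r_n <- stats::setNames(rank_of(nf_full), ids)
  r_b <- stats::setNames(rank_of(bk$stats$sd[match(ids, bk$stats$gene_id)]), ids)
  comp <- comprehensive_rank(list(deltaCt = r_d, geNorm = r_g,
                                  NormFinder = r_n, BestKeeper = r_b))
  scores <- data.frame(gene_id = comp$gene_id,
                       deltaCt_score = dsc[comp$gene_id],
                       genorm_M = gn$M[comp$gene_id],
                       normfinder_score = nf_full[comp$gene_id],
                       bestkeeper_sd = bk$stats$sd[match(comp$gene_id, bk$stats$gene_id)],
                       bestkeeper_cv_pct = bk$stats$cv_pct[match(comp$gene_id, bk$stats$gene_id)],
                       bestkeeper_r = bk$stats$r[match(comp$gene_id, bk$stats$gene_id)],
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = cbind(scores, comp[, -1L]),
                 genorm = gn, bestkeeper = bk),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat("RT-qPCR stability report (lower rank = more stable)\n")
  print(x$table[, c("gene_id", "deltaCt_score", "genorm_M",
                    "normfinder_score", "bestkeeper_sd",
                    "geomean_rank", "final_rank")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Standard-curve amplification efficiency
#'
#' Fits `Ct = slope * x + intercept` by ordinary least squares to a dilution
#' series (x = log10 relative template concentration) and derives the
#' amplification factor `E = 10^(-1/slope)` and percent efficiency
#' `(E - 1) * 100`. A curve is flagged reliable when the percent efficiency
#' lies in the closed band \[90, 115\]. Curves with non-negative slope are
#' invalid and report no efficiency.
#'
#' @param points Data frame or matrix with two columns: log10 dilution and Ct
#'   (>= 3 points, distinct x).
#' @return List of class `"StandardCurve"`: `slope`, `intercept`,
#'   `r_squared`, `E`, `efficiency_pct`, `reliable`, `valid`.
#' @export
standard_curve <- function(points) {
  points <- as.data.frame(points)
  if (ncol(points) < 2L) stop("points must have columns (log10 dilution, Ct)")
  x <- as.numeric(points[[1L]]); y <- as.numeric(points[[2L]])
  if (length(x) < 3L) stop("need at least 3 dilution points")
  if (length(unique(x)) < 2L) stop("dilution points must span distinct x values")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- stats::cor(x, y)^2
  valid <- slope < 0
  E <- if (valid) 10^(-1 / slope) else NA_real_
  eff <- if (valid) (E - 1) * 100 else NA_real_
  # tolerance so exact band-edge efficiencies are not lost to rounding
  tol <- 1e-9
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 E = E, efficiency_pct = eff,
                 reliable = valid && eff >= 90 - tol && eff <= 115 + tol,
                 valid = valid),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("Invalid standard curve (slope %.4f >= 0)\n", x$slope))
  } else {
    cat(sprintf("Standard curve: slope %.4f, R2 %.4f, E %.4f (%.2f%%), %s\n",
                x$slope, x$r_squared, x$E, x$efficiency_pct,
                if (x$reliable) "reliable [90-115%]" else "outside 90-115% band"))
  }
  invisible(x)
}

#' Collapse technical replicate columns
#'
#' Averages Ct columns sharing a sample label (e.g. `s1_a`, `s1_b` with
#' labels `s1`, `s1`), the conventional pre-processing before stability
#' analysis, which expects one averaged Ct per biological sample.
#'
#' @param ct A [ct_table()] or Ct matrix.
#' @param labels Per-column sample labels defining the collapsing.
#' @return A [ct_table()] with one column per unique label (first-seen order).
#' @export
collapse_replicates <- function(ct, labels) {
  tab <- as_ct_table(ct)
  if (length(labels) != ncol(tab$ct)) stop("one label per column required")
  labs <- unique(labels)
  m <- sapply(labs, function(l)
    rowMeans(tab$ct[, labels == l, drop = FALSE], na.rm = TRUE))
  m[is.nan(m)] <- NA_real_
  groups <- if (!is.null(tab$groups)) {
    stats::setNames(tab$groups[match(labs, labels)], labs)
  } else NULL
  colnames(m) <- labs
  ct_table(m, groups = groups, efficiencies = tab$efficiencies)
}
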