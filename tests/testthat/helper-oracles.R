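# Independent straight-line oracles: loop-based recomputations of every
# statistic from its defining formula, sharing no code with the package.

oracle_mor <- function(m) {
  keep <- which(apply(m, 1, function(r) all(r > 0)))
  ref <- numeric(length(keep))
  for (i in seq_along(keep)) ref[i] <- prod(m[keep[i], ])^(1 / ncol(m))
  f <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(length(keep))
    for (i in seq_along(keep)) ratios[i] <- m[keep[i], j] / ref[i]
    f[j] <- median(ratios)
  }
  f
}

oracle_tmm <- function(m, logratio_trim = 0.3, sum_trim = 0.05) {
  N <- colSums(m)
  uq <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) uq[j] <- quantile(m[, j], 0.75) / N[j]
  ref <- which.min(abs(uq - mean(uq)))
  lf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep <- m[, j] > 0 & m[, ref] > 0
    x <- m[keep, j]; r <- m[keep, ref]
    M <- log2((x / N[j]) / (r / N[ref]))
    A <- 0.5 * log2((x / N[j]) * (r / N[ref]))
    if (max(abs(M)) < 1e-6) { lf[j] <- 0; next }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    w <- 1 / ((N[j] - x) / (N[j] * x) + (N[ref] - r) / (N[ref] * r))
    lf[j] <- sum((M * w)[sel]) / sum(w[sel])
  }
  f <- 2^lf
  f / exp(mean(log(f)))
}

# all-pairs SD of Ct differences
oracle_deltact <- function(ct) {
  G <- nrow(ct)
  score <- numeric(G)
  for (j in seq_len(G)) {
    sds <- numeric(0)
    for (k in seq_len(G)) {
      if (k == j) next
      sds <- c(sds, sd(ct[j, ] - ct[k, ]))
    }
    score[j] <- mean(sds)
  }
  setNames(score, rownames(ct))
}

# geNorm on log2 relative quantities with E = 2: M values and stepwise
# exclusion recomputing pairwise SDs at every iteration
oracle_genorm <- function(ct) {
  lq <- ct
  for (j in seq_len(nrow(ct))) lq[j, ] <- (min(ct[j, ]) - ct[j, ]) * 1
  m_of <- function(mat) {
    g <- nrow(mat)
    M <- numeric(g)
    for (j in seq_len(g)) {
      s <- numeric(0)
      for (k in seq_len(g)) {
        if (k == j) next
        s <- c(s, sd(mat[j, ] - mat[k, ]))
      }
      M[j] <- mean(s)
    }
    setNames(M, rownames(mat))
  }
  M0 <- m_of(lq)
  cur <- lq
  excl <- character(0)
  while (nrow(cur) > 2) {
    M <- m_of(cur)
    worst <- which(M == max(M))
    if (length(worst) > 1)
      worst <- worst[order(rownames(cur)[worst], decreasing = TRUE)][1]
    excl <- c(excl, rownames(cur)[worst])
    cur <- cur[-worst, , drop = FALSE]
  }
  # final pair ordered by full-set M (worse first)
  pair <- rownames(cur)[order(M0[rownames(cur)], rownames(cur))]
  list(M = M0, exclusion_order = c(excl, pair[2], pair[1]))
}

# NormFinder ungrouped: explicit double-centering + bias adjustment
oracle_normfinder <- function(ct) {
  G <- nrow(ct); S <- ncol(ct)
  lq <- matrix(0, G, S)
  for (j in seq_len(G)) lq[j, ] <- (min(ct[j, ]) - ct[j, ]) * 1
  d <- matrix(0, G, S)
  for (i in seq_len(S)) {
    colmean <- mean(lq[, i])
    for (j in seq_len(G)) d[j, i] <- lq[j, i] - colmean
  }
  for (j in seq_len(G)) d[j, ] <- d[j, ] - mean(d[j, ])
  v <- numeric(G)
  for (j in seq_len(G)) v[j] <- sum(d[j, ]^2) / (S - 1)
  score <- numeric(G)
  for (j in seq_len(G)) score[j] <- sqrt(max(v[j] - mean(v[-j]) / (G - 1), 0))
  setNames(score, rownames(ct))
}

oracle_bestkeeper <- function(ct) {
  G <- nrow(ct); S <- ncol(ct)
  sds <- cvs <- rs <- numeric(G)
  idx <- numeric(S)
  for (i in seq_len(S)) idx[i] <- prod(ct[, i])^(1 / G)
  for (j in seq_len(G)) {
    sds[j] <- sd(ct[j, ])
    cvs[j] <- 100 * sd(ct[j, ]) / mean(ct[j, ])
    rs[j] <- cor(ct[j, ], idx)
  }
  list(sd = setNames(sds, rownames(ct)), cv_pct = setNames(cvs, rownames(ct)),
       r = setNames(rs, rownames(ct)), index = idx)
}

# random Ct table fixture
random_ct <- function(G = 8, S = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(G * S, 18, 30), G, S,
              dimnames = list(paste0("g", seq_len(G)), paste0("s", seq_len(S))))
  m
}

random_counts <- function(G = 200, S = 4, seed = 1, mu = 100, size = 2) {
  set.seed(seed)
  matrix(rnbinom(G * S, mu = mu, size = size), G, S,
         dimnames = list(sprintf("g%03d", seq_len(G)), paste0("s", seq_len(S))))
}

random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
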