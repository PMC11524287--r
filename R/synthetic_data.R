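# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Component seeds are derived from the global seed
# by fixed offsets so e.g. sample depths do not change when n_genes changes.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

child_seed <- function(seed, stream) {
  (as.integer(seed) * 101L + stream * 7919L) %% 2147483629L
}

#' Count-simulation parameters
#'
#' Defaults emulate a multi-experiment training compendium: 5,000 genes, 60
#' samples spread over 10 conditions, 5 percent planted stable genes.
#' Negative-binomial dispersion is the phi of `variance = mu + phi mu^2`.
#'
#' @param n_genes,n_samples,n_conditions Matrix shape; samples are split
#'   evenly over conditions (`n_samples >= 2 * n_conditions`).
#' @param stable_fraction Fraction of genes planted as stable, default 0.05.
#' @param stable_dispersion NB dispersion of stable genes, default 0.01.
#' @param unstable_dispersion NB dispersion of unstable genes, default 0.3.
#' @param fold_change_sd SD of per-condition log2 fold changes applied to
#'   unstable genes, default 1.
#' @param libsize_log_sd SD of log-normal per-sample depth factors, default
#'   0.3.
#' @param mean_log_mu,mean_log_sd Natural-log mean/SD of the log-normal
#'   distribution of gene base means, defaults 5 and 1.5.
#' @param rng_seed Integer seed.
#' @return List of class `"CountSimulationParams"`.
#' @export
count_sim_params <- function(n_genes = 5000L, n_samples = 60L,
                             n_conditions = 10L, stable_fraction = 0.05,
                             stable_dispersion = 0.01,
                             unstable_dispersion = 0.3, fold_change_sd = 1,
                             libsize_log_sd = 0.3, mean_log_mu = 5,
                             mean_log_sd = 1.5, rng_seed = 1L) {
  stopifnot(stable_fraction > 0, stable_fraction < 1,
            stable_dispersion > 0, unstable_dispersion > 0,
            n_samples >= 2L * n_conditions)
  structure(as.list(environment()), class = "CountSimulationParams")
}

#' Simulate a count matrix with planted stable genes
#'
#' Gene base means are log-normal. Stable genes keep one mean across all
#' conditions and draw counts at the low `stable_dispersion`; unstable genes
#' receive an independent log2 fold change per condition
#' (`Normal(0, fold_change_sd)`) and draw at `unstable_dispersion`. Counts
#' are negative binomial with per-sample log-normal depth factors. Fully
#' reproducible from the seed; depth factors use their own child seed so the
#' same seed yields the same depths regardless of gene count.
#'
#' @param p A [count_sim_params()].
#' @return List with `counts` (a [count_matrix()] with unit lengths), `truth`
#'   (data frame `gene_id`, `stable`), `depth_factors` (true per-sample
#'   factors, geometric mean 1) and `condition` (per-sample labels).
#' @export
simulate_counts <- function(p = count_sim_params()) {
  stopifnot(inherits(p, "CountSimulationParams"))
  G <- p$n_genes; S <- p$n_samples; C <- p$n_conditions
  cond <- rep_len(seq_len(C), S)
  depth <- with_seed(child_seed(p$rng_seed, 1L),
                     exp(stats::rnorm(S, 0, p$libsize_log_sd)))
  depth <- depth / exp(mean(log(depth)))
  gene <- with_seed(child_seed(p$rng_seed, 2L), {
    mu <- exp(stats::rnorm(G, p$mean_log_mu, p$mean_log_sd))
    n_stable <- max(1L, round(p$stable_fraction * G))
    stable <- seq_len(G) %in% sample.int(G, n_stable)
    fc <- matrix(0, G, C)
    fc[!stable, ] <- stats::rnorm(sum(!stable) * C, 0, p$fold_change_sd)
    list(mu = mu, stable = stable, fc = fc)
  })
  counts <- with_seed(child_seed(p$rng_seed, 3L), {
    phi <- ifelse(gene$stable, p$stable_dispersion, p$unstable_dispersion)
    m <- matrix(0L, G, S)
    for (j in seq_len(S)) {
      mu_j <- gene$mu * 2^gene$fc[, cond[j]] * depth[j]
      m[, j] <- stats::rnbinom(G, mu = mu_j, size = 1 / phi)
    }
    m
  })
  rownames(counts) <- sprintf("gene%05d", seq_len(G))
  colnames(counts) <- sprintf("sample%03d", seq_len(S))
  list(counts = count_matrix(counts,
                             lengths = stats::setNames(rep(1000, G), rownames(counts))),
       truth = data.frame(gene_id = rownames(counts), stable = gene$stable,
                          base_mean = gene$mu, stringsAsFactors = FALSE),
       depth_factors = stats::setNames(depth, colnames(counts)),
       condition = stats::setNames(cond, colnames(counts)))
}

#' Ct-simulation parameters
#'
#' Defaults: 18 genes and 24 samples, per-gene baseline Ct uniform in
#' \[18, 28\] (mid-range quantification cycles), planted per-gene noise SDs
#' spanning 0.05-1.5 cycles.
#'
#' @param n_genes,n_samples Table shape.
#' @param base_ct_range Range of per-gene baseline Ct, default `c(18, 28)`.
#' @param noise_sd Per-gene Gaussian Ct noise SDs (recycled/defaulted to an
#'   even grid from `noise_sd_range`).
#' @param noise_sd_range Range used when `noise_sd` is `NULL`, default
#'   `c(0.05, 1.5)`.
#' @param n_groups Number of sample groups; with more than one group the
#'   noisier half of the genes also receive per-group Ct shifts of SD
#'   `group_effect_sd`.
#' @param group_effect_sd SD of the per-group shifts, default 0.
#' @param rng_seed Integer seed.
#' @return List of class `"CtSimulationParams"`.
#' @export
ct_sim_params <- function(n_genes = 18L, n_samples = 24L,
                          base_ct_range = c(18, 28), noise_sd = NULL,
                          noise_sd_range = c(0.05, 1.5), n_groups = 1L,
                          group_effect_sd = 0, rng_seed = 1L) {
  if (is.null(noise_sd))
    noise_sd <- seq(noise_sd_range[1L], noise_sd_range[2L],
                    length.out = n_genes)
  stopifnot(all(noise_sd > 0), base_ct_range[1L] > 10, base_ct_range[2L] < 35)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 base_ct_range = base_ct_range, noise_sd = noise_sd,
                 n_groups = as.integer(n_groups),
                 group_effect_sd = group_effect_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "CtSimulationParams")
}

#' Simulate a Ct table with planted stability ordering
#'
#' `Ct_gi = base_g + group_effect + Normal(0, noise_sd_g)`: genes with small
#' planted noise SD are the true stable genes, so the planted SD vector is
#' the ground-truth stability ordering for benchmarking the delta-Ct, geNorm,
#' NormFinder and BestKeeper estimators.
#'
#' @param p A [ct_sim_params()].
#' @param gene_ids Optional gene ids (default `gene01`...).
#' @return List with `ct` (a [ct_table()]), `noise_sd` (planted per-gene SD)
#'   and `groups`.
#' @export
simulate_ct <- function(p = ct_sim_params(), gene_ids = NULL) {
  stopifnot(inherits(p, "CtSimulationParams"))
  G <- p$n_genes; S <- p$n_samples
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%02d", seq_len(G))
  stopifnot(length(gene_ids) == G)
  grp <- rep_len(seq_len(p$n_groups), S)
  base <- with_seed(child_seed(p$rng_seed, 11L),
                    stats::runif(G, p$base_ct_range[1L], p$base_ct_range[2L]))
  shifts <- with_seed(child_seed(p$rng_seed, 12L), {
    sh <- matrix(0, G, p$n_groups)
    if (p$n_groups > 1L && p$group_effect_sd > 0) {
      noisy <- p$noise_sd > stats::median(p$noise_sd)
      sh[noisy, ] <- stats::rnorm(sum(noisy) * p$n_groups, 0, p$group_effect_sd)
    }
    sh
  })
  ctm <- with_seed(child_seed(p$rng_seed, 13L), {
    m <- base + shifts[, grp, drop = FALSE] +
      matrix(stats::rnorm(G * S, 0, p$noise_sd), G, S)
    m
  })
  rownames(ctm) <- gene_ids
  colnames(ctm) <- sprintf("s%02d", seq_len(S))
  groups <- if (p$n_groups > 1L)
    stats::setNames(paste0("grp", grp), colnames(ctm)) else NULL
  list(ct = ct_table(ctm, groups = groups),
       noise_sd = stats::setNames(p$noise_sd, gene_ids), groups = groups)
}

#' Simulate a diverged ortholog sequence set
#'
#' Draws a random root sequence and derives one sequence per species by
#' substituting bases at the given divergence rate outside the conserved
#' windows and never inside them. Substitutions only (no indels), so the true
#' alignment is columnwise and the true consensus is known exactly.
#'
#' @param root_length Root sequence length in bases.
#' @param n_species Number of species sequences to derive.
#' @param divergence Per-species substitution rate in \[0, 0.3); scalar or
#'   per-species vector.
#' @param conserved_windows Matrix/data frame of 0-based half-open
#'   `(start, end)` windows protected from substitutions; overlapping windows
#'   are merged with a warning.
#' @param gc Root GC fraction, default 0.5.
#' @param rng_seed Integer seed.
#' @return List with `set` (a [sequence_set()] of the species sequences),
#'   `root`, `edits` (data frame `species`, `pos` 0-based, `from`, `to`) and
#'   `conserved_windows` (merged).
#' @export
simulate_ortholog_set <- function(root_length = 1000L, n_species = 5L,
                                  divergence = 0.02,
                                  conserved_windows = NULL, gc = 0.5,
                                  rng_seed = 1L) {
  stopifnot(all(divergence >= 0), all(divergence < 0.3))
  divergence <- rep_len(divergence, n_species)
  if (!is.null(conserved_windows)) {
    w <- as.matrix(conserved_windows)
    stopifnot(ncol(w) == 2L, all(w[, 1L] < w[, 2L]), all(w[, 1L] >= 0),
              all(w[, 2L] <= root_length))
    w <- w[order(w[, 1L]), , drop = FALSE]
    merged <- w[1L, , drop = FALSE]
    for (i in seq_len(nrow(w))[-1L]) {
      if (w[i, 1L] <= merged[nrow(merged), 2L]) {
        warning("overlapping conserved windows merged")
        merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], w[i, 2L])
      } else merged <- rbind(merged, w[i, , drop = FALSE])
    }
    conserved_windows <- merged
  }
  protected <- rep(FALSE, root_length)
  if (!is.null(conserved_windows)) {
    for (i in seq_len(nrow(conserved_windows)))
      protected[(conserved_windows[i, 1L] + 1L):conserved_windows[i, 2L]] <- TRUE
  }
  bases <- c("A", "C", "G", "T")
  root <- with_seed(child_seed(rng_seed, 21L),
                    sample(bases, root_length, replace = TRUE,
                           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
  edits <- list()
  seqs <- character(n_species)
  for (s in seq_len(n_species)) {
    res <- with_seed(child_seed(rng_seed, 21L + s), {
      mut <- root
      editable <- which(!protected)
      n_mut <- round(divergence[s] * length(editable))
      ed <- NULL
      if (n_mut > 0L) {
        pos <- sort(sample(editable, n_mut))
        for (pp in pos) mut[pp] <- sample(setdiff(bases, root[pp]), 1L)
        ed <- data.frame(species = sprintf("sp%d", s), pos = pos - 1L,
                         from = root[pos], to = mut[pos],
                         stringsAsFactors = FALSE)
      }
      list(seq = paste(mut, collapse = ""), edits = ed)
    })
    seqs[s] <- res$seq
    if (!is.null(res$edits)) edits[[length(edits) + 1L]] <- res$edits
  }
  species <- sprintf("sp%d", seq_len(n_species))
  list(set = sequence_set(paste0("tx_", species), seqs, species),
       root = paste(root, collapse = ""),
       edits = if (length(edits)) do.call(rbind, edits) else
         data.frame(species = character(0), pos = integer(0),
                    from = character(0), to = character(0)),
       conserved_windows = conserved_windows)
}
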