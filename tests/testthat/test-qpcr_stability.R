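test_that("delta-Ct scores follow hand-computed values", {
  par <- rbind(A = c(20, 21, 22), B = c(25, 26, 27))
  colnames(par) <- paste0("s", 1:3)
  expect_equal(unname(delta_ct_stability(par)), c(0, 0))

  two <- rbind(A = c(20, 20), B = c(20, 22))
  colnames(two) <- c("s1", "s2")
  expect_equal(unname(delta_ct_stability(two)), rep(sqrt(2), 2),
               tolerance = 1e-9)
})

test_that("delta-Ct matches the all-pairs oracle on random tables", {
  for (seed in 1:6) {
    m <- random_ct(G = 4 + seed %% 3, S = 10, seed = seed)
    expect_equal(delta_ct_stability(m), oracle_deltact(m), tolerance = 1e-12)
  }
})

test_that("geNorm gives M = 0 for perfectly covarying genes and ranks spread", {
  par <- rbind(A = c(20, 21, 22), B = c(25, 26, 27))
  colnames(par) <- paste0("s", 1:3)
  g <- genorm(par)
  expect_equal(unname(g$M), c(0, 0))

  # gene C has twice the dCt spread of the tight A-B pair
  m <- rbind(A = c(20, 20.1, 19.9, 20), B = c(22, 22.1, 21.9, 22),
             C = c(24, 25, 23, 24.6))
  colnames(m) <- paste0("s", 1:4)
  g3 <- genorm(m)
  expect_equal(g3$exclusion_order[1], "C")
  expect_setequal(g3$ranking[1:2], c("A", "B"))
})

test_that("geNorm M values, exclusion order and V match the oracle", {
  for (seed in 1:5) {
    m <- random_ct(G = 8, S = 12, seed = 100 + seed)
    g <- genorm(m)
    o <- oracle_genorm(m)
    expect_equal(g$M, o$M, tolerance = 1e-12)
    expect_equal(g$exclusion_order, o$exclusion_order)
    expect_equal(length(g$V), 6)  # V2/3 ... V7/8
    expect_true(all(g$V >= 0))
  }
})

test_that("NormFinder matches the variance-decomposition oracle", {
  for (seed in 1:6) {
    m <- random_ct(G = 6, S = 10, seed = 200 + seed)
    expect_equal(normfinder(m), oracle_normfinder(m), tolerance = 1e-9)
  }
  flat <- matrix(20, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  expect_equal(unname(normfinder(flat)), rep(0, 4))
})

test_that("an inflated-noise gene gets the largest NormFinder score", {
  set.seed(9)
  m <- matrix(rnorm(7 * 12, 22, 0.2), 7, 12,
              dimnames = list(paste0("g", 1:7), paste0("s", 1:12)))
  m[4, ] <- rnorm(12, 22, 1.0)  # 5x noise SD
  sc <- normfinder(m)
  expect_equal(names(which.max(sc)), "g4")
})

test_that("grouped NormFinder validates group sizes", {
  m <- random_ct(G = 5, S = 6, seed = 31)
  expect_error(normfinder(m, groups = c("a", "a", "b", "b", "c", "a")),
               "fewer than 2")
  sc <- normfinder(m, groups = rep(c("ctl", "salt"), each = 3))
  expect_length(sc, 5)
  expect_true(all(sc >= 0))
})

test_that("BestKeeper statistics follow their formulas", {
  m <- random_ct(G = 6, S = 12, seed = 77)
  bk <- bestkeeper(m)
  o <- oracle_bestkeeper(m)
  expect_equal(setNames(bk$stats$sd, bk$stats$gene_id), o$sd, tolerance = 1e-12)
  expect_equal(setNames(bk$stats$cv_pct, bk$stats$gene_id), o$cv_pct,
               tolerance = 1e-12)
  expect_equal(setNames(bk$stats$r, bk$stats$gene_id), o$r, tolerance = 1e-12)
  expect_equal(unname(bk$index), o$index, tolerance = 1e-12)

  # hand value: Ct (20, 22) -> sd = sqrt(2), cv_pct = 100 * sqrt(2) / 21
  two <- rbind(a = c(20, 22), b = c(21, 21.5))
  colnames(two) <- c("s1", "s2")
  bk2 <- bestkeeper(two)
  expect_equal(bk2$stats$sd[1], sqrt(2), tolerance = 1e-9)
  expect_equal(bk2$stats$cv_pct[1], 100 * sqrt(2) / 21, tolerance = 1e-6)

  # a gene identical to the index correlates perfectly
  idx <- bk$index
  m2 <- rbind(m, mirror = idx)
  bk3 <- bestkeeper(m2)
  expect_equal(bk3$stats$r[bk3$stats$gene_id == "mirror"], 1, tolerance = 1e-6)
})

test_that("stability scores are location-invariant except BestKeeper CV%", {
  m <- random_ct(G = 6, S = 10, seed = 55)
  shifted <- m
  shifted[2, ] <- shifted[2, ] + 4
  expect_equal(delta_ct_stability(m), delta_ct_stability(shifted),
               tolerance = 1e-12)
  expect_equal(genorm(m)$M, genorm(shifted)$M, tolerance = 1e-12)
  expect_equal(normfinder(m), normfinder(shifted), tolerance = 1e-12)
  bk1 <- bestkeeper(m); bk2 <- bestkeeper(shifted)
  expect_equal(bk1$stats$sd, bk2$stats$sd, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(bk1$stats$cv_pct[2], bk2$stats$cv_pct[2])))
})

test_that("all four algorithms are order-invariant", {
  m <- random_ct(G = 7, S = 9, seed = 66)
  set.seed(1); pg <- sample(nrow(m)); ps <- sample(ncol(m))
  p <- m[pg, ps]
  expect_equal(delta_ct_stability(p)[rownames(m)], delta_ct_stability(m),
               tolerance = 1e-12)
  expect_equal(genorm(p)$M[rownames(m)], genorm(m)$M, tolerance = 1e-12)
  expect_equal(normfinder(p)[rownames(m)], normfinder(m), tolerance = 1e-12)
  b1 <- bestkeeper(m)$stats; b2 <- bestkeeper(p)$stats
  expect_equal(setNames(b2$sd, b2$gene_id)[rownames(m)],
               setNames(b1$sd, b1$gene_id), tolerance = 1e-12)
})

test_that("comprehensive ranking is the geometric mean with stated tie-breaks", {
  ranks <- list(deltaCt = c(a = 1, b = 2, c = 3),
                geNorm = c(a = 1, b = 2, c = 3),
                NormFinder = c(a = 1, b = 2, c = 3),
                BestKeeper = c(a = 1, b = 2, c = 3))
  cr <- comprehensive_rank(ranks)
  expect_equal(cr$geomean_rank, c(1, 2, 3))
  expect_equal(cr$gene_id, c("a", "b", "c"))

  ranks2 <- list(deltaCt = c(x = 1), geNorm = c(x = 2),
                 NormFinder = c(x = 4), BestKeeper = c(x = 8))
  expect_equal(comprehensive_rank(ranks2)$geomean_rank, 64^(1 / 4),
               tolerance = 1e-9)
  expect_error(comprehensive_rank(ranks[1:3]), "BestKeeper")
})

test_that("qpcr_rank recovers a planted most-stable gene", {
  sim <- simulate_ct(ct_sim_params(n_genes = 12, n_samples = 24,
                                   rng_seed = 23))
  rep <- qpcr_rank(sim$ct)
  best <- names(which.min(sim$noise_sd))
  expect_equal(rep$table$gene_id[1], best)
  expect_equal(sort(rep$table$final_rank), 1:12)
})

test_that("missing Ct cells are handled pairwise and flagged", {
  m <- random_ct(G = 5, S = 8, seed = 88)
  m[2, 1:2] <- NA
  expect_warning(bk <- bestkeeper(m), "excluded")
  expect_false(bk$stats$in_index[2])
  expect_warning(nf <- normfinder(m), "dropping")
  expect_false("g2" %in% names(nf))
  d <- delta_ct_stability(m)
  expect_true(all(is.finite(d)))
})

test_that("standard curves recover efficiency and classify the band", {
  sc <- standard_curve(cbind(x = c(0, -1, -2), ct = c(10, 11, 12)))
  expect_equal(sc$E, 10)

  x <- 0:-5
  perfect <- standard_curve(cbind(x, 10 - 3.321928 * x))
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)
  expect_equal(perfect$E, 2, tolerance = 1e-6)
  expect_equal(perfect$efficiency_pct, 100, tolerance = 0.01)
  expect_true(perfect$reliable)

  # band edges: build perfect series at target efficiencies
  eff_curve <- function(eff_pct) {
    E <- 1 + eff_pct / 100
    slope <- -1 / log10(E)
    standard_curve(cbind(x, 20 + slope * x))
  }
  expect_true(eff_curve(90)$reliable)
  expect_true(eff_curve(115)$reliable)
  expect_false(eff_curve(89.9)$reliable)
  expect_false(eff_curve(115.1)$reliable)

  up <- standard_curve(cbind(x = c(0, -1, -2), ct = c(10, 9.5, 9)))
  expect_false(up$valid)
  expect_true(is.na(up$E))
  expect_error(standard_curve(cbind(x = c(0, 0, 0), ct = c(1, 2, 3))), "distinct")
})

test_that("replicate collapsing averages technical replicates", {
  m <- rbind(g1 = c(20, 20.4, 21, 21.2), g2 = c(25, 25.2, 24, 24.2))
  colnames(m) <- c("s1_a", "s1_b", "s2_a", "s2_b")
  cc <- collapse_replicates(m, c("s1", "s1", "s2", "s2"))
  expect_equal(unname(cc$ct["g1", ]), c(20.2, 21.1))
  expect_equal(colnames(cc$ct), c("s1", "s2"))
})
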