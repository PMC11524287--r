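test_that("ortholog search keeps the best hit per species", {
  set.seed(12)
  q <- random_dna(600, seed = 12)
  # ortholog: ~95% identity; paralog: ~75% identity, same species
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), round(rate * length(ch)))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  db <- sequence_set(c("self", "orth", "para", "junk"),
                     c(q, mutate(q, 0.05), mutate(q, 0.25), random_dna(600)),
                     c("Ptri", "Peup", "Peup", "Palb"))
  expect_warning(og <- find_orthologs(q, db), "Palb")
  expect_equal(og$members$seq_id[og$members$species == "Ptri"], "self")
  expect_equal(og$members$identity[og$members$seq_id == "self"], 100)
  expect_equal(og$members$seq_id[og$members$species == "Peup"], "orth")
  expect_false("junk" %in% og$members$seq_id)
})

test_that("raising min_identity never grows the ortholog group", {
  set.seed(42)
  q <- random_dna(500, seed = 42)
  mut <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), round(rate * length(ch)))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  db <- sequence_set(paste0("t", 1:4),
                     c(mut(q, 0.02), mut(q, 0.10), mut(q, 0.2), mut(q, 0.28)),
                     paste0("sp", 1:4))
  sizes <- vapply(c(60, 75, 90, 99), function(mi)
    nrow(suppressWarnings(find_orthologs(q, db, min_identity = mi))$members), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("consensus of identical sequences is the sequence itself", {
  s <- random_dna(300, seed = 5)
  cons <- align_group(setNames(c(s, s, s), paste0("m", 1:3)))
  expect_equal(cons$consensus, s)
  expect_true(all(cons$conservation == 1))
})

test_that("a single substitution yields the forced IUPAC code", {
  s <- random_dna(250, seed = 6)
  ch <- strsplit(s, "")[[1]]
  ch[100] <- "A"
  a <- paste(ch, collapse = "")
  ch[100] <- "G"
  b <- paste(ch, collapse = "")
  cons <- align_group(c(x = a, y = b))
  expect_equal(substr(cons$consensus, 100, 100), "R")
  expect_equal(cons$conservation[100], 0.5)
  expect_true(all(cons$conservation[-100] == 1))
})

test_that("center-star alignment recovers planted substitution columns", {
  os <- simulate_ortholog_set(root_length = 300, n_species = 3,
                              divergence = 0.017, rng_seed = 31)
  cons <- align_group(os$set)
  expect_equal(nchar(cons$consensus), 300)  # substitution-only: no gaps
  # hand-compute the expected consensus from the planted edits
  mat <- do.call(rbind, strsplit(unname(os$set$sequences), ""))
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  expected <- vapply(seq_len(300), function(p)
    codes[[paste(sort(unique(mat[, p])), collapse = "")]], "")
  expect_equal(cons$consensus, paste(expected, collapse = ""))
  # member order does not change the consensus
  cons2 <- align_group(rev(os$set$sequences))
  expect_equal(cons2$consensus, cons$consensus)
})

test_that("low-identity groups are rejected", {
  expect_error(align_group(c(a = random_dna(200, seed = 1),
                             b = random_dna(200, seed = 2))),
               "identity")
})

test_that("every enumerated pair satisfies all design constraints", {
  set.seed(314)
  audited <- 0L
  for (i in 1:25) {
    s <- random_dna(300, gc = 0.55)
    pl <- enumerate_primers(s)
    if (!nrow(pl)) next
    audited <- audited + nrow(pl)
    expect_true(all(pl$length_f >= 18 & pl$length_f <= 27))
    expect_true(all(pl$length_r >= 18 & pl$length_r <= 27))
    expect_true(all(nchar(pl$forward) == pl$length_f))
    expect_true(all(nchar(pl$reverse) == pl$length_r))
    expect_true(all(pl$product_size >= 100 & pl$product_size <= 300))
    expect_equal(pl$product_size, pl$reverse_end - pl$forward_start)
    # recompute Tm from scratch for both primers; reverse primer Tm equals
    # its window Tm (perfect-complement duplex)
    tm_f <- vapply(pl$forward, primer_tm, 0)
    expect_equal(unname(tm_f), pl$tm_f, tolerance = 1e-9)
    expect_true(all(pl$tm_f >= 59 & pl$tm_f <= 63))
    expect_true(all(pl$tm_r >= 59 & pl$tm_r <= 63))
    expect_true(all(pl$gc_f >= 0.4 & pl$gc_f <= 0.6))
  }
  expect_gt(audited, 0)
})

test_that("a conserved block yields pairs and full ambiguity yields none", {
  s <- random_dna(400, gc = 0.55, seed = 99)
  pl <- enumerate_primers(s)
  expect_gt(nrow(pl), 0)
  # deterministic output
  pl2 <- enumerate_primers(s)
  expect_identical(as.data.frame(pl), as.data.frame(pl2))

  noisy <- structure(list(alignment = NULL,
                          consensus = paste(rep("N", 400), collapse = ""),
                          conservation = rep(0.5, 400),
                          gap_free = rep(TRUE, 400)),
                     class = "ConsensusSequence")
  pl3 <- enumerate_primers(noisy)
  expect_equal(nrow(pl3), 0L)
  d <- attr(pl3, "diagnostics")
  expect_true(d[["conservation"]] > 0 && d[["tm"]] == 0)
})

test_that("the published CNOT2 pair passes the primer length invariant", {
  pp <- primer_pair("GGTCTGACGAGCCAGCAAAGGGT", "CGCCGCTGCTCCTTGTGGT")
  expect_s3_class(pp, "PrimerPair")
  expect_error(primer_pair("ACGTACGTACGTACGTA", "CGCCGCTGCTCCTTGTGGT"),
               "length")
  expect_error(primer_pair("GGTCTGACGAGCCAGCAAAGGGT", "CGCCGCTGCTCCTTGTGGT",
                           tm_f = 70, tm_r = 60), "Tm")
})

test_that("specificity verdicts react to duplications and 3' mismatches", {
  s <- random_dna(600, gc = 0.55, seed = 7)
  pl <- enumerate_primers(s)
  expect_gt(nrow(pl), 0)
  pair <- pl[1, ]
  g1 <- sequence_set("chr1", s)
  rep1 <- check_specificity(pair, list(gen = g1))
  expect_true(rep1$gen$specific)
  expect_equal(nrow(rep1$gen$amplicons), 1L)
  amp <- rep1$gen$amplicons
  expect_equal(amp$start, pair$forward_start)
  expect_equal(amp$end, pair$reverse_end)

  # plant a second copy of the amplicon downstream
  ampseq <- substr(s, pair$forward_start + 1, pair$reverse_end)
  g2 <- sequence_set("chr1", paste0(s, random_dna(50, seed = 8), ampseq))
  rep2 <- check_specificity(pair, list(gen = g2))
  expect_false(rep2$gen$specific)
  expect_equal(rep2$gen$reason, "multiple_amplicons")

  # a 3'-terminal mismatch in the forward site abolishes the amplicon
  ch <- strsplit(s, "")[[1]]
  tpos <- pair$forward_end  # 3' base of the forward primer (1-based)
  ch[tpos] <- setdiff(c("A", "C", "G", "T"), ch[tpos])[1]
  g3 <- sequence_set("chr1", paste(ch, collapse = ""))
  rep3 <- check_specificity(pair, list(gen = g3))
  expect_equal(rep3$gen$reason, "no_amplicon")

  # interior mismatches up to the allowance keep the site
  ch2 <- strsplit(s, "")[[1]]
  inner <- (pair$forward_start + 2):(pair$forward_end - 5)
  for (p in inner[1:2]) ch2[p] <- setdiff(c("A", "C", "G", "T"), ch2[p])[1]
  g4 <- sequence_set("chr1", paste(ch2, collapse = ""))
  rep4 <- check_specificity(pair, list(gen = g4))
  expect_true(rep4$gen$specific)
  expect_equal(rep4$gen$amplicons$mismatch_plus, 2L)
})

test_that("specificity is mirrored on the reverse-complemented genome", {
  s <- random_dna(500, gc = 0.55, seed = 21)
  pl <- enumerate_primers(s)
  expect_gt(nrow(pl), 0)
  pair <- pl[1, ]
  g <- sequence_set("chr1", s)
  rc <- sequence_set("chr1", Biostrings::toString(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  r1 <- check_specificity(pair, list(gen = g))
  r2 <- check_specificity(pair, list(gen = rc))
  expect_equal(r1$gen$specific, r2$gen$specific)
  L <- nchar(s)
  expect_equal(r2$gen$amplicons$start, L - r1$gen$amplicons$end)
  expect_equal(r2$gen$amplicons$end, L - r1$gen$amplicons$start)
})

test_that("the end-to-end designer yields universal primers on orthologs", {
  os <- simulate_ortholog_set(root_length = 900, n_species = 5,
                              divergence = 0.03,
                              conserved_windows = cbind(300, 650),
                              gc = 0.55, rng_seed = 77)
  dbs <- lapply(seq_len(5), function(i)
    sequence_set(os$set$ids[i], os$set$sequences[i], os$set$species[i]))
  genomes <- lapply(dbs, function(d) d)
  names(genomes) <- vapply(dbs, function(d) d$species[[1]], "")
  des <- design_universal_primers(os$set$sequences[[1]], dbs, genomes,
                                  query_id = os$set$ids[[1]])
  expect_s3_class(des, "UniversalPrimerDesign")
  expect_gte(nrow(des$orthologs$members), 5)
  expect_gt(nrow(des$primers), 0)
  # every emitted pair sits on fully conserved consensus columns and is
  # specific in all five genomes
  keep <- des$consensus$conservation == 1 & des$consensus$gap_free
  for (i in seq_len(nrow(des$primers))) {
    expect_true(all(keep[(des$primers$forward_start[i] + 1):des$primers$forward_end[i]]))
    expect_true(all(keep[(des$primers$reverse_start[i] + 1):des$primers$reverse_end[i]]))
  }
  for (r in des$specificity) expect_true(r$all_specific)
})

test_that("single-species input degenerates to primers on the query", {
  q <- random_dna(400, gc = 0.55, seed = 55)
  db <- sequence_set("self", q, "sp1")
  des <- design_universal_primers(q, db, list(sp1 = db), query_id = "self")
  expect_gt(nrow(des$candidates), 0)
  expect_equal(nchar(des$consensus$consensus), 400)
})
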