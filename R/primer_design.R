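# IUPAC nucleotide codes as base-set bitmasks (A=1, C=2, G=4, T=8)
IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
                V = 7L, H = 11L, D = 13L, B = 14L, N = 15L, `-` = 0L)
MASK_TO_CODE <- stats::setNames(names(IUPAC_MASK)[1:15],
                                IUPAC_MASK[1:15])

iupac_degeneracy <- function(chars) {
  n <- vapply(IUPAC_MASK[chars], function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), 0L)
  prod(n)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# chartr-based reverse complement for plain character strings (IUPAC-aware)
revcomp_str <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

#' Find the best ortholog per species
#'
#' Screens a database of transcripts for matches to a query sequence using a
#' shared k-mer prefilter followed by local pairwise alignment, and keeps the
#' single highest-scoring hit per species that passes the identity and
#' coverage thresholds. This replaces a phylogeny-based ortholog pick with a
#' deterministic best-reciprocal-score criterion suitable for congeneric
#' transcript sets.
#'
#' @param query Query nucleotide sequence (character string) or a one-record
#'   [sequence_set()].
#' @param db A [sequence_set()] with species tags.
#' @param min_identity Minimum percent identity of the local alignment,
#'   default 70.
#' @param min_coverage Minimum fraction of the query covered by the aligned
#'   region, default 0.5.
#' @param kmer Seed k-mer length for the prefilter, default 11.
#' @param query_id Id used for the query, default `"query"`.
#' @return List of class `"OrthologGroup"`: `query_id`, `query_seq`,
#'   `members` (data frame `species`, `seq_id`, `identity`, `coverage`,
#'   `score`, sorted by descending score) and `sequences` (named character
#'   vector of the member transcripts).
#' @export
find_orthologs <- function(query, db, min_identity = 70, min_coverage = 0.5,
                           kmer = 11L, query_id = "query") {
  if (inherits(query, "SequenceSet")) {
    stopifnot(length(query) == 1L)
    query_id <- query$ids[[1L]]
    query <- query$sequences[[1L]]
  }
  query <- toupper(query)
  stopifnot(inherits(db, "SequenceSet"), length(db) > 0L)
  qk <- unique(substring(query, seq_len(max(nchar(query) - kmer + 1L, 0L)),
                         seq_len(max(nchar(query) - kmer + 1L, 0L)) + kmer - 1L))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  hits <- list()
  for (i in seq_along(db$ids)) {
    subj <- db$sequences[[i]]
    sk <- substring(subj, seq_len(max(nchar(subj) - kmer + 1L, 0L)),
                    seq_len(max(nchar(subj) - kmer + 1L, 0L)) + kmer - 1L)
    if (!any(qk %in% sk)) next  # no shared seed: no hit
    aln <- Biostrings::pairwiseAlignment(query, subj, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2)
    ident <- Biostrings::pid(aln)
    cov <- Biostrings::nchar(Biostrings::pattern(aln)) / nchar(query)
    if (ident < min_identity || cov < min_coverage) next
    hits[[length(hits) + 1L]] <- data.frame(
      species = db$species[[i]], seq_id = db$ids[[i]],
      identity = ident, coverage = cov, score = Biostrings::score(aln),
      stringsAsFactors = FALSE)
  }
  members <- if (length(hits)) do.call(rbind, hits) else
    data.frame(species = character(0), seq_id = character(0),
               identity = numeric(0), coverage = numeric(0),
               score = numeric(0), stringsAsFactors = FALSE)
  # best hit per species, then sort by descending score
  if (nrow(members)) {
    members <- members[order(-members$score, members$seq_id), , drop = FALSE]
    lost <- unique(db$species[!is.na(db$species)])
    members <- members[!duplicated(members$species), , drop = FALSE]
    lost <- setdiff(lost, members$species)
    if (length(lost))
      warning("no passing hit in species: ", paste(lost, collapse = ", "))
    rownames(members) <- NULL
  }
  structure(list(query_id = query_id, query_seq = query, members = members,
                 sequences = db$sequences[members$seq_id]),
            class = "OrthologGroup")
}

#' @export
print.OrthologGroup <- function(x, ...) {
  cat(sprintf("OrthologGroup for %s: %d member(s)\n", x$query_id,
              nrow(x$members)))
  if (nrow(x$members)) print(x$members, digits = 4, row.names = FALSE)
  invisible(x)
}

# Merge a new center/member pairwise alignment into a growing center-star MSA.
# msa: list of gapped strings (center first); c_aln/s_aln: gapped center and
# member from the new pairwise alignment. Returns the updated msa.
merge_star <- function(msa, c_aln, s_aln) {
  M <- strsplit(msa[[1L]], "")[[1L]]
  C <- strsplit(c_aln, "")[[1L]]
  S <- strsplit(s_aln, "")[[1L]]
  i <- 1L; j <- 1L
  mapM <- integer(0); mapC <- integer(0)
  nM <- length(M); nC <- length(C)
  while (i <= nM || j <= nC) {
    a <- if (i <= nM) M[i] else NULL
    b <- if (j <= nC) C[j] else NULL
    if (!is.null(a) && !is.null(b) && ((a != "-") == (b != "-"))) {
      mapM <- c(mapM, i); mapC <- c(mapC, j); i <- i + 1L; j <- j + 1L
    } else if (!is.null(a) && a == "-") {
      mapM <- c(mapM, i); mapC <- c(mapC, NA_integer_); i <- i + 1L
    } else if (!is.null(b) && b == "-") {
      mapM <- c(mapM, NA_integer_); mapC <- c(mapC, j); j <- j + 1L
    } else if (is.null(a)) {
      mapM <- c(mapM, NA_integer_); mapC <- c(mapC, j); j <- j + 1L
    } else {
      mapM <- c(mapM, i); mapC <- c(mapC, NA_integer_); i <- i + 1L
    }
  }
  regap <- function(str, map) {
    ch <- strsplit(str, "")[[1L]]
    out <- rep("-", length(map))
    out[!is.na(map)] <- ch[map[!is.na(map)]]
    paste(out, collapse = "")
  }
  out <- lapply(msa, regap, map = mapM)
  out[[length(out) + 1L]] <- regap(s_aln, mapC)
  out
}

#' Align an ortholog group and build its consensus
#'
#' Center-star multiple alignment: the member with the highest mean pairwise
#' identity is the center; every other member is aligned to it globally and
#' the pairwise alignments are merged by gap propagation. The consensus emits
#' the plain base at unanimous columns and the IUPAC ambiguity code of the
#' observed bases elsewhere; per-column conservation is the frequency of the
#' most common non-gap base among the non-gap members.
#'
#' @param seqs Named character vector of 2-10 nucleotide sequences (or a
#'   [sequence_set()] or [find_orthologs()] result).
#' @param min_identity Minimum allowed pairwise identity (percent), default
#'   60; more diverged sets should be re-examined for paralogs.
#' @return List of class `"ConsensusSequence"`: `alignment` (named gapped
#'   strings), `consensus` (IUPAC string, alignment length), `conservation`
#'   (fraction per column), `gap_free` (logical per column).
#' @export
align_group <- function(seqs, min_identity = 60) {
  if (inherits(seqs, "OrthologGroup"))
    seqs <- c(stats::setNames(seqs$query_seq, seqs$query_id),
              seqs$sequences[setdiff(names(seqs$sequences), seqs$query_id)])
  if (inherits(seqs, "SequenceSet")) seqs <- seqs$sequences
  seqs <- toupper(seqs)
  n <- length(seqs)
  if (n < 2L || n > 10L) stop("align_group expects 2-10 sequences")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_len(n))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  pw_aln <- function(a, b)
    Biostrings::pairwiseAlignment(a, b, type = "global",
                                  substitutionMatrix = submat,
                                  gapOpening = 8, gapExtension = 2)
  pid_mat <- matrix(100, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    pid_mat[a, b] <- pid_mat[b, a] <- Biostrings::pid(pw_aln(seqs[[a]], seqs[[b]]))
  }
  if (min(pid_mat) < min_identity)
    stop(sprintf(paste("pairwise identity %.1f%% below the %.0f%% floor;",
                       "review the ortholog selection"),
                 min(pid_mat), min_identity))
  center <- which.max(rowMeans(pid_mat))
  msa <- list(seqs[[center]])
  order_rest <- setdiff(seq_len(n), center)
  for (b in order_rest) {
    aln <- pw_aln(msa_degap(msa[[1L]]), seqs[[b]])
    c_aln <- as.character(Biostrings::alignedPattern(aln))
    s_aln <- as.character(Biostrings::alignedSubject(aln))
    msa <- merge_star(msa, c_aln, s_aln)
  }
  names(msa) <- names(seqs)[c(center, order_rest)]
  msa <- msa[names(seqs)]  # restore input order
  consensus_from_alignment(msa)
}

msa_degap <- function(s) gsub("-", "", s)

# Column-wise consensus with IUPAC codes and conservation fractions.
consensus_from_alignment <- function(msa) {
  mat <- do.call(rbind, strsplit(unlist(msa), ""))
  L <- ncol(mat)
  cons <- character(L); conserv <- numeric(L); gap_free <- logical(L)
  for (p in seq_len(L)) {
    col <- mat[, p]
    bases <- col[col != "-"]
    gap_free[p] <- length(bases) == length(col)
    if (length(bases) == 0L) {
      cons[p] <- "-"; conserv[p] <- 0
      next
    }
    mask <- Reduce(bitwOr, IUPAC_MASK[bases])
    cons[p] <- MASK_TO_CODE[[as.character(mask)]]
    conserv[p] <- max(table(bases)) / length(bases)
  }
  structure(list(alignment = unlist(msa), consensus = paste(cons, collapse = ""),
                 conservation = conserv, gap_free = gap_free),
            class = "ConsensusSequence")
}

#' @export
print.ConsensusSequence <- function(x, ...) {
  cat(sprintf("ConsensusSequence: %d members, %d columns, %.1f%% fully conserved\n",
              length(x$alignment), nchar(x$consensus),
              100 * mean(x$conservation == 1 & x$gap_free)))
  invisible(x)
}

#' Primer pair constructor
#'
#' Validates the primer-pair design constraints on whichever fields are
#' supplied: primer lengths 18-27 nt always; Tm 59-63 degrees C and product
#' size 100-300 bp when given.
#'
#' @param forward,reverse Primer sequences, each 5'->3' (the reverse primer
#'   on the minus strand).
#' @param tm_f,tm_r Optional melting temperatures (degrees C).
#' @param product_size Optional amplicon length in bases.
#' @return A list of class `"PrimerPair"`.
#' @export
primer_pair <- function(forward, reverse, tm_f = NULL, tm_r = NULL,
                        product_size = NULL) {
  for (p in c(forward, reverse)) {
    if (nchar(p) < 18L || nchar(p) > 27L)
      stop(sprintf("primer length %d outside 18-27 nt: %s", nchar(p), p))
  }
  for (tm in c(tm_f, tm_r)) {
    if (tm < 59 || tm > 63) stop(sprintf("Tm %.2f outside 59-63 C", tm))
  }
  if (!is.null(product_size) && (product_size < 100L || product_size > 300L))
    stop("product size outside 100-300 bp")
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 tm_f = tm_f, tm_r = tm_r, product_size = product_size),
            class = "PrimerPair")
}

#' Enumerate candidate primer pairs on a consensus
#'
#' Slides all windows of 18-27 nt whose every column reaches the required
#' conservation, contains no gap, and (by default) no ambiguity code;
#' windows are kept when their nearest-neighbor Tm lies in `tm_range` and
#' their GC fraction in `gc_range`. Forward windows are paired with reverse
#' windows (the reverse primer is the reverse complement of its window) at
#' product sizes within `product_range`; pairs are ranked by Tm difference,
#' then by product size closest to 150 bp, then by position.
#'
#' @param cons A [align_group()] consensus (or a plain character string,
#'   treated as fully conserved).
#' @param primer_len Length range, default `c(18, 27)`.
#' @param tm_range Melting-temperature range in degrees C, default `c(59, 63)`.
#' @param product_range Amplicon size range in bp, default `c(100, 300)`.
#' @param gc_range GC-fraction range, default `c(0.4, 0.6)`.
#' @param min_window_conservation Minimum per-column conservation, default 1.
#' @param max_degeneracy Maximum IUPAC expansion count per primer; the default
#'   1 forbids ambiguity codes entirely. Degenerate primers (`> 1`, up to 8)
#'   require every expansion to satisfy the Tm constraint.
#' @param max_pairs Cap on returned pairs after ranking, default 1000.
#' @return Data frame of ranked pairs (class `"PrimerPairList"`) with primer
#'   sequences, 0-based half-open consensus coordinates, Tm, GC, degeneracy
#'   and product size; attribute `diagnostics` counts windows failing each
#'   constraint.
#' @export
enumerate_primers <- function(cons, primer_len = c(18L, 27L),
                              tm_range = c(59, 63), product_range = c(100, 300),
                              gc_range = c(0.4, 0.6),
                              min_window_conservation = 1,
                              max_degeneracy = 1L, max_pairs = 1000L) {
  if (is.character(cons) && length(cons) == 1L) {
    cons <- structure(list(alignment = NULL, consensus = toupper(cons),
                           conservation = rep(1, nchar(cons)),
                           gap_free = rep(TRUE, nchar(cons))),
                      class = "ConsensusSequence")
  }
  stopifnot(inherits(cons, "ConsensusSequence"))
  s <- cons$consensus
  L <- nchar(s)
  if (L < 150L) stop("consensus shorter than 150 bases; too short for design")
  ch <- strsplit(s, "")[[1L]]
  plain <- ch %in% c("A", "C", "G", "T")
  usable <- cons$conservation >= min_window_conservation & cons$gap_free
  if (max_degeneracy <= 1L) usable <- usable & plain
  diag <- c(conservation = 0L, degeneracy = 0L, tm = 0L, gc = 0L)
  # cumulative nearest-neighbor sums over unambiguous stacks for vectorized Tm
  stacks <- paste0(ch[seq_len(L - 1L)], ch[2L:L])
  sH <- unname(NN_DH[stacks]); sS <- unname(NN_DS[stacks])
  sH[is.na(sH)] <- 0; sS[is.na(sS)] <- 0  # ambiguous stacks handled separately
  cumH <- c(0, cumsum(sH)); cumS <- c(0, cumsum(sS))
  cumBad <- c(0L, cumsum(!usable))
  cumAmb <- c(0L, cumsum(!plain))
  cumGC <- c(0L, cumsum(ch %in% c("C", "G", "S")))
  Rgas <- 1.98720425864083
  logCT <- log(250e-9 / 4)
  windows <- NULL
  for (len in seq(primer_len[1L], primer_len[2L])) {
    if (len > L) break
    st <- seq_len(L - len + 1L)
    en <- st + len - 1L
    ok_cons <- (cumBad[en + 1L] - cumBad[st]) == 0L
    diag[["conservation"]] <- diag[["conservation"]] + sum(!ok_cons)
    amb <- (cumAmb[en + 1L] - cumAmb[st]) > 0L
    idx <- which(ok_cons & !amb)
    if (length(idx)) {
      stI <- st[idx]; enI <- en[idx]
      dH <- cumH[enI] - cumH[stI] + INIT_DH[ch[stI]] + INIT_DH[ch[enI]]
      dS <- cumS[enI] - cumS[stI] + INIT_DS[ch[stI]] + INIT_DS[ch[enI]] +
        0.368 * (len - 1L) * log(0.05)
      tm <- 1000 * dH / (dS + Rgas * logCT) - 273.15
      gc <- (cumGC[enI + 1L] - cumGC[stI]) / len
      ok_tm <- tm >= tm_range[1L] & tm <= tm_range[2L]
      diag[["tm"]] <- diag[["tm"]] + sum(!ok_tm)
      ok_gc <- gc >= gc_range[1L] & gc <= gc_range[2L]
      diag[["gc"]] <- diag[["gc"]] + sum(ok_tm & !ok_gc)
      keep <- ok_tm & ok_gc
      if (any(keep))
        windows <- rbind(windows, data.frame(
          start = stI[keep], end = enI[keep], len = len,
          tm = tm[keep], gc = gc[keep], degen = 1L))
    }
    # degenerate windows: slow path, only in opt-in degenerate mode
    if (max_degeneracy > 1L) {
      for (i in which(ok_cons & amb)) {
        wseq <- paste(ch[st[i]:en[i]], collapse = "")
        degen <- iupac_degeneracy(ch[st[i]:en[i]])
        if (degen > max_degeneracy) {
          diag[["degeneracy"]] <- diag[["degeneracy"]] + 1L
          next
        }
        variants <- expand_iupac(wseq)
        tms <- vapply(variants, primer_tm, 0)
        if (any(tms < tm_range[1L] | tms > tm_range[2L])) {
          diag[["tm"]] <- diag[["tm"]] + 1L
          next
        }
        gcs <- vapply(variants, gc_fraction, 0)
        if (mean(gcs) < gc_range[1L] || mean(gcs) > gc_range[2L]) {
          diag[["gc"]] <- diag[["gc"]] + 1L
          next
        }
        windows <- rbind(windows, data.frame(
          start = st[i], end = en[i], len = len,
          tm = mean(tms), gc = mean(gcs), degen = degen))
      }
    }
  }
  out <- NULL
  if (!is.null(windows) && nrow(windows) >= 2L) {
    w <- windows
    n <- nrow(w)
    fi <- rep(seq_len(n), each = n)
    ri <- rep(seq_len(n), times = n)
    prod <- w$end[ri] - w$start[fi] + 1L
    sel <- prod >= product_range[1L] & prod <= product_range[2L]
    fi <- fi[sel]; ri <- ri[sel]; prod <- prod[sel]
    if (length(fi)) {
      wseq <- substring(s, w$start, w$end)
      rseq <- vapply(unique(ri), function(i) revcomp_str(wseq[i]), "")
      names(rseq) <- as.character(unique(ri))
      out <- data.frame(
        forward = wseq[fi], reverse = rseq[as.character(ri)],
        forward_start = w$start[fi] - 1L, forward_end = w$end[fi],
        reverse_start = w$start[ri] - 1L, reverse_end = w$end[ri],
        length_f = w$len[fi], length_r = w$len[ri],
        tm_f = w$tm[fi], tm_r = w$tm[ri], gc_f = w$gc[fi], gc_r = w$gc[ri],
        degeneracy = w$degen[fi] * w$degen[ri],
        product_size = prod, stringsAsFactors = FALSE)
    }
  }
  if (is.null(out))
    out <- data.frame(forward = character(0), reverse = character(0),
                      forward_start = integer(0), forward_end = integer(0),
                      reverse_start = integer(0), reverse_end = integer(0),
                      length_f = integer(0), length_r = integer(0),
                      tm_f = numeric(0), tm_r = numeric(0),
                      gc_f = numeric(0), gc_r = numeric(0),
                      degeneracy = numeric(0), product_size = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- out[order(abs(out$tm_f - out$tm_r), abs(out$product_size - 150L),
                     out$forward_start, out$reverse_start), , drop = FALSE]
    if (nrow(out) > max_pairs) out <- out[seq_len(max_pairs), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, diagnostics = diag, class = c("PrimerPairList", "data.frame"))
}

# All concrete A/C/G/T expansions of an IUPAC string (small degeneracy only).
expand_iupac <- function(s) {
  sets <- lapply(strsplit(s, "")[[1L]], function(c) {
    m <- IUPAC_MASK[[c]]
    c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
  })
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}

# Vectorized IUPAC-compatible mismatch scan of `primer` along genome chars gv
# (integer masks). Returns starts (1-based) and mismatch counts for sites with
# <= max_mismatch mismatches and an exact 3' tail of `exact_tail` bases, where
# tail_side is "right" (plus-strand orientation) or "left" (minus strand).
scan_sites <- function(gmask, primer, max_mismatch, exact_tail, tail_side) {
  k <- nchar(primer)
  L <- length(gmask)
  if (L < k) return(data.frame(start = integer(0), mismatches = integer(0)))
  pmask <- IUPAC_MASK[strsplit(primer, "")[[1L]]]
  n <- L - k + 1L
  mm <- integer(n)
  tail_pos <- if (tail_side == "right") (k - exact_tail + 1L):k else seq_len(exact_tail)
  tail_mm <- integer(n)
  for (o in seq_len(k)) {
    hit <- bitwAnd(gmask[o:(o + n - 1L)], pmask[o]) > 0L
    mm <- mm + !hit
    if (o %in% tail_pos) tail_mm <- tail_mm + !hit
  }
  keep <- mm <= max_mismatch & tail_mm == 0L
  data.frame(start = which(keep), mismatches = mm[keep])
}

#' In-silico PCR specificity check
#'
#' Finds all binding sites of a primer pair on both strands of each genome
#' (allowing up to `max_mismatch` IUPAC-compatible mismatches but none in the
#' 3'-terminal `three_prime_exact` bases), pairs facing sites within
#' `max_product`, and reports every predicted amplicon. A pair is specific in
#' a genome when exactly one amplicon is predicted.
#'
#' @param pair A [primer_pair()], one row of an [enumerate_primers()] result,
#'   or a list with `forward` and `reverse`.
#' @param genomes A named list of [sequence_set()] objects (one per genome);
#'   a single `SequenceSet` is treated as one genome.
#' @param max_mismatch Maximum mismatches per primer site, default 2.
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly, default 5.
#' @param max_product Maximum amplicon length in bases, default 5000.
#' @return List of class `"SpecificityReport"`: per genome a list with
#'   `amplicons` (data frame: `contig`, `start`, `end` 0-based half-open,
#'   `plus_primer`, `minus_primer`, `mismatch_plus`, `mismatch_minus`),
#'   `specific` and `reason`; plus `all_specific` over genomes.
#' @export
check_specificity <- function(pair, genomes, max_mismatch = 2L,
                              three_prime_exact = 5L, max_product = 5000L) {
  fwd <- toupper(pair$forward); rev <- toupper(pair$reverse)
  if (inherits(genomes, "SequenceSet")) genomes <- list(genome = genomes)
  if (is.null(names(genomes)))
    names(genomes) <- sprintf("genome%d", seq_along(genomes))
  primers <- c(F = fwd, R = rev)
  res <- lapply(genomes, function(gs) {
    amps <- list()
    for (ci in seq_along(gs$ids)) {
      contig <- gs$ids[[ci]]
      gmask <- IUPAC_MASK[strsplit(gs$sequences[[ci]], "")[[1L]]]
      plus <- lapply(primers, scan_sites, gmask = gmask,
                     max_mismatch = max_mismatch,
                     exact_tail = three_prime_exact, tail_side = "right")
      minus <- lapply(primers, function(p)
        scan_sites(gmask, revcomp(p), max_mismatch, three_prime_exact, "left"))
      for (pa in names(primers)) for (pb in names(primers)) {
        sp <- plus[[pa]]; sm <- minus[[pb]]
        if (!nrow(sp) || !nrow(sm)) next
        kb <- nchar(primers[[pb]])
        for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(sm))) {
          s1 <- sp$start[i]; s2 <- sm$start[j]
          prod <- s2 + kb - s1
          if (s2 >= s1 && prod <= max_product) {
            amps[[length(amps) + 1L]] <- data.frame(
              contig = contig, start = s1 - 1L, end = s2 + kb - 1L,
              plus_primer = pa, minus_primer = pb,
              mismatch_plus = sp$mismatches[i],
              mismatch_minus = sm$mismatches[j],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    amps <- if (length(amps)) unique(do.call(rbind, amps)) else
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 plus_primer = character(0), minus_primer = character(0),
                 mismatch_plus = integer(0), mismatch_minus = integer(0),
                 stringsAsFactors = FALSE)
    rownames(amps) <- NULL
    list(amplicons = amps, specific = nrow(amps) == 1L,
         reason = if (nrow(amps) == 1L) "unique_amplicon"
                  else if (nrow(amps) == 0L) "no_amplicon"
                  else "multiple_amplicons")
  })
  structure(c(res, list(all_specific = all(vapply(res, `[[`, TRUE, "specific")))),
            class = "SpecificityReport")
}

#' Design universal primers across congeneric species
#'
#' Full pipeline: best-per-species ortholog selection against the species
#' databases, center-star consensus of the ortholog group, constrained
#' enumeration of primer pairs on the consensus, and in-silico specificity
#' verification against each genome. Only pairs specific in every genome are
#' returned as universal.
#'
#' @param query Query transcript (character string or one-record
#'   [sequence_set()]).
#' @param dbs A [sequence_set()] (with species tags) or list of them,
#'   providing the per-species transcript databases.
#' @param genomes Named list of [sequence_set()] genomes for the specificity
#'   scan (defaults to `dbs` when omitted).
#' @param max_candidates How many top-ranked enumerated pairs to carry into
#'   the specificity scan, default 20.
#' @param ... Passed to [enumerate_primers()].
#' @inheritParams find_orthologs
#' @return List of class `"UniversalPrimerDesign"`: `orthologs`, `consensus`,
#'   `primers` (universal pairs with a `specificity` report each) and
#'   `candidates` (all enumerated pairs).
#' @export
design_universal_primers <- function(query, dbs, genomes = NULL,
                                     min_identity = 70, min_coverage = 0.5,
                                     max_candidates = 20L,
                                     query_id = "query", ...) {
  if (inherits(dbs, "SequenceSet")) dbs <- list(dbs)
  db <- do.call(combine_sequence_sets, dbs)
  if (is.null(genomes)) genomes <- stats::setNames(dbs, vapply(
    dbs, function(d) d$species[[1L]], ""))
  og <- find_orthologs(query, db, min_identity = min_identity,
                       min_coverage = min_coverage, query_id = query_id)
  seqs <- og$sequences
  qid <- og$query_id
  if (!og$query_id %in% names(seqs))
    seqs <- c(stats::setNames(og$query_seq, qid), seqs)
  cons <- if (length(seqs) >= 2L) align_group(seqs) else
    structure(list(alignment = seqs,
                   consensus = seqs[[1L]],
                   conservation = rep(1, nchar(seqs[[1L]])),
                   gap_free = rep(TRUE, nchar(seqs[[1L]]))),
              class = "ConsensusSequence")
  cand <- enumerate_primers(cons, ...)
  keep <- list(); reports <- list()
  for (i in seq_len(min(nrow(cand), max_candidates))) {
    rep_i <- check_specificity(cand[i, ], genomes)
    if (rep_i$all_specific) {
      keep[[length(keep) + 1L]] <- cand[i, , drop = FALSE]
      reports[[length(reports) + 1L]] <- rep_i
    }
  }
  primers <- if (length(keep)) do.call(rbind, keep) else cand[0, , drop = FALSE]
  rownames(primers) <- NULL
  structure(list(orthologs = og, consensus = cons, primers = primers,
                 specificity = reports, candidates = cand),
            class = "UniversalPrimerDesign")
}

#' Combine sequence sets
#' @param ... [sequence_set()] objects.
#' @return A single [sequence_set()] with all records.
#' @export
combine_sequence_sets <- function(...) {
  sets <- list(...)
  sequence_set(unlist(lapply(sets, `[[`, "ids")),
               unlist(lapply(sets, `[[`, "sequences")),
               unlist(lapply(sets, `[[`, "species")))
}
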