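# Nearest-neighbor duplex thermodynamics (unified DNA parameters):
# dH in kcal/mol, dS in cal/(mol K) per 5'->3' dinucleotide stack.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation terms by terminal base pair
INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Primer melting temperature (nearest-neighbor model)
#'
#' Tm of a DNA oligo against its perfect complement from nearest-neighbor
#' enthalpy/entropy sums with duplex-initiation terms, an entropic salt
#' correction `dS + 0.368 (L-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15` for a non-self-complementary
#' oligo at total strand concentration C.
#'
#' @param seq Primer sequence, 5'->3', A/C/G/T only.
#' @param monovalent Monovalent cation concentration in mol/L; default 0.05.
#' @param oligo_conc Oligo concentration in mol/L; default 250e-9.
#' @return Tm in degrees Celsius.
#' @export
#' @examples
#' primer_tm("ACGTAGCTAGGCTAGCTAGG")
primer_tm <- function(seq, monovalent = 0.05, oligo_conc = 250e-9) {
  s <- toupper(seq)
  if (grepl("[^ACGT]", s)) stop("Tm model requires an unambiguous A/C/G/T sequence")
  n <- nchar(s)
  if (n < 8L) stop("sequence too short for the nearest-neighbor model")
  b <- strsplit(s, "")[[1L]]
  stacks <- paste0(b[-n], b[-1L])
  dH <- sum(NN_DH[stacks]) + INIT_DH[[b[1L]]] + INIT_DH[[b[n]]]
  dS <- sum(NN_DS[stacks]) + INIT_DS[[b[1L]]] + INIT_DS[[b[n]]]
  dS <- dS + 0.368 * (n - 1L) * log(monovalent)
  R <- 1.98720425864083
  1000 * dH / (dS + R * log(oligo_conc / 4)) - 273.15
}

#' GC fraction of a sequence
#' @param seq Nucleotide string.
#' @return Fraction of G or C bases.
#' @export
gc_fraction <- function(seq) {
  s <- toupper(seq)
  nchar(gsub("[^GCS]", "", s)) / nchar(s)
}
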