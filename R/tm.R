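# Nearest-neighbor duplex thermodynamics (SantaLucia 1998 unified parameters).

# dH in kcal/mol, dS in cal/(mol K); keyed by the sense-strand dinucleotide.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation at a terminal A/T or G/C base pair
.INIT_AT <- c(dh = 2.3, ds = 4.1)
.INIT_GC <- c(dh = 0.1, ds = -2.8)
.GAS_CONSTANT <- 1.987 # cal/(mol K)

#' Nearest-neighbor melting temperature of a short DNA duplex
#'
#' Predicts the melting temperature of a primer-length oligonucleotide
#' hybridised to its perfect complement, using unified nearest-neighbor
#' enthalpy/entropy parameters with terminal initiation terms, a monovalent
#' salt entropy correction of 0.368 (N-1) ln\[Na+\], and the two-state
#' formula Tm = 1000 dH / (dS + R ln CT). Defaults correspond to standard
#' assay-design conditions (25 nM each strand, 50 mM Na+).
#'
#' @param seq character vector of DNA sequences over A/C/G/T.
#' @param dnac1,dnac2 concentrations of the two strands in nM; the effective
#'   duplex concentration is `dnac1 - dnac2/2` (non-self-complementary case).
#' @param na monovalent cation concentration in mM.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
#' @examples
#' tm_nearest_neighbor("ACGTAGCTAGCATGCATGCAGCT")
tm_nearest_neighbor <- function(seq, dnac1 = 25, dnac2 = 25, na = 50) {
  vapply(seq, function(s) {
    s <- toupper(s)
    .assert_dna(s)
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    if (n < 2) stop("sequence too short for nearest-neighbor model", call. = FALSE)
    nn <- paste0(b[-n], b[-1])
    dh <- sum(.NN_DH[nn])
    ds <- sum(.NN_DS[nn])
    for (end in c(b[1], b[n])) {
      init <- if (end %in% c("A", "T")) .INIT_AT else .INIT_GC
      dh <- dh + init[["dh"]]
      ds <- ds + init[["ds"]]
    }
    selfcomp <- identical(s, .revcomp(s))
    if (selfcomp) {
      ds <- ds - 1.4                      # symmetry correction
      ct <- dnac1 * 1e-9
    } else {
      ct <- (dnac1 - dnac2 / 2) * 1e-9
    }
    ds <- ds + 0.368 * (n - 1) * log(na / 1000)
    1000 * dh / (ds + .GAS_CONSTANT * log(ct)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.assert_dna <- function(s) {
  if (grepl("[^ACGT]", s))
    stop("sequence contains characters outside {A,C,G,T}: ", s, call. = FALSE)
  invisible(s)
}
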