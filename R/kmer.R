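# Exact k-mer background index for uniqueness screening.

#' Build a background k-mer index
#'
#' Indexes every k-mer of a background sequence collection (e.g. a genome
#' or transcriptome slice) on both strands, stored in canonical form (the
#' lexicographic minimum of a k-mer and its reverse complement). A
#' candidate UR is "unique" when none of its k-mers occurs in the
#' background on either strand.
#'
#' @param background a `Biostrings::DNAStringSet`, a named character vector
#'   of sequences, or the path to a FASTA file.
#' @param k k-mer size (default 12).
#' @return an object of class `ur_background_index`.
#' @export
background_index <- function(background, k = 12L) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.character(background) && length(background) == 1 &&
      file.exists(background)) {
    background <- read_fasta(background)
  }
  if (is.character(background)) {
    background <- Biostrings::DNAStringSet(toupper(background))
  }
  seqs <- as.character(background)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  canon <- canonical_kmer(kmers)
  structure(list(k = k, kmers = unique(canon)),
            class = "ur_background_index")
}

canonical_kmer <- function(kmers) {
  if (!length(kmers)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' @export
print.ur_background_index <- function(x, ...) {
  cat(sprintf("Background k-mer index: k = %d, %d distinct canonical k-mers\n",
              x$k, length(x$kmers)))
  invisible(x)
}

#' Screen a candidate UR for background uniqueness
#'
#' Returns `FALSE` (and appends the reason `not_unique` when a candidate
#' row is supplied) if any k-mer of the candidate occurs in the indexed
#' background on either strand; `TRUE` otherwise.
#'
#' @param candidate candidate row, list, or a bare sequence string.
#' @param index an [background_index()] object.
#' @return logical scalar; when `candidate` is a row/list the updated
#'   candidate is available via attribute `candidate`.
#' @export
check_uniqueness <- function(candidate, index) {
  s <- if (is.character(candidate) && length(candidate) == 1) toupper(candidate)
       else candidate_sequence(candidate)
  .assert_dna(s)
  if (index$k > nchar(s))
    stop("index k exceeds candidate length", call. = FALSE)
  starts <- seq_len(nchar(s) - index$k + 1L)
  kmers <- canonical_kmer(substring(s, starts, starts + index$k - 1L))
  unique_ok <- !any(kmers %in% index$kmers)
  out <- unique_ok
  if (!is.character(candidate)) {
    cand <- if (unique_ok) candidate else add_reasons(candidate, "not_unique")
    attr(out, "candidate") <- cand
  }
  out
}

#' Screen a candidate UR against already accepted URs
#'
#' Computes ungapped same-length identity between the candidate and every
#' accepted UR, and between the candidate and each accepted UR's reverse
#' complement; returns `FALSE` when any identity exceeds the constraint
#' ceiling (strict inequality, default 0.75).
#'
#' @param candidate candidate row, list, or sequence string.
#' @param accepted character vector of accepted UR sequences (may be empty).
#' @param constraints an [design_constraints()] object.
#' @return logical scalar.
#' @export
check_cross_specificity <- function(candidate, accepted, constraints) {
  s <- if (is.character(candidate) && length(candidate) == 1) toupper(candidate)
       else candidate_sequence(candidate)
  if (!length(accepted)) return(TRUE)
  accepted <- toupper(accepted)
  if (any(nchar(accepted) != nchar(s)))
    stop("accepted URs must match candidate length", call. = FALSE)
  xi <- utf8ToInt(s)
  ri <- utf8ToInt(revcomp_chr(s))
  ids <- vapply(accepted, function(a) {
    ai <- utf8ToInt(a)
    max(mean(xi == ai), mean(ri == ai))
  }, numeric(1), USE.NAMES = FALSE)
  all(ids <= constraints$max_pairwise_identity)
}

#' Ungapped identity between two equal-length sequences
#' @param a,b sequences of equal length.
#' @return fraction of positions with identical nucleotides.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must be of equal length", call. = FALSE)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  mean(x == y)
}
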