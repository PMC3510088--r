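# Candidate UR generation and per-sequence screening.

#' Generate candidate UR sequences
#'
#' Draws `n` random sequences of the constrained length, uniformly over
#' A/C/G/T, reproducibly from the seed carried by the constraints. No
#' screening is applied; GC fraction and nearest-neighbor Tm are annotated
#' so downstream screens and the Tm-window pass can filter without
#' recomputation.
#'
#' @param constraints an [design_constraints()] object.
#' @param n number of candidates to draw.
#' @return data.frame with columns `sequence`, `gc`, `tm` and an empty
#'   `rejection_reasons` list-column.
#' @export
generate_candidates <- function(constraints, n) {
  validate_constraints(constraints)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  seqs <- with_preserved_rng(constraints$seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), constraints$ur_length,
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  data.frame(sequence = seqs,
             gc = gc_fraction(seqs),
             tm = tm_nearest_neighbor(seqs),
             rejection_reasons = I(replicate(n, character(0), simplify = FALSE)),
             stringsAsFactors = FALSE)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' GC fraction of DNA sequences
#' @param seq character vector over A/C/G/T.
#' @return numeric vector of GC fractions.
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Screen a candidate's base composition
#'
#' Appends a rejection reason for each violated rule: `gc_out_of_range`
#' when the GC fraction leaves the constraint window, `tm_out_of_range`
#' when the nearest-neighbor Tm does, and `identical_run` when the sequence
#' contains a run of more than `max_identical_run` identical nucleotides
#' (default: tetranucleotide runs and longer rejected).
#'
#' @param candidate one row of a candidate data.frame (or a list with
#'   `sequence`, `gc`, `tm`, `rejection_reasons`).
#' @param constraints an [design_constraints()] object.
#' @return the candidate with `rejection_reasons` updated.
#' @export
check_composition <- function(candidate, constraints) {
  s <- candidate_sequence(candidate)
  .assert_dna(s)
  if (nchar(s) != constraints$ur_length)
    stop("candidate length differs from constrained ur_length", call. = FALSE)
  reasons <- character(0)
  gc <- if (!is.null(candidate$gc) && length(candidate$gc)) candidate$gc else gc_fraction(s)
  tm <- if (!is.null(candidate$tm) && length(candidate$tm)) candidate$tm else tm_nearest_neighbor(s)
  if (gc < constraints$gc_min || gc > constraints$gc_max)
    reasons <- c(reasons, "gc_out_of_range")
  if (tm < constraints$tm_min || tm > constraints$tm_max)
    reasons <- c(reasons, "tm_out_of_range")
  if (max_run_length(s) > constraints$max_identical_run)
    reasons <- c(reasons, "identical_run")
  add_reasons(candidate, reasons)
}

#' Longest run of identical nucleotides
#' @param seq character vector of DNA sequences.
#' @return integer vector of maximal run lengths.
#' @export
max_run_length <- function(seq) {
  vapply(seq, function(s) {
    max(rle(strsplit(s, "")[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Screen a candidate for secondary-structure potential
#'
#' Scans the candidate fused to its downstream constant-region context for
#' (i) intramolecular inverted repeats — two non-overlapping windows, at
#' least three nucleotides apart (the minimal hairpin loop), where one is
#' the reverse complement of the other — with stem length exceeding
#' `max_hairpin_stem`, and (ii) self-complementary windows (a window whose
#' reverse complement also occurs anywhere in the molecule, the
#' intermolecular self-dimer case) longer than `max_self_dimer`. Both
#' bounds are strict: a stem of exactly the maximum passes.
#'
#' @param candidate candidate row or list.
#' @param context constant-region sequence appended 3' of the UR (may be "").
#' @param constraints an [design_constraints()] object.
#' @return the candidate with `rejection_reasons` updated (labels
#'   `hairpin`, `self_dimer`).
#' @export
check_secondary_structure <- function(candidate, context = "", constraints) {
  s <- candidate_sequence(candidate)
  .assert_dna(s)
  if (nzchar(context)) .assert_dna(toupper(context))
  full <- paste0(s, toupper(context))
  reasons <- character(0)
  if (has_inverted_repeat(full, constraints$max_hairpin_stem + 1L, min_loop = 3L))
    reasons <- c(reasons, "hairpin")
  if (has_self_complementary_window(full, constraints$max_self_dimer + 1L))
    reasons <- c(reasons, "self_dimer")
  add_reasons(candidate, reasons)
}

# reverse complement on a plain string, no external types
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Any pair of windows of length len, separated by >= min_loop nt, that are
# reverse complements of each other. A window of length len exists in every
# longer stem, so testing one length suffices. The reverse complement of
# the window at i is a window of revcomp(seq), so one full-sequence
# complement serves all windows.
has_inverted_repeat <- function(seq, len, min_loop = 3L) {
  n <- nchar(seq)
  if (len > floor((n - min_loop) / 2)) return(FALSE)
  starts <- seq_len(n - len + 1L)
  wins <- substring(seq, starts, starts + len - 1L)
  rc <- revcomp_chr(seq)
  rcs <- substring(rc, n - starts - len + 2L, n - starts + 1L)
  last <- n - len + 1L
  for (i in starts) {
    j_min <- i + len + min_loop
    if (j_min > last) break
    if (rcs[i] %in% wins[j_min:last]) return(TRUE)
  }
  FALSE
}

# A window whose reverse complement occurs anywhere in the molecule
# (including overlapping itself): two copies of the molecule could anneal.
has_self_complementary_window <- function(seq, len) {
  n <- nchar(seq)
  if (len > n) return(FALSE)
  starts <- seq_len(n - len + 1L)
  wins <- substring(seq, starts, starts + len - 1L)
  rc <- revcomp_chr(seq)
  rcs <- substring(rc, n - starts - len + 2L, n - starts + 1L)
  any(rcs %in% wins)
}

candidate_sequence <- function(candidate) {
  s <- candidate$sequence
  if (is.null(s) || length(s) != 1 || !nzchar(s))
    stop("candidate must carry a single non-empty sequence", call. = FALSE)
  toupper(s)
}

add_reasons <- function(candidate, reasons) {
  existing <- candidate$rejection_reasons
  if (is.list(existing)) existing <- existing[[1]]
  if (is.null(existing)) existing <- character(0)
  updated <- union(existing, reasons)
  if (is.data.frame(candidate)) {
    candidate$rejection_reasons <- I(list(updated))
  } else {
    candidate$rejection_reasons <- updated
  }
  candidate
}
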