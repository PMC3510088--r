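# Reporter construct assembly: UR + constant region + assay oligos.

# Fixed architecture of the reporter transcript/amplicon. The published
# constant-region and universal-primer sequences live in supplementary
# material that is not redistributed here; these are synthetic stand-ins
# with the same lengths and roles, screened by the package's own filters.
#   5' tag (39 nt, carries the universal labelled forward primer site)
#   + UR variable region (23 nt)
#   + constant region (58 nt, carries the hydrolysis-probe site and the
#     universal reverse primer site)
#   = 120 bp amplicon.
UR_FIVE_PRIME_TAG <- "TCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCA"
UR_CONSTANT_REGION <-
  "CGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGT"
UR_UNIVERSAL_FORWARD <- substr(UR_FIVE_PRIME_TAG, 1L, 22L)
UR_PROBE_SITE <- substr(UR_CONSTANT_REGION, 7L, 30L)

#' Universal assay oligos of the reporter architecture
#'
#' Returns the constant sequences shared by every reporter: the 5' tag
#' with the universal labelled forward primer, the 58-nt constant region,
#' the hydrolysis-probe site within it, and the universal reverse primer
#' (reverse complement of the constant region's 3' end).
#' @return named character vector.
#' @export
universal_oligos <- function() {
  rev_site <- substr(UR_CONSTANT_REGION, nchar(UR_CONSTANT_REGION) - 19L,
                     nchar(UR_CONSTANT_REGION))
  c(five_prime_tag = UR_FIVE_PRIME_TAG,
    constant_region = UR_CONSTANT_REGION,
    universal_forward_primer = UR_UNIVERSAL_FORWARD,
    universal_probe = UR_PROBE_SITE,
    universal_reverse_primer = .revcomp(rev_site))
}

#' Design a UR reporter library for a TFBS catalogue
#'
#' Generates candidate URs from the constraint seed, screens each for base
#' composition, melting temperature, secondary structure against the
#' constant-region context, exact k-mer uniqueness against the background
#' index, and cross-specificity against previously accepted URs; then
#' applies a second pass restricting the pool to `tm_spread` degrees around
#' the pool's median Tm, and deterministically assigns URs to catalogue
#' entries in order. One extra UR is reserved as the Rluc-analogue
#' normalization control.
#'
#' @param tfbs_catalogue data.frame with columns `tfbs_name`,
#'   `tfbs_sequence` (distinct names).
#' @param constraints an [design_constraints()] object.
#' @param index an [background_index()] object (may index an empty
#'   background).
#' @param batch candidates generated per screening round.
#' @param max_candidates give up after screening this many candidates.
#' @return data.frame of class `ur_library`, one row per catalogue entry
#'   plus the `Rluc` control, with the UR, its physicochemical annotation,
#'   all assay oligos and the amplicon length.
#' @export
design_library <- function(tfbs_catalogue, constraints, index,
                           batch = 500L, max_candidates = 50000L) {
  stopifnot(is.data.frame(tfbs_catalogue),
            all(c("tfbs_name", "tfbs_sequence") %in% names(tfbs_catalogue)))
  if (!nrow(tfbs_catalogue)) stop("catalogue is empty", call. = FALSE)
  if (anyDuplicated(tfbs_catalogue$tfbs_name))
    stop("catalogue names must be distinct", call. = FALSE)
  validate_constraints(constraints)
  if (index$k > constraints$ur_length)
    stop("index k exceeds ur_length", call. = FALSE)

  needed <- nrow(tfbs_catalogue) + 1L   # + Rluc-analogue control
  pool <- screen_pool(constraints, index, needed, batch, max_candidates)
  # second pass: keep URs within tm_spread of the pool median, preserving
  # generation order; top up if the window thins the pool too far
  repeat {
    med <- stats::median(pool$tm)
    keep <- abs(pool$tm - med) <= constraints$tm_spread
    if (sum(keep) >= needed) { pool <- pool[keep, , drop = FALSE]; break }
    if (attr(pool, "exhausted")) {
      stop(sprintf(paste0("candidate pool exhausted: %d accepted of %d needed ",
                          "after screening %d candidates (Tm window pass)"),
                   sum(keep), needed, attr(pool, "screened")), call. = FALSE)
    }
    pool <- screen_pool(constraints, index, 2L * nrow(pool) + needed,
                        batch, max_candidates)
  }
  pool <- pool[seq_len(needed), , drop = FALSE]

  names_out <- c(tfbs_catalogue$tfbs_name, "Rluc")
  tfbs_seq <- c(toupper(tfbs_catalogue$tfbs_sequence), NA_character_)
  uni <- universal_oligos()
  amplicon_length <- nchar(UR_FIVE_PRIME_TAG) + constraints$ur_length +
    nchar(UR_CONSTANT_REGION)
  lib <- data.frame(
    tfbs_name = names_out,
    tfbs_sequence = tfbs_seq,
    promoter_tag = "P_TK",
    ur_sequence = pool$sequence,
    gc = pool$gc,
    tm = pool$tm,
    constant_region = UR_CONSTANT_REGION,
    capture_oligo = vapply(pool$sequence, .revcomp, character(1),
                           USE.NAMES = FALSE),
    specific_forward_primer = pool$sequence,
    universal_probe_site = uni[["universal_probe"]],
    universal_reverse_site = uni[["universal_reverse_primer"]],
    amplicon_length = amplicon_length,
    stringsAsFactors = FALSE
  )
  class(lib) <- c("ur_library", "data.frame")
  lib
}

# Generate-and-screen until `needed` URs pass all per-sequence and
# pairwise screens. Regeneration from the same seed reproduces the prefix,
# so growing the request keeps the accepted pool deterministic.
screen_pool <- function(constraints, index, needed, batch, max_candidates) {
  n_req <- max(batch, needed * 4L)
  repeat {
    cands <- generate_candidates(constraints, n_req)
    accepted <- character(0)
    rows <- integer(0)
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, ]
      cand <- check_composition(cand, constraints)
      cand <- check_secondary_structure(cand, UR_CONSTANT_REGION, constraints)
      if (length(cand$rejection_reasons[[1]])) next
      if (!check_uniqueness(cand$sequence, index)) next
      if (!check_cross_specificity(cand$sequence, accepted, constraints)) next
      accepted <- c(accepted, cand$sequence)
      rows <- c(rows, i)
      if (length(accepted) >= needed * 2L && n_req >= max_candidates) break
    }
    pool <- cands[rows, c("sequence", "gc", "tm"), drop = FALSE]
    rownames(pool) <- NULL
    attr(pool, "screened") <- n_req
    attr(pool, "exhausted") <- n_req >= max_candidates
    if (length(accepted) >= needed || n_req >= max_candidates) {
      if (length(accepted) < needed) {
        stop(sprintf(paste0("candidate pool exhausted: %d accepted of %d ",
                            "needed after screening %d candidates"),
                     length(accepted), needed, n_req), call. = FALSE)
      }
      return(pool)
    }
    n_req <- min(max_candidates, n_req * 2L)
  }
}

#' Write a designed library to FASTA and a manifest TSV
#'
#' Emits `urs.fasta` (one record per UR, id = tfbs_name),
#' `assay_oligos.fasta` (captures, specific forward primers and the
#' universal oligos) and `manifest.tsv`.
#'
#' @param lib an `ur_library` from [design_library()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  urs <- Biostrings::DNAStringSet(lib$ur_sequence)
  names(urs) <- lib$tfbs_name
  write_fasta(urs, file.path(dir, "urs.fasta"))
  oligos <- c(
    stats::setNames(lib$capture_oligo, paste0(lib$tfbs_name, "_capture")),
    stats::setNames(lib$specific_forward_primer, paste0(lib$tfbs_name, "_fwd")),
    universal_oligos()
  )
  write_fasta(Biostrings::DNAStringSet(oligos),
              file.path(dir, "assay_oligos.fasta"))
  manifest <- lib[, c("tfbs_name", "ur_sequence", "gc", "tm",
                      "amplicon_length")]
  manifest$gc <- sprintf("%.4f", manifest$gc)
  manifest$tm <- sprintf("%.3f", manifest$tm)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
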