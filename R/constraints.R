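# Design constraints for unique-reporter (UR) tag sequences.

#' Constraints governing UR sequence design
#'
#' Bundles the physicochemical and uniqueness rules a candidate UR must
#' satisfy: fixed length, GC-content window, melting-temperature window,
#' no runs of four or more identical nucleotides, bounded inverted-repeat
#' (hairpin) and self-complementary (self-dimer) window lengths, exact
#' k-mer absence from a background sequence collection, and a ceiling on
#' pairwise identity with every previously accepted UR (both strands).
#'
#' Defaults encode the published reporter architecture: 23-nt variable
#' region, GC between 40 and 60 percent, no tetranucleotide runs, and a
#' 0.75 identity ceiling chosen because assay oligos were shown to
#' discriminate reporters sharing 74 percent identity. In library design a
#' second pass additionally restricts accepted URs to `tm_spread` degrees
#' around the pool median so all reporters amplify under one cycling
#' program.
#'
#' @param ur_length UR length in nucleotides.
#' @param gc_min,gc_max allowed GC fraction.
#' @param tm_min,tm_max allowed nearest-neighbor melting temperature, Celsius.
#' @param tm_spread half-width (Celsius) of the library-median Tm window
#'   enforced during library assembly.
#' @param max_identical_run longest permitted run of one nucleotide;
#'   a run of `max_identical_run + 1` is rejected.
#' @param max_hairpin_stem longest permitted intramolecular inverted-repeat
#'   stem, base pairs (strict: a stem of exactly this length passes).
#' @param max_self_dimer longest permitted self-complementary window, base
#'   pairs (strict inequality, as for hairpins).
#' @param uniqueness_k k-mer size for background uniqueness screening.
#' @param max_pairwise_identity ceiling on ungapped identity between any two
#'   accepted URs (either strand); strict inequality.
#' @param seed integer seed making candidate generation reproducible.
#' @return an object of class `ur_constraints`.
#' @export
#' @examples
#' cons <- design_constraints()
#' cons$ur_length
design_constraints <- function(ur_length = 23,
                               gc_min = 0.40, gc_max = 0.60,
                               tm_min = 50, tm_max = 64,
                               tm_spread = 3,
                               max_identical_run = 3,
                               max_hairpin_stem = 6,
                               max_self_dimer = 8,
                               uniqueness_k = 12,
                               max_pairwise_identity = 0.75,
                               seed = 1L) {
  x <- list(ur_length = as.integer(ur_length),
            gc_min = gc_min, gc_max = gc_max,
            tm_min = tm_min, tm_max = tm_max, tm_spread = tm_spread,
            max_identical_run = as.integer(max_identical_run),
            max_hairpin_stem = as.integer(max_hairpin_stem),
            max_self_dimer = as.integer(max_self_dimer),
            uniqueness_k = as.integer(uniqueness_k),
            max_pairwise_identity = max_pairwise_identity,
            seed = as.integer(seed))
  class(x) <- "ur_constraints"
  validate_constraints(x)
  x
}

validate_constraints <- function(x) {
  stopifnot(inherits(x, "ur_constraints"))
  ok <- x$ur_length >= 1 &&
    x$gc_min >= 0 && x$gc_min <= x$gc_max && x$gc_max <= 1 &&
    x$tm_min <= x$tm_max &&
    x$max_identical_run >= 2 &&
    x$max_pairwise_identity > 0 && x$max_pairwise_identity <= 1 &&
    x$uniqueness_k >= 1 && x$tm_spread >= 0
  if (!ok) stop("invalid design constraints", call. = FALSE)
  invisible(x)
}

#' @export
print.ur_constraints <- function(x, ...) {
  cat(sprintf(
    "UR design constraints: length %d nt, GC [%.2f, %.2f], Tm [%.1f, %.1f] C,\n",
    x$ur_length, x$gc_min, x$gc_max, x$tm_min, x$tm_max))
  cat(sprintf(
    "  max run %d, hairpin stem <= %d bp, self-dimer <= %d bp, k = %d,\n",
    x$max_identical_run, x$max_hairpin_stem, x$max_self_dimer, x$uniqueness_k))
  cat(sprintf("  pairwise identity < %.2f, seed %d\n",
              x$max_pairwise_identity, x$seed))
  invisible(x)
}
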