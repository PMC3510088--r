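# UR design: generation, physicochemical screens, uniqueness,
# cross-specificity and library assembly.

test_that("candidate generation is seed-reproducible and correctly annotated", {
  cons <- design_constraints(seed = 1L)
  a <- generate_candidates(cons, 5)
  b <- generate_candidates(cons, 5)
  expect_identical(a$sequence, b$sequence)
  expect_true(all(nchar(a$sequence) == 23L))

  many <- generate_candidates(cons, 1000)
  expect_equal(many$gc, vapply(many$sequence, oracle_gc, numeric(1),
                               USE.NAMES = FALSE))
  expect_error(generate_candidates(cons, 0), "positive")
})

test_that("nearest-neighbor Tm matches an independent thermodynamic-table implementation", {
  # reference values from an independent nearest-neighbor implementation
  # on the same unified parameter set (25 nM strands, 50 mM Na+)
  oracle <- c(ACGTAGCTAGCATGCATGCAGCT = 59.081396,
              GGGCCCGGGCCCGGGCCCGGGCC = 77.771105,
              ATATATATATATATATATATATA = 27.880341,
              ACGTACGTACGTACGTACGTACG = 56.467628,
              TGCAGTCCATGGACTGACTTGCA = 58.506530,
              AATTCCGGAATTCCGGAATTCCG = 55.655112,
              CAGTCAGTCAGTCAGTCAGTCAG = 54.491660,
              GCGCATATGCGCATATGCGCATA = 59.234866)
  expect_equal(tm_nearest_neighbor(names(oracle)), unname(oracle),
               tolerance = 1e-5)
})

test_that("composition screen flags GC, Tm and identical-run violations", {
  cons <- design_constraints()
  tetra <- list(sequence = "ACGTAAAAGCTAGCTAGCATGCA", rejection_reasons = character(0))
  out <- check_composition(tetra, cons)
  expect_true("identical_run" %in% out$rejection_reasons)

  all_g <- list(sequence = strrep("G", 23), rejection_reasons = character(0))
  out <- check_composition(all_g, cons)
  expect_setequal(out$rejection_reasons, c("gc_out_of_range", "identical_run",
                                           "tm_out_of_range"))

  # a probe whose Tm (58.5 C by the independent oracle) is inside the window
  ok <- list(sequence = "TGCAGTCCATGGACTGACTTGCA", rejection_reasons = character(0))
  out <- check_composition(ok, cons)
  expect_false("tm_out_of_range" %in% out$rejection_reasons)

  expect_error(check_composition(list(sequence = strrep("N", 23)), cons),
               "outside")
  # runs of exactly max_identical_run are accepted
  run3 <- list(sequence = "AAACGTCGTACGATCGTACGCAT", rejection_reasons = character(0))
  expect_false("identical_run" %in%
                 check_composition(run3, cons)$rejection_reasons)
})

test_that("secondary-structure screen agrees with exhaustive window search", {
  cons <- design_constraints()
  # perfect palindromic stem: x + revcomp(x) is maximally self-complementary
  pal <- paste0("ACGTGCTAGCA", oracle_revcomp("ACGTGCTAGCA"), "A")
  out <- check_secondary_structure(list(sequence = pal,
                                        rejection_reasons = character(0)),
                                   "", cons)
  expect_true(all(c("hairpin", "self_dimer") %in% out$rejection_reasons))

  set.seed(11)
  for (s in random_dna(120, 23L)) {
    cand <- list(sequence = s, rejection_reasons = character(0))
    out <- check_secondary_structure(cand, "", cons)
    expect_identical("hairpin" %in% out$rejection_reasons,
                     oracle_has_hairpin(s, cons$max_hairpin_stem + 1L))
    expect_identical("self_dimer" %in% out$rejection_reasons,
                     oracle_has_self_dimer(s, cons$max_self_dimer + 1L))
  }
})

test_that("a stem of exactly max_hairpin_stem passes (strict inequality)", {
  cons <- design_constraints(max_hairpin_stem = 6, max_self_dimer = 8)
  stem <- "GCATCG"                       # 6 bp
  s <- paste0(stem, "TTTT", oracle_revcomp(stem), "ATCGATA")
  expect_false(oracle_has_hairpin(s, 7L))
  out <- check_secondary_structure(list(sequence = s,
                                        rejection_reasons = character(0)),
                                   "", cons)
  expect_false("hairpin" %in% out$rejection_reasons)
})

test_that("uniqueness screen equals a naive substring scan of the background", {
  set.seed(3)
  bg <- random_dna(4, 300L)
  idx <- background_index(setNames(bg, paste0("bg", 1:4)), k = 12)

  # verbatim copy of a background window is never unique
  copied <- substr(bg[1], 10, 32)
  expect_false(check_uniqueness(copied, idx))

  # empty background accepts anything
  empty_idx <- background_index(character(0), k = 12)
  expect_true(check_uniqueness("ACGTACGTAAGCTTGCACGTCCA", empty_idx))

  # sharing only an 11-mer with the background is still unique at k = 12
  frag11 <- substr(bg[2], 50, 60)
  cand <- paste0(frag11, paste(rep("A", 12), collapse = ""))
  while (oracle_shares_kmer(cand, bg, 12L)) {
    cand <- paste0(frag11, random_dna(1, 12L))
  }
  expect_true(check_uniqueness(cand, idx))

  for (s in random_dna(60, 23L)) {
    expect_identical(check_uniqueness(s, idx),
                     !oracle_shares_kmer(s, bg, 12L))
  }
  # spiked candidates that must collide
  for (i in 1:10) {
    s <- substr(bg[sample(4, 1)], 100 + i, 122 + i)
    expect_false(check_uniqueness(s, idx))
  }
})

test_that("cross-specificity enforces the identity ceiling on both strands", {
  cons <- design_constraints()
  a <- "ACGTACGTAAGCTTGCACGTCCA"
  expect_false(check_cross_specificity(a, a, cons))          # identity 1.0
  b <- chartr("ACGT", "CATC", a)                             # every position differs
  expect_true(all(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  expect_true(check_cross_specificity(b, a, cons))
  expect_false(check_cross_specificity(oracle_revcomp(a), a, cons))

  # exactly 17/23 matches (~0.739) is below the 0.75 ceiling
  v <- strsplit(a, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  v[1:6] <- rot[v[1:6]]
  c17 <- paste(v, collapse = "")
  expect_equal(oracle_identity(a, c17), 17 / 23)
  expect_true(check_cross_specificity(c17, a, cons))

  expect_error(check_cross_specificity("ACGT", a, cons), "length")

  set.seed(21)
  pool <- random_dna(30, 23L)
  for (s in random_dna(50, 23L)) {
    ids <- vapply(pool, function(p)
      max(oracle_identity(s, p), oracle_identity(s, oracle_revcomp(p))),
      numeric(1))
    expect_identical(check_cross_specificity(s, pool, cons),
                     all(ids <= cons$max_pairwise_identity))
  }
})

test_that("library design is deterministic and yields the published architecture", {
  set.seed(7)
  cons <- design_constraints(seed = 5L)
  catalogue <- toy_catalogue(6L)
  idx <- background_index(setNames(random_dna(2, 400L), c("b1", "b2")), k = 12)
  lib <- design_library(catalogue, cons, idx)

  expect_equal(nrow(lib), 7L)                       # 6 TFBS + Rluc control
  expect_identical(lib$tfbs_name[7], "Rluc")
  expect_true(all(nchar(lib$ur_sequence) == 23L))
  expect_true(all(nchar(lib$constant_region) == 58L))
  expect_true(all(lib$amplicon_length == 120L))
  # capture is the reverse complement of its UR target window
  expect_identical(lib$capture_oligo,
                   vapply(lib$ur_sequence, oracle_revcomp, character(1),
                          USE.NAMES = FALSE))
  # accepted URs respect pairwise identity and background uniqueness
  for (i in seq_len(nrow(lib))) {
    expect_true(check_uniqueness(lib$ur_sequence[i], idx))
    others <- lib$ur_sequence[-i]
    expect_true(check_cross_specificity(lib$ur_sequence[i], others, cons))
  }
  # Tm window pass: all accepted within tm_spread of the library median
  expect_true(all(abs(lib$tm - median(lib$tm)) <= cons$tm_spread + 1e-9))

  # byte-identical manifests across runs
  d1 <- file.path(tempdir(), "lib1"); d2 <- file.path(tempdir(), "lib2")
  write_library(lib, d1)
  lib2 <- design_library(catalogue, cons, idx)
  write_library(lib2, d2)
  expect_identical(readLines(file.path(d1, "manifest.tsv")),
                   readLines(file.path(d2, "manifest.tsv")))
  expect_identical(readLines(file.path(d1, "urs.fasta")),
                   readLines(file.path(d2, "urs.fasta")))
})

test_that("library design fails loudly when constraints are unsatisfiable", {
  cons <- design_constraints(gc_min = 0.999, gc_max = 1.0, seed = 2L)
  idx <- background_index(character(0), k = 12)
  expect_error(design_library(toy_catalogue(2L), cons, idx,
                              max_candidates = 2000L),
               "exhausted")
})
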