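# Brute-force oracles, deliberately independent of the package internals.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_gc <- function(s) {
  b <- strsplit(s, "")[[1]]
  (sum(b == "G") + sum(b == "C")) / length(b)
}

oracle_max_run <- function(s) {
  b <- strsplit(s, "")[[1]]
  best <- 1L; cur <- 1L
  for (i in seq_along(b)[-1]) {
    cur <- if (b[i] == b[i - 1]) cur + 1L else 1L
    best <- max(best, cur)
  }
  best
}

# exhaustive (i, j) window-pair scan for an inverted repeat of stem `len`
# with loop >= min_loop
oracle_has_hairpin <- function(s, len, min_loop = 3L) {
  b <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  for (i in seq_len(n - len + 1L)) {
    for (j in seq_len(n - len + 1L)) {
      if (j < i + len + min_loop) next
      w1 <- b[i:(i + len - 1L)]
      w2 <- b[j:(j + len - 1L)]
      if (all(w1 == rev(comp[w2]))) return(TRUE)
    }
  }
  FALSE
}

# exhaustive scan for any window whose reverse complement also occurs
oracle_has_self_dimer <- function(s, len) {
  b <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  for (i in seq_len(n - len + 1L)) {
    w_rc <- rev(comp[b[i:(i + len - 1L)]])
    for (j in seq_len(n - len + 1L)) {
      if (all(b[j:(j + len - 1L)] == w_rc)) return(TRUE)
    }
  }
  FALSE
}

# naive substring scan of the background (both strands) for any shared k-mer
oracle_shares_kmer <- function(candidate, background, k) {
  for (i in seq_len(nchar(candidate) - k + 1L)) {
    km <- substr(candidate, i, i + k - 1L)
    for (bg in background) {
      if (grepl(km, bg, fixed = TRUE)) return(TRUE)
      if (grepl(km, oracle_revcomp(bg), fixed = TRUE)) return(TRUE)
    }
  }
  FALSE
}

oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  sum(x == y) / length(x)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# small TFBS catalogue for library tests
toy_catalogue <- function(n = 3L) {
  data.frame(tfbs_name = paste0("TF", seq_len(n)),
             tfbs_sequence = random_dna(n, 10L),
             stringsAsFactors = FALSE)
}

# fast model spec for unit tests
fast_spec <- function(seed = 1L, platform = "qpcr") {
  model_spec(platform, chains = 2L, iterations = 1000L, burn_in = 300L,
             adapt = 300L, seed = seed)
}
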