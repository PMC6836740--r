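# Independent oracles used by the tests. These deliberately use naive
# implementations (explicit loops, exhaustive dynamic programming,
# position sets) so they share no code with the package internals.

# per-bit hamming distance
oracle_hamming <- function(a, b) {
  d <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) d <- d + 1L
  d
}

# Gotoh global alignment score; a gap of length L costs open + L * ext
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 4, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x (horizontal)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# pointwise run-length crossover oracle: a point is accepted when its
# maximal same-phase run has length >= min_run; events are transitions
# between consecutive accepted points of different phase
oracle_crossovers <- function(phases, positions, min_run) {
  n <- length(phases)
  if (n == 0L) return(data.frame(left = numeric(0), right = numeric(0)))
  rid <- cumsum(c(TRUE, phases[-1] != phases[-n]))
  runlen <- as.integer(table(rid))[rid]
  idx <- which(runlen >= min_run)
  out <- list()
  if (length(idx) >= 2L) {
    for (t in seq_len(length(idx) - 1L)) {
      i <- idx[t]; j <- idx[t + 1L]
      if (phases[i] != phases[j])
        out[[length(out) + 1L]] <- data.frame(left = positions[i],
                                              right = positions[j])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(left = numeric(0), right = numeric(0))
}

# canonical k-mers of a sequence, one per start position
oracle_canon_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  km <- substring(seq, starts, starts + k - 1)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  pmin(km, rc)
}

# position-set breadth of coverage: matched k-mer starts expanded to
# covered positions, counted as a set
oracle_breadth <- function(frag, ref_seqs, chrom_ids, k, max_hits = 10) {
  all_ref <- unlist(lapply(ref_seqs, oracle_canon_kmers, k = k))
  tab <- table(all_ref)
  kept <- names(tab)[tab <= max_hits]
  fk <- oracle_canon_kmers(frag, k)
  out <- numeric(0)
  for (ch in unique(chrom_ids)) {
    refk <- unlist(lapply(ref_seqs[chrom_ids == ch], oracle_canon_kmers, k = k))
    hits <- which(fk %in% intersect(refk, kept))
    covered <- unique(unlist(lapply(hits, function(s) s:(s + k - 1))))
    out[ch] <- length(covered) / nchar(frag)
  }
  out
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")
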