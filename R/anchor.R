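#' Build a canonical k-mer index over reference chromosomes
#'
#' Desk-scale replacement for whole-genome aligner anchoring: every
#' k-mer of the reference is stored under its canonical form (the
#' lexicographically smaller of the k-mer and its reverse complement),
#' so lookups are strand-invariant. K-mers occurring at more than
#' `max_hits` locations are dropped as repetitive, preventing repeats
#' from dominating the coverage vote.
#'
#' @param sequences named character vector or `DNAStringSet` of
#'   reference sequences.
#' @param k odd k-mer length in `[11, 31]`.
#' @param max_hits drop k-mers with more than this many occurrences.
#' @param chrom_ids chromosome id per sequence; defaults to sequence
#'   names. Several records may share one id (e.g. the two haplotypes of
#'   a chromosome in a diploid reference).
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(sequences, k = 21L, max_hits = 10L,
                             chrom_ids = names(sequences)) {
  if (methods::is(sequences, "DNAStringSet")) {
    if (is.null(chrom_ids)) chrom_ids <- names(sequences)
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0L || all(nchar(sequences) == 0L))
    stop("build_kmer_index: empty reference", call. = FALSE)
  if (is.null(chrom_ids) || any(is.na(chrom_ids)) || any(chrom_ids == ""))
    stop("build_kmer_index: reference sequences must have chromosome ids",
         call. = FALSE)
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stop("build_kmer_index: k must be odd and in [11, 31]", call. = FALSE)
  ptr <- kmer_index_build_cpp(unname(sequences), as.character(chrom_ids),
                              k, as.integer(max_hits))
  stats <- kmer_index_stats_cpp(ptr)
  structure(list(ptr = ptr, k = k, max_hits = as.integer(max_hits),
                 chromosomes = stats$chromosomes,
                 n_kmers = stats$n_kmers,
                 n_positions = stats$n_positions,
                 n_dropped_kmers = stats$n_dropped_kmers),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d chromosome(s), %.0f kept positions, %.0f repetitive k-mers dropped\n",
              x$k, length(x$chromosomes), x$n_positions, x$n_dropped_kmers))
  invisible(x)
}

# shared best/runner-up rule; ties on the best chromosome -> unanchored
pick_anchor <- function(cov, min_coverage, fragment) {
  if (length(cov) == 0L || all(cov <= 0)) {
    return(data.frame(fragment = fragment, chromosome = NA_character_,
                      coverage = 0, runner_up = 0, reason = "no_hits",
                      stringsAsFactors = FALSE))
  }
  ord <- order(cov, decreasing = TRUE)
  best <- cov[ord[1]]
  runner <- if (length(cov) > 1L) cov[ord[2]] else 0
  if (best >= min_coverage && best > runner) {
    data.frame(fragment = fragment, chromosome = names(cov)[ord[1]],
               coverage = unname(best), runner_up = unname(runner),
               reason = NA_character_, stringsAsFactors = FALSE)
  } else if (best >= min_coverage) {
    data.frame(fragment = fragment, chromosome = NA_character_,
               coverage = unname(best), runner_up = unname(runner),
               reason = "ambiguous", stringsAsFactors = FALSE)
  } else {
    data.frame(fragment = fragment, chromosome = NA_character_,
               coverage = unname(best), runner_up = unname(runner),
               reason = "below_min_coverage", stringsAsFactors = FALSE)
  }
}

#' Anchor a fragment to a reference chromosome by breadth of coverage
#'
#' Matched k-mer start positions on the fragment are expanded to
#' k-length intervals and merged per chromosome; the union length
#' divided by the fragment length is the breadth of coverage. The
#' fragment is assigned to the best chromosome iff its coverage reaches
#' `min_coverage` (default 80%) and strictly beats the runner-up;
#' exact ties are reported unanchored with reason "ambiguous".
#'
#' @param sequence fragment sequence (character scalar).
#' @param index a [build_kmer_index()].
#' @param min_coverage minimum breadth of coverage to anchor.
#' @param fragment fragment id used in the output row.
#' @param stride query every `stride`-th k-mer start (1 = every window).
#' @return one-row data.frame: fragment, chromosome (NA = unanchored),
#'   coverage, runner_up, reason (NA when anchored).
#' @export
anchor_fragment <- function(sequence, index, min_coverage = 0.80,
                            fragment = "fragment", stride = 1L) {
  stopifnot(inherits(index, "kmer_index"))
  len <- nchar(sequence)
  if (len < index$k) {
    warning(sprintf("fragment '%s' shorter than k=%d; unanchored", fragment, index$k))
    return(data.frame(fragment = fragment, chromosome = NA_character_,
                      coverage = 0, runner_up = 0, reason = "too_short",
                      stringsAsFactors = FALSE))
  }
  covered <- kmer_query_coverage_cpp(index$ptr, sequence, as.integer(stride))
  pick_anchor(covered / len, min_coverage, fragment)
}

#' Anchor a set of fragments
#'
#' @param sequences named character vector (or `DNAStringSet`) of
#'   fragment sequences.
#' @inheritParams anchor_fragment
#' @return data.frame with one row per fragment (see [anchor_fragment()]).
#' @export
anchor_fragments <- function(sequences, index, min_coverage = 0.80, stride = 1L) {
  if (methods::is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("fragment%05d", seq_along(sequences))
  out <- lapply(seq_along(sequences), function(i)
    anchor_fragment(sequences[[i]], index, min_coverage, ids[i], stride))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read fragment anchors from a PAF alignment file
#'
#' For each (query, target) pair the query-interval union length divided
#' by the query length gives the breadth of coverage, and the same
#' >=80% single-best rule as [anchor_fragment()] is applied.
#'
#' @param path PAF file (12+ tab-separated fields per line, 0-based
#'   half-open query coordinates).
#' @param min_coverage minimum breadth of coverage to anchor.
#' @return data.frame as in [anchor_fragments()]; empty file gives an
#'   empty data.frame.
#' @export
read_paf_anchors <- function(path, min_coverage = 0.80) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(fragment = character(0), chromosome = character(0),
                      coverage = numeric(0), runner_up = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop(sprintf("read_paf_anchors: malformed PAF line %d (%d fields, expected >= 12)",
                 which(nf < 12L)[1], nf[which(nf < 12L)[1]]), call. = FALSE)
  paf <- data.frame(
    qname = vapply(fields, `[`, "", 1L),
    qlen = as.numeric(vapply(fields, `[`, "", 2L)),
    qstart = as.numeric(vapply(fields, `[`, "", 3L)),
    qend = as.numeric(vapply(fields, `[`, "", 4L)),
    tname = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE)
  if (anyNA(paf$qlen) || anyNA(paf$qstart) || anyNA(paf$qend))
    stop("read_paf_anchors: non-numeric coordinate field", call. = FALSE)
  out <- lapply(split(paf, paf$qname), function(q) {
    cov <- vapply(split(q, q$tname), function(t) {
      ir <- IRanges::reduce(IRanges::IRanges(start = t$qstart + 1, end = t$qend))
      sum(IRanges::width(ir)) / t$qlen[1]
    }, numeric(1))
    pick_anchor(cov, min_coverage, q$qname[1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize an anchor table
#'
#' @param anchors data.frame from [anchor_fragments()] or
#'   [read_paf_anchors()].
#' @return list: n_anchored, n_unanchored, total, per-chromosome counts.
#' @export
anchor_summary <- function(anchors) {
  anchored <- !is.na(anchors$chromosome)
  list(n_anchored = sum(anchored),
       n_unanchored = sum(!anchored),
       total = nrow(anchors),
       per_chromosome = table(anchors$chromosome[anchored]))
}
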