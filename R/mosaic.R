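#' Globally align a haplotype sequence to a reference gene
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (match +1, mismatch -1, gap open -4, gap extend -1 per base by
#' default), projected onto reference coordinates: each reference
#' position maps to the aligned haplotype base or "-" for a gap.
#'
#' @param ref reference gene sequence.
#' @param hap haplotype gene sequence.
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (penalties given as positive magnitudes).
#' @return list: `score` and `map` (character vector of length
#'   `nchar(ref)`).
#' @export
align_to_ref <- function(ref, hap, match = 1, mismatch = -1,
                         gap_open = 4, gap_extend = 1) {
  if (!nzchar(ref) || !nzchar(hap))
    stop("align_to_ref: empty sequence", call. = FALSE)
  if (nchar(ref) > 50000 || nchar(hap) > 50000)
    stop("align_to_ref: sequences exceed the 50 kb gene scale", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(hap),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- s != "-"
  map <- p[keep]
  stopifnot(length(map) == nchar(ref))
  list(score = Biostrings::score(al), map = map)
}

#' Diagnostic sites of a reference / haplotype-A / haplotype-B triplet
#'
#' Reference positions where the aligned A and B bases differ (both
#' non-gap) discriminate the haplotypes: the site MATCHES_A when the
#' reference base equals the A base, MATCHES_B when it equals the B
#' base, and NEITHER when the reference carries a third allele.
#' Indel-only differences (gap columns) are excluded and counted
#' separately.
#'
#' @param ref reference gene sequence.
#' @param hapA,hapB haplotype gene sequences.
#' @param exons optional data.frame (start, end), 0-based half-open
#'   gene-relative exon intervals.
#' @param ... alignment parameters for [align_to_ref()].
#' @return data.frame (pos, state, in_exon) with attribute
#'   `n_indel_cols`.
#' @export
diagnostic_sites <- function(ref, hapA, hapB, exons = NULL, ...) {
  mapA <- align_to_ref(ref, hapA, ...)$map
  mapB <- align_to_ref(ref, hapB, ...)$map
  refc <- strsplit(ref, "")[[1]]
  differ <- mapA != mapB
  both <- mapA != "-" & mapB != "-"
  idx <- which(differ & both)
  n_indel <- sum(differ & !both)
  state <- ifelse(refc[idx] == mapA[idx], "MATCHES_A",
                  ifelse(refc[idx] == mapB[idx], "MATCHES_B", "NEITHER"))
  pos <- idx - 1L
  in_exon <- if (is.null(exons) || nrow(exons) == 0L) {
    rep(FALSE, length(pos))
  } else {
    vapply(pos, function(p) any(exons$start <= p & p < exons$end), logical(1))
  }
  structure(data.frame(pos = pos, state = state, in_exon = in_exon,
                       stringsAsFactors = FALSE),
            n_indel_cols = n_indel)
}

MOSAIC_CLASSES <- c("consistent_A", "consistent_B", "identical_AB",
                    "mosaic_exon", "mosaic_intron", "unresolved")

#' Classify a gene from its diagnostic sites
#'
#' A gene is `identical_AB` with no diagnostic sites, `unresolved` when
#' NEITHER sites exceed half of all sites, `consistent_A`/`consistent_B`
#' when all informative sites match one haplotype, and mosaic when both
#' haplotypes are matched at `min_sites` or more sites each. The
#' minority haplotype's sites are the mosaic errors: any exonic minority
#' site makes the gene `mosaic_exon`, otherwise `mosaic_intron`. A
#' minority tie is broken deterministically toward the segment after the
#' first A/B switch.
#'
#' @param sites data.frame from [diagnostic_sites()].
#' @param gene gene id.
#' @param min_sites minimum sites per haplotype to call a mosaic.
#' @return one-row data.frame: gene, class, n_A, n_B, n_neither,
#'   switch_positions (comma-separated).
#' @export
classify_gene <- function(sites, gene = "gene", min_sites = 1L) {
  n_a <- sum(sites$state == "MATCHES_A")
  n_b <- sum(sites$state == "MATCHES_B")
  n_n <- sum(sites$state == "NEITHER")
  inf <- sites[sites$state != "NEITHER", , drop = FALSE]
  inf <- inf[order(inf$pos), , drop = FALSE]
  switches <- if (nrow(inf) > 1L) {
    at <- which(inf$state[-1] != inf$state[-nrow(inf)])
    inf$pos[at + 1L]
  } else integer(0)
  cls <- if (nrow(sites) == 0L) {
    "identical_AB"
  } else if (n_n > nrow(sites) / 2) {
    "unresolved"
  } else if (n_a >= min_sites && n_b >= min_sites) {
    minority <- if (n_a < n_b) "MATCHES_A"
      else if (n_b < n_a) "MATCHES_B"
      else inf$state[min(which(inf$state != inf$state[1]))]  # tie: later segment
    if (any(inf$in_exon[inf$state == minority])) "mosaic_exon" else "mosaic_intron"
  } else if (n_a > 0L && n_b == 0L) {
    "consistent_A"
  } else if (n_b > 0L && n_a == 0L) {
    "consistent_B"
  } else {
    "unresolved"
  }
  data.frame(gene = gene, class = cls, n_A = n_a, n_B = n_b, n_neither = n_n,
             switch_positions = paste(switches, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Classify a gene triplet end to end
#'
#' @param gene gene id.
#' @param ref,hapA,hapB sequences.
#' @param exons exon intervals (see [diagnostic_sites()]).
#' @param min_sites see [classify_gene()].
#' @param ... alignment parameters.
#' @return one-row data.frame as [classify_gene()].
#' @export
classify_triplet <- function(gene, ref, hapA, hapB, exons = NULL,
                             min_sites = 1L, ...) {
  classify_gene(diagnostic_sites(ref, hapA, hapB, exons, ...),
                gene = gene, min_sites = min_sites)
}

#' Summarize mosaic calls
#'
#' @param calls data.frame of [classify_gene()] rows.
#' @return list: per-class counts, n_mosaic, total, mosaic_pct
#'   (percentage of genes with mosaic errors, two decimals).
#' @export
mosaic_report <- function(calls) {
  counts <- table(factor(calls$class, levels = MOSAIC_CLASSES))
  n_mosaic <- sum(counts[c("mosaic_exon", "mosaic_intron")])
  total <- nrow(calls)
  list(counts = counts, n_mosaic = unname(n_mosaic), total = total,
       mosaic_pct = if (total) round(100 * n_mosaic / total, 2) else 0)
}
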