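#' Genotype a fragment against the pollen cells
#'
#' For each SNP site falling inside the fragment interval and each
#' pollen cell the entry is MATCH (1) when the cell's observed base
#' equals the fragment's base at that position, MISMATCH (0) when
#' observed and different, and NOCALL (NA) when the site was not
#' observed in that cell (allelic dropout).
#'
#' @param sequence fragment sequence.
#' @param chrom chromosome the fragment is anchored to.
#' @param start 0-based start of the fragment on the chromosome.
#' @param sites SNP site data.frame (chrom, pos, alleleA, alleleB).
#' @param calls per-cell observations (data.frame cell, chrom, pos, base).
#' @param cells cell ids fixing the column order (barcode bit order).
#' @param fragment fragment id.
#' @return genotype matrix: integer matrix (rows = SNPs ascending,
#'   columns = cells) with entries 1/0/NA and attributes `positions`,
#'   `fragment`, `chrom`, `start`, `end`. A fragment with no overlapping
#'   sites yields a 0-row matrix.
#' @export
genotype_fragment <- function(sequence, chrom, start, sites, calls, cells,
                              fragment = "fragment") {
  end <- start + nchar(sequence)
  sub <- sites[sites$chrom == chrom & sites$pos >= start & sites$pos < end, ,
               drop = FALSE]
  sub <- sub[order(sub$pos), , drop = FALSE]
  frag_base <- if (nrow(sub)) {
    substring(sequence, sub$pos - start + 1, sub$pos - start + 1)
  } else character(0)
  mat <- matrix(NA_integer_, nrow = nrow(sub), ncol = length(cells),
                dimnames = list(NULL, cells))
  cc <- calls[calls$chrom == chrom, , drop = FALSE]
  for (cell in cells) {
    one <- cc[cc$cell == cell, , drop = FALSE]
    m <- match(sub$pos, one$pos)
    obs <- one$base[m]
    mat[, cell] <- ifelse(is.na(obs), NA_integer_,
                          as.integer(obs == frag_base))
  }
  structure(mat, positions = sub$pos, fragment = fragment, chrom = chrom,
            start = start, end = end)
}

#' Minimum-support filter for genotype matrices
#'
#' Removes SNP rows observed (non-NOCALL) in fewer than `min_cells`
#' pollen cells; the prerequisite that a genotype must occur in at least
#' two pollen cells guards against single-cell amplification artifacts.
#' Row order is preserved and the operation is idempotent.
#'
#' @param mat a [genotype_fragment()] matrix.
#' @param min_cells minimum number of non-NOCALL cells per row.
#' @return filtered genotype matrix (attributes preserved, `positions`
#'   subset accordingly).
#' @export
filter_min_support <- function(mat, min_cells = 2L) {
  keep <- rowSums(!is.na(mat)) >= min_cells
  out <- mat[keep, , drop = FALSE]
  attributes(out) <- c(attributes(out),
                       attributes(mat)[c("fragment", "chrom", "start", "end")])
  attr(out, "positions") <- attr(mat, "positions")[keep]
  out
}

#' Per-SNP binary barcodes
#'
#' Encodes each retained SNP row as a bit vector over cells: MATCH -> 1,
#' MISMATCH -> 0, NOCALL -> 0 (absent collapses to 0; the tri-state
#' matrix is kept alongside so masked distances remain available).
#'
#' @param mat a (filtered) genotype matrix.
#' @return integer 0/1 matrix of the same shape (rows = SNP barcodes).
#' @export
snp_barcodes <- function(mat) {
  bits <- mat
  bits[is.na(bits)] <- 0L
  bits[] <- as.integer(bits > 0L)
  bits
}

#' Hamming distance between two barcodes
#'
#' Exclusive disjunction (XOR) of the bit vectors followed by a count of
#' one-bits.
#'
#' @param a,b equal-width integer 0/1 vectors.
#' @return integer distance.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b))
    stop("hamming: barcode widths differ", call. = FALSE)
  as.integer(sum(bitwXor(as.integer(a), as.integer(b))))
}

#' Bitwise complement of a barcode
#'
#' Fragments from opposite haplotypes carry complementary barcodes at
#' informative positions; `complement_barcode` flips every bit.
#'
#' @param a integer 0/1 vector.
#' @return integer 0/1 vector.
#' @export
complement_barcode <- function(a) 1L - as.integer(a)

#' @rdname hamming
#' @param observed logical mask; when given, the distance is computed
#'   over the masked bits only (mutually observed cells).
#' @export
masked_hamming <- function(a, b, observed) {
  if (length(a) != length(b) || length(a) != length(observed))
    stop("masked_hamming: widths differ", call. = FALSE)
  hamming(a[observed], b[observed])
}

barcode_to_string <- function(bits) paste0(bits, collapse = "")
string_to_barcode <- function(s) as.integer(strsplit(s, "")[[1]])

#' Summarize a fragment's SNP barcodes into a barcode profile
#'
#' Tallies barcode types over the fragment's SNP rows and computes the
#' consensus barcode: bit c is the majority over the non-NOCALL entries
#' of cell c's column (ties break to 0 and are flagged low-confidence).
#' Per-cell anchor positions (median position of the rows on which the
#' cell voted its majority bit) are retained for crossover tracking, and
#' the mean per-bit agreement with the consensus (`consensus_support`)
#' summarizes barcode-type homogeneity.
#'
#' @param mat a filtered genotype matrix ([filter_min_support()]).
#' @return object of class `barcode_profile`: fragment, chrom, start,
#'   end, midpoint, n_snps, n_supporting_cells, consensus (0/1 vector),
#'   observed (logical mask of cells with >= 1 call), low_conf (per-cell
#'   tie flag), cell_pos (per-cell median voting position),
#'   consensus_support, type_counts (named, decreasing).
#' @export
profile_fragment <- function(mat) {
  cells <- colnames(mat)
  positions <- attr(mat, "positions")
  ones <- colSums(mat == 1L, na.rm = TRUE)
  zeros <- colSums(mat == 0L, na.rm = TRUE)
  consensus <- as.integer(ones > zeros)
  low_conf <- (ones == zeros) & (ones + zeros) > 0L
  observed <- (ones + zeros) > 0L
  cell_pos <- rep(NA_real_, length(cells))
  names(cell_pos) <- cells
  for (j in seq_along(cells)) {
    if (!observed[j]) next
    votes <- which(!is.na(mat[, j]) & mat[, j] == consensus[j])
    if (!length(votes)) votes <- which(!is.na(mat[, j]))
    cell_pos[j] <- median(positions[votes])
  }
  n_obs <- sum(ones) + sum(zeros)
  support <- if (n_obs > 0) {
    agree <- sum(vapply(seq_along(cells), function(j)
      sum(mat[, j] == consensus[j], na.rm = TRUE), numeric(1)))
    agree / n_obs
  } else NA_real_
  bits <- snp_barcodes(mat)
  type_counts <- if (nrow(bits)) {
    tc <- table(apply(bits, 1L, barcode_to_string))
    sort(tc, decreasing = TRUE)
  } else table(character(0))
  start <- attr(mat, "start"); end <- attr(mat, "end")
  structure(list(
    fragment = attr(mat, "fragment"),
    chrom = attr(mat, "chrom"),
    start = start, end = end,
    midpoint = if (!is.null(start)) (start + end) / 2 else NA_real_,
    n_snps = nrow(mat),
    n_supporting_cells = sum(observed),
    consensus = setNames(consensus, cells),
    observed = setNames(observed, cells),
    low_conf = setNames(low_conf, cells),
    cell_pos = cell_pos,
    consensus_support = support,
    type_counts = type_counts
  ), class = "barcode_profile")
}

#' @export
print.barcode_profile <- function(x, ...) {
  cat(sprintf("barcode_profile %s (%s): %d SNPs, %d cells, consensus %s\n",
              x$fragment, x$chrom %||% "?", x$n_snps, x$n_supporting_cells,
              barcode_to_string(x$consensus)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genotype + filter + profile every fragment of a bac_set.
# Pre-splits the calls by (chrom, cell) so the per-fragment work is a
# vector of match() lookups.
profile_bacs <- function(bacs, sites, calls, cells, min_cells = 2L,
                         anchors = NULL) {
  recs <- bacs$records
  chrom_of <- recs$chrom
  if (!is.null(anchors)) {
    m <- match(recs$id, anchors$fragment)
    chrom_of <- anchors$chromosome[m]
  }
  lookup <- list()
  for (ch in unique(chrom_of[!is.na(chrom_of)])) {
    ccal <- calls[calls$chrom == ch, , drop = FALSE]
    lookup[[ch]] <- split(ccal[c("pos", "base")], factor(ccal$cell, levels = cells))
  }
  sites_by_chrom <- split(sites, sites$chrom)
  out <- vector("list", nrow(recs))
  names(out) <- recs$id
  for (i in seq_len(nrow(recs))) {
    ch <- chrom_of[i]
    if (is.na(ch)) next
    ssub <- sites_by_chrom[[ch]]
    if (is.null(ssub)) ssub <- sites[0, , drop = FALSE]
    sel <- ssub$pos >= recs$start[i] & ssub$pos < recs$end[i]
    sub <- ssub[sel, , drop = FALSE]
    frag_base <- substring(bacs$sequences[[recs$id[i]]],
                           sub$pos - recs$start[i] + 1,
                           sub$pos - recs$start[i] + 1)
    mat <- matrix(NA_integer_, nrow = nrow(sub), ncol = length(cells),
                  dimnames = list(NULL, cells))
    for (j in seq_along(cells)) {
      one <- lookup[[ch]][[cells[j]]]
      m <- match(sub$pos, one$pos)
      obs <- one$base[m]
      mat[, j] <- ifelse(is.na(obs), NA_integer_, as.integer(obs == frag_base))
    }
    mat <- structure(mat, positions = sub$pos, fragment = recs$id[i],
                     chrom = ch, start = recs$start[i], end = recs$end[i])
    out[[recs$id[i]]] <- profile_fragment(filter_min_support(mat, min_cells))
  }
  out[!vapply(out, is.null, logical(1))]
}
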