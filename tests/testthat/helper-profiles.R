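# construct a barcode_profile by hand for phase/mco unit tests
make_profile <- function(fragment, consensus, midpoint, chrom = "chr01",
                         n_snps = 5L, observed = NULL, low_conf = NULL,
                         cell_pos = NULL) {
  cells <- sprintf("c%d", seq_along(consensus))
  if (is.null(observed)) observed <- rep(TRUE, length(consensus))
  if (is.null(low_conf)) low_conf <- rep(FALSE, length(consensus))
  if (is.null(cell_pos)) cell_pos <- rep(midpoint, length(consensus))
  structure(list(
    fragment = fragment, chrom = chrom,
    start = midpoint - 50, end = midpoint + 50, midpoint = midpoint,
    n_snps = n_snps, n_supporting_cells = sum(observed),
    consensus = setNames(as.integer(consensus), cells),
    observed = setNames(observed, cells),
    low_conf = setNames(low_conf, cells),
    cell_pos = setNames(ifelse(observed, cell_pos, NA_real_), cells),
    consensus_support = 1.0,
    type_counts = setNames(n_snps, paste0(consensus, collapse = ""))
  ), class = "barcode_profile")
}
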