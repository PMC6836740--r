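#' Write the two haplotype sequences as FASTA
#'
#' Two records per chromosome, ids `<chrom>_A` / `<chrom>_B`.
#'
#' @param genome a `diploid_genome`.
#' @param path output FASTA path.
#' @export
write_haplotype_fasta <- function(genome, path) {
  seqs <- c(setNames(genome$hapA, paste0(names(genome$hapA), "_A")),
            setNames(genome$hapB, paste0(names(genome$hapB), "_B")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write truth SNP sites as a minimal VCF
#'
#' POS is 1-based, REF = allele A, ALT = allele B.
#'
#' @param snps SNP data.frame (chrom, pos, alleleA, alleleB).
#' @param path output path.
#' @export
write_snp_vcf <- function(snps, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=pollenphase",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  snps$chrom, snps$pos + 1L, snps$alleleA, snps$alleleB)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read biallelic SNP sites from a VCF
#'
#' 1-based VCF POS is converted to 0-based; multi-allelic and indel
#' records are skipped with a counted warning.
#'
#' @param path VCF path.
#' @return data.frame (chrom, pos, alleleA = REF, alleleB = ALT) with
#'   attribute `n_skipped`.
#' @export
read_vcf_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(structure(data.frame(chrom = character(0), pos = integer(0),
                                alleleA = character(0), alleleB = character(0),
                                stringsAsFactors = FALSE), n_skipped = 0L))
  }
  ok <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF %in% DNA_ALPHABET &
    fix$ALT %in% DNA_ALPHABET
  ok[is.na(ok)] <- FALSE
  n_skipped <- sum(!ok)
  if (n_skipped) warning(sprintf("read_vcf_snps: skipped %d non-biallelic-SNP record(s)",
                                 n_skipped))
  structure(data.frame(chrom = fix$CHROM[ok],
                       pos = as.integer(fix$POS[ok]) - 1L,
                       alleleA = fix$REF[ok], alleleB = fix$ALT[ok],
                       stringsAsFactors = FALSE),
            n_skipped = n_skipped)
}

#' Write / read per-cell SNP observations as TSV
#'
#' Columns: chrom, pos (0-based), cell, base.
#'
#' @param calls `pollen_calls` data.frame.
#' @param path file path.
#' @export
write_pollen_calls <- function(calls, path) {
  write.table(calls[c("chrom", "pos", "cell", "base")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pollen_calls
#' @export
read_pollen_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos)
  df[c("cell", "chrom", "pos", "base")]
}

#' Write fragments as FASTA plus a BED of truth intervals
#'
#' @param bacs a `bac_set`.
#' @param fasta_path,bed_path output paths.
#' @export
write_fragments <- function(bacs, fasta_path, bed_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bacs$sequences),
                              fasta_path)
  r <- bacs$records
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.\t%s",
                     r$chrom, r$start, r$end, r$id, r$haplotype), bed_path)
  invisible(fasta_path)
}

#' Read fragment truth intervals written by [write_fragments()]
#'
#' @param bed_path BED path (chrom, start, end, name, score, strand,
#'   haplotype).
#' @return data.frame (id, chrom, start, end, haplotype).
#' @export
read_fragment_bed <- function(bed_path) {
  df <- read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(id = df$V4, chrom = df$V1, start = as.integer(df$V2),
             end = as.integer(df$V3), haplotype = df$V7,
             stringsAsFactors = FALSE)
}

#' Write gamete truth as BED, one file per cell
#'
#' @param gametes a `gamete_truth`.
#' @param chrom_lengths named chromosome lengths.
#' @param dir output directory.
#' @export
write_gamete_bed <- function(gametes, chrom_lengths, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cell in names(gametes)) {
    lines <- character(0)
    for (ch in names(gametes[[cell]])) {
      g <- gametes[[cell]][[ch]]
      bounds <- c(0, g$breakpoints, chrom_lengths[[ch]])
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", ch,
                                as.integer(bounds[-length(bounds)]),
                                as.integer(bounds[-1]), g$sources))
    }
    writeLines(lines, file.path(dir, paste0(cell, ".bed")))
  }
  invisible(dir)
}

#' Write / read a per-fragment genotype matrix TSV
#'
#' Dialect: columns `fragment`, `pos` (0-based), then one column per
#' cell with values 1 (match), 0 (mismatch), "." (no call).
#'
#' @param mats named list of genotype matrices.
#' @param path file path.
#' @export
write_genotype_matrix <- function(mats, path) {
  cells <- colnames(mats[[1]])
  rows <- lapply(mats, function(m) {
    if (nrow(m) == 0L) return(NULL)
    vals <- ifelse(is.na(m), ".", as.character(m))
    data.frame(fragment = attr(m, "fragment"), pos = attr(m, "positions"),
               matrix(vals, nrow = nrow(m), dimnames = list(NULL, cells)),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @param cell_order authoritative cell ordering (barcode bit order);
#'   header cells are reconciled against it.
#' @export
read_genotype_matrix <- function(path, cell_order) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  header_cells <- setdiff(colnames(df), c("fragment", "pos"))
  unknown <- setdiff(header_cells, cell_order)
  if (length(unknown))
    stop(sprintf("read_genotype_matrix: unknown cell(s) in header: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  key <- paste(df$fragment, df$pos)
  if (anyDuplicated(key))
    stop(sprintf("read_genotype_matrix: duplicated (fragment, pos) row: %s",
                 key[anyDuplicated(key)]), call. = FALSE)
  df$pos <- as.integer(df$pos)
  lapply(split(df, df$fragment), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    m <- matrix(NA_integer_, nrow = nrow(d), ncol = length(cell_order),
                dimnames = list(NULL, cell_order))
    for (cell in header_cells) {
      v <- d[[cell]]
      v[v == "."] <- NA_character_
      m[, cell] <- as.integer(v)
    }
    structure(m, positions = d$pos, fragment = d$fragment[1],
              chrom = NULL, start = NULL, end = NULL)
  })
}

#' Write barcode profiles as TSV
#'
#' Columns: fragment, chrom, midpoint, n_snps, n_cells, consensus
#' (0/1 string in cell order), top_type, top_type_count.
#'
#' @param profiles named list of barcode profiles.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) data.frame(
    fragment = p$fragment, chrom = p$chrom %||% NA_character_,
    midpoint = p$midpoint, n_snps = p$n_snps,
    n_cells = p$n_supporting_cells,
    consensus = barcode_to_string(p$consensus),
    top_type = if (length(p$type_counts)) names(p$type_counts)[1] else "",
    top_type_count = if (length(p$type_counts)) as.integer(p$type_counts[1]) else 0L,
    stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phase-call table as TSV
#'
#' @param calls phase-call data.frame.
#' @param path file path.
#' @export
write_phase_table <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname write_phase_table
#' @export
read_phase_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  df$margin <- as.integer(df$margin)
  df
}

#' Write crossover events as BED
#'
#' Columns: chrom, left, right, name = cell, score = 0, strand = ".".
#'
#' @param events crossover event data.frame.
#' @param path file path.
#' @export
write_events_bed <- function(events, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.",
                     events$chromosome, as.integer(events$left),
                     as.integer(events$right), events$cell), path)
  invisible(path)
}

#' @rdname write_events_bed
#' @export
read_events_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(cell = character(0), chromosome = character(0),
                      left = numeric(0), right = numeric(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(cell = vapply(f, `[`, "", 4L),
             chromosome = vapply(f, `[`, "", 1L),
             left = as.numeric(vapply(f, `[`, "", 2L)),
             right = as.numeric(vapply(f, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Read / write a run configuration as YAML
#'
#' @param config a `sim_config` (or plain list).
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_config, cfg)
}
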