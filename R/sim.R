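#' Simulation configuration
#'
#' Parameters of the diploid-genome / gamete / single-cell simulator.
#' Defaults emulate the study system: a highly heterozygous (~1.02%)
#' outcrossing diploid sampled through 12 haploid pollen cells whose
#' per-cell breadth of coverage varies between 50% and 78% after
#' whole-genome amplification, with on average 1.3 meiotic crossovers
#' per chromosome per gamete concentrated at chromosome ends, and
#' haplotype-pure fragments of 10-120 kb as the phasing unit. Genome
#' size defaults to a desk-scale two-chromosome genome.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param het_rate per-bp heterozygosity, i.e. probability a position is
#'   a SNP site. In `[0, 1)`.
#' @param n_cells number of haploid pollen cells (barcode width).
#' @param coverage_range length-2 vector `(low, high)`: per-cell SNP
#'   observation fraction is drawn uniformly from this range. In `(0, 1]`.
#' @param genotype_error_rate probability an observed allele is flipped
#'   to the other allele (amplification/genotyping error).
#' @param co_rate mean crossovers per chromosome per gamete (Poisson).
#' @param end_bias shape parameter of the symmetric Beta(a, a) crossover
#'   position density; `a < 1` concentrates crossovers at both
#'   chromosome ends.
#' @param n_fragments number of haplotype-pure fragments to simulate.
#' @param fragment_length_range length-2 vector `(min_bp, max_bp)`.
#' @param seed integer seed; all simulator stages are deterministic
#'   given the configuration.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 200000L,
                       het_rate = 0.0102,
                       n_cells = 12L,
                       coverage_range = c(0.50, 0.78),
                       genotype_error_rate = 1e-3,
                       co_rate = 1.3,
                       end_bias = 0.5,
                       n_fragments = 300L,
                       fragment_length_range = c(10000L, 120000L),
                       seed = 1L) {
  bad <- function(field, why) {
    stop(sprintf("sim_config: invalid '%s' (%s)", field, why), call. = FALSE)
  }
  if (!is.numeric(n_chromosomes) || length(n_chromosomes) != 1L || n_chromosomes < 1)
    bad("n_chromosomes", "must be a positive count")
  if (!is.numeric(chrom_length) || length(chrom_length) != 1L || chrom_length < 1)
    bad("chrom_length", "must be a positive length in bp")
  if (!is.numeric(het_rate) || length(het_rate) != 1L || het_rate < 0 || het_rate >= 1)
    bad("het_rate", "must be a fraction in [0, 1)")
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    bad("n_cells", "must be a positive count")
  if (!is.numeric(coverage_range) || length(coverage_range) != 2L ||
      coverage_range[1] > coverage_range[2] ||
      any(coverage_range <= 0) || any(coverage_range > 1))
    bad("coverage_range", "must be (low, high) with 0 < low <= high <= 1")
  if (!is.numeric(genotype_error_rate) || length(genotype_error_rate) != 1L ||
      genotype_error_rate < 0 || genotype_error_rate > 1)
    bad("genotype_error_rate", "must be in [0, 1]")
  if (!is.numeric(co_rate) || length(co_rate) != 1L || co_rate < 0)
    bad("co_rate", "must be >= 0")
  if (!is.numeric(end_bias) || length(end_bias) != 1L || end_bias <= 0)
    bad("end_bias", "must be > 0")
  if (!is.numeric(n_fragments) || length(n_fragments) != 1L || n_fragments < 0)
    bad("n_fragments", "must be a non-negative count")
  if (!is.numeric(fragment_length_range) || length(fragment_length_range) != 2L ||
      fragment_length_range[1] > fragment_length_range[2] ||
      fragment_length_range[1] < 1)
    bad("fragment_length_range", "must be (min_bp, max_bp) with 1 <= min <= max")
  if (fragment_length_range[1] > chrom_length)
    bad("fragment_length_range", "minimum fragment length exceeds chrom_length")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) >= 2^31 - 16)
    bad("seed", "must be a 32-bit integer")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    het_rate = het_rate,
    n_cells = as.integer(n_cells),
    coverage_range = as.numeric(coverage_range),
    genotype_error_rate = genotype_error_rate,
    co_rate = co_rate,
    end_bias = end_bias,
    n_fragments = as.integer(n_fragments),
    fragment_length_range = as.integer(fragment_length_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_cells <- function(config) sprintf("cell%02d", seq_len(config$n_cells))
sim_chroms <- function(config) sprintf("chr%02d", seq_len(config$n_chromosomes))

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Simulate a diploid genome with heterozygous SNP sites
#'
#' Draws a random reference-like haplotype A per chromosome, selects SNP
#' sites independently at rate `het_rate`, and derives haplotype B by
#' substituting a different allele at every SNP site. Positions are
#' 0-based.
#'
#' @param config a [sim_config()].
#' @return object of class `diploid_genome`: list with `chrom_lengths`
#'   (named), `hapA`/`hapB` (named character sequences) and `snps`
#'   (data.frame: chrom, pos, alleleA, alleleB).
#' @export
simulate_diploid_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sim_chroms(config)
  L <- config$chrom_length
  hapA <- hapB <- setNames(character(length(chroms)), chroms)
  snps <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    baseA <- sample(DNA_ALPHABET, L, replace = TRUE)
    site <- which(runif(L) < config$het_rate)
    baseB <- baseA
    if (length(site)) {
      # substitute one of the three other bases at each site
      shift <- sample.int(3L, length(site), replace = TRUE)
      alt <- DNA_ALPHABET[(match(baseA[site], DNA_ALPHABET) - 1L + shift) %% 4L + 1L]
      baseB[site] <- alt
    }
    hapA[i] <- paste0(baseA, collapse = "")
    hapB[i] <- paste0(baseB, collapse = "")
    snps[[i]] <- data.frame(
      chrom = rep(chroms[i], length(site)),
      pos = site - 1L,
      alleleA = baseA[site],
      alleleB = baseB[site],
      stringsAsFactors = FALSE)
  }
  structure(list(
    chrom_lengths = setNames(rep(L, length(chroms)), chroms),
    hapA = hapA,
    hapB = hapB,
    snps = do.call(rbind, snps)
  ), class = "diploid_genome")
}

#' Simulate gametes with Poisson crossovers
#'
#' Per gamete and chromosome the crossover count is Poisson(`co_rate`)
#' and positions are drawn from a symmetric Beta(`end_bias`, `end_bias`)
#' density scaled to chromosome length, concentrating crossovers at both
#' chromosome ends when `end_bias < 1`. Segment sources alternate
#' between haplotypes A and B starting from a fair coin.
#'
#' @param genome a [simulate_diploid_genome()] result.
#' @param config the same [sim_config()].
#' @return object of class `gamete_truth`: per cell, per chromosome a
#'   list with `breakpoints` (strictly increasing bp) and `sources`
#'   (alternating "A"/"B", length = breakpoints + 1).
#' @export
simulate_gametes <- function(genome, config) {
  stopifnot(inherits(genome, "diploid_genome"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  cells <- sim_cells(config)
  chroms <- names(genome$chrom_lengths)
  out <- lapply(cells, function(cell) {
    per_chrom <- lapply(chroms, function(ch) {
      L <- genome$chrom_lengths[[ch]]
      n <- rpois(1L, config$co_rate)
      bp <- numeric(0)
      if (n > 0) {
        bp <- round(L * rbeta(n, config$end_bias, config$end_bias))
        bp <- sort(unique(pmin(pmax(bp, 1), L - 1)))
      }
      first <- sample(c("A", "B"), 1L)
      sources <- rep(c(first, setdiff(c("A", "B"), first)),
                     length.out = length(bp) + 1L)
      list(breakpoints = bp, sources = sources)
    })
    setNames(per_chrom, chroms)
  })
  structure(setNames(out, cells), class = "gamete_truth")
}

#' Source haplotype of a gamete at given positions
#'
#' @param gamete_chrom one `gametes[[cell]][[chrom]]` element.
#' @param pos 0-based positions.
#' @return character vector of "A"/"B".
#' @export
gamete_source <- function(gamete_chrom, pos) {
  gamete_chrom$sources[findInterval(pos, gamete_chrom$breakpoints) + 1L]
}

#' Simulate per-cell single-cell SNP observations
#'
#' Each cell draws a breadth-of-coverage fraction uniformly from
#' `coverage_range`; every SNP site is observed independently with that
#' probability (site-independent allelic dropout). The observed base is
#' the gamete's allele, flipped to the other allele with probability
#' `genotype_error_rate`; injected errors are flagged in the truth.
#'
#' @param genome,gametes,config simulator objects.
#' @return data.frame (class `pollen_calls`) with columns cell, chrom,
#'   pos, base, is_error; attribute `coverage_drawn` holds the per-cell
#'   coverage fractions.
#' @export
simulate_pollen_calls <- function(genome, gametes, config) {
  stopifnot(inherits(genome, "diploid_genome"), inherits(gametes, "gamete_truth"))
  set.seed(config$seed + 2L)
  cells <- names(gametes)
  snps <- genome$snps
  cov_drawn <- setNames(numeric(length(cells)), cells)
  res <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[i]
    p <- runif(1L, config$coverage_range[1], config$coverage_range[2])
    cov_drawn[cell] <- p
    obs <- runif(nrow(snps)) < p
    sub <- snps[obs, , drop = FALSE]
    if (nrow(sub)) {
      src <- unlist(lapply(split(seq_len(nrow(sub)), sub$chrom), function(idx) {
        gamete_source(gametes[[cell]][[sub$chrom[idx[1]]]], sub$pos[idx])
      }), use.names = FALSE)
      # split() orders groups by factor level; restore row order
      ord <- order(unlist(split(seq_len(nrow(sub)), sub$chrom), use.names = FALSE))
      src <- src[ord]
      base <- ifelse(src == "A", sub$alleleA, sub$alleleB)
      err <- runif(nrow(sub)) < config$genotype_error_rate
      base[err] <- ifelse(src[err] == "A", sub$alleleB[err], sub$alleleA[err])
      res[[i]] <- data.frame(cell = cell, chrom = sub$chrom, pos = sub$pos,
                             base = base, is_error = err,
                             stringsAsFactors = FALSE)
    } else {
      res[[i]] <- data.frame(cell = character(0), chrom = character(0),
                             pos = integer(0), base = character(0),
                             is_error = logical(0), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "coverage_drawn") <- cov_drawn
  class(out) <- c("pollen_calls", "data.frame")
  out
}

#' Simulate haplotype-pure fragments (BACs)
#'
#' Each fragment picks a chromosome proportional to length, a haplotype
#' by fair coin, a length uniform in `fragment_length_range` (capped at
#' chromosome length), and a uniform start; the sequence is copied
#' verbatim from the chosen haplotype. Coordinates 0-based half-open.
#'
#' @param genome,config simulator objects.
#' @return object of class `bac_set`: list with `records` (data.frame:
#'   id, chrom, start, end, haplotype) and `sequences` (named character).
#' @export
simulate_bacs <- function(genome, config) {
  stopifnot(inherits(genome, "diploid_genome"), inherits(config, "sim_config"))
  if (config$fragment_length_range[1] > min(genome$chrom_lengths))
    stop("sim_config: invalid 'fragment_length_range' (minimum fragment length exceeds chrom_length)",
         call. = FALSE)
  set.seed(config$seed + 3L)
  n <- config$n_fragments
  chroms <- names(genome$chrom_lengths)
  if (n == 0L) {
    return(structure(list(
      records = data.frame(id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           haplotype = character(0), stringsAsFactors = FALSE),
      sequences = setNames(character(0), character(0))
    ), class = "bac_set"))
  }
  chrom <- sample(chroms, n, replace = TRUE,
                  prob = genome$chrom_lengths / sum(genome$chrom_lengths))
  hap <- sample(c("A", "B"), n, replace = TRUE)
  len <- round(runif(n, config$fragment_length_range[1],
                     config$fragment_length_range[2]))
  L <- genome$chrom_lengths[chrom]
  len <- pmin(len, L)
  start <- floor(runif(n) * (L - len + 1))
  end <- start + len
  id <- sprintf("bac%05d", seq_len(n))
  seqs <- ifelse(hap == "A", genome$hapA[chrom], genome$hapB[chrom])
  sequences <- setNames(substring(seqs, start + 1, end), id)
  structure(list(
    records = data.frame(id = id, chrom = chrom, start = as.integer(start),
                         end = as.integer(end), haplotype = hap,
                         stringsAsFactors = FALSE),
    sequences = sequences
  ), class = "bac_set")
}

#' Simulate reference/haplotype gene triplets for mosaic detection
#'
#' Generates gene-scale sequence triplets: haplotypes A and B differ at
#' SNP sites drawn at `het_rate`; the reference copy of each gene is
#' either a clean copy of one haplotype or, with probability
#' `mosaic_fraction`, a mosaic splice of a haplotype-A prefix and a
#' haplotype-B suffix (emulating collapsed diploid assembly). A single
#' central exon covering `exon_fraction` of the gene is annotated.
#'
#' @param n_genes number of genes.
#' @param gene_length gene length in bp.
#' @param het_rate per-bp difference rate between haplotypes.
#' @param mosaic_fraction probability a gene's reference copy is mosaic.
#' @param exon_fraction fraction of the gene covered by the exon.
#' @param seed integer seed.
#' @return list of gene triplets: each has `gene`, `ref`, `hapA`,
#'   `hapB`, `exons` (data.frame start/end, 0-based half-open) and
#'   `truth_mosaic` (logical).
#' @export
simulate_gene_triplets <- function(n_genes = 50L, gene_length = 1200L,
                                   het_rate = 0.0102, mosaic_fraction = 0.08,
                                   exon_fraction = 0.5, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_genes), function(i) {
    hapA <- sample(DNA_ALPHABET, gene_length, replace = TRUE)
    site <- which(runif(gene_length) < het_rate)
    hapB <- hapA
    if (length(site)) {
      shift <- sample.int(3L, length(site), replace = TRUE)
      hapB[site] <- DNA_ALPHABET[(match(hapA[site], DNA_ALPHABET) - 1L + shift) %% 4L + 1L]
    }
    mosaic <- length(site) >= 2L && runif(1) < mosaic_fraction
    if (mosaic) {
      # splice between two diagnostic sites so both haplotypes contribute
      cut <- sample(site[-1], 1L)
      ref <- c(hapA[seq_len(cut - 1L)], hapB[cut:gene_length])
    } else {
      ref <- if (runif(1) < 0.5) hapA else hapB
    }
    half <- round(gene_length * exon_fraction / 2)
    mid <- gene_length %/% 2
    list(gene = sprintf("gene%04d", i),
         ref = paste0(ref, collapse = ""),
         hapA = paste0(hapA, collapse = ""),
         hapB = paste0(hapB, collapse = ""),
         exons = data.frame(start = mid - half, end = mid + half),
         truth_mosaic = mosaic)
  })
}
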