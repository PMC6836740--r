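#' Run the simulated phasing pipeline end to end
#'
#' Simulates a diploid genome, gametes, single-cell observations and
#' haplotype-pure fragments, anchors the fragments against the diploid
#' reference by k-mer breadth of coverage, builds barcode profiles,
#' phases the fragments into haplotype families, detects meiotic
#' crossovers, and evaluates every stage against the simulated truth.
#'
#' @param config a [sim_config()].
#' @param params a [phase_params()].
#' @param min_cells minimum-support filter for SNP rows.
#' @param min_run crossover persistence filter ([detect_crossovers()]).
#' @param k,max_hits,min_coverage,stride anchoring parameters.
#' @param outdir optional output directory; when given, all tables and
#'   a manifest are written there.
#' @return list: genome, gametes, calls, bacs, anchors, profiles,
#'   phase (calls + summary + families), phase_eval, events, tracks,
#'   co_summary, landscape, co_eval.
#' @export
run_pipeline <- function(config = sim_config(), params = phase_params(),
                         min_cells = 2L, min_run = 2L,
                         k = 21L, max_hits = 10L, min_coverage = 0.80,
                         stride = 1L, outdir = NULL) {
  genome <- simulate_diploid_genome(config)
  gametes <- simulate_gametes(genome, config)
  calls <- simulate_pollen_calls(genome, gametes, config)
  bacs <- simulate_bacs(genome, config)
  cells <- sim_cells(config)
  chroms <- names(genome$chrom_lengths)

  # diploid reference: both haplotypes of a chromosome share its id, so
  # anchoring never leaks haplotype identity
  ref <- c(genome$hapA, genome$hapB)
  index <- build_kmer_index(ref, k = k, max_hits = max_hits,
                            chrom_ids = rep(chroms, 2L))
  anchors <- anchor_fragments(bacs$sequences, index,
                              min_coverage = min_coverage, stride = stride)

  profiles <- profile_bacs(bacs, genome$snps, calls, cells,
                           min_cells = min_cells, anchors = anchors)
  phase <- phase_genome(anchors, profiles, params)
  phase_eval <- evaluate_phasing(phase$calls, bacs$records)

  det <- detect_all_crossovers(phase$calls, profiles, cells, chroms,
                               min_run = min_run)
  co_summary <- crossover_summary(det$events, length(cells), length(chroms))
  landscape <- crossover_landscape(det$events, genome$chrom_lengths)
  co_eval <- evaluate_crossovers(det$events, gametes, det$tracks,
                                 n_flank = min_run)

  res <- list(config = config, params = params, genome = genome,
              gametes = gametes, calls = calls, bacs = bacs,
              anchors = anchors, profiles = profiles, phase = phase,
              phase_eval = phase_eval, events = det$events,
              tracks = det$tracks, co_summary = co_summary,
              landscape = landscape, co_eval = co_eval)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir,
                                               min_cells = min_cells,
                                               min_run = min_run)
  res
}

write_pipeline_outputs <- function(res, outdir, min_cells, min_run) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_haplotype_fasta(res$genome, p("haplotypes.fasta"))
  write_snp_vcf(res$genome$snps, p("truth_snps.vcf"))
  write_pollen_calls(res$calls, p("pollen_calls.tsv"))
  write_fragments(res$bacs, p("fragments.fasta"), p("fragments_truth.bed"))
  write_gamete_bed(res$gametes, res$genome$chrom_lengths, p("gametes"))
  write.table(res$anchors, p("anchors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "UNANCHORED")
  write_profiles(res$profiles, p("profiles.tsv"))
  write_phase_table(res$phase$calls, p("phase_table.tsv"))
  s <- res$phase$summary
  writeLines(c("metric\tvalue",
               sprintf("total\t%d", s$total),
               sprintf("phased_A\t%d", s$phased_A),
               sprintf("phased_B\t%d", s$phased_B),
               sprintf("unphased\t%d", s$unphased),
               sprintf("phased_pct\t%.2f", s$phased_pct),
               sprintf("unphased_pct\t%.2f", s$unphased_pct)),
             p("phase_summary.tsv"))
  write_events_bed(res$events, p("events.bed"))
  writeLines(c("metric\tvalue",
               sprintf("total_events\t%d", res$co_summary$total),
               sprintf("mean_per_chromosome\t%.1f", res$co_summary$mean_per_chromosome),
               sprintf("terminal_fraction\t%s", format(res$landscape$terminal_fraction))),
             p("crossover_summary.tsv"))
  write.table(res$landscape$bins, p("landscape.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("metric\tvalue",
               sprintf("phasing_accuracy\t%s", format(res$phase_eval$accuracy)),
               sprintf("unphased_rate\t%s", format(res$phase_eval$unphased_rate)),
               sprintf("switch_errors\t%d", res$phase_eval$switch_errors)),
             p("evaluation.tsv"))
  manifest <- list(package = "pollenphase",
                   version = as.character(packageVersion("pollenphase")),
                   config = unclass(res$config),
                   phase_params = unclass(res$params),
                   min_cells = min_cells, min_run = min_run,
                   seed = res$config$seed)
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(outdir)
}

#' Export each haplotype family's fragment sequences as FASTA
#'
#' One record per phased fragment, grouped by chromosome and family
#' label, for downstream assemblers.
#'
#' @param phase result of [phase_genome()].
#' @param bacs a `bac_set`.
#' @param path output FASTA.
#' @export
export_family_fasta <- function(phase, bacs, path) {
  calls <- phase$calls
  sel <- calls$call %in% c("A", "B")
  ids <- calls$fragment[sel]
  nm <- sprintf("%s_%s|%s", calls$chromosome[sel], calls$call[sel], ids)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(bacs$sequences[ids], nm)), path)
  invisible(path)
}
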