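#' Build a cell's phase track along one chromosome
#'
#' For each phased fragment on the chromosome where the cell is
#' informative (>= 1 non-NOCALL genotype, no consensus tie), the cell's
#' consensus bit is converted to a haplotype phase: a cell matching a
#' fragment phased A (bit 1) carries haplotype A there, a cell matching
#' a B fragment carries B, and a mismatching cell carries the opposite
#' haplotype. The track point is placed at the median position of the
#' SNP rows on which the cell voted, so a fragment spanning a crossover
#' localizes the cell's evidence on the correct side.
#'
#' @param calls phase-call data.frame.
#' @param profiles named list of barcode profiles.
#' @param cell cell id.
#' @param chromosome chromosome id.
#' @return data.frame (position ascending, phase in "A"/"B") with
#'   attributes `cell` and `chromosome`.
#' @export
build_phase_track <- function(calls, profiles, cell, chromosome) {
  sel <- calls$call %in% c("A", "B") & calls$chromosome == chromosome
  ids <- calls$fragment[sel]
  labs <- calls$call[sel]
  pos <- numeric(0); phase <- character(0)
  known_cell <- FALSE
  for (i in seq_along(ids)) {
    p <- profiles[[ids[i]]]
    if (is.null(p)) next
    if (!cell %in% names(p$observed))
      stop(sprintf("build_phase_track: unknown cell '%s'", cell), call. = FALSE)
    known_cell <- TRUE
    if (!p$observed[[cell]] || p$low_conf[[cell]]) next
    bit <- p$consensus[[cell]]
    ph <- if (bit == 1L) labs[i] else setdiff(c("A", "B"), labs[i])
    pos <- c(pos, p$cell_pos[[cell]])
    phase <- c(phase, ph)
  }
  if (!known_cell && length(ids))
    stop(sprintf("build_phase_track: unknown cell '%s'", cell), call. = FALSE)
  ord <- order(pos)
  structure(data.frame(position = pos[ord], phase = phase[ord],
                       stringsAsFactors = FALSE),
            cell = cell, chromosome = chromosome)
}

#' Detect meiotic crossovers from a phase track
#'
#' Run-length encodes the phase sequence; a switch is accepted as a
#' crossover only when the new phase persists for at least `min_run`
#' consecutive informative points, suppressing isolated flickers from
#' genotype or assignment noise (`min_run = 1` reproduces the literal
#' identity/non-identity switch rule). Runs shorter than `min_run` at
#' the track ends are likewise suppressed. The event interval runs from
#' the last informative position of the old phase to the first
#' informative position of the accepted new phase.
#'
#' @param track a [build_phase_track()] data.frame.
#' @param min_run minimum run length to accept a new phase.
#' @return data.frame: cell, chromosome, left, right, from_phase,
#'   to_phase; attribute `n_suppressed` counts dropped flicker runs.
#' @export
detect_crossovers <- function(track, min_run = 2L) {
  empty <- data.frame(cell = character(0), chromosome = character(0),
                      left = numeric(0), right = numeric(0),
                      from_phase = character(0), to_phase = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(track) == 0L) return(structure(empty, n_suppressed = 0L))
  r <- rle(track$phase)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$lengths >= min_run)
  n_suppressed <- length(r$lengths) - length(keep)
  if (length(keep) <= 1L) return(structure(empty, n_suppressed = n_suppressed))
  # merge adjacent kept runs with equal phase (separated by dropped flickers)
  kp <- r$values[keep]
  ks <- starts[keep]; ke <- ends[keep]
  merged <- list()
  for (i in seq_along(keep)) {
    last <- length(merged)
    if (last && merged[[last]]$phase == kp[i]) {
      merged[[last]]$end <- ke[i]
    } else {
      merged[[last + 1L]] <- list(phase = kp[i], start = ks[i], end = ke[i])
    }
  }
  if (length(merged) <= 1L) return(structure(empty, n_suppressed = n_suppressed))
  ev <- lapply(seq_len(length(merged) - 1L), function(i) {
    data.frame(cell = attr(track, "cell") %||% NA_character_,
               chromosome = attr(track, "chromosome") %||% NA_character_,
               left = track$position[merged[[i]]$end],
               right = track$position[merged[[i + 1L]]$start],
               from_phase = merged[[i]]$phase,
               to_phase = merged[[i + 1L]]$phase,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, ev), n_suppressed = n_suppressed)
}

#' Detect crossovers for every cell and chromosome
#'
#' @param calls phase-call data.frame.
#' @param profiles named list of barcode profiles.
#' @param cells cell ids.
#' @param chromosomes chromosome ids.
#' @param min_run passed to [detect_crossovers()].
#' @return list with `events` (combined data.frame) and `tracks`
#'   (nested list `tracks[[cell]][[chromosome]]`).
#' @export
detect_all_crossovers <- function(calls, profiles, cells, chromosomes,
                                  min_run = 2L) {
  tracks <- lapply(setNames(cells, cells), function(cell)
    lapply(setNames(chromosomes, chromosomes), function(ch)
      build_phase_track(calls, profiles, cell, ch)))
  events <- do.call(rbind, unlist(lapply(cells, function(cell)
    lapply(chromosomes, function(ch)
      detect_crossovers(tracks[[cell]][[ch]], min_run))), recursive = FALSE))
  rownames(events) <- NULL
  list(events = events, tracks = tracks)
}

#' Summarize crossover events
#'
#' @param events crossover event data.frame.
#' @param n_cells number of cells observed.
#' @param n_chromosomes number of chromosomes.
#' @return list: total, mean_per_chromosome (total / (cells x
#'   chromosomes), one decimal), per_cell and per_chromosome tables.
#' @export
crossover_summary <- function(events, n_cells, n_chromosomes) {
  if (n_cells <= 0 || n_chromosomes <= 0)
    stop("crossover_summary: n_cells and n_chromosomes must be positive",
         call. = FALSE)
  total <- nrow(events)
  list(total = total,
       mean_per_chromosome = round(total / (n_cells * n_chromosomes), 1),
       per_cell = table(events$cell),
       per_chromosome = table(events$chromosome))
}

#' Genome-wide crossover landscape
#'
#' Event midpoints are assigned to equal-width relative-position bins;
#' the terminal fraction is the share of events in the outer 20% of
#' either chromosome end (0.4 expected under a uniform landscape).
#'
#' @param events crossover event data.frame.
#' @param chrom_lengths named chromosome lengths.
#' @param n_bins number of relative-position bins.
#' @return list: `bins` (data.frame bin, count) and `terminal_fraction`.
#' @export
crossover_landscape <- function(events, chrom_lengths, n_bins = 10L) {
  if (nrow(events) == 0L) {
    return(list(bins = data.frame(bin = seq_len(n_bins), count = 0L),
                terminal_fraction = NA_real_))
  }
  mid <- (events$left + events$right) / 2
  rel <- mid / chrom_lengths[events$chromosome]
  bin <- pmin(pmax(ceiling(rel * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  list(bins = data.frame(bin = seq_len(n_bins), count = counts),
       terminal_fraction = mean(rel <= 0.2 | rel >= 0.8))
}

#' Evaluate detected crossovers against simulated truth
#'
#' A truth breakpoint is only observable from marker data when
#' informative track points exist on both sides; breakpoints falling in
#' even-sized groups between the same two adjacent track points cancel
#' in parity and leave no phase switch. Each truth breakpoint is
#' assigned to its inter-point gap; gaps holding an odd number of
#' breakpoints with at least `n_flank` informative points per side are
#' "detectable" and should be matched by exactly one event whose
#' interval (left, right] brackets the breakpoint group.
#'
#' @param events detected events ([detect_all_crossovers()]).
#' @param gametes truth ([simulate_gametes()]).
#' @param tracks nested track list ([detect_all_crossovers()]).
#' @param n_flank minimum informative points required on each side of
#'   the breakpoint, counted only up to the neighboring breakpoint
#'   group: a crossover whose flank is shared with the next crossover
#'   needs that many points strictly between the two.
#' @return list: `truth` (per-breakpoint data.frame with detectable /
#'   detected / bracketed flags), `n_detectable`, `n_detected`,
#'   `n_spurious` (events matching no detectable breakpoint group).
#' @export
evaluate_crossovers <- function(events, gametes, tracks, n_flank = 1L) {
  rows <- list()
  matched_events <- rep(FALSE, nrow(events))
  for (cell in names(gametes)) {
    for (ch in names(gametes[[cell]])) {
      bps <- gametes[[cell]][[ch]]$breakpoints
      if (!length(bps)) next
      tr <- tracks[[cell]][[ch]]
      pts <- if (!is.null(tr)) tr$position else numeric(0)
      ev_idx <- which(events$cell == cell & events$chromosome == ch)
      gap <- vapply(bps, function(b) sum(pts < b), numeric(1))
      gaps <- sort(unique(gap))
      reps <- vapply(gaps, function(g) median(bps[gap == g]), numeric(1))
      for (gi in seq_along(gaps)) {
        g <- gaps[gi]
        grp <- bps[gap == g]
        odd <- length(grp) %% 2L == 1L
        b_rep <- reps[gi]
        lo <- if (gi > 1L) reps[gi - 1L] else -Inf
        hi <- if (gi < length(gaps)) reps[gi + 1L] else Inf
        n_left <- sum(pts > lo & pts < b_rep)
        n_right <- sum(pts >= b_rep & pts < hi)
        detectable <- odd && n_left >= n_flank && n_right >= n_flank
        hit <- ev_idx[events$left[ev_idx] < b_rep & b_rep <= events$right[ev_idx]]
        detected <- detectable && length(hit) > 0L
        if (detectable && length(hit)) matched_events[hit[1]] <- TRUE
        for (b in grp) {
          rows[[length(rows) + 1L]] <- data.frame(
            cell = cell, chromosome = ch, pos = b, gap = g,
            group_size = length(grp), detectable = detectable,
            detected = detected,
            bracketed = detected &&
              any(events$left[hit] < b_rep & b_rep <= events$right[hit]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(0), chromosome = character(0), pos = numeric(0),
               gap = numeric(0), group_size = integer(0), detectable = logical(0),
               detected = logical(0), bracketed = logical(0))
  grp_key <- paste(truth$cell, truth$chromosome, truth$gap)
  detectable_groups <- unique(grp_key[truth$detectable])
  detected_groups <- unique(grp_key[truth$detectable & truth$detected])
  list(truth = truth,
       n_detectable = length(detectable_groups),
       n_detected = length(detected_groups),
       n_spurious = sum(!matched_events))
}
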