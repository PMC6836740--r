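#' Phasing parameters
#'
#' @param min_margin minimum |dA - dB| (hamming distances to the two
#'   family barcodes) to accept an assignment; smaller margins are
#'   reported UNPHASED with reason "ambiguous_distance".
#' @param window number of most recent family members whose consensus
#'   barcodes define the family's current barcode (bitwise majority),
#'   letting the family barcode drift across meiotic crossovers.
#' @param min_snps minimum informative SNPs for a fragment to be
#'   phaseable; below this, one genotype error could outvote the signal.
#' @param min_consensus_support minimum mean per-bit agreement of a
#'   fragment's SNP barcodes with its consensus; low support indicates a
#'   heterogeneous (chimeric or repeat-borne) barcode profile.
#' @param masked_distance compute hamming distances over the fragment's
#'   observed cells only instead of the absent-collapses-to-0 encoding.
#' @return list of class `phase_params`.
#' @export
phase_params <- function(min_margin = 1L, window = 5L, min_snps = 3L,
                         min_consensus_support = 0.6,
                         masked_distance = FALSE) {
  stopifnot(min_margin >= 0, window >= 1, min_snps >= 0)
  structure(list(min_margin = as.integer(min_margin),
                 window = as.integer(window),
                 min_snps = as.integer(min_snps),
                 min_consensus_support = min_consensus_support,
                 masked_distance = isTRUE(masked_distance)),
            class = "phase_params")
}

# bitwise majority over the last `window` member barcodes; ties keep the
# previous bit so the family barcode cannot oscillate on balanced input
family_current <- function(members, window, prev) {
  m <- members[max(1L, length(members) - window + 1L):length(members)]
  mat <- do.call(rbind, m)
  ones <- colSums(mat == 1L)
  zeros <- colSums(mat == 0L)
  ifelse(ones > zeros, 1L, ifelse(zeros > ones, 0L, prev))
}

phase_distance <- function(profile, family_barcode, params) {
  if (params$masked_distance) {
    masked_hamming(profile$consensus, family_barcode, profile$observed)
  } else {
    hamming(profile$consensus, family_barcode)
  }
}

unphased_row <- function(fragment, chromosome, reason, n_snps = NA_integer_) {
  n <- length(fragment)
  data.frame(fragment = fragment,
             chromosome = rep_len(chromosome, n),
             call = rep_len("UNPHASED", n),
             reason = rep_len(reason, n),
             margin = rep_len(NA_integer_, n),
             n_snps = rep_len(n_snps, n), stringsAsFactors = FALSE)
}

#' Phase the fragments of one chromosome into haplotype families A and B
#'
#' Greedy positional chain with windowed consensus, two passes:
#' fragments are sorted by anchor midpoint; the first phaseable
#' fragment's consensus seeds family A (its complement seeds B); each
#' subsequent fragment joins the family with the smaller hamming
#' distance when the margin is large enough, and the winning family's
#' barcode is updated as the bitwise majority over its last `window`
#' members so crossovers can move the family barcode along the
#' chromosome. A second pass re-scores every fragment against the final
#' piecewise family barcodes at its position; calls that flip between
#' passes become UNPHASED. Fragments observed in at most one cell are
#' UNPHASED("single_cell_support"); the A/B label orientation per
#' chromosome is arbitrary.
#'
#' @param profiles list of [profile_fragment()] objects, all anchored to
#'   the same chromosome with positions available.
#' @param params a [phase_params()].
#' @param chromosome chromosome id (defaults to the profiles').
#' @return list with `calls` (data.frame: fragment, chromosome, call,
#'   reason, margin, n_snps), `families` (per label: member table and
#'   piecewise barcode track) and `complementarity` (per-update hamming
#'   distance between family A's barcode and the complement of B's, a
#'   diagnostic that is 0 in clean data).
#' @export
phase_chromosome <- function(profiles, params = phase_params(),
                             chromosome = NULL) {
  if (length(profiles) == 0L) {
    return(list(calls = unphased_row(character(0), character(0), character(0)),
                families = list(), complementarity = integer(0)))
  }
  if (is.null(chromosome)) chromosome <- profiles[[1]]$chrom
  mids <- vapply(profiles, function(p) p$midpoint, numeric(1))
  profiles <- profiles[order(mids)]
  mids <- sort(mids)

  pre_reason <- vapply(profiles, function(p) {
    if (sum(p$observed) <= 1L) "single_cell_support"
    else if (p$n_snps < params$min_snps) "too_few_snps"
    else if (!is.na(p$consensus_support) &&
             p$consensus_support < params$min_consensus_support) "ambiguous_distance"
    else NA_character_
  }, character(1))
  phaseable <- which(is.na(pre_reason))

  n <- length(profiles)
  call1 <- rep(NA_character_, n)
  if (length(phaseable)) {
    seed <- phaseable[1]
    members <- list(A = list(profiles[[seed]]$consensus),
                    B = list())
    current <- list(A = unname(profiles[[seed]]$consensus),
                    B = complement_barcode(profiles[[seed]]$consensus))
    call1[seed] <- "A"
    snap_pos <- mids[seed]
    snap_A <- list(current$A)
    snap_B <- list(current$B)
    compl_diag <- integer(0)
    for (i in phaseable[-1]) {
      p <- profiles[[i]]
      dA <- phase_distance(p, current$A, params)
      dB <- phase_distance(p, current$B, params)
      if (abs(dA - dB) < params$min_margin) next  # ambiguous in pass 1
      lab <- if (dA < dB) "A" else "B"
      call1[i] <- lab
      members[[lab]] <- c(members[[lab]], list(unname(p$consensus)))
      current[[lab]] <- family_current(members[[lab]], params$window,
                                       current[[lab]])
      snap_pos <- c(snap_pos, mids[i])
      snap_A <- c(snap_A, list(current$A))
      snap_B <- c(snap_B, list(current$B))
      compl_diag <- c(compl_diag,
                      hamming(current$A, complement_barcode(current$B)))
    }
  } else {
    warning(sprintf("phase_chromosome: no phaseable fragments on %s", chromosome))
    calls <- do.call(rbind, lapply(seq_len(n), function(i)
      unphased_row(profiles[[i]]$fragment, chromosome, pre_reason[i],
                   profiles[[i]]$n_snps)))
    return(list(calls = calls, families = list(), complementarity = integer(0)))
  }

  # pass 2: re-score against the final piecewise family barcodes
  calls <- vector("list", n)
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    if (!is.na(pre_reason[i])) {
      calls[[i]] <- unphased_row(p$fragment, chromosome, pre_reason[i], p$n_snps)
      next
    }
    s <- findInterval(mids[i], snap_pos)
    if (s == 0L) s <- 1L
    dA <- phase_distance(p, snap_A[[s]], params)
    dB <- phase_distance(p, snap_B[[s]], params)
    margin <- abs(dA - dB)
    call2 <- if (margin >= params$min_margin) (if (dA < dB) "A" else "B") else NA_character_
    final <- if (!is.na(call1[i]) && !is.na(call2) && call1[i] == call2) call2
             else if (is.na(call1[i]) && !is.na(call2)) call2
             else NA_character_
    calls[[i]] <- if (is.na(final)) {
      unphased_row(p$fragment, chromosome, "ambiguous_distance", p$n_snps)
    } else {
      data.frame(fragment = p$fragment, chromosome = chromosome,
                 call = final, reason = NA_character_,
                 margin = as.integer(margin), n_snps = p$n_snps,
                 stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  track <- data.frame(position = snap_pos,
                      A = vapply(snap_A, barcode_to_string, ""),
                      B = vapply(snap_B, barcode_to_string, ""),
                      stringsAsFactors = FALSE)
  families <- lapply(c(A = "A", B = "B"), function(lab) {
    sel <- calls$call == lab
    list(chromosome = chromosome, label = lab,
         members = data.frame(fragment = calls$fragment[sel],
                              midpoint = mids[match(calls$fragment[sel],
                                                    vapply(profiles, `[[`, "", "fragment"))],
                              stringsAsFactors = FALSE),
         barcode_track = track)
  })
  list(calls = calls, families = families, complementarity = compl_diag)
}

#' Phase a whole genome of anchored fragments
#'
#' Runs [phase_chromosome()] per chromosome. Unanchored fragments are
#' reported UNPHASED("unanchored"); anchored fragments without a barcode
#' profile (no SNP rows surviving the minimum-support filter) are
#' UNPHASED("too_few_snps").
#'
#' @param anchors anchor table ([anchor_fragments()]).
#' @param profiles named list of [profile_fragment()] objects.
#' @param params a [phase_params()].
#' @return list with `calls`, `summary` ([phase_summary()]) and
#'   `families` (per chromosome).
#' @export
phase_genome <- function(anchors, profiles, params = phase_params()) {
  rows <- list()
  families <- list()
  unanch <- is.na(anchors$chromosome)
  if (any(unanch))
    rows$unanchored <- unphased_row(anchors$fragment[unanch],
                                    NA_character_, "unanchored")
  anch <- anchors[!unanch, , drop = FALSE]
  for (ch in unique(anch$chromosome)) {
    ids <- anch$fragment[anch$chromosome == ch]
    have <- ids[ids %in% names(profiles)]
    have <- have[vapply(profiles[have], function(p) p$n_snps > 0L, logical(1))]
    miss <- setdiff(ids, have)
    if (length(miss))
      rows[[paste0(ch, "_miss")]] <- unphased_row(miss, ch, "too_few_snps", 0L)
    if (length(have)) {
      res <- phase_chromosome(profiles[have], params, chromosome = ch)
      rows[[ch]] <- res$calls
      families[[ch]] <- res$families
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    unphased_row(character(0), character(0), character(0))
  rownames(calls) <- NULL
  list(calls = calls, summary = phase_summary(calls), families = families)
}

#' Summarize phase calls
#'
#' @param calls phase-call data.frame.
#' @return list: total, phased_A, phased_B, phased, unphased,
#'   phased_pct / unphased_pct (two decimals; 0 when empty) and a
#'   per-chromosome A/B/unphased table.
#' @export
phase_summary <- function(calls) {
  total <- nrow(calls)
  a <- sum(calls$call == "A")
  b <- sum(calls$call == "B")
  un <- sum(calls$call == "UNPHASED")
  per_chrom <- if (total) {
    tab <- table(chromosome = calls$chromosome, call = calls$call,
                 useNA = "no")
    as.data.frame.matrix(tab)
  } else data.frame()
  list(total = total, phased_A = a, phased_B = b, phased = a + b,
       unphased = un,
       phased_pct = if (total) round(100 * (a + b) / total, 2) else 0,
       unphased_pct = if (total) round(100 * un / total, 2) else 0,
       per_chromosome = per_chrom)
}

#' Evaluate phase calls against simulated truth
#'
#' Per chromosome the label orientation maximizing agreement with the
#' truth haplotypes is chosen (a global A/B swap is not an error), then
#' phasing accuracy (agreeing calls / phased calls), the unphased rate,
#' and switch errors (adjacent phased fragments whose relative
#' assignment disagrees with truth) are reported.
#'
#' @param calls phase-call data.frame.
#' @param records truth fragment records (`bac_set$records`).
#' @return list: accuracy, unphased_rate, switch_errors, n_phased,
#'   per_chromosome data.frame.
#' @export
evaluate_phasing <- function(calls, records) {
  if (is.null(records)) stop("evaluate_phasing: truth records missing", call. = FALSE)
  m <- match(calls$fragment, records$id)
  if (anyNA(m)) stop("evaluate_phasing: truth records missing for some fragments",
                     call. = FALSE)
  truth <- records$haplotype[m]
  start <- records$start[m]
  truth_chrom <- records$chrom[m]
  phased <- calls$call %in% c("A", "B")
  per <- lapply(split(seq_len(nrow(calls))[phased], truth_chrom[phased]),
                function(idx) {
    agree <- sum(calls$call[idx] == truth[idx])
    n <- length(idx)
    flip <- agree < n - agree
    correct <- max(agree, n - agree)
    ord <- idx[order(start[idx])]
    same_call <- calls$call[ord][-1] == calls$call[ord][-length(ord)]
    same_truth <- truth[ord][-1] == truth[ord][-length(ord)]
    data.frame(n_phased = n, n_correct = correct,
               accuracy = if (n) correct / n else NA_real_,
               flipped = flip,
               switch_errors = sum(same_call != same_truth),
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, per)
  n_phased <- sum(phased)
  list(accuracy = if (n_phased) sum(per_chrom$n_correct) / n_phased else NA_real_,
       unphased_rate = if (nrow(calls)) sum(!phased) / nrow(calls) else 0,
       switch_errors = sum(per_chrom$switch_errors),
       n_phased = n_phased,
       per_chromosome = per_chrom)
}
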