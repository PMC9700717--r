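#' Default P-site offset table
#'
#' Canonical eukaryotic footprint geometry places the P-site ~12 nt from
#' the footprint 5' end; this table assigns offset 12 with confidence
#' `default` to each requested length.
#'
#' @param lengths Integer vector of footprint lengths.
#' @param offset Default offset (nt).
#' @return An offset table data.frame: `length`, `offset`, `confidence`,
#'   `frame0_fraction`.
#' @export
default_offset_table <- function(lengths = 25:35, offset = 12L) {
  data.frame(length = as.integer(lengths), offset = as.integer(offset),
             confidence = "default", frame0_fraction = NA_real_,
             stringsAsFactors = FALSE)
}

#' Calibrate P-site offsets from start-codon metagene alignment
#'
#' For each footprint length, candidate offsets in `candidate_offsets` are
#' scored by how many P-sites (5' end + offset) land exactly on an
#' annotated start codon's first nucleotide, summed over transcripts - the
#' initiation pileup makes the true offset the unique maximiser.  Ties are
#' broken by the higher in-frame (frame-0) fraction of CDS-internal
#' P-sites.  Lengths with fewer than `min_reads_per_length` reads fall back
#' to the default offset (confidence `default`); lengths whose best
#' frame-0 fraction is below `min_frame0` (no 3-nt periodicity) are marked
#' `failed` and excluded downstream.
#'
#' @param alignments Footprints data.frame (transcript space).
#' @param models Named list of `TranscriptModel`s with annotated start
#'   codons.
#' @param lengths Lengths to calibrate (default: all observed within
#'   `length_range`).
#' @param min_reads_per_length Minimum reads to attempt calibration.
#' @param candidate_offsets Candidate offsets (nt), default 10:14.
#' @param default_offset Fallback offset.
#' @param min_frame0 Periodicity-failure threshold on the frame-0 fraction.
#' @param length_range Footprint lengths considered at all (gel-size
#'   selection window); lengths outside are not reported.
#' @return An offset table data.frame (see [default_offset_table()]).
#' @export
calibrate_offsets <- function(alignments, models, lengths = NULL,
                              min_reads_per_length = 100L,
                              candidate_offsets = 10:14,
                              default_offset = 12L, min_frame0 = 0.4,
                              length_range = c(25L, 35L)) {
  if (length(models) == 0L) {
    stop_ribortc("no transcript models with annotated start codons",
                 "ribortc_bad_input")
  }
  tx_ids <- vapply(models, function(m) m$transcript_id, character(1))
  cds_start <- vapply(models, function(m) m$cds_start_codon_tx, integer(1))
  cds_stop3 <- vapply(models, function(m) m$canonical_stop_tx + 3L, integer(1))
  names(cds_start) <- names(cds_stop3) <- tx_ids

  aln <- alignments[alignments$transcript_id %in% tx_ids, , drop = FALSE]
  if (is.null(lengths)) {
    lengths <- sort(unique(aln$length))
  }
  lengths <- lengths[lengths >= length_range[1] & lengths <= length_range[2]]

  rows <- lapply(lengths, function(L) {
    sub <- aln[aln$length == L, , drop = FALSE]
    if (nrow(sub) < min_reads_per_length) {
      return(data.frame(length = L, offset = as.integer(default_offset),
                        confidence = "default", frame0_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    }
    starts <- cds_start[sub$transcript_id]
    stops3 <- cds_stop3[sub$transcript_id]
    score <- function(off) {
      ps <- sub$five_prime_tx + off
      in_cds <- ps >= starts & ps < stops3
      f0 <- sum(in_cds & (ps - starts) %% 3L == 0L)
      c(start_hits = sum(ps == starts),
        frame0 = if (any(in_cds)) f0 / sum(in_cds) else 0)
    }
    sc <- vapply(candidate_offsets, score, numeric(2))
    best <- which(sc["start_hits", ] == max(sc["start_hits", ]))
    if (length(best) > 1L) best <- best[which.max(sc["frame0", best])]
    f0 <- sc["frame0", best]
    data.frame(length = L, offset = as.integer(candidate_offsets[best]),
               confidence = if (f0 < min_frame0) "failed" else "calibrated",
               frame0_fraction = as.numeric(f0), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign P-sites and build per-transcript profiles
#'
#' P-site position = `five_prime_tx + offset(length)`.  Reads whose length
#' has no usable offset are discarded with a reason; so are reads on
#' transcripts absent from `models` or whose P-site falls outside the
#' transcript.  Within the CDS, frame = `(psite - cds_start) mod 3`; codon
#' counts tally frame-0 P-sites by codon index in the CDS reading frame
#' extended into the 3'UTR.
#'
#' @param alignments Footprints data.frame.
#' @param models Named list of `TranscriptModel`s.
#' @param offsets Offset table ([calibrate_offsets()] or
#'   [default_offset_table()]); rows with confidence `failed` discard their
#'   length.
#' @return A named list of `PsiteProfile` objects (one per model, in model
#'   order), each with: `counts` (per-nt P-site counts), `codon_counts`
#'   (in-frame counts per codon), `frame_counts` (f0, f1, f2 within the
#'   CDS), region tallies, per-length tallies, `n_assigned` and
#'   `discarded` (named vector).  Attribute `discarded` on the list gives
#'   library-wide totals; assigned + discarded = input reads.
#' @export
assign_psites <- function(alignments, models, offsets = default_offset_table()) {
  usable <- offsets[offsets$confidence != "failed", , drop = FALSE]
  m <- match(alignments$length, usable$length)
  failed_len <- alignments$length %in% offsets$length[offsets$confidence == "failed"]
  tx_known <- alignments$transcript_id %in% names(models)

  reason <- rep(NA_character_, nrow(alignments))
  reason[!tx_known] <- "unknown_transcript"
  reason[tx_known & failed_len] <- "failed_length"
  reason[tx_known & !failed_len & is.na(m)] <- "no_offset"

  off <- usable$offset[m]
  psite <- alignments$five_prime_tx + off

  profiles <- lapply(models, function(mod) {
    sel <- which(is.na(reason) & alignments$transcript_id == mod$transcript_id)
    ps <- psite[sel]
    ln <- alignments$length[sel]
    oob <- ps < 0L | ps >= mod$tx_length
    n_oob <- sum(oob)
    ps <- ps[!oob]; ln <- ln[!oob]
    counts <- tabulate(ps + 1L, nbins = mod$tx_length)
    d <- ps - mod$cds_start_codon_tx
    frame <- ((d %% 3L) + 3L) %% 3L
    codon <- d %/% 3L + 1L
    n_ext <- max_frame_codon(mod)
    inframe_sel <- frame == 0L & codon >= 1L & codon <= n_ext
    codon_counts <- tabulate(codon[inframe_sel], nbins = n_ext)
    cds_lo <- mod$cds_start_codon_tx
    cds_hi <- mod$canonical_stop_tx + 3L
    in_cds <- ps >= cds_lo & ps < cds_hi
    frame_counts <- tabulate(frame[in_cds] + 1L, nbins = 3L)
    names(frame_counts) <- c("f0", "f1", "f2")
    region_counts <- c(utr5 = sum(ps < cds_lo), cds = sum(in_cds),
                       utr3 = sum(ps >= cds_hi))
    lh <- table(factor(ln, levels = sort(unique(offsets$length))))
    lf0 <- vapply(as.integer(names(lh)), function(L) {
      c(sum(in_cds & ln == L & frame == 0L), sum(in_cds & ln == L))
    }, numeric(2))
    length_frame0 <- data.frame(length = as.integer(names(lh)),
                                n_total = as.integer(lh),
                                n_cds = lf0[2, ], n_cds_frame0 = lf0[1, ])
    structure(list(
      transcript_id = mod$transcript_id,
      counts = counts,
      codon_counts = codon_counts,
      frame_counts = frame_counts,
      region_counts = region_counts,
      length_frame0 = length_frame0,
      n_assigned = length(ps),
      discarded = c(psite_out_of_range = n_oob)
    ), class = "PsiteProfile")
  })
  names(profiles) <- names(models)

  tallied <- table(factor(reason,
                          levels = c("unknown_transcript", "failed_length",
                                     "no_offset")))
  oob_total <- sum(vapply(profiles, function(p) p$discarded[["psite_out_of_range"]],
                          numeric(1)))
  discarded <- c(as.vector(tallied), psite_out_of_range = oob_total)
  names(discarded)[1:3] <- names(tallied)
  attr(profiles, "discarded") <- discarded
  attr(profiles, "n_input") <- nrow(alignments)
  profiles
}

#' @export
print.PsiteProfile <- function(x, ...) {
  cat(sprintf("PsiteProfile %s: %d P-sites (f0/f1/f2 = %d/%d/%d in CDS)\n",
              x$transcript_id, x$n_assigned,
              x$frame_counts[1], x$frame_counts[2], x$frame_counts[3]))
  invisible(x)
}

#' Library-level quality-control summary
#'
#' Aggregates per-transcript profiles into the standard Ribo-seq QC
#' readouts: the read-length histogram, per-length frame-0 (periodicity)
#' fractions, and the fraction of P-sites falling in CDS / 5'UTR / 3'UTR.
#'
#' @param profiles List of `PsiteProfile`s from [assign_psites()].
#' @param models The matching list of `TranscriptModel`s.
#' @return A `QcReport` list: `length_hist` (data.frame length, n,
#'   fraction), `frame0_by_length`, `region_fractions` (sums to 1 over
#'   classified reads), `n_assigned`, `n_discarded`.
#' @export
qc_summary <- function(profiles, models) {
  stopifnot(length(profiles) >= 1L)
  lf <- do.call(rbind, lapply(profiles, function(p) p$length_frame0))
  agg <- stats::aggregate(lf[, c("n_total", "n_cds", "n_cds_frame0")],
                          by = list(length = lf$length), FUN = sum)
  total <- sum(agg$n_total)
  length_hist <- data.frame(length = agg$length, n = agg$n_total,
                            fraction = if (total > 0) agg$n_total / total else 0)
  frame0_by_length <- data.frame(
    length = agg$length,
    frame0_fraction = ifelse(agg$n_cds > 0, agg$n_cds_frame0 / agg$n_cds, NA_real_))
  reg <- Reduce(`+`, lapply(profiles, function(p) p$region_counts))
  region_fractions <- if (sum(reg) > 0) reg / sum(reg) else reg
  structure(list(
    length_hist = length_hist,
    frame0_by_length = frame0_by_length,
    frame0_fraction = {
      f <- Reduce(`+`, lapply(profiles, function(p) p$frame_counts))
      if (sum(f) > 0) unname(f[1] / sum(f)) else NA_real_
    },
    region_fractions = region_fractions,
    n_assigned = sum(vapply(profiles, function(p) p$n_assigned, numeric(1)))
  ), class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport: %d P-sites; frame0 %.3f; CDS %.1f%% / 5'UTR %.1f%% / 3'UTR %.1f%%\n",
              x$n_assigned, x$frame0_fraction,
              100 * x$region_fractions[["cds"]],
              100 * x$region_fractions[["utr5"]],
              100 * x$region_fractions[["utr3"]]))
  invisible(x)
}
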