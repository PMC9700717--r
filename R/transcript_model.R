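#' Transcript coordinate model
#'
#' A `TranscriptModel` pins down a transcript's coordinate system once, and
#' every other operation in the package works in those coordinates.  All
#' internal coordinates are 0-based, half-open; GTF's 1-based closed
#' intervals are converted on read.  Transcript coordinates increase 5' to
#' 3' in the direction of transcription, on both strands.
#'
#' Codon indexing is 1-based with codon 1 = the start codon, so mutation
#' nomenclature maps directly (R213X is codon 213).  `canonical_stop_tx` is
#' the transcript coordinate of the first nucleotide of the canonical stop
#' codon; the stop codon itself is the last CDS codon, so the number of CDS
#' codons is `(canonical_stop_tx - cds_start_codon_tx)/3 + 1`.
#'
#' @param transcript_id Transcript identifier.
#' @param gene_id Gene identifier.
#' @param seqname Genomic sequence (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column data.frame (`start`, `end`) of genomic exon
#'   intervals, 0-based half-open, ordered in transcription direction
#'   (decreasing genomic coordinate on the minus strand).
#' @param cds_start_codon_tx Transcript coordinate (0-based) of the first
#'   nucleotide of the start codon.
#' @param canonical_stop_tx Transcript coordinate of the first nucleotide of
#'   the canonical stop codon.
#' @param ptc_codon_index Optional 1-based codon index of a premature
#'   termination codon, strictly inside the CDS.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id = transcript_id,
                             seqname = transcript_id, strand = c("+", "-"),
                             exons, cds_start_codon_tx, canonical_stop_tx,
                             ptc_codon_index = NA_integer_) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  if (any(exons$end <= exons$start)) {
    stop_ribortc("exon intervals must be non-empty half-open [start, end)",
                 "ribortc_bad_model")
  }
  # non-overlap + transcription order
  g5 <- if (strand == "+") exons$start else -exons$end
  if (nrow(exons) > 1L && any(diff(g5) <= 0)) {
    stop_ribortc("exons must be sorted in transcription order and non-overlapping",
                 "ribortc_bad_model")
  }
  widths <- exons$end - exons$start
  tx_length <- sum(widths)
  cds_start_codon_tx <- as.integer(cds_start_codon_tx)
  canonical_stop_tx <- as.integer(canonical_stop_tx)
  span <- canonical_stop_tx - cds_start_codon_tx
  if (span <= 0L || span %% 3L != 0L) {
    stop_ribortc(sprintf(
      "%s: canonical_stop_tx - cds_start_codon_tx must be a positive multiple of 3 (got %d)",
      transcript_id, span), "ribortc_bad_model")
  }
  if (canonical_stop_tx + 3L > tx_length || cds_start_codon_tx < 0L) {
    stop_ribortc(sprintf("%s: CDS extends outside the transcript", transcript_id),
                 "ribortc_bad_model")
  }
  n_codons <- span %/% 3L + 1L
  ptc_codon_index <- as.integer(ptc_codon_index)
  if (!is.na(ptc_codon_index) &&
      (ptc_codon_index <= 1L || ptc_codon_index >= n_codons)) {
    stop_ribortc(sprintf(
      "%s: ptc_codon_index %d outside the CDS interior (1, %d)",
      transcript_id, ptc_codon_index, n_codons), "ribortc_bad_ptc")
  }
  structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    seqname = as.character(seqname),
    strand = strand,
    exons = exons,
    tx_length = as.integer(tx_length),
    cds_start_codon_tx = cds_start_codon_tx,
    canonical_stop_tx = canonical_stop_tx,
    ptc_codon_index = ptc_codon_index,
    exon_tx_start = c(0L, cumsum(widths))[seq_len(nrow(exons))]
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf(
    "TranscriptModel %s (gene %s, %s strand): %d exon(s), %d nt\n",
    x$transcript_id, x$gene_id, x$strand, nrow(x$exons), x$tx_length))
  cat(sprintf("  CDS: tx %d..%d (%d codons incl. stop)%s\n",
              x$cds_start_codon_tx, x$canonical_stop_tx + 3L,
              n_cds_codons(x),
              if (is.na(x$ptc_codon_index)) "" else
                sprintf("; PTC at codon %d", x$ptc_codon_index)))
  invisible(x)
}

#' Number of CDS codons (start through stop, inclusive)
#' @param model A `TranscriptModel`.
#' @return Integer codon count.
#' @export
n_cds_codons <- function(model) {
  (model$canonical_stop_tx - model$cds_start_codon_tx) %/% 3L + 1L
}

#' Last codon index with a P-site position inside the transcript
#'
#' Codons are counted in the CDS reading frame extended into the 3'UTR, so
#' this bounds how far readthrough signal can be tallied.
#' @param model A `TranscriptModel`.
#' @return Integer codon index.
#' @export
max_frame_codon <- function(model) {
  (model$tx_length - 1L - model$cds_start_codon_tx) %/% 3L + 1L
}

#' Map transcript coordinates to genomic coordinates
#'
#' @param model A `TranscriptModel`.
#' @param pos Vector of 0-based transcript coordinates.
#' @return Integer vector of 0-based genomic coordinates (`NA` outside the
#'   transcript).
#' @export
tx_to_genome <- function(model, pos) {
  pos <- as.integer(pos)
  out <- rep(NA_integer_, length(pos))
  widths <- model$exons$end - model$exons$start
  for (i in seq_len(nrow(model$exons))) {
    lo <- model$exon_tx_start[i]
    sel <- !is.na(pos) & pos >= lo & pos < lo + widths[i]
    if (!any(sel)) next
    off <- pos[sel] - lo
    out[sel] <- if (model$strand == "+") {
      model$exons$start[i] + off
    } else {
      model$exons$end[i] - 1L - off
    }
  }
  out
}

#' Map genomic coordinates to transcript coordinates
#'
#' @param model A `TranscriptModel`.
#' @param gpos Vector of 0-based genomic coordinates.
#' @return Integer vector of 0-based transcript coordinates (`NA` for
#'   positions outside the exons).
#' @export
genome_to_tx <- function(model, gpos) {
  gpos <- as.integer(gpos)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(model$exons))) {
    sel <- !is.na(gpos) & gpos >= model$exons$start[i] & gpos < model$exons$end[i]
    if (!any(sel)) next
    out[sel] <- if (model$strand == "+") {
      model$exon_tx_start[i] + (gpos[sel] - model$exons$start[i])
    } else {
      model$exon_tx_start[i] + (model$exons$end[i] - 1L - gpos[sel])
    }
  }
  out
}

#' Build a single-exon toy transcript
#'
#' Convenience constructor used by the simulators, examples and tests: a
#' plus-strand, single-exon transcript with the given UTR and CDS geometry.
#'
#' @param transcript_id Identifier (also used as seqname).
#' @param n_codons Number of CDS codons including the stop codon.
#' @param utr5,utr3 UTR lengths in nt.
#' @param ptc_codon_index Optional PTC codon index.
#' @param gene_id Gene identifier.
#' @return A `TranscriptModel`.
#' @examples
#' tp53_like <- toy_transcript("tx1", n_codons = 394, ptc_codon_index = 213)
#' n_cds_codons(tp53_like)
#' @export
toy_transcript <- function(transcript_id, n_codons, utr5 = 30L, utr3 = 200L,
                           ptc_codon_index = NA_integer_,
                           gene_id = transcript_id) {
  len <- utr5 + 3L * n_codons + utr3
  transcript_model(
    transcript_id = transcript_id, gene_id = gene_id,
    exons = data.frame(start = 0L, end = len),
    cds_start_codon_tx = utr5,
    canonical_stop_tx = utr5 + 3L * (n_codons - 1L),
    ptc_codon_index = ptc_codon_index
  )
}
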