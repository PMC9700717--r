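#' Footprint alignments in transcript space
#'
#' Footprint alignments are kept as a plain data.frame with one row per
#' (read, transcript) assignment and columns `read_id`, `transcript_id`,
#' `five_prime_tx` (0-based transcript coordinate of the biological 5'
#' end), `length`, `mapq`, `multimap_count`.
#'
#' @param read_id,transcript_id,five_prime_tx,length,mapq,multimap_count
#'   Column vectors, recycled to a common length.
#' @return A validated `footprints` data.frame.
#' @export
footprint_alignments <- function(read_id, transcript_id, five_prime_tx,
                                 length, mapq = 255L, multimap_count = 1L) {
  df <- data.frame(
    read_id = as.character(read_id),
    transcript_id = as.character(transcript_id),
    five_prime_tx = as.integer(five_prime_tx),
    length = as.integer(length),
    mapq = as.integer(mapq),
    multimap_count = as.integer(multimap_count),
    stringsAsFactors = FALSE
  )
  if (any(df$five_prime_tx < 0L) || any(df$length <= 0L)) {
    stop_ribortc("five_prime_tx must be >= 0 and length > 0",
                 "ribortc_bad_input")
  }
  df
}

#' Read genome- or transcript-space alignments from SAM/BAM
#'
#' SAM files are converted to BAM on the fly (Rsamtools) and read with
#' GenomicAlignments, keeping qname, mapq and the NH tag.
#'
#' @param path SAM or BAM path.
#' @return A `GAlignments` object with metadata columns `qname`, `mapq`,
#'   `NH`.
#' @export
read_genome_alignments <- function(path) {
  if (!file.exists(path)) {
    stop_ribortc(sprintf("alignment file not found: %s", path),
                 "ribortc_io_error")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "mapq"), tag = "NH")
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Write transcript-space footprints as SAM
#'
#' Minimal single-end SAM: one `@SQ` line per transcript model and one
#' unpaired, forward-strand record per footprint (`<length>M` CIGAR, no
#' sequence stored).  Round-trips through [read_genome_alignments()].
#'
#' @param footprints A footprints data.frame.
#' @param models Named list of `TranscriptModel`s (supplies `@SQ` lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_footprints_sam <- function(footprints, models, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(models, function(m) {
             sprintf("@SQ\tSN:%s\tLN:%d", m$transcript_id, m$tx_length)
           }, character(1)))
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                  footprints$read_id, footprints$transcript_id,
                  footprints$five_prime_tx + 1L, footprints$mapq,
                  footprints$length, footprints$multimap_count)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a transcript-space `GAlignments` back to a footprints data.frame
#'
#' Inverse of [write_footprints_sam()] for alignments whose reference
#' sequences are transcripts (all forward strand).
#' @param aln A `GAlignments` from [read_genome_alignments()].
#' @return A footprints data.frame.
#' @export
galignments_to_footprints <- function(aln) {
  nh <- S4Vectors::mcols(aln)$NH
  footprint_alignments(
    read_id = S4Vectors::mcols(aln)$qname,
    transcript_id = as.character(GenomicRanges::seqnames(aln)),
    five_prime_tx = GenomicRanges::start(aln) - 1L,
    length = GenomicAlignments::qwidth(aln),
    mapq = S4Vectors::mcols(aln)$mapq,
    multimap_count = ifelse(is.na(nh), 1L, nh)
  )
}

#' Project genome-space alignments onto transcript coordinates
#'
#' Each input alignment whose aligned bases all fall inside a transcript's
#' exons, contiguously in transcript space and on the transcript's strand,
#' is emitted once per compatible transcript with `five_prime_tx` at the
#' biological 5' end.  Everything else is tallied as discarded:
#' `multimapper` (NH above `max_multimap`), `no_transcript_overlap`, or
#' `incompatible_structure` (intron overlap, exon-boundary inconsistency or
#' strand mismatch).  Assigned + discarded = total input alignments.
#'
#' @param aln A `GAlignments` (see [read_genome_alignments()]).
#' @param models Named list of `TranscriptModel`s (exon structure required).
#' @param max_multimap Keep reads with `NH <= max_multimap` (default 1,
#'   unique mappers only).
#' @return A footprints data.frame with attribute `discarded`, a named
#'   integer vector of per-reason read counts.
#' @export
project_to_transcript <- function(aln, models, max_multimap = 1L) {
  if (length(models) == 0L) {
    stop_ribortc("no transcript models supplied", "ribortc_bad_input")
  }
  for (m in models) {
    if (is.null(m$exons) || nrow(m$exons) == 0L) {
      stop_ribortc(sprintf("model %s lacks exon structure", m$transcript_id),
                   "ribortc_bad_input")
    }
  }
  n <- length(aln)
  qname <- S4Vectors::mcols(aln)$qname
  mapq <- S4Vectors::mcols(aln)$mapq
  nh <- S4Vectors::mcols(aln)$NH
  nh[is.na(nh)] <- 1L
  seqn <- as.character(GenomicRanges::seqnames(aln))
  astrand <- as.character(GenomicRanges::strand(aln))

  multim <- nh > max_multimap
  assigned <- rep(FALSE, n)
  touched <- rep(FALSE, n)   # overlapped some transcript on the right seqname
  blocks <- GenomicAlignments::grglist(aln)   # aligned genomic blocks

  out <- vector("list", length(models))
  oi <- 0L
  for (m in models) {
    span_lo <- min(m$exons$start)
    span_hi <- max(m$exons$end)
    cand <- which(!multim &
                    seqn == m$seqname &
                    GenomicRanges::start(aln) - 1L < span_hi &
                    GenomicRanges::end(aln) > span_lo)
    if (length(cand) == 0L) next
    bl <- blocks[cand]
    flat <- BiocGenerics::unlist(bl, use.names = FALSE)
    per <- S4Vectors::elementNROWS(bl)
    ridx <- rep(seq_along(cand), per)
    # expand aligned bases (footprints are short, this stays small)
    wid <- GenomicRanges::width(flat)
    base_read <- factor(rep(ridx, wid), levels = seq_along(cand))
    gpos <- unlist(lapply(seq_along(flat), function(j) {
      seq.int(GenomicRanges::start(flat)[j] - 1L,
              length.out = GenomicRanges::width(flat)[j])
    }), use.names = FALSE)
    tpos <- genome_to_tx(m, gpos)
    ok_na <- tapply(!is.na(tpos), base_read, all)
    tmin <- tapply(tpos, base_read, function(x) suppressWarnings(min(x)))
    tmax <- tapply(tpos, base_read, function(x) suppressWarnings(max(x)))
    nb <- tapply(tpos, base_read, length)
    contiguous <- !is.na(tmin) & (tmax - tmin + 1L == nb)
    strand_ok <- astrand[cand] == m$strand
    touched[cand] <- TRUE
    ok <- as.logical(ok_na) & contiguous & strand_ok
    if (!any(ok)) next
    sel <- cand[ok]
    assigned[sel] <- TRUE
    oi <- oi + 1L
    out[[oi]] <- footprint_alignments(
      read_id = qname[sel],
      transcript_id = m$transcript_id,
      five_prime_tx = as.integer(tmin[ok]),
      length = as.integer(nb[ok]),
      mapq = mapq[sel],
      multimap_count = nh[sel]
    )
  }
  res <- if (oi > 0L) do.call(rbind, out[seq_len(oi)]) else
    footprint_alignments(character(), character(), integer(), integer())
  discarded <- c(
    multimapper = sum(multim & !assigned),
    incompatible_structure = sum(!multim & !assigned & touched),
    no_transcript_overlap = sum(!multim & !assigned & !touched)
  )
  attr(res, "discarded") <- discarded
  attr(res, "n_input") <- n
  res
}
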