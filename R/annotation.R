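#' Read transcript models from a GTF/GFF3 annotation
#'
#' Builds one [transcript_model()] per protein-coding transcript with a
#' complete CDS.  Exon and CDS features are grouped by `transcript_id`.
#' If the annotation carries `stop_codon` features (Ensembl convention,
#' where CDS features exclude the stop codon) the CDS extent is extended by
#' them; otherwise the CDS features are assumed to include the stop codon.
#' Either way the first nucleotide of the canonical stop codon sits 3 nt
#' before the CDS 3' end.  Transcripts whose CDS length is not a multiple
#' of 3 (or whose CDS falls outside their exons) are skipped and tallied.
#'
#' @param gtf_path Path to a GTF/GFF3 file readable by rtracklayer.
#' @param ptc_table Optional premature-termination-codon table: a
#'   data.frame with columns `transcript_id` and `ptc_codon_index`
#'   (1-based, codon 1 = start codon), or a named integer vector.  A PTC
#'   index outside the CDS interior of its transcript is a fatal error.
#' @return A named list of `TranscriptModel` objects with attribute
#'   `skipped`: a data.frame of `transcript_id`, `reason` for transcripts
#'   that were dropped.
#' @export
read_annotation <- function(gtf_path, ptc_table = NULL) {
  if (!file.exists(gtf_path)) {
    stop_ribortc(sprintf("annotation file not found: %s", gtf_path),
                 "ribortc_io_error")
  }
  gr <- tryCatch(rtracklayer::import(gtf_path),
                 error = function(e) stop_ribortc(
                   sprintf("failed to parse annotation %s: %s",
                           gtf_path, conditionMessage(e)),
                   "ribortc_io_error"))
  ptc <- normalize_ptc_table(ptc_table)

  type <- as.character(gr$type)
  txid <- as.character(gr$transcript_id)
  keep <- type %in% c("exon", "CDS", "stop_codon") & !is.na(txid)
  gr <- gr[keep]; type <- type[keep]; txid <- txid[keep]

  df <- data.frame(
    transcript_id = txid,
    gene_id = if (!is.null(gr$gene_id)) as.character(gr$gene_id) else txid,
    seqname = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    type = type,
    stringsAsFactors = FALSE
  )

  models <- list()
  skipped <- data.frame(transcript_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(id, why) {
    skipped[nrow(skipped) + 1L, ] <<- list(id, why)
  }

  for (id in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == id, ]
    ex <- sub[sub$type == "exon", ]
    cds <- sub[sub$type %in% c("CDS", "stop_codon"), ]
    if (nrow(ex) == 0L || nrow(cds) == 0L) {
      skip(id, "no_exon_or_cds"); next
    }
    strand <- ex$strand[1]
    if (!strand %in% c("+", "-")) { skip(id, "unstranded"); next }
    ex <- ex[order(ex$start, decreasing = (strand == "-")), ]
    model <- tryCatch({
      m0 <- transcript_model(
        transcript_id = id, gene_id = ex$gene_id[1], seqname = ex$seqname[1],
        strand = strand,
        exons = ex[, c("start", "end")],
        # placeholder CDS: fill below after coordinate mapping
        cds_start_codon_tx = 0L, canonical_stop_tx = 3L
      )
      # map CDS genomic extremes into transcript space
      g5 <- if (strand == "+") min(cds$start) else max(cds$end) - 1L
      g3 <- if (strand == "+") max(cds$end) - 1L else min(cds$start)
      t5 <- genome_to_tx(m0, g5)
      t3 <- genome_to_tx(m0, g3)
      if (is.na(t5) || is.na(t3)) stop("CDS outside exons")
      cds_len <- t3 - t5 + 1L
      if (cds_len <= 3L || cds_len %% 3L != 0L) stop("malformed CDS")
      transcript_model(
        transcript_id = id, gene_id = ex$gene_id[1], seqname = ex$seqname[1],
        strand = strand, exons = ex[, c("start", "end")],
        cds_start_codon_tx = t5, canonical_stop_tx = t3 + 1L - 3L,
        ptc_codon_index = ptc[[id]] %||% NA_integer_
      )
    }, error = function(e) e)
    if (inherits(model, "ribortc_bad_ptc")) {
      stop_ribortc(sprintf("PTC index outside CDS for transcript %s", id),
                   "ribortc_bad_ptc")
    }
    if (inherits(model, "error")) {
      why <- conditionMessage(model)
      skip(id, if (grepl("malformed CDS", why)) "malformed_cds" else "bad_structure")
      next
    }
    models[[id]] <- model
  }
  attr(models, "skipped") <- skipped
  models
}

normalize_ptc_table <- function(ptc_table) {
  if (is.null(ptc_table)) return(list())
  if (is.data.frame(ptc_table)) {
    stopifnot(all(c("transcript_id", "ptc_codon_index") %in% names(ptc_table)))
    out <- as.list(as.integer(ptc_table$ptc_codon_index))
    names(out) <- as.character(ptc_table$transcript_id)
    return(out)
  }
  if (is.numeric(ptc_table) && !is.null(names(ptc_table))) {
    out <- as.list(as.integer(ptc_table))
    names(out) <- names(ptc_table)
    return(out)
  }
  stop_ribortc("ptc_table must be a data.frame or a named integer vector",
               "ribortc_bad_input")
}

#' Read a PTC table from a TSV file
#'
#' Expects columns `transcript_id` and `ptc_codon_index`.
#' @param path TSV path.
#' @return A data.frame suitable for [read_annotation()]'s `ptc_table`.
#' @export
read_ptc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "ptc_codon_index") %in% names(df)))
  df
}

#' Pick one representative transcript per gene (longest CDS)
#'
#' Metagene analyses use a single transcript per gene to avoid double
#' counting; the longest CDS is the standard convention.
#' @param models List of `TranscriptModel`s.
#' @return Subset of `models`, one per gene.
#' @export
representative_transcripts <- function(models) {
  genes <- vapply(models, function(m) m$gene_id, character(1))
  cds_len <- vapply(models, function(m) n_cds_codons(m), integer(1))
  keep <- unlist(lapply(split(seq_along(models), genes), function(idx) {
    idx[which.max(cds_len[idx])]
  }), use.names = FALSE)
  models[sort(keep)]
}
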