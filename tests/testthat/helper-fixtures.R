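# Fixtures are built in code at test time; no binary data on disk.

# GTF writer for toy annotations (1-based closed intervals, GTF-style
# attributes).  `features` is a data.frame: seqname, source, type, start,
# end, strand, gene_id, transcript_id -- start/end already 1-based closed.
write_toy_gtf <- function(features, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    features$seqname, features$source, features$type,
    features$start, features$end, features$strand,
    features$gene_id, features$transcript_id)
  writeLines(lines, path)
  path
}

# Single-exon plus-strand toy annotation: exon genomic 0..1300, CDS at
# transcript positions [10, 1192) including the stop codon.
toy_gtf_single <- function(path = tempfile(fileext = ".gtf")) {
  write_toy_gtf(data.frame(
    seqname = "chr1", source = "toy", type = c("exon", "CDS"),
    start = c(1L, 11L), end = c(1300L, 1192L), strand = "+",
    gene_id = "g1", transcript_id = "tx1"), path)
}

# Two-exon minus-strand toy: genomic exons [100,112) and [130,139),
# CDS covering the full 21-nt transcript (7 codons).
toy_gtf_minus <- function(path = tempfile(fileext = ".gtf")) {
  write_toy_gtf(data.frame(
    seqname = "chr2", source = "toy", type = c("exon", "exon", "CDS", "CDS"),
    start = c(101L, 131L, 101L, 131L), end = c(112L, 139L, 112L, 139L),
    strand = "-", gene_id = "g2", transcript_id = "tx2"), path)
}

# Minimal PsiteProfile carrying given in-frame codon counts (for operations
# that consume codon counts directly).
make_codon_profile <- function(model, codon_counts) {
  n_ext <- max_frame_codon(model)
  cc <- numeric(n_ext)
  cc[seq_along(codon_counts)] <- codon_counts
  counts <- numeric(model$tx_length)
  pos <- model$cds_start_codon_tx + 3L * (seq_len(n_ext) - 1L)
  counts[pos + 1L] <- cc
  structure(list(
    transcript_id = model$transcript_id, counts = counts, codon_counts = cc,
    frame_counts = c(f0 = sum(cc), f1 = 0L, f2 = 0L),
    region_counts = c(utr5 = 0L, cds = sum(cc), utr3 = 0L),
    length_frame0 = data.frame(length = 28L, n_total = sum(cc),
                               n_cds = sum(cc), n_cds_frame0 = sum(cc)),
    n_assigned = sum(cc), discarded = c(psite_out_of_range = 0L)
  ), class = "PsiteProfile")
}

# Naive per-codon recount of the PTC readthrough ratio: the brute-force
# oracle the fast implementation must match exactly.
naive_ptc_ratio <- function(codon_counts, ptc, n_stop) {
  n_pre <- 0
  for (i in seq_len(ptc - 1L)) n_pre <- n_pre + codon_counts[i]
  n_post <- 0
  for (i in (ptc + 1L):(n_stop - 1L)) n_post <- n_post + codon_counts[i]
  (n_post / (n_stop - ptc - 1L)) / (n_pre / (ptc - 1L))
}

# GAlignments built in code for projection tests.
make_galn <- function(seqnames, pos, cigar, strand, qname = NULL,
                      mapq = 60L, NH = 1L) {
  n <- length(pos)
  GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(rep_len(seqnames, n)),
    pos = as.integer(pos), cigar = rep_len(cigar, n),
    strand = GenomicRanges::strand(rep_len(strand, n)),
    qname = qname %||% sprintf("r%03d", seq_len(n)),
    mapq = rep_len(as.integer(mapq), n), NH = rep_len(as.integer(NH), n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small bank of toy canonical-stop transcripts for metagene tests.
toy_gene_set <- function(n_genes, n_codons = 200L, utr3 = 200L) {
  ids <- sprintf("g%03d", seq_len(n_genes))
  mods <- lapply(ids, function(id) {
    toy_transcript(id, n_codons = n_codons, utr3 = utr3, gene_id = id)
  })
  names(mods) <- ids
  mods
}
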