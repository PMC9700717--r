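test_that("single-exon GTF maps CDS and PTC into transcript coordinates", {
  models <- read_annotation(toy_gtf_single(),
                            ptc_table = c(tx1 = 213L))
  expect_length(models, 1L)
  m <- models$tx1
  expect_equal(m$cds_start_codon_tx, 10L)
  expect_equal(m$canonical_stop_tx, 1189L)
  expect_equal(m$ptc_codon_index, 213L)
  expect_equal(n_cds_codons(m), 394L)
  expect_equal(m$tx_length, 1300L)
})

test_that("transcripts with malformed CDS are skipped and tallied", {
  path <- write_toy_gtf(data.frame(
    seqname = "chr1", source = "toy", type = c("exon", "CDS"),
    start = c(1L, 11L), end = c(300L, 114L),  # CDS 104 nt, not mult of 3
    strand = "+", gene_id = "g1", transcript_id = "txbad"))
  models <- read_annotation(path)
  expect_length(models, 0L)
  skipped <- attr(models, "skipped")
  expect_equal(skipped$transcript_id, "txbad")
  expect_equal(skipped$reason, "malformed_cds")
})

test_that("PTC index outside the CDS is fatal with the transcript id", {
  expect_error(read_annotation(toy_gtf_single(), ptc_table = c(tx1 = 394L)),
               class = "ribortc_bad_ptc")
  expect_error(read_annotation(toy_gtf_single(), ptc_table = c(tx1 = 1L)),
               class = "ribortc_bad_ptc")
})

test_that("unreadable annotation file is fatal", {
  expect_error(read_annotation(tempfile()), class = "ribortc_io_error")
})

test_that("minus-strand two-exon transcript follows transcription order", {
  models <- read_annotation(toy_gtf_minus())
  m <- models$tx2
  expect_equal(m$strand, "-")
  expect_equal(m$tx_length, 21L)
  expect_equal(m$cds_start_codon_tx, 0L)
  expect_equal(m$canonical_stop_tx, 18L)
  # hand-built coordinate oracle: tx 0..8 <- genomic 138..130,
  # tx 9..20 <- genomic 111..100
  oracle <- c(138:130, 111:100)
  expect_equal(tx_to_genome(m, 0:20), oracle)
  expect_equal(genome_to_tx(m, oracle), 0:20)
})

test_that("tx->genome->tx round-trip is the identity on both strands", {
  for (str in c("+", "-")) {
    exons <- if (str == "+") data.frame(start = c(50L, 90L), end = c(71L, 111L))
             else data.frame(start = c(90L, 50L), end = c(111L, 71L))
    m <- transcript_model("rt", strand = str, exons = exons,
                          cds_start_codon_tx = 3L, canonical_stop_tx = 36L)
    pos <- 0:(m$tx_length - 1L)
    g <- tx_to_genome(m, pos)
    expect_false(anyNA(g))
    expect_equal(genome_to_tx(m, g), pos)
  }
})

test_that("projection maps exon-contained reads and discards the rest", {
  gtf <- write_toy_gtf(data.frame(
    seqname = "chr3", source = "toy", type = c("exon", "exon", "CDS"),
    start = c(101L, 201L, 111L), end = c(150L, 250L, 208L),
    strand = "+", gene_id = "g3", transcript_id = "tx3"))
  models <- read_annotation(gtf)
  m <- models$tx3
  aln <- make_galn(
    seqnames = "chr3",
    pos = c(101L,        # at exon1 start -> five_prime_tx 0
            141L,        # spliced across the intron with N cigar
            145L,        # runs into the intron (no N)
            500L,        # no transcript overlap
            120L,        # on the wrong strand
            130L),       # multimapper
    cigar = c("20M", "10M50N10M", "20M", "20M", "20M", "20M"),
    strand = c("+", "+", "+", "+", "-", "+"),
    NH = c(1L, 1L, 1L, 1L, 1L, 5L))
  fp <- project_to_transcript(aln, models)
  expect_equal(nrow(fp), 2L)
  expect_equal(fp$five_prime_tx, c(0L, 40L))
  expect_equal(fp$length, c(20L, 20L))
  disc <- attr(fp, "discarded")
  expect_equal(unname(disc["multimapper"]), 1L)
  expect_equal(unname(disc["incompatible_structure"]), 2L)
  expect_equal(unname(disc["no_transcript_overlap"]), 1L)
  # conservation: assigned reads + discarded = total input
  expect_equal(length(unique(fp$read_id)) + sum(disc), length(aln))
})

test_that("minus-strand projection puts the 5' end at the genomic rightmost base", {
  models <- read_annotation(toy_gtf_minus())
  m <- models$tx2
  # brute-force per-base table: a 6-nt read at genomic [133, 139) covers
  # tx coords genome_to_tx(138:133) = 0..5, so five_prime_tx = 0
  aln <- make_galn("chr2", pos = 134L, cigar = "6M", strand = "-")
  fp <- project_to_transcript(aln, models)
  expect_equal(fp$five_prime_tx, 0L)
  expect_equal(fp$length, 6L)
  # read bridging the two exons with the correct N gap maps contiguously
  aln2 <- make_galn("chr2", pos = 107L, cigar = "6M18N5M", strand = "-")
  fp2 <- project_to_transcript(aln2, models)
  expect_equal(fp2$five_prime_tx, 4L)  # genomic rightmost base 138-135=..
  expect_equal(fp2$length, 11L)
})

test_that("simulated SAM round-trips through Rsamtools", {
  m <- toy_transcript("tx1", n_codons = 60, utr5 = 20, utr3 = 60)
  sim <- simulate_footprints(sim_config(seed = 11, transcripts = list(tx1 = m),
                                        lambda_pre = 5))
  path <- tempfile(fileext = ".sam")
  write_footprints_sam(sim$alignments, list(tx1 = m), path)
  back <- galignments_to_footprints(read_genome_alignments(path))
  ord <- order(back$read_id)
  expect_equal(back$five_prime_tx[ord],
               sim$alignments$five_prime_tx[order(sim$alignments$read_id)])
  expect_equal(back$length[ord],
               sim$alignments$length[order(sim$alignments$read_id)])
})

test_that("one representative transcript per gene keeps the longest CDS", {
  iso1 <- toy_transcript("txA", n_codons = 100, gene_id = "geneX")
  iso2 <- toy_transcript("txB", n_codons = 150, gene_id = "geneX")
  other <- toy_transcript("txC", n_codons = 80, gene_id = "geneY")
  rep <- representative_transcripts(list(txA = iso1, txB = iso2, txC = other))
  expect_setequal(names(rep), c("txB", "txC"))
})

test_that("bedGraph writer merges runs and round-trips the profile", {
  m <- toy_transcript("txc", n_codons = 10, utr5 = 6, utr3 = 6)
  p <- make_codon_profile(m, rep(0, 10))
  p$counts <- numeric(m$tx_length)
  p$counts[6:7] <- 3   # positions 5,6 (0-based)
  p$counts[10] <- 1    # position 9
  path <- tempfile(fileext = ".bedGraph")
  write_coverage_track(p, path)
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(lines[-1], c("txc\t5\t7\t3", "txc\t9\t10\t1"))
  expect_equal(read_coverage_track(path, m$tx_length), p$counts)
})

test_that("empty profile writes a header-only track", {
  m <- toy_transcript("txe", n_codons = 10, utr5 = 6, utr3 = 6)
  p <- make_codon_profile(m, rep(0, 10))
  path <- tempfile(fileext = ".bedGraph")
  write_coverage_track(p, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^track")
  expect_equal(read_coverage_track(path, m$tx_length), numeric(m$tx_length))
})
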