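test_that("uniform-density hand oracle: 10/codon pre, 1/codon post gives 10%", {
  m <- toy_transcript("tp53", n_codons = 394, ptc_codon_index = 213)
  cc <- numeric(394)
  cc[1:212] <- 10
  cc[214:393] <- 1
  p <- make_codon_profile(m, cc)
  r <- ptc_readthrough_ratio(p, m)
  expect_equal(r$n_pre, 2120)
  expect_equal(r$L_pre, 212L)
  expect_equal(r$n_post, 180)
  expect_equal(r$L_post, 180L)
  expect_equal(r$ratio, 0.1)
  expect_equal(r$percent, 10)
})

test_that("edge ratios: empty post is 0, equal densities are 1, empty pre errors", {
  m <- toy_transcript("t1", n_codons = 100, ptc_codon_index = 40)
  cc0 <- numeric(100); cc0[1:39] <- 5
  expect_equal(ptc_readthrough_ratio(make_codon_profile(m, cc0), m)$ratio, 0)
  cc1 <- numeric(100); cc1[1:39] <- 7; cc1[41:99] <- 7
  expect_equal(ptc_readthrough_ratio(make_codon_profile(m, cc1), m)$ratio, 1)
  ccpre0 <- numeric(100); ccpre0[41:99] <- 3
  expect_error(ptc_readthrough_ratio(make_codon_profile(m, ccpre0), m),
               class = "ribortc_no_coverage")
  expect_error(
    ptc_readthrough_ratio(make_codon_profile(toy_transcript("t2", 100),
                                             numeric(100)),
                          toy_transcript("t2", 100)),
    class = "ribortc_no_ptc")
})

test_that("ratio is scale-invariant and monotone in where reads are added", {
  m <- toy_transcript("t1", n_codons = 80, ptc_codon_index = 30)
  set.seed(12)
  cc <- rpois(80, 4) + 1
  base <- ptc_readthrough_ratio(make_codon_profile(m, cc), m)$ratio
  expect_equal(ptc_readthrough_ratio(make_codon_profile(m, cc * 7), m)$ratio,
               base)
  # adding a read strictly after the PTC never decreases the ratio
  for (i in c(31, 50, 79)) {
    cc2 <- cc; cc2[i] <- cc2[i] + 5
    expect_gte(ptc_readthrough_ratio(make_codon_profile(m, cc2), m)$ratio, base)
  }
  # adding a read before the PTC never increases it
  for (i in c(1, 15, 29)) {
    cc2 <- cc; cc2[i] <- cc2[i] + 5
    expect_lte(ptc_readthrough_ratio(make_codon_profile(m, cc2), m)$ratio, base)
  }
})

test_that("the boundary-inclusion flag folds the stop pileups into the regions", {
  m <- toy_transcript("t1", n_codons = 100, ptc_codon_index = 40)
  cc <- numeric(100); cc[1:39] <- 10; cc[40] <- 50; cc[41:99] <- 1; cc[100] <- 5
  p <- make_codon_profile(m, cc)
  excl <- ptc_readthrough_ratio(p, m)
  incl <- ptc_readthrough_ratio(p, m, include_boundary = TRUE)
  expect_equal(excl$ratio, (59 / 59) / (390 / 39))
  expect_equal(incl$ratio, ((59 + 5) / 60) / ((390 + 50) / 40))
})

test_that("simulated PTC readthrough is recovered near the planted fraction", {
  m <- toy_transcript("t1", n_codons = 394, ptc_codon_index = 213)
  rho <- 0.12
  sim <- simulate_footprints(sim_config(seed = 99, transcripts = list(t1 = m),
                                        lambda_pre = 20, rho_ptc = rho,
                                        beta_bg = 0))
  p <- assign_psites(sim$alignments, list(t1 = m))$t1
  r <- ptc_readthrough_ratio(p, m)
  n_post_exp <- 180 * 20 * rho
  se <- rho * sqrt(1 / n_post_exp + 1 / (212 * 20))
  expect_lt(abs(r$ratio - rho), 3 * se + 0.02 * rho)
})

test_that("metagene ratio: uniform window is 1, empty 3'UTR is 0", {
  mods <- toy_gene_set(3, n_codons = 100, utr3 = 200)
  flat <- lapply(mods, function(m) {
    cc <- numeric(max_frame_codon(m)); cc[1:150] <- 4
    make_codon_profile(m, cc)
  })
  mg <- metagene_stop_readthrough(flat, mods, window_before = 40,
                                  window_after = 40, min_cds_reads = 10)
  expect_equal(mg$readthrough_ratio, 1)
  expect_equal(sum(mg$bins$percent), 100)
  empty3 <- lapply(mods, function(m) {
    cc <- numeric(max_frame_codon(m)); cc[1:99] <- 4
    make_codon_profile(m, cc)
  })
  mg0 <- metagene_stop_readthrough(empty3, mods, window_before = 40,
                                   window_after = 40, min_cds_reads = 10)
  expect_equal(mg0$readthrough_ratio, 0)
  expect_equal(mg0$n_genes_included, 3L)
})

test_that("metagene ratio is invariant to gene order and compatible bin widths", {
  mods <- toy_gene_set(10, n_codons = 150, utr3 = 200)
  sim <- simulate_footprints(sim_config(seed = 13, transcripts = mods,
                                        lambda_pre = 10, rho_canonical = 0.05,
                                        utr3_span_codons = 40))
  profiles <- assign_psites(sim$alignments, mods)
  base <- metagene_stop_readthrough(profiles, mods, window_before = 40,
                                    window_after = 40)
  perm <- rev(names(profiles))
  shuffled <- metagene_stop_readthrough(profiles[perm], mods[perm],
                                        window_before = 40, window_after = 40)
  expect_equal(shuffled$readthrough_ratio, base$readthrough_ratio)
  for (bw in c(2, 5, 10)) {
    reb <- metagene_stop_readthrough(profiles, mods, window_before = 40,
                                     window_after = 40, bin_codons = bw)
    expect_equal(reb$readthrough_ratio, base$readthrough_ratio)
    expect_equal(sum(reb$bins$count), sum(base$bins$count))
  }
})

test_that("genes below the CDS-read threshold are excluded; none left errors", {
  mods <- toy_gene_set(2, n_codons = 100, utr3 = 200)
  sparse <- lapply(mods, function(m) {
    cc <- numeric(max_frame_codon(m)); cc[60] <- 5   # inside the pre-stop window
    make_codon_profile(m, cc)
  })
  expect_error(metagene_stop_readthrough(sparse, mods, min_cds_reads = 32),
               class = "ribortc_no_coverage")
  mg <- metagene_stop_readthrough(sparse, mods, min_cds_reads = 1)
  expect_equal(mg$n_genes_included, 2L)
})

test_that("short 3'UTRs contribute only their defined bins (masked mean)", {
  long <- toy_transcript("gl", n_codons = 100, utr3 = 200, gene_id = "gl")
  short <- toy_transcript("gs", n_codons = 100, utr3 = 30, gene_id = "gs")
  mods <- list(gl = long, gs = short)
  profs <- lapply(mods, function(m) {
    cc <- numeric(max_frame_codon(m))
    cc[1:99] <- 2                                  # pre-stop density 2
    cc[101:min(110, length(cc))] <- 1              # post-stop density 1
    make_codon_profile(m, cc)
  })
  mg <- metagene_stop_readthrough(profs, mods, window_before = 10,
                                  window_after = 10, min_cds_reads = 5)
  # gs has exactly 10 extended codons past the stop (utr3 = 30 nt), so both
  # genes define all 10 post bins here; widening to 20 masks gs's tail
  mg2 <- metagene_stop_readthrough(profs, mods, window_before = 20,
                                   window_after = 20, min_cds_reads = 5)
  # oracle: post slots = 20 (gl) + 10 (gs); post counts = 10 + 10
  # pre slots = 40, pre counts = 2 * 40
  expect_equal(mg2$readthrough_ratio, (20 / 30) / (80 / 40))
  expect_equal(mg$readthrough_ratio, (20 / 20) / (40 / 20))
})

test_that("readthrough report gives order statistics and a seeded bootstrap CI", {
  res <- data.frame(sample_id = letters[1:4], condition = "FUr",
                    ratio = c(4, 6, 8, 100))
  rep1 <- readthrough_report(res, seed = 7)
  expect_equal(rep1$median, 7)
  expect_equal(rep1$n, 4L)
  expect_false(rep1$degenerate)
  expect_true(rep1$ci_lo <= 7 && rep1$ci_hi >= 7)
  rep2 <- readthrough_report(res, seed = 7)
  expect_identical(rep1, rep2)
  single <- readthrough_report(data.frame(sample_id = "a", condition = "NT",
                                          ratio = 5))
  expect_true(single$degenerate)
  expect_equal(single$ci_lo, 5)
})

test_that("bootstrap CI of the median covers the sample median (Monte-Carlo)", {
  set.seed(202)
  hits <- 0L
  n_draws <- 400L
  for (i in seq_len(n_draws)) {
    x <- rlnorm(4, meanlog = log(0.08), sdlog = 0.5)
    df <- data.frame(sample_id = 1:4, condition = "c", ratio = x)
    rp <- readthrough_report(df, n_boot = 500L, seed = i)
    if (rp$ci_lo <= rp$median && rp$median <= rp$ci_hi) hits <- hits + 1L
  }
  expect_gte(hits / n_draws, 0.99)
})
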