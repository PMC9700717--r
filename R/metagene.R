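#' Metagene stop-codon readthrough ratio
#'
#' Aligns all included genes at their annotated stop codon, accumulates
#' in-frame P-site counts into codon bins over a window
#' `[-window_before, +window_after]`, and reports each bin as a percentage
#' of the window total.  The readthrough ratio is the length-normalised
#' pooled density after the stop over the density before it,
#' \deqn{ratio = (\sum_{after} c / S_{after}) / (\sum_{before} c / S_{before}),}
#' where the S are the numbers of contributing (gene, codon) slots (genes
#' whose transcript does not span the full window contribute only their
#' defined bins - a masked mean).  The stop-codon bin itself is excluded
#' from both sides because the terminating-ribosome pileup would dominate.
#'
#' @param profiles Named list of `PsiteProfile`s.
#' @param models Matching named list of `TranscriptModel`s (one
#'   representative transcript per gene; see
#'   [representative_transcripts()]).
#' @param window_before,window_after Window extents in codons.
#' @param bin_codons Bin width in codons; must divide both window extents.
#' @param min_cds_reads Minimum in-frame CDS reads for a gene to be
#'   included ("translated" genes).
#' @return A `MetageneProfile` list: `bins` (data.frame `codon_from`,
#'   `codon_to` relative to the stop codon at 0, `count`, `n_slots`,
#'   `percent`), `n_genes_included`, `readthrough_ratio`,
#'   `readthrough_percent`, window parameters.
#' @export
metagene_stop_readthrough <- function(profiles, models, window_before = 50L,
                                      window_after = 50L, bin_codons = 1L,
                                      min_cds_reads = 32L) {
  stopifnot(length(profiles) >= 1L)
  if (window_before %% bin_codons != 0L || window_after %% bin_codons != 0L) {
    stop_ribortc("bin_codons must divide both window extents",
                 "ribortc_bad_input")
  }
  offsets <- (-window_before):window_after       # codon offset, 0 = stop
  sum_counts <- numeric(length(offsets))
  n_slots <- integer(length(offsets))
  n_genes <- 0L

  for (id in names(profiles)) {
    mod <- models[[id]]
    if (is.null(mod)) next
    p <- profiles[[id]]
    n_stop <- n_cds_codons(mod)
    cds_reads <- sum(p$codon_counts[seq_len(min(n_stop, length(p$codon_counts)))])
    if (cds_reads < min_cds_reads) next
    n_genes <- n_genes + 1L
    codon_idx <- n_stop + offsets
    ok <- codon_idx >= 1L & codon_idx <= length(p$codon_counts)
    sum_counts[ok] <- sum_counts[ok] + p$codon_counts[codon_idx[ok]]
    n_slots[ok] <- n_slots[ok] + 1L
  }
  if (n_genes == 0L) {
    stop_ribortc("no gene passes the CDS read threshold", "ribortc_no_coverage")
  }

  before <- offsets < 0L
  after <- offsets > 0L
  pre_slots <- sum(n_slots[before])
  post_slots <- sum(n_slots[after])
  pre_sum <- sum(sum_counts[before])
  post_sum <- sum(sum_counts[after])
  if (pre_sum == 0) {
    stop_ribortc("zero pre-stop signal: metagene ratio undefined",
                 "ribortc_no_coverage")
  }
  ratio <- if (post_slots > 0L) {
    (post_sum / post_slots) / (pre_sum / pre_slots)
  } else NA_real_

  # codon bins -> requested bin width
  bin_id <- floor(offsets / bin_codons)
  bins <- data.frame(
    codon_from = tapply(offsets, bin_id, min),
    codon_to = tapply(offsets, bin_id, max),
    count = as.numeric(tapply(sum_counts, bin_id, sum)),
    n_slots = as.integer(tapply(n_slots, bin_id, sum))
  )
  rownames(bins) <- NULL
  total <- sum(bins$count)
  bins$percent <- if (total > 0) 100 * bins$count / total else 0

  structure(list(
    bins = bins,
    window_before = as.integer(window_before),
    window_after = as.integer(window_after),
    bin_codons = as.integer(bin_codons),
    n_genes_included = n_genes,
    readthrough_ratio = ratio,
    readthrough_percent = 100 * ratio
  ), class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf(
    "MetageneProfile: %d genes, window -%d..+%d codons (bin %d); readthrough %.3g%%\n",
    x$n_genes_included, x$window_before, x$window_after, x$bin_codons,
    x$readthrough_percent))
  invisible(x)
}
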