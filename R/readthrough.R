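#' PTC readthrough ratio on a single transcript
#'
#' The headline statistic: the length-normalised in-frame P-site density
#' downstream of a premature termination codon divided by the density
#' upstream of it,
#' \deqn{ratio = (n_{post}/L_{post}) / (n_{pre}/L_{pre}),}
#' with `n_pre` summed over codons `1..(ptc-1)` and `n_post` over codons
#' `(ptc+1)..(N_stop-1)` (`N_stop` = canonical stop codon index).  The PTC
#' codon itself and the canonical stop codon are excluded by default
#' because terminating-ribosome pileups at both would bias the densities;
#' `include_boundary = TRUE` folds the PTC codon into the upstream region
#' and the canonical stop into the downstream region instead.
#'
#' @param profile A `PsiteProfile` with frame-0 codon counts.
#' @param model The matching `TranscriptModel`; must carry
#'   `ptc_codon_index`.
#' @param sample_id Label attached to the result.
#' @param include_boundary Include the PTC and canonical stop codons in
#'   their flanking regions (default `FALSE`).
#' @return A `ReadthroughResult` list: `transcript_id`, `sample_id`,
#'   `n_pre`, `n_post`, `L_pre`, `L_post`, `ratio`, `percent`.
#' @examples
#' m <- toy_transcript("tx1", n_codons = 394, ptc_codon_index = 213)
#' sim <- simulate_footprints(sim_config(seed = 1, transcripts = list(tx1 = m),
#'                                       lambda_pre = 20, rho_ptc = 0.1))
#' prof <- assign_psites(sim$alignments, list(tx1 = m))
#' ptc_readthrough_ratio(prof$tx1, m)$ratio
#' @export
ptc_readthrough_ratio <- function(profile, model, sample_id = NA_character_,
                                  include_boundary = FALSE) {
  stopifnot(inherits(profile, "PsiteProfile"))
  ptc <- model$ptc_codon_index
  if (is.na(ptc)) {
    stop_ribortc(sprintf("transcript %s has no PTC annotation",
                         model$transcript_id), "ribortc_no_ptc")
  }
  n_stop <- n_cds_codons(model)
  cc <- profile$codon_counts
  if (include_boundary) {
    pre_idx <- 1:ptc
    post_idx <- (ptc + 1L):n_stop
  } else {
    pre_idx <- 1:(ptc - 1L)
    post_idx <- (ptc + 1L):(n_stop - 1L)
  }
  n_pre <- sum(cc[pre_idx])
  n_post <- sum(cc[post_idx])
  L_pre <- length(pre_idx)
  L_post <- length(post_idx)
  if (n_pre == 0) {
    stop_ribortc(sprintf("no pre-PTC signal on %s: ratio undefined",
                         model$transcript_id), "ribortc_no_coverage")
  }
  ratio <- (n_post / L_post) / (n_pre / L_pre)
  structure(list(
    transcript_id = model$transcript_id, sample_id = sample_id,
    n_pre = n_pre, n_post = n_post, L_pre = L_pre, L_post = L_post,
    ratio = ratio, percent = 100 * ratio
  ), class = "ReadthroughResult")
}

#' @export
print.ReadthroughResult <- function(x, ...) {
  cat(sprintf(
    "ReadthroughResult %s%s: %.3g%% (post %d/%d codons vs pre %d/%d codons)\n",
    x$transcript_id,
    if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
    x$percent, x$n_post, x$L_post, x$n_pre, x$L_pre))
  invisible(x)
}

#' Summarise readthrough ratios by condition
#'
#' Per condition: median, quartiles and a seeded bootstrap 95% confidence
#' interval of the median.  Single-replicate conditions get a degenerate
#' CI and are flagged.
#'
#' @param results Data.frame with columns `sample_id`, `condition`,
#'   `ratio` (one row per replicate).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return Data.frame with one row per condition: `condition`, `n`,
#'   `median`, `q25`, `q75`, `ci_lo`, `ci_hi`, `degenerate`.
#' @export
readthrough_report <- function(results, n_boot = 2000L, conf = 0.95,
                               seed = 1L) {
  stopifnot(all(c("condition", "ratio") %in% names(results)),
            nrow(results) >= 1L)
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    out <- lapply(split(results$ratio, results$condition), function(x) {
      med <- stats::median(x)
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
      if (length(x) == 1L) {
        data.frame(n = 1L, median = med, q25 = q[1], q75 = q[2],
                   ci_lo = med, ci_hi = med, degenerate = TRUE)
      } else {
        idx <- matrix(sample.int(length(x), length(x) * n_boot,
                                 replace = TRUE), nrow = n_boot)
        meds <- apply(idx, 1L, function(i) stats::median(x[i]))
        ci <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE)
        data.frame(n = length(x), median = med, q25 = q[1], q75 = q[2],
                   ci_lo = ci[1], ci_hi = ci[2], degenerate = FALSE)
      }
    })
    df <- do.call(rbind, out)
    df <- cbind(condition = names(out), df)
    rownames(df) <- NULL
    df
  })
}
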