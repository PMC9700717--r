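#' Simulation configuration for synthetic ribosome footprints
#'
#' Describes a Ribo-seq library with the statistical structure the
#' downstream analyses assume: footprint lengths concentrated at 28-29 nt,
#' strong 3-nt periodicity, uniform in-frame density over the translated
#' CDS, a configurable readthrough fraction past a PTC and past canonical
#' stops, terminating-ribosome pileups at stop codons, an initiation
#' pileup at the start codon, and optional uniform background.
#'
#' @param seed Integer seed; the same seed and config give a byte-identical
#'   library.
#' @param transcripts Named list of `TranscriptModel`s.
#' @param lambda_pre Mean in-frame footprints per codon before the PTC (or
#'   over the CDS for transcripts without a PTC).
#' @param rho_ptc Readthrough fraction at the PTC in `[0, 1]`: post-PTC
#'   per-codon density is `rho_ptc * lambda_pre`.
#' @param rho_canonical Readthrough fraction at canonical stop codons.
#' @param length_dist Named numeric vector mapping footprint length (nt) to
#'   probability; must sum to 1.
#' @param true_offsets Named integer vector mapping length to the true
#'   P-site offset (nt from the 5' end).
#' @param pi_frame Probability a footprint falls exactly in frame; the
#'   remaining mass is shifted +/- 1 nt with equal probability.
#' @param stop_peak Density multiplier at a terminating stop codon
#'   (piled-up ribosomes prior to release).
#' @param start_peak Density multiplier at the start codon (initiation
#'   pileup); also what anchors P-site offset calibration.
#' @param beta_bg Uniform background footprints per nt of transcript.
#' @param utr3_span_codons How many in-frame codons of readthrough
#'   extension to simulate past a canonical stop.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed, transcripts, lambda_pre = 20,
                       rho_ptc = 0, rho_canonical = 0,
                       length_dist = c("28" = 0.5, "29" = 0.5),
                       true_offsets = c("28" = 12L, "29" = 12L),
                       pi_frame = 0.9, stop_peak = 5, start_peak = 5,
                       beta_bg = 0, utr3_span_codons = 50L) {
  stopifnot(is_count(seed), length(transcripts) >= 1L)
  if (lambda_pre <= 0) stop_ribortc("lambda_pre must be > 0", "ribortc_bad_input")
  probs <- c(rho_ptc, rho_canonical, pi_frame)
  if (any(probs < 0) || any(probs > 1)) {
    stop_ribortc("rho_ptc, rho_canonical and pi_frame must lie in [0, 1]",
                 "ribortc_bad_input")
  }
  if (abs(sum(length_dist) - 1) > 1e-8 || any(length_dist < 0)) {
    stop_ribortc("length_dist must be a probability distribution",
                 "ribortc_bad_input")
  }
  if (!all(names(length_dist) %in% names(true_offsets))) {
    stop_ribortc("every length in length_dist needs a true offset",
                 "ribortc_bad_input")
  }
  if (is.null(names(transcripts))) {
    names(transcripts) <- vapply(transcripts, function(m) m$transcript_id,
                                 character(1))
  }
  structure(list(
    seed = as.integer(seed), transcripts = transcripts,
    lambda_pre = lambda_pre, rho_ptc = rho_ptc,
    rho_canonical = rho_canonical,
    length_dist = length_dist,
    true_offsets = true_offsets,
    pi_frame = pi_frame, stop_peak = stop_peak, start_peak = start_peak,
    beta_bg = beta_bg, utr3_span_codons = as.integer(utr3_span_codons)
  ), class = "SimConfig")
}

# Per-codon mean footprint counts over the extended reading frame of one
# transcript.  Categories label where each codon's ribosomes terminate-
# relative regions, for ground-truth bookkeeping.
codon_intensity <- function(model, cfg) {
  n_stop <- n_cds_codons(model)
  utr3_codons <- min(cfg$utr3_span_codons, max_frame_codon(model) - n_stop)
  n_ext <- n_stop + max(utr3_codons, 0L)
  lam <- numeric(n_ext)
  cat <- character(n_ext)
  ptc <- model$ptc_codon_index
  L <- cfg$lambda_pre
  if (!is.na(ptc)) {
    lam[1:(ptc - 1L)] <- L
    cat[1:(ptc - 1L)] <- "pre_ptc"
    lam[ptc] <- cfg$stop_peak * L
    cat[ptc] <- "ptc"
    if (ptc + 1L <= n_stop - 1L) {
      lam[(ptc + 1L):(n_stop - 1L)] <- cfg$rho_ptc * L
      cat[(ptc + 1L):(n_stop - 1L)] <- "post_ptc"
    }
    lam[n_stop] <- cfg$stop_peak * cfg$rho_ptc * L
    cat[n_stop] <- "stop"
    if (n_ext > n_stop) {
      lam[(n_stop + 1L):n_ext] <- cfg$rho_canonical * cfg$rho_ptc * L
      cat[(n_stop + 1L):n_ext] <- "post_stop"
    }
  } else {
    lam[1:(n_stop - 1L)] <- L
    cat[1:(n_stop - 1L)] <- "pre_stop"
    lam[n_stop] <- cfg$stop_peak * L
    cat[n_stop] <- "stop"
    if (n_ext > n_stop) {
      lam[(n_stop + 1L):n_ext] <- cfg$rho_canonical * L
      cat[(n_stop + 1L):n_ext] <- "post_stop"
    }
  }
  lam[1] <- cfg$start_peak * L          # initiation pileup
  list(lambda = lam, category = cat)
}

#' Simulate a synthetic ribosome-footprint library with ground truth
#'
#' Ribosome counts are drawn codon-wise Poisson with per-codon means from
#' the config (see [sim_config()]).  Each ribosome emits one footprint: a
#' length is drawn from `length_dist`, the P-site nucleotide is the first
#' nucleotide of the codon (jittered +/- 1 nt with probability
#' `1 - pi_frame`), and the 5' end is the P-site minus the length's true
#' offset.  Background footprints are uniform over each transcript.
#'
#' @param config A `SimConfig`.
#' @return A list with `alignments` (footprints data.frame, plus a
#'   `category` truth column and an `in_frame` flag) and `truth`
#'   (`SimTruth`): per-transcript placed-ribosome counts by category
#'   (`n_pre_ptc`, `n_post_ptc`, `n_pre_stop`, `n_post_stop`, region codon
#'   lengths) and realized readthrough fractions computed exactly as the
#'   analysis defines them (length-normalised density ratios, boundary
#'   codons excluded).
#' @export
simulate_footprints <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  lens <- as.integer(names(cfg$length_dist))
  max_off <- max(cfg$true_offsets[as.character(lens)])
  min_off <- min(cfg$true_offsets[as.character(lens)])
  max_len <- max(lens)
  for (m in cfg$transcripts) {
    if (m$tx_length < max_len) {
      stop_ribortc(sprintf("transcript %s shorter than the longest footprint",
                           m$transcript_id), "ribortc_bad_input")
    }
    if (m$cds_start_codon_tx < max_off + 1L) {
      stop_ribortc(sprintf(
        "transcript %s: 5'UTR too short for footprint geometry (need >= %d nt)",
        m$transcript_id, max_off + 1L), "ribortc_bad_input")
    }
  }

  with_seed(cfg$seed, {
    per_tx <- lapply(cfg$transcripts, function(m) {
      ci <- codon_intensity(m, cfg)
      counts <- stats::rpois(length(ci$lambda), ci$lambda)
      n_rib <- sum(counts)
      codon <- rep(seq_along(counts), counts)
      category <- rep(ci$category, counts)
      # footprint emission
      len <- if (n_rib > 0L) {
        lens[sample.int(length(lens), n_rib, replace = TRUE,
                        prob = cfg$length_dist)]
      } else integer(0)
      jit <- if (n_rib > 0L) {
        sample(c(0L, -1L, 1L), n_rib, replace = TRUE,
               prob = c(cfg$pi_frame, (1 - cfg$pi_frame) / 2,
                        (1 - cfg$pi_frame) / 2))
      } else integer(0)
      psite <- m$cds_start_codon_tx + 3L * (codon - 1L) + jit
      fp <- psite - cfg$true_offsets[as.character(len)]
      bad <- fp < 0L | fp + len > m$tx_length
      if (any(bad)) {
        stop_ribortc(sprintf(
          "transcript %s too short for simulated footprint geometry",
          m$transcript_id), "ribortc_bad_input")
      }
      # uniform background over the transcript
      n_bg <- stats::rpois(1L, cfg$beta_bg * m$tx_length)
      if (n_bg > 0L) {
        bg_len <- lens[sample.int(length(lens), n_bg, replace = TRUE,
                                  prob = cfg$length_dist)]
        bg_fp <- vapply(bg_len, function(l) {
          sample.int(m$tx_length - l + 1L, 1L) - 1L
        }, integer(1))
        fp <- c(fp, bg_fp)
        len <- c(len, bg_len)
        category <- c(category, rep("bg", n_bg))
        jit <- c(jit, rep(NA_integer_, n_bg))
      }
      data.frame(transcript_id = m$transcript_id,
                 five_prime_tx = as.integer(fp), length = as.integer(len),
                 category = category, in_frame = jit == 0L,
                 stringsAsFactors = FALSE)
    })
    aln <- do.call(rbind, c(per_tx, list(make.row.names = FALSE)))
    aln <- cbind(read_id = sprintf("sim_%07d", seq_len(nrow(aln))), aln,
                 mapq = 255L, multimap_count = 1L)
    aln <- aln[, c("read_id", "transcript_id", "five_prime_tx", "length",
                   "mapq", "multimap_count", "category", "in_frame")]

    truth <- do.call(rbind, lapply(cfg$transcripts, function(m) {
      sub <- aln[aln$transcript_id == m$transcript_id, ]
      n_stop <- n_cds_codons(m)
      ptc <- m$ptc_codon_index
      cnt <- function(what) sum(sub$category == what)
      n_pre_ptc <- cnt("pre_ptc"); n_post_ptc <- cnt("post_ptc")
      n_pre_stop <- if (is.na(ptc)) cnt("pre_stop") else NA_integer_
      n_post_stop <- cnt("post_stop")
      L_pre <- if (is.na(ptc)) NA_integer_ else ptc - 1L
      L_post <- if (is.na(ptc)) NA_integer_ else n_stop - ptc - 1L
      utr3_codons <- min(cfg$utr3_span_codons, max_frame_codon(m) - n_stop)
      realized_rho_ptc <- if (!is.na(ptc) && n_pre_ptc > 0L) {
        (n_post_ptc / L_post) / (n_pre_ptc / L_pre)
      } else NA_real_
      realized_rho_canonical <- if (is.na(ptc) && n_pre_stop > 0L &&
                                    utr3_codons > 0L) {
        (n_post_stop / utr3_codons) / (n_pre_stop / (n_stop - 1L))
      } else NA_real_
      data.frame(transcript_id = m$transcript_id,
                 n_pre_ptc = n_pre_ptc, n_post_ptc = n_post_ptc,
                 n_pre_stop = n_pre_stop, n_post_stop = n_post_stop,
                 n_bg = cnt("bg"),
                 realized_rho_ptc = realized_rho_ptc,
                 realized_rho_canonical = realized_rho_canonical,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    list(alignments = aln, truth = truth)
  })
}
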