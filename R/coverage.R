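#' Normalised coverage over a region
#'
#' Per-position P-site counts divided by the region total, so the output
#' sums to 1 over the region and is invariant to uniform scaling of the
#' counts.
#'
#' @param profile A `PsiteProfile`.
#' @param region Length-2 integer vector `c(start, end)`, 0-based
#'   half-open transcript coordinates.
#' @return Numeric vector of length `end - start` summing to 1.
#' @export
normalized_coverage <- function(profile, region) {
  stopifnot(inherits(profile, "PsiteProfile"), length(region) == 2L)
  start <- as.integer(region[1]); end <- as.integer(region[2])
  if (start < 0L || end > length(profile$counts) || end <= start) {
    stop_ribortc("region outside the transcript", "ribortc_bad_input")
  }
  x <- profile$counts[(start + 1L):end]
  tot <- sum(x)
  if (tot == 0) {
    stop_ribortc(sprintf("no coverage in region [%d, %d) of %s",
                         start, end, profile$transcript_id),
                 "ribortc_no_coverage")
  }
  x / tot
}

#' Per-segment coverage change between two samples
#'
#' Splits `region` into `n_segments` (near-)equal bins and reports, per
#' bin, the difference in normalised coverage, treated minus untreated.
#' Positive values mean a relative gain of footprint density under
#' treatment; because both inputs are normalised the deltas sum to zero.
#'
#' @param treated_profile,untreated_profile `PsiteProfile`s covering
#'   `region`.
#' @param region Length-2 `c(start, end)`, 0-based half-open.
#' @param n_segments Number of bins.
#' @return Numeric vector of length `n_segments`.
#' @export
coverage_delta <- function(treated_profile, untreated_profile, region,
                           n_segments) {
  nt <- normalized_coverage(treated_profile, region)
  nu <- normalized_coverage(untreated_profile, region)
  len <- length(nt)
  stopifnot(is_count(n_segments), n_segments >= 1L, n_segments <= len)
  bounds <- round(seq(0L, len, length.out = n_segments + 1L))
  vapply(seq_len(n_segments), function(k) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    sum(nt[idx]) - sum(nu[idx])
  }, numeric(1))
}

#' Write a P-site profile as a transcript-space bedGraph track
#'
#' One record per run of equal nonzero values (adjacent equal values
#' merged), preceded by a `track type=bedGraph` header line.
#'
#' @param profile A `PsiteProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_track <- function(profile, path) {
  stopifnot(inherits(profile, "PsiteProfile"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_ribortc(
                    sprintf("cannot write %s", path), "ribortc_io_error"))
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s_psites"',
                     profile$transcript_id), con)
  x <- profile$counts
  if (length(x) > 0L && any(x != 0)) {
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    writeLines(sprintf("%s\t%d\t%d\t%g", profile$transcript_id,
                       starts[keep], ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph coverage track back into per-position counts
#'
#' Inverse of [write_coverage_track()] (rtracklayer parses the track).
#'
#' @param path bedGraph path.
#' @param tx_length Transcript length (sizes the output vector).
#' @return Numeric vector of per-position values.
#' @export
read_coverage_track <- function(path, tx_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- numeric(tx_length)
  if (length(gr) > 0L) {
    st <- GenomicRanges::start(gr) - 1L
    en <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) {
      out[(st[i] + 1L):en[i]] <- gr$score[i]
    }
  }
  out
}
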