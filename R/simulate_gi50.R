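#' The default NCI-60 colon/renal cell-line panel
#'
#' The 15-line panel used by the differential-sensitivity screen: colon and
#' renal lines labelled by TP53 status (`nonsense`, `WT`, `other-mut`).
#' Colon: HCC-2998 (nonsense), HCT116 (WT), HCT-15/HT29/KM12/SW-620/COLO205
#' (other-mut).  Renal: SN12C (nonsense), A498/ACHN/CAKI-1/UO-31 (WT),
#' RXF-393/786-0/TK-10 (other-mut).
#'
#' @return A data.frame with columns `cell_line`, `tissue`, `tp53_status`.
#' @export
default_nci_panel <- function() {
  data.frame(
    cell_line = c("HCC-2998", "HCT116", "HCT-15", "HT29", "KM12", "SW-620",
                  "COLO205",
                  "SN12C", "A498", "ACHN", "CAKI-1", "UO-31",
                  "RXF-393", "786-0", "TK-10"),
    tissue = c(rep("colon", 7L), rep("renal", 8L)),
    tp53_status = c("nonsense", "WT", rep("other-mut", 5L),
                    "nonsense", rep("WT", 4L), rep("other-mut", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a GI50 matrix with planted differential compounds
#'
#' Generates a compounds x cell-lines matrix of GI50 concentrations
#' (molar, linear scale) over a labelled panel.  Unplanted compounds get
#' the same value in every line of a tissue (all group-mean ratios 1).
#' A planted compound's nonsense lines keep the baseline value while its
#' other-mut lines are multiplied by `ratio_mut` and its WT lines by
#' `ratio_wt`, in both tissues, so at `noise_sd = 0` the group-mean ratios
#' equal the planted ratios exactly.  Log-normal multiplicative noise with
#' standard deviation `noise_sd` (natural-log scale) is then applied per
#' cell.
#'
#' @param n_compounds Number of compounds.
#' @param panel_spec Panel data.frame (`cell_line`, `tissue`,
#'   `tp53_status`); defaults to [default_nci_panel()].
#' @param planted Optional data.frame with columns `compound` (index or
#'   name), `ratio_mut`, `ratio_wt`; ratios must be positive.
#' @param noise_sd Log-normal noise SD (0 for exact construction).
#' @param seed Integer seed.
#' @return A list with `matrix` (a [gi50_matrix()]) and `truth`: the
#'   planted table plus `would_select`, whether the planted ratios pass the
#'   default screen thresholds (> 4 and > 1.5) in both tissues.
#' @export
simulate_gi50_matrix <- function(n_compounds, panel_spec = default_nci_panel(),
                                 planted = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(is_count(n_compounds), n_compounds >= 1L)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("compound", "ratio_mut", "ratio_wt") %in% names(planted)))
    if (any(planted$ratio_mut <= 0) || any(planted$ratio_wt <= 0)) {
      stop_ribortc("planted ratios must be > 0", "ribortc_bad_input")
    }
  }
  compounds <- sprintf("cmpd_%05d", seq_len(n_compounds))
  with_seed(seed, {
    # per-compound baseline potency around 1 uM, snapped to a power-of-two
    # grid so that noiseless group means and ratios are exact in floating
    # point (boundary compounds then sit exactly on their planted ratios)
    baseline <- 2^round(log2(stats::rlnorm(n_compounds,
                                           meanlog = log(1e-6), sdlog = 1)))
    vals <- matrix(rep(baseline, times = nrow(panel_spec)),
                   nrow = n_compounds, ncol = nrow(panel_spec),
                   dimnames = list(compounds, panel_spec$cell_line))
    if (!is.null(planted)) {
      idx <- if (is.numeric(planted$compound)) as.integer(planted$compound)
             else match(as.character(planted$compound), compounds)
      if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_compounds)) {
        stop_ribortc("planted compound outside the matrix", "ribortc_bad_input")
      }
      mut_cols <- panel_spec$tp53_status == "other-mut"
      wt_cols <- panel_spec$tp53_status == "WT"
      for (k in seq_along(idx)) {
        vals[idx[k], mut_cols] <- vals[idx[k], mut_cols] * planted$ratio_mut[k]
        vals[idx[k], wt_cols] <- vals[idx[k], wt_cols] * planted$ratio_wt[k]
      }
    }
    if (noise_sd > 0) {
      vals <- vals * exp(matrix(stats::rnorm(length(vals), 0, noise_sd),
                                nrow = nrow(vals)))
    }
    truth <- if (is.null(planted)) {
      data.frame(compound = character(), ratio_mut = numeric(),
                 ratio_wt = numeric(), would_select = logical())
    } else {
      data.frame(
        compound = compounds[if (is.numeric(planted$compound))
          as.integer(planted$compound) else
          match(as.character(planted$compound), compounds)],
        ratio_mut = planted$ratio_mut, ratio_wt = planted$ratio_wt,
        would_select = planted$ratio_mut > 4 & planted$ratio_wt > 1.5,
        stringsAsFactors = FALSE)
    }
    list(matrix = gi50_matrix(vals, panel_spec), truth = truth)
  })
}

#' Simulate a logistic confluence time series
#'
#' `C(t) = A + (K - A) / (1 + exp(-r (t - t0)))` plus Gaussian noise,
#' clipped to `[0, 100]` percent confluency.
#'
#' @param K Plateau confluency (%); must exceed `A`.
#' @param A Baseline confluency (%), `>= 0`.
#' @param r Growth-rate constant (per hour), `> 0`.
#' @param t0 Inflection time (h).
#' @param noise_sd Gaussian noise SD (percentage points).
#' @param times Strictly increasing time points (h); default every 3 h for
#'   72 h, the cadence of live-cell imaging runs.
#' @param seed Integer seed.
#' @param condition,replicate Labels attached to the output.
#' @return A `ConfluenceSeries` data.frame: `time_h`, `condition`,
#'   `replicate`, `confluence_pct`.
#' @export
simulate_confluence <- function(K = 95, A = 5, r = 0.1, t0 = 36,
                                noise_sd = 0, times = seq(0, 72, by = 3),
                                seed = 1L, condition = "NT", replicate = 1L) {
  if (!(K > A && A >= 0)) {
    stop_ribortc("need K > A >= 0", "ribortc_bad_input")
  }
  if (r <= 0) stop_ribortc("need r > 0", "ribortc_bad_input")
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop_ribortc("times must be strictly increasing", "ribortc_bad_input")
  }
  mu <- logistic_value(times, A, K, r, t0)
  vals <- with_seed(seed, mu + stats::rnorm(length(times), 0, noise_sd))
  data.frame(time_h = times, condition = condition, replicate = replicate,
             confluence_pct = pmin(pmax(vals, 0), 100),
             stringsAsFactors = FALSE)
}
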