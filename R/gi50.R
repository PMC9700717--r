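#' GI50 matrix with cell-line labels
#'
#' Container for a compounds x cell-lines matrix of GI50 concentrations
#' (molar, linear scale) plus per-line tissue and TP53-status labels.
#' Missing values are allowed; present values must be positive.
#'
#' @param values Numeric matrix, rows = compounds, columns = cell lines
#'   (dimnames required).
#' @param labels Data.frame with columns `cell_line`, `tissue`,
#'   `tp53_status` (statuses `nonsense`, `WT`, `other-mut`), one row per
#'   matrix column.
#' @return A `GI50Matrix` object.
#' @export
gi50_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)),
            all(c("cell_line", "tissue", "tp53_status") %in% names(labels)))
  if (!setequal(colnames(values), labels$cell_line) ||
      anyDuplicated(labels$cell_line)) {
    stop_ribortc("labels must cover every matrix column exactly once",
                 "ribortc_bad_input")
  }
  labels <- labels[match(colnames(values), labels$cell_line), ]
  if (any(is.na(labels$tissue)) || any(is.na(labels$tp53_status))) {
    stop_ribortc("every cell line needs tissue and TP53-status labels",
                 "ribortc_bad_input")
  }
  if (any(values[!is.na(values)] <= 0)) {
    stop_ribortc("GI50 values must be positive where present",
                 "ribortc_bad_input")
  }
  structure(list(values = values, labels = labels), class = "GI50Matrix")
}

#' @export
print.GI50Matrix <- function(x, ...) {
  cat(sprintf("GI50Matrix: %d compounds x %d cell lines (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$labels$tissue), collapse = ", ")))
  invisible(x)
}

#' Read a GI50 matrix and its labels from TSV files
#'
#' @param matrix_path TSV with a `compound` column then one column per
#'   cell line.
#' @param labels_path TSV with columns `cell_line`, `tissue`,
#'   `tp53_status`.
#' @return A `GI50Matrix`.
#' @export
read_gi50_tsv <- function(matrix_path, labels_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), "compound"), drop = FALSE])
  rownames(vals) <- df$compound
  gi50_matrix(vals, labels)
}

#' Per-compound, per-tissue GI50 group-mean ratios
#'
#' For each tissue, group means of GI50 are taken over the available
#' values per TP53 status, and two ratios computed per compound:
#' `ratio_mut` = mean(other-mut)/mean(nonsense) and `ratio_wt` =
#' mean(WT)/mean(nonsense).  A compound with no value in any nonsense (or
#' no value in a numerator) group of a tissue is flagged unevaluable for
#' that tissue.  Means are arithmetic on the linear concentration scale by
#' default; `log_mean = TRUE` uses geometric means instead (NCI-60 data
#' are often stored as -log10 M).
#'
#' @param matrix A `GI50Matrix`.
#' @param log_mean Use geometric means.
#' @return Data.frame: `compound`, `tissue`, `ratio_mut`, `ratio_wt`,
#'   `evaluable`.
#' @export
compute_ratios <- function(matrix, log_mean = FALSE) {
  stopifnot(inherits(matrix, "GI50Matrix"))
  labs <- matrix$labels
  vals <- matrix$values
  mean_fn <- if (log_mean) function(x) exp(mean(log(x))) else mean
  tissues <- unique(labs$tissue)
  out <- lapply(tissues, function(ti) {
    lines_ti <- labs$cell_line[labs$tissue == ti]
    status <- labs$tp53_status[labs$tissue == ti]
    for (st in c("nonsense", "WT", "other-mut")) {
      if (!st %in% status) {
        stop_ribortc(sprintf("tissue %s has no '%s' cell line", ti, st),
                     "ribortc_bad_input")
      }
    }
    grp_mean <- function(compound_row, st) {
      x <- compound_row[lines_ti[status == st]]
      x <- x[!is.na(x)]
      if (length(x) == 0L) NA_real_ else mean_fn(x)
    }
    res <- t(apply(vals, 1L, function(row) {
      c(grp_mean(row, "nonsense"), grp_mean(row, "other-mut"),
        grp_mean(row, "WT"))
    }))
    data.frame(compound = rownames(vals), tissue = ti,
               ratio_mut = res[, 2] / res[, 1],
               ratio_wt = res[, 3] / res[, 1],
               evaluable = !is.na(res[, 1]) & !is.na(res[, 2]) & !is.na(res[, 3]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  df <- do.call(rbind, out)
  df$ratio_mut[!df$evaluable] <- NA_real_
  df$ratio_wt[!df$evaluable] <- NA_real_
  df
}

#' Select compounds by the two-ratio, two-tissue screen rule
#'
#' A compound is selected iff, in every required tissue, `ratio_mut >
#' t_mut` and `ratio_wt > t_wt` (strict inequalities, matching the printed
#' ">4" and ">1.5" thresholds).  A compound unevaluable in a required
#' tissue is never selected.
#'
#' @param ratios Output of [compute_ratios()].
#' @param t_mut,t_wt Thresholds (defaults 4 and 1.5).
#' @param tissues_required Tissues in which both criteria must hold;
#'   default all tissues present.
#' @return A `ScreenResult` list: `ratios` (with a per-row `pass` flag),
#'   `selected` (character vector of compounds), `t_mut`, `t_wt`,
#'   `tissues_required`.
#' @export
select_compounds <- function(ratios, t_mut = 4, t_wt = 1.5,
                             tissues_required = NULL) {
  stopifnot(all(c("compound", "tissue", "ratio_mut", "ratio_wt", "evaluable")
                %in% names(ratios)))
  tissues_required <- tissues_required %||% unique(ratios$tissue)
  ratios$pass <- ratios$evaluable &
    !is.na(ratios$ratio_mut) & ratios$ratio_mut > t_mut &
    !is.na(ratios$ratio_wt) & ratios$ratio_wt > t_wt
  sub <- ratios[ratios$tissue %in% tissues_required, ]
  by_cmpd <- tapply(sub$pass, sub$compound, all)
  n_tissue <- tapply(sub$tissue, sub$compound, function(x) length(unique(x)))
  sel <- names(by_cmpd)[by_cmpd & n_tissue == length(tissues_required)]
  structure(list(
    ratios = ratios,
    selected = sort(sel),
    t_mut = t_mut, t_wt = t_wt,
    tissues_required = tissues_required
  ), class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf(
    "ScreenResult: %d compound(s) pass ratio_mut > %g and ratio_wt > %g in %s\n",
    length(x$selected), x$t_mut, x$t_wt,
    paste(x$tissues_required, collapse = " + ")))
  invisible(x)
}

#' Export the per-tissue ratio plane for plotting
#'
#' One row per evaluable compound per tissue, with `x = ratio_wt`
#' (WT/nonsense) and `y = ratio_mut` (other-mut/nonsense) - the scatter
#' coordinates of the screen.
#'
#' @param result A `ScreenResult`.
#' @return Data.frame: `compound`, `tissue`, `x`, `y`, `pass`, `selected`.
#' @export
ratio_plane_export <- function(result) {
  stopifnot(inherits(result, "ScreenResult"))
  df <- result$ratios[result$ratios$evaluable, ]
  data.frame(compound = df$compound, tissue = df$tissue,
             x = df$ratio_wt, y = df$ratio_mut, pass = df$pass,
             selected = df$compound %in% result$selected,
             stringsAsFactors = FALSE, row.names = NULL)
}
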