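#' Four-parameter logistic growth curve
#'
#' `C(t) = A + (K - A) / (1 + exp(-r (t - t0)))`.
#'
#' @param t Time (h).
#' @param A Baseline confluency (%).
#' @param K Plateau confluency (%).
#' @param r Rate constant (per h).
#' @param t0 Inflection time (h).
#' @return Confluency values.
#' @export
logistic_value <- function(t, A, K, r, t0) {
  A + (K - A) / (1 + exp(-r * (t - t0)))
}

#' Analytic growth rate dC/dt of the logistic curve
#'
#' `dC/dt = r (K - A) e^{-r(t-t0)} / (1 + e^{-r(t-t0)})^2`; maximal at
#' `t = t0` where it equals `r (K - A) / 4`.
#'
#' @inheritParams logistic_value
#' @return Growth rate in %confluency/h.
#' @export
logistic_rate <- function(t, A, K, r, t0) {
  e <- exp(-r * (t - t0))
  r * (K - A) * e / (1 + e)^2
}

#' Fit a logistic growth curve to a confluence series
#'
#' Least-squares fit of the 4-parameter logistic (via
#' [minpack.lm::nlsLM()]) with bounds `A >= 0`, `K <= 105`, `r > 0`.
#' Initial values: `A = min(C)`, `K = max(C)`, `t0` at the half-range
#' crossing, `r` from the central finite-difference slope.  A constant
#' series is flagged `"no growth"` and non-convergence is reported, never
#' silently returned.
#'
#' @param series A `ConfluenceSeries` data.frame (`time_h`,
#'   `confluence_pct`, optional `condition`/`replicate` labels), with at
#'   least 6 strictly increasing time points.
#' @return A `GrowthFit` list: `A`, `K`, `r`, `t0`, `cp` (= `t0`, the time
#'   of maximal growth rate), `rate_at_cp` (= `r (K - A)/4`),
#'   `residual_sd`, `converged`, `flag`, plus the series labels.
#' @examples
#' s <- simulate_confluence(K = 95, A = 5, r = 0.1, t0 = 36, noise_sd = 0)
#' fit_logistic(s)$r
#' @export
fit_logistic <- function(series) {
  stopifnot(all(c("time_h", "confluence_pct") %in% names(series)))
  t <- series$time_h
  y <- series$confluence_pct
  if (length(t) < 6L) {
    stop_ribortc("need at least 6 time points to fit", "ribortc_bad_input")
  }
  if (any(diff(t) <= 0)) {
    stop_ribortc("times must be strictly increasing", "ribortc_bad_input")
  }
  label <- list(condition = series$condition[1] %||% NA_character_,
                replicate = series$replicate[1] %||% NA_integer_)
  base_fit <- function(converged, flag, A = NA_real_, K = NA_real_,
                       r = NA_real_, t0 = NA_real_, resid_sd = NA_real_) {
    structure(c(list(A = A, K = K, r = r, t0 = t0,
                     cp = t0, rate_at_cp = if (converged) r * (K - A) / 4 else NA_real_,
                     residual_sd = resid_sd, converged = converged,
                     flag = flag), label), class = "GrowthFit")
  }
  if (diff(range(y)) < 1e-8 || stats::sd(y) < 0.25) {
    return(base_fit(FALSE, "no growth"))
  }
  A0 <- min(y); K0 <- max(y)
  half <- A0 + (K0 - A0) / 2
  t0_0 <- t[which.min(abs(y - half))]
  slope <- max(diff(y) / diff(t))
  r0 <- max(4 * slope / (K0 - A0), 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A + (K - A) / (1 + exp(-r * (time - t0))),
      data = data.frame(time = t, y = y),
      start = list(A = A0, K = K0, r = r0, t0 = t0_0),
      lower = c(A = 0, K = 0, r = 1e-6, t0 = min(t) - diff(range(t))),
      upper = c(A = 100, K = 105, r = 10, t0 = max(t) + diff(range(t))),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(base_fit(FALSE, paste("fit failed:", conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  if (cf[["K"]] <= cf[["A"]]) {
    return(base_fit(FALSE, "degenerate fit (K <= A)",
                    A = cf[["A"]], K = cf[["K"]], r = cf[["r"]],
                    t0 = cf[["t0"]]))
  }
  base_fit(TRUE, "ok", A = cf[["A"]], K = cf[["K"]], r = cf[["r"]],
           t0 = cf[["t0"]],
           resid_sd = sqrt(mean(stats::residuals(fit)^2)))
}

#' @export
print.GrowthFit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "GrowthFit%s: A=%.2f K=%.2f r=%.4f/h t0=%.2f h; rate at cp %.3f %%/h\n",
      if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
      x$A, x$K, x$r, x$t0, x$rate_at_cp))
  } else {
    cat(sprintf("GrowthFit (not converged): %s\n", x$flag))
  }
  invisible(x)
}

#' Growth rates of all conditions at the control's critical point
#'
#' The critical point `cp` is the time at which the untreated control's
#' growth rate is maximal - its logistic inflection `t0`.  Every
#' condition's rate is then its own fitted `dC/dt` evaluated at `cp`
#' ([logistic_rate()]).  An unconverged control is fatal; an unconverged
#' condition gets a missing rate.
#'
#' @param fits Named list of `GrowthFit`s (names = condition ids), or a
#'   list of fits carrying `condition` labels.
#' @param control_id Name of the control condition.
#' @return Data.frame: `condition`, `converged`, `rate_at_cp`
#'   (%confluency/h), with the control `cp` (h) as an attribute.
#' @export
rate_at_control_cp <- function(fits, control_id) {
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) as.character(f$condition),
                          character(1))
  }
  ctrl <- fits[[control_id]]
  if (is.null(ctrl)) {
    stop_ribortc(sprintf("control condition '%s' not found", control_id),
                 "ribortc_bad_input")
  }
  if (!isTRUE(ctrl$converged)) {
    stop_ribortc("control fit did not converge: cp undefined",
                 "ribortc_unconverged")
  }
  cp <- ctrl$t0
  rates <- vapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(NA_real_)
    logistic_rate(cp, f$A, f$K, f$r, f$t0)
  }, numeric(1))
  out <- data.frame(condition = names(fits),
                    converged = vapply(fits, function(f) isTRUE(f$converged),
                                       logical(1)),
                    rate_at_cp = rates,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cp") <- cp
  out
}

#' Fit every (condition, replicate) series in a confluence table
#'
#' Replicates are fitted independently; per-condition summaries are the
#' mean and SEM of the replicate rates at the control's critical point,
#' where the control cp is taken from the control's replicate-mean `t0`.
#'
#' @param data Confluence table: `time_h`, `condition`, `replicate`,
#'   `confluence_pct`.
#' @param control_id Control condition id.
#' @return A list with `fits` (per condition x replicate), `rates`
#'   (per-replicate rates at cp), `summary` (per-condition mean, SEM, n)
#'   and `cp`.
#' @export
fit_confluence <- function(data, control_id) {
  stopifnot(all(c("time_h", "condition", "replicate", "confluence_pct")
                %in% names(data)))
  key <- interaction(data$condition, data$replicate, drop = TRUE)
  fits <- lapply(split(data, key), fit_logistic)
  conds <- vapply(fits, function(f) as.character(f$condition), character(1))
  ctrl_fits <- fits[conds == control_id & vapply(fits, function(f)
    isTRUE(f$converged), logical(1))]
  if (length(ctrl_fits) == 0L) {
    stop_ribortc("no converged control replicate: cp undefined",
                 "ribortc_unconverged")
  }
  cp <- mean(vapply(ctrl_fits, function(f) f$t0, numeric(1)))
  rates <- data.frame(
    condition = conds,
    replicate = vapply(fits, function(f) f$replicate, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    rate_at_cp = vapply(fits, function(f) {
      if (!isTRUE(f$converged)) return(NA_real_)
      logistic_rate(cp, f$A, f$K, f$r, f$t0)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  summ <- do.call(rbind, lapply(split(rates, rates$condition), function(d) {
    x <- d$rate_at_cp[!is.na(d$rate_at_cp)]
    data.frame(condition = d$condition[1], n = length(x),
               mean_rate = mean(x),
               sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(fits = fits, rates = rates, summary = summ, cp = cp)
}
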