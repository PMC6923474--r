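# Concentration-inhibition curves from staircase protocols and Hill fits.

#' Extract concentration-inhibition points from a staircase trace
#'
#' Finds the agonist application containing rising blocker levels,
#' measures the baseline-subtracted steady-state current of each level,
#' and normalizes within the application to the pre-blocker (control)
#' steady state, giving the relative amplitude `I_b/I_c` per level.
#'
#' @param trace a `current_trace` from a staircase protocol (a control
#'   agonist epoch followed by >= 1 blocker levels within the same
#'   application).
#' @param cell optional cell identifier carried into the output.
#' @param tau_exchange exchange time constant (s) for settling guards.
#' @return Data frame of class `dose_response_points` with columns
#'   `atl`, `rel_amplitude`, `cell`, `vm`, `ca_out`, `bapta`.
#' @export
extract_staircase <- function(trace, cell = NA_character_, tau_exchange = 0.01) {
  eps <- trace$protocol$epochs
  ag <- which(eps$NMDA > 0)
  if (!length(ag)) stop(validation_error("no agonist application in protocol"))
  ctrl <- ag[eps$ATL[ag] == 0][1]
  if (is.na(ctrl))
    stop(validation_error("missing pre-blocker (control) steady state"))
  lev <- ag[ag > ctrl & eps$ATL[ag] > 0]
  base <- baseline_current(trace, tau_exchange)
  i_c <- measure_steady_state(trace, ctrl, tau_exchange = tau_exchange,
                              baseline = base)$mean
  rel <- vapply(lev, function(i)
    measure_steady_state(trace, i, tau_exchange = tau_exchange,
                         baseline = base)$mean / i_c, numeric(1))
  out <- data.frame(atl = eps$ATL[lev], rel_amplitude = rel, cell = cell,
                    vm = trace$protocol$holding_voltage,
                    ca_out = eps$Ca_out[ctrl],
                    bapta = trace$protocol$bapta_loaded)
  if (any(out$rel_amplitude < 0 | out$rel_amplitude > 1.2))
    warning("relative amplitudes outside [0, 1.2]; check baseline/normalization")
  class(out) <- c("dose_response_points", class(out))
  out
}

#' Fit the Hill concentration-inhibition equation
#'
#' Nonlinear least squares of `I_b/I_c = 1 / (1 + ([B]/IC50)^h)` on the
#' relative amplitudes, parameterized in `log10(IC50)` for conditioning,
#' with the Hill coefficient bounded to `h_bounds`.
#'
#' @param atl blocker concentrations (uM), or a `dose_response_points`
#'   data frame (then `rel_amplitude` is ignored).
#' @param rel_amplitude relative amplitudes `I_b/I_c`.
#' @param h_bounds bounds on the Hill coefficient.
#' @return List of class `hill_fit`: `ic50` (uM), `h`, `se` (named,
#'   delta-method for ic50), `n_points`, `rms`, `condition`.
#' @export
fit_hill <- function(atl, rel_amplitude = NULL, h_bounds = c(0.3, 4)) {
  condition <- NULL
  if (is.data.frame(atl)) {
    condition <- list(vm = atl$vm[1], ca_out = atl$ca_out[1], bapta = atl$bapta[1])
    rel_amplitude <- atl$rel_amplitude
    atl <- atl$atl
  }
  stopifnot(length(atl) == length(rel_amplitude))
  keep <- atl > 0
  atl <- atl[keep]; rel <- rel_amplitude[keep]
  if (length(unique(atl)) < 3)
    stop(validation_error("Hill fit requires >= 3 distinct blocker concentrations"))
  if (all(rel > 0.9))
    stop(errorCondition("insufficient inhibition: all relative amplitudes > 0.9, IC50 unidentifiable",
                        class = c("nmdarblock_fit_error", "error", "condition")))
  # start: log-linear interpolation of the 0.5 crossing
  ord <- order(atl)
  lx <- log10(atl[ord]); ly <- rel[ord]
  ic0 <- 10^stats::approx(ly, lx, xout = 0.5, ties = mean, rule = 2)$y
  fit <- minpack.lm::nlsLM(
    rel ~ 1 / (1 + (atl / 10^lic)^h),
    start = list(lic = log10(ic0), h = 1),
    lower = c(log10(min(atl)) - 4, h_bounds[1]),
    upper = c(log10(max(atl)) + 4, h_bounds[2]),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  ic50 <- 10^cf[["lic"]]
  out <- list(ic50 = ic50, h = cf[["h"]],
              se = c(ic50 = ic50 * log(10) * se[1], h = se[2]),
              n_points = length(atl),
              rms = sqrt(mean(stats::resid(fit)^2)),
              condition = condition)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> IC50 = %.4g uM, h = %.3g (n = %d points, rms = %.3g)\n",
              x$ic50, x$h, x$n_points, x$rms))
  invisible(x)
}

#' Per-cell Hill fits and the condition-level summary
#'
#' Fits the Hill equation to each cell's points separately and reports
#' the condition mean +/- SEM of the per-cell IC50s and Hill
#' coefficients (matching per-cell symbols with mean +/- SEM, rather
#' than one pooled fit).
#'
#' @param points a `dose_response_points` data frame with a `cell`
#'   column (rbind over cells).
#' @return List of class `hill_condition_fit`: `per_cell` (data frame),
#'   `ic50_mean`, `ic50_sem`, `h_mean`, `h_sem`, `n_cells`, `fits`.
#' @export
fit_hill_by_cell <- function(points) {
  stopifnot(is.data.frame(points), "cell" %in% names(points))
  cells <- unique(points$cell)
  fits <- lapply(cells, function(cl) fit_hill(points[points$cell == cl, , drop = FALSE]))
  per_cell <- data.frame(cell = cells,
                         ic50 = vapply(fits, `[[`, numeric(1), "ic50"),
                         h = vapply(fits, `[[`, numeric(1), "h"))
  out <- list(per_cell = per_cell,
              ic50_mean = mean(per_cell$ic50), ic50_sem = sem(per_cell$ic50),
              h_mean = mean(per_cell$h), h_sem = sem(per_cell$h),
              n_cells = length(cells), fits = fits)
  class(out) <- "hill_condition_fit"
  out
}

#' Standard error of the mean
#'
#' `sd(x)/sqrt(n)` over cells.
#'
#' @param x numeric vector.
#' @return SEM (NA for n < 2).
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))
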