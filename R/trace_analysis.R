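# Per-trace measurements: steady-state amplitudes, blocked fraction, and
# exponential relaxation fits.

#' Steady-state current of one protocol epoch
#'
#' Averages the trace over the final `window_frac` of the epoch (the
#' conventional "measured at steady state" window), never closer than
#' `3 * tau_exchange` to the epoch start.  A linear drift fit over the
#' window supplies a steadiness criterion: the fitted change across the
#' window must stay below `tolerance` times the mean magnitude.
#'
#' @param trace a `current_trace`.
#' @param epoch epoch row index.
#' @param window_frac fraction of the epoch used, from the end (default
#'   0.2).
#' @param tau_exchange solution-exchange time constant (s) used for the
#'   settling guard.
#' @param tolerance steadiness criterion on `|slope| * window / |mean|`.
#' @param baseline current offset (pA) subtracted before reporting.
#' @return List with `mean` (pA, baseline-subtracted), `slope` (pA/s),
#'   `window` (s), `steady` (logical), `epoch`.
#' @export
measure_steady_state <- function(trace, epoch, window_frac = 0.2,
                                 tau_exchange = 0.01, tolerance = 0.1,
                                 baseline = 0) {
  e <- trace$protocol$epochs[epoch, ]
  w0 <- max(e$t_end - window_frac * (e$t_end - e$t_start),
            e$t_start + 3 * tau_exchange)
  sel <- which(trace$time >= w0 & trace$time <= e$t_end + 1e-12)
  if (length(sel) < 3)
    stop(validation_error(sprintf("epoch %d: too few samples in steady-state window", epoch)))
  tt <- trace$time[sel]; yy <- trace$current[sel] - baseline
  m <- mean(yy)
  sl <- unname(stats::coef(stats::lm(yy ~ tt))[2])
  win <- max(tt) - min(tt)
  list(mean = m, slope = sl, window = win,
       steady = abs(sl) * win < tolerance * max(abs(m), .Machine$double.eps),
       epoch = epoch)
}

#' Baseline (zero-current) level of a trace
#'
#' Mean current over the pre-agonist epoch (the first epoch with no
#' NMDA), skipping the initial exchange-settling samples.
#'
#' @param trace a `current_trace`.
#' @param tau_exchange settling guard (s).
#' @return Baseline current (pA).
#' @export
baseline_current <- function(trace, tau_exchange = 0.01) {
  eps <- trace$protocol$epochs
  i <- which(eps$NMDA == 0)[1]
  if (is.na(i)) return(0)
  sel <- epoch_samples(trace, i, skip = 3 * tau_exchange)
  if (!length(sel)) return(0)
  mean(trace$current[sel])
}

#' Fraction of current blocked
#'
#' `1 - I_b / I_c`, where `I_c` is the steady-state current under
#' agonists alone and `I_b` the steady-state current with blocker, both
#' at the same holding voltage.
#'
#' @param i_c control steady-state current (pA), non-zero.
#' @param i_b steady-state current in blocker (pA).
#' @return Dimensionless blocked fraction.
#' @export
blocked_fraction <- function(i_c, i_b) {
  if (any(i_c == 0)) stop(validation_error("control current i_c must be non-zero"))
  if (any(sign(i_b) * sign(i_c) < 0))
    warning("i_b and i_c have opposite signs; check the baseline subtraction")
  1 - i_b / i_c
}

#' Fit a mono-exponential relaxation
#'
#' Nonlinear least-squares fit of
#' `I(t) = (I_max - I_min) * exp(-t / tau) + I_min`
#' to a relaxation segment, with `t` measured from the segment start.
#' Initial guesses: the segment endpoints for the amplitudes and the
#' 1/e-crossing time for `tau`.
#'
#' @param time,current the relaxation segment; `time` need not start at
#'   zero (it is re-origined internally).
#' @param tau_bounds allowed range for `tau` (s).
#' @return List of class `relaxation_fit`: `i_max`, `i_min`, `tau`,
#'   `rms` (residual RMS, pA), `converged`, `at_bound`.
#' @export
fit_monoexp <- function(time, current, tau_bounds = c(1e-4, 1e4)) {
  stopifnot(length(time) == length(current), length(time) >= 4)
  t <- time - time[1]
  n <- length(t)
  i0 <- mean(current[seq_len(max(2, n %/% 50))])
  i1 <- mean(current[seq(n - max(2, n %/% 10) + 1, n)])
  # 1/e crossing of the normalized decay
  z <- (current - i1) / (i0 - i1)
  cross <- which(z <= exp(-1))[1]
  tau0 <- if (is.na(cross) || cross < 2) max(t) / 3 else t[cross]
  tau0 <- min(max(tau0, tau_bounds[1] * 2), tau_bounds[2] / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(current ~ (imax - imin) * exp(-t / tau) + imin,
                      start = list(imax = i0, imin = i1, tau = tau0),
                      lower = c(-Inf, -Inf, tau_bounds[1]),
                      upper = c(Inf, Inf, tau_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop(errorCondition(
      sprintf("mono-exponential fit failed (%s); starts: imax=%.4g imin=%.4g tau=%.4g",
              conditionMessage(fit), i0, i1, tau0),
      class = c("nmdarblock_fit_error", "error", "condition")))
  cf <- stats::coef(fit)
  out <- list(i_max = unname(cf["imax"]), i_min = unname(cf["imin"]),
              tau = unname(cf["tau"]),
              rms = sqrt(mean(stats::resid(fit)^2)),
              converged = TRUE,
              at_bound = cf["tau"] <= tau_bounds[1] * (1 + 1e-6) ||
                cf["tau"] >= tau_bounds[2] * (1 - 1e-6))
  class(out) <- "relaxation_fit"
  out
}

#' Extract and fit a relaxation within one epoch
#'
#' Convenience wrapper: takes the samples of `epoch` starting
#' `skip` seconds after the epoch boundary (default three exchange time
#' constants) and fits [fit_monoexp()].
#'
#' @param trace a `current_trace`.
#' @param epoch epoch row index where the relaxation occurs.
#' @param skip onset delay after the epoch edge (s); default
#'   `3 * tau_exchange` with `tau_exchange` read from the argument.
#' @param tau_exchange exchange time constant (s).
#' @return A `relaxation_fit`.
#' @export
fit_epoch_relaxation <- function(trace, epoch, tau_exchange = 0.01,
                                 skip = 3 * tau_exchange) {
  sel <- epoch_samples(trace, epoch, skip = skip)
  fit_monoexp(trace$time[sel], trace$current[sel])
}

#' Fit the bi-exponential rise of a trapping test pulse
#'
#' Constrained double-exponential fit of the test-pulse current,
#' `I(t) = I_1 exp(-t/tau_1) + I_2 exp(-t/tau_2) - C` with
#' `C = I_1 + I_2 + I_b`, so the fit starts at `-I_b` (the residual
#' non-blocked current, inward-negative convention) and approaches
#' `-(I_1 + I_2 + I_b)`.  The fast/slow labels are assigned by
#' time-constant ordering.  When the two time constants differ by less
#' than a factor of 3 the components are degenerate: the fit is flagged
#' and a single-exponential fallback is reported alongside.
#'
#' @param time,current the rise segment (current in pA, inward negative).
#' @param i_b magnitude (pA, >= 0) of the residual non-blocked current
#'   entering the constraint.
#' @param degenerate_ratio minimal tau ratio for distinct components.
#' @return List of class `biexp_fit`: `i_f`, `i_s` (pA, >= 0), `tau_f`,
#'   `tau_s` (s), `c`, `fraction_fast` = `i_f/(i_f+i_s)`, `rms`,
#'   `degenerate`, and `fallback` (a `relaxation_fit` or `NULL`).
#' @export
fit_biexp_rise <- function(time, current, i_b, degenerate_ratio = 3) {
  stopifnot(length(time) == length(current), length(time) >= 6, i_b >= 0)
  t <- time - time[1]
  total <- abs(mean(current[seq(length(current) - max(2, length(current) %/% 20) + 1,
                                length(current))])) - i_b
  total <- max(total, .Machine$double.eps)
  span <- max(t)
  start <- list(i1 = 0.6 * total, i2 = 0.4 * total,
                lt1 = log(span / 100), lt2 = log(span / 3))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      current ~ -(i1 * (1 - exp(-t / exp(lt1))) +
                    i2 * (1 - exp(-t / exp(lt2))) + i_b),
      start = start,
      lower = c(0, 0, log(span / 1e5), log(span / 1e5)),
      upper = c(Inf, Inf, log(span * 100), log(span * 100)),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop(errorCondition(
      sprintf("bi-exponential rise fit failed: %s", conditionMessage(fit)),
      class = c("nmdarblock_fit_error", "error", "condition")))
  cf <- stats::coef(fit)
  amps <- c(cf[["i1"]], cf[["i2"]])
  taus <- exp(c(cf[["lt1"]], cf[["lt2"]]))
  fast <- which.min(taus)
  ratio <- max(taus) / min(taus)
  degenerate <- ratio < degenerate_ratio
  fallback <- if (degenerate) fit_monoexp(time, current) else NULL
  out <- list(i_f = amps[fast], i_s = amps[3 - fast],
              tau_f = taus[fast], tau_s = taus[3 - fast],
              c = sum(amps) + i_b,
              fraction_fast = amps[fast] / sum(amps),
              rms = sqrt(mean(stats::resid(fit)^2)),
              degenerate = degenerate, fallback = fallback)
  class(out) <- "biexp_fit"
  out
}

#' Detect a tail current upon agonist/blocker washout
#'
#' A tail is flagged when, during a washout epoch with agonist and
#' blocker both removed, the current magnitude transiently exceeds the
#' pre-removal steady-state magnitude by more than `threshold`
#' (relative) for at least `min_duration` seconds.  Sequential
#' ("foot-in-the-door") blockers produce such tails because blocked
#' channels must re-open to release the blocker; trapping blockers do
#' not.
#'
#' @param trace a `current_trace`.
#' @param washout_epoch epoch row index of the washout (must have
#'   NMDA = 0 and ATL = 0).
#' @param threshold relative exceedance (default 0.05).
#' @param min_duration minimal exceedance duration (s, default 0.05).
#' @param tau_exchange settling guard (s).
#' @return List: `tail` (logical), `area` (pA*s of excess magnitude),
#'   `pre_steady` (pA).
#' @export
detect_tail_current <- function(trace, washout_epoch, threshold = 0.05,
                                min_duration = 0.05, tau_exchange = 0.01) {
  eps <- trace$protocol$epochs
  e <- eps[washout_epoch, ]
  if (e$NMDA != 0 || e$ATL != 0)
    stop(validation_error("washout epoch must have agonist and blocker at zero"))
  base <- baseline_current(trace, tau_exchange)
  pre <- measure_steady_state(trace, washout_epoch - 1,
                              tau_exchange = tau_exchange, baseline = base)
  sel <- epoch_samples(trace, washout_epoch, skip = 3 * tau_exchange)
  if (!length(sel)) return(list(tail = FALSE, area = 0, pre_steady = pre$mean))
  y <- abs(trace$current[sel] - base)
  lim <- (1 + threshold) * abs(pre$mean)
  over <- y > lim
  dt <- 1 / trace$protocol$sample_rate
  # longest run of consecutive exceedances
  r <- rle(over)
  longest <- if (any(r$values)) max(r$lengths[r$values]) * dt else 0
  area <- sum(pmax(y - abs(pre$mean), 0)) * dt
  list(tail = longest >= min_duration, area = area, pre_steady = pre$mean)
}
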