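# Rate constants of open-channel block from relaxation time constants.
# For a bimolecular open-channel block the relaxation rate onto a new
# blocker concentration B is 1/tau = k_on * B + k_off, so two onset time
# constants at two concentrations give k_on by finite difference, the
# unblock time constant gives k_off directly, and Kd = k_off / k_on.

#' Binding rate constant from two block-onset time constants
#'
#' `k_on = (1/tau_on(C2) - 1/tau_on(C1)) / (C2 - C1)`.
#' The default concentration pair is (10, 100) uM; any pair with
#' `C2 >= 3 * C1` is accepted (closer pairs are ill-conditioned).
#'
#' @param tau_on_c1,tau_on_c2 onset time constants (s) at `c1` and `c2`.
#' @param c1,c2 blocker concentrations (uM), `c2 > c1 > 0`.
#' @return k_on in 1/(s*uM).
#' @export
estimate_kon <- function(tau_on_c1, tau_on_c2, c1 = 10, c2 = 100) {
  if (!(c1 > 0 && c2 > c1)) stop(validation_error("need c2 > c1 > 0"))
  if (c2 < 3 * c1)
    stop(validation_error("concentration pair too close (need c2 >= 3 * c1)"))
  if (tau_on_c1 <= 0 || tau_on_c2 <= 0)
    stop(validation_error("time constants must be positive"))
  k <- (1 / tau_on_c2 - 1 / tau_on_c1) / (c2 - c1)
  if (k <= 0)
    stop(errorCondition(
      "no concentration dependence: tau_on must shorten as the blocker concentration rises",
      class = c("nmdarblock_kinetics_error", "error", "condition")))
  k
}

#' Dissociation rate constant from the unblock time constant
#'
#' `k_off = 1 / tau_off`.
#'
#' @param tau_off unblock time constant (s), positive.
#' @return k_off in 1/s.
#' @export
estimate_koff <- function(tau_off) {
  if (any(tau_off <= 0)) stop(validation_error("tau_off must be positive"))
  1 / tau_off
}

#' Equilibrium dissociation constant
#'
#' `Kd = k_off / k_on`.
#'
#' @param k_on binding rate, 1/(s*uM), positive.
#' @param k_off dissociation rate, 1/s.
#' @return Kd in uM.
#' @export
equilibrium_kd <- function(k_on, k_off) {
  if (any(k_on <= 0)) stop(validation_error("k_on must be positive"))
  k_off / k_on
}

#' Blocker kinetics from a pair of block-step traces
#'
#' End-to-end convenience: takes two single-step block traces recorded
#' at the same voltage with blocker concentrations `c1 < c2`, fits the
#' block-onset relaxation in each and the unblock relaxation (averaged
#' over both washouts), and returns the derived rate constants.
#' The protocol is expected in [protocol_block_step()] form: baseline,
#' control agonist, agonist + blocker (onset), agonist washout of the
#' blocker (offset).
#'
#' @param trace_c1,trace_c2 `current_trace` objects at the two
#'   concentrations.
#' @param tau_exchange exchange time constant (s).
#' @return List of class `block_kinetics`: `k_on` (1/(s*uM)), `k_off`
#'   (1/s), `kd` (uM), `vm`, `c1`, `c2`, `tau_on_c1`, `tau_on_c2`,
#'   `tau_off`.
#' @export
fit_block_kinetics <- function(trace_c1, trace_c2, tau_exchange = 0.01) {
  conc_of <- function(tr) {
    a <- tr$protocol$epochs$ATL
    max(a)
  }
  c1 <- conc_of(trace_c1); c2 <- conc_of(trace_c2)
  if (c1 > c2) stop(validation_error("trace_c1 must carry the lower concentration"))
  onset_epoch <- function(tr) which(tr$protocol$epochs$ATL > 0)[1]
  offset_epoch <- function(tr) {
    i <- onset_epoch(tr)
    j <- i + 1
    eps <- tr$protocol$epochs
    if (j > nrow(eps) || eps$ATL[j] != 0 || eps$NMDA[j] == 0)
      stop(validation_error("no unblock (agonist-only) epoch after the blocker step"))
    j
  }
  f_on1 <- fit_epoch_relaxation(trace_c1, onset_epoch(trace_c1), tau_exchange)
  f_on2 <- fit_epoch_relaxation(trace_c2, onset_epoch(trace_c2), tau_exchange)
  f_off1 <- fit_epoch_relaxation(trace_c1, offset_epoch(trace_c1), tau_exchange)
  f_off2 <- fit_epoch_relaxation(trace_c2, offset_epoch(trace_c2), tau_exchange)
  tau_off <- mean(c(f_off1$tau, f_off2$tau))
  k_on <- estimate_kon(f_on1$tau, f_on2$tau, c1, c2)
  k_off <- estimate_koff(tau_off)
  out <- list(k_on = k_on, k_off = k_off, kd = equilibrium_kd(k_on, k_off),
              vm = trace_c1$protocol$holding_voltage, c1 = c1, c2 = c2,
              tau_on_c1 = f_on1$tau, tau_on_c2 = f_on2$tau, tau_off = tau_off)
  class(out) <- "block_kinetics"
  out
}

#' @export
print.block_kinetics <- function(x, ...) {
  cat(sprintf("<block_kinetics> Vm = %g mV, C = (%g, %g) uM\n", x$vm, x$c1, x$c2))
  cat(sprintf("  k_on = %.4g 1/(s uM), k_off = %.4g 1/s, Kd = %.4g uM\n",
              x$k_on, x$k_off, x$kd))
  invisible(x)
}
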