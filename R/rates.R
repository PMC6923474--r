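# Kinetic scheme: five aggregated channel states.
#   C  closed (agonist-responsive)
#   O  open (conducting)
#   D  desensitized (Ca2+/calmodulin pathway, lumped)
#   OB open-blocked (blocker in the pore, channel gate open)
#   CB closed-blocked (gate shut on the blocker; "trapped")
NMDAR_STATES <- c("C", "O", "D", "OB", "CB")

#' Rate-constant set for the five-state NMDAR gating/block scheme
#'
#' Bundles every rate constant and physical constant used by the
#' master-equation simulator.  The block branch follows the Woodhull
#' picture of a charged blocker binding at fractional electrical depth
#' `delta_block` inside the pore: all voltage dependence is carried by
#' the binding (on) rate, so the equilibrium dissociation constant obeys
#' `Kd(Vm) = k_off0 / k_on0 * exp(delta_block * z_block * Vm / rt_over_f)`.
#' Calcium-dependent desensitization is driven by a Ca2+-influx surrogate
#' proportional to bath calcium times the electrical driving force,
#' normalized so that the surrogate equals `Ca_out` at -70 mV.
#'
#' Defaults describe a cortical-neuron whole-cell recording at room
#' temperature with amitriptyline as the blocker: dissociation rate
#' 0.204 1/s and an apparent Kd of 127.5 uM at -70 mV, an electrical
#' depth of 0.51 for a +1 charge, and desensitization parameters
#' calibrated so the steady-state IC50 at -70 mV runs from about 63 uM
#' in 0.25 mM bath Ca2+ down to about 0.7 uM in 4 mM Ca2+.
#'
#' @param alpha_close channel closing rate O -> C (1/s).
#' @param beta_open_max maximal opening rate at saturating agonist (1/s);
#'   the effective opening rate is scaled by NMDA occupancy
#'   `[NMDA]/([NMDA] + ec50_nmda)` and set to zero while AP5 is present.
#' @param ec50_nmda NMDA concentration of half-maximal activation (uM).
#' @param k_des0 baseline desensitization rate per unit Ca2+-influx
#'   surrogate (1/s).
#' @param k_rec recovery rate from desensitization D -> O (1/s).
#' @param atl_des_gain dimensionless maximal enhancement of
#'   desensitization by the blocker (saturable).
#' @param atl_des_k blocker concentration of half-maximal desensitization
#'   enhancement (uM).
#' @param ca_coupling scale of the Ca2+-influx surrogate (1/mM).
#' @param bapta_factor multiplier applied to the desensitization rate
#'   when the cell is BAPTA-loaded, in [0, 1]; the default 0 models
#'   complete chelation of the incoming Ca2+ (BAPTA loading abolishes
#'   Ca2+-dependent desensitization).
#' @param k_on0 blocker binding rate at 0 mV (1/(s*uM)).
#' @param k_off0 blocker unbinding rate, voltage independent (1/s).
#' @param delta_block fraction of the membrane electric field at the
#'   blocker binding site, in [0, 1].
#' @param z_block blocker valence (elementary charges).
#' @param k_escape escape rate of the trapped blocker from the closed
#'   channel, CB -> C (1/s); 0 gives full trapping.
#' @param n_channels_gamma lumped conductance N*gamma (pA/mV).
#' @param e_rev current reversal potential (mV).
#' @param tau_exchange first-order solution-exchange time constant (s).
#' @param rt_over_f RT/F in mV (25.7 mV at 25 C).
#' @param alpha_close_blocked closing rate of the blocked channel
#'   OB -> CB (1/s); `NULL` means equal to `alpha_close`.  Setting this
#'   to 0 forbids closure while blocked and yields a sequential
#'   ("foot-in-the-door") blocker.
#' @return An object of class `rate_set` (a named list).
#' @seealso [build_rate_matrix()], [simulate_trace()], [rate_set_pure_block()]
#' @export
rate_set <- function(alpha_close = 60,
                     beta_open_max = 90,
                     ec50_nmda = 30,
                     k_des0 = 0.4,
                     k_rec = 0.5,
                     atl_des_gain = 8.21,
                     atl_des_k = 3.02,
                     ca_coupling = 1,
                     bapta_factor = 0,
                     k_on0 = 3.9936e-4,
                     k_off0 = 0.204,
                     delta_block = 0.51,
                     z_block = 1,
                     k_escape = 0.2,
                     n_channels_gamma = 24,
                     e_rev = 0,
                     tau_exchange = 0.01,
                     rt_over_f = 25.7,
                     alpha_close_blocked = NULL) {
  r <- list(alpha_close = alpha_close, beta_open_max = beta_open_max,
            ec50_nmda = ec50_nmda, k_des0 = k_des0, k_rec = k_rec,
            atl_des_gain = atl_des_gain, atl_des_k = atl_des_k,
            ca_coupling = ca_coupling, bapta_factor = bapta_factor,
            k_on0 = k_on0, k_off0 = k_off0, delta_block = delta_block,
            z_block = z_block, k_escape = k_escape,
            n_channels_gamma = n_channels_gamma, e_rev = e_rev,
            tau_exchange = tau_exchange, rt_over_f = rt_over_f,
            alpha_close_blocked = alpha_close_blocked)
  class(r) <- "rate_set"
  validate_rate_set(r)
  r
}

validate_rate_set <- function(r) {
  stopifnot(inherits(r, "rate_set"))
  nonneg <- c("alpha_close", "beta_open_max", "ec50_nmda", "k_des0", "k_rec",
              "atl_des_gain", "atl_des_k", "ca_coupling", "k_on0", "k_off0",
              "k_escape", "tau_exchange")
  for (nm in nonneg) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(validation_error(sprintf("rate_set$%s must be a single finite value >= 0", nm)))
  }
  if (!is.null(r$alpha_close_blocked) &&
      (!is.finite(r$alpha_close_blocked) || r$alpha_close_blocked < 0))
    stop(validation_error("rate_set$alpha_close_blocked must be >= 0 or NULL"))
  if (r$delta_block < 0 || r$delta_block > 1)
    stop(validation_error("delta_block must lie in [0, 1]"))
  if (r$bapta_factor < 0 || r$bapta_factor > 1)
    stop(validation_error("bapta_factor must lie in [0, 1]"))
  if (r$rt_over_f <= 0) stop(validation_error("rt_over_f must be positive"))
  invisible(r)
}

validation_error <- function(msg) {
  errorCondition(msg, class = c("nmdarblock_validation_error", "error", "condition"))
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> five-state NMDAR gating/block scheme\n")
  cat(sprintf("  gating : alpha_close=%g 1/s, beta_open_max=%g 1/s, EC50(NMDA)=%g uM\n",
              x$alpha_close, x$beta_open_max, x$ec50_nmda))
  cat(sprintf("  desens : k_des0=%g 1/s, k_rec=%g 1/s, gain=%g, K=%g uM, bapta_factor=%g\n",
              x$k_des0, x$k_rec, x$atl_des_gain, x$atl_des_k, x$bapta_factor))
  cat(sprintf("  block  : k_on0=%g 1/(s uM), k_off0=%g 1/s, delta=%g, z=%g, k_escape=%g 1/s\n",
              x$k_on0, x$k_off0, x$delta_block, x$z_block, x$k_escape))
  cat(sprintf("  Kd(0 mV)=%.4g uM, Kd(-70 mV)=%.4g uM\n",
              kd_at_voltage(x, 0), kd_at_voltage(x, -70)))
  invisible(x)
}

#' Voltage-dependent blocker binding rate and dissociation constant
#'
#' `k_on_at_voltage()` evaluates the Woodhull-scaled binding rate
#' `k_on0 * exp(-delta * z * Vm / (RT/F))`; `kd_at_voltage()` returns
#' `k_off0 / k_on(Vm)`.  For a cationic blocker and negative holding
#' voltages the on-rate is faster and the Kd smaller than at 0 mV.
#'
#' @param rates a [rate_set()].
#' @param vm membrane voltage (mV), vectorized.
#' @return Rate in 1/(s*uM), or Kd in uM.
#' @export
k_on_at_voltage <- function(rates, vm) {
  rates$k_on0 * exp(-rates$delta_block * rates$z_block * vm / rates$rt_over_f)
}

#' @rdname k_on_at_voltage
#' @export
kd_at_voltage <- function(rates, vm) {
  rates$k_off0 / k_on_at_voltage(rates, vm)
}

#' Build the transition-rate matrix for one solution/voltage condition
#'
#' Assembles the generator (Q) matrix of the five-state scheme for a
#' fixed set of effective concentrations and a fixed membrane voltage.
#' Entry `Q[i, j]` is the rate from state i to state j (1/s); each
#' diagonal entry is minus the sum of the off-diagonal entries of its
#' row, so `p' = t(Q) %*% p` conserves probability.
#'
#' Transitions:
#' * `C -> O` at `beta_open_max * NMDA / (NMDA + ec50_nmda)`, forced to 0
#'   while AP5 is present (competitive shutoff of activation);
#' * `O -> C` at `alpha_close`;
#' * `O -> D` at `k_des0 * ca_coupling * influx * (1 + atl_des_gain *
#'   ATL/(ATL + atl_des_k))`, multiplied by `bapta_factor` for
#'   BAPTA-loaded cells, with `influx = Ca_out * max(0, e_rev - Vm) /
#'   (e_rev + 70)` (equal to `Ca_out` at -70 mV);
#' * `D -> O` at `k_rec`;
#' * `O -> OB` at `k_on(Vm) * ATL` (see [k_on_at_voltage()]);
#' * `OB -> O` at `k_off0`;
#' * `OB -> CB` at `alpha_close_blocked` (default `alpha_close`);
#' * `CB -> OB` at the `C -> O` rate;
#' * `CB -> C` at `k_escape`.
#'
#' @param rates a [rate_set()].
#' @param solution named numeric vector or list with effective
#'   concentrations `NMDA`, `Gly`, `ATL`, `AP5` (uM) and `Ca_out` (mM);
#'   missing entries default to 0.
#' @param vm membrane voltage (mV).
#' @param bapta logical; is the cell BAPTA-loaded?
#' @return 5x5 numeric matrix with dimnames `NMDAR_STATES`.
#' @export
build_rate_matrix <- function(rates, solution, vm, bapta = FALSE) {
  validate_rate_set(rates)
  if (!is.finite(vm)) stop(validation_error("vm must be finite"))
  conc <- function(nm) {
    v <- solution[[nm]]
    if (is.null(v) || is.na(v)) 0 else v
  }
  nmda <- conc("NMDA"); atl <- conc("ATL"); ap5 <- conc("AP5")
  ca <- conc("Ca_out")
  if (nmda < 0 || atl < 0 || ap5 < 0 || ca < 0)
    stop(validation_error("concentrations must be >= 0"))

  k_open <- if (ap5 > 0) 0 else rates$beta_open_max * nmda / (nmda + rates$ec50_nmda)
  if (!is.finite(k_open)) k_open <- 0  # NMDA = ec50 = 0

  scale <- rates$e_rev + 70
  influx <- if (scale <= 0) 0 else ca * max(0, rates$e_rev - vm) / scale
  des <- rates$k_des0 * rates$ca_coupling * influx *
    (1 + rates$atl_des_gain * atl / (atl + rates$atl_des_k))
  if (atl == 0 && rates$atl_des_k == 0) # 0/0 guard
    des <- rates$k_des0 * rates$ca_coupling * influx
  if (bapta) des <- des * rates$bapta_factor

  k_block <- k_on_at_voltage(rates, vm) * atl
  a_blk <- if (is.null(rates$alpha_close_blocked)) rates$alpha_close else rates$alpha_close_blocked

  q <- matrix(0, 5, 5, dimnames = list(NMDAR_STATES, NMDAR_STATES))
  q["C", "O"] <- k_open
  q["O", "C"] <- rates$alpha_close
  q["O", "D"] <- des
  q["D", "O"] <- rates$k_rec
  q["O", "OB"] <- k_block
  q["OB", "O"] <- rates$k_off0
  q["OB", "CB"] <- a_blk
  q["CB", "OB"] <- k_open
  q["CB", "C"] <- rates$k_escape
  diag(q) <- -rowSums(q)
  q
}

#' Stationary state occupancy of the scheme under a fixed condition
#'
#' Solves `t(Q) %*% p = 0` with `sum(p) = 1` for the stationary
#' distribution.  Used for calibration and as an algebraic cross-check
#' of the time-dependent integrator.
#'
#' @inheritParams build_rate_matrix
#' @return Named probability vector over `NMDAR_STATES`.
#' @export
steady_state_occupancy <- function(rates, solution, vm, bapta = FALSE) {
  q <- build_rate_matrix(rates, solution, vm, bapta)
  a <- rbind(t(q), rep(1, 5))
  b <- c(rep(0, 5), 1)
  p <- qr.solve(a, b)
  names(p) <- NMDAR_STATES
  p
}

#' Preset: pure open-channel block parameter set
#'
#' A parameter set with desensitization and trapped-blocker escape
#' switched off and fast gating relative to block, so that the
#' macroscopic block behaves as the two-state open/open-blocked system:
#' steady-state relative current `Kd/(Kd + B)` and relaxation rate
#' `1/tau = k_on(Vm)*B + k_off`.  By default the block is voltage
#' independent with the rates measured at -70 mV (binding 0.0016
#' 1/(s*uM), dissociation 0.204 1/s, Kd 127.5 uM); pass `delta_block`
#' and `k_on0` to restore voltage dependence.
#'
#' @param ... overrides passed to [rate_set()].
#' @return A [rate_set()].
#' @export
rate_set_pure_block <- function(...) {
  defaults <- list(alpha_close = 1, beta_open_max = 260, ec50_nmda = 30,
                   k_des0 = 0, atl_des_gain = 0, k_escape = 0,
                   k_on0 = 0.0016, k_off0 = 0.204, delta_block = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(rate_set, args)
}

#' Preset: sequential ("foot-in-the-door") blocker
#'
#' The blocked channel cannot close (`alpha_close_blocked = 0`), gating
#' is slow relative to unbinding, and block is strong, so simultaneous
#' washout of agonist and blocker produces a transient tail current as
#' blocked channels must re-open to release the blocker.
#'
#' @param ... overrides passed to [rate_set()].
#' @return A [rate_set()].
#' @export
rate_set_sequential <- function(...) {
  defaults <- list(alpha_close = 2, beta_open_max = 10.4, ec50_nmda = 30,
                   k_des0 = 0, atl_des_gain = 0, k_escape = 0,
                   k_on0 = 0.1, k_off0 = 0.5, delta_block = 0,
                   alpha_close_blocked = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(rate_set, args)
}

#' Preset: trapping blocker with fast gating
#'
#' Strong, fast-binding block (Kd 5 uM) with normal closure of the
#' blocked channel, used for trapping-protocol fixtures.  `k_escape = 0`
#' gives full trapping; a positive value gives partial trapping.
#'
#' @param k_escape escape rate CB -> C (1/s).
#' @param ... further overrides passed to [rate_set()].
#' @return A [rate_set()].
#' @export
rate_set_trapping <- function(k_escape = 0.25, ...) {
  defaults <- list(alpha_close = 60, beta_open_max = 90, ec50_nmda = 30,
                   k_des0 = 0, atl_des_gain = 0,
                   k_on0 = 0.04, k_off0 = 0.2, delta_block = 0,
                   k_escape = k_escape)
  args <- utils::modifyList(defaults, list(...))
  do.call(rate_set, args)
}
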