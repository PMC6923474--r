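# Solution-application protocols: ordered epochs of bath composition at a
# fixed holding voltage.  Concentrations are stored in the package's fixed
# unit convention: time s, current pA, voltage mV, NMDA/Gly/ATL/AP5 uM,
# Ca2+ mM.

#' Construct one timed solution-application epoch
#'
#' @param t_start,t_end epoch boundaries (s), `t_end > t_start`.
#' @param NMDA,Gly,ATL,AP5 applied concentrations (uM).
#' @param Ca_out bath calcium (mM).
#' @return One-row data frame.
#' @export
solution_epoch <- function(t_start, t_end, NMDA = 0, Gly = 0, ATL = 0,
                           AP5 = 0, Ca_out = 1) {
  e <- data.frame(t_start = t_start, t_end = t_end, NMDA = NMDA, Gly = Gly,
                  ATL = ATL, AP5 = AP5, Ca_out = Ca_out)
  validate_epochs(e)
  e
}

validate_epochs <- function(epochs) {
  req <- c("t_start", "t_end", "NMDA", "Gly", "ATL", "AP5", "Ca_out")
  miss <- setdiff(req, names(epochs))
  if (length(miss))
    stop(epoch_error(paste("epoch table lacks columns:", paste(miss, collapse = ", "))))
  if (nrow(epochs) == 0) stop(epoch_error("protocol must contain at least one epoch"))
  if (any(!is.finite(as.matrix(epochs[req]))))
    stop(epoch_error("epoch fields must be finite"))
  if (any(epochs$t_end <= epochs$t_start))
    stop(epoch_error("each epoch requires t_end > t_start"))
  if (any(as.matrix(epochs[c("NMDA", "Gly", "ATL", "AP5", "Ca_out")]) < 0))
    stop(epoch_error("concentrations must be >= 0"))
  if (is.unsorted(epochs$t_start, strictly = TRUE) && nrow(epochs) > 1)
    stop(epoch_error("epochs must be time-ordered"))
  if (nrow(epochs) > 1 &&
      any(epochs$t_start[-1] < epochs$t_end[-nrow(epochs)] - 1e-12))
    stop(epoch_error("epochs must not overlap"))
  invisible(epochs)
}

epoch_error <- function(msg) {
  errorCondition(msg, class = c("nmdarblock_epoch_error",
                                "nmdarblock_validation_error", "error", "condition"))
}

#' Construct a recording protocol
#'
#' A protocol is an ordered, non-overlapping set of solution epochs at a
#' fixed holding voltage, plus the sampling of the recorded current.
#' Between epochs the bath reverts to drug- and agonist-free solution
#' carrying the calcium level of the preceding epoch.
#'
#' @param epochs data frame of epochs (rbind of [solution_epoch()] rows).
#' @param holding_voltage holding potential (mV).
#' @param bapta_loaded logical; cell loaded with the fast Ca2+ chelator
#'   BAPTA (suppresses Ca2+-dependent desensitization).
#' @param total_duration recording length (s); defaults to the last epoch
#'   end.
#' @param sample_rate output sampling rate (samples/s).
#' @return Object of class `protocol`.
#' @export
protocol <- function(epochs, holding_voltage = -70, bapta_loaded = FALSE,
                     total_duration = NULL, sample_rate = 200) {
  validate_epochs(epochs)
  if (is.null(total_duration)) total_duration <- max(epochs$t_end)
  if (total_duration < max(epochs$t_end))
    stop(epoch_error("total_duration must cover every epoch"))
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop(validation_error("sample_rate must be positive"))
  if (!is.finite(holding_voltage))
    stop(validation_error("holding_voltage must be finite"))
  p <- list(epochs = epochs, holding_voltage = holding_voltage,
            bapta_loaded = isTRUE(bapta_loaded),
            total_duration = total_duration, sample_rate = sample_rate)
  class(p) <- "protocol"
  p
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %d epochs, %.6g s at %g Hz, Vm = %g mV%s\n",
              nrow(x$epochs), x$total_duration, x$sample_rate,
              x$holding_voltage, if (x$bapta_loaded) ", BAPTA-loaded" else ""))
  print(x$epochs)
  invisible(x)
}

# Piecewise-constant solution targets on the breakpoint grid.
# Gaps between epochs carry the preceding epoch's Ca_out with all drugs 0.
protocol_breakpoints <- function(p) {
  eps <- p$epochs
  bks <- sort(unique(c(0, eps$t_start, eps$t_end, p$total_duration)))
  bks <- bks[bks <= p$total_duration + 1e-12]
  species <- c("NMDA", "Gly", "ATL", "AP5", "Ca_out")
  n <- length(bks) - 1L
  tgt <- matrix(0, n, length(species), dimnames = list(NULL, species))
  ca_carry <- eps$Ca_out[1]
  for (i in seq_len(n)) {
    mid <- (bks[i] + bks[i + 1]) / 2
    j <- which(eps$t_start <= mid & eps$t_end > mid)
    if (length(j) == 1L) {
      tgt[i, ] <- as.numeric(eps[j, species])
      ca_carry <- eps$Ca_out[j]
    } else {
      tgt[i, "Ca_out"] <- ca_carry
    }
  }
  list(breaks = bks, targets = tgt)
}

# Effective (lagged) concentrations: first-order exchange with time
# constant tau toward the piecewise-constant target.  AP5 is exempt from
# the lag: it acts as a binary valve state (activation shutoff while the
# antagonist solution is applied), so it follows the nominal application.
# Returns the anchor concentrations at every breakpoint plus an
# evaluator conc(t).
solution_time_course <- function(p, tau) {
  bp <- protocol_breakpoints(p)
  bks <- bp$breaks; tgt <- bp$targets
  n <- nrow(tgt)
  anchors <- matrix(0, n + 1L, ncol(tgt), dimnames = list(NULL, colnames(tgt)))
  anchors[1L, ] <- tgt[1L, ]  # bath equilibrated before recording starts
  if (tau > 0) {
    for (i in seq_len(n)) {
      dt <- bks[i + 1L] - bks[i]
      anchors[i + 1L, ] <- tgt[i, ] + (anchors[i, ] - tgt[i, ]) * exp(-dt / tau)
    }
  } else {
    for (i in seq_len(n)) anchors[i + 1L, ] <- tgt[i, ]
  }
  conc <- function(t, segment = NULL) {
    i <- if (is.null(segment)) {
      max(1L, min(n, findInterval(t, bks, rightmost.closed = TRUE)))
    } else segment
    out <- if (tau > 0) {
      tgt[i, ] + (anchors[i, ] - tgt[i, ]) * exp(-(t - bks[i]) / tau)
    } else tgt[i, ]
    out["AP5"] <- tgt[i, "AP5"]
    out
  }
  list(breaks = bks, targets = tgt, anchors = anchors, conc = conc)
}

# ---- protocol builders used throughout fixtures and examples ----------

#' Standard protocols for the block and trapping experiments
#'
#' Convenience builders mirroring the recording designs the analysis
#' expects.
#'
#' `protocol_staircase()`: a control agonist application followed by the
#' same application with stepwise-rising blocker concentrations
#' (concentration-inhibition staircase).
#'
#' `protocol_block_step()`: agonist to steady state, a single blocker
#' step, then blocker washout in the continued presence of agonist
#' (block onset and offset relaxations).
#'
#' `protocol_trapping()`: agonist to steady state, blocker added, then
#' simultaneous washout of agonist and blocker under AP5 for `t_ap5`
#' seconds, followed by a test agonist application.
#'
#' @param atl_levels blocker concentrations (uM), applied in order.
#' @param atl single blocker concentration (uM).
#' @param ca_out bath calcium (mM).
#' @param vm holding voltage (mV).
#' @param nmda,gly agonist concentrations (uM).
#' @param bapta logical, BAPTA-loaded cell.
#' @param baseline pre-agonist baseline duration (s).
#' @param control_duration agonist-alone duration before the first
#'   blocker application (s).
#' @param level_duration duration of each blocker level (s).
#' @param on_duration,off_duration blocker application and washout
#'   durations in `protocol_block_step()` (s).
#' @param t_ap5 agonist/blocker washout duration under AP5 (s).
#' @param ap5 AP5 concentration during washout (uM).
#' @param block_duration blocker application duration in the trapping
#'   protocol (s).
#' @param test_duration test-pulse duration (s).
#' @param sample_rate output sampling rate (samples/s).
#' @return A [protocol()].
#' @export
protocol_staircase <- function(atl_levels, ca_out = 1, vm = -70,
                               nmda = 100, gly = 30, bapta = FALSE,
                               baseline = 5, control_duration = 25,
                               level_duration = 25, sample_rate = 50) {
  stopifnot(length(atl_levels) >= 1, all(atl_levels >= 0))
  t0 <- baseline
  eps <- solution_epoch(0, t0, Ca_out = ca_out)
  eps <- rbind(eps, solution_epoch(t0, t0 + control_duration, NMDA = nmda,
                                   Gly = gly, Ca_out = ca_out))
  t <- t0 + control_duration
  for (b in atl_levels) {
    eps <- rbind(eps, solution_epoch(t, t + level_duration, NMDA = nmda,
                                     Gly = gly, ATL = b, Ca_out = ca_out))
    t <- t + level_duration
  }
  protocol(eps, holding_voltage = vm, bapta_loaded = bapta,
           sample_rate = sample_rate)
}

#' @rdname protocol_staircase
#' @export
protocol_block_step <- function(atl, ca_out = 0.25, vm = -70,
                                nmda = 100, gly = 30, bapta = FALSE,
                                baseline = 5, control_duration = 20,
                                on_duration = 30, off_duration = 30,
                                sample_rate = 50) {
  t0 <- baseline
  t1 <- t0 + control_duration
  t2 <- t1 + on_duration
  t3 <- t2 + off_duration
  eps <- rbind(
    solution_epoch(0, t0, Ca_out = ca_out),
    solution_epoch(t0, t1, NMDA = nmda, Gly = gly, Ca_out = ca_out),
    solution_epoch(t1, t2, NMDA = nmda, Gly = gly, ATL = atl, Ca_out = ca_out),
    solution_epoch(t2, t3, NMDA = nmda, Gly = gly, Ca_out = ca_out))
  protocol(eps, holding_voltage = vm, bapta_loaded = bapta,
           sample_rate = sample_rate)
}

#' @rdname protocol_staircase
#' @export
protocol_trapping <- function(t_ap5, atl = 200, ca_out = 0.25, vm = -70,
                              nmda = 100, gly = 30, ap5 = 50, bapta = FALSE,
                              baseline = 2, control_duration = 10,
                              block_duration = 12, test_duration = 20,
                              sample_rate = 400) {
  stopifnot(t_ap5 > 0)
  t0 <- baseline
  t1 <- t0 + control_duration
  t2 <- t1 + block_duration
  t3 <- t2 + t_ap5
  t4 <- t3 + test_duration
  eps <- rbind(
    solution_epoch(0, t0, Ca_out = ca_out),
    solution_epoch(t0, t1, NMDA = nmda, Gly = gly, Ca_out = ca_out),
    solution_epoch(t1, t2, NMDA = nmda, Gly = gly, ATL = atl, Ca_out = ca_out),
    solution_epoch(t2, t3, AP5 = ap5, Ca_out = ca_out),
    solution_epoch(t3, t4, NMDA = nmda, Gly = gly, Ca_out = ca_out))
  protocol(eps, holding_voltage = vm, bapta_loaded = bapta,
           sample_rate = sample_rate)
}
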