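# Deterministic master-equation simulation of macroscopic NMDAR currents.

#' Simulate a whole-cell current trace under a solution-exchange protocol
#'
#' Integrates the master equation `p' = t(Q(t)) p` of the five-state
#' scheme along the protocol with a stiff solver ([deSolve::lsoda()]),
#' segment by segment between solution breakpoints.  Solution changes are
#' smoothed by a first-order exchange lag (`tau_exchange` in the rate
#' set).  The recorded current is
#' `I(t) = n_channels_gamma * (Vm - e_rev) * P(O, t)` plus optional white
#' Gaussian noise.  With `noise_sd = 0` the trace is bit-for-bit
#' reproducible; with noise it is reproducible given `seed`.
#'
#' @param rates a [rate_set()].
#' @param protocol a [protocol()].
#' @param noise_sd standard deviation of additive Gaussian noise (pA).
#' @param seed integer seed for the noise stream, or `NULL`.
#' @param return_states if `TRUE`, attach the state-occupancy matrix as
#'   the `occupancy` element.
#' @param atol,rtol absolute and relative integration tolerances on the
#'   occupancies.
#' @return Object of class `current_trace`: a list with `time` (s),
#'   `current` (pA), `protocol`, `seed`, `noise_sd`, `units` and
#'   optionally `occupancy`.
#' @export
simulate_trace <- function(rates, protocol, noise_sd = 0, seed = NULL,
                           return_states = FALSE, atol = 1e-10, rtol = 1e-8) {
  validate_rate_set(rates)
  stopifnot(inherits(protocol, "protocol"))
  sc <- solution_time_course(protocol, rates$tau_exchange)
  vm <- protocol$holding_voltage
  bapta <- protocol$bapta_loaded

  times <- seq(0, protocol$total_duration, by = 1 / protocol$sample_rate)
  occ <- matrix(NA_real_, length(times), 5,
                dimnames = list(NULL, NMDAR_STATES))
  p <- c(1, 0, 0, 0, 0)  # rested: all channels closed and unblocked
  occ[1, ] <- p

  bks <- sc$breaks
  n_seg <- length(bks) - 1L
  for (i in seq_len(n_seg)) {
    t0 <- bks[i]; t1 <- bks[i + 1L]
    sel <- which(times > t0 + 1e-12 & times <= t1 + 1e-12)
    tt <- unique(c(t0, times[sel], t1))
    if (length(tt) < 2L) tt <- c(t0, t1)
    rhs <- function(t, y, parms) {
      q <- build_rate_matrix(rates, sc$conc(t, segment = i), vm, bapta)
      list(as.vector(crossprod(q, y)))
    }
    sol <- deSolve::lsoda(y = p, times = tt, func = rhs, parms = NULL,
                          atol = atol, rtol = rtol)
    if (anyNA(sol) || any(!is.finite(sol)))
      stop(sprintf("integration failure: non-finite occupancy near t = %.6g s",
                   tt[which(!stats::complete.cases(sol))[1]]))
    y <- sol[, -1, drop = FALSE]
    # project back onto the probability simplex (solver tolerance drift)
    y[y < 0 & y > -1e-8] <- 0
    y <- y / rowSums(y)
    if (length(sel)) occ[sel, ] <- y[match(times[sel], tt), ]
    p <- y[nrow(y), ]
  }
  if (anyNA(occ[, 1])) {
    # samples exactly at t = 0 (already set) or rounding stragglers
    miss <- which(is.na(occ[, 1]))
    for (m in miss) occ[m, ] <- occ[max(1, m - 1), ]
  }

  current <- rates$n_channels_gamma * (vm - rates$e_rev) * occ[, "O"]
  if (noise_sd > 0) {
    current <- current + local_seed(seed, stats::rnorm(length(current), 0, noise_sd))
  }
  tr <- list(time = times, current = current, protocol = protocol,
             seed = seed, noise_sd = noise_sd,
             units = list(time = "s", current = "pA"))
  if (return_states) tr$occupancy <- occ
  class(tr) <- "current_trace"
  tr
}

# Evaluate `expr` under a temporary RNG state; the global stream is
# untouched.  seed = NULL evaluates as-is.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples over %.6g s (%g Hz), Vm = %g mV\n",
              length(x$time), max(x$time), x$protocol$sample_rate,
              x$protocol$holding_voltage))
  cat(sprintf("  current range [%.4g, %.4g] pA, noise_sd = %g pA, seed = %s\n",
              min(x$current), max(x$current), x$noise_sd,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

validate_trace <- function(tr) {
  stopifnot(inherits(tr, "current_trace"))
  if (length(tr$time) != length(tr$current))
    stop(validation_error("time and current must have equal length"))
  dt <- diff(tr$time)
  if (any(dt <= 0)) stop(validation_error("time must be strictly increasing"))
  if (length(dt) > 1 && (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop(errorCondition("time grid is not uniform within 1 part in 1e6",
                        class = c("nmdarblock_nonuniform_sampling",
                                  "nmdarblock_validation_error",
                                  "error", "condition")))
  invisible(tr)
}

#' Index the samples of a trace belonging to one epoch
#'
#' @param trace a `current_trace`.
#' @param epoch epoch row index into `trace$protocol$epochs`.
#' @param skip seconds to drop after epoch start (solution-exchange
#'   settling); default three exchange time constants' worth is the
#'   caller's responsibility.
#' @return Integer vector of sample indices.
#' @export
epoch_samples <- function(trace, epoch, skip = 0) {
  e <- trace$protocol$epochs[epoch, ]
  which(trace$time >= e$t_start + skip & trace$time <= e$t_end + 1e-12)
}
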