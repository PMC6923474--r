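# Voltage and calcium dependence of the half-inhibition concentration,
# and the composite IC50(Vm, [Ca2+]) surface.

#' Fit the Woodhull voltage dependence of IC50
#'
#' `IC50(Vm) = IC50(0 mV) * exp(Vm * z * delta * F / RT)`.  The model is
#' exactly linear in log(IC50), so the fit is ordinary least squares of
#' `log(IC50)` on `Vm`; the slope gives the electrical depth
#' `delta = slope * (RT/F) / z` and the e-fold voltage `1/slope`.
#' For a cationic blocker the IC50 must grow with depolarization
#' (positive slope); a significantly negative slope indicates a sign
#' convention error and is rejected.
#'
#' @param vm membrane voltages (mV), or a data frame with columns `vm`
#'   and `ic50`.
#' @param ic50 per-cell or mean IC50 values (uM).
#' @param z blocker valence (fixed at 1 by default).
#' @param rt_over_f RT/F (mV).
#' @param flat_delta below this `delta` the dependence is flagged as
#'   voltage independent.
#' @return List of class `woodhull_fit`: `ic50_0mv` (uM), `delta`,
#'   `e_fold_mv`, `slope` (1/mV), `se` (of slope), `z`, `rt_over_f`,
#'   `voltage_independent` (flag), `n`.
#' @export
fit_woodhull <- function(vm, ic50 = NULL, z = 1, rt_over_f = 25.7,
                         flat_delta = 0.05) {
  if (is.data.frame(vm)) { ic50 <- vm$ic50; vm <- vm$vm }
  stopifnot(length(vm) == length(ic50), all(ic50 > 0))
  if (length(unique(vm)) < 3)
    stop(validation_error("Woodhull fit requires >= 3 distinct voltages"))
  fit <- stats::lm(log(ic50) ~ vm)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))  # exact data: se ~ 0
  slope <- unname(cf[2])
  if (slope < 0 && abs(slope) > 2 * se[2])
    stop(errorCondition(
      "log(IC50) falls with depolarization: sign-convention error for a cationic blocker",
      class = c("nmdarblock_fit_error", "error", "condition")))
  delta <- max(slope, 0) * rt_over_f / z
  out <- list(ic50_0mv = exp(unname(cf[1])), delta = delta,
              e_fold_mv = if (slope > 0) 1 / slope else Inf,
              slope = slope, se = unname(se[2]), z = z, rt_over_f = rt_over_f,
              voltage_independent = delta < flat_delta,
              n = length(vm))
  class(out) <- "woodhull_fit"
  out
}

#' Electrical depth from an e-fold voltage
#'
#' `delta = (RT/F) / (z * e_fold_mv)`: the depth of the blocker binding
#' site implied by the voltage shift that changes IC50 e-fold.
#'
#' @param e_fold_mv e-fold voltage (mV).
#' @param z blocker valence.
#' @param rt_over_f RT/F (mV).
#' @return delta (dimensionless).
#' @export
woodhull_delta <- function(e_fold_mv, z = 1, rt_over_f = 25.7) {
  rt_over_f / (z * e_fold_mv)
}

#' @export
print.woodhull_fit <- function(x, ...) {
  cat(sprintf("<woodhull_fit> IC50(0 mV) = %.4g uM, delta = %.3g (z = %g), e-fold %.3g mV%s\n",
              x$ic50_0mv, x$delta, x$z, x$e_fold_mv,
              if (x$voltage_independent) " [voltage independent]" else ""))
  invisible(x)
}

#' Fit the calcium dependence of IC50 as a single exponential
#'
#' Unweighted nonlinear least squares of `IC50 = A * exp(-Ca / b)` on
#' the linear IC50 scale (this is the scale on which the condition-mean
#' IC50 values are conventionally summarized).  `A` extrapolates the
#' IC50 to zero bath calcium and `b` is the e-fold calcium shift.
#'
#' @param ca bath calcium (mM), or a data frame with columns `ca` and
#'   `ic50`.
#' @param ic50 IC50 values (uM).
#' @param reversal_tol relative reversal of monotonicity tolerated
#'   before a warning (default 0.2).
#' @return List of class `ca_exp_fit`: `a` (uM), `b` (mM), `se`, `flat`
#'   (flag: no resolvable calcium dependence), `n`, `rms`.
#' @export
fit_ca_exponential <- function(ca, ic50 = NULL, reversal_tol = 0.2) {
  if (is.data.frame(ca)) { ic50 <- ca$ic50; ca <- ca$ca }
  stopifnot(length(ca) == length(ic50), all(ic50 > 0))
  if (length(unique(ca)) < 3)
    stop(validation_error("calcium-dependence fit requires >= 3 distinct [Ca2+]"))
  means <- tapply(ic50, ca, mean)
  ord <- order(as.numeric(names(means)))
  m <- as.numeric(means[ord])
  if (any(diff(m) > reversal_tol * m[-length(m)]))
    warning("IC50 means are non-monotonic in [Ca2+] beyond tolerance")
  # start values from the log-linear regression
  lf <- stats::lm(log(ic50) ~ ca)
  b0 <- -1 / min(unname(stats::coef(lf)[2]), -1e-6)
  a0 <- exp(unname(stats::coef(lf)[1]))
  lf_se <- suppressWarnings(sqrt(stats::vcov(lf)[2, 2]))
  flat <- stats::coef(lf)[2] > -1e-8 || abs(stats::coef(lf)[2]) < 2 * lf_se
  fit <- tryCatch(
    minpack.lm::nlsLM(ic50 ~ a * exp(-ca / b),
                      start = list(a = a0, b = min(b0, 10 * max(ca))),
                      lower = c(1e-12, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    if (flat) {
      out <- list(a = mean(ic50), b = Inf, se = c(a = sem(ic50), b = NA),
                  flat = TRUE, n = length(ca), rms = stats::sd(ic50))
      class(out) <- "ca_exp_fit"
      return(out)
    }
    stop(errorCondition(sprintf("calcium-dependence fit failed: %s",
                                conditionMessage(fit)),
                        class = c("nmdarblock_fit_error", "error", "condition")))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  # flat when the fitted e-fold constant exceeds the sampled range several-fold
  flat <- flat || cf[["b"]] > 5 * max(ca)
  out <- list(a = cf[["a"]], b = cf[["b"]], se = c(a = se[1], b = se[2]),
              flat = flat, n = length(ca),
              rms = sqrt(mean(stats::resid(fit)^2)))
  class(out) <- "ca_exp_fit"
  out
}

#' @export
print.ca_exp_fit <- function(x, ...) {
  cat(sprintf("<ca_exp_fit> IC50 = %.4g * exp(-[Ca2+]/%.3g) uM%s\n",
              x$a, x$b, if (x$flat) " [flat: no resolvable Ca dependence]" else ""))
  invisible(x)
}

#' Fit the composite IC50(Vm, [Ca2+]) surface
#'
#' Least squares of `log(IC50) ~ Vm + Ca`, i.e. the separable product
#' model `IC50 = prefactor * exp(a * Vm - Ca / b)`.  Voltage and calcium
#' act through independent mechanisms (open-channel block and
#' Ca2+-dependent desensitization), so their contributions multiply.
#' The implied electrical depth `a * (RT/F) / z` is reported for
#' comparison with the directly fitted Woodhull depth.
#'
#' @param vm,ca,ic50 the observations, or a data frame (first argument)
#'   with columns `vm`, `ca`, `ic50`.
#' @param z,rt_over_f blocker valence and RT/F (mV) used only for the
#'   implied depth.
#' @return List of class `surface_fit`: `prefactor` (uM), `a` (1/mV),
#'   `b` (mM), `delta_implied`, `n`, `r_squared`.
#' @export
fit_surface <- function(vm, ca = NULL, ic50 = NULL, z = 1, rt_over_f = 25.7) {
  if (is.data.frame(vm)) { ca <- vm$ca; ic50 <- vm$ic50; vm <- vm$vm }
  stopifnot(length(vm) == length(ca), length(ca) == length(ic50), all(ic50 > 0))
  if (length(unique(vm)) < 2 || length(unique(ca)) < 2)
    stop(validation_error("surface fit needs >= 2 distinct voltages and >= 2 distinct [Ca2+] (rank-deficient design)"))
  fit <- stats::lm(log(ic50) ~ vm + ca)
  cf <- stats::coef(fit)
  out <- list(prefactor = exp(unname(cf[1])), a = unname(cf["vm"]),
              b = -1 / unname(cf["ca"]),
              delta_implied = unname(cf["vm"]) * rt_over_f / z,
              n = length(ic50),
              r_squared = suppressWarnings(summary(fit)$r.squared))
  class(out) <- "surface_fit"
  out
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("<surface_fit> IC50 = %.4g * exp(%.4g * Vm - [Ca2+]/%.3g) uM (implied delta %.3g)\n",
              x$prefactor, x$a, x$b, x$delta_implied))
  invisible(x)
}

#' Compose the surface prefactor from its component fits
#'
#' The composite model is `IC50(Vm, Ca) = IC50(Vm) * IC50(Ca) /
#' IC50(Ca_ref)`, so its prefactor (0 mV, zero calcium) equals
#' `IC50(0 mV) * IC50(Ca = 0) / IC50(Ca_ref)`, where `IC50(Ca_ref)` is
#' the IC50 at the reference calcium level shared by the two component
#' data sets (0.25 mM in the block-characterization condition).
#'
#' @param ic50_0mv IC50 at 0 mV from the Woodhull fit (uM).
#' @param ic50_ca0 zero-calcium amplitude from the calcium fit (uM).
#' @param ic50_ref IC50 at the reference calcium level (uM).
#' @return Prefactor (uM).
#' @export
compose_prefactor <- function(ic50_0mv, ic50_ca0, ic50_ref) {
  stopifnot(ic50_0mv > 0, ic50_ca0 > 0, ic50_ref > 0)
  ic50_0mv * ic50_ca0 / ic50_ref
}

#' Evaluate a fitted IC50 surface
#'
#' @param surface a `surface_fit`, or any list with `prefactor`, `a`, `b`.
#' @param vm membrane voltage (mV), vectorized.
#' @param ca bath calcium (mM), vectorized.
#' @return IC50 (uM).
#' @export
predict_ic50 <- function(surface, vm, ca) {
  surface$prefactor * exp(surface$a * vm - ca / surface$b)
}

#' Tabulate a fitted IC50 surface on a voltage x calcium grid
#'
#' @param surface a `surface_fit`.
#' @param vm,ca grid axes.
#' @return Data frame with columns `vm`, `ca`, `ic50`.
#' @export
surface_grid <- function(surface, vm = seq(-100, 40, by = 10),
                         ca = seq(0.25, 4, by = 0.25)) {
  g <- expand.grid(vm = vm, ca = ca)
  g$ic50 <- predict_ic50(surface, g$vm, g$ca)
  g
}
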