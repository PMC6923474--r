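# Shared oracles and fixture shorthands.
#
# Two-state open-channel block closed forms (hand-derived):
#   relative steady-state current  I_b/I_c = Kd(Vm) / (Kd(Vm) + B)
#   relaxation rate                1/tau   = k_on(Vm) * B + k_off
# with k_on(Vm) = k_on0 * exp(-delta * z * Vm / (RT/F)), Kd = k_off / k_on.

two_state_rel_amplitude <- function(b, k_on, k_off) {
  kd <- k_off / k_on
  kd / (kd + b)
}

two_state_rate <- function(b, k_on, k_off) k_on * b + k_off

woodhull_kon <- function(k_on0, vm, delta, z = 1, rt_over_f = 25.7) {
  k_on0 * exp(-delta * z * vm / rt_over_f)
}

# Fit the per-cell condition IC50s of a staircase fixture set, split by
# (vm, ca, bapta) condition.
fixture_condition_ic50 <- function(fx) {
  pts <- do.call(rbind, lapply(seq_along(fx$traces), function(i)
    extract_staircase(fx$traces[[i]], cell = fx$manifest$cell[i])))
  by_cond <- split(pts, interaction(pts$vm, pts$ca_out, pts$bapta, drop = TRUE))
  out <- lapply(by_cond, function(d) {
    f <- fit_hill_by_cell(d)
    list(vm = d$vm[1], ca = d$ca_out[1], bapta = d$bapta[1],
         ic50_mean = f$ic50_mean, per_cell = f$per_cell)
  })
  out
}

# Short pure-block relaxation protocol used by the kinetics tests.
short_block_step <- function(atl, vm = -70, sample_rate = 25) {
  protocol_block_step(atl, ca_out = 0.25, vm = vm, baseline = 2,
                      control_duration = 10, on_duration = 25,
                      off_duration = 25, sample_rate = sample_rate)
}
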