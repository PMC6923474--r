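#' Published whole-cell estimates for amitriptyline block of NMDARs
#'
#' Summary values reported for amitriptyline (ATL) inhibition of
#' NMDA-activated whole-cell currents in cultured cortical neurons,
#' used as calibration anchors for the simulator defaults and as inputs
#' to the dependence-model fits when no raw recordings are available.
#'
#' @return A list:
#' \describe{
#'   \item{ic50_by_ca}{data frame of condition-mean IC50 (uM), Hill
#'     coefficient and cell count at -70 mV across bath calcium
#'     0.25-4 mM.}
#'   \item{bapta}{IC50 (uM) in 1 mM calcium for BAPTA-loaded cells.}
#'   \item{kinetics}{binding/unbinding rate constants at -70 mV in
#'     0.25 mM calcium: `k_on` 1/(s*uM), `k_off` 1/s, `kd` uM, and the
#'     concentration pair used (uM).}
#'   \item{voltage}{Woodhull parameters in 0.25 mM calcium: `ic50_0mv`
#'     (uM), `slope` (1/mV), `e_fold_mv`, `delta`, `z`, `rt_over_f`.}
#'   \item{ca_exponential}{single-exponential calcium dependence:
#'     amplitude `a` (uM) and e-fold constant `b` (mM).}
#'   \item{surface}{composite-surface parameters: `prefactor` (uM),
#'     `a` (1/mV), `b` (mM), and the 0.25 mM reference IC50 (uM) used in
#'     the composition.}
#' }
#' @export
atl_reference_values <- function() {
  list(
    ic50_by_ca = data.frame(
      ca = c(0.25, 0.5, 1, 2, 4),
      ic50 = c(63.0, 37.6, 21.6, 4.9, 0.72),
      ic50_sem = c(9.3, 7.7, 8.7, 1.0, 0.12),
      h = c(1.4, 1.5, 1.6, 1.2, 1.5),
      n = c(8, 7, 5, 9, 10)),
    bapta = list(ca = 1, ic50 = 105.8, ic50_sem = 9.5, n = 10),
    kinetics = list(k_on = 0.0016, k_off = 0.204, kd = 127.5,
                    conc_pair = c(10, 100), vm = -70, ca = 0.25),
    voltage = list(ic50_0mv = 220, slope = 0.021, e_fold_mv = 50,
                   delta = 0.51, z = 1, rt_over_f = 25.7),
    ca_exponential = list(a = 91, b = 0.63),
    surface = list(prefactor = 317, a = 0.018, b = 0.69, ic50_ref = 64,
                   ref_ca = 0.25))
}
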