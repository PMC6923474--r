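# Study-fixture generation: per-"cell" simulated recordings with
# cell-to-cell variability, plus the machine-readable ground truth.

#' Analytic steady-state IC50 of the simulator
#'
#' Solves for the blocker concentration at which the stationary open
#' probability falls to half its blocker-free value, using the algebraic
#' stationary distribution of the scheme (no time integration).  Used to
#' position staircase concentrations and as the model-level ground truth
#' for fitted IC50s.
#'
#' @param rates a [rate_set()].
#' @param ca bath calcium (mM).
#' @param vm holding voltage (mV).
#' @param bapta logical.
#' @param nmda,gly agonist concentrations (uM).
#' @param interval search interval for the root (uM).
#' @return IC50 (uM).
#' @export
analytic_ic50 <- function(rates, ca, vm = -70, bapta = FALSE,
                          nmda = 100, gly = 30, interval = c(1e-5, 1e6)) {
  po <- function(b) steady_state_occupancy(
    rates, list(NMDA = nmda, Gly = gly, ATL = b, Ca_out = ca), vm, bapta)[["O"]]
  p0 <- po(0)
  stats::uniroot(function(b) po(b) / p0 - 0.5, interval, tol = 1e-9)$root
}

#' Configuration for a fixture set
#'
#' Describes the recording conditions of a simulated study: the bath
#' calcium levels, holding voltages, number of cells per condition, the
#' blocker staircases, the trapping washout durations, the recording
#' noise, and the cell-to-cell variability.  Staircase concentrations
#' default to five log-spaced levels from 1/9 to 9 times the analytic
#' IC50 of each condition (the same bracketing an experimenter applies).
#'
#' @param kind one of `"staircase"`, `"relaxation"`, `"trapping"`.
#' @param rates generating [rate_set()].
#' @param ca_levels bath calcium levels (mM).
#' @param voltages holding voltages (mV).
#' @param bapta logical vector of BAPTA conditions to include.
#' @param n_cells cells per condition (>= 2).
#' @param noise_sd recording noise (pA).
#' @param atl_levels staircase concentrations (uM) or `NULL` for
#'   automatic bracketing.
#' @param kinetics_conc the two blocker concentrations for relaxation
#'   fixtures (uM).
#' @param t_ap5 washout durations for trapping fixtures (s).
#' @param trapping_atl blocker concentration in the trapping protocol (uM).
#' @param jitter_conductance lognormal sd of the per-cell conductance.
#' @param jitter_rates lognormal sd of the per-cell kinetic rates.
#' @param sample_rate output sampling rate (samples/s); `NULL` picks a
#'   per-kind default (50 Hz staircase/relaxation, 400 Hz trapping).
#' @return List of class `study_config`.
#' @export
study_config <- function(kind = c("staircase", "relaxation", "trapping"),
                         rates = rate_set(),
                         ca_levels = c(0.25, 0.5, 1, 2, 4),
                         voltages = -70,
                         bapta = FALSE,
                         n_cells = 5,
                         noise_sd = 5,
                         atl_levels = NULL,
                         kinetics_conc = c(10, 100),
                         t_ap5 = c(0.5, 1, 2, 4),
                         trapping_atl = 200,
                         jitter_conductance = 0.25,
                         jitter_rates = 0.08,
                         sample_rate = NULL) {
  kind <- match.arg(kind)
  if (n_cells < 2)
    stop(validation_error("need n_cells >= 2 per condition (SEM undefined otherwise)"))
  cfg <- list(kind = kind, rates = rates, ca_levels = ca_levels,
              voltages = voltages, bapta = bapta, n_cells = n_cells,
              noise_sd = noise_sd, atl_levels = atl_levels,
              kinetics_conc = kinetics_conc, t_ap5 = t_ap5,
              trapping_atl = trapping_atl,
              jitter_conductance = jitter_conductance,
              jitter_rates = jitter_rates,
              sample_rate = sample_rate %||%
                switch(kind, staircase = 50, relaxation = 50, trapping = 400))
  class(cfg) <- "study_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-cell parameter jitter: lognormal on conductance and on the kinetic
# rates that vary between cells.  Derived deterministically from the cell
# seed.
jitter_rates_for_cell <- function(rates, cell_seed, sd_conductance, sd_rates) {
  r <- rates
  local_seed(cell_seed, {
    r$n_channels_gamma <- r$n_channels_gamma * exp(stats::rnorm(1, 0, sd_conductance))
    for (nm in c("k_on0", "k_off0", "k_des0", "k_rec", "k_escape")) {
      if (r[[nm]] > 0) r[[nm]] <- r[[nm]] * exp(stats::rnorm(1, 0, sd_rates))
    }
    r
  })
}

#' Generate a study fixture set with ground truth
#'
#' Simulates per-cell recordings for every condition in `config`, with
#' cell-to-cell lognormal variability on conductance and kinetic rates,
#' and returns the traces together with a manifest and a ground-truth
#' record of the true per-cell parameters.  Re-running with the same
#' seed reproduces the set exactly.
#'
#' @param config a [study_config()].
#' @param seed integer master seed; per-cell streams are derived by
#'   fixed offsets.
#' @param out_dir optional directory; when given, every trace is written
#'   via [write_trace()] and the ground truth as `ground_truth.json`.
#' @return List of class `fixture_set`: `traces` (list of
#'   `current_trace`), `manifest` (data frame: trace index, cell, vm,
#'   ca_out, bapta, kind and condition extras), `ground_truth` (list per
#'   cell).
#' @export
make_study_fixtures <- function(config = study_config(), seed = 1,
                                out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  conditions <- expand.grid(ca = config$ca_levels, vm = config$voltages,
                            bapta = config$bapta, stringsAsFactors = FALSE)
  traces <- list(); manifest <- list(); truth <- list()
  idx <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    levels <- config$atl_levels
    if (config$kind == "staircase" && is.null(levels)) {
      ic <- analytic_ic50(config$rates, cond$ca, cond$vm, cond$bapta)
      levels <- signif(ic * 3^seq(-2, 2), 3)
    }
    for (cell in seq_len(config$n_cells)) {
      cell_seed <- seed + 7919L * ci + 104729L * cell
      cell_seed <- cell_seed %% .Machine$integer.max
      r <- jitter_rates_for_cell(config$rates, cell_seed,
                                 config$jitter_conductance, config$jitter_rates)
      cell_id <- sprintf("c%02d_v%g_ca%g%s", cell, cond$vm, cond$ca,
                         if (cond$bapta) "_bapta" else "")
      if (config$kind == "staircase") {
        prots <- list(staircase = protocol_staircase(
          levels, ca_out = cond$ca, vm = cond$vm, bapta = cond$bapta,
          sample_rate = config$sample_rate))
      } else if (config$kind == "relaxation") {
        prots <- lapply(config$kinetics_conc, function(b)
          protocol_block_step(b, ca_out = cond$ca, vm = cond$vm,
                              bapta = cond$bapta,
                              sample_rate = config$sample_rate))
        names(prots) <- paste0("step_", config$kinetics_conc, "uM")
      } else {
        prots <- lapply(config$t_ap5, function(tw)
          protocol_trapping(tw, atl = config$trapping_atl, ca_out = cond$ca,
                            vm = cond$vm, bapta = cond$bapta,
                            sample_rate = config$sample_rate))
        names(prots) <- paste0("tap5_", config$t_ap5, "s")
      }
      for (pi in seq_along(prots)) {
        idx <- idx + 1L
        tr_seed <- (cell_seed + 13L * pi) %% .Machine$integer.max
        traces[[idx]] <- simulate_trace(r, prots[[pi]],
                                        noise_sd = config$noise_sd,
                                        seed = tr_seed)
        manifest[[idx]] <- data.frame(
          index = idx, cell = cell_id, vm = cond$vm, ca_out = cond$ca,
          bapta = cond$bapta, kind = config$kind,
          variant = names(prots)[pi] %||% "staircase",
          seed = tr_seed)
      }
      truth[[cell_id]] <- list(
        cell = cell_id, vm = cond$vm, ca_out = cond$ca, bapta = cond$bapta,
        rates = unclass(r),
        analytic_ic50 = if (config$kind == "staircase")
          analytic_ic50(r, cond$ca, cond$vm, cond$bapta) else NULL)
    }
  }
  manifest <- do.call(rbind, manifest)
  out <- list(traces = traces, manifest = manifest, ground_truth = truth,
              config = config, seed = seed)
  class(out) <- "fixture_set"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(traces)) {
      f <- file.path(out_dir, sprintf("trace_%03d_%s_%s.tsv", i,
                                      manifest$cell[i], manifest$variant[i]))
      write_trace(traces[[i]], f,
                  provenance = list(rates = unclass(truth[[manifest$cell[i]]]$rates)))
    }
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> %d traces (%s), %d cells, seed %d\n",
              length(x$traces), x$config$kind,
              length(x$ground_truth), x$seed))
  invisible(x)
}
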