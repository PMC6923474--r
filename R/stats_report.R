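# Group statistics (two-tailed t tests, one-way ANOVA with Bonferroni
# pairwise correction, mean +/- SEM) and the end-to-end study pipeline.

#' Significance stars
#'
#' Caption convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001.
#'
#' @param p p value(s).
#' @return Character vector of stars ("" for n.s.).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Unpaired two-tailed Student's t test between two cell groups
#'
#' Pooled-variance (classical Student) two-sample test.
#'
#' @param values_a,values_b per-cell values, each of length >= 2.
#' @return List of class `group_comparison`: `test`, `statistic`, `p`,
#'   `stars`, `n` (per group), `means`, `sems`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop(validation_error("each group needs n >= 2"))
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      stop(errorCondition("both groups have zero variance: t statistic undefined",
                          class = c("nmdarblock_stats_error", "error", "condition")))
    tt <- list(statistic = c(t = sign(mean(values_a) - mean(values_b)) * Inf),
               p.value = 0)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = TRUE,
                        alternative = "two.sided")
  }
  out <- list(test = "t_two_tailed",
              statistic = unname(tt$statistic), p = tt$p.value,
              stars = significance_stars(tt$p.value),
              n = c(length(values_a), length(values_b)),
              means = c(mean(values_a), mean(values_b)),
              sems = c(sem(values_a), sem(values_b)))
  class(out) <- "group_comparison"
  out
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' @param groups named list of numeric vectors (>= 3 groups, each
#'   n >= 2).
#' @return List of class `group_comparison`: `test`, `statistic` (F),
#'   `p` (omnibus), `stars`, `n`, `pairwise` (data frame of
#'   Bonferroni-adjusted pairwise p values and flags at alpha 0.05).
#' @export
anova_bonferroni <- function(groups) {
  if (length(groups) < 3)
    stop(validation_error("ANOVA requires >= 3 groups"))
  if (any(vapply(groups, length, integer(1)) < 2))
    stop(validation_error("each group needs n >= 2"))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  fit <- stats::aov(values ~ labels)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  pw <- stats::pairwise.t.test(values, labels, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  m <- pw$p.value
  pairs <- which(!is.na(m), arr.ind = TRUE)
  pairwise <- data.frame(
    group_a = rownames(m)[pairs[, 1]],
    group_b = colnames(m)[pairs[, 2]],
    p_adjusted = m[pairs],
    significant = m[pairs] < 0.05)
  out <- list(test = "anova_bonferroni", statistic = f, p = p,
              stars = significance_stars(p),
              n = vapply(groups, length, integer(1)),
              pairwise = pairwise)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g %s\n",
              x$test, x$statistic, x$p, x$stars))
  invisible(x)
}

#' Configuration of the end-to-end study pipeline
#'
#' @param rates generating [rate_set()].
#' @param ca_levels calcium levels for the concentration-inhibition
#'   stage (mM).
#' @param voltages holding voltages for the voltage-dependence stage
#'   (mV), run at `voltage_ca` mM calcium.
#' @param voltage_ca calcium level of the voltage-dependence stage (mM).
#' @param bapta_ca calcium level of the BAPTA comparison (mM).
#' @param n_cells cells per condition.
#' @param noise_sd recording noise (pA).
#' @param kinetics_conc concentration pair for the rate-constant stage
#'   (uM).
#' @param t_ap5 washout durations of the trapping stage (s).
#' @param run_trapping,run_kinetics logical switches for the slower
#'   stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(rates = rate_set(),
                            ca_levels = c(0.25, 0.5, 1, 2, 4),
                            voltages = c(-100, -70, -30),
                            voltage_ca = 0.25,
                            bapta_ca = 1,
                            n_cells = 3,
                            noise_sd = 2,
                            kinetics_conc = c(10, 100),
                            t_ap5 = c(0.5, 1, 2, 4),
                            run_trapping = TRUE,
                            run_kinetics = TRUE) {
  cfg <- list(rates = rates, ca_levels = ca_levels, voltages = voltages,
              voltage_ca = voltage_ca, bapta_ca = bapta_ca,
              n_cells = n_cells, noise_sd = noise_sd,
              kinetics_conc = kinetics_conc, t_ap5 = t_ap5,
              run_trapping = run_trapping, run_kinetics = run_kinetics)
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, result = expr, error = NULL),
                  error = function(e) list(ok = FALSE, result = NULL,
                                           error = conditionMessage(e)))
  report[[name]] <- res
  report
}

# Hill condition summary for one (ca, vm, bapta) condition from a
# staircase fixture set.
condition_hill <- function(fx) {
  pts <- do.call(rbind, lapply(seq_along(fx$traces), function(i)
    extract_staircase(fx$traces[[i]], cell = fx$manifest$cell[i])))
  by_cond <- split(pts, interaction(pts$vm, pts$ca_out, pts$bapta, drop = TRUE))
  lapply(by_cond, function(d) {
    f <- fit_hill_by_cell(d)
    list(vm = d$vm[1], ca_out = d$ca_out[1], bapta = d$bapta[1],
         ic50_mean = f$ic50_mean, ic50_sem = f$ic50_sem,
         h_mean = f$h_mean, h_sem = f$h_sem, n = f$n_cells,
         per_cell_ic50 = f$per_cell$ic50)
  })
}

#' Run the full simulated study and collect a machine-readable report
#'
#' Executes simulate, measure and fit end to end: concentration-
#' inhibition staircases across bath calcium (with the BAPTA
#' comparison), the voltage-dependence series, rate-constant estimation
#' from relaxations, the Woodhull / calcium-exponential / composite-
#' surface fits, the trapping-protocol analysis, and the group
#' statistics.  Stage failures are recorded in the report and do not
#' abort independent stages.  The report is deterministic given `seed`.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @param out_dir optional directory for `report.json` and per-stage
#'   tables.
#' @return Nested list of class `study_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = seed,
                 config = list(ca_levels = config$ca_levels,
                               voltages = config$voltages,
                               n_cells = config$n_cells,
                               noise_sd = config$noise_sd))

  # --- calcium dependence of IC50 (with BAPTA comparison) -------------
  report <- run_stage(report, "ca_dependence", {
    fx <- make_study_fixtures(study_config(
      "staircase", rates = config$rates, ca_levels = config$ca_levels,
      voltages = -70, n_cells = config$n_cells,
      noise_sd = config$noise_sd), seed = seed)
    hills <- condition_hill(fx)
    ic50s <- data.frame(
      ca = vapply(hills, `[[`, numeric(1), "ca_out"),
      ic50 = vapply(hills, `[[`, numeric(1), "ic50_mean"),
      sem = vapply(hills, `[[`, numeric(1), "ic50_sem"))
    ic50s <- ic50s[order(ic50s$ca), ]
    ca_fit <- fit_ca_exponential(ic50s$ca, ic50s$ic50)
    list(conditions = hills, ic50_by_ca = ic50s,
         ca_exponential = unclass(ca_fit),
         monotone_decreasing = all(diff(ic50s$ic50) < 0))
  })

  report <- run_stage(report, "bapta_comparison", {
    fx_b <- make_study_fixtures(study_config(
      "staircase", rates = config$rates, ca_levels = config$bapta_ca,
      voltages = -70, bapta = TRUE, n_cells = config$n_cells,
      noise_sd = config$noise_sd), seed = seed + 101)
    hb <- condition_hill(fx_b)[[1]]
    ctrl <- report$ca_dependence$result$conditions
    ctrl <- ctrl[[which(vapply(ctrl, `[[`, numeric(1), "ca_out") == config$bapta_ca)]]
    cmp <- compare_groups(ctrl$per_cell_ic50, hb$per_cell_ic50)
    list(control_ic50 = ctrl$ic50_mean, bapta_ic50 = hb$ic50_mean,
         shift_upward = hb$ic50_mean > ctrl$ic50_mean,
         t_test = unclass(cmp))
  })

  # --- voltage dependence ---------------------------------------------
  report <- run_stage(report, "voltage_dependence", {
    fx_v <- make_study_fixtures(study_config(
      "staircase", rates = config$rates, ca_levels = config$voltage_ca,
      voltages = config$voltages, n_cells = config$n_cells,
      noise_sd = config$noise_sd), seed = seed + 202)
    hv <- condition_hill(fx_v)
    tab <- do.call(rbind, lapply(hv, function(h)
      data.frame(vm = h$vm, ic50 = h$per_cell_ic50)))
    wf <- fit_woodhull(tab$vm, tab$ic50, rt_over_f = config$rates$rt_over_f)
    list(ic50_by_vm = tab, woodhull = unclass(wf))
  })

  # --- composite surface ----------------------------------------------
  report <- run_stage(report, "surface", {
    ca_res <- report$ca_dependence$result
    v_res <- report$voltage_dependence$result
    if (is.null(ca_res) || is.null(v_res)) stop("upstream stages failed")
    tab <- rbind(
      data.frame(vm = -70, ca = ca_res$ic50_by_ca$ca,
                 ic50 = ca_res$ic50_by_ca$ic50),
      data.frame(vm = v_res$ic50_by_vm$vm, ca = config$voltage_ca,
                 ic50 = v_res$ic50_by_vm$ic50))
    sf <- fit_surface(tab)
    ref <- ca_res$ic50_by_ca$ic50[ca_res$ic50_by_ca$ca == config$voltage_ca]
    composed <- if (length(ref) == 1 && !ca_res$ca_exponential$flat)
      compose_prefactor(v_res$woodhull$ic50_0mv, ca_res$ca_exponential$a, ref)
    else NA_real_
    list(fit = unclass(sf), composed_prefactor = composed)
  })

  # --- block rate constants -------------------------------------------
  # Recorded in BAPTA-loaded cells at low calcium so that the block
  # relaxation is not contaminated by the (much faster) Ca2+-dependent
  # desensitization relaxation.
  if (config$run_kinetics) {
    report <- run_stage(report, "block_kinetics", {
      fx_k <- make_study_fixtures(study_config(
        "relaxation", rates = config$rates, ca_levels = config$voltage_ca,
        voltages = -70, bapta = TRUE, n_cells = config$n_cells,
        noise_sd = config$noise_sd,
        kinetics_conc = config$kinetics_conc), seed = seed + 303)
      cells <- unique(fx_k$manifest$cell)
      per_cell <- lapply(cells, function(cl) {
        ii <- which(fx_k$manifest$cell == cl)
        fit_block_kinetics(fx_k$traces[[ii[1]]], fx_k$traces[[ii[2]]])
      })
      data.frame(cell = cells,
                 k_on = vapply(per_cell, `[[`, numeric(1), "k_on"),
                 k_off = vapply(per_cell, `[[`, numeric(1), "k_off"),
                 kd = vapply(per_cell, `[[`, numeric(1), "kd"))
    })
  }

  # --- trapping --------------------------------------------------------
  if (config$run_trapping) {
    report <- run_stage(report, "trapping", {
      fx_t <- make_study_fixtures(study_config(
        "trapping", rates = config$rates, ca_levels = config$voltage_ca,
        voltages = -70, n_cells = max(2, config$n_cells - 1),
        noise_sd = config$noise_sd, t_ap5 = config$t_ap5), seed = seed + 404)
      res <- analyze_trapping(fx_t$traces, cells = fx_t$manifest$cell)
      list(mode = res$mode, escape_rate = res$escape_rate,
           tail_detected = res$tail_detected,
           per_washout = res$per_washout,
           tau_s_anova = if (!is.null(res$tau_s_anova))
             list(f = res$tau_s_anova$statistic, p = res$tau_s_anova$p)
           else NULL)
    })
  }

  class(report) <- "study_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(strip_classes(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", force = TRUE)
  }
  report
}

# plain nested lists for serialization
strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else x
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in setdiff(names(x), c("seed", "config"))) {
    st <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (isTRUE(st$ok)) "ok" else paste("FAILED:", st$error)))
  }
  invisible(x)
}
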