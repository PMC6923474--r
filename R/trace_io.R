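# Trace container: one delimited text file per trace (columns time_s,
# current_pA) plus a JSON sidecar holding the protocol, units, seed and
# rate-set provenance.  The unit contract is fixed: s, pA, mV, uM for
# drugs, mM for calcium.

io_error <- function(msg, class) {
  errorCondition(msg, class = c(class, "nmdarblock_io_error", "error", "condition"))
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a current trace to a data file plus JSON sidecar
#'
#' The data file is tab-delimited text with columns `time_s` and
#' `current_pA`, written with 17 significant digits so 64-bit doubles
#' round-trip losslessly.  The sidecar (same basename, `.json`) stores
#' the protocol, the unit contract, `seed`, `noise_sd` and optional
#' provenance (e.g. the generating rate set).
#'
#' @param trace a `current_trace`.
#' @param path path of the data file; the sidecar replaces its extension
#'   with `.json`.
#' @param provenance optional list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, provenance = NULL) {
  validate_trace(trace)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("time_s\tcurrent_pA", con)
  writeLines(sprintf("%.17g\t%.17g", trace$time, trace$current), con)
  meta <- list(
    units = list(time = "s", current = "pA", voltage = "mV",
                 drug = "uM", calcium = "mM"),
    protocol = list(
      epochs = trace$protocol$epochs,
      holding_voltage = trace$protocol$holding_voltage,
      bapta_loaded = trace$protocol$bapta_loaded,
      total_duration = trace$protocol$total_duration,
      sample_rate = trace$protocol$sample_rate),
    seed = trace$seed,
    noise_sd = trace$noise_sd,
    provenance = provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}

#' Read a current trace written by [write_trace()]
#'
#' Validates the unit contract, the epoch table and the uniformity of
#' the time grid (within 1 part in 1e6).
#'
#' @param path path of the data file.
#' @return A `current_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    stop(io_error(paste("trace data file not found:", path), "nmdarblock_missing_file"))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(io_error(paste("missing sidecar for trace:", path), "nmdarblock_missing_sidecar"))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$units) || !identical(meta$units$time, "s") ||
      !identical(meta$units$current, "pA"))
    stop(io_error(sprintf("unit mismatch in %s: expected time 's', current 'pA'", sc),
                  "nmdarblock_unit_mismatch"))
  dat <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "current_pA") %in% names(dat)))
    stop(io_error(paste("trace file lacks time_s/current_pA columns:", path),
                  "nmdarblock_bad_columns"))
  eps <- as.data.frame(meta$protocol$epochs)
  prot <- tryCatch(
    protocol(eps,
             holding_voltage = meta$protocol$holding_voltage,
             bapta_loaded = isTRUE(meta$protocol$bapta_loaded),
             total_duration = meta$protocol$total_duration,
             sample_rate = meta$protocol$sample_rate),
    error = function(e) stop(io_error(
      sprintf("invalid protocol in sidecar %s: %s", sc, conditionMessage(e)),
      "nmdarblock_epoch_error")))
  tr <- list(time = dat$time_s, current = dat$current_pA, protocol = prot,
             seed = if (is.null(meta$seed)) NULL else meta$seed,
             noise_sd = if (is.null(meta$noise_sd)) 0 else meta$noise_sd,
             units = list(time = "s", current = "pA"))
  class(tr) <- "current_trace"
  tryCatch(validate_trace(tr), error = function(e) stop(io_error(
    sprintf("%s: %s", path, conditionMessage(e)),
    class(e)[1])))
  tr
}

#' Build a manifest of the traces in a directory
#'
#' One record per sidecar found; the manifest carries the per-trace
#' recording condition (holding voltage, bath calcium of the first
#' epoch, BAPTA flag, seed) used to group traces for analysis.
#'
#' @param dir directory containing trace files written by [write_trace()].
#' @return Data frame with one row per trace.
#' @export
build_manifest <- function(dir) {
  sidecars <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  recs <- lapply(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(meta$protocol)) return(NULL)  # not a trace sidecar
    eps <- as.data.frame(meta$protocol$epochs)
    data.frame(file = sub("\\.json$", ".tsv", sc),
               vm = meta$protocol$holding_voltage,
               ca_out = eps$Ca_out[1],
               bapta = isTRUE(meta$protocol$bapta_loaded),
               seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
               n_epochs = nrow(eps))
  })
  do.call(rbind, recs)
}

#' Lint a directory of trace files
#'
#' Attempts to read every trace (data + sidecar) under `dir` and
#' collects per-file errors instead of stopping at the first.
#'
#' @param dir directory to validate.
#' @return Data frame with columns `file`, `ok`, `message`.
#' @export
validate_trace_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  res <- lapply(files, function(f) {
    msg <- tryCatch({ read_trace(f); "" }, error = function(e) conditionMessage(e))
    data.frame(file = f, ok = !nzchar(msg), message = msg)
  })
  do.call(rbind, res)
}
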