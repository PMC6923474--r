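test_that("write/read round-trip preserves samples and metadata exactly", {
  r <- rate_set()
  p <- protocol_block_step(50, baseline = 0.5, control_duration = 1,
                           on_duration = 1, off_duration = 1, sample_rate = 200)
  tr <- simulate_trace(r, p, noise_sd = 4, seed = 77)
  f <- file.path(withr::local_tempdir(), "trace.tsv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_identical(back$time, tr$time)
  expect_identical(back$current, tr$current)
  expect_equal(back$seed, 77)
  expect_equal(back$noise_sd, 4)
  expect_equal(back$protocol$epochs, tr$protocol$epochs)
  expect_equal(back$protocol$holding_voltage, -70)
})

test_that("a 20 kHz trace parses with a 5e-5 s step", {
  r <- rate_set()
  p <- protocol(rbind(solution_epoch(0, 0.02, Ca_out = 1),
                      solution_epoch(0.02, 0.05, NMDA = 100, Gly = 30, Ca_out = 1)),
                sample_rate = 20000)
  tr <- simulate_trace(r, p)
  f <- file.path(withr::local_tempdir(), "fast.tsv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(unique(round(diff(back$time), 12)), 5e-5)
})

test_that("missing sidecars, unit mismatches and bad epochs raise typed errors", {
  dir <- withr::local_tempdir()
  r <- rate_set()
  p <- protocol_block_step(50, baseline = 0.5, control_duration = 1,
                           on_duration = 1, off_duration = 1, sample_rate = 100)
  tr <- simulate_trace(r, p)
  f <- file.path(dir, "t.tsv")
  write_trace(tr, f)

  file.remove(nmdarblock:::sidecar_path(f))
  expect_error(read_trace(f), class = "nmdarblock_missing_sidecar")

  write_trace(tr, f)
  meta <- jsonlite::read_json(nmdarblock:::sidecar_path(f), simplifyVector = TRUE)
  meta$units$current <- "nA"
  jsonlite::write_json(meta, nmdarblock:::sidecar_path(f), auto_unbox = TRUE)
  expect_error(read_trace(f), class = "nmdarblock_unit_mismatch")

  meta$units$current <- "pA"
  meta$protocol$epochs$t_end[1] <- -1  # t_end < t_start
  jsonlite::write_json(meta, nmdarblock:::sidecar_path(f), auto_unbox = TRUE)
  expect_error(read_trace(f), class = "nmdarblock_epoch_error")
})

test_that("non-uniform sampling is rejected on read", {
  dir <- withr::local_tempdir()
  r <- rate_set()
  p <- protocol_block_step(50, baseline = 0.5, control_duration = 1,
                           on_duration = 1, off_duration = 1, sample_rate = 100)
  tr <- simulate_trace(r, p)
  f <- file.path(dir, "t.tsv")
  write_trace(tr, f)
  dat <- utils::read.table(f, header = TRUE, sep = "\t")
  dat$time_s[10] <- dat$time_s[10] + 2e-3
  utils::write.table(dat, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_trace(f), class = "nmdarblock_io_error")
})

test_that("the manifest counts one record per sidecar", {
  dir <- withr::local_tempdir()
  cfg <- study_config("staircase", rates = rate_set_pure_block(),
                      ca_levels = 0.25, n_cells = 2, noise_sd = 0,
                      atl_levels = c(30, 100, 300), sample_rate = 25)
  make_study_fixtures(cfg, seed = 5, out_dir = dir)
  man <- build_manifest(dir)
  expect_equal(nrow(man), 2)  # ground_truth.json is not a trace sidecar
  lint <- validate_trace_dir(dir)
  expect_true(all(lint$ok))
})
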