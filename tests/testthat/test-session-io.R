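test_that("recordings round-trip bit-exactly through the disk format", {
  s <- generate_session(synth_config(seed = 19, duration = 12))
  base <- file.path(withr::local_tempdir(), "rec1")
  write_recording(s$recording, base)
  back <- read_recording(base)
  expect_identical(back$samples, s$recording$samples)
  expect_equal(back$sampling_rate, s$recording$sampling_rate)
  expect_equal(back$metadata$subject, "sim")
  # writing again from the read copy is byte-identical
  base2 <- file.path(withr::local_tempdir(), "rec2")
  write_recording(back, base2)
  expect_identical(readBin(paste0(base2, ".bin"), "raw",
                           file.size(paste0(base2, ".bin"))),
                   readBin(paste0(base, ".bin"), "raw",
                           file.size(paste0(base, ".bin"))))
})

test_that("corrupt recording files raise descriptive errors", {
  s <- generate_session(synth_config(seed = 19, duration = 12))
  dir <- withr::local_tempdir()
  base <- file.path(dir, "rec")
  write_recording(s$recording, base)
  # payload truncated by one byte: error names expected and actual sizes
  sz <- file.size(paste0(base, ".bin"))
  raw <- readBin(paste0(base, ".bin"), "raw", sz)
  writeBin(raw[-length(raw)], paste0(base, ".bin"))
  expect_error(read_recording(base), paste0("expected ", sz))
  writeBin(raw, paste0(base, ".bin"))
  # header channel count inconsistent with the label list
  h <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  h$n_channels <- 3
  jsonlite::write_json(h, paste0(base, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(base), "inconsistency|mismatch")
  expect_error(read_recording(file.path(dir, "nothere")), "missing")
})

test_that("a full session and its manifest round-trip through disk", {
  s <- generate_session(synth_config(seed = 23, duration = 12))
  dir <- withr::local_tempdir()
  base <- file.path(dir, "sess")
  write_session(s, base)
  back <- read_session(base)
  expect_identical(back$recording$samples, s$recording$samples)
  expect_equal(back$stimulus, s$stimulus)
  expect_equal(back$manifest$true_threshold_db, 35)
  expect_equal(back$manifest$kernel$latency_slope, 6.9e-6)
})

test_that("session manifests validate recording counts per speaker side", {
  recs <- data.frame(recording = c("r1", "r2", "r3", "r4"),
                     speaker_side = c("L", "L", "R", "R"),
                     path = paste0("p", 1:4),
                     stimulus_path = paste0("s", 1:4))
  m <- session_manifest("m7", "2024-01-01", recs)
  path <- withr::local_tempfile(fileext = ".json")
  write_session_manifest(m, path)
  back <- read_session_manifest(path)
  expect_equal(back$subject, "m7")
  expect_equal(back$recordings$speaker_side, recs$speaker_side)
  expect_warning(session_manifest("m7", "d", recs[c(1, 3, 4), ]),
                 "fewer than 2")
})

test_that("configurations serialize to a JSON fixed point", {
  cfg <- pipeline_config()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  a <- readLines(path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(back, path2, auto_unbox = TRUE, digits = NA)
  expect_identical(readLines(path2), a)
})

test_that("the pipeline is deterministic and tags errors with the recording id", {
  s <- generate_session(synth_config(seed = 29, duration = 30))
  r1 <- run_pipeline(s)
  r2 <- run_pipeline(s)
  expect_identical(r1$thresholds, r2$thresholds)
  expect_identical(r1$strengths, r2$strengths)
  expect_identical(r1$log$config_hash, r2$log$config_hash)
  # stage failures carry the recording id
  bad <- s
  bad$stimulus$onset_sample <- bad$stimulus$onset_sample + 10^7
  expect_error(run_pipeline(bad), "recording 'r1'")
  expect_message(run_pipeline(list()), "empty")
})

test_that("pipeline results are written as microvolt CSV tables plus a log", {
  s <- generate_session(synth_config(seed = 29, duration = 30))
  dir <- file.path(withr::local_tempdir(), "out")
  r <- run_pipeline(s, out_dir = dir)
  st <- utils::read.csv(file.path(dir, "strengths.csv"))
  expect_true(all(c("strength_uV", "baseline_uV") %in% names(st)))
  expect_equal(sort(st$strength_uV), sort(r$strengths$strength * 1e6))
  th <- utils::read.csv(file.path(dir, "thresholds.csv"))
  expect_equal(nrow(th), 3)
  log <- jsonlite::read_json(file.path(dir, "run_log.json"),
                             simplifyVector = TRUE)
  expect_equal(log$package, "abrkit")
  expect_true(nzchar(log$config_hash))
})

test_that("a healthy simulated session yields thresholds near the ground truth", {
  r <- healthy_result()
  truth <- healthy_session()$manifest$true_threshold_db
  ears <- r$thresholds[r$thresholds$channel %in% c("LV", "RV"), ]
  expect_true(all(ears$censoring == "none"))
  expect_true(all(abs(ears$threshold_db - truth) <= 4))
})

test_that("the command-line interface simulates and reports end to end", {
  bin <- system.file("exec", "abrkit", package = "abrkit")
  if (!nzchar(bin)) bin <- system.file("../exec/abrkit", package = "abrkit")
  expect_true(nzchar(bin))
  dir <- withr::local_tempdir()
  base <- file.path(dir, "cli")
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(bin, "simulate", "--seed", "4", "--duration", "12",
                   "--out", base),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(paste0(base, ".bin")))
  expect_true(file.exists(paste0(base, ".stimulus.csv")))
  s <- read_session(base)
  expect_identical(s$manifest$seed, 4L)
})
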