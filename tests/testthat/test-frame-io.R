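make_trace <- function(seed = 1, noise = noise_model(), duration = 0.2) {
  generate_trace(hand_spec(),
                 motion_script(roll_amplitude_deg = 20,
                               spread_amplitude_deg = 15,
                               duration_s = duration),
                 noise, seed = seed)$trace
}

test_that("write then read round-trips every field", {
  set.seed(41)
  tr <- make_trace(seed = 42, noise = noise_model(0.5, 0.3))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_length(tr2, length(tr))
  expect_identical(attr(tr2, "n_skipped"), 0L)
  for (i in c(1L, length(tr))) {
    a <- tr$samples[[i]]; b <- tr2$samples[[i]]
    expect_identical(b$timestamp_us, a$timestamp_us)
    expect_identical(b$side, a$side)
    expect_equal(unclass(b$wrist_pose), unclass(a$wrist_pose),
                 tolerance = 1e-12)
    expect_setequal(b$graph$nodes, a$graph$nodes)
    for (f in setdiff(a$graph$nodes, "wrist")) {
      expect_equal(unclass(b$graph$edges[[f]]$transform),
                   unclass(a$graph$edges[[f]]$transform), tolerance = 1e-9)
    }
  }
})

test_that("serialization is canonical and byte-stable across a read", {
  tr <- make_trace(seed = 7)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  p3 <- withr::local_tempfile()
  write_trace(tr, p1)
  write_trace(tr, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))  # equal traces, equal bytes
  write_trace(read_trace(p1), p3)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p3, "raw", file.size(p3)))  # write-read-write
})

test_that("an empty trace yields a header-only file and reads back empty", {
  path <- withr::local_tempfile()
  write_trace(motion_trace(), path)
  expect_length(readLines(path), 1L)
  tr <- read_trace(path)
  expect_length(tr, 0L)
  expect_identical(attr(tr, "n_skipped"), 0L)
})

test_that("corrupted lines abort in strict mode and are counted in lenient mode", {
  tr <- make_trace(seed = 8, duration = 1.64)  # ~100 frames
  path <- withr::local_tempfile()
  write_trace(tr, path)
  lines <- readLines(path)
  lines[51] <- substr(lines[51], 1, 40)  # truncate frame 50 mid-object
  writeLines(lines, path)
  expect_error(read_trace(path), "line 51")
  lenient <- read_trace(path, strict = FALSE)
  expect_identical(attr(lenient, "n_malformed"), 1L)
  expect_length(lenient, length(tr) - 1L)
})

test_that("schema versions, hand-less frames and extra fields follow the contract", {
  tr <- make_trace(seed = 9)
  path <- withr::local_tempfile()
  write_trace(tr, path)
  lines <- readLines(path)

  bad <- sub('"schema_version":"1.0"', '"schema_version":"9.9"', lines[1])
  p2 <- withr::local_tempfile()
  writeLines(c(bad, lines[-1]), p2)
  expect_error(read_trace(p2), "schema_version")

  # a frame without a tracked hand is skipped and counted
  writeLines(c(lines[1], '{"timestamp_us":0,"side":"right"}', lines[-1]),
             p2)
  tr2 <- read_trace(p2)
  expect_identical(attr(tr2, "n_skipped"), 1L)
  expect_length(tr2, length(tr))

  # unknown extra fields are tolerated
  extra <- sub('"side":"right"', '"side":"right","confidence":0.93', lines[2])
  writeLines(c(lines[1], extra, lines[-(1:2)]), p2)
  expect_length(read_trace(p2), length(tr))

  # timestamp regression is an ordering error
  writeLines(c(lines[1], lines[3], lines[2]), p2)
  expect_error(read_trace(p2), "regression")
})

test_that("results export has fixed columns and rejects mixed units", {
  one <- data.frame(participant = "P01", device = "lm", hand_side = "right",
                    hand_part = "hand_length", repetition = 1L,
                    value = 154.2, units = "mm")
  path <- withr::local_tempfile(fileext = ".csv")
  export_results(one, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  expect_match(lines[1],
               "^\"participant\",\"device\",\"hand_side\",\"hand_part\",\"repetition\",\"value\",\"units\"$")
  expect_identical(read_results(path)$value, 154.2)

  mixed <- rbind(one, transform(one, repetition = 2L, units = "deg"))
  expect_error(export_results(mixed, path), "mixed units")
  expect_error(export_results(one[, -3], path), "missing columns")
})

test_that("the full study design exports 525 rows", {
  # 5 participants x 15 repetitions x 7 hand parts
  grid <- expand.grid(participant = sprintf("P%02d", 1:5),
                      repetition = 1:15,
                      hand_part = c("thumb_length", "index_length",
                                    "middle_length", "ring_length",
                                    "pinky_length", "hand_length",
                                    "hand_width"),
                      stringsAsFactors = FALSE)
  grid$device <- "lm"; grid$hand_side <- "right"
  grid$value <- seq_len(nrow(grid)); grid$units <- "mm"
  path <- withr::local_tempfile(fileext = ".csv")
  export_results(grid, path)
  expect_length(readLines(path), 525L + 1L)
})
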