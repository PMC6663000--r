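test_that("write/read roundtrip preserves counts, channels, values and metadata", {
  set.seed(7)
  ev <- matrix(rexp(500 * 3, rate = 1e-4), 500, 3)
  tb <- event_table(ev, c("SSC-A", "FL1-A", "FSC-A"),
                    metadata = list(sample_id = "mix/1:1", strain = "Bs02003",
                                    time_h = 48, replicate = "r2"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tb, path)
  back <- read_fcs(path)
  expect_equal(n_events(back), 500)
  expect_identical(channels(back), channels(tb))  # order preserved
  # data stored as float32: relative error bounded by 2^-23
  expect_lt(max(abs(back$events - tb$events) / pmax(abs(tb$events), 1)),
            2^-22)
  expect_identical(back$metadata$sample_id, "mix/1:1")  # delimiter escaping
  expect_identical(back$metadata$strain, "Bs02003")
  expect_equal(back$metadata$time_h, 48)
})

test_that("an empty (0-event) file roundtrips with channels intact", {
  tb <- event_table(matrix(numeric(0), 0, 2), c("FSC-A", "FL1-A"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tb, path)
  back <- read_fcs(path)
  expect_equal(n_events(back), 0)
  expect_identical(channels(back), c("FSC-A", "FL1-A"))
})

test_that("a simulated culture written to FCS keeps the configured event count", {
  cfg <- synth_config(n_events = 100000L, seed = 5)
  sim <- simulate_culture(cfg)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(sim$table, path)
  expect_equal(n_events(read_fcs(path)), 100000L)
})

test_that("malformed inputs raise format errors", {
  expect_error(write_fcs(event_table(matrix(numeric(0), 3, 0),
                                     character(0)), tempfile()),
               "unique|zero channels|channel")
  bad <- withr::local_tempfile(fileext = ".fcs")
  writeLines("this is not an fcs file, just text padded to length", bad)
  expect_error(read_fcs(bad), "unsupported FCS version|truncated")
  # truncate a valid file inside the DATA segment
  tb <- event_table(matrix(runif(400, 1, 100), 100, 4),
                    c("FSC-A", "FSC-H", "SSC-A", "FL1-A"))
  good <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tb, good)
  raw <- readBin(good, "raw", file.size(good))
  cut <- withr::local_tempfile(fileext = ".fcs")
  writeBin(raw[1:(length(raw) - 150)], cut)
  expect_error(read_fcs(cut), "truncated")
  expect_error(read_fcs(tempfile()), "not found")
})

test_that("subsampling returns tables unchanged below the cap and exact draws above it", {
  tb <- event_table(matrix(rnorm(50 * 2), 50, 2), c("A", "B"))
  expect_identical(subsample_events(tb, 100, seed = 1), tb)

  big <- event_table(matrix(rnorm(1e6), ncol = 1), "FL1-A")
  sub <- subsample_events(big, 1e5, seed = 3)
  expect_equal(n_events(sub), 1e5)
  # determinism
  sub2 <- subsample_events(big, 1e5, seed = 3)
  expect_identical(sub$events, sub2$events)
  sub3 <- subsample_events(big, 1e5, seed = 4)
  expect_false(identical(sub$events, sub3$events))
  expect_error(subsample_events(tb, 0), "n_max")
})

test_that("subsampling preserves per-channel means within 3 standard errors", {
  cfg <- synth_config(n_events = 50000L, seed = 11)
  tb <- simulate_culture(cfg)$table
  sub <- subsample_events(tb, 5000L, seed = 2)
  for (ch in channels(tb)) {
    full <- channel_values(tb, ch)
    drawn <- channel_values(sub, ch)
    se <- stats::sd(full) / sqrt(length(drawn))
    expect_lt(abs(mean(drawn) - mean(full)), 3 * se)
  }
})

test_that("sample sheets are validated and paths resolved relative to the sheet", {
  dir <- withr::local_tempdir()
  sheet_path <- file.path(dir, "samples.csv")
  write.csv(data.frame(sample_id = c("a", "b"),
                       path = c("a.fcs", file.path(dir, "b.fcs")),
                       strain = "X", time_h = c(48, 56), replicate = 1),
            sheet_path, row.names = FALSE)
  sheet <- read_sample_sheet(sheet_path)
  expect_equal(sheet$path[1], file.path(dir, "a.fcs"))
  expect_equal(sheet$path[2], file.path(dir, "b.fcs"))
  expect_equal(sheet$time_h, c(48, 56))

  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(sample_id = "a"), bad, row.names = FALSE)
  expect_error(read_sample_sheet(bad), "missing column")
  dup <- file.path(dir, "dup.csv")
  write.csv(data.frame(sample_id = c("a", "a"), path = "x"), dup,
            row.names = FALSE)
  expect_error(read_sample_sheet(dup), "duplicated")
})

test_that("event tables enforce their invariants", {
  expect_error(event_table(matrix(1:4, 2, 2), c("A", "A")), "unique")
  expect_error(event_table(matrix(c(1, NA), 1, 2), c("A", "B")), "missing")
  tb <- event_table(matrix(1:6, 3, 2), c("A", "B"))
  expect_equal(channel_values(tb, "B"), c(4, 5, 6))
  expect_error(channel_values(tb, "C"), "unknown channel")
  expect_error(subset_events(tb, c(TRUE, FALSE)), "length")
})
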