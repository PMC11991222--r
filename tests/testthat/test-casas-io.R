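test_that("annotated and plain lines parse into events per the CASAS dialect", {
  f <- write_log_lines(c(
    "2010-11-04 00:03:50.209589 M003 ON Sleeping begin",
    "2010-11-04 00:03:57 M003 OFF"))
  ev <- read_events(f)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$sensor_id, c("M003", "M003"))
  expect_equal(ev$value, c("ON", "OFF"))
  expect_equal(ev$activity, c("Sleeping", NA))
  expect_equal(ev$boundary, c("begin", NA))
  expect_equal(format_casas_time(ev$timestamp[1]),
               "2010-11-04 00:03:50.209589")
  expect_equal(attr(ev, "skipped_lines"), 0L)
})

test_that("fused Activity=begin annotations are normalized", {
  ev <- read_events(write_log_lines(
    "2010-11-04 08:00:00 M001 ON Eating=begin"))
  expect_equal(ev$activity, "Eating")
  expect_equal(ev$boundary, "begin")
})

test_that("malformed lines are skipped, counted and warned about", {
  f <- write_log_lines(c(
    "2010-11-04 00:03:50 M003 ON",
    "not-a-date garbage M003 ON",
    "2010-11-04 00:04:00 M004 OFF"))
  expect_warning(ev <- read_events(f), "skipped 1")
  expect_equal(nrow(ev), 2)
  expect_equal(attr(ev, "skipped_lines"), 1L)
  expect_error(read_events(tempfile()), "cannot read")
})

test_that("out-of-order timestamps are stable-sorted with a warning", {
  f <- write_log_lines(c(
    "2010-11-04 00:05:00 M001 ON",
    "2010-11-04 00:03:00 M002 ON"))
  expect_warning(ev <- read_events(f), "out of chronological order")
  expect_equal(ev$sensor_id, c("M002", "M001"))
  expect_true(attr(ev, "reordered"))
})

test_that("label_events applies interval semantics with Other outside", {
  ev <- toy_events()
  lab <- label_events(ev)
  expect_equal(lab$label, c("Other", "A", "A", "A", "Other"))
  expect_equal(nrow(lab), nrow(ev))
})

test_that("the innermost interval wins on overlapping annotations", {
  f <- write_log_lines(c(
    "2010-11-04 00:01:00 M001 ON",
    "2010-11-04 00:02:00 M001 ON A begin",
    "2010-11-04 00:03:00 M001 ON B begin",
    "2010-11-04 00:04:00 M001 ON B end",
    "2010-11-04 00:05:00 M001 ON A end"))
  lab <- label_events(read_events(f))
  expect_equal(lab$label, c("Other", "A", "B", "B", "A"))
})

test_that("stray end is ignored and unclosed begin auto-closes, with warnings", {
  f <- write_log_lines(c(
    "2010-11-04 00:01:00 M001 ON A end",
    "2010-11-04 00:02:00 M001 ON B begin",
    "2010-11-04 00:03:00 M001 OFF"))
  ev <- read_events(f)
  expect_warning(expect_warning(lab <- label_events(ev), "no open 'begin'"),
                 "auto-closed")
  expect_equal(lab$label, c("Other", "B", "B"))
})

test_that("empty stream labels to an empty result", {
  ev <- toy_events()[0, ]
  class(ev) <- c("casas_events", "data.frame")
  expect_equal(nrow(label_events(ev)), 0)
})

test_that("write then read is the identity, microseconds included", {
  ev <- toy_events()
  f <- tempfile()
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(format_casas_time(back$timestamp), format_casas_time(ev$timestamp))
  expect_equal(back$sensor_id, ev$sensor_id)
  expect_equal(back$value, ev$value)
  expect_equal(back$activity, ev$activity)
  expect_equal(back$boundary, ev$boundary)
  # empty stream -> empty file
  f2 <- tempfile()
  write_events(ev[0, ], f2)
  expect_equal(length(readLines(f2)), 0)
})

test_that("round-trip holds across random streams and labels stay in the set", {
  for (seed in 1:5) {
    ev <- random_events(40, seed)
    f <- tempfile()
    write_events(ev, f)
    back <- read_events(f)
    expect_equal(format_casas_time(back$timestamp),
                 format_casas_time(ev$timestamp))
    expect_identical(back$sensor_id, ev$sensor_id)
    expect_identical(back$value, ev$value)
    expect_identical(back$activity, ev$activity)
    lab <- label_events(back)
    expect_equal(length(lab$label), nrow(ev))
    expect_true(all(lab$label %in% c("Cooking", "Other")))
  }
})
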