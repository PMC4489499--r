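test_that("a simple stream parses into one stroke and preserves event order", {
  rec <- make_record(list(
    e_start(), e_color(0.2, "red"), e_tool(0.3, "pencil"),
    e_down(1.0, 1, 1), e_move(1.5, 2, 1), e_up(2.0, 3, 1), e_end(5)))
  expect_equal(nrow(rec$events), 7)
  strokes <- extract_strokes(rec)
  expect_length(strokes, 1)
  expect_equal(strokes[[1]]$color, "red")
  expect_equal(strokes[[1]]$tool, "pencil")
  expect_equal(strokes[[1]]$samples$t, c(1.0, 1.5, 2.0))
})

test_that("stream invariant violations are rejected with the offending event named", {
  expect_error(make_record(list(e_start(), e_move(1, 1, 1), e_end(2))),
               "event 2.*pen_move outside a stroke")
  expect_error(make_record(list(e_start(), e_down(1, 1, 1), e_down(2, 2, 2))),
               "pen_down inside an open stroke")
  expect_error(make_record(list(e_start(), e_color(1, "turquoise"), e_end(2))),
               "unknown color")
  expect_error(make_record(list(e_start(), e_down(2, 1, 1), e_up(1, 1, 1))),
               "decreasing timestamp")
  expect_error(make_record(list(e_start(), e_down(1, 99, 1), e_up(2, 99, 1))),
               "outside the page")
  expect_error(make_record(list(e_down(0, 1, 1), e_up(1, 1, 1))),
               "session_start")
})

test_that("write/read round-trips are identities and writes are byte-stable", {
  rec <- make_record(list(
    e_start(), e_color(0.5, "blue"), e_tool(0.5, "oils"),
    e_down(1, 1.25, 2.5, 0.7), e_move(1.37, 3.141593, 2.71828, 0.65),
    e_up(2, 4, 4, 0.6), e_end(6.5)),
    meta = session_meta("s1", groups = list(gender = "F"), task = "positive"))
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_session(rec, f1)
  back <- read_session(f1)
  expect_equal(back$events, rec$events)
  expect_equal(back$geometry, rec$geometry)
  expect_equal(back$config, rec$config)
  expect_equal(back$meta$groups, rec$meta$groups)
  write_session(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # write -> read -> write of the same record twice is byte-identical
  f3 <- tempfile(fileext = ".jsonl")
  write_session(rec, f3)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f3, "raw", file.size(f3)))
})

test_that("malformed files raise parse errors naming the line", {
  f <- tempfile()
  writeLines(c("{not json", "{}"), f)
  expect_error(read_session(f), "line 1")
  rec <- make_record(list(e_start(), e_end(1)))
  f2 <- tempfile()
  write_session(rec, f2)
  lines <- readLines(f2)
  writeLines(c(lines, "{\"kind\":\"pen_up\"}"), f2)
  expect_error(read_session(f2), "line 4")
})

test_that("non-finite coordinates are refused at write time", {
  rec <- make_record(list(e_start(), e_down(1, 1, 1), e_up(2, 2, 2), e_end(3)))
  rec$events$x[2] <- NaN
  expect_error(write_session(rec, tempfile()), "event|non-finite|missing")
})

test_that("stroke extraction handles defaults, truncation and the eraser", {
  # defaults before any selection, with a warning
  rec <- make_record(list(e_start(), e_down(1, 1, 1), e_up(2, 2, 2), e_end(3)))
  expect_warning(strokes <- extract_strokes(rec), "defaulting")
  expect_equal(strokes[[1]]$color, DEFAULT_PALETTE[1])
  expect_equal(strokes[[1]]$tool, DEFAULT_TOOLSET[1])

  # eraser selection applies to the following stroke
  rec2 <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.2, "pencil"),
    e_down(1, 1, 1), e_up(2, 2, 2),
    e_down(3, 3, 3), e_up(4, 4, 4),
    e_tool(5, "eraser"),
    e_down(6, 5, 5), e_up(7, 6, 6), e_end(8)))
  strokes2 <- extract_strokes(rec2)
  expect_length(strokes2, 3)
  expect_equal(strokes2[[3]]$tool, "eraser")
  expect_equal(vapply(strokes2, function(s) s$color, ""), rep("red", 3))

  # stream ending inside an open stroke closes at the last sample
  rec3 <- make_record(list(e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
                           e_down(1, 1, 1), e_move(2, 2, 2)))
  expect_warning(strokes3 <- extract_strokes(rec3), "open stroke")
  expect_length(strokes3, 1)
  expect_equal(nrow(strokes3[[1]]$samples), 2)

  # single-point stroke has length zero
  rec4 <- make_record(list(e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
                           e_down(1, 2, 2), e_up(1, 2, 2), e_end(2)))
  strokes4 <- extract_strokes(rec4)
  expect_equal(stroke_length(strokes4[[1]]), 0)
})

test_that("the installed demo session loads and validates", {
  path <- system.file("extdata", "three_object_synthetic.jsonl",
                      package = "strokechart")
  expect_true(nzchar(path))
  rec <- read_session(path)
  expect_equal(sum(rec$events$kind == "pen_down"), 13)
  expect_equal(rec$geometry$width, 28)
  m <- compute_metrics(rec)
  expect_equal(m$stroke_count, 13)
})

test_that("every pen sample belongs to exactly one stroke", {
  set.seed(7)
  out <- random_session(sample_rate = 30)
  strokes <- extract_strokes(out$record)
  n_pen <- sum(out$record$events$kind %in% c("pen_down", "pen_move", "pen_up"))
  expect_equal(sum(vapply(strokes, function(s) nrow(s$samples), 0L)), n_pen)
  expect_equal(length(strokes), sum(out$record$events$kind == "pen_down"))
  expect_equal(length(strokes), sum(out$record$events$kind == "pen_up"))
})
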