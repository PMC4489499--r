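test_that("stroke length sums consecutive sample distances", {
  st <- structure(list(samples = data.frame(t = 0:2, x = c(0, 3, 6),
                                            y = c(0, 4, 8),
                                            pressure = rep(0.5, 3)),
                       color = "red", tool = "pencil", t_start = 0, t_end = 2),
                  class = "stroke")
  expect_equal(stroke_length(st), 10)
  # noisy 1000-sample arc equals the naive pairwise sum
  set.seed(31)
  n <- 1000
  th <- seq(0, pi, length.out = n)
  x <- 10 + 5 * cos(th) + rnorm(n, 0, 0.01)
  y <- 10 + 5 * sin(th) + rnorm(n, 0, 0.01)
  st2 <- structure(list(samples = data.frame(t = seq(0, 5, length.out = n),
                                             x = x, y = y, pressure = 0.5),
                        color = "red", tool = "pencil", t_start = 0, t_end = 5),
                   class = "stroke")
  brute <- 0
  for (i in 2:n) brute <- brute + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  expect_equal(stroke_length(st2), brute, tolerance = 1e-12)
})

test_that("session kinematics aggregate as documented", {
  rec <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
    e_down(1, 1, 1, 0.7), e_up(3, 11, 1, 0.7),        # 10 cm in 2 s
    e_down(5, 1, 3, 0.7), e_up(7, 1, 19.5, 0.7),      # 16.5 cm in 2 s
    e_end(8)), geometry = page_geometry(20, 20))
  kin <- session_kinematics(extract_strokes(rec))
  expect_equal(kin$total_stroke_length, 26.5)
  expect_equal(kin$avg_velocity, 26.5 / 4)
  expect_equal(kin$avg_stroke_length, 13.25)
  expect_equal(kin$strokes_per_second, 0.5)
  expect_equal(kin$avg_pressure, 0.7)     # constant pressure everywhere
  # avg_velocity * total in-stroke time = total length
  expect_equal(kin$avg_velocity * kin$drawing_time, kin$total_stroke_length)
})

test_that("the scripted two-stroke session recovers hand-computed kinematics", {
  scripts <- list(
    stroke_script("line", from = c(2, 2), to = c(12, 2), speed = 5,
                  pressure = 0.5, color = "red", tool = "pencil", pre_gap = 1),
    stroke_script("line", from = c(2, 6), to = c(22, 6), speed = 10,
                  pressure = 0.5, color = "red", tool = "pencil", pre_gap = 1))
  out <- realize_scripts(scripts, geometry = page_geometry(28, 16),
                         sample_rate = 100)
  m <- compute_metrics(out$record)
  expect_equal(m$avg_velocity, 7.5, tolerance = 1e-4)
  expect_equal(m$avg_stroke_length, 15, tolerance = 1e-4)
  expect_equal(m$strokes_per_second, 0.5, tolerance = 1e-4)
})

test_that("occupancy splits conserve and classify single-category sessions", {
  rec <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.2, "pencil"),
    e_down(1, 2, 2), e_move(2.5, 4, 2), e_up(4, 4, 4), e_end(9)),
    geometry = page_geometry(20, 16))
  m <- compute_metrics(rec)
  expect_equal(m$drawing_pct, 100 / 3, tolerance = 1e-9)
  expect_equal(m$idle_pct, 200 / 3, tolerance = 1e-9)
  # whole drawing time in red pencil in the top-left quarter
  expect_equal(m$colors$pct[m$colors$color == "red"], 100)
  expect_equal(m$tools$pct[m$tools$tool == "pencil"], 100)
  expect_equal(m$quarters$pct[m$quarters$quarter == "Q1"], 100)
  cs <- m$cross_sections
  expect_equal(cs$time[cs$color == "red" & cs$tool == "pencil"],
               m$drawing_time)
})

test_that("eraser time is its own pseudo-color, excluded from real colors", {
  rec <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.2, "pencil"),
    e_down(1, 2, 2), e_up(3, 6, 2),
    e_tool(3.5, "eraser"),
    e_down(4, 2, 2), e_up(5, 4, 2),
    e_end(6)), geometry = page_geometry(20, 16))
  m <- compute_metrics(rec)
  expect_equal(m$colors$time_s[m$colors$color == "erase"], 1)
  expect_equal(m$colors$time_s[m$colors$color == "red"], 2)
  expect_equal(m$erase_time_pct, 100 / 3, tolerance = 1e-9)
  expect_equal(sum(m$colors$pct), 100)
})

test_that("switch counts follow the stroke sequence", {
  mk <- function(colors, tools) {
    lapply(seq_along(colors), function(i)
      structure(list(samples = data.frame(t = i, x = 1, y = 1, pressure = 0.5),
                     color = colors[i], tool = tools[i],
                     t_start = i, t_end = i), class = "stroke"))
  }
  cfg <- studio_config()
  sw <- switch_counts(mk(c("red", "red", "blue", "red"), rep("pencil", 4)), cfg)
  expect_equal(sw$color_switches, 2)
  expect_equal(sw$switches_per_color, 1.0)
  expect_equal(sw$tool_switches, 0)
  expect_equal(sw$colors_used_pct, 20)

  # random 50-stroke sequence equals the brute-force pairwise count
  set.seed(13)
  cols <- sample(cfg$palette, 50, replace = TRUE)
  tls <- sample(setdiff(cfg$toolset, "eraser"), 50, replace = TRUE)
  sw2 <- switch_counts(mk(cols, tls), cfg)
  brute_c <- 0; brute_t <- 0
  for (i in 2:50) {
    if (cols[i] != cols[i - 1]) brute_c <- brute_c + 1
    if (tls[i] != tls[i - 1]) brute_t <- brute_t + 1
  }
  expect_equal(sw2$color_switches, brute_c)
  expect_equal(sw2$tool_switches, brute_t)
})

test_that("midline crossings and start crossovers count correctly", {
  geo <- page_geometry(20, 16)
  # straight stroke crossing the horizontal midline once
  rec <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
    e_down(1, 5, 4), e_move(2, 5, 7), e_move(3, 5, 10), e_up(4, 5, 12),
    e_end(5)), geometry = geo)
  m <- compute_metrics(rec)
  expect_equal(m$stroke_crossovers_h, 1)
  expect_equal(m$stroke_crossovers_v, 0)
  # second stroke starting in the quarter below the first stroke's end
  rec2 <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
    e_down(1, 5, 4), e_up(2, 6, 4),          # ends in Q1
    e_down(3, 5, 12), e_up(4, 6, 12),        # starts in Q2 (adjacent)
    e_down(5, 15, 12), e_up(6, 16, 12),      # starts in Q4 (adjacent to Q2)
    e_down(7, 15, 4), e_up(8, 16, 4),        # Q3, adjacent to Q4
    e_end(9)), geometry = geo)
  m2 <- compute_metrics(rec2)
  expect_equal(m2$stroke_start_crossovers, 3)
  # diagonal jump Q1 -> Q4 is not a crossover
  rec3 <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
    e_down(1, 5, 4), e_up(2, 5, 4),
    e_down(3, 15, 12), e_up(4, 15, 12),
    e_end(5)), geometry = geo)
  expect_equal(compute_metrics(rec3)$stroke_start_crossovers, 0)
})

test_that("area coverage equals the naive pixel-count oracle", {
  geo <- page_geometry(20, 20)
  cfg <- studio_config(raster_cell = 0.5, tool_widths = c(pencil = 0.6))
  rec <- make_record(list(
    e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
    e_down(1, 5, 10.13), e_up(3, 15, 10.13),
    e_down(4, 10.07, 5), e_up(6, 10.07, 15),
    e_end(7)), geometry = geo, config = cfg)
  m <- compute_metrics(rec)
  strokes <- extract_strokes(rec)
  expect_equal(m$area_used_pct, oracle_coverage_pct(strokes, geo, cfg))
  expect_gt(m$area_used_pct, 0)
})

test_that("area estimate approaches the analytic capsule area as cells shrink", {
  geo <- page_geometry(20, 20)
  analytic <- (10 * 0.2 + pi * 0.1^2) / 400 * 100
  est <- vapply(c(0.4, 0.1, 0.04), function(cell) {
    cfg <- studio_config(raster_cell = cell, tool_widths = c(pencil = 0.2))
    rec <- make_record(list(
      e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
      e_down(1, 5.03, 10.11), e_up(3, 15.03, 10.11), e_end(4)),
      geometry = geo, config = cfg)
    compute_metrics(rec)$area_used_pct
  }, 0)
  err <- abs(est - analytic)
  expect_lt(err[3], err[1])
  expect_lt(err[3] / analytic, 0.10)
})

test_that("adding a stroke never decreases count, length or coverage", {
  set.seed(17)
  base <- list(
    e_start(), e_color(0.1, "red"), e_tool(0.1, "pencil"),
    e_down(1, 2, 2), e_up(2, 8, 8))
  rec1 <- make_record(c(base, list(e_end(10))))
  rec2 <- make_record(c(base, list(e_down(3, 12, 12), e_up(4, 18, 12), e_end(10))))
  m1 <- compute_metrics(rec1); m2 <- compute_metrics(rec2)
  expect_gte(m2$stroke_count, m1$stroke_count)
  expect_gte(m2$total_stroke_length, m1$total_stroke_length)
  expect_gte(m2$area_used_pct, m1$area_used_pct)
})

test_that("an empty session yields zero counts and a 0/100 split", {
  rec <- make_record(list(e_start(), e_end(5)))
  m <- compute_metrics(rec)
  expect_equal(m$stroke_count, 0)
  expect_equal(m$drawing_pct, 0)
  expect_equal(m$idle_pct, 100)
  expect_equal(m$total_stroke_length, 0)
  expect_true(m$degenerate)
})

test_that("trace-derived occupancy equals the direct stroke-derived oracle", {
  set.seed(19)
  out <- random_session(sample_rate = 30)
  m <- compute_metrics(out$record)
  want <- oracle_occupancy(out$record)
  expect_equal(m$drawing_time, want$drawing_time, tolerance = 1e-9)
  expect_equal(m$selecting_time, want$selecting_time, tolerance = 1e-9)
  expect_equal(structure(m$colors$time_s, names = m$colors$color),
               want$color_time, tolerance = 1e-9)
  expect_equal(structure(m$tools$time_s, names = m$tools$tool),
               want$tool_time, tolerance = 1e-9)
  expect_equal(structure(m$quarters$time_s, names = m$quarters$quarter),
               want$quarter_time, tolerance = 1e-9)
  expect_equal(structure(m$parts$time_s, names = m$parts$part),
               want$part_time, tolerance = 1e-9)
})

test_that("session comparison is an identity on itself and schema-complete", {
  fx <- bundled_fixtures(sample_rate = 25)
  a <- compute_metrics(fx$three_object$record)
  cmp <- compare_sessions(a, a)
  expect_true(all(cmp$difference == 0))
  expect_true(all(cmp$ratio == 1))
  expect_equal(nrow(cmp), length(metrics_row(a)))
  b <- compute_metrics(fx$vertical_mass$record)
  cmp2 <- compare_sessions(a, b)
  dp <- cmp2[cmp2$metric == "drawing_pct", ]
  expect_equal(dp$difference, a$drawing_pct - b$drawing_pct)
  # mismatched configurations are refused
  cfg2 <- studio_config(palette = c("red", "blue"))
  rec2 <- make_record(list(e_start(), e_end(1)), config = cfg2)
  expect_error(compare_sessions(a, compute_metrics(rec2)), "configuration")
})
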