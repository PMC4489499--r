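test_that("a line realizes with the documented duration and sample count", {
  s <- stroke_script("line", from = c(0.5, 0.5), to = c(10.5, 0.5), speed = 5,
                     pressure = 0.5, color = "red", tool = "pencil", pre_gap = 1)
  out <- realize_scripts(list(s), sample_rate = 50)
  strokes <- extract_strokes(out$record)
  expect_length(strokes, 1)
  samp <- strokes[[1]]$samples
  expect_equal(nrow(samp), 101)
  expect_equal(samp$t[nrow(samp)] - samp$t[1], 2.0)
  expect_equal(out$truth$total_stroke_length, 10)
  expect_equal(stroke_length(strokes[[1]]), 10, tolerance = 1e-9)
})

test_that("a finely sampled circle's polyline length approaches 2*pi*r", {
  s <- stroke_script("circle_arc", center = c(10, 8), radius = 3,
                     theta_start = 0, theta_end = 360, speed = 5,
                     pressure = 0.5, color = "red", tool = "pencil")
  out <- realize_scripts(list(s), sample_rate = 100)
  sampled <- stroke_length(extract_strokes(out$record)[[1]])
  expect_equal(out$truth$total_stroke_length, 2 * pi * 3, tolerance = 1e-12)
  expect_lt(abs(sampled - 2 * pi * 3) / (2 * pi * 3), 0.001)
})

test_that("script-sequence switch counts appear in the ground truth", {
  scripts <- list(
    stroke_script("line", from = c(2, 2), to = c(6, 2), color = "red",
                  tool = "pencil", pre_gap = 1),
    stroke_script("line", from = c(2, 4), to = c(6, 4), color = "blue",
                  tool = "pencil", pre_gap = 1))
  gt <- ground_truth_scripts(scripts)
  expect_equal(gt$color_switches, 1)
  expect_equal(gt$tool_switches, 0)
  expect_equal(gt$stroke_count, 2)
})

test_that("realization is deterministic: same scripts give identical bytes", {
  fx1 <- bundled_fixtures(sample_rate = 25)
  fx2 <- bundled_fixtures(sample_rate = 25)
  f1 <- tempfile(); f2 <- tempfile()
  write_session(fx1$three_object$record, f1)
  write_session(fx2$three_object$record, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the generated cohort has the study shape and is seed-stable", {
  spec <- cohort_spec(groups = c("F", "M"), subjects_per_group = 6,
                      tasks = c("positive", "negative", "htp"),
                      params = session_params(stroke_count_mean = 3),
                      seed = 99)
  coh1 <- generate_cohort(spec, sample_rate = 25)
  expect_length(coh1$records, 36)
  subj <- vapply(coh1$records, function(r) r$meta$subject, "")
  expect_equal(length(unique(subj)), 12)
  coh2 <- generate_cohort(spec, sample_rate = 25)
  f1 <- tempfile(); f2 <- tempfile()
  write_session(coh1$records[[17]], f1)
  write_session(coh2$records[[17]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("bundled fixtures match their narrative ground truth", {
  fx <- bundled_fixtures(sample_rate = 50)
  # vertical mass: crossovers overwhelmingly horizontal, vertical sectors
  gt <- fx$vertical_mass$truth
  expect_gt(gt$stroke_crossovers_h, 20)
  expect_equal(gt$stroke_crossovers_v, 0)
  tr <- run_statechart(fx$vertical_mass$record)
  grad <- tr[tr$region == "Gradient", ]
  vert <- grad$state %in% c("Gradient:N", "Gradient:S")
  expect_gt(sum((grad$t_end - grad$t_start)[vert]) /
              sum(grad$t_end - grad$t_start), 0.95)
  expect_lt(abs(gt$avg_gradient), 10)
  # empty session
  expect_equal(fx$empty$truth$drawing_pct, 0)
  expect_equal(compute_metrics(fx$empty$record)$drawing_pct, 0)
  # single dot: one zero-length stroke
  m_dot <- compute_metrics(fx$single_dot$record)
  expect_equal(m_dot$stroke_count, 1)
  expect_equal(m_dot$total_stroke_length, 0)
  # three-object: exactly one contiguous run of eraser strokes
  tools <- vapply(fx$three_object$scripts, function(s) s$tool, "")
  runs <- rle(tools == "eraser")
  expect_equal(sum(runs$values), 1)
})

test_that("planted speed differences show in cohort averages", {
  spec <- cohort_spec(groups = c("A", "B"), subjects_per_group = 4,
                      tasks = "free",
                      params = session_params(stroke_count_mean = 6,
                                              speed_sigma = 0.3),
                      group_overrides = list(A = list(speed_median = 19.2)),
                      seed = 7)
  coh <- generate_cohort(spec, sample_rate = 25)
  frame <- aggregate_sessions(coh$records)
  ratio <- mean(frame$avg_velocity[frame$gender == "A"]) /
    mean(frame$avg_velocity[frame$gender == "B"])
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})
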