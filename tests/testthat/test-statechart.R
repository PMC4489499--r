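test_that("the artwork model reflects the configured palette and toolset", {
  model <- build_artwork_model(studio_config())
  idx <- model_regions(model)
  expect_equal(sum(idx$parent == "Color", na.rm = TRUE), 10)
  expect_equal(sum(idx$parent == "Tool", na.rm = TRUE), 6)
  expect_equal(sum(idx$parent == "Gradient", na.rm = TRUE), 8)
  small <- build_artwork_model(studio_config(palette = "red",
                                             toolset = c("pencil", "eraser")))
  idx2 <- model_regions(small)
  expect_equal(sum(idx2$parent == "Color", na.rm = TRUE), 1)
  # exclusive ArtWork children
  expect_setequal(idx$name[idx$parent == "ArtWork" & !is.na(idx$parent)],
                  c("Idle", "Materials_Selecting", "Painting"))
})

test_that("step follows the modeled transitions", {
  cfg <- studio_config()
  geo <- page_geometry(20, 20)
  model <- build_artwork_model(cfg)
  c0 <- step(model, character(0), list(kind = "session_start"),
             config = cfg, geometry = geo)
  expect_true(all(c("ArtRoomSessionOn", "ArtWork", "Idle") %in% c0))
  expect_true(isTRUE(configuration_consistent(model, c0)))

  c1 <- step(model, c0, list(kind = "select_color", color = "blue"),
             config = cfg, geometry = geo)
  expect_true("Materials_Selecting" %in% c1)
  expect_false("Idle" %in% c1)

  ctx <- list(color = "blue", tool = "pencil", velocity = 5, angle = 90,
              pressure = 0.5, cum_length = 0, x = 4, y = 4)
  c2 <- step(model, c1, list(kind = "pen_down"), context = ctx,
             config = cfg, geometry = geo)
  expect_true(isTRUE(configuration_consistent(model, c2)))
  leaves <- grep(":", c2, value = TRUE)
  expect_length(leaves, 8)   # one leaf per orthogonal painting region
  expect_true("Color:blue" %in% c2)
  expect_true("Velocity:medium" %in% c2)
  expect_true("Gradient:N" %in% c2)
  expect_true("Quarters:Q1" %in% c2)

  c3 <- step(model, c2, list(kind = "pen_up"), config = cfg, geometry = geo)
  expect_true("Idle" %in% c3)
  expect_false("Painting" %in% c3)

  c4 <- step(model, c3, list(kind = "session_end"), config = cfg, geometry = geo)
  expect_true("ArtRoomSessionOff" %in% c4)
  expect_error(step(model, c4, list(kind = "pen_down"), context = ctx,
                    config = cfg, geometry = geo), "session is off")
})

test_that("kinematic and spatial classifiers follow their conventions", {
  cfg <- studio_config()
  expect_equal(classify_velocity(c(1, 5, 15), cfg), c("low", "medium", "high"))
  expect_equal(classify_pressure(c(0.1, 0.5, 0.9), cfg), c("low", "medium", "high"))
  expect_equal(classify_size(c(1, 5, 15), cfg), c("short", "medium", "long"))
  # screen y grows downward: moving up the page is +90 degrees
  expect_equal(gradient_angle(0, -1), 90)
  expect_equal(gradient_angle(1, 0), 0)
  expect_equal(gradient_angle(-1, 0), 180)
  expect_equal(classify_gradient(c(10, 50, -100, 170)), c("E", "NE", "S", "W"))
  geo <- page_geometry(20, 16)
  expect_equal(quarter_of(5, 4, geo), "Q1")
  expect_equal(quarter_of(5, 12, geo), "Q2")
  expect_equal(quarter_of(15, 4, geo), "Q3")
  expect_equal(quarter_of(15, 12, geo), "Q4")
  # ties go left/top
  expect_equal(quarter_of(10, 8, geo), "Q1")
  expect_equal(part_of(10, 8, geo), "center")
  expect_equal(part_of(1, 1, geo), "boundary")
})

test_that("a simple session yields conserving occupancy and a tiling trace", {
  rec <- make_record(list(
    e_start(), e_color(0.2, "red"), e_tool(0.3, "pencil"),
    e_down(0.5, 5, 5), e_move(1.5, 6, 5), e_up(2.5, 7, 5), e_end(3)))
  tr <- run_statechart(rec)
  expect_equal(state_occupancy(tr, "Painting"), 2.0)
  expect_equal(state_occupancy(tr, "Idle") +
                 state_occupancy(tr, "Materials_Selecting"), 1.0)
  expect_equal(state_occupancy(tr, "ArtWork"), 3.0)
  expect_equal(state_occupancy(tr, "Materials_Selecting"), 0.3)
  # exclusive children tile their parent's active time
  kids <- c("Idle", "Materials_Selecting", "Painting")
  expect_equal(sum(vapply(kids, function(s) state_occupancy(tr, s), 0)),
               state_occupancy(tr, "ArtWork"))
})

test_that("an empty session is a single idle interval", {
  rec <- make_record(list(e_start(), e_end(4)))
  tr <- run_statechart(rec)
  idle <- tr[tr$state == "Idle", ]
  expect_equal(nrow(idle), 1)
  expect_equal(idle$t_start, 0)
  expect_equal(idle$t_end, 4)
})

test_that("a vertical stroke occupies a vertical gradient sector throughout", {
  rec <- make_record(list(
    e_start(), e_color(0.1, "black"), e_tool(0.1, "pastel"),
    e_down(1, 10, 2), e_move(2, 10, 8), e_move(3, 10, 14), e_up(4, 10, 18),
    e_end(5)))
  tr <- run_statechart(rec)
  grad <- tr[tr$region == "Gradient", ]
  expect_true(all(grad$state == "Gradient:S"))  # downward = -90 degrees
  rec_up <- make_record(list(
    e_start(), e_color(0.1, "black"), e_tool(0.1, "pastel"),
    e_down(1, 10, 18), e_move(2, 10, 10), e_up(3, 10, 2), e_end(4)))
  tr_up <- run_statechart(rec_up)
  expect_true(all(tr_up[tr_up$region == "Gradient", "state"] == "Gradient:N"))
})

test_that("every intermediate configuration is region-consistent", {
  model <- build_artwork_model(studio_config())
  fx <- bundled_fixtures(sample_rate = 25)
  for (nm in c("three_object", "empty", "single_dot")) {
    tr <- run_statechart(fx[[nm]]$record, keep_configurations = TRUE)
    confs <- attr(tr, "configurations")
    ok <- vapply(confs, function(cf) isTRUE(configuration_consistent(model, cf)), TRUE)
    expect_true(all(ok), info = nm)
  }
})

test_that("trace intervals tile each region's parent activity", {
  set.seed(11)
  out <- random_session(sample_rate = 30)
  tr <- run_statechart(out$record)
  # per exclusive region under Painting: children occupancy sums to Painting
  painting <- state_occupancy(tr, "Painting")
  for (region in c("Velocity", "Gradient", "Pressure", "Size", "Quarters",
                   "Parts", "Color", "Tool")) {
    rows <- tr[tr$region == region, ]
    expect_equal(sum(rows$t_end - rows$t_start), painting,
                 tolerance = 1e-9, info = region)
    # no overlap within the region
    rows <- rows[order(rows$t_start), ]
    if (nrow(rows) > 1)
      expect_true(all(diff(rows$t_start) >= (rows$t_end - rows$t_start)[-nrow(rows)] - 1e-9),
                  info = region)
  }
  expect_equal(state_occupancy(tr, "ArtWork"), attr(tr, "session_duration"))
})

test_that("velocity-leaf occupancy matches the brute-force window oracle", {
  set.seed(23)
  for (rep in 1:3) {
    out <- random_session(sample_rate = 30)
    tr <- run_statechart(out$record)
    want <- oracle_velocity_class_time(out$record)
    got <- c(low = state_occupancy(tr, "Velocity:low"),
             medium = state_occupancy(tr, "Velocity:medium"),
             high = state_occupancy(tr, "Velocity:high"))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("identical records yield identical traces", {
  set.seed(5)
  out <- random_session(sample_rate = 30)
  tr1 <- run_statechart(out$record)
  tr2 <- run_statechart(out$record)
  expect_identical(tr1, tr2)
})
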