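# Per-session parameter/metric table of the art-making process, computed
# from the extracted strokes and the statechart occupancy trace.

#' Polyline length of a stroke
#'
#' Sum of Euclidean distances between consecutive samples; a single-sample
#' stroke has length 0.
#'
#' @param stroke A `stroke` (see [extract_strokes()]).
#' @return Length in cm.
#' @export
stroke_length <- function(stroke) {
  s <- stroke$samples
  if (nrow(s) < 2L) return(0)
  sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
}

stroke_duration <- function(stroke) stroke$t_end - stroke$t_start

#' Session-level stroke kinematics
#'
#' Aggregates the stroke trajectories of one session:
#' * `avg_velocity` = total stroke length / total in-stroke time (cm/s);
#' * `avg_pressure` = time-weighted mean of sample pressures (each sample's
#'   pressure holds until the next sample);
#' * `avg_gradient` = direction (degrees, see [gradient_angle()]) of the
#'   length-weighted resultant of all segment directions, which avoids the
#'   +-180 wrap-around artifacts of an arithmetic mean of angles;
#' * `strokes_per_second` = stroke count / total in-stroke time.
#'
#' Sessions with zero total in-stroke time report 0 for the ratio metrics
#' and are flagged degenerate.
#'
#' @param strokes List of `stroke` objects.
#' @return List with `total_stroke_length`, `avg_stroke_length`,
#'   `avg_velocity`, `avg_pressure`, `avg_gradient`, `strokes_per_second`,
#'   `drawing_time`, `stroke_count`, `degenerate`.
#' @export
session_kinematics <- function(strokes) {
  n <- length(strokes)
  if (n == 0L)
    return(list(total_stroke_length = 0, avg_stroke_length = 0,
                avg_velocity = 0, avg_pressure = 0, avg_gradient = 0,
                strokes_per_second = 0, drawing_time = 0, stroke_count = 0,
                degenerate = TRUE))
  lengths <- vapply(strokes, stroke_length, 0)
  durations <- vapply(strokes, stroke_duration, 0)
  drawing_time <- sum(durations)
  total_len <- sum(lengths)
  pw <- 0
  vx <- 0; vy <- 0
  all_p <- numeric(0)
  for (st in strokes) {
    s <- st$samples
    m <- nrow(s)
    all_p <- c(all_p, s$pressure)
    if (m >= 2L) {
      dt <- diff(s$t)
      pw <- pw + sum(s$pressure[-m] * dt)
      vx <- vx + (s$x[m] - s$x[1])
      vy <- vy + (s$y[m] - s$y[1])
    }
  }
  degenerate <- drawing_time <= 0
  avg_pressure <- if (degenerate) mean(all_p) else pw / drawing_time
  resultant <- sqrt(vx^2 + vy^2)
  avg_gradient <- if (resultant < 1e-12) 0 else gradient_angle(vx, vy)
  list(total_stroke_length = total_len,
       avg_stroke_length = total_len / n,
       avg_velocity = if (degenerate) 0 else total_len / drawing_time,
       avg_pressure = avg_pressure,
       avg_gradient = avg_gradient,
       strokes_per_second = if (degenerate) 0 else n / drawing_time,
       drawing_time = drawing_time,
       stroke_count = n,
       degenerate = degenerate)
}

# Sum of pairwise interval overlaps between two sets of intervals, grouped
# by (stateA, stateB).  Both inputs are data frames state/t_start/t_end.
joint_occupancy <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(state_a = character(0), state_b = character(0),
                      time = numeric(0), stringsAsFactors = FALSE))
  acc <- list()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$t_start[i], b$t_start)
    hi <- pmin(a$t_end[i], b$t_end)
    ov <- hi - lo
    keep <- which(ov > 0)
    for (j in keep) {
      key <- paste0(a$state[i], "\r", b$state[j])
      acc[[key]] <- (acc[[key]] %||% 0) + ov[j]
    }
  }
  if (length(acc) == 0L)
    return(data.frame(state_a = character(0), state_b = character(0),
                      time = numeric(0), stringsAsFactors = FALSE))
  keys <- strsplit(names(acc), "\r", fixed = TRUE)
  data.frame(state_a = vapply(keys, `[[`, "", 1),
             state_b = vapply(keys, `[[`, "", 2),
             time = unlist(acc, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Occupancy metrics from the statechart trace
#'
#' Time-in-state metrics of the session: the drawing/idle split (time spent
#' Painting versus everything else, as percentages of the session), the
#' Materials_Selecting time (reported on its own, but folded into idle for
#' the two-way split), per-color and per-tool occupancy as percentages of
#' drawing time, the per-quarter and center/boundary page-use split, the
#' eraser-time percentage, and the color-by-tool cross sections.
#'
#' Color accounting treats erasing as its own pseudo-color: time stroking
#' with the eraser is reported as color `"erase"` and excluded from the
#' real colors' occupancy.
#'
#' @param trace A `timed_trace` from [run_statechart()].
#' @param config The session's [studio_config()].
#' @return List of occupancy metrics (see Details); percentage vectors are
#'   named by category.  `degenerate` is `TRUE` when drawing time is zero,
#'   in which case per-drawing-time percentages are reported as 0.
#' @export
occupancy_metrics <- function(trace, config) {
  duration <- attr(trace, "session_duration")
  painting_t <- state_occupancy(trace, "Painting")
  selecting_t <- state_occupancy(trace, "Materials_Selecting")
  drawing_pct <- if (duration > 0) painting_t / duration * 100 else 0
  degenerate <- painting_t <= 0
  pct_of_draw <- function(t) if (degenerate) 0 else t / painting_t * 100

  color_rows <- trace[trace$region == "Color", , drop = FALSE]
  tool_rows <- trace[trace$region == "Tool", , drop = FALSE]
  cross <- joint_occupancy(color_rows, tool_rows)
  cross$color <- sub("^Color:", "", cross$state_a)
  cross$tool <- sub("^Tool:", "", cross$state_b)
  cross <- cross[order(cross$color, cross$tool), c("color", "tool", "time")]
  rownames(cross) <- NULL

  tool_time <- vapply(config$toolset, function(tl)
    state_occupancy(trace, paste0("Tool:", tl)), 0)
  erase_t <- if ("eraser" %in% config$toolset) tool_time[["eraser"]] else 0
  color_time <- vapply(config$palette, function(cl) {
    rows <- cross$color == cl & cross$tool != "eraser"
    sum(cross$time[rows])
  }, 0)
  color_time <- c(color_time, erase = erase_t)

  quarter_time <- vapply(c("Q1", "Q2", "Q3", "Q4"), function(q)
    state_occupancy(trace, paste0("Quarters:", q)), 0)
  part_time <- vapply(c("center", "boundary"), function(p)
    state_occupancy(trace, paste0("Parts:", p)), 0)

  list(session_duration = duration,
       drawing_time = painting_t,
       drawing_pct = drawing_pct,
       idle_pct = 100 - drawing_pct,
       selecting_time = selecting_t,
       color_time = color_time,
       color_pct = vapply(color_time, pct_of_draw, 0),
       tool_time = tool_time,
       tool_pct = vapply(tool_time, pct_of_draw, 0),
       erase_time_pct = pct_of_draw(erase_t),
       quarter_time = quarter_time,
       quarter_pct = vapply(quarter_time, pct_of_draw, 0),
       part_time = part_time,
       part_pct = vapply(part_time, pct_of_draw, 0),
       cross_sections = cross,
       degenerate = degenerate)
}

#' Color and tool switching metrics
#'
#' Color switches are counted over the color sequence of the non-eraser
#' strokes (an eraser stroke "uses" no color); tool switches over the tool
#' sequence of all strokes.  `switches_per_color` divides color switches by
#' the number of distinct colors used (0 when no color was used).  The
#' used-percentages relate distinct used colors/tools to the configured
#' palette/toolset sizes (the eraser counts as a tool).
#'
#' @param strokes List of `stroke` objects, in session order.
#' @param config The session's [studio_config()].
#' @return List with `color_switches`, `tool_switches`,
#'   `switches_per_color`, `colors_used_pct`, `tools_used_pct`.
#' @export
switch_counts <- function(strokes, config) {
  tools <- vapply(strokes, function(s) s$tool, "")
  colors <- vapply(strokes, function(s) s$color, "")[tools != "eraser"]
  n_switch <- function(x) if (length(x) < 2L) 0L else sum(x[-1] != x[-length(x)])
  color_switches <- n_switch(colors)
  tool_switches <- n_switch(tools)
  n_colors <- length(unique(colors))
  n_tools <- length(unique(tools))
  list(color_switches = color_switches,
       tool_switches = tool_switches,
       switches_per_color = if (n_colors > 0) color_switches / n_colors else 0,
       colors_used_pct = n_colors / length(config$palette) * 100,
       tools_used_pct = n_tools / length(config$toolset) * 100)
}

quarter_adjacent <- function(a, b) {
  # edge adjacency on the 2x2 quarter grid; the diagonal pair is not adjacent
  paste(a, b) %in% c("Q1 Q2", "Q2 Q1", "Q1 Q3", "Q3 Q1",
                     "Q2 Q4", "Q4 Q2", "Q3 Q4", "Q4 Q3")
}

#' Page-use geometry metrics
#'
#' Spatial metrics of the session's strokes:
#' * `area_used_pct` — percentage of page covered, on a grid of
#'   `config$raster_cell` cells, a cell counting as covered when its center
#'   lies within half the tool width of any stroke segment;
#' * `stroke_start_crossovers` — number of strokes whose first sample lies
#'   in a quarter edge-adjacent to the quarter of the previous stroke's
#'   last sample (where the hand last was);
#' * `stroke_crossovers_h` / `stroke_crossovers_v` — within-stroke
#'   consecutive-sample pairs crossing the horizontal / vertical page
#'   midline (a pair crossing both increments both);
#' * `first_stroke_in_center` — whether the first stroke starts in the
#'   center part of the page.
#'
#' @param strokes List of `stroke` objects, in session order.
#' @param geometry The [page_geometry()].
#' @param config The [studio_config()] (tool widths, raster cell).
#' @return List of the metrics above plus `start_quarters` (quarter of each
#'   stroke's first sample).
#' @export
page_geometry_metrics <- function(strokes, geometry, config) {
  n <- length(strokes)
  if (n == 0L)
    return(list(area_used_pct = 0, stroke_start_crossovers = 0L,
                stroke_crossovers_h = 0L, stroke_crossovers_v = 0L,
                first_stroke_in_center = FALSE,
                start_quarters = character(0)))
  start_q <- character(n)
  end_q <- character(n)
  cross_h <- 0L
  cross_v <- 0L
  for (i in seq_len(n)) {
    s <- strokes[[i]]$samples
    start_q[i] <- quarter_of(s$x[1], s$y[1], geometry)
    m <- nrow(s)
    end_q[i] <- quarter_of(s$x[m], s$y[m], geometry)
    if (m >= 2L) {
      top <- s$y <= geometry$height / 2
      left <- s$x <= geometry$width / 2
      cross_h <- cross_h + sum(top[-1] != top[-m])
      cross_v <- cross_v + sum(left[-1] != left[-m])
    }
  }
  ssc <- if (n >= 2L)
    sum(quarter_adjacent(start_q[-1], end_q[-n])) else 0L
  list(area_used_pct = coverage_pct(strokes, geometry, config),
       stroke_start_crossovers = as.integer(ssc),
       stroke_crossovers_h = as.integer(cross_h),
       stroke_crossovers_v = as.integer(cross_v),
       first_stroke_in_center =
         part_of(strokes[[1]]$samples$x[1], strokes[[1]]$samples$y[1],
                 geometry) == "center",
       start_quarters = start_q)
}

# Swept-stroke coverage on a regular grid: a cell is covered when its
# center is within tool_width/2 of some stroke segment.
coverage_pct <- function(strokes, geometry, config, cell = config$raster_cell) {
  nx <- max(1L, ceiling(geometry$width / cell))
  ny <- max(1L, ceiling(geometry$height / cell))
  cx <- (seq_len(nx) - 0.5) * cell
  cy <- (seq_len(ny) - 0.5) * cell
  covered <- matrix(FALSE, nrow = ny, ncol = nx)
  for (st in strokes) {
    r <- config$tool_widths[[st$tool]] / 2
    s <- st$samples
    m <- nrow(s)
    segs <- if (m >= 2L) seq_len(m - 1L) else integer(0)
    if (m == 1L) {
      ix <- which(abs(cx - s$x[1]) <= r)
      iy <- which(abs(cy - s$y[1]) <= r)
      if (length(ix) && length(iy)) {
        d2 <- outer((cy[iy] - s$y[1])^2, (cx[ix] - s$x[1])^2, "+")
        covered[iy, ix] <- covered[iy, ix] | (d2 <= r^2)
      }
      next
    }
    for (k in segs) {
      x1 <- s$x[k]; y1 <- s$y[k]; x2 <- s$x[k + 1]; y2 <- s$y[k + 1]
      ix <- which(cx >= min(x1, x2) - r & cx <= max(x1, x2) + r)
      iy <- which(cy >= min(y1, y2) - r & cy <= max(y1, y2) + r)
      if (!length(ix) || !length(iy)) next
      px <- matrix(cx[ix], nrow = length(iy), ncol = length(ix), byrow = TRUE)
      py <- matrix(cy[iy], nrow = length(iy), ncol = length(ix))
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx^2 + dy^2
      tt <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2)) else 0
      d2 <- (px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2
      covered[iy, ix] <- covered[iy, ix] | (d2 <= r^2)
    }
  }
  sum(covered) / (nx * ny) * 100
}

#' Compute the full per-session metrics table
#'
#' Assembles every process metric of the session: duration and the
#' drawing/idle split, per-color and per-tool occupancy (with erasing as a
#' pseudo-color), switching counts, stroke kinematics, page-use geometry,
#' and the color-by-tool cross sections.  Occupancy metrics come from the
#' statechart trace; kinematic and geometric metrics from the extracted
#' strokes.
#'
#' @param record A valid `session_record`.
#' @param trace Optionally a precomputed `timed_trace` for the record.
#' @return An object of class `metrics_table`: a list of scalar metrics
#'   plus data frames `colors`, `tools`, `quarters`, `parts`,
#'   `cross_sections`.  See [metrics_row()] for a flat numeric view.
#' @export
compute_metrics <- function(record, trace = NULL) {
  if (is.null(trace)) trace <- run_statechart(record)
  strokes <- withCallingHandlers(extract_strokes(record),
                                 warning = function(w) invokeRestart("muffleWarning"))
  cfg <- record$config
  geo <- record$geometry
  occ <- occupancy_metrics(trace, cfg)
  kin <- session_kinematics(strokes)
  sw <- switch_counts(strokes, cfg)
  pg <- page_geometry_metrics(strokes, geo, cfg)
  colors <- data.frame(color = names(occ$color_time),
                       time_s = unname(occ$color_time),
                       pct = unname(occ$color_pct), stringsAsFactors = FALSE)
  tools <- data.frame(tool = names(occ$tool_time),
                      time_s = unname(occ$tool_time),
                      pct = unname(occ$tool_pct), stringsAsFactors = FALSE)
  quarters <- data.frame(quarter = names(occ$quarter_time),
                         time_s = unname(occ$quarter_time),
                         pct = unname(occ$quarter_pct), stringsAsFactors = FALSE)
  parts <- data.frame(part = names(occ$part_time),
                      time_s = unname(occ$part_time),
                      pct = unname(occ$part_pct), stringsAsFactors = FALSE)
  structure(list(
    session_duration = occ$session_duration,
    drawing_time = occ$drawing_time,
    drawing_pct = occ$drawing_pct,
    idle_pct = occ$idle_pct,
    selecting_time = occ$selecting_time,
    erase_time_pct = occ$erase_time_pct,
    colors_used_pct = sw$colors_used_pct,
    tools_used_pct = sw$tools_used_pct,
    color_switches = sw$color_switches,
    tool_switches = sw$tool_switches,
    switches_per_color = sw$switches_per_color,
    stroke_count = kin$stroke_count,
    total_stroke_length = kin$total_stroke_length,
    avg_stroke_length = kin$avg_stroke_length,
    avg_velocity = kin$avg_velocity,
    strokes_per_second = kin$strokes_per_second,
    avg_pressure = kin$avg_pressure,
    avg_gradient = kin$avg_gradient,
    area_used_pct = pg$area_used_pct,
    stroke_start_crossovers = pg$stroke_start_crossovers,
    stroke_crossovers_h = pg$stroke_crossovers_h,
    stroke_crossovers_v = pg$stroke_crossovers_v,
    first_stroke_in_center = pg$first_stroke_in_center,
    colors = colors,
    tools = tools,
    quarters = quarters,
    parts = parts,
    cross_sections = occ$cross_sections,
    degenerate = occ$degenerate || kin$degenerate,
    palette = cfg$palette,
    toolset = cfg$toolset
  ), class = "metrics_table")
}

#' Flatten a metrics table to one named numeric row
#'
#' Scalars keep their names; categorical occupancies become
#' `color_<name>_pct`, `tool_<name>_pct`, `quarter_<id>_pct`, `center_pct`,
#' `boundary_pct`; `first_stroke_in_center` becomes 0/1.
#'
#' @param m A `metrics_table`.
#' @return A named numeric vector.
#' @export
metrics_row <- function(m) {
  scalars <- c(session_duration = m$session_duration,
               drawing_time = m$drawing_time,
               drawing_pct = m$drawing_pct,
               idle_pct = m$idle_pct,
               selecting_time = m$selecting_time,
               erase_time_pct = m$erase_time_pct,
               colors_used_pct = m$colors_used_pct,
               tools_used_pct = m$tools_used_pct,
               color_switches = m$color_switches,
               tool_switches = m$tool_switches,
               switches_per_color = m$switches_per_color,
               stroke_count = m$stroke_count,
               total_stroke_length = m$total_stroke_length,
               avg_stroke_length = m$avg_stroke_length,
               avg_velocity = m$avg_velocity,
               strokes_per_second = m$strokes_per_second,
               avg_pressure = m$avg_pressure,
               avg_gradient = m$avg_gradient,
               area_used_pct = m$area_used_pct,
               stroke_start_crossovers = m$stroke_start_crossovers,
               stroke_crossovers_h = m$stroke_crossovers_h,
               stroke_crossovers_v = m$stroke_crossovers_v,
               first_stroke_in_center = as.numeric(m$first_stroke_in_center))
  cp <- structure(m$colors$pct, names = paste0("color_", m$colors$color, "_pct"))
  tp <- structure(m$tools$pct, names = paste0("tool_", m$tools$tool, "_pct"))
  qp <- structure(m$quarters$pct, names = paste0("quarter_", m$quarters$quarter, "_pct"))
  pp <- structure(m$parts$pct, names = paste0(m$parts$part, "_pct"))
  c(scalars, cp, tp, qp, pp)
}

#' Side-by-side comparison of two sessions' metrics
#'
#' @param a,b `metrics_table` objects computed under the same studio
#'   configuration.
#' @return Data frame with one row per flattened metric: columns `metric`,
#'   `a`, `b`, `difference` (`a - b`) and `ratio` (`a / b`; 1 when both are
#'   0, `NA` when only `b` is 0).
#' @export
compare_sessions <- function(a, b) {
  stopifnot(inherits(a, "metrics_table"), inherits(b, "metrics_table"))
  if (!identical(a$palette, b$palette) || !identical(a$toolset, b$toolset))
    stop("sessions were recorded under different studio configurations")
  ra <- metrics_row(a)
  rb <- metrics_row(b)
  stopifnot(identical(names(ra), names(rb)))
  ratio <- ifelse(rb != 0, ra / rb, ifelse(ra == 0, 1, NA_real_))
  data.frame(metric = names(ra), a = unname(ra), b = unname(rb),
             difference = unname(ra - rb), ratio = unname(ratio),
             stringsAsFactors = FALSE)
}

#' Export a metrics table as CSV
#'
#' One row per flattened metric with its value; deterministic formatting.
#'
#' @param m A `metrics_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(m, path) {
  row <- metrics_row(m)
  df <- data.frame(metric = names(row),
                   value = sprintf("%.9g", unname(row)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("<metrics_table> %.1f s session, %.1f%% drawing, %d strokes, %.1f cm\n",
              x$session_duration, x$drawing_pct, x$stroke_count,
              x$total_stroke_length))
  invisible(x)
}
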