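# Synthetic session generation: scripted stroke primitives realized into
# event streams at a given sampling rate, with a symbolic ground-truth
# metrics table computed from the script parameters (never from the
# sampled points), plus a seeded random-cohort generator for calibration
# and power studies.

#' Describe one scripted stroke
#'
#' A stroke script is a geometric primitive traced at constant speed with
#' a constant or linearly ramping pressure, preceded by an idle gap during
#' which color/tool selections are emitted if they change.
#'
#' @param primitive One of `"line"`, `"polyline"`, `"circle_arc"`,
#'   `"zigzag"`.
#' @param from,to Endpoints `c(x, y)` in cm (line, zigzag).
#' @param points Vertex matrix (n x 2) for `polyline`.
#' @param center,radius Arc center `c(x, y)` and radius (cm).
#' @param theta_start,theta_end Arc angles in degrees in the page-direction
#'   convention (0 = rightward, 90 = up); increasing angle is visually
#'   counter-clockwise.  The swept angle may be up to a full turn.
#' @param amplitude,n_zags Zigzag perpendicular amplitude (cm) and number
#'   of zig pairs.
#' @param speed Constant drawing speed (cm/s, > 0).
#' @param pressure Either a single pressure in `[0, 1]` or `c(p0, p1)` for
#'   a linear ramp along the stroke.
#' @param color,tool Palette color / toolset tool active for the stroke.
#' @param pre_gap Idle seconds before the stroke begins.
#' @return An object of class `stroke_script`.
#' @export
stroke_script <- function(primitive, from = NULL, to = NULL, points = NULL,
                          center = NULL, radius = NULL,
                          theta_start = NULL, theta_end = NULL,
                          amplitude = NULL, n_zags = 3,
                          speed = 5, pressure = 0.6,
                          color = "black", tool = "pencil", pre_gap = 1) {
  primitive <- match.arg(primitive, c("line", "polyline", "circle_arc", "zigzag"))
  if (speed <= 0) stop("speed must be positive")
  if (any(pressure < 0 | pressure > 1)) stop("pressure must lie in [0, 1]")
  if (pre_gap < 0) stop("pre_gap must be non-negative")
  s <- structure(list(primitive = primitive, from = from, to = to,
                      points = points, center = center, radius = radius,
                      theta_start = theta_start, theta_end = theta_end,
                      amplitude = amplitude, n_zags = n_zags,
                      speed = speed, pressure = as.numeric(pressure),
                      color = color, tool = tool, pre_gap = pre_gap),
                 class = "stroke_script")
  script_path(s)   # validates geometry arguments
  s
}

zigzag_points <- function(from, to, amplitude, n_zags) {
  nseg <- 2L * n_zags
  d <- to - from
  L <- sqrt(sum(d^2))
  if (L == 0) stop("zigzag endpoints coincide")
  u <- d / L
  perp <- c(-u[2], u[1])
  pts <- matrix(0, nrow = nseg + 1L, ncol = 2)
  for (k in 0:nseg) {
    base <- from + d * (k / nseg)
    off <- if (k %% 2L == 1L) amplitude * (-1)^((k - 1) / 2) else 0
    pts[k + 1L, ] <- base + off * perp
  }
  pts
}

# Exact geometric path of a script: a vertex polyline or an analytic arc.
script_path <- function(s) {
  switch(s$primitive,
    line = {
      if (is.null(s$from) || is.null(s$to)) stop("line needs from and to")
      list(type = "poly", pts = rbind(s$from, s$to))
    },
    polyline = {
      if (is.null(s$points) || nrow(s$points) < 2L)
        stop("polyline needs a points matrix with >= 2 rows")
      list(type = "poly", pts = s$points)
    },
    zigzag = {
      if (is.null(s$from) || is.null(s$to) || is.null(s$amplitude))
        stop("zigzag needs from, to and amplitude")
      list(type = "poly", pts = zigzag_points(s$from, s$to, s$amplitude, s$n_zags))
    },
    circle_arc = {
      if (is.null(s$center) || is.null(s$radius) ||
          is.null(s$theta_start) || is.null(s$theta_end))
        stop("circle_arc needs center, radius, theta_start, theta_end")
      if (s$radius <= 0) stop("radius must be positive")
      if (abs(s$theta_end - s$theta_start) > 360 + 1e-9)
        stop("arc sweep must not exceed a full turn")
      list(type = "arc", cx = s$center[1], cy = s$center[2], r = s$radius,
           a0 = s$theta_start, a1 = s$theta_end)
    })
}

arc_point <- function(p, theta_deg) {
  th <- theta_deg * pi / 180
  c(p$cx + p$r * cos(th), p$cy - p$r * sin(th))
}

path_length <- function(p) {
  if (p$type == "poly") {
    d <- diff(p$pts)
    sum(sqrt(rowSums(d^2)))
  } else {
    p$r * abs(p$a1 - p$a0) * pi / 180
  }
}

path_endpoints <- function(p) {
  if (p$type == "poly") list(start = p$pts[1, ], end = p$pts[nrow(p$pts), ])
  else list(start = arc_point(p, p$a0), end = arc_point(p, p$a1))
}

# Position at arc length s along the path (vectorized over s).
path_position <- function(p, s) {
  if (p$type == "poly") {
    d <- diff(p$pts)
    seg_len <- sqrt(rowSums(d^2))
    cum <- c(0, cumsum(seg_len))
    L <- cum[length(cum)]
    s <- pmin(pmax(s, 0), L)
    k <- findInterval(s, cum, rightmost.closed = TRUE)
    k <- pmin(k, length(seg_len))
    frac <- ifelse(seg_len[k] > 0, (s - cum[k]) / seg_len[k], 0)
    cbind(p$pts[k, 1] + frac * d[k, 1], p$pts[k, 2] + frac * d[k, 2])
  } else {
    L <- path_length(p)
    th <- p$a0 + (p$a1 - p$a0) * (if (L > 0) s / L else 0)
    cbind(p$cx + p$r * cos(th * pi / 180), p$cy - p$r * sin(th * pi / 180))
  }
}

# Arc lengths of interior vertices (always sampled so that measured and
# symbolic crossover counts coincide).
path_vertex_s <- function(p) {
  if (p$type != "poly" || nrow(p$pts) <= 2L) return(numeric(0))
  d <- diff(p$pts)
  cum <- cumsum(sqrt(rowSums(d^2)))
  cum[-length(cum)]
}

# Arc lengths at which the path changes page quarter or part.  These are
# always sampled, so the trace's region occupancy (midpoint rule) matches
# the symbolic clipping exactly.
path_boundary_s <- function(p, geometry) {
  W2 <- geometry$width / 2; H2 <- geometry$height / 2
  f <- geometry$center_fraction
  xs <- c(W2, W2 - f * geometry$width / 2, W2 + f * geometry$width / 2)
  ys <- c(H2, H2 - f * geometry$height / 2, H2 + f * geometry$height / 2)
  L <- path_length(p)
  out <- numeric(0)
  if (p$type == "poly") {
    d <- diff(p$pts)
    seg_len <- sqrt(rowSums(d^2))
    cum <- c(0, cumsum(seg_len))
    for (k in seq_len(nrow(p$pts) - 1L)) {
      tt <- segment_cuts(p$pts[k, ], p$pts[k + 1L, ], xs, ys)
      out <- c(out, cum[k] + tt * seg_len[k])
    }
  } else {
    angs <- arc_cuts(p, xs, ys)
    out <- p$r * abs(angs - p$a0) * pi / 180
  }
  if (length(out) == 0L) return(out)
  # keep only crossings where the classification actually changes
  delta <- min(1e-5, L * 1e-7)
  keep <- vapply(out, function(s) {
    a <- path_position(p, max(0, s - delta))
    b <- path_position(p, min(L, s + delta))
    quarter_of(a[1], a[2], geometry) != quarter_of(b[1], b[2], geometry) ||
      part_of(a[1], a[2], geometry) != part_of(b[1], b[2], geometry)
  }, TRUE)
  sort(out[keep])
}

#' Realize stroke scripts into a session record with ground truth
#'
#' Samples each scripted primitive along its arc length at a constant
#' rate (stroke endpoints, polyline vertices and page-region boundary
#' crossings are always included),
#' emits the corresponding pen and selection events, and assembles a
#' validated [session_record()].  Selection events are emitted midway
#' through a script's pre-gap whenever its color or tool differs from the
#' current selection (always for the first script).  The attached ground
#' truth is computed in closed form from the script parameters, not from
#' the sampled points.
#'
#' @param scripts List of [stroke_script()]s.
#' @param geometry,config Page geometry and studio configuration.
#' @param meta Session metadata.
#' @param sample_rate Pen sampling rate in Hz (> 0).
#' @param post_gap Idle seconds between the last stroke and session end.
#' @return List with `record` (a `session_record`) and `truth` (a
#'   `ground_truth` metrics table, see [ground_truth_scripts()]).
#' @export
realize_scripts <- function(scripts, geometry = page_geometry(),
                            config = studio_config(), meta = session_meta(),
                            sample_rate = 100, post_gap = 1) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  t_ev <- numeric(0); kind <- character(0)
  x <- numeric(0); y <- numeric(0); pr <- numeric(0)
  col <- character(0); tool <- character(0)
  add <- function(tt, kk, xx = NA, yy = NA, pp = NA, cc = NA, ll = NA) {
    t_ev <<- c(t_ev, tt); kind <<- c(kind, kk)
    x <<- c(x, xx); y <<- c(y, yy); pr <<- c(pr, pp)
    col <<- c(col, cc); tool <<- c(tool, ll)
  }
  add(0, "session_start")
  cur_color <- config$palette[1]
  cur_tool <- config$toolset[1]
  t <- 0
  for (si in seq_along(scripts)) {
    s <- scripts[[si]]
    p <- script_path(s)
    L <- path_length(p)
    dur <- L / s$speed
    sel_t <- t + s$pre_gap / 2
    if (si == 1L || s$color != cur_color) {
      add(sel_t, "select_color", cc = s$color); cur_color <- s$color
    }
    if (si == 1L || s$tool != cur_tool) {
      add(sel_t, "select_tool", ll = s$tool); cur_tool <- s$tool
    }
    t_down <- t + s$pre_gap
    n_uniform <- floor(dur * sample_rate + 1e-9)
    ts <- (0:n_uniform) / sample_rate
    if (dur - ts[length(ts)] > 1e-9) ts <- c(ts, dur)
    ss <- sort(unique(c(ts * s$speed, path_vertex_s(p),
                        path_boundary_s(p, geometry))))
    ss <- ss[ss <= L + 1e-9]
    pos <- path_position(p, ss)
    press <- if (length(s$pressure) == 2L) {
      if (L > 0) s$pressure[1] + (s$pressure[2] - s$pressure[1]) * ss / L
      else rep(s$pressure[1], length(ss))
    } else rep(s$pressure, length(ss))
    tsmp <- t_down + ss / s$speed
    m <- length(ss)
    add(tsmp[1], "pen_down", pos[1, 1], pos[1, 2], press[1])
    if (m > 2L)
      for (k in 2:(m - 1L))
        add(tsmp[k], "pen_move", pos[k, 1], pos[k, 2], press[k])
    add(tsmp[max(m, 1)], "pen_up", pos[max(m, 1), 1], pos[max(m, 1), 2],
        press[max(m, 1)])
    t <- t_down + dur
  }
  add(t + post_gap, "session_end")
  ev <- data.frame(t = t_ev, kind = kind, x = x, y = y, pressure = pr,
                   color = col, tool = tool, stringsAsFactors = FALSE)
  record <- session_record(ev, geometry = geometry, config = config, meta = meta)
  truth <- ground_truth_scripts(scripts, geometry = geometry, config = config,
                                post_gap = post_gap)
  list(record = record, truth = truth)
}

# --- symbolic ground truth ---------------------------------------------------

# Cut parameters (fractions in (0,1)) where a segment crosses any of the
# given vertical (x = xs) or horizontal (y = ys) lines.
segment_cuts <- function(a, b, xs, ys) {
  cuts <- numeric(0)
  d <- b - a
  for (v in xs) if (d[1] != 0) {
    tt <- (v - a[1]) / d[1]
    if (tt > 1e-12 && tt < 1 - 1e-12) cuts <- c(cuts, tt)
  }
  for (h in ys) if (d[2] != 0) {
    tt <- (h - a[2]) / d[2]
    if (tt > 1e-12 && tt < 1 - 1e-12) cuts <- c(cuts, tt)
  }
  sort(unique(cuts))
}

# Angles (degrees, strictly inside the arc's swept interval) where the arc
# crosses any of the given vertical/horizontal lines.
arc_cuts <- function(p, xs, ys) {
  lo <- min(p$a0, p$a1); hi <- max(p$a0, p$a1)
  sols <- numeric(0)
  base_candidates <- function(bases) {
    out <- numeric(0)
    for (b in bases) {
      k0 <- floor((lo - b) / 360) - 1
      k1 <- ceiling((hi - b) / 360) + 1
      out <- c(out, b + 360 * (k0:k1))
    }
    out
  }
  for (v in xs) {
    cc <- (v - p$cx) / p$r
    if (abs(cc) < 1 - 1e-12) {
      b <- acos(cc) * 180 / pi
      sols <- c(sols, base_candidates(c(b, -b)))
    }
  }
  for (h in ys) {
    ssin <- (p$cy - h) / p$r
    if (abs(ssin) < 1 - 1e-12) {
      b <- asin(ssin) * 180 / pi
      sols <- c(sols, base_candidates(c(b, 180 - b)))
    }
  }
  sols <- sols[sols > lo + 1e-9 & sols < hi - 1e-9]
  sort(unique(round(sols, 9)))
}

# Length of a path inside each category of a classifier driven by the
# given cut lines.  classify(x, y) must return a single label.
path_category_lengths <- function(p, xs, ys, classify) {
  acc <- list()
  bump <- function(lab, len) acc[[lab]] <<- (acc[[lab]] %||% 0) + len
  if (p$type == "poly") {
    n <- nrow(p$pts)
    for (k in seq_len(n - 1L)) {
      a <- p$pts[k, ]; b <- p$pts[k + 1L, ]
      seg_len <- sqrt(sum((b - a)^2))
      if (seg_len == 0) next
      tt <- c(0, segment_cuts(a, b, xs, ys), 1)
      for (j in seq_len(length(tt) - 1L)) {
        mid <- a + (b - a) * (tt[j] + tt[j + 1L]) / 2
        bump(classify(mid[1], mid[2]), seg_len * (tt[j + 1L] - tt[j]))
      }
    }
  } else {
    angs <- c(min(p$a0, p$a1), arc_cuts(p, xs, ys), max(p$a0, p$a1))
    for (j in seq_len(length(angs) - 1L)) {
      mid <- arc_point(p, (angs[j] + angs[j + 1L]) / 2)
      bump(classify(mid[1], mid[2]), p$r * (angs[j + 1L] - angs[j]) * pi / 180)
    }
  }
  unlist(acc)
}

# Number of transversal crossings of a path with a vertical (x = v) or
# horizontal (y = h) line, counted as side changes with the left/top tie
# rule (matching the sampled-stream counting).
path_crossings <- function(p, v = NULL, h = NULL) {
  if (p$type == "poly") {
    if (!is.null(v)) side <- p$pts[, 1] <= v else side <- p$pts[, 2] <= h
    sum(side[-1] != side[-length(side)])
  } else {
    length(arc_cuts(p, xs = if (!is.null(v)) v else numeric(0),
                    ys = if (!is.null(h)) h else numeric(0)))
  }
}

#' Closed-form ground-truth metrics for a script list
#'
#' Computes the exact metrics table implied by stroke scripts without
#' realizing them: durations and occupancies from `length/speed`, switch
#' and crossover counts from the script sequence and exact path geometry
#' (segment clipping; analytic arc-line intersections), quarter and
#' center/boundary times from arc-length clipping against the page
#' partitions, and the pressure/gradient aggregates in closed form.
#' `area_used_pct` has no closed form and is reported as `NA`.
#'
#' @param scripts List of [stroke_script()]s.
#' @param geometry,config Page geometry and studio configuration.
#' @param post_gap Idle seconds after the last stroke.
#' @return An object of class `ground_truth` mirroring the
#'   [compute_metrics()] field layout.
#' @export
ground_truth_scripts <- function(scripts, geometry = page_geometry(),
                                 config = studio_config(), post_gap = 1) {
  n <- length(scripts)
  W2 <- geometry$width / 2; H2 <- geometry$height / 2
  f <- geometry$center_fraction
  part_xs <- c(W2 - f * geometry$width / 2, W2 + f * geometry$width / 2)
  part_ys <- c(H2 - f * geometry$height / 2, H2 + f * geometry$height / 2)

  lengths <- numeric(n); durs <- numeric(n); gaps <- numeric(n)
  colors <- character(n); tools <- character(n); pbar <- numeric(n)
  sel_time <- 0
  cur_color <- config$palette[1]; cur_tool <- config$toolset[1]
  quarter_time <- c(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 0)
  part_time <- c(center = 0, boundary = 0)
  cross_h <- 0L; cross_v <- 0L
  vx <- 0; vy <- 0
  start_q <- character(n); end_q <- character(n)
  first_center <- FALSE
  for (i in seq_len(n)) {
    s <- scripts[[i]]
    p <- script_path(s)
    L <- path_length(p)
    lengths[i] <- L
    durs[i] <- L / s$speed
    gaps[i] <- s$pre_gap
    colors[i] <- s$color; tools[i] <- s$tool
    pbar[i] <- mean(s$pressure)
    sel_changed <- (i == 1L) || s$color != cur_color || s$tool != cur_tool
    if (sel_changed) sel_time <- sel_time + s$pre_gap / 2
    cur_color <- s$color; cur_tool <- s$tool
    ep <- path_endpoints(p)
    start_q[i] <- quarter_of(ep$start[1], ep$start[2], geometry)
    end_q[i] <- quarter_of(ep$end[1], ep$end[2], geometry)
    if (i == 1L)
      first_center <- part_of(ep$start[1], ep$start[2], geometry) == "center"
    qt <- path_category_lengths(p, xs = W2, ys = H2,
                                function(x, y) quarter_of(x, y, geometry))
    quarter_time[names(qt)] <- quarter_time[names(qt)] + qt / s$speed
    pt <- path_category_lengths(p, xs = part_xs, ys = part_ys,
                                function(x, y) part_of(x, y, geometry))
    part_time[names(pt)] <- part_time[names(pt)] + pt / s$speed
    cross_h <- cross_h + path_crossings(p, h = H2)
    cross_v <- cross_v + path_crossings(p, v = W2)
    vx <- vx + (ep$end[1] - ep$start[1])
    vy <- vy + (ep$end[2] - ep$start[2])
  }
  drawing_time <- sum(durs)
  duration <- sum(gaps) + drawing_time + post_gap
  degenerate <- drawing_time <= 0
  pct_draw <- function(t) if (degenerate) 0 else t / drawing_time * 100
  drawing_pct <- if (duration > 0) drawing_time / duration * 100 else 0

  erase_t <- sum(durs[tools == "eraser"])
  color_time <- vapply(config$palette, function(cl)
    sum(durs[colors == cl & tools != "eraser"]), 0)
  color_time <- c(color_time, erase = erase_t)
  tool_time <- vapply(config$toolset, function(tl) sum(durs[tools == tl]), 0)

  nonerase_colors <- colors[tools != "eraser"]
  n_switch <- function(v) if (length(v) < 2L) 0L else sum(v[-1] != v[-length(v)])
  color_switches <- n_switch(nonerase_colors)
  tool_switches <- n_switch(tools)
  n_colors <- length(unique(nonerase_colors))

  ssc <- if (n >= 2L) sum(quarter_adjacent(start_q[-1], end_q[-n])) else 0L
  resultant <- sqrt(vx^2 + vy^2)
  structure(list(
    session_duration = duration,
    drawing_time = drawing_time,
    drawing_pct = drawing_pct,
    idle_pct = 100 - drawing_pct,
    selecting_time = sel_time,
    erase_time_pct = pct_draw(erase_t),
    colors_used_pct = n_colors / length(config$palette) * 100,
    tools_used_pct = length(unique(tools)) / length(config$toolset) * 100,
    color_switches = color_switches,
    tool_switches = tool_switches,
    switches_per_color = if (n_colors > 0) color_switches / n_colors else 0,
    stroke_count = n,
    total_stroke_length = sum(lengths),
    avg_stroke_length = if (n > 0) sum(lengths) / n else 0,
    avg_velocity = if (degenerate) 0 else sum(lengths) / drawing_time,
    strokes_per_second = if (degenerate) 0 else n / drawing_time,
    avg_pressure = if (degenerate) {
      if (n > 0) mean(pbar) else 0
    } else sum(pbar * durs) / drawing_time,
    avg_gradient = if (resultant < 1e-12) 0 else gradient_angle(vx, vy),
    area_used_pct = NA_real_,
    stroke_start_crossovers = as.integer(ssc),
    stroke_crossovers_h = as.integer(cross_h),
    stroke_crossovers_v = as.integer(cross_v),
    first_stroke_in_center = first_center,
    colors = data.frame(color = names(color_time), time_s = unname(color_time),
                        pct = vapply(color_time, pct_draw, 0),
                        stringsAsFactors = FALSE, row.names = NULL),
    tools = data.frame(tool = names(tool_time), time_s = unname(tool_time),
                       pct = vapply(tool_time, pct_draw, 0),
                       stringsAsFactors = FALSE, row.names = NULL),
    quarters = data.frame(quarter = names(quarter_time),
                          time_s = unname(quarter_time),
                          pct = vapply(quarter_time, pct_draw, 0),
                          stringsAsFactors = FALSE, row.names = NULL),
    parts = data.frame(part = names(part_time), time_s = unname(part_time),
                       pct = vapply(part_time, pct_draw, 0),
                       stringsAsFactors = FALSE, row.names = NULL),
    cross_sections = local({
      if (n == 0L)
        return(data.frame(color = character(0), tool = character(0),
                          time = numeric(0), stringsAsFactors = FALSE))
      key <- paste(colors, tools)
      agg <- tapply(durs, key, sum)
      parts2 <- strsplit(names(agg), " ", fixed = TRUE)
      df <- data.frame(color = vapply(parts2, `[[`, "", 1),
                       tool = vapply(parts2, `[[`, "", 2),
                       time = as.numeric(agg), stringsAsFactors = FALSE)
      df <- df[order(df$color, df$tool), ]
      rownames(df) <- NULL
      df
    }),
    degenerate = degenerate,
    palette = config$palette,
    toolset = config$toolset,
    start_quarters = start_q
  ), class = c("ground_truth", "metrics_table"))
}

# --- random sessions and cohorts ---------------------------------------------

#' Session-level distribution parameters for the random generator
#'
#' Defaults emulate the scale of tablet drawing-session studies: stroke
#' counts around 20 per session, log-normal speeds with median 9.6 cm/s,
#' stroke lengths a few cm, a Beta-distributed idle fraction with mean
#' about 0.63, occasional eraser strokes, and Dirichlet-weighted color
#' preferences over the palette.
#'
#' @param stroke_count_mean Poisson mean of the stroke count (min 1 drawn).
#' @param stroke_len_median,stroke_len_sigma Log-normal stroke length (cm).
#' @param speed_median,speed_sigma Log-normal drawing speed (cm/s).
#' @param color_conc Dirichlet concentration over the palette (recycled).
#' @param erase_p Probability a stroke is an eraser stroke.
#' @param idle_alpha,idle_beta Beta parameters of the session idle
#'   fraction.
#' @param pressure_mean,pressure_sd Normal pressure parameters (clamped to
#'   `[0.02, 0.98]`).
#' @return A plain list of parameters.
#' @export
session_params <- function(stroke_count_mean = 20,
                           stroke_len_median = 4, stroke_len_sigma = 0.6,
                           speed_median = 9.6, speed_sigma = 0.5,
                           color_conc = 1,
                           erase_p = 0.15,
                           idle_alpha = 6.3, idle_beta = 3.7,
                           pressure_mean = 0.6, pressure_sd = 0.15) {
  as.list(environment())
}

clamp <- function(v, lo, hi) pmin(hi, pmax(lo, v))

# Draw one random stroke script inside the page margins.
random_script <- function(params, geometry, cur_color, color_w, config) {
  m <- 1
  bx <- c(m, geometry$width - m)
  by <- c(m, geometry$height - m)
  len <- clamp(stats::rlnorm(1, log(params$stroke_len_median),
                             params$stroke_len_sigma), 0.5, 18)
  speed <- stats::rlnorm(1, log(params$speed_median), params$speed_sigma)
  pr_m <- clamp(stats::rnorm(1, params$pressure_mean, params$pressure_sd),
                0.02, 0.98)
  pressure <- if (stats::runif(1) < 0.3)
    clamp(c(pr_m - 0.1, pr_m + 0.1), 0.02, 0.98) else pr_m
  is_erase <- stats::runif(1) < params$erase_p
  tool <- if (is_erase) "eraser"
          else sample(setdiff(config$toolset, "eraser"), 1)
  color <- if (is_erase) cur_color
           else sample(config$palette, 1, prob = color_w)
  prim <- sample(c("line", "polyline", "zigzag", "circle_arc"), 1,
                 prob = c(0.4, 0.25, 0.2, 0.15))
  start <- c(stats::runif(1, bx[1], bx[2]), stats::runif(1, by[1], by[2]))
  ang <- stats::runif(1, 0, 2 * pi)
  gap <- stats::rexp(1, 1)     # reshaped later to the target idle fraction
  if (prim == "line") {
    to <- clamp(start + len * c(cos(ang), sin(ang)), c(bx[1], by[1]), c(bx[2], by[2]))
    if (all(abs(to - start) < 1e-6)) to <- start + c(0.5, 0)
    stroke_script("line", from = start, to = to, speed = speed,
                  pressure = pressure, color = color, tool = tool, pre_gap = gap)
  } else if (prim == "polyline") {
    k <- sample(3:5, 1)
    pts <- matrix(0, k, 2)
    pts[1, ] <- start
    for (j in 2:k) {
      step_ang <- stats::runif(1, 0, 2 * pi)
      pts[j, ] <- clamp(pts[j - 1, ] + (len / (k - 1)) * c(cos(step_ang), sin(step_ang)),
                        c(bx[1], by[1]), c(bx[2], by[2]))
    }
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-6)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 2L) pts <- rbind(pts, pts[1, ] + c(0.5, 0))
    stroke_script("polyline", points = pts, speed = speed,
                  pressure = pressure, color = color, tool = tool, pre_gap = gap)
  } else if (prim == "zigzag") {
    axis_len <- max(1, len * 0.6)
    amp <- stats::runif(1, 0.3, 0.9)
    lo <- c(bx[1], by[1]) + amp; hi <- c(bx[2], by[2]) - amp
    start <- clamp(start, lo, hi)
    to <- clamp(start + axis_len * c(cos(ang), sin(ang)), lo, hi)
    if (all(abs(to - start) < 1e-6)) to <- start + c(1, 0)
    stroke_script("zigzag", from = start, to = to,
                  amplitude = amp,
                  n_zags = sample(2:4, 1), speed = speed,
                  pressure = pressure, color = color, tool = tool, pre_gap = gap)
  } else {
    r <- stats::runif(1, 1, min(3, (by[2] - by[1]) / 2 - 0.1))
    cx <- stats::runif(1, bx[1] + r, bx[2] - r)
    cy <- stats::runif(1, by[1] + r, by[2] - r)
    a0 <- stats::runif(1, 0, 360)
    sweep <- stats::runif(1, 90, 360) * sample(c(-1, 1), 1)
    stroke_script("circle_arc", center = c(cx, cy), radius = r,
                  theta_start = a0, theta_end = a0 + sweep, speed = speed,
                  pressure = pressure, color = color, tool = tool, pre_gap = gap)
  }
}

#' Generate one random session with its ground truth
#'
#' Draws a random script list under `params` (using the current RNG
#' state) and realizes it.  Idle gaps are rescaled so the session's idle
#' fraction matches the Beta draw.
#'
#' @param params A [session_params()] list.
#' @param geometry,config Page geometry and studio configuration.
#' @param meta Session metadata.
#' @param sample_rate Pen sampling rate (Hz).
#' @return List with `record`, `truth`, `scripts`.
#' @export
random_session <- function(params = session_params(),
                           geometry = page_geometry(),
                           config = studio_config(),
                           meta = session_meta(), sample_rate = 50) {
  n <- max(1L, stats::rpois(1, params$stroke_count_mean))
  conc <- rep_len(params$color_conc, length(config$palette))
  color_w <- stats::rgamma(length(conc), conc)
  color_w <- color_w / sum(color_w)
  cur_color <- config$palette[1]
  scripts <- vector("list", n)
  for (i in seq_len(n)) {
    scripts[[i]] <- random_script(params, geometry, cur_color, color_w, config)
    if (scripts[[i]]$tool != "eraser") cur_color <- scripts[[i]]$color
  }
  drawing <- sum(vapply(scripts, function(s) path_length(script_path(s)) / s$speed, 0))
  idle_frac <- stats::rbeta(1, params$idle_alpha, params$idle_beta)
  idle_total <- min(drawing * idle_frac / (1 - idle_frac), 900)
  w <- stats::rexp(n + 1L, 1)
  gaps <- idle_total * w / sum(w)
  for (i in seq_len(n)) scripts[[i]]$pre_gap <- gaps[i]
  out <- realize_scripts(scripts, geometry = geometry, config = config,
                         meta = meta, sample_rate = sample_rate,
                         post_gap = gaps[n + 1L])
  out$scripts <- scripts
  out
}

#' Specification of a synthetic two-group cohort
#'
#' @param group_label Name of the grouping attribute (e.g. `"gender"`).
#' @param groups Character vector of exactly two group names.
#' @param subjects_per_group Subjects per group.
#' @param tasks Task labels; each subject contributes one session per
#'   task.
#' @param params Baseline [session_params()].
#' @param group_overrides Named list (by group) of parameter overrides —
#'   the planted group differences.
#' @param seed Mandatory integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_label = "gender", groups = c("F", "M"),
                        subjects_per_group = 6,
                        tasks = c("positive", "negative", "htp"),
                        params = session_params(), group_overrides = list(),
                        seed) {
  if (missing(seed)) stop("a seed is mandatory for cohort generation")
  if (length(groups) != 2L) stop("exactly two groups are required")
  structure(list(group_label = group_label, groups = groups,
                 subjects_per_group = subjects_per_group, tasks = tasks,
                 params = params, group_overrides = group_overrides,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a full synthetic cohort
#'
#' Deterministic given the specification's seed: group differences are
#' exactly as planted via `group_overrides`.
#'
#' @param spec A [cohort_spec()].
#' @param geometry,config Page geometry and studio configuration.
#' @param sample_rate Pen sampling rate (Hz).
#' @return List with `records` (one per subject x task) and `truths`.
#' @export
generate_cohort <- function(spec, geometry = page_geometry(),
                            config = studio_config(), sample_rate = 50) {
  set.seed(spec$seed)
  records <- list(); truths <- list()
  for (g in spec$groups) {
    par_g <- spec$params
    ov <- spec$group_overrides[[g]]
    if (!is.null(ov)) par_g[names(ov)] <- ov
    for (i in seq_len(spec$subjects_per_group)) {
      subj <- paste0(g, i)
      for (task in spec$tasks) {
        groups <- list(); groups[[spec$group_label]] <- g
        meta <- session_meta(subject = subj, groups = groups, task = task)
        out <- random_session(par_g, geometry = geometry, config = config,
                              meta = meta, sample_rate = sample_rate)
        records[[length(records) + 1L]] <- out$record
        truths[[length(truths) + 1L]] <- out$truth
      }
    }
  }
  list(records = records, truths = truths)
}

# --- bundled fixtures --------------------------------------------------------

#' Deterministic bundled fixture sessions
#'
#' Ships four scripted sessions with known ground truth:
#' `three_object` — a red rectangle, blue diamond and yellow circle in
#' quarters 1-3, plus a four-stroke "pink-black" object in quarter 4 that
#' is subsequently removed by six eraser strokes (one erase epoch);
#' `vertical_mass` — four long black pastel zigzag strokes of near-vertical
#' legs sweeping the page, whose midline crossovers are overwhelmingly
#' horizontal; `empty` — a session with no strokes; `single_dot` — one
#' zero-length stroke.
#'
#' @param sample_rate Pen sampling rate (Hz).
#' @return Named list; each element has `record`, `truth`, `scripts`.
#' @export
bundled_fixtures <- function(sample_rate = 100) {
  geo <- page_geometry(28, 16)
  cfg <- studio_config()
  fx <- list()

  three_scripts <- list(
    stroke_script("polyline",
                  points = rbind(c(3, 2), c(9, 2), c(9, 6), c(3, 6), c(3, 2)),
                  speed = 6, pressure = 0.6, color = "red", tool = "oils",
                  pre_gap = 2),
    stroke_script("polyline",
                  points = rbind(c(6, 9.5), c(9, 12.5), c(6, 15.3),
                                 c(3, 12.5), c(6, 9.5)),
                  speed = 5, pressure = 0.55, color = "blue",
                  tool = "water_color", pre_gap = 2),
    stroke_script("circle_arc", center = c(21, 4), radius = 2.5,
                  theta_start = 90, theta_end = 450, speed = 5,
                  pressure = 0.5, color = "yellow", tool = "ink_pen",
                  pre_gap = 2),
    stroke_script("zigzag", from = c(16, 10), to = c(24, 10),
                  amplitude = 0.8, n_zags = 3, speed = 7,
                  pressure = c(0.3, 0.8), color = "white", tool = "pastel",
                  pre_gap = 2),
    stroke_script("line", from = c(20, 9.5), to = c(20, 14.5), speed = 6,
                  pressure = c(0.35, 0.85), color = "black", tool = "pastel",
                  pre_gap = 1.5),
    stroke_script("line", from = c(16.5, 9.5), to = c(23.5, 14.5), speed = 6,
                  pressure = c(0.4, 0.9), color = "skin", tool = "pastel",
                  pre_gap = 1.5),
    stroke_script("line", from = c(17, 10.5), to = c(25, 15), speed = 6,
                  pressure = c(0.45, 0.95), color = "pink", tool = "pastel",
                  pre_gap = 1.5)
  )
  erase_y <- c(9.15, 10.29, 11.43, 12.57, 13.71, 14.85)
  for (k in seq_along(erase_y)) {
    x0 <- if (k %% 2 == 1) 15.5 else 25.5
    x1 <- if (k %% 2 == 1) 25.5 else 15.5
    three_scripts[[length(three_scripts) + 1L]] <-
      stroke_script("line", from = c(x0, erase_y[k]), to = c(x1, erase_y[k]),
                    speed = 12, pressure = 0.7, color = "pink",
                    tool = "eraser", pre_gap = if (k == 1) 2 else 0.3)
  }
  fx$three_object <- realize_scripts(
    three_scripts, geometry = geo, config = cfg,
    meta = session_meta("fixture", task = "three_object"),
    sample_rate = sample_rate, post_gap = 2)
  fx$three_object$scripts <- three_scripts

  vm_scripts <- list()
  x0s <- c(2, 8, 14.3, 20.3)
  for (si in seq_along(x0s)) {
    pts <- matrix(0, 7, 2)
    for (k in 0:6)
      pts[k + 1, ] <- c(x0s[si] + k, if (k %% 2 == 0) 2.1 else 14.9)
    vm_scripts[[si]] <- stroke_script("polyline", points = pts, speed = 30,
                                      pressure = c(0.4, 0.9), color = "black",
                                      tool = "pastel",
                                      pre_gap = if (si == 1) 1.5 else 0.4)
  }
  fx$vertical_mass <- realize_scripts(
    vm_scripts, geometry = geo, config = cfg,
    meta = session_meta("fixture", task = "vertical_mass"),
    sample_rate = sample_rate, post_gap = 1)
  fx$vertical_mass$scripts <- vm_scripts

  fx$empty <- realize_scripts(
    list(), geometry = geo, config = cfg,
    meta = session_meta("fixture", task = "empty"),
    sample_rate = sample_rate, post_gap = 5)
  fx$empty$scripts <- list()

  dot <- list(stroke_script("line", from = c(10.2, 5.1), to = c(10.2, 5.1),
                            speed = 5, pressure = 0.5, color = "red",
                            tool = "pencil", pre_gap = 1))
  fx$single_dot <- realize_scripts(
    dot, geometry = geo, config = cfg,
    meta = session_meta("fixture", task = "single_dot"),
    sample_rate = sample_rate, post_gap = 1)
  fx$single_dot$scripts <- dot

  fx
}

#' Deterministic suite of scripted validation sessions
#'
#' A fixed battery of scripted sessions (at least 20) covering every
#' primitive, midline-crossing geometries, pressure ramps, eraser strokes
#' and selection patterns, each with closed-form ground truth.  Used for
#' ground-truth recovery checks.
#'
#' @param sample_rate Pen sampling rate (Hz).
#' @return List of elements with `record`, `truth`, `scripts`.
#' @export
scripted_fixture_suite <- function(sample_rate = 100) {
  geo <- page_geometry(28, 16)
  cfg <- studio_config()
  suite <- list()
  addf <- function(scripts, name) {
    out <- realize_scripts(scripts, geometry = geo, config = cfg,
                           meta = session_meta("suite", task = name),
                           sample_rate = sample_rate, post_gap = 1)
    out$scripts <- scripts
    out$name <- name
    suite[[name]] <<- out
  }

  colors <- DEFAULT_PALETTE
  tools <- setdiff(DEFAULT_TOOLSET, "eraser")
  # sloped lines crossing both midlines at distinct angles
  for (k in 1:6) {
    a <- c(2.3 + k * 0.7, 2.1 + k * 0.9)
    b <- c(25.7 - k * 0.6, 14.3 - k * 0.5)
    addf(list(
      stroke_script("line", from = a, to = b, speed = 4 + k,
                    pressure = 0.3 + 0.05 * k, color = colors[k],
                    tool = tools[(k - 1) %% 5 + 1], pre_gap = 1 + 0.2 * k),
      stroke_script("line", from = b + c(-0.3, 0.2), to = a + c(0.4, -0.3),
                    speed = 5, pressure = c(0.2, 0.8),
                    color = colors[k + 1], tool = tools[k %% 5 + 1],
                    pre_gap = 0.8)),
      paste0("lines_", k))
  }
  # polylines with vertices on and off the midlines
  for (k in 1:4) {
    pts <- rbind(c(3 + k, 3), c(14, 3 + k), c(24 - k, 8 + k), c(14, 14 - k / 2))
    addf(list(
      stroke_script("polyline", points = pts, speed = 5 + k,
                    pressure = 0.5, color = colors[k + 2], tool = "pencil",
                    pre_gap = 1.2),
      stroke_script("polyline", points = pts[nrow(pts):1, ] + 0.37,
                    speed = 6, pressure = c(0.6, 0.3),
                    color = colors[k + 3], tool = "oils", pre_gap = 0.9)),
      paste0("poly_", k))
  }
  # zigzags along both axes
  for (k in 1:4) {
    addf(list(
      stroke_script("zigzag", from = c(3.1, 4 + k), to = c(24.9, 4 + k),
                    amplitude = 0.6 + 0.2 * k, n_zags = 2 + k, speed = 8,
                    pressure = 0.55, color = colors[k], tool = "pastel",
                    pre_gap = 1.1),
      stroke_script("zigzag", from = c(5 + 4 * k, 2.2), to = c(5 + 4 * k, 14.4),
                    amplitude = 1.1, n_zags = 3, speed = 9,
                    pressure = c(0.3, 0.9), color = colors[k + 4],
                    tool = "water_color", pre_gap = 0.7)),
      paste0("zig_", k))
  }
  # arcs: inside one quarter, crossing midlines, partial sweeps
  arcspecs <- list(
    list(c = c(7, 4), r = 2.2, a = c(0, 360)),
    list(c = c(14, 8), r = 4.6, a = c(30, 300)),
    list(c = c(20.5, 11.5), r = 3.1, a = c(-60, 200)),
    list(c = c(10.5, 8.2), r = 3.7, a = c(120, -90))
  )
  for (k in seq_along(arcspecs)) {
    as_ <- arcspecs[[k]]
    addf(list(
      stroke_script("circle_arc", center = as_$c, radius = as_$r,
                    theta_start = as_$a[1], theta_end = as_$a[2],
                    speed = 5.5, pressure = 0.45, color = colors[k + 1],
                    tool = "ink_pen", pre_gap = 1.3),
      stroke_script("line", from = as_$c + c(0.3, 0.2),
                    to = as_$c + c(3.1, 2.3), speed = 4,
                    pressure = 0.6, color = colors[k + 5], tool = "pencil",
                    pre_gap = 0.6)),
      paste0("arc_", k))
  }
  # eraser interleavings and repeated colors (switch counting)
  for (k in 1:3) {
    addf(list(
      stroke_script("line", from = c(4, 4 + k), to = c(12, 4 + k), speed = 6,
                    pressure = 0.5, color = "red", tool = "pencil", pre_gap = 1),
      stroke_script("line", from = c(4, 5.5 + k), to = c(12, 5.5 + k), speed = 6,
                    pressure = 0.5, color = "red", tool = "pencil", pre_gap = 0.5),
      stroke_script("line", from = c(4, 7 + k), to = c(12, 7 + k), speed = 8,
                    pressure = 0.6, color = "red", tool = "eraser", pre_gap = 0.5),
      stroke_script("line", from = c(16, 7 + k), to = c(24, 7 + k), speed = 6,
                    pressure = 0.5, color = "blue", tool = "pastel", pre_gap = 0.5),
      stroke_script("line", from = c(16, 9 + k), to = c(24, 9 + k), speed = 6,
                    pressure = 0.5, color = "red", tool = "pastel", pre_gap = 0.4)),
      paste0("erase_", k))
  }
  # bundled fixtures join the suite
  fx <- bundled_fixtures(sample_rate = sample_rate)
  for (nm in names(fx)) suite[[nm]] <- fx[[nm]]
  suite
}
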