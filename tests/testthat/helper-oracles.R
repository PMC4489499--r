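# Independent brute-force oracles: these recompute quantities straight
# from the raw samples, bypassing the statechart engine, and are kept
# deliberately naive.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct stroke-derived occupancy: drawing/selecting time, per-color and
# per-tool time (erase pseudo-color convention), per-quarter and part time
# under the same interval conventions as the tracker (each inter-sample
# interval classified at its trajectory midpoint for page use).
oracle_occupancy <- function(record) {
  strokes <- suppressWarnings(extract_strokes(record))
  cfg <- record$config
  geo <- record$geometry
  duration <- session_duration(record)
  durs <- vapply(strokes, function(s) s$t_end - s$t_start, 0)
  cols <- vapply(strokes, function(s) s$color, "")
  tls <- vapply(strokes, function(s) s$tool, "")
  painting <- sum(durs)
  tool_time <- vapply(cfg$toolset, function(tl) sum(durs[tls == tl]), 0)
  erase_t <- sum(durs[tls == "eraser"])
  color_time <- vapply(cfg$palette, function(cl)
    sum(durs[cols == cl & tls != "eraser"]), 0)
  color_time <- c(color_time, erase = erase_t)
  quarter_time <- c(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 0)
  part_time <- c(center = 0, boundary = 0)
  for (st in strokes) {
    s <- st$samples
    m <- nrow(s)
    if (m < 2L) next
    for (i in seq_len(m - 1L)) {
      dt <- s$t[i + 1] - s$t[i]
      if (dt <= 0) next
      mx <- (s$x[i] + s$x[i + 1]) / 2
      my <- (s$y[i] + s$y[i + 1]) / 2
      q <- quarter_of(mx, my, geo)
      p <- part_of(mx, my, geo)
      quarter_time[q] <- quarter_time[q] + dt
      part_time[p] <- part_time[p] + dt
    }
  }
  # selecting: from each selection event (outside a stroke) to next pen_down
  ev <- record$events
  selecting <- 0
  open_sel <- NA_real_
  inside <- FALSE
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k %in% c("select_color", "select_tool") && !inside) {
      if (is.na(open_sel)) open_sel <- ev$t[i]
    } else if (k == "pen_down") {
      inside <- TRUE
      if (!is.na(open_sel)) { selecting <- selecting + ev$t[i] - open_sel; open_sel <- NA }
    } else if (k == "pen_up") inside <- FALSE
    else if (k == "session_end" && !is.na(open_sel)) {
      selecting <- selecting + ev$t[i] - open_sel; open_sel <- NA
    }
  }
  list(session_duration = duration, drawing_time = painting,
       selecting_time = selecting, color_time = color_time,
       tool_time = tool_time, quarter_time = quarter_time,
       part_time = part_time)
}

# Per-sample velocity-class times computed directly from raw samples and
# thresholds (left-endpoint rule; first sample inherits the second's
# class; zero-dt windows keep the previous class).
oracle_velocity_class_time <- function(record) {
  strokes <- suppressWarnings(extract_strokes(record))
  cfg <- record$config
  out <- c(low = 0, medium = 0, high = 0)
  for (st in strokes) {
    s <- st$samples
    m <- nrow(s)
    if (m < 2L) next
    v <- numeric(m)
    prev <- 0
    for (i in 2:m) {
      dt <- s$t[i] - s$t[i - 1]
      d <- sqrt((s$x[i] - s$x[i - 1])^2 + (s$y[i] - s$y[i - 1])^2)
      if (dt > 0) prev <- d / dt
      v[i] <- prev
    }
    v[1] <- v[2]
    cl <- classify_velocity(v, cfg)
    for (i in seq_len(m - 1L))
      out[cl[i]] <- out[cl[i]] + (s$t[i + 1] - s$t[i])
  }
  out
}

# Naive pixel-count coverage oracle: every cell against every segment.
oracle_coverage_pct <- function(strokes, geometry, config) {
  cell <- config$raster_cell
  nx <- max(1L, ceiling(geometry$width / cell))
  ny <- max(1L, ceiling(geometry$height / cell))
  covered <- 0L
  for (iy in seq_len(ny)) {
    cy <- (iy - 0.5) * cell
    for (ix in seq_len(nx)) {
      cx <- (ix - 0.5) * cell
      hit <- FALSE
      for (st in strokes) {
        r <- config$tool_widths[[st$tool]] / 2
        s <- st$samples
        m <- nrow(s)
        for (k in seq_len(max(m - 1L, 1L))) {
          x1 <- s$x[k]; y1 <- s$y[k]
          x2 <- s$x[min(k + 1L, m)]; y2 <- s$y[min(k + 1L, m)]
          dx <- x2 - x1; dy <- y2 - y1
          L2 <- dx^2 + dy^2
          tt <- if (L2 > 0) min(1, max(0, ((cx - x1) * dx + (cy - y1) * dy) / L2)) else 0
          d2 <- (cx - (x1 + tt * dx))^2 + (cy - (y1 + tt * dy))^2
          if (d2 <= r^2) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) covered <- covered + 1L
    }
  }
  covered / (nx * ny) * 100
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
oracle_ranksum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Simple deterministic session records built straight from event rows.
make_record <- function(rows, geometry = page_geometry(20, 20),
                        config = studio_config(), meta = session_meta()) {
  ev <- do.call(rbind, lapply(rows, function(r)
    data.frame(t = r$t, kind = r$kind,
               x = r$x %||% NA_real_, y = r$y %||% NA_real_,
               pressure = r$pressure %||% NA_real_,
               color = r$color %||% NA_character_,
               tool = r$tool %||% NA_character_,
               stringsAsFactors = FALSE)))
  session_record(ev, geometry = geometry, config = config, meta = meta)
}

e_start <- function(t = 0) list(t = t, kind = "session_start")
e_end <- function(t) list(t = t, kind = "session_end")
e_down <- function(t, x, y, p = 0.5) list(t = t, kind = "pen_down", x = x, y = y, pressure = p)
e_move <- function(t, x, y, p = 0.5) list(t = t, kind = "pen_move", x = x, y = y, pressure = p)
e_up <- function(t, x, y, p = 0.5) list(t = t, kind = "pen_up", x = x, y = y, pressure = p)
e_color <- function(t, color) list(t = t, kind = "select_color", color = color)
e_tool <- function(t, tool) list(t = t, kind = "select_tool", tool = tool)
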