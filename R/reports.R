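# Documentation outputs: canvas playback rendering, the multi-track visual
# report of the session dynamics, and the textual quantitative report.
# All raster output is produced by a pure-R compositor and written with
# png::writePNG, so identical inputs yield byte-identical files.

#' Default color map for rendering
#'
#' Maps palette color names to hex RGB.  Standard R color names resolve via
#' [grDevices::col2rgb()]; the tablet palette's `"skin"` tone has a fixed
#' hex value; any remaining unknown name falls back to a deterministic
#' gray.
#'
#' @param palette Character vector of color names.
#' @return Named character vector of `#RRGGBB` strings.
#' @export
default_color_map <- function(palette = DEFAULT_PALETTE) {
  fixed <- c(skin = "#E8B89A")
  out <- character(length(palette))
  names(out) <- palette
  for (nm in palette) {
    if (nm %in% names(fixed)) {
      out[nm] <- fixed[[nm]]
    } else if (nm %in% grDevices::colors()) {
      rgb <- grDevices::col2rgb(nm)
      out[nm] <- sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])
    } else {
      out[nm] <- "#808080"
    }
  }
  out
}

CANVAS_BACKGROUND <- "#F7F2E3"   # off-white yellowish page

hex_to_rgb01 <- function(hex) as.numeric(grDevices::col2rgb(hex)) / 255

# Stamp a capsule (segment swept by a disc of radius r_cm) into an integer
# pixel matrix.  Pixel (i, j) has center ((j-.5)/ppc, (i-.5)/ppc).
stamp_segment <- function(pix, x1, y1, x2, y2, r_cm, value, ppc) {
  ny <- nrow(pix); nx <- ncol(pix)
  j0 <- max(1L, floor((min(x1, x2) - r_cm) * ppc + 0.5))
  j1 <- min(nx, ceiling((max(x1, x2) + r_cm) * ppc + 0.5))
  i0 <- max(1L, floor((min(y1, y2) - r_cm) * ppc + 0.5))
  i1 <- min(ny, ceiling((max(y1, y2) + r_cm) * ppc + 0.5))
  if (j0 > j1 || i0 > i1) return(pix)
  jj <- j0:j1; ii <- i0:i1
  cx <- (jj - 0.5) / ppc
  cy <- (ii - 0.5) / ppc
  px <- matrix(cx, nrow = length(ii), ncol = length(jj), byrow = TRUE)
  py <- matrix(cy, nrow = length(ii), ncol = length(jj))
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  tt <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2)) else 0
  d2 <- (px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2
  hit <- d2 <= r_cm^2
  sub <- pix[ii, jj, drop = FALSE]
  sub[hit] <- value
  pix[ii, jj] <- sub
  pix
}

#' Render the canvas as it looked at a session time
#'
#' Replays the stroke record up to time `t`: every stroke segment whose
#' samples lie at or before `t` is stamped, in stream order, as a capsule
#' of the stroke's tool width in its stroke color; eraser strokes stamp
#' background (destination-out), removing prior ink along their sweep.
#' Rendering is deterministic.
#'
#' @param record A valid `session_record`.
#' @param t Playback time in seconds, within `[0, session end]`.
#' @param px_per_cm Raster resolution (pixels per cm).
#' @return An object of class `canvas_image`: list with `pixels` (integer
#'   matrix, 0 = background, k = k-th palette color), `colors` (hex map for
#'   the palette), `px_per_cm`, `geometry`, `t`.
#' @seealso [write_canvas_png()], [inked_pixels()]
#' @export
render_canvas <- function(record, t = session_duration(record), px_per_cm = 8) {
  T_end <- session_duration(record)
  if (t < 0 || t > T_end) stop("playback time out of range [0, ", T_end, "]")
  geo <- record$geometry
  cfg <- record$config
  nx <- max(1L, round(geo$width * px_per_cm))
  ny <- max(1L, round(geo$height * px_per_cm))
  pix <- matrix(0L, nrow = ny, ncol = nx)
  strokes <- suppressWarnings(extract_strokes(record))
  for (st in strokes) {
    if (st$t_start > t) next
    s <- st$samples[st$samples$t <= t, , drop = FALSE]
    if (nrow(s) == 0L) next
    value <- if (st$tool == "eraser") 0L else match(st$color, cfg$palette)
    r <- cfg$tool_widths[[st$tool]] / 2
    if (nrow(s) == 1L) {
      pix <- stamp_segment(pix, s$x[1], s$y[1], s$x[1], s$y[1], r, value, px_per_cm)
    } else {
      for (k in seq_len(nrow(s) - 1L))
        pix <- stamp_segment(pix, s$x[k], s$y[k], s$x[k + 1], s$y[k + 1],
                             r, value, px_per_cm)
    }
  }
  structure(list(pixels = pix, colors = default_color_map(cfg$palette),
                 px_per_cm = px_per_cm, geometry = geo, t = t),
            class = "canvas_image")
}

#' Set of inked pixel indices of a canvas image
#'
#' @param img A `canvas_image`.
#' @return Integer vector of linear indices of non-background pixels.
#' @export
inked_pixels <- function(img) which(img$pixels != 0L)

canvas_rgb_array <- function(img) {
  ny <- nrow(img$pixels); nx <- ncol(img$pixels)
  arr <- array(0, dim = c(ny, nx, 3))
  bg <- hex_to_rgb01(CANVAS_BACKGROUND)
  cols <- rbind(bg, t(vapply(img$colors, hex_to_rgb01, numeric(3))))
  idx <- img$pixels + 1L
  for (ch in 1:3) arr[, , ch] <- matrix(cols[idx, ch], nrow = ny, ncol = nx)
  arr
}

#' Write a canvas image (or raw RGB array) as PNG
#'
#' @param img A `canvas_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canvas_png <- function(img, path) {
  png::writePNG(canvas_rgb_array(img), path)
  invisible(path)
}

# --- visual report -----------------------------------------------------------

fill_rect <- function(arr, i0, i1, j0, j1, rgb) {
  i0 <- max(1L, i0); j0 <- max(1L, j0)
  i1 <- min(dim(arr)[1], i1); j1 <- min(dim(arr)[2], j1)
  if (i0 > i1 || j0 > j1) return(arr)
  for (ch in 1:3) arr[i0:i1, j0:j1, ch] <- rgb[ch]
  arr
}

draw_line_px <- function(arr, x0, y0, x1, y1, rgb) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) * 2L)
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  keep <- xs >= 1 & xs <= dim(arr)[2] & ys >= 1 & ys <= dim(arr)[1]
  for (ch in 1:3) arr[cbind(ys[keep], xs[keep], ch)] <- rgb[ch]
  arr
}

TRACK_PALETTE <- c("#4477AA", "#EE6677", "#228833", "#CCBB44",
                   "#66CCEE", "#AA3377", "#BBBBBB", "#222255",
                   "#999933", "#882255")

#' Render the visual session report
#'
#' A multi-track timeline of the session dynamics, drawn from the timed
#' statechart trace: a stroke on/off band with erase epochs shaded gray,
#' categorical bands for the active color, tool, page quarter and
#' center/boundary part of each painting interval, line plots of pressure
#' and gradient (wrap-aware), and canvas snapshots inset below, taken by
#' default at the stroke-count quartiles.  Every painting-region interval
#' of the trace is drawn; nothing is dropped.  Output is deterministic:
#' fixed input gives byte-identical PNG files.
#'
#' @param record A valid `session_record`.
#' @param path Output PNG path, or `NULL` to skip writing.
#' @param trace Optional precomputed `timed_trace`.
#' @param snapshot_times Numeric times of the inset snapshots; defaults to
#'   the stroke-count quartile times.
#' @param width_px Plot width in pixels.
#' @return Invisibly, a list with `intervals` (the trace intervals drawn,
#'   by region) and `path`.
#' @export
visual_report <- function(record, path = NULL, trace = NULL,
                          snapshot_times = NULL, width_px = 900) {
  if (is.null(trace)) trace <- run_statechart(record)
  T_end <- max(attr(trace, "session_duration"), 1e-9)
  cfg <- record$config
  margin <- 20L
  plot_w <- width_px - 2L * margin
  tx <- function(t) margin + 1L + round(t / T_end * (plot_w - 1L))

  strokes <- suppressWarnings(extract_strokes(record))
  if (is.null(snapshot_times)) {
    ns <- length(strokes)
    snapshot_times <- if (ns == 0L) T_end else {
      qs <- ceiling(ns * c(0.25, 0.5, 0.75, 1))
      vapply(unique(qs), function(k) strokes[[k]]$t_end, 0)
    }
  }

  cat_h <- 26L; num_h <- 56L; gap <- 6L
  thumb_ppc <- 2
  thumb_h <- max(1L, round(record$geometry$height * thumb_ppc))
  tracks <- c(stroke = cat_h, colors = cat_h, tools = cat_h,
              quarters = cat_h, parts = cat_h,
              pressure = num_h, gradient = num_h)
  total_h <- margin + sum(tracks + gap) + thumb_h + margin
  arr <- array(1, dim = c(total_h, width_px, 3))  # white

  pick <- function(region) {
    rows <- trace[trace$region == region, , drop = FALSE]
    rows[order(rows$t_start), , drop = FALSE]
  }
  painting <- trace[trace$state == "Painting", , drop = FALSE]
  erase <- trace[trace$state == "Tool:eraser", , drop = FALSE]
  color_iv <- pick("Color"); tool_iv <- pick("Tool")
  quarter_iv <- pick("Quarters"); part_iv <- pick("Parts")
  pressure_iv <- pick("Pressure"); gradient_iv <- pick("Gradient")

  cmap <- default_color_map(cfg$palette)
  cat_color <- function(state, region) {
    val <- sub("^[^:]+:", "", state)
    if (region == "Color") return(cmap[[val]])
    pool <- switch(region,
                   Tool = cfg$toolset,
                   Quarters = c("Q1", "Q2", "Q3", "Q4"),
                   Parts = c("center", "boundary"))
    TRACK_PALETTE[(match(val, pool) - 1L) %% length(TRACK_PALETTE) + 1L]
  }

  y <- margin
  band <- function(arr, ivs, region, y, h) {
    arr <- fill_rect(arr, y, y + h, margin + 1L, margin + plot_w, c(.96, .96, .96))
    for (k in seq_len(nrow(ivs))) {
      rgb <- hex_to_rgb01(cat_color(ivs$state[k], region))
      arr <- fill_rect(arr, y, y + h, tx(ivs$t_start[k]), tx(ivs$t_end[k]), rgb)
    }
    arr
  }
  # stroke on/off band, with erase epochs in gray
  arr <- fill_rect(arr, y, y + cat_h, margin + 1L, margin + plot_w, c(.96, .96, .96))
  for (k in seq_len(nrow(painting)))
    arr <- fill_rect(arr, y, y + cat_h, tx(painting$t_start[k]),
                     tx(painting$t_end[k]), c(.15, .15, .35))
  for (k in seq_len(nrow(erase)))
    arr <- fill_rect(arr, y, y + cat_h, tx(erase$t_start[k]),
                     tx(erase$t_end[k]), c(.55, .55, .55))
  y <- y + cat_h + gap
  arr <- band(arr, color_iv, "Color", y, cat_h); y <- y + cat_h + gap
  arr <- band(arr, tool_iv, "Tool", y, cat_h); y <- y + cat_h + gap
  arr <- band(arr, quarter_iv, "Quarters", y, cat_h); y <- y + cat_h + gap
  arr <- band(arr, part_iv, "Parts", y, cat_h); y <- y + cat_h + gap

  numeric_track <- function(arr, ivs, y, h, lo, hi, wrap = FALSE) {
    arr <- fill_rect(arr, y, y + h, margin + 1L, margin + plot_w, c(.98, .98, .98))
    vals <- suppressWarnings(as.numeric(ivs$annotation))
    ty <- function(v) y + h - round((v - lo) / (hi - lo) * (h - 2L)) - 1L
    if (nrow(ivs) >= 1L) {
      for (k in seq_len(nrow(ivs))) {
        if (is.na(vals[k])) next
        if (k > 1L && !is.na(vals[k - 1L]) &&
            ivs$t_start[k] <= ivs$t_end[k - 1L] + 1e-9 &&
            (!wrap || abs(vals[k] - vals[k - 1L]) <= 180))
          arr <- draw_line_px(arr, tx(ivs$t_start[k - 1L]), ty(vals[k - 1L]),
                              tx(ivs$t_start[k]), ty(vals[k]), c(.1, .1, .6))
        else
          arr <- draw_line_px(arr, tx(ivs$t_start[k]), ty(vals[k]),
                              tx(ivs$t_start[k]), ty(vals[k]), c(.1, .1, .6))
      }
    }
    arr
  }
  arr <- numeric_track(arr, pressure_iv, y, num_h, 0, 1); y <- y + num_h + gap
  arr <- numeric_track(arr, gradient_iv, y, num_h, -180, 180, wrap = TRUE)
  y <- y + num_h + gap

  # snapshots
  thumb_w <- max(1L, round(record$geometry$width * thumb_ppc))
  xoff <- margin
  for (ts in snapshot_times) {
    img <- render_canvas(record, min(ts, T_end), px_per_cm = thumb_ppc)
    sub <- canvas_rgb_array(img)
    i_rng <- y + seq_len(nrow(sub)) - 1L
    j_rng <- xoff + seq_len(ncol(sub)) - 1L
    if (max(j_rng) <= width_px) {
      for (ch in 1:3) arr[i_rng, j_rng, ch] <- sub[, , ch]
    }
    xoff <- xoff + thumb_w + 10L
  }

  if (!is.null(path)) png::writePNG(arr, path)
  invisible(list(intervals = list(painting = painting, erase = erase,
                                  colors = color_iv, tools = tool_iv,
                                  quarters = quarter_iv, parts = part_iv,
                                  pressure = pressure_iv, gradient = gradient_iv),
                 path = path))
}

# --- textual report ----------------------------------------------------------

fmt_pct <- function(x) sprintf("%.1f", x)
fmt_s <- function(x) sprintf("%.3f", x)

#' Render the textual quantitative session report
#'
#' Fixed-layout plain-text sections (session times, colors, tools, strokes,
#' page use, color-by-tool cross sections) with percentages rounded to one
#' decimal.  The report is parseable back into the values it prints with
#' [parse_textual_report()].
#'
#' @param m A `metrics_table` from [compute_metrics()].
#' @return Character vector of report lines.
#' @export
textual_report <- function(m) {
  lines <- c(
    "=== session ===",
    paste0("session duration (s): ", fmt_s(m$session_duration)),
    paste0("drawing time (s): ", fmt_s(m$drawing_time)),
    paste0("drawing time (pct): ", fmt_pct(m$drawing_pct)),
    paste0("idle time (pct): ", fmt_pct(m$idle_pct)),
    paste0("selecting time (s): ", fmt_s(m$selecting_time)),
    "=== colors (pct of drawing time) ===")
  for (k in seq_len(nrow(m$colors)))
    lines <- c(lines, paste0(m$colors$color[k], ": ", fmt_pct(m$colors$pct[k])))
  lines <- c(lines, "=== tools (pct of drawing time) ===")
  for (k in seq_len(nrow(m$tools)))
    lines <- c(lines, paste0(m$tools$tool[k], ": ", fmt_pct(m$tools$pct[k])))
  lines <- c(lines,
    "=== strokes ===",
    paste0("stroke count: ", m$stroke_count),
    paste0("total stroke length (cm): ", fmt_s(m$total_stroke_length)),
    paste0("average stroke length (cm): ", fmt_s(m$avg_stroke_length)),
    paste0("average velocity (cm/s): ", fmt_s(m$avg_velocity)),
    paste0("strokes per second (1/s): ", fmt_s(m$strokes_per_second)),
    paste0("average pressure: ", fmt_s(m$avg_pressure)),
    paste0("average gradient (deg): ", fmt_s(m$avg_gradient)),
    paste0("color switches: ", m$color_switches),
    paste0("tool switches: ", m$tool_switches),
    paste0("switches per color: ", fmt_s(m$switches_per_color)),
    paste0("colors used (pct): ", fmt_pct(m$colors_used_pct)),
    paste0("tools used (pct): ", fmt_pct(m$tools_used_pct)),
    "=== page use (pct of drawing time) ===")
  for (k in seq_len(nrow(m$quarters)))
    lines <- c(lines, paste0(m$quarters$quarter[k], ": ", fmt_pct(m$quarters$pct[k])))
  for (k in seq_len(nrow(m$parts)))
    lines <- c(lines, paste0(m$parts$part[k], ": ", fmt_pct(m$parts$pct[k])))
  lines <- c(lines,
    paste0("area used (pct of page): ", fmt_pct(m$area_used_pct)),
    paste0("stroke start crossovers: ", m$stroke_start_crossovers),
    paste0("stroke crossovers horizontal: ", m$stroke_crossovers_h),
    paste0("stroke crossovers vertical: ", m$stroke_crossovers_v),
    paste0("first stroke in center: ", if (m$first_stroke_in_center) "yes" else "no"),
    "=== cross sections (s of drawing time) ===")
  cs <- m$cross_sections
  for (k in seq_len(nrow(cs)))
    lines <- c(lines, paste0(cs$color[k], " x ", cs$tool[k], ": ", fmt_s(cs$time[k])))
  lines
}

#' Parse a textual report back into numbers
#'
#' @param lines Character vector as produced by [textual_report()].
#' @return Named list of numeric values (section-qualified names for the
#'   per-category lines); `first stroke in center` parses to 0/1.
#' @export
parse_textual_report <- function(lines) {
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^=== ", ln)) {
      section <- sub("^=== (.*) ===$", "\\1", ln)
      next
    }
    m <- regmatches(ln, regexec("^(.*): ([-0-9.]+|yes|no)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- if (m[3] == "yes") 1 else if (m[3] == "no") 0 else as.numeric(m[3])
      key <- if (section %in% c("session", "strokes")) m[2] else paste0(section, "/", m[2])
      out[[key]] <- val
    }
  }
  out
}

#' Write a textual report to a UTF-8 file
#'
#' @param m A `metrics_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_textual_report <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(textual_report(m), con, sep = "\n")
  invisible(path)
}
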