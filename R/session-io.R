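# Session recording format: JSON Lines, one header object followed by one
# event object per line.  All coordinates are cm with the origin at the
# top-left page corner (x rightward, y downward); times are seconds from
# session start.

EVENT_KINDS <- c("session_start", "session_end", "pen_down", "pen_move",
                 "pen_up", "select_color", "select_tool")

DEFAULT_PALETTE <- c("yellow", "red", "blue", "orange", "violet",
                     "green", "black", "white", "pink", "skin")
DEFAULT_TOOLSET <- c("pencil", "pastel", "oils", "water_color",
                     "ink_pen", "eraser")

#' Studio configuration: palette, toolset and tracker thresholds
#'
#' Bundles everything about the drawing apparatus that the tracker needs:
#' the ordered color palette and toolset offered to the sitter, the
#' velocity/pressure/stroke-size class boundaries used by the statechart's
#' stroke-characteristic regions, nominal tool widths for rasterisation,
#' and the coverage-grid cell size.
#'
#' @param palette Ordered character vector of color names (unique).
#' @param toolset Ordered character vector of tool names (unique); the
#'   eraser, if present, must be named `"eraser"`.
#' @param velocity_thresholds Named numeric `c(low_max=, high_min=)` in cm/s;
#'   sample velocities below `low_max` classify as low, above `high_min` as
#'   high, otherwise medium.
#' @param pressure_thresholds Named numeric `c(low_max=, high_min=)` on the
#'   dimensionless pressure scale `[0, 1]`.
#' @param size_thresholds Named numeric `c(short_max=, long_min=)` in cm for
#'   the running stroke-length class.
#' @param tool_widths Named numeric vector of nominal stroke widths (cm),
#'   one per tool; missing tools default to 0.3 cm (eraser 1.2 cm).
#' @param raster_cell Cell size (cm) of the page-coverage grid.
#' @param sample_rate_hint Nominal pen sampling rate (Hz), informational.
#' @return An object of class `studio_config`.
#' @export
studio_config <- function(palette = DEFAULT_PALETTE,
                          toolset = DEFAULT_TOOLSET,
                          velocity_thresholds = c(low_max = 2, high_min = 10),
                          pressure_thresholds = c(low_max = 1 / 3, high_min = 2 / 3),
                          size_thresholds = c(short_max = 2, long_min = 10),
                          tool_widths = NULL,
                          raster_cell = 0.25,
                          sample_rate_hint = 50) {
  palette <- as.character(palette)
  toolset <- as.character(toolset)
  if (length(palette) == 0L) stop("palette must contain at least one color")
  if (length(toolset) == 0L) stop("toolset must contain at least one tool")
  if (anyDuplicated(palette)) stop("palette names must be unique")
  if (anyDuplicated(toolset)) stop("toolset names must be unique")
  vt <- as.numeric(velocity_thresholds)
  if (length(vt) != 2L || !(vt[1] < vt[2]))
    stop("velocity_thresholds must satisfy low_max < high_min")
  pt <- as.numeric(pressure_thresholds)
  if (length(pt) != 2L || !(pt[1] < pt[2]))
    stop("pressure_thresholds must satisfy low_max < high_min")
  st <- as.numeric(size_thresholds)
  if (length(st) != 2L || !(st[1] < st[2]))
    stop("size_thresholds must satisfy short_max < long_min")
  widths <- rep(0.3, length(toolset))
  names(widths) <- toolset
  if ("eraser" %in% toolset) widths[["eraser"]] <- 1.2
  if (!is.null(tool_widths)) {
    bad <- setdiff(names(tool_widths), toolset)
    if (length(bad)) stop("tool_widths for unknown tools: ", paste(bad, collapse = ", "))
    widths[names(tool_widths)] <- as.numeric(tool_widths)
  }
  if (any(widths <= 0)) stop("all tool widths must be positive")
  if (!is.numeric(raster_cell) || raster_cell <= 0) stop("raster_cell must be > 0")
  # numeric fields live at the serializer's 1e-6 precision so that
  # write/read round-trips reproduce the configuration exactly
  r6 <- function(x) round(x, 6)
  structure(list(
    palette = palette,
    toolset = toolset,
    velocity_thresholds = c(low_max = r6(vt[1]), high_min = r6(vt[2])),
    pressure_thresholds = c(low_max = r6(pt[1]), high_min = r6(pt[2])),
    size_thresholds = c(short_max = r6(st[1]), long_min = r6(st[2])),
    tool_widths = r6(widths),
    raster_cell = r6(raster_cell),
    sample_rate_hint = r6(as.numeric(sample_rate_hint))
  ), class = "studio_config")
}

#' Page geometry: dimensions and the center/boundary split
#'
#' The page is partitioned two ways: into four quarters by its midlines
#' (Q1 top-left, Q2 bottom-left, Q3 top-right, Q4 bottom-right) and into a
#' centered "center" rectangle versus its "boundary" complement.
#'
#' @param width,height Page dimensions in cm (> 0).
#' @param center_fraction Linear scale of the centered center rectangle
#'   relative to the page, strictly in (0, 1).
#' @return An object of class `page_geometry`.
#' @export
page_geometry <- function(width = 28, height = 16, center_fraction = 0.5) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("page dimensions must be positive")
  if (!is.numeric(center_fraction) || center_fraction <= 0 || center_fraction >= 1)
    stop("center_fraction must lie strictly inside (0, 1)")
  structure(list(width = round(as.numeric(width), 6),
                 height = round(as.numeric(height), 6),
                 center_fraction = round(as.numeric(center_fraction), 6)),
            class = "page_geometry")
}

#' Session metadata
#'
#' @param subject Subject identifier.
#' @param groups Named list of group labels (e.g. `list(gender="F")`).
#' @param task Task label, e.g. `"calibration"`, `"positive"`, `"negative"`,
#'   `"htp"`.
#' @return A plain list with class `session_meta`.
#' @export
session_meta <- function(subject = "anonymous", groups = list(), task = "free") {
  structure(list(subject = as.character(subject),
                 groups = lapply(groups, as.character),
                 task = as.character(task)),
            class = "session_meta")
}

# Round the numeric payload of events to the canonical 1e-6 precision the
# serializer writes, so that write/read round-trips are exact identities.
canonicalize_events <- function(events) {
  for (col in c("t", "x", "y", "pressure"))
    events[[col]] <- round(events[[col]], 6)
  events
}

empty_events <- function() {
  data.frame(t = numeric(0), kind = character(0), x = numeric(0),
             y = numeric(0), pressure = numeric(0), color = character(0),
             tool = character(0), stringsAsFactors = FALSE)
}

#' Construct and validate a session record
#'
#' A session record is the full timestamped event stream of one drawing
#' session (pen trajectory samples, color/tool selections, session
#' start/end) plus the page geometry, studio configuration and metadata.
#'
#' @param events Data frame with columns `t`, `kind`, `x`, `y`, `pressure`,
#'   `color`, `tool`; non-applicable fields are `NA`.
#' @param geometry A [page_geometry()].
#' @param config A [studio_config()].
#' @param meta A [session_meta()].
#' @return A validated object of class `session_record`.
#' @seealso [read_session()], [write_session()], [extract_strokes()]
#' @export
session_record <- function(events, geometry = page_geometry(),
                           config = studio_config(), meta = session_meta()) {
  stopifnot(inherits(geometry, "page_geometry"),
            inherits(config, "studio_config"))
  if (is.null(events) || nrow(events) == 0L) events <- empty_events()
  need <- c("t", "kind", "x", "y", "pressure", "color", "tool")
  for (col in setdiff(need, names(events))) events[[col]] <- NA
  events <- events[, need]
  events$t <- as.numeric(events$t)
  events$kind <- as.character(events$kind)
  events$x <- as.numeric(events$x)
  events$y <- as.numeric(events$y)
  events$pressure <- as.numeric(events$pressure)
  events$color <- as.character(events$color)
  events$tool <- as.character(events$tool)
  events <- canonicalize_events(events)
  rownames(events) <- NULL
  rec <- structure(list(events = events, geometry = geometry,
                        config = config, meta = meta),
                   class = "session_record")
  validate_session(rec)
  rec
}

#' Validate a session record against the stream invariants
#'
#' Checks monotone timestamps, pen event nesting (`pen_move`/`pen_up` only
#' between a `pen_down` and its `pen_up`), the placement of
#' `session_start`/`session_end`, palette/toolset membership of selections,
#' coordinate bounds and pressure range.  Errors name the offending event's
#' line (1-based position in the stream).
#'
#' @param record A `session_record`.
#' @return The record, invisibly, if valid.
#' @export
validate_session <- function(record) {
  ev <- record$events
  geo <- record$geometry
  cfg <- record$config
  n <- nrow(ev)
  fail <- function(i, msg) stop(sprintf("event %d: %s", i, msg), call. = FALSE)
  if (n == 0L) return(invisible(record))
  bad_kind <- which(!ev$kind %in% EVENT_KINDS)
  if (length(bad_kind)) fail(bad_kind[1], paste0("unknown event kind '", ev$kind[bad_kind[1]], "'"))
  if (anyNA(ev$t)) fail(which(is.na(ev$t))[1], "missing timestamp")
  if (any(ev$t < 0)) fail(which(ev$t < 0)[1], "negative timestamp")
  dec <- which(diff(ev$t) < 0)
  if (length(dec)) fail(dec[1] + 1L, "decreasing timestamp")
  starts <- which(ev$kind == "session_start")
  if (length(starts) != 1L || starts != 1L)
    fail(if (length(starts)) starts[length(starts)] else 1L,
         "exactly one session_start required, as the first event")
  ends <- which(ev$kind == "session_end")
  if (length(ends) > 1L) fail(ends[2], "at most one session_end allowed")
  if (length(ends) == 1L && ends != n) fail(ends, "session_end must be the last event")
  pen <- ev$kind %in% c("pen_down", "pen_move", "pen_up")
  # nesting: depth 0 outside strokes, 1 inside
  depth <- 0L
  for (i in seq_len(n)) {
    k <- ev$kind[i]
    if (k == "pen_down") {
      if (depth != 0L) fail(i, "pen_down inside an open stroke")
      depth <- 1L
    } else if (k == "pen_move") {
      if (depth != 1L) fail(i, "pen_move outside a stroke")
    } else if (k == "pen_up") {
      if (depth != 1L) fail(i, "pen_up without matching pen_down")
      depth <- 0L
    } else if (k %in% c("select_color", "select_tool", "session_end")) {
      if (depth != 0L) fail(i, paste0(k, " inside an open stroke"))
    }
  }
  if (any(pen)) {
    idx <- which(pen)
    if (anyNA(ev$x[idx]) || anyNA(ev$y[idx]) || anyNA(ev$pressure[idx]))
      fail(idx[which(is.na(ev$x[idx]) | is.na(ev$y[idx]) | is.na(ev$pressure[idx]))[1]],
           "pen event missing x/y/pressure")
    if (any(!is.finite(ev$x[idx])) || any(!is.finite(ev$y[idx])))
      fail(idx[which(!is.finite(ev$x[idx]) | !is.finite(ev$y[idx]))[1]],
           "non-finite coordinate")
    out <- ev$x[idx] < 0 | ev$x[idx] > geo$width | ev$y[idx] < 0 | ev$y[idx] > geo$height
    if (any(out)) fail(idx[which(out)[1]], "coordinate outside the page")
    pr <- ev$pressure[idx] < 0 | ev$pressure[idx] > 1
    if (any(pr)) fail(idx[which(pr)[1]], "pressure outside [0, 1]")
  }
  sc <- which(ev$kind == "select_color")
  badc <- sc[!ev$color[sc] %in% cfg$palette]
  if (length(badc)) fail(badc[1], paste0("unknown color '", ev$color[badc[1]], "'"))
  st <- which(ev$kind == "select_tool")
  badt <- st[!ev$tool[st] %in% cfg$toolset]
  if (length(badt)) fail(badt[1], paste0("unknown tool '", ev$tool[badt[1]], "'"))
  invisible(record)
}

# --- canonical JSON (sorted keys, fixed float precision) ---------------------

canon_num <- function(x) {
  if (!is.finite(x)) stop("non-finite number in canonical serialization")
  if (x == floor(x) && abs(x) < 1e12) return(sprintf("%.0f", x))
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  s
}

canon_str <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

canon_json <- function(x, named = !is.null(names(x))) {
  if (is.list(x)) {
    if (named) {
      ord <- order(names(x))
      parts <- vapply(ord, function(i)
        paste0(canon_str(names(x)[i]), ":", canon_json(x[[i]])), "")
      paste0("{", paste(parts, collapse = ","), "}")
    } else {
      paste0("[", paste(vapply(x, canon_json, ""), collapse = ","), "]")
    }
  } else if (length(x) != 1L) {
    paste0("[", paste(vapply(x, canon_json, ""), collapse = ","), "]")
  } else if (is.character(x)) {
    canon_str(x)
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else {
    canon_num(as.numeric(x))
  }
}

header_list <- function(record) {
  geo <- record$geometry
  cfg <- record$config
  meta <- record$meta
  list(
    geometry = list(width = geo$width, height = geo$height,
                    center_fraction = geo$center_fraction),
    config = list(
      palette = as.list(cfg$palette),
      toolset = as.list(cfg$toolset),
      velocity_thresholds = list(low_max = cfg$velocity_thresholds[["low_max"]],
                                 high_min = cfg$velocity_thresholds[["high_min"]]),
      pressure_thresholds = list(low_max = cfg$pressure_thresholds[["low_max"]],
                                 high_min = cfg$pressure_thresholds[["high_min"]]),
      size_thresholds = list(short_max = cfg$size_thresholds[["short_max"]],
                             long_min = cfg$size_thresholds[["long_min"]]),
      tool_widths = as.list(cfg$tool_widths),
      raster_cell = cfg$raster_cell,
      sample_rate_hint = cfg$sample_rate_hint
    ),
    meta = list(subject = meta$subject,
                groups = if (length(meta$groups)) meta$groups else structure(list(), names = character(0)),
                task = meta$task)
  )
}

event_list <- function(row) {
  out <- list(t = row$t, kind = row$kind)
  if (row$kind %in% c("pen_down", "pen_move", "pen_up")) {
    out$x <- row$x; out$y <- row$y; out$pressure <- row$pressure
  } else if (row$kind == "select_color") {
    out$color <- row$color
  } else if (row$kind == "select_tool") {
    out$tool <- row$tool
  }
  out
}

#' Write a session record to a JSON-Lines file
#'
#' Line 1 is a header object (geometry, config, meta); each subsequent line
#' is one event.  Serialization is canonical — keys sorted, floats at fixed
#' 1e-6 precision, LF line endings — so writing the same record twice
#' produces byte-identical files and write/read round-trips are stable.
#'
#' @param record A valid `session_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  validate_session(record)
  ev <- record$events
  pen <- ev$kind %in% c("pen_down", "pen_move", "pen_up")
  if (any(pen & (!is.finite(ev$x) | !is.finite(ev$y) | !is.finite(ev$pressure))))
    stop("refusing to write non-finite pen sample")
  lines <- character(nrow(ev) + 1L)
  lines[1] <- canon_json(header_list(record))
  for (i in seq_len(nrow(ev)))
    lines[i + 1L] <- canon_json(event_list(ev[i, ]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a session record from a JSON-Lines file
#'
#' Parses the header and event lines written by [write_session()] (or any
#' producer of the documented schema), then validates the full stream.
#' Malformed lines raise a parse error naming the line number; invariant
#' violations raise a validation error naming the offending event.
#'
#' @param path Path to a session `.jsonl` file.
#' @return A validated `session_record`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty session file: ", path)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e)
               stop(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(e)),
                    call. = FALSE))
  }
  hdr <- parse_line(1)
  if (is.null(hdr$geometry) || is.null(hdr$config))
    stop("line 1: header must carry geometry and config", call. = FALSE)
  geo <- page_geometry(hdr$geometry$width, hdr$geometry$height,
                       hdr$geometry$center_fraction)
  hc <- hdr$config
  cfg <- studio_config(
    palette = unlist(hc$palette),
    toolset = unlist(hc$toolset),
    velocity_thresholds = c(low_max = hc$velocity_thresholds$low_max,
                            high_min = hc$velocity_thresholds$high_min),
    pressure_thresholds = c(low_max = hc$pressure_thresholds$low_max,
                            high_min = hc$pressure_thresholds$high_min),
    size_thresholds = c(short_max = hc$size_thresholds$short_max,
                        long_min = hc$size_thresholds$long_min),
    tool_widths = unlist(hc$tool_widths),
    raster_cell = hc$raster_cell,
    sample_rate_hint = hc$sample_rate_hint
  )
  meta <- session_meta(subject = hdr$meta$subject %||% "anonymous",
                       groups = as.list(hdr$meta$groups),
                       task = hdr$meta$task %||% "free")
  n <- length(lines) - 1L
  ev <- data.frame(t = numeric(n), kind = character(n), x = rep(NA_real_, n),
                   y = rep(NA_real_, n), pressure = rep(NA_real_, n),
                   color = rep(NA_character_, n), tool = rep(NA_character_, n),
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    e <- parse_line(i + 1L)
    if (is.null(e$t) || is.null(e$kind))
      stop(sprintf("line %d: event missing t or kind", i + 1L), call. = FALSE)
    ev$t[i] <- as.numeric(e$t)
    ev$kind[i] <- as.character(e$kind)
    if (!is.null(e$x)) ev$x[i] <- as.numeric(e$x)
    if (!is.null(e$y)) ev$y[i] <- as.numeric(e$y)
    if (!is.null(e$pressure)) ev$pressure[i] <- as.numeric(e$pressure)
    if (!is.null(e$color)) ev$color[i] <- as.character(e$color)
    if (!is.null(e$tool)) ev$tool[i] <- as.character(e$tool)
  }
  session_record(ev, geometry = geo, config = cfg, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract strokes from a session record
#'
#' Cuts the event stream into strokes — one per pen-down ... pen-up span —
#' each carrying its sample trajectory `(t, x, y, pressure)` and the color
#' and tool most recently selected before its pen-down.  If drawing begins
#' before any selection, the first configured palette color / tool are
#' assumed (with a warning).  A stream that ends inside an open stroke is
#' closed at its last pen sample (with a warning).
#'
#' @param record A valid `session_record`.
#' @return A list of `stroke` objects, ordered by start time.  Each stroke
#'   is a list with `samples` (data frame `t,x,y,pressure`), `color`,
#'   `tool`, `t_start`, `t_end`.
#' @export
extract_strokes <- function(record) {
  ev <- record$events
  cfg <- record$config
  strokes <- list()
  cur_color <- cfg$palette[1]
  cur_tool <- cfg$toolset[1]
  selected_once <- FALSE
  open_idx <- NULL
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k == "select_color") {
      cur_color <- ev$color[i]; selected_once <- TRUE
    } else if (k == "select_tool") {
      cur_tool <- ev$tool[i]; selected_once <- TRUE
    } else if (k == "pen_down") {
      open_idx <- i
      if (!selected_once && length(strokes) == 0L)
        warning("drawing before any selection: defaulting to first palette color and first tool")
    } else if (k == "pen_up") {
      strokes[[length(strokes) + 1L]] <-
        new_stroke(ev[open_idx:i, ], cur_color, cur_tool)
      open_idx <- NULL
    }
  }
  if (!is.null(open_idx)) {
    warning("stream ended inside an open stroke; closing at last pen sample")
    strokes[[length(strokes) + 1L]] <-
      new_stroke(ev[open_idx:nrow(ev), ], cur_color, cur_tool)
  }
  strokes
}

new_stroke <- function(ev_rows, color, tool) {
  pen <- ev_rows[ev_rows$kind %in% c("pen_down", "pen_move", "pen_up"), ]
  samples <- data.frame(t = pen$t, x = pen$x, y = pen$y,
                        pressure = pen$pressure, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  structure(list(samples = samples, color = color, tool = tool,
                 t_start = samples$t[1], t_end = samples$t[nrow(samples)]),
            class = "stroke")
}

#' @export
print.session_record <- function(x, ...) {
  ev <- x$events
  n_strokes <- sum(ev$kind == "pen_down")
  cat(sprintf("<session_record> subject=%s task=%s: %d events, %d strokes, %.2f s\n",
              x$meta$subject, x$meta$task, nrow(ev), n_strokes,
              session_duration(x)))
  invisible(x)
}

#' Session duration in seconds
#'
#' Time of `session_end` if present, otherwise of the last event (a stream
#' truncated before its explicit end is closed at its last event).
#'
#' @param record A `session_record`.
#' @return Duration in seconds (0 for an eventless record).
#' @export
session_duration <- function(record) {
  ev <- record$events
  if (nrow(ev) == 0L) return(0)
  max(ev$t)
}
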