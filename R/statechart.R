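# Hierarchical/orthogonal statechart of the artwork's construction process,
# executed over a session's event stream to yield a timed occupancy trace.
#
# State tree (leaf names are "Region:value"):
#   ArtRoom (exclusive)
#     ArtRoomSessionOff
#     ArtRoomSessionOn (orthogonal)
#       Client, ArtTherapist                  -- structural stubs, never driven
#       ArtWork (exclusive)
#         Idle | Materials_Selecting | Painting (orthogonal)
#           Materials_Selected (orthogonal)
#             Color (exclusive: one leaf per palette color)
#             Tool  (exclusive: one leaf per tool)
#           Stroke_Characteristics (orthogonal)
#             Velocity (low/medium/high), Gradient (8 compass sectors),
#             Pressure (low/medium/high), Size (short/medium/long)
#           Page_Use (orthogonal)
#             Quarters (Q1..Q4), Parts (center/boundary)

GRADIENT_SECTORS <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")

state_node <- function(name, kind, children = list()) {
  structure(list(name = name, kind = kind, children = children),
            class = "state_node")
}

#' Build the artwork statechart for a studio configuration
#'
#' Constructs the hierarchical state tree tracking the artwork: the session
#' on/off toggle at the root, the exclusive Idle / Materials_Selecting /
#' Painting modes of the creator, and — while Painting — the orthogonal
#' regions for the selected materials (one color leaf per palette entry,
#' one tool leaf per toolset entry), the stroke characteristics (velocity,
#' gradient as 8 compass sectors, pressure, running stroke size) and the
#' page use (quarters and center/boundary parts), all simultaneously
#' active.
#'
#' @param config A [studio_config()]; its palette and toolset size the
#'   Color and Tool regions.
#' @return The root `state_node`; use [model_regions()] for a flat index.
#' @export
build_artwork_model <- function(config = studio_config()) {
  stopifnot(inherits(config, "studio_config"))
  if (length(config$palette) == 0L) stop("empty palette")
  if (length(config$toolset) == 0L) stop("empty toolset")
  excl_leaves <- function(region, values)
    state_node(region, "exclusive",
               lapply(values, function(v) state_node(paste0(region, ":", v), "leaf")))
  painting <- state_node("Painting", "orthogonal", list(
    state_node("Materials_Selected", "orthogonal", list(
      excl_leaves("Color", config$palette),
      excl_leaves("Tool", config$toolset)
    )),
    state_node("Stroke_Characteristics", "orthogonal", list(
      excl_leaves("Velocity", c("low", "medium", "high")),
      excl_leaves("Gradient", GRADIENT_SECTORS),
      excl_leaves("Pressure", c("low", "medium", "high")),
      excl_leaves("Size", c("short", "medium", "long"))
    )),
    state_node("Page_Use", "orthogonal", list(
      excl_leaves("Quarters", c("Q1", "Q2", "Q3", "Q4")),
      excl_leaves("Parts", c("center", "boundary"))
    ))
  ))
  artwork <- state_node("ArtWork", "exclusive", list(
    state_node("Idle", "leaf"),
    state_node("Materials_Selecting", "leaf"),
    painting
  ))
  session_on <- state_node("ArtRoomSessionOn", "orthogonal", list(
    artwork,
    state_node("Client", "leaf"),
    state_node("ArtTherapist", "leaf")
  ))
  state_node("ArtRoom", "exclusive", list(
    state_node("ArtRoomSessionOff", "leaf"),
    session_on
  ))
}

#' Flat index of a state model
#'
#' @param model Root `state_node` from [build_artwork_model()].
#' @return Data frame with one row per state: `name`, `kind`, `parent`
#'   (`NA` for the root).
#' @export
model_regions <- function(model) {
  rows <- list()
  walk <- function(node, parent) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = node$name, kind = node$kind,
      parent = if (is.null(parent)) NA_character_ else parent,
      stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, node$name)
  }
  walk(model, NULL)
  do.call(rbind, rows)
}

#' Check a configuration for region consistency
#'
#' A configuration (set of active state names) is valid when it is
#' root-closed and region-consistent: the root is active, every active
#' exclusive region has exactly one active child, every active orthogonal
#' state has all children active, and no inactive state has active
#' children.
#'
#' @param model Root `state_node`.
#' @param configuration Character vector of active state names.
#' @return `TRUE` if consistent, otherwise `FALSE` with attribute
#'   `"reason"`.
#' @export
configuration_consistent <- function(model, configuration) {
  bad <- function(reason) structure(FALSE, reason = reason)
  idx <- model_regions(model)
  unknown <- setdiff(configuration, idx$name)
  if (length(unknown)) return(bad(paste("unknown states:", paste(unknown, collapse = ", "))))
  check <- function(node) {
    active <- node$name %in% configuration
    kids_active <- vapply(node$children, function(ch) ch$name %in% configuration, TRUE)
    if (!active && any(kids_active))
      return(bad(paste0("inactive ", node$name, " has active children")))
    if (active && node$kind == "exclusive" && sum(kids_active) != 1L)
      return(bad(paste0("exclusive region ", node$name, " has ",
                        sum(kids_active), " active children")))
    if (active && node$kind == "orthogonal" && !all(kids_active))
      return(bad(paste0("orthogonal state ", node$name, " missing active children")))
    for (ch in node$children) {
      r <- check(ch)
      if (!isTRUE(r)) return(r)
    }
    TRUE
  }
  if (!model$name %in% configuration) return(bad("root not active"))
  check(model)
}

# --- sample classifiers ------------------------------------------------------

#' Kinematic and spatial classifiers for pen samples
#'
#' `classify_velocity`, `classify_pressure` and `classify_size` map a value
#' to its low/medium/high (short/medium/long) class using the thresholds in
#' the studio configuration (class boundaries belong to "medium").
#' `gradient_angle` converts a displacement to a direction angle in degrees
#' with 0 = rightward and +90 = up (screen y grows downward), range
#' (-180, 180]; `classify_gradient` maps an angle to one of eight 45-degree
#' compass sectors centered on 0, +-45, +-90, +-135 and 180 degrees.
#' `quarter_of` returns Q1..Q4 (Q1 top-left, Q2 bottom-left, Q3 top-right,
#' Q4 bottom-right; points on a midline go left/top).  `part_of` returns
#' `"center"` for points inside the centered center rectangle (edge
#' inclusive), else `"boundary"`.
#'
#' @param v Velocity in cm/s.
#' @param p Pressure in `[0, 1]`.
#' @param len Running stroke length in cm.
#' @param dx,dy Displacement components in page coordinates (cm).
#' @param angle Direction angle in degrees.
#' @param x,y Page coordinates (cm).
#' @param config A [studio_config()].
#' @param geometry A [page_geometry()].
#' @return Class name(s) as character; `gradient_angle` returns degrees.
#'   All are vectorized.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classify_velocity <- function(v, config) {
  th <- config$velocity_thresholds
  ifelse(v < th[["low_max"]], "low", ifelse(v > th[["high_min"]], "high", "medium"))
}

#' @rdname classifiers
#' @export
classify_pressure <- function(p, config) {
  th <- config$pressure_thresholds
  ifelse(p < th[["low_max"]], "low", ifelse(p > th[["high_min"]], "high", "medium"))
}

#' @rdname classifiers
#' @export
classify_size <- function(len, config) {
  th <- config$size_thresholds
  ifelse(len < th[["short_max"]], "short",
         ifelse(len > th[["long_min"]], "long", "medium"))
}

#' @rdname classifiers
#' @export
gradient_angle <- function(dx, dy) {
  a <- atan2(-dy, dx) * 180 / pi
  ifelse(a <= -180, a + 360, a)     # fold -180 onto +180
}

#' @rdname classifiers
#' @export
classify_gradient <- function(angle) {
  k <- round(angle / 45) %% 8      # 0=E, 1=NE, ..., 7=SE
  GRADIENT_SECTORS[k + 1]
}

#' @rdname classifiers
#' @export
quarter_of <- function(x, y, geometry) {
  left <- x <= geometry$width / 2
  top <- y <= geometry$height / 2
  ifelse(top, ifelse(left, "Q1", "Q3"), ifelse(left, "Q2", "Q4"))
}

#' @rdname classifiers
#' @export
part_of <- function(x, y, geometry) {
  f <- geometry$center_fraction
  hw <- f * geometry$width / 2
  hh <- f * geometry$height / 2
  inside <- abs(x - geometry$width / 2) <= hw & abs(y - geometry$height / 2) <= hh
  ifelse(inside, "center", "boundary")
}

# Leaf set for a painting sample context.  Page-use leaves are evaluated
# at the forward segment midpoint (px, py) — the trajectory the sample's
# occupancy interval covers — falling back to the sample position itself.
painting_leaves <- function(ctx, config, geometry) {
  px <- ctx$px %||% ctx$x
  py <- ctx$py %||% ctx$y
  c(paste0("Color:", ctx$color),
    paste0("Tool:", ctx$tool),
    paste0("Velocity:", classify_velocity(ctx$velocity, config)),
    paste0("Gradient:", classify_gradient(ctx$angle)),
    paste0("Pressure:", classify_pressure(ctx$pressure, config)),
    paste0("Size:", classify_size(ctx$cum_length, config)),
    paste0("Quarters:", quarter_of(px, py, geometry)),
    paste0("Parts:", part_of(px, py, geometry)))
}

PAINTING_SCAFFOLD <- c("Painting", "Materials_Selected", "Stroke_Characteristics",
                       "Page_Use", "Color", "Tool", "Velocity", "Gradient",
                       "Pressure", "Size", "Quarters", "Parts")
SESSION_ON_BASE <- c("ArtRoom", "ArtRoomSessionOn", "Client", "ArtTherapist", "ArtWork")

#' Single statechart transition
#'
#' Applies one event to a configuration.  `context` supplies the concrete
#' values that drive leaf-state choice while Painting: the active `color`
#' and `tool`, the current sample window's `velocity` (cm/s), `angle`
#' (degrees), `pressure`, `cum_length` (stroke length so far, cm), the
#' sample position `x`, `y`, and optionally the forward-segment midpoint
#' `px`, `py` used for the page-use leaves (defaults to `x`, `y`).
#' Events other than `session_start` arriving while the
#' session is off raise a validation error; event/state pairs with no
#' modeled transition are no-ops.
#'
#' @param model Root `state_node`.
#' @param configuration Character vector of active states.
#' @param event A one-row data frame (or list) with at least `kind`.
#' @param context List of concrete sample-window values (see above).
#' @param config,geometry The session's [studio_config()] and
#'   [page_geometry()].
#' @return The next configuration (character vector, sorted).
#' @export
step <- function(model, configuration, event, context = list(),
                 config = studio_config(), geometry = page_geometry()) {
  kind <- event$kind
  on <- "ArtRoomSessionOn" %in% configuration
  if (!on && kind != "session_start")
    stop("event '", kind, "' while the session is off", call. = FALSE)
  idle_conf <- sort(c(SESSION_ON_BASE, "Idle"))
  switch(kind,
    session_start = idle_conf,
    session_end = sort(c("ArtRoom", "ArtRoomSessionOff")),
    pen_down = sort(c(SESSION_ON_BASE, PAINTING_SCAFFOLD,
                      painting_leaves(context, config, geometry))),
    pen_move = {
      if (!"Painting" %in% configuration) configuration
      else sort(c(SESSION_ON_BASE, PAINTING_SCAFFOLD,
                  painting_leaves(context, config, geometry)))
    },
    pen_up = idle_conf,
    select_color = ,
    select_tool = {
      if ("Painting" %in% configuration) configuration
      else sort(c(SESSION_ON_BASE, "Materials_Selecting"))
    },
    configuration)
}

#' Execute the artwork statechart over a full session
#'
#' Folds [step()] over the record's event stream and emits a timed trace:
#' one interval per maximal span over which a state stays active, for every
#' state in the tree (leaves and ancestors).  While Painting, the
#' stroke-characteristic leaves are re-evaluated at every pen sample from
#' the local two-sample window (the segment ending at the sample); the
#' first sample of a stroke inherits the second sample's kinematic
#' classification, and a single-sample stroke classifies as velocity 0 and
#' angle 0.  A zero-dt window keeps the previous classification.  The
#' page-use leaves (quarter, center/boundary) of a sample are evaluated at
#' the midpoint of the forward segment — the piece of trajectory the
#' sample's occupancy interval actually covers — so occupancy is exact for
#' streams sampled at region boundaries.  Zero-length intervals are not
#' emitted.
#'
#' @param record A valid `session_record`.
#' @param keep_configurations If `TRUE`, attach the list of intermediate
#'   configurations (one per event, after the event) as attribute
#'   `"configurations"`.
#' @return A `timed_trace`: data frame with columns `state`, `region`
#'   (parent region of the state, `""` for the root), `t_start`, `t_end`,
#'   `annotation`; attribute `"session_duration"`.
#' @export
run_statechart <- function(record, keep_configurations = FALSE) {
  validate_session(record)
  ev <- record$events
  cfg <- record$config
  geo <- record$geometry
  model <- build_artwork_model(cfg)
  idx <- model_regions(model)
  parent_of <- structure(idx$parent, names = idx$name)
  n <- nrow(ev)
  T_end <- session_duration(record)

  # Pre-compute, for each pen event, the window context driving the leaves.
  pen_idx <- which(ev$kind %in% c("pen_down", "pen_move", "pen_up"))
  ctxs <- vector("list", n)
  cur_color <- cfg$palette[1]
  cur_tool <- cfg$toolset[1]
  prev_sample <- NULL
  cum_len <- 0
  pend_v <- 0; pend_a <- 0
  i2 <- 0L
  for (i in seq_len(n)) {
    k <- ev$kind[i]
    if (k == "select_color") cur_color <- ev$color[i]
    if (k == "select_tool") cur_tool <- ev$tool[i]
    if (k == "pen_down") {
      cum_len <- 0
      # first sample inherits the second's kinematic classification
      j <- i + 1L
      v <- 0; a <- 0
      if (j <= n && ev$kind[j] %in% c("pen_move", "pen_up")) {
        dt <- ev$t[j] - ev$t[i]
        dx <- ev$x[j] - ev$x[i]; dy <- ev$y[j] - ev$y[i]
        if (dt > 0) { v <- sqrt(dx^2 + dy^2) / dt; a <- gradient_angle(dx, dy) }
      }
      ctxs[[i]] <- list(color = cur_color, tool = cur_tool, velocity = v,
                        angle = a, pressure = ev$pressure[i], cum_length = 0,
                        x = ev$x[i], y = ev$y[i])
      prev_sample <- list(t = ev$t[i], x = ev$x[i], y = ev$y[i])
      pend_v <- v; pend_a <- a
      if (j <= n && ev$kind[j] %in% c("pen_move", "pen_up")) {
        ctxs[[i]]$px <- (ev$x[i] + ev$x[j]) / 2
        ctxs[[i]]$py <- (ev$y[i] + ev$y[j]) / 2
      }
    } else if (k %in% c("pen_move", "pen_up")) {
      dt <- ev$t[i] - prev_sample$t
      dx <- ev$x[i] - prev_sample$x; dy <- ev$y[i] - prev_sample$y
      d <- sqrt(dx^2 + dy^2)
      cum_len <- cum_len + d
      if (dt > 0) { pend_v <- d / dt; pend_a <- gradient_angle(dx, dy) }
      ctxs[[i]] <- list(color = cur_color, tool = cur_tool, velocity = pend_v,
                        angle = pend_a, pressure = ev$pressure[i],
                        cum_length = cum_len,
                        x = ev$x[i], y = ev$y[i])
      j <- i + 1L
      if (k == "pen_move" && j <= n && ev$kind[j] %in% c("pen_move", "pen_up")) {
        ctxs[[i]]$px <- (ev$x[i] + ev$x[j]) / 2
        ctxs[[i]]$py <- (ev$y[i] + ev$y[j]) / 2
      }
      prev_sample <- list(t = ev$t[i], x = ev$x[i], y = ev$y[i])
    }
  }

  # Fold step, recording interval openings/closings on configuration diffs.
  open_t <- list()        # state -> t opened
  open_ann <- list()      # state -> annotation
  out_state <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  out_ann <- character(0)
  configs <- if (keep_configurations) vector("list", n) else NULL
  conf <- character(0)    # before session_start nothing is active

  annotation_for <- function(state, ctx) {
    if (is.null(ctx)) return("")
    pre <- sub(":.*$", "", state)
    switch(pre,
      Color = ctx$color, Tool = ctx$tool,
      Velocity = sprintf("%.4f", ctx$velocity),
      Gradient = sprintf("%.2f", ctx$angle),
      Pressure = sprintf("%.4f", ctx$pressure),
      Size = sprintf("%.4f", ctx$cum_length),
      Quarters = sub("^Quarters:", "", state),
      Parts = sub("^Parts:", "", state),
      "")
  }

  for (i in seq_len(n)) {
    t <- ev$t[i]
    ctx <- ctxs[[i]]
    new_conf <- step(model, conf, ev[i, ], context = ctx,
                     config = cfg, geometry = geo)
    closed <- setdiff(conf, new_conf)
    opened <- setdiff(new_conf, conf)
    # also refresh annotations: a leaf that stays active keeps its interval
    for (s in closed) {
      t0 <- open_t[[s]]
      if (t > t0) {
        out_state <- c(out_state, s); out_start <- c(out_start, t0)
        out_end <- c(out_end, t); out_ann <- c(out_ann, open_ann[[s]])
      }
      open_t[[s]] <- NULL; open_ann[[s]] <- NULL
    }
    for (s in opened) {
      open_t[[s]] <- t
      open_ann[[s]] <- annotation_for(s, ctx)
    }
    conf <- new_conf
    if (keep_configurations) configs[[i]] <- conf
  }
  for (s in names(open_t)) {
    t0 <- open_t[[s]]
    if (T_end > t0) {
      out_state <- c(out_state, s); out_start <- c(out_start, t0)
      out_end <- c(out_end, T_end); out_ann <- c(out_ann, open_ann[[s]])
    }
  }
  region_of <- unname(parent_of[out_state])
  region_of[is.na(region_of)] <- ""
  trace <- data.frame(state = out_state,
                      region = region_of,
                      t_start = out_start, t_end = out_end,
                      annotation = out_ann, stringsAsFactors = FALSE)
  trace <- trace[order(trace$t_start, trace$state), ]
  rownames(trace) <- NULL
  class(trace) <- c("timed_trace", "data.frame")
  attr(trace, "session_duration") <- T_end
  if (keep_configurations) attr(trace, "configurations") <- configs
  trace
}

#' Total occupancy of a state in a timed trace
#'
#' @param trace A `timed_trace` from [run_statechart()].
#' @param state State name (e.g. `"Painting"`, `"Color:red"`).
#' @return Total active time in seconds.
#' @export
state_occupancy <- function(trace, state) {
  rows <- trace$state == state
  sum(trace$t_end[rows] - trace$t_start[rows])
}

#' Export a timed trace as CSV
#'
#' @param trace A `timed_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$t_start <- sprintf("%.6f", df$t_start)
  df$t_end <- sprintf("%.6f", df$t_end)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
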