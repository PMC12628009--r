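## Portable session format.
##
## A session directory stands in for the multimodal recording of a tracked,
## AR-enabled procedure:
##   manifest.json          structured manifest (frame graph, calibrations,
##                          camera, anatomy and instrument declarations)
##   streams/*.csv          timestamped rigid-transform streams, header
##                          t,qw,qx,qy,qz,tx,ty,tz,valid
##   meshes/*.ply           anatomy meshes in the patient frame
##   frames.csv             video frame clock (timestamps, seconds)
## Video pixels are deliberately NOT stored: annotations derive from the
## tracked scene, and the frame clock plus camera model fully determine the
## annotation rasters.  All clocks are session-relative, starting near 0 s.

FLOAT_FMT <- "%.9g"  # fixed 9-significant-digit formatting => deterministic IO

sl_error <- function(code, msg, ...) {
  stop(errorCondition(msg, class = c(paste0("sl_error_", code), "error",
                                     "condition"), ...))
}

fmt_num <- function(x) sprintf(FLOAT_FMT, x)

## ------------------------------------------------------------------ streams

#' Construct a transform stream
#'
#' A time-sorted sequence of rigid transforms on one edge of the coordinate
#' frame graph, with per-sample validity (tracking dropouts are recorded as
#' `valid = FALSE` rows, not omitted).
#'
#' @param parent_frame,child_frame frame names; samples map child-frame
#'   points into the parent frame.
#' @param samples data.frame with columns `t, qw, qx, qy, qz, tx, ty, tz,
#'   valid`; timestamps strictly increasing, at least one row.
#' @export
transform_stream <- function(parent_frame, child_frame, samples) {
  need <- c("t", "qw", "qx", "qy", "qz", "tx", "ty", "tz", "valid")
  if (!all(need %in% names(samples)))
    sl_error("stream_format", "transform_stream: missing columns")
  samples <- as.data.frame(samples)[, need]
  if (nrow(samples) < 1L)
    sl_error("stream_format", "transform_stream: need >= 1 sample")
  if (any(diff(samples$t) <= 0))
    sl_error("unsorted_stream", sprintf(
      "transform_stream %s->%s: timestamps not strictly increasing",
      parent_frame, child_frame))
  samples$valid <- as.logical(samples$valid)
  structure(list(parent_frame = parent_frame, child_frame = child_frame,
                 samples = samples),
            class = "transform_stream")
}

stream_pose_at_index <- function(stream, i) {
  s <- stream$samples
  rigid_transform(c(s$qw[i], s$qx[i], s$qy[i], s$qz[i]),
                  c(s$tx[i], s$ty[i], s$tz[i]))
}

#' Read / write a transform stream CSV
#' @param path CSV path, header `t,qw,qx,qy,qz,tx,ty,tz,valid`.
#' @inheritParams transform_stream
#' @export
read_stream_csv <- function(path, parent_frame = "", child_frame = "") {
  if (!file.exists(path))
    sl_error("missing_file", paste("stream file not found:", path))
  df <- utils::read.csv(path)
  transform_stream(parent_frame, child_frame, df)
}

#' @rdname read_stream_csv
#' @param stream a `transform_stream`.
#' @export
write_stream_csv <- function(stream, path) {
  s <- stream$samples
  lines <- c("t,qw,qx,qy,qz,tx,ty,tz,valid",
             paste(fmt_num(s$t), fmt_num(s$qw), fmt_num(s$qx), fmt_num(s$qy),
                   fmt_num(s$qz), fmt_num(s$tx), fmt_num(s$ty), fmt_num(s$tz),
                   as.integer(s$valid), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

## ------------------------------------------------------------------ session

#' Assemble an in-memory session
#'
#' Validates the coordinate-frame graph (every referenced frame declared,
#' connected, no duplicate edges, no redundant cycles), label ids
#' (unique, 1-255; 0 is background), and stream ordering.  A static
#' `array -> tip` edge (pure translation by `tip_offset`) is added for every
#' instrument that does not already have one.
#'
#' @param session_id identifier string.
#' @param frames character vector of frame names.
#' @param dynamic_edges list of `list(stream_file, parent_frame, child_frame,
#'   stream)` where `stream` is a [transform_stream()].
#' @param static_edges list of `list(name, parent_frame, child_frame,
#'   transform)` with `rigid_transform` transforms.
#' @param camera `list(camera_frame, model)` with a [camera_model()].
#' @param anatomies list of `list(name, label_id, frame, mesh_file, mesh)`.
#' @param instruments list of `list(name, array_frame, tip_frame, tip_offset,
#'   tool_radius, shaft_length, verbs)`; may be empty.
#' @param frame_clock `list(times, nominal_rate)`, strictly increasing
#'   timestamps in seconds.
#' @param patient_frame frame in which anatomy is static (default
#'   `"patient"`).
#' @export
new_session <- function(session_id, frames, dynamic_edges, static_edges,
                        camera, anatomies, instruments, frame_clock,
                        patient_frame = "patient") {
  ## add implicit tip edges
  for (ins in instruments) {
    tipf <- ins$tip_frame
    have <- any(vapply(static_edges, function(e)
      e$parent_frame == ins$array_frame && e$child_frame == tipf, TRUE))
    if (!have)
      static_edges[[length(static_edges) + 1L]] <- list(
        name = paste0(ins$name, "_tip_offset"),
        parent_frame = ins$array_frame, child_frame = tipf,
        transform = rigid_transform(t = ins$tip_offset))
  }
  s <- structure(list(session_id = session_id, frames = frames,
                      dynamic_edges = dynamic_edges,
                      static_edges = static_edges, camera = camera,
                      anatomies = anatomies, instruments = instruments,
                      frame_clock = frame_clock,
                      patient_frame = patient_frame),
                 class = "surg_session")
  check_session(s)
  s
}

is_surg_session <- function(x) inherits(x, "surg_session")

session_edges <- function(session) {
  c(lapply(session$dynamic_edges, function(e)
      list(parent = e$parent_frame, child = e$child_frame, type = "dynamic",
           edge = e)),
    lapply(session$static_edges, function(e)
      list(parent = e$parent_frame, child = e$child_frame, type = "static",
           edge = e)))
}

## hard invariants; raises named errors
check_session <- function(s) {
  edges <- session_edges(s)
  for (e in edges) {
    if (!(e$parent %in% s$frames))
      sl_error("unknown_frame", paste("edge references undeclared frame:", e$parent))
    if (!(e$child %in% s$frames))
      sl_error("unknown_frame", paste("edge references undeclared frame:", e$child))
  }
  for (a in s$anatomies)
    if (!(a$frame %in% s$frames))
      sl_error("unknown_frame", paste("anatomy in undeclared frame:", a$frame))
  if (!(s$camera$camera_frame %in% s$frames))
    sl_error("unknown_frame", paste("camera frame undeclared:",
                                    s$camera$camera_frame))
  keys <- vapply(edges, function(e)
    paste(sort(c(e$parent, e$child)), collapse = "|"), "")
  if (anyDuplicated(keys))
    sl_error("duplicate_edge", paste("duplicate edge between frames:",
                                     keys[duplicated(keys)][1]))
  labs <- vapply(s$anatomies, function(a) as.integer(a$label_id), 0L)
  if (length(labs)) {
    if (any(labs < 1L | labs > 255L))
      sl_error("label_range", "label_id outside [1, 255]")
    if (anyDuplicated(labs))
      sl_error("duplicate_label", sprintf("duplicate label_id %d",
                                          labs[duplicated(labs)][1]))
  }
  if (any(diff(s$frame_clock$times) <= 0))
    sl_error("unsorted_clock", "frame clock not strictly increasing")
  ## the undirected frame graph must be a tree over the frames it touches:
  ## extra edges would make transform resolution ambiguous
  comp <- graph_components(s$frames, edges)
  used <- unique(unlist(lapply(edges, function(e) c(e$parent, e$child))))
  ncomp_used <- length(unique(comp[used]))
  if (length(edges) > length(used) - ncomp_used)
    sl_error("cyclic_edges", "frame graph contains redundant cycles")
  invisible(TRUE)
}

graph_components <- function(frames, edges) {
  comp <- stats::setNames(seq_along(frames), frames)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (e in edges) {
    a <- find(match(e$parent, frames)); b <- find(match(e$child, frames))
    if (a != b) comp[b] <- a
  }
  stats::setNames(vapply(seq_along(frames), function(i) find(i), 0L), frames)
}

## ---------------------------------------------------------------- write/load

#' Write a session directory
#'
#' Layout: `manifest.json`, `streams/*.csv`, `meshes/*.ply`, `frames.csv`.
#' Output is deterministic: stable key ordering and fixed 9-significant-digit
#' float formatting, so writing the same session twice gives byte-identical
#' directories.
#'
#' @param session a `surg_session`.
#' @param path output directory (created).
#' @export
write_session <- function(session, path) {
  stopifnot(is_surg_session(session))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "streams"), showWarnings = FALSE)
  dir.create(file.path(path, "meshes"), showWarnings = FALSE)

  for (e in session$dynamic_edges)
    write_stream_csv(e$stream, file.path(path, e$stream_file))
  for (a in session$anatomies)
    write_ply(a$mesh, file.path(path, a$mesh_file))
  writeLines(c("t", fmt_num(session$frame_clock$times)),
             file.path(path, "frames.csv"))

  tf_json <- function(tr) list(q = num9(tr$q), t = num9(tr$t))
  num9 <- function(x) as.numeric(fmt_num(x))
  cm <- session$camera$model
  manifest <- list(
    session_id = session$session_id,
    patient_frame = session$patient_frame,
    frames = session$frames,
    dynamic_edges = lapply(session$dynamic_edges, function(e)
      list(stream_file = e$stream_file, parent_frame = e$parent_frame,
           child_frame = e$child_frame)),
    static_edges = lapply(session$static_edges, function(e)
      list(name = e$name, parent_frame = e$parent_frame,
           child_frame = e$child_frame, transform = tf_json(e$transform))),
    camera = list(camera_frame = session$camera$camera_frame,
                  model = lapply(cm[c("fx", "fy", "cx", "cy", "k1", "k2",
                                      "p1", "p2", "k3")], num9)),
    camera_size = c(cm$width, cm$height),
    anatomies = lapply(session$anatomies, function(a)
      list(name = a$name, label_id = as.integer(a$label_id), frame = a$frame,
           mesh_file = a$mesh_file)),
    instruments = lapply(session$instruments, function(i)
      list(name = i$name, array_frame = i$array_frame,
           tip_frame = i$tip_frame, tip_offset = num9(i$tip_offset),
           tool_radius = num9(i$tool_radius),
           shaft_length = num9(i$shaft_length), verbs = i$verbs)),
    frame_clock = list(file = "frames.csv",
                       nominal_rate = num9(session$frame_clock$nominal_rate)))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(path, "manifest.json"))
  invisible(path)
}

#' Load and validate a session directory
#'
#' Enforces all manifest, stream and mesh invariants at load time; failure
#' modes are distinct error classes (`sl_error_missing_file`,
#' `sl_error_unknown_frame`, `sl_error_duplicate_label`,
#' `sl_error_unsorted_stream`, `sl_error_cyclic_edges`, ...).
#'
#' @param path session directory.
#' @return A `surg_session`.
#' @export
load_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) sl_error("missing_file", paste("no manifest at", mf))
  m <- jsonlite::fromJSON(mf, simplifyVector = FALSE)

  dyn <- lapply(m$dynamic_edges, function(e) {
    sf <- file.path(path, e$stream_file)
    list(stream_file = e$stream_file, parent_frame = e$parent_frame,
         child_frame = e$child_frame,
         stream = read_stream_csv(sf, e$parent_frame, e$child_frame))
  })
  stat <- lapply(m$static_edges, function(e)
    list(name = e$name, parent_frame = e$parent_frame,
         child_frame = e$child_frame,
         transform = rigid_transform(unlist(e$transform$q),
                                     unlist(e$transform$t))))
  cmv <- m$camera$model
  cam <- list(camera_frame = m$camera$camera_frame,
              model = camera_model(cmv$fx, cmv$fy, cmv$cx, cmv$cy,
                                   m$camera_size[[1]], m$camera_size[[2]],
                                   cmv$k1, cmv$k2, cmv$p1, cmv$p2, cmv$k3))
  anat <- lapply(m$anatomies, function(a) {
    mp <- file.path(path, a$mesh_file)
    if (!file.exists(mp)) sl_error("missing_file", paste("missing mesh:", mp))
    list(name = a$name, label_id = as.integer(a$label_id), frame = a$frame,
         mesh_file = a$mesh_file, mesh = read_ply(mp, a$name))
  })
  inst <- lapply(m$instruments, function(i)
    list(name = i$name, array_frame = i$array_frame, tip_frame = i$tip_frame,
         tip_offset = unlist(i$tip_offset), tool_radius = i$tool_radius,
         shaft_length = i$shaft_length,
         verbs = as.character(unlist(i$verbs))))
  fcf <- file.path(path, m$frame_clock$file)
  if (!file.exists(fcf)) sl_error("missing_file", paste("missing clock:", fcf))
  times <- utils::read.csv(fcf)$t
  s <- new_session(m$session_id, as.character(unlist(m$frames)), dyn, stat,
                   cam, anat, inst,
                   list(times = times, nominal_rate = m$frame_clock$nominal_rate),
                   patient_frame = m$patient_frame)
  s
}

## --------------------------------------------------------------- validation

#' Validate a session (non-raising)
#'
#' Unlike [load_session()] (which enforces hard invariants), this reports
#' soft data-quality findings without mutating anything: tracking gaps
#' longer than `max_gap`, per-stream coverage of the frame clock, frame-graph
#' connectivity from the camera and instrument frames to the patient frame,
#' and clock-range vs stream-range mismatches.
#'
#' @param session a `surg_session`.
#' @param max_gap maximum sample gap to interpolate across, seconds.
#' @return A `validation_report`: `issues` data.frame (severity, code,
#'   message) and `coverage` (named numeric, fraction of frame-clock
#'   timestamps each stream can serve).
#' @export
validate_session <- function(session, max_gap = 0.2) {
  issues <- data.frame(severity = character(), code = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(severity, code, message)
    issues[nrow(issues) + 1L, ] <<- list(severity, code, message)

  edges <- session_edges(session)
  comp <- graph_components(session$frames, edges)
  pf <- session$patient_frame
  want <- c(session$camera$camera_frame,
            vapply(session$instruments, `[[`, "", "tip_frame"),
            vapply(session$anatomies, `[[`, "", "frame"))
  for (fr in unique(want))
    if (comp[fr] != comp[pf])
      add("error", "disconnected",
          sprintf("frame '%s' not connected to patient frame '%s'", fr, pf))

  clock <- session$frame_clock$times
  coverage <- numeric(0)
  for (e in session$dynamic_edges) {
    rs <- resample_stream(e$stream, clock, max_gap = max_gap)
    cov <- mean(rs$valid)
    coverage[paste0(e$parent_frame, "->", e$child_frame)] <- cov
    if (cov < 1)
      add("warning", "tracking_gap",
          sprintf("stream %s->%s covers %.1f%% of the frame clock (gaps > %g s or range mismatch)",
                  e$parent_frame, e$child_frame, 100 * cov, max_gap))
    st <- e$stream$samples$t
    if (min(st) > min(clock) + max_gap || max(st) < max(clock) - max_gap)
      add("warning", "clock_range",
          sprintf("stream %s->%s range [%.3f, %.3f] does not span clock [%.3f, %.3f]",
                  e$parent_frame, e$child_frame, min(st), max(st),
                  min(clock), max(clock)))
  }
  structure(list(issues = issues, coverage = coverage),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x$issues) == 0L) cat("session valid: no findings\n")
  else for (i in seq_len(nrow(x$issues)))
    cat(sprintf("[%s] %s: %s\n", x$issues$severity[i], x$issues$code[i],
                x$issues$message[i]))
  if (length(x$coverage))
    cat("coverage:", paste(sprintf("%s=%.3f", names(x$coverage), x$coverage),
                           collapse = "  "), "\n")
  invisible(x)
}
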