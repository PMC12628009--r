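## Workflow-level annotations: per-frame instrument-structure distance
## series, tip kinematics, and rule-based surgical action triplets
## (instrument, verb, target) with contact hysteresis and temporal
## aggregation.
##
## The closeness metric is the unsigned distance from the tip point (not the
## full shaft): the target structure is "the tissue closest to the
## instrument tip".  A known limitation is inherited deliberately: a tool
## merely resting on tissue is labelled as interacting -- proximity rules
## cannot tell passive contact from active engagement without force or
## instrument-state signals.

#' Rule configuration for triplet inference
#'
#' @param tau_enter contact entry threshold, mm: contact starts when the
#'   tip-structure distance drops below this.
#' @param tau_exit contact exit threshold, mm (> tau_enter): contact persists
#'   until the distance exceeds this (hysteresis prevents toggling).
#' @param tau_far beyond this distance, mm, no target is assigned
#'   (`null_target`, verb `idle`).
#' @param s_static,s_active speed-class boundaries, mm/s: speed < s_static is
#'   `static`, <= s_active `moving`, else `fast`.
#' @param min_duration events shorter than this, s, are discarded.
#' @param merge_gap gaps up to this, s, between identical events are merged.
#' @param kinematics_window window (frames, odd, >= 3) for the local linear
#'   fit that estimates tip velocity.  The default 15 frames (0.5 s at
#'   30 fps) resolves speed at the same timescale as `min_duration`; see the
#'   methods vignette for why shorter windows are too noise-sensitive.
#' @param structure_priority ordered character vector breaking exact distance
#'   ties (then name order).
#' @param verb_table per instrument archetype, a named list
#'   `contact_static, contact_moving, contact_fast, no_contact` -> verb.
#' @export
rule_config <- function(tau_enter = 3, tau_exit = 5, tau_far = 20,
                        s_static = 2, s_active = 8, min_duration = 0.5,
                        merge_gap = 0.2, kinematics_window = 15,
                        structure_priority = character(),
                        verb_table = default_verb_table()) {
  if (!(tau_enter < tau_exit && tau_exit < tau_far))
    stop("rule_config: need tau_enter < tau_exit < tau_far", call. = FALSE)
  if (min_duration <= 0) stop("rule_config: min_duration must be > 0", call. = FALSE)
  if (kinematics_window %% 2 != 1 || kinematics_window < 3)
    stop("rule_config: kinematics_window must be odd and >= 3", call. = FALSE)
  structure(list(tau_enter = tau_enter, tau_exit = tau_exit, tau_far = tau_far,
                 s_static = s_static, s_active = s_active,
                 min_duration = min_duration, merge_gap = merge_gap,
                 kinematics_window = kinematics_window,
                 structure_priority = structure_priority,
                 verb_table = verb_table),
            class = "rule_config")
}

#' Default verb vocabulary per instrument archetype
#'
#' Four archetypes ship by default (grasper: grasp/retract; scissors: cut;
#' hook: dissect; stapler: staple), fully overridable.  Non-contact states
#' always map to `idle` so only genuine contact produces events.
#' @export
default_verb_table <- function() {
  list(
    grasper = list(contact_static = "grasp", contact_moving = "grasp",
                   contact_fast = "retract", no_contact = "idle"),
    scissors = list(contact_static = "cut", contact_moving = "cut",
                    contact_fast = "cut", no_contact = "idle"),
    hook = list(contact_static = "dissect", contact_moving = "dissect",
                contact_fast = "dissect", no_contact = "idle"),
    stapler = list(contact_static = "staple", contact_moving = "staple",
                   contact_fast = "staple", no_contact = "idle"))
}

verbs_for <- function(config, instrument_name) {
  vt <- config$verb_table
  key <- if (instrument_name %in% names(vt)) instrument_name
    else {
      hit <- names(vt)[vapply(names(vt), function(k)
        grepl(k, instrument_name, fixed = TRUE), TRUE)]
      if (length(hit)) hit[1] else NA_character_
    }
  if (is.na(key))
    sl_error("config", sprintf(
      "verb_table has no entry (or archetype match) for instrument '%s'", key))
  tab <- vt[[key]]
  need <- c("contact_static", "contact_moving", "contact_fast", "no_contact")
  if (!all(need %in% names(tab)))
    sl_error("config", sprintf("verb_table entry '%s' missing keys: %s", key,
                               paste(setdiff(need, names(tab)), collapse = ", ")))
  tab
}

## ----------------------------------------------------------------- distances

#' Per-frame instrument-structure distance series
#'
#' For every frame-clock timestamp, every instrument and every anatomy:
#' unsigned mesh distance from the tip point expressed in the patient frame,
#' plus a containment flag for watertight meshes.  Distances are computed
#' regardless of camera visibility -- off-screen instruments are annotated
#' like any other -- and flagged invalid where the tip chain has a tracking
#' gap.
#'
#' @param session a `surg_session`.
#' @param clock optional numeric timestamps (defaults to the session frame
#'   clock).
#' @param max_gap replay gap policy, s.
#' @return data.frame `t, frame, instrument, structure, distance, inside,
#'   valid`.
#' @export
compute_distance_series <- function(session, clock = NULL,
                                    max_gap = DEFAULT_MAX_GAP) {
  if (is.null(clock)) clock <- session$frame_clock$times
  tips <- tip_positions(session, clock, max_gap)
  anat <- session$anatomies
  water <- vapply(anat, function(a) mesh_is_watertight(a$mesh), TRUE)
  rows <- vector("list", length(session$instruments) * length(anat))
  k <- 0L
  for (ins in session$instruments) {
    tp <- tips[[ins$name]]
    ok <- tp$valid
    for (ai in seq_along(anat)) {
      a <- anat[[ai]]
      d <- rep(NA_real_, length(clock)); ins_flag <- rep(NA, length(clock))
      if (any(ok)) {
        P <- cbind(tp$x[ok], tp$y[ok], tp$z[ok])
        d[ok] <- cpp_mesh_distance(P, a$mesh$vertices, a$mesh$faces - 1L,
                                   TRUE)$distance
        ins_flag[ok] <- if (water[ai])
          cpp_point_in_mesh(P, a$mesh$vertices, a$mesh$faces - 1L) else FALSE
      }
      k <- k + 1L
      rows[[k]] <- data.frame(t = clock, frame = seq_along(clock),
                              instrument = ins$name, structure = a$name,
                              distance = d, inside = ins_flag, valid = ok,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$frame, out$instrument, out$structure), , drop = FALSE]
}

## resolve a whole frame chain on a clock, vectorized: returns Q (n x 4),
## T (n x 3), valid (n).  Shared by tip positions and batch scene queries.
resolve_chain_series <- function(session, frame_a, frame_b, clock,
                                 max_gap = DEFAULT_MAX_GAP) {
  path <- frame_path(session, frame_a, frame_b)
  n <- length(clock)
  Q <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  Tm <- matrix(0, n, 3)
  ok <- rep(TRUE, n)
  for (step in path) {
    if (step$edge$type == "static") {
      tr <- step$edge$edge$transform
      if (!step$forward) tr <- rt_invert(tr)
      Tm <- vq_rotate(Q, matrix(tr$t, n, 3, byrow = TRUE)) + Tm
      Q <- vq_mul(Q, matrix(tr$q, 1, 4))
    } else {
      rs <- resample_stream(step$edge$edge$stream, clock, max_gap)
      ok <- ok & rs$valid
      Qe <- cbind(rs$qw, rs$qx, rs$qy, rs$qz)
      Te <- cbind(rs$tx, rs$ty, rs$tz)
      if (!step$forward) {
        Qe <- cbind(Qe[, 1], -Qe[, 2], -Qe[, 3], -Qe[, 4])
        Te <- -vq_rotate(Qe, Te)
      }
      bad <- !ok
      if (any(bad)) {
        Qe[bad, ] <- matrix(c(1, 0, 0, 0), sum(bad), 4, byrow = TRUE)
        Te[bad, ] <- 0
      }
      Tm <- vq_rotate(Q, Te) + Tm
      Q <- vq_mul(Q, Qe)
    }
  }
  Q <- Q / sqrt(rowSums(Q^2))
  Q[!ok, ] <- NA_real_; Tm[!ok, ] <- NA_real_
  list(Q = Q, T = Tm, valid = ok)
}

## tip positions in the patient frame on the clock, per instrument
tip_positions <- function(session, clock, max_gap = DEFAULT_MAX_GAP) {
  out <- list()
  for (ins in session$instruments) {
    ch <- resolve_chain_series(session, session$patient_frame,
                               ins$tip_frame, clock, max_gap)
    out[[ins$name]] <- data.frame(t = clock, x = ch$T[, 1], y = ch$T[, 2],
                                  z = ch$T[, 3], valid = ch$valid)
  }
  out
}

## ---------------------------------------------------------------- kinematics

## least-squares slope of y over t (local linear fit)
ls_slope <- function(t, y) {
  tm <- t - mean(t)
  denom <- sum(tm^2)
  if (denom <= 0) return(0)
  sum(tm * (y - mean(y))) / denom
}

#' Tip kinematics from per-frame positions
#'
#' Velocity is the local least-squares linear fit of position over a
#' centred window of `window` frames (one-sided, shrunken windows at span
#' endpoints); speed is its norm.  `approach_rate` is minus the same local
#' slope of the distance to the currently nearest structure (positive =
#' approaching).  Invalid frames break fitting spans.
#'
#' @param positions data.frame `t, x, y, z, valid` (e.g. one element of the
#'   internal tip-position table).
#' @param window odd integer >= 3, frames.
#' @param nearest_distance optional numeric vector (per frame) of distance to
#'   the nearest structure, for `approach_rate`.
#' @return data.frame `t, speed, approach_rate, valid`.
#' @export
compute_kinematics <- function(positions, window = 15,
                               nearest_distance = NULL) {
  if (window %% 2 != 1 || window < 3)
    stop("compute_kinematics: window must be odd and >= 3", call. = FALSE)
  n <- nrow(positions)
  h <- (window - 1) %/% 2
  speed <- rep(NA_real_, n); appr <- rep(NA_real_, n)
  valid <- positions$valid
  ## contiguous valid spans
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (si in which(r$values)) {
    a <- starts[si]; b <- ends[si]
    for (i in a:b) {
      lo <- max(a, i - h); hi <- min(b, i + h)
      if (hi - lo < 1L) { speed[i] <- 0; appr[i] <- 0; next }
      tt <- positions$t[lo:hi]
      vx <- ls_slope(tt, positions$x[lo:hi])
      vy <- ls_slope(tt, positions$y[lo:hi])
      vz <- ls_slope(tt, positions$z[lo:hi])
      speed[i] <- sqrt(vx^2 + vy^2 + vz^2)
      if (!is.null(nearest_distance))
        appr[i] <- -ls_slope(tt, nearest_distance[lo:hi])
      else appr[i] <- 0
    }
  }
  data.frame(t = positions$t, speed = speed, approach_rate = appr,
             valid = valid)
}

## -------------------------------------------------------------- frame states

#' Per-frame per-instrument interaction state
#'
#' The target is the structure with minimal tip distance (exact ties broken
#' by `structure_priority`, then name order).  Contact uses hysteresis:
#' enters below `tau_enter`, exits above `tau_exit`.  Beyond `tau_far` the
#' target is `null_target` and the verb `idle`.  Otherwise the verb is looked
#' up in the instrument's verb table by (contact?, speed class).  Confidence
#' is `max(0, 1 - distance / tau_enter)` in contact, else 0.
#'
#' @param distances distance series from [compute_distance_series()].
#' @param kinematics named list (per instrument) of data.frames from
#'   [compute_kinematics()]; NULL treats all speeds as 0.
#' @param config a [rule_config()].
#' @return data.frame `frame, t, instrument, target, distance, contact, verb,
#'   confidence, valid`.
#' @export
infer_frame_state <- function(distances, kinematics = NULL,
                              config = rule_config()) {
  instruments <- unique(distances$instrument)
  ## validate verb table up front: configuration errors must never
  ## surface mid-run
  tabs <- lapply(instruments, function(i) verbs_for(config, i))
  names(tabs) <- instruments
  out <- list()
  for (ins in instruments) {
    di <- distances[distances$instrument == ins, , drop = FALSE]
    frames <- sort(unique(di$frame))
    nf <- length(frames)
    ## structures ordered by priority, then name: which.min over columns in
    ## this order implements the tie rule
    structs <- sort(unique(di$structure))
    pr <- match(structs, config$structure_priority)
    structs <- structs[order(ifelse(is.na(pr), Inf, pr), structs)]
    di <- di[order(match(di$structure, structs), di$frame), , drop = FALSE]
    D <- matrix(di$distance, nf, length(structs))
    INS <- matrix(di$inside %in% TRUE, nf, length(structs))
    VAL <- matrix(di$valid, nf, length(structs))
    tvec <- di$t[seq_len(nf)]
    rowvalid <- rowSums(!VAL) == 0L
    tgt_idx <- max.col(-ifelse(is.na(D), Inf, D), ties.method = "first")
    dmin <- D[cbind(seq_len(nf), tgt_idx)]
    inside_t <- INS[cbind(seq_len(nf), tgt_idx)]
    sp <- rep(0, nf)
    if (!is.null(kinematics) && !is.null(kinematics[[ins]])) {
      kv <- kinematics[[ins]]$speed[seq_len(nf)]
      sp <- ifelse(is.na(kv), 0, kv)
    }
    ## temporal smoothing of the closeness metric: the contact decision uses
    ## a running median of the min distance over the kinematics window
    ## (tracking jitter would otherwise shift the hysteresis crossings); the
    ## reported per-frame distance stays raw.  A median leaves noiseless
    ## monotone approaches and dwells untouched.
    dsm <- dmin
    if (config$kinematics_window >= 3 && nf >= 3) {
      r <- rle(rowvalid)
      ee <- cumsum(r$lengths); ss <- ee - r$lengths + 1L
      for (si in which(r$values)) {
        span <- ss[si]:ee[si]
        k <- min(config$kinematics_window,
                 if (length(span) %% 2 == 1) length(span) else length(span) - 1L)
        if (k >= 3)
          dsm[span] <- stats::runmed(dmin[span], k, endrule = "median")
      }
    }
    ## hysteresis scan (dropouts reset the contact state)
    contact <- logical(nf); on <- FALSE
    for (i in seq_len(nf)) {
      if (!rowvalid[i]) { on <- FALSE; next }
      if (dsm[i] > config$tau_far) { on <- FALSE; next }
      if (!on && (dsm[i] < config$tau_enter || inside_t[i])) on <- TRUE
      else if (on && dsm[i] > config$tau_exit && !inside_t[i]) on <- FALSE
      contact[i] <- on
    }
    far <- rowvalid & dsm > config$tau_far
    cls <- ifelse(sp < config$s_static, "static",
                  ifelse(sp <= config$s_active, "moving", "fast"))
    verb <- ifelse(contact,
                   unlist(tabs[[ins]][paste0("contact_", cls)]),
                   tabs[[ins]]$no_contact)
    verb[far] <- "idle"
    target <- structs[tgt_idx]
    target[far] <- "null_target"
    conf <- ifelse(contact, pmax(0, 1 - dmin / config$tau_enter), 0)
    df <- data.frame(frame = frames, t = tvec, instrument = ins,
                     target = target, distance = dmin, contact = contact,
                     verb = verb, confidence = conf, valid = rowvalid,
                     stringsAsFactors = FALSE)
    df$target[!rowvalid] <- NA_character_
    df$distance[!rowvalid] <- NA_real_
    df$contact[!rowvalid] <- NA
    df$verb[!rowvalid] <- NA_character_
    df$confidence[!rowvalid] <- NA_real_
    out[[ins]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$frame, res$instrument), , drop = FALSE]
}

## ------------------------------------------------------------------- events

#' Aggregate per-frame states into triplet events
#'
#' Maximal runs of identical (instrument, verb, target) become candidate
#' events; identical events separated by gaps of at most `merge_gap` seconds
#' are merged; events shorter than `min_duration` are discarded, as are
#' idle / null-target events (which stay in the per-frame table but are not
#' exported).  Event intervals are `[first frame t, last frame t + dt]`
#' where `dt` is the median frame interval.
#'
#' @param frame_states data.frame from [infer_frame_state()].
#' @param config a [rule_config()].
#' @return data.frame `instrument, verb, target, t_start, t_end,
#'   mean_confidence, frames`.
#' @export
aggregate_triplets <- function(frame_states, config = rule_config()) {
  empty <- data.frame(instrument = character(), verb = character(),
                      target = character(), t_start = numeric(),
                      t_end = numeric(), mean_confidence = numeric(),
                      frames = integer(), stringsAsFactors = FALSE)
  if (nrow(frame_states) == 0L) return(empty)
  tall <- sort(unique(frame_states$t))
  dt <- if (length(tall) > 1L) stats::median(diff(tall)) else config$min_duration
  evs <- list()
  for (ins in unique(frame_states$instrument)) {
    fs <- frame_states[frame_states$instrument == ins, , drop = FALSE]
    fs <- fs[order(fs$frame), , drop = FALSE]
    key <- ifelse(fs$valid, paste(fs$verb, fs$target, sep = "\r"), "\rINVALID")
    r <- rle(key)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- data.frame(key = r$values, start = starts, end = ends,
                       stringsAsFactors = FALSE)
    runs <- runs[runs$key != "\rINVALID", , drop = FALSE]
    if (nrow(runs) == 0L) next
    ## merge identical runs whose time gap is <= merge_gap, regardless of
    ## what lies in the gap (e.g. brief loss of contact or a few frames of a
    ## different speed class)
    for (kk in unique(runs$key)) {
      rk <- runs[runs$key == kk, , drop = FALSE]
      merged <- list(); cur <- rk[1, ]
      if (nrow(rk) > 1L) for (i in 2:nrow(rk)) {
        nxt <- rk[i, ]
        gap <- fs$t[nxt$start] - fs$t[cur$end]
        if (gap <= config$merge_gap) cur$end <- nxt$end
        else { merged[[length(merged) + 1L]] <- cur; cur <- nxt }
      }
      merged[[length(merged) + 1L]] <- cur
      parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
      verb <- parts[1]; target <- parts[2]
      if (verb == "idle" || target == "null_target") next
      for (m in merged) {
        sel <- m$start:m$end
        sel <- sel[key[sel] == kk]      # exclude merged-over gap frames
        t_start <- fs$t[m$start]; t_end <- fs$t[m$end] + dt
        if (t_end - t_start < config$min_duration) next
        evs[[length(evs) + 1L]] <- data.frame(
          instrument = ins, verb = verb, target = target,
          t_start = t_start, t_end = t_end,
          mean_confidence = mean(fs$confidence[sel]),
          frames = length(sel), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(evs)) return(empty)
  out <- do.call(rbind, evs)
  out <- out[order(out$t_start, out$instrument), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score predicted triplet events against reference events
#'
#' Greedy matching by descending interval IoU among label-identical pairs
#' (same instrument, verb and target); a pair matches when its IoU reaches
#' `iou_threshold`.
#'
#' @param predicted,truth event data.frames as from [aggregate_triplets()].
#' @param iou_threshold in (0, 1].
#' @return `list(precision, recall, mean_iou, matches)`.
#' @export
score_events <- function(predicted, truth, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  interval_iou <- function(a0, a1, b0, b1) {
    inter <- max(0, min(a1, b1) - max(a0, b0))
    uni <- max(a1, b1) - min(a0, b0)
    if (uni <= 0) 0 else inter / uni
  }
  np <- nrow(predicted); nt <- nrow(truth)
  if (np == 0L || nt == 0L)
    return(list(precision = if (np == 0L && nt == 0L) 1 else 0,
                recall = if (nt == 0L) 1 else 0,
                mean_iou = NA_real_,
                matches = data.frame(pred = integer(), truth = integer(),
                                     iou = numeric())))
  cand <- list()
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    if (predicted$instrument[i] != truth$instrument[j] ||
        predicted$verb[i] != truth$verb[j] ||
        predicted$target[i] != truth$target[j]) next
    iou <- interval_iou(predicted$t_start[i], predicted$t_end[i],
                        truth$t_start[j], truth$t_end[j])
    if (iou >= iou_threshold)
      cand[[length(cand) + 1L]] <- c(i, j, iou)
  }
  matches <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
    usedp <- logical(np); usedt <- logical(nt)
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (usedp[i] || usedt[j]) next
      usedp[i] <- TRUE; usedt[j] <- TRUE
      matches[nrow(matches) + 1L, ] <- list(i, j, cm[r, 3])
    }
  }
  list(precision = nrow(matches) / np, recall = nrow(matches) / nt,
       mean_iou = if (nrow(matches)) mean(matches$iou) else NA_real_,
       matches = matches)
}

#' Run the full event pipeline on a session
#'
#' distances -> kinematics -> per-frame states -> aggregated triplets.
#'
#' @param session a `surg_session`.
#' @param config a [rule_config()].
#' @param max_gap replay gap policy, s.
#' @return `list(distances, kinematics, frame_states, events)`.
#' @export
compute_triplets <- function(session, config = rule_config(),
                             max_gap = DEFAULT_MAX_GAP) {
  clock <- session$frame_clock$times
  dist <- compute_distance_series(session, clock, max_gap)
  tips <- tip_positions(session, clock, max_gap)
  kin <- list()
  for (ins in session$instruments) {
    di <- dist[dist$instrument == ins$name, , drop = FALSE]
    ndist <- tapply(di$distance, di$frame, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    kin[[ins$name]] <- compute_kinematics(tips[[ins$name]],
                                          config$kinematics_window,
                                          as.numeric(ndist))
  }
  fs <- infer_frame_state(dist, kin, config)
  ev <- aggregate_triplets(fs, config)
  list(distances = dist, kinematics = kin, frame_states = fs, events = ev)
}

#' Write event outputs to a session directory
#'
#' `events/distances.csv` (t, instrument, structure, distance_mm, inside,
#' valid) and `events/triplets.json` (event list with a config echo and the
#' session id).
#'
#' @param result list from [compute_triplets()].
#' @param session the session (for its id).
#' @param out_dir output directory.
#' @export
write_events <- function(result, session, out_dir) {
  dir.create(file.path(out_dir, "events"), recursive = TRUE,
             showWarnings = FALSE)
  d <- result$distances
  lines <- c("t,instrument,structure,distance_mm,inside,valid",
             paste(fmt_num(d$t), d$instrument, d$structure,
                   ifelse(is.na(d$distance), "", fmt_num(d$distance)),
                   ifelse(is.na(d$inside), "", as.integer(d$inside)),
                   as.integer(d$valid), sep = ","))
  writeLines(lines, file.path(out_dir, "events", "distances.csv"))
  ev <- result$events
  cfg <- unclass(attr(result, "config") %||% rule_config())
  payload <- list(session_id = session$session_id,
                  config = cfg[setdiff(names(cfg), "verb_table")],
                  events = ev)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE),
             file.path(out_dir, "events", "triplets.json"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
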