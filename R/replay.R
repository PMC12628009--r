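## Time-synchronized replay: resample transform streams onto the video frame
## clock and resolve arbitrary frame-to-frame transforms through the scene
## graph at a given time.
##
## Gap policy: interpolation only between bracketing valid samples whose
## spacing is <= max_gap (default 0.2 s, about 12 samples at 60 Hz tracking;
## longer gaps mean an occluded tracking array, and interpolating across
## them would fabricate data).  No extrapolation beyond the first/last valid
## sample except within half the median sample interval, where the endpoint
## pose is held.

DEFAULT_MAX_GAP <- 0.2   # seconds
EXACT_MATCH_TOL <- 1e-9  # seconds

#' Resample a transform stream onto query times
#'
#' For each query time: `exact` when a sample timestamp matches within 1e-9 s
#' (the stored pose is returned bit-equal), `interpolated` when bracketing
#' valid samples are no further than `max_gap` apart, `gap` (invalid)
#' otherwise.
#'
#' @param stream a [transform_stream()].
#' @param times numeric vector of query times (s), or a frame-clock list
#'   with a `times` element.
#' @param max_gap maximum bracketing-sample spacing to interpolate across, s.
#' @return data.frame `t, qw, qx, qy, qz, tx, ty, tz, valid, source` with
#'   `source` one of `"exact"`, `"interpolated"`, `"gap"`.
#' @export
resample_stream <- function(stream, times, max_gap = DEFAULT_MAX_GAP) {
  if (is.list(times)) times <- times$times
  if (length(times) == 0L)
    sl_error("empty_clock", "resample_stream: empty query clock")
  stopifnot(max_gap > 0)
  s <- stream$samples
  vidx <- which(s$valid)
  tv <- s$t[vidx]
  half_med <- if (nrow(s) > 1L) stats::median(diff(s$t)) / 2 else 0

  n <- length(times)
  Q <- matrix(NA_real_, n, 4); Tr <- matrix(NA_real_, n, 3)
  valid <- rep(FALSE, n)
  source <- rep("gap", n)

  ## exact timestamp matches (against all samples, valid or not)
  j <- findInterval(times, s$t)
  jn <- pmax(j, 1L)
  bump <- j >= 1L & j < nrow(s) & (times - s$t[jn]) > (s$t[pmin(j + 1L, nrow(s))] - times)
  jn[bump] <- jn[bump] + 1L
  exact <- abs(s$t[jn] - times) <= EXACT_MATCH_TOL
  ex_ok <- exact & s$valid[jn]
  if (any(ex_ok)) {
    m <- jn[ex_ok]
    Q[ex_ok, ] <- cbind(s$qw[m], s$qx[m], s$qy[m], s$qz[m])
    Tr[ex_ok, ] <- cbind(s$tx[m], s$ty[m], s$tz[m])
    valid[ex_ok] <- TRUE
    source[ex_ok] <- "exact"
  }

  ## exact matches to an invalid sample fall through to the interpolation
  ## policy (the bracketing valid samples decide, as for any other query)
  todo <- which(!ex_ok)
  if (length(todo) && length(tv)) {
    tq <- times[todo]
    k <- findInterval(tq, tv)
    ## hold the endpoint pose within half the median sample interval
    hold_lo <- k == 0L & (tv[1] - tq) <= half_med
    hold_hi <- k == length(tv) & (tq - tv[length(tv)]) <= half_med
    for (hh in list(list(sel = hold_lo, idx = vidx[1]),
                    list(sel = hold_hi, idx = vidx[length(vidx)]))) {
      if (any(hh$sel)) {
        w <- todo[hh$sel]; m <- hh$idx
        Q[w, ] <- matrix(c(s$qw[m], s$qx[m], s$qy[m], s$qz[m]),
                         length(w), 4, byrow = TRUE)
        Tr[w, ] <- matrix(c(s$tx[m], s$ty[m], s$tz[m]), length(w), 3,
                          byrow = TRUE)
        valid[w] <- TRUE; source[w] <- "interpolated"
      }
    }
    interior <- k >= 1L & k < length(tv)
    if (any(interior)) {
      ki <- k[interior]
      ok <- (tv[ki + 1L] - tv[ki]) <= max_gap
      sel <- which(interior)[ok]
      if (length(sel)) {
        i0 <- vidx[k[sel]]; i1 <- vidx[k[sel] + 1L]
        u <- (tq[sel] - s$t[i0]) / (s$t[i1] - s$t[i0])
        Q0 <- cbind(s$qw[i0], s$qx[i0], s$qy[i0], s$qz[i0])
        Q1 <- cbind(s$qw[i1], s$qx[i1], s$qy[i1], s$qz[i1])
        ## shortest-arc slerp, vectorized over rows
        d <- rowSums(Q0 * Q1)
        Q1[d < 0, ] <- -Q1[d < 0, , drop = FALSE]
        d <- abs(d)
        th <- acos(pmin(1, d))
        w0 <- ifelse(d > 1 - 1e-12, 1 - u, sin((1 - u) * th) / sin(th))
        w1 <- ifelse(d > 1 - 1e-12, u, sin(u * th) / sin(th))
        Qi <- Q0 * w0 + Q1 * w1
        Qi <- Qi / sqrt(rowSums(Qi^2))
        w <- todo[sel]
        Q[w, ] <- Qi
        Tr[w, ] <- (1 - u) * cbind(s$tx[i0], s$ty[i0], s$tz[i0]) +
          u * cbind(s$tx[i1], s$ty[i1], s$tz[i1])
        valid[w] <- TRUE; source[w] <- "interpolated"
      }
    }
  }
  data.frame(t = times, qw = Q[, 1], qx = Q[, 2], qy = Q[, 3], qz = Q[, 4],
             tx = Tr[, 1], ty = Tr[, 2], tz = Tr[, 3], valid = valid,
             source = source, stringsAsFactors = FALSE)
}

resampled_pose <- function(rs, i)
  rigid_transform(c(rs$qw[i], rs$qx[i], rs$qy[i], rs$qz[i]),
                  c(rs$tx[i], rs$ty[i], rs$tz[i]))

## BFS path a -> b through the undirected frame tree.  Returns a list of
## steps list(edge, forward) or raises sl_error_disconnected_frames.
frame_path <- function(session, frame_a, frame_b) {
  if (!(frame_a %in% session$frames) || !(frame_b %in% session$frames))
    sl_error("unknown_frame", sprintf("unknown frame in path query: %s -> %s",
                                      frame_a, frame_b))
  if (frame_a == frame_b) return(list())
  edges <- session_edges(session)
  adj <- list()
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    adj[[e$parent]] <- c(adj[[e$parent]], i)
    adj[[e$child]] <- c(adj[[e$child]], i)
  }
  prev <- list(); visited <- frame_a; queue <- frame_a
  while (length(queue)) {
    f <- queue[1]; queue <- queue[-1]
    for (i in adj[[f]]) {
      e <- edges[[i]]
      nxt <- if (e$parent == f) e$child else e$parent
      if (nxt %in% visited) next
      visited <- c(visited, nxt)
      prev[[nxt]] <- list(frame = f, edge_idx = i)
      if (nxt == frame_b) {
        path <- list(); cur <- frame_b
        while (cur != frame_a) {
          pr <- prev[[cur]]
          e2 <- edges[[pr$edge_idx]]
          path <- c(list(list(edge = e2, forward = (e2$child == cur))), path)
          cur <- pr$frame
        }
        return(path)
      }
      queue <- c(queue, nxt)
    }
  }
  sl_error("disconnected_frames",
           sprintf("no path between frames '%s' and '%s'", frame_a, frame_b))
}

edge_pose_at <- function(edge_entry, t, max_gap) {
  if (edge_entry$type == "static")
    return(list(pose = edge_entry$edge$transform, valid = TRUE))
  rs <- resample_stream(edge_entry$edge$stream, t, max_gap = max_gap)
  if (!rs$valid[1]) return(list(pose = NULL, valid = FALSE))
  list(pose = resampled_pose(rs, 1), valid = TRUE)
}

#' Resolve the transform between two frames at a time
#'
#' Composes the edges along the unique path through the frame tree (found by
#' breadth-first search), inverting edges traversed against their stored
#' direction.  The returned transform maps `frame_b` coordinates into
#' `frame_a`.  Static edges are always valid; the result is invalid iff any
#' dynamic edge on the path has no valid pose at `t` under the gap policy.
#'
#' @param session a `surg_session`.
#' @param frame_a,frame_b frame names.
#' @param t query time, s.
#' @param max_gap gap policy passed to [resample_stream()].
#' @return `list(transform, valid)`; `transform` is NULL when invalid.
#' @export
resolve_transform <- function(session, frame_a, frame_b, t,
                              max_gap = DEFAULT_MAX_GAP) {
  path <- frame_path(session, frame_a, frame_b)
  acc <- rt_identity()
  for (step in path) {
    ep <- edge_pose_at(step$edge, t, max_gap)
    if (!ep$valid) return(list(transform = NULL, valid = FALSE))
    ## stored edge maps child -> parent coordinates
    p <- if (step$forward) ep$pose else rt_invert(ep$pose)
    acc <- rt_compose(acc, p)
  }
  list(transform = acc, valid = TRUE)
}

#' Resolve the whole scene at a time
#'
#' One [resolve_transform()] per frame of interest (camera optical frame,
#' every instrument tip, every anatomy frame), expressed in `root_frame`.
#' The default root is the patient frame, so anatomy is static while the
#' camera and instruments move -- mirroring a table-anchored coordinate
#' design.  Invalid chains yield `valid = FALSE` entries rather than being
#' omitted.
#'
#' @inheritParams resolve_transform
#' @param root_frame frame in which all poses are expressed.
#' @return A `resolved_scene`: `t`, `root_frame`, and `poses` (named list of
#'   `list(transform, valid)`).
#' @export
resolve_scene <- function(session, t, root_frame = session$patient_frame,
                          max_gap = DEFAULT_MAX_GAP) {
  want <- unique(c(session$camera$camera_frame,
                   vapply(session$instruments, `[[`, "", "tip_frame"),
                   vapply(session$anatomies, `[[`, "", "frame")))
  poses <- lapply(want, function(f)
    resolve_transform(session, root_frame, f, t, max_gap))
  names(poses) <- want
  poses[[root_frame]] <- list(transform = rt_identity(), valid = TRUE)
  structure(list(t = t, root_frame = root_frame, poses = poses),
            class = "resolved_scene")
}
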