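## Synthetic session generator with scripted ground truth.
##
## Emulates a recorded tracked laparoscopic procedure: an infrared tracker
## observes arrays on the laparoscope, the operating table and each
## instrument; the patient frame hangs off the table array via a static
## registration edge; anatomy meshes live in the patient frame.  Anatomy is
## generated primitives (icospheres, a capped tube standing in for a
## ureter-like structure) so analytic oracles exist for every stage.
##
## The default demo (60 s, 30 fps video clock, 60 Hz tracking, 2 instruments,
## 3 structures, 6 scripted contact events of which one lies entirely
## outside the camera frustum, zero noise) is small enough for CI.
##
## Noise model (all seeded): isotropic Gaussian jitter on stream
## translations, small-angle Gaussian jitter on rotations, per-sample
## Bernoulli dropouts, and a constant rigid registration offset in a seeded
## random direction.  One RNG substream per consumer so toggling one noise
## source never changes another: trajectory jitter uses seed+1, dropouts
## seed+2, registration direction seed+3.

## ------------------------------------------------- vectorized quaternion ops

## rows of Q1, Q2 are (w,x,y,z); either may be a single quaternion
vq_mul <- function(Q1, Q2) {
  if (is.null(dim(Q1))) Q1 <- matrix(Q1, 1, 4)
  if (is.null(dim(Q2))) Q2 <- matrix(Q2, 1, 4)
  n <- max(nrow(Q1), nrow(Q2))
  if (nrow(Q1) == 1L) Q1 <- Q1[rep(1, n), , drop = FALSE]
  if (nrow(Q2) == 1L) Q2 <- Q2[rep(1, n), , drop = FALSE]
  w1 <- Q1[, 1]; x1 <- Q1[, 2]; y1 <- Q1[, 3]; z1 <- Q1[, 4]
  w2 <- Q2[, 1]; x2 <- Q2[, 2]; y2 <- Q2[, 3]; z2 <- Q2[, 4]
  cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

## rotate rows of V (n x 3) by rows of Q (n x 4)
vq_rotate <- function(Q, V) {
  if (is.null(dim(V))) V <- matrix(V, nrow(Q), 3, byrow = TRUE)
  w <- Q[, 1]; qx <- Q[, 2]; qy <- Q[, 3]; qz <- Q[, 4]
  # t = 2 q_vec x v ; v' = v + w t + q_vec x t
  tx <- 2 * (qy * V[, 3] - qz * V[, 2])
  ty <- 2 * (qz * V[, 1] - qx * V[, 3])
  tz <- 2 * (qx * V[, 2] - qy * V[, 1])
  cbind(V[, 1] + w * tx + qy * tz - qz * ty,
        V[, 2] + w * ty + qz * tx - qx * tz,
        V[, 3] + w * tz + qx * ty - qy * tx)
}

## vectorized rotation-matrix -> quaternion (Shepperd); xc, yc, zc are the
## n x 3 images of the basis vectors (columns of R)
vmat_to_quat <- function(xc, yc, zc) {
  r11 <- xc[, 1]; r21 <- xc[, 2]; r31 <- xc[, 3]
  r12 <- yc[, 1]; r22 <- yc[, 2]; r32 <- yc[, 3]
  r13 <- zc[, 1]; r23 <- zc[, 2]; r33 <- zc[, 3]
  t0 <- 1 + r11 + r22 + r33
  t1 <- 1 + r11 - r22 - r33
  t2 <- 1 - r11 + r22 - r33
  t3 <- 1 - r11 - r22 + r33
  pick <- max.col(cbind(t0, t1, t2, t3), ties.method = "first")
  n <- length(r11)
  q <- matrix(0, n, 4)
  i <- pick == 1L
  if (any(i)) {
    s <- 2 * sqrt(t0[i])
    q[i, ] <- cbind(s / 4, (r32[i] - r23[i]) / s, (r13[i] - r31[i]) / s,
                    (r21[i] - r12[i]) / s)
  }
  i <- pick == 2L
  if (any(i)) {
    s <- 2 * sqrt(t1[i])
    q[i, ] <- cbind((r32[i] - r23[i]) / s, s / 4, (r12[i] + r21[i]) / s,
                    (r13[i] + r31[i]) / s)
  }
  i <- pick == 3L
  if (any(i)) {
    s <- 2 * sqrt(t2[i])
    q[i, ] <- cbind((r13[i] - r31[i]) / s, (r12[i] + r21[i]) / s, s / 4,
                    (r23[i] + r32[i]) / s)
  }
  i <- pick == 4L
  if (any(i)) {
    s <- 2 * sqrt(t3[i])
    q[i, ] <- cbind((r21[i] - r12[i]) / s, (r13[i] + r31[i]) / s,
                    (r23[i] + r32[i]) / s, s / 4)
  }
  q <- q * ifelse(q[, 1] < 0, -1, 1)
  q / sqrt(rowSums(q^2))
}

vnormalize <- function(V) V / sqrt(rowSums(V^2))
vcross <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, nrow(B), 3, byrow = TRUE)
  if (is.null(dim(B))) B <- matrix(B, nrow(A), 3, byrow = TRUE)
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

smoothstep <- function(u) { u <- pmin(pmax(u, 0), 1); u * u * (3 - 2 * u) }

## pose of a camera at `eye` looking at `target` (optical frame: +z forward,
## +x right, +y down); returns a rigid_transform mapping camera -> world
lookat_pose <- function(eye, target, up = c(0, 1, 0)) {
  z <- target - eye; z <- z / sqrt(sum(z^2))
  x <- c(up[2] * z[3] - up[3] * z[2],
         up[3] * z[1] - up[1] * z[3],
         up[1] * z[2] - up[2] * z[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rigid_transform(matrix_to_quat(cbind(x, y, z)), eye)
}

## ----------------------------------------------------------------- config

#' Synthetic session configuration
#'
#' The defaults define the demo world: 60 s, 60 Hz tracking, 30 fps video,
#' three generated structures, a laparoscope on a gentle arc, and two
#' instruments executing six scripted contact events (grasper on a
#' ureter-like tube once, entirely off-screen) with in-contact tip speeds
#' below the static threshold.  All noise defaults to zero.
#'
#' @param duration session length, s.
#' @param tracking_rate tracking sample rate, Hz.
#' @param frame_rate video frame rate, Hz.
#' @param noise list: `jitter_sigma_t` (mm, translation jitter),
#'   `jitter_sigma_r` (deg, rotation jitter), `dropout_prob` in [0,1),
#'   `registration_offset` (mm, constant patient-registration error).
#' @param seed integer RNG seed.
#' @param image_size c(width, height) of the annotation raster; the demo
#'   default is 640x480 (use 1920x1080 for FullHD-scale output).
#' @export
synth_config <- function(duration = 60, tracking_rate = 60, frame_rate = 30,
                         noise = list(), seed = 1,
                         image_size = c(640L, 480L)) {
  stopifnot(duration > 0, tracking_rate > 0, frame_rate > 0)
  nz <- utils::modifyList(list(jitter_sigma_t = 0, jitter_sigma_r = 0,
                               dropout_prob = 0, registration_offset = 0),
                          noise)
  stopifnot(nz$dropout_prob >= 0, nz$dropout_prob < 1)
  structure(list(duration = duration, tracking_rate = tracking_rate,
                 frame_rate = frame_rate, noise = nz, seed = as.integer(seed),
                 image_size = as.integer(image_size)),
            class = "synth_config")
}

## scripted radial distance profile of one contact event, relative to event
## start; phases: fast approach (2 s, 25 -> 3.5 mm), slow creep-in
## (2 s at 1 mm/s to 1.5 mm), dwell (3 s at 1.5 mm), slow creep-out
## (8/3 s at 1.5 mm/s to 5.5 mm), fast retreat (2 s back to 25 mm).
## In-contact speeds stay below the 2 mm/s static threshold by construction;
## the dwell clearance (1.5 mm) is below tau_enter - 1 and the standoff
## (25 mm) above tau_exit + 2.
EVENT_PHASES <- list(standoff = 25, creep_in_from = 3.5, dwell_d = 1.5,
                     creep_out_to = 5.5,
                     t_app = 2, t_creep_in = 2, t_dwell = 3,
                     t_creep_out = 8 / 3, t_ret = 2)
EVENT_SPAN <- with(EVENT_PHASES, t_app + t_creep_in + t_dwell +
                     t_creep_out + t_ret)

event_distance_profile <- function(tau) {
  p <- EVENT_PHASES
  d <- rep(p$standoff, length(tau))
  b1 <- p$t_app; b2 <- b1 + p$t_creep_in; b3 <- b2 + p$t_dwell
  b4 <- b3 + p$t_creep_out; b5 <- b4 + p$t_ret
  i <- tau >= 0 & tau < b1
  d[i] <- p$standoff + (p$creep_in_from - p$standoff) * smoothstep(tau[i] / b1)
  i <- tau >= b1 & tau < b2
  d[i] <- p$creep_in_from - 1.0 * (tau[i] - b1)
  i <- tau >= b2 & tau < b3
  d[i] <- p$dwell_d
  i <- tau >= b3 & tau < b4
  d[i] <- p$dwell_d + 1.5 * (tau[i] - b3)
  i <- tau >= b4 & tau < b5
  d[i] <- p$creep_out_to +
    (p$standoff - p$creep_out_to) * smoothstep((tau[i] - b4) / p$t_ret)
  d
}

## the demo world: structures, camera arc, instrument scripts
demo_world <- function(config) {
  structures <- list(
    list(name = "gallbladder", shape = "sphere", center = c(0, 0, 0),
         radius = 12, label_id = 1L),
    list(name = "liver", shape = "sphere", center = c(45, 20, 0),
         radius = 20, label_id = 2L),
    list(name = "ureter", shape = "tube", center = c(-110, 0, 0),
         radius = 4, length = 70, axis = c(0, 1, 0), label_id = 3L))
  anchor_dir <- function(st) {
    ## approach from the camera side (-z), radially outward from the surface
    list(anchor = st$center + st$radius * c(0, 0, -1), dir = c(0, 0, -1))
  }
  ev <- function(structure, start) {
    st <- structures[[which(vapply(structures, `[[`, "", "name") == structure)]]
    ad <- anchor_dir(st)
    list(structure = structure, start = start, end = start + EVENT_SPAN,
         anchor = ad$anchor, dir = ad$dir)
  }
  instruments <- list(
    list(name = "grasper", archetype = "grasper",
         entry = c(-80, -90, -60), tool_radius = 2.5, shaft_length = 150,
         tip_offset = c(0, 0, 150), verbs = c("grasp", "retract"),
         events = list(ev("gallbladder", 1.2), ev("ureter", 21.2),
                       ev("gallbladder", 41.2))),
    list(name = "scissors", archetype = "scissors",
         entry = c(80, -90, -60), tool_radius = 2.5, shaft_length = 150,
         tip_offset = c(0, 0, 150), verbs = c("cut"),
         events = list(ev("liver", 8.2), ev("gallbladder", 28.2),
                       ev("liver", 46.2))))
  camera <- list(v0 = c(0, -40, -140), target = c(0, 0, 0),
                 sway_deg = 8, period = config$duration,
                 model = camera_model(800, 800,
                                      (config$image_size[1] - 1) / 2,
                                      (config$image_size[2] - 1) / 2,
                                      config$image_size[1],
                                      config$image_size[2]))
  ## fixed "calibrations" of the stated world
  list(structures = structures, instruments = instruments, camera = camera,
       hand_eye = rigid_transform(quat_axis_angle(c(1, 2, 3), 0.7),
                                  c(3, -4, 25)),
       registration = rigid_transform(quat_axis_angle(c(0.2, 1, 0.5), 0.5),
                                      c(100, -50, 300)),
       tracker_table = rigid_transform(quat_axis_angle(c(1, 0.3, -0.2), 2.0),
                                       c(-400, 250, 1600)))
}

## vectorized tip trajectory of one instrument over times tv
tip_trajectory <- function(instrument, tv) {
  evs <- instrument$events
  standoff_pt <- function(e) e$anchor + EVENT_PHASES$standoff * e$dir
  P <- matrix(NA_real_, length(tv), 3)
  ## hold/approach before first event, after last, and transit between
  first <- evs[[1]]; last <- evs[[length(evs)]]
  if (any(tv < first$start))
    P[tv < first$start, ] <- matrix(standoff_pt(first), sum(tv < first$start),
                                    3, byrow = TRUE)
  if (any(tv >= last$end))
    P[tv >= last$end, ] <- matrix(standoff_pt(last), sum(tv >= last$end), 3,
                                  byrow = TRUE)
  for (k in seq_along(evs)) {
    e <- evs[[k]]
    i <- tv >= e$start & tv < e$end
    if (any(i)) {
      d <- event_distance_profile(tv[i] - e$start)
      P[i, ] <- matrix(e$anchor, sum(i), 3, byrow = TRUE) + outer(d, e$dir)
    }
    if (k < length(evs)) {
      nxt <- evs[[k + 1]]
      i <- tv >= e$end & tv < nxt$start
      if (any(i)) {
        u <- smoothstep((tv[i] - e$end) / (nxt$start - e$end))
        a <- standoff_pt(e); b <- standoff_pt(nxt)
        P[i, ] <- outer(1 - u, a) + outer(u, b)
      }
    }
  }
  P
}

## camera pose (optical -> patient) over times tv: base look-at pose rotated
## about the y axis through the target by sway * sin(2 pi t / period)
camera_trajectory <- function(camworld, tv) {
  base <- lookat_pose(camworld$target + camworld$v0, camworld$target)
  beta <- camworld$sway_deg * pi / 180 * sin(2 * pi * tv / camworld$period)
  qy <- cbind(cos(beta / 2), 0, sin(beta / 2), 0)
  Q <- vq_mul(qy, matrix(base$q, 1, 4))
  eye <- vq_rotate(qy, matrix(camworld$v0, length(tv), 3, byrow = TRUE)) +
    matrix(camworld$target, length(tv), 3, byrow = TRUE)
  list(Q = Q, T = eye)
}

## instrument array pose (array -> patient): z axis along the shaft from
## entry towards the tip, array origin tip_offset behind the tip
array_trajectory <- function(instrument, tv) {
  tip <- tip_trajectory(instrument, tv)
  z <- vnormalize(tip - matrix(instrument$entry, length(tv), 3, byrow = TRUE))
  x <- vnormalize(vcross(c(0, 1, 0), z))
  y <- vcross(z, x)
  Q <- vmat_to_quat(x, y, z)
  Tm <- tip - z * instrument$tip_offset[3]
  list(Q = Q, T = Tm, tip = tip)
}

## compose constant transform L with per-row poses (Q, T):  L o P(t)
vcompose_left <- function(L, Q, Tm) {
  RL <- quat_to_matrix(L$q)
  list(Q = vq_mul(matrix(L$q, 1, 4), Q),
       T = Tm %*% t(RL) + matrix(L$t, nrow(Tm), 3, byrow = TRUE))
}
## compose per-row poses with constant transform R:  P(t) o R
vcompose_right <- function(Q, Tm, R) {
  list(Q = vq_mul(Q, matrix(R$q, 1, 4)),
       T = vq_rotate(Q, matrix(R$t, nrow(Q), 3, byrow = TRUE)) + Tm)
}

jitter_stream <- function(Q, Tm, sigma_t, sigma_r_deg) {
  n <- nrow(Q)
  if (sigma_t > 0)
    Tm <- Tm + matrix(stats::rnorm(3 * n, sd = sigma_t), n, 3)
  if (sigma_r_deg > 0) {
    eps <- matrix(stats::rnorm(3 * n, sd = sigma_r_deg * pi / 180), n, 3)
    qe <- cbind(1, eps / 2)
    qe <- qe / sqrt(rowSums(qe^2))
    Q <- vq_mul(Q, qe)
  }
  list(Q = Q, T = Tm)
}

make_stream <- function(parent, child, tv, Q, Tm, valid) {
  transform_stream(parent, child, data.frame(
    t = tv, qw = Q[, 1], qx = Q[, 2], qy = Q[, 3], qz = Q[, 4],
    tx = Tm[, 1], ty = Tm[, 2], tz = Tm[, 3], valid = valid))
}

## ---------------------------------------------------------------- generator

#' Generate a synthetic session with ground truth
#'
#' Deterministic given the seed.  Streams are sampled from smooth analytic
#' scripts at `tracking_rate`; the frame clock runs at `frame_rate`; noise is
#' drawn from seeded substreams (see the module header).  Scripted contacts
#' keep the true tip-structure distance below `tau_enter - 1` mm during the
#' dwell and above `tau_exit + 2` mm outside the event.
#'
#' @param config a [synth_config()].
#' @param rules the [rule_config()] used to derive ground-truth events from
#'   the analytic distance profiles.
#' @return `list(session, truth)`; `truth` carries `contact_events`,
#'   `true_hand_eye`, `true_tip_offsets`, `true_registration`, the sphere
#'   parameters for silhouette oracles, and analytic evaluators
#'   `eval_camera(t)`, `eval_tip(name, t)`.
#' @export
generate_session <- function(config = synth_config(), rules = rule_config()) {
  stopifnot(inherits(config, "synth_config"))
  world <- demo_world(config)
  for (ins in world$instruments)
    for (e in ins$events) {
      ok <- any(vapply(world$structures, function(s) s$name == e$structure, TRUE))
      if (!ok) sl_error("script", paste("scripted contact with nonexistent structure:",
                                        e$structure))
      if (e$end > config$duration + 1e-9)
        sl_error("script", "scripted event extends beyond session duration")
    }
  nz <- config$noise
  tv <- seq(0, by = 1 / config$tracking_rate,
            length.out = round(config$duration * config$tracking_rate))
  ftimes <- seq(0, by = 1 / config$frame_rate,
                length.out = round(config$duration * config$frame_rate))

  ## registration edge, optionally perturbed by a constant seeded offset
  reg <- world$registration
  if (nz$registration_offset > 0) {
    set.seed(config$seed + 3L)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    reg <- rt_compose(rigid_transform(t = nz$registration_offset * dir), reg)
  }

  L_tr_pat <- rt_compose(world$tracker_table, world$registration)

  ## noiseless analytic poses in the tracker frame
  cam <- camera_trajectory(world$camera, tv)
  cam_tr <- vcompose_right(cam$Q, cam$T, rt_invert(world$hand_eye))
  cam_tr <- vcompose_left(L_tr_pat, cam_tr$Q, cam_tr$T)
  arrays <- lapply(world$instruments, function(ins) {
    a <- array_trajectory(ins, tv)
    vcompose_left(L_tr_pat, a$Q, a$T)
  })
  table_Q <- matrix(world$tracker_table$q, length(tv), 4, byrow = TRUE)
  table_T <- matrix(world$tracker_table$t, length(tv), 3, byrow = TRUE)

  ## seeded noise: one substream for jitter, one for dropouts
  set.seed(config$seed + 1L)
  cam_n <- jitter_stream(cam_tr$Q, cam_tr$T, nz$jitter_sigma_t, nz$jitter_sigma_r)
  arr_n <- lapply(arrays, function(a)
    jitter_stream(a$Q, a$T, nz$jitter_sigma_t, nz$jitter_sigma_r))
  tab_n <- jitter_stream(table_Q, table_T, nz$jitter_sigma_t, nz$jitter_sigma_r)
  set.seed(config$seed + 2L)
  nstreams <- 2L + length(world$instruments)
  valid <- lapply(seq_len(nstreams), function(i)
    stats::runif(length(tv)) >= nz$dropout_prob)

  dyn <- list(
    list(stream_file = "streams/table.csv", parent_frame = "tracker",
         child_frame = "table_array",
         stream = make_stream("tracker", "table_array", tv, tab_n$Q, tab_n$T,
                              valid[[1]])),
    list(stream_file = "streams/scope.csv", parent_frame = "tracker",
         child_frame = "scope_array",
         stream = make_stream("tracker", "scope_array", tv, cam_n$Q, cam_n$T,
                              valid[[2]])))
  for (k in seq_along(world$instruments)) {
    ins <- world$instruments[[k]]
    dyn[[length(dyn) + 1L]] <- list(
      stream_file = sprintf("streams/%s.csv", ins$name),
      parent_frame = "tracker", child_frame = paste0(ins$name, "_array"),
      stream = make_stream("tracker", paste0(ins$name, "_array"), tv,
                           arr_n[[k]]$Q, arr_n[[k]]$T, valid[[2L + k]]))
  }

  stat <- list(
    list(name = "registration", parent_frame = "table_array",
         child_frame = "patient", transform = reg),
    list(name = "hand_eye", parent_frame = "scope_array",
         child_frame = "camera_optical", transform = world$hand_eye))

  meshes <- lapply(world$structures, function(st) {
    if (st$shape == "sphere")
      mesh_icosphere(st$radius, 4, st$center, st$name)
    else
      mesh_tube(st$radius, st$length, st$center, st$axis, 32, st$name)
  })
  anat <- lapply(seq_along(world$structures), function(i) {
    st <- world$structures[[i]]
    list(name = st$name, label_id = st$label_id, frame = "patient",
         mesh_file = sprintf("meshes/%s.ply", st$name), mesh = meshes[[i]])
  })
  instr <- lapply(world$instruments, function(ins)
    list(name = ins$name, array_frame = paste0(ins$name, "_array"),
         tip_frame = paste0(ins$name, "_tip"), tip_offset = ins$tip_offset,
         tool_radius = ins$tool_radius, shaft_length = ins$shaft_length,
         verbs = ins$verbs))

  frames <- c("tracker", "table_array", "patient", "scope_array",
              "camera_optical",
              unlist(lapply(world$instruments, function(i)
                c(paste0(i$name, "_array"), paste0(i$name, "_tip")))))

  session <- new_session(
    session_id = sprintf("synthetic-demo-seed%d", config$seed),
    frames = frames, dynamic_edges = dyn, static_edges = stat,
    camera = list(camera_frame = "camera_optical", model = world$camera$model),
    anatomies = anat, instruments = instr,
    frame_clock = list(times = ftimes, nominal_rate = config$frame_rate))

  truth <- build_truth(world, config, ftimes, rules)
  list(session = session, truth = truth)
}

## ground-truth events from the analytic distance profiles with the same
## hysteresis the rule engine applies; in-contact scripted speeds are below
## s_static by construction so the truth verb is the contact_static verb
build_truth <- function(world, config, ftimes, rules) {
  dt <- 1 / config$frame_rate
  evs <- list()
  for (ins in world$instruments) {
    vt <- verbs_for(rules, ins$archetype)
    for (e in ins$events) {
      i <- which(ftimes >= e$start & ftimes < e$end)
      d <- event_distance_profile(ftimes[i] - e$start)
      contact <- logical(length(i)); on <- FALSE
      for (k in seq_along(i)) {
        if (!on && d[k] < rules$tau_enter) on <- TRUE
        else if (on && d[k] > rules$tau_exit) on <- FALSE
        contact[k] <- on
      }
      sel <- which(contact)
      if (!length(sel)) next
      evs[[length(evs) + 1L]] <- data.frame(
        instrument = ins$name, verb = vt$contact_static,
        target = e$structure,
        t_start = ftimes[i[sel[1]]], t_end = ftimes[i[sel[length(sel)]]] + dt,
        mean_confidence = mean(pmax(0, 1 - d[sel] / rules$tau_enter)),
        frames = length(sel), stringsAsFactors = FALSE)
    }
  }
  contact_events <- if (length(evs)) {
    ce <- do.call(rbind, evs)
    ce <- ce[order(ce$t_start, ce$instrument), , drop = FALSE]
    rownames(ce) <- NULL
    ce
  } else data.frame()

  spheres <- Filter(function(s) s$shape == "sphere", world$structures)
  eval_camera <- function(t) {
    ct <- camera_trajectory(world$camera, t)
    rigid_transform(ct$Q[1, ], ct$T[1, ])
  }
  eval_tip <- function(name, t) {
    ins <- world$instruments[[which(vapply(world$instruments, `[[`, "",
                                           "name") == name)]]
    as.numeric(tip_trajectory(ins, t))
  }
  off_screen_event <- which(contact_events$instrument == "grasper" &
                              contact_events$target == "ureter")
  list(contact_events = contact_events,
       true_hand_eye = world$hand_eye,
       true_tip_offsets = stats::setNames(
         lapply(world$instruments, `[[`, "tip_offset"),
         vapply(world$instruments, `[[`, "", "name")),
       true_registration = world$registration,
       spheres = spheres,
       off_screen_events = off_screen_event,
       eval_camera = eval_camera, eval_tip = eval_tip)
}

#' Perturb the patient registration of a session
#'
#' Replaces the table-to-patient static edge with a copy offset by
#' `offset_mm` along a seeded random direction and rotated by `offset_deg`
#' about a seeded random axis -- emulating a rigid patient-registration
#' error of a stated magnitude (for example the 8.2 mm target registration
#' error typical of tracked laparoscopic AR).
#'
#' @param session a `surg_session`.
#' @param offset_mm translation offset magnitude, mm.
#' @param offset_deg rotation offset magnitude, degrees.
#' @param seed RNG seed for the directions.
#' @return The perturbed session (input is not modified).
#' @export
perturb_registration <- function(session, offset_mm, offset_deg = 0, seed = 1) {
  stopifnot(offset_mm >= 0, offset_deg >= 0)
  if (offset_mm == 0 && offset_deg == 0) return(session)
  set.seed(seed)
  dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
  axv <- stats::rnorm(3); axv <- axv / sqrt(sum(axv^2))
  delta <- rigid_transform(quat_axis_angle(axv, offset_deg * pi / 180),
                           offset_mm * dirv)
  idx <- which(vapply(session$static_edges, function(e)
    e$child_frame == session$patient_frame, TRUE))
  if (!length(idx))
    sl_error("missing_edge", "session has no patient registration edge")
  e <- session$static_edges[[idx[1]]]
  e$transform <- rt_compose(delta, e$transform)
  session$static_edges[[idx[1]]] <- e
  session
}

#' Analytic silhouette of a sphere under a pinhole camera
#'
#' Exact projected conic of the tangent cone from the camera centre to the
#' sphere (no distortion).  For an on-axis sphere this reduces to a circle
#' of radius `f r / sqrt(z^2 - r^2)`.
#'
#' @param camera a [camera_model()] with zero distortion.
#' @param center numeric(3) sphere centre in the camera optical frame, mm.
#' @param r sphere radius, mm (camera must be outside: `||center|| > r`).
#' @return `list(center_px = c(u, v), radius_px, area_px2)`; `radius_px` is
#'   the effective radius `sqrt(area / pi / (fx fy))` scaled by `fx` (exact
#'   for on-axis spheres).
#' @export
analytic_sphere_silhouette <- function(camera, center, r) {
  stopifnot(is_camera_model(camera))
  if (any(c(camera$k1, camera$k2, camera$p1, camera$p2, camera$k3) != 0))
    stop("analytic_sphere_silhouette: camera must be distortion-free",
         call. = FALSE)
  d2 <- sum(center^2)
  if (d2 <= r^2)
    sl_error("camera_inside_sphere",
             "analytic_sphere_silhouette: camera centre inside the sphere")
  ## tangent cone: (x . c)^2 = |x|^2 (d^2 - r^2); conic in the plane z = 1.
  ## Flip the sign so the leading 2x2 block is positive definite (the area
  ## formula below assumes that normalization).
  M <- outer(center, center) - (d2 - r^2) * diag(3)
  if (M[1, 1] + M[2, 2] < 0) M <- -M
  A <- M[1:2, 1:2]
  if (det(A) <= 0 || A[1, 1] <= 0)
    sl_error("silhouette_unbounded",
             "sphere silhouette is not a bounded ellipse in the image plane")
  area_norm <- pi * (-det(M)) / det(A)^1.5
  ctr_norm <- -solve(A, M[1:2, 3])
  area_px <- area_norm * camera$fx * camera$fy
  list(center_px = c(camera$fx * ctr_norm[1] + camera$cx,
                     camera$fy * ctr_norm[2] + camera$cy),
       radius_px = sqrt(area_px / pi),
       area_px2 = area_px)
}

#' Simulate pivot-calibration poses
#'
#' Poses of a tracked array rotating about a fixed pivot point with a known
#' tip offset; the forward model for testing [pivot_calibrate()].
#'
#' @param n number of poses.
#' @param tip_offset numeric(3), mm, in the array frame.
#' @param pivot numeric(3) fixed pivot point, mm, tracker frame.
#' @param sigma isotropic translation jitter, mm.
#' @param seed RNG seed.
#' @return list of `rigid_transform` (tracker -> array).
#' @export
synth_pivot_poses <- function(n = 100, tip_offset = c(0, 0, 150),
                              pivot = c(100, -50, 1200), sigma = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quat_to_matrix(q)
    t <- pivot - as.numeric(R %*% tip_offset) +
      if (sigma > 0) stats::rnorm(3, sd = sigma) else c(0, 0, 0)
    rigid_transform(q, t)
  })
}

#' Simulate hand-eye motion pairs
#'
#' Relative motion pairs `(A_i, B_i)` satisfying `A_i X = X B_i` for a known
#' `X`; the forward model for testing [hand_eye_calibrate()].
#'
#' @param x the true `rigid_transform` X.
#' @param n number of motion pairs.
#' @param sigma translation jitter on B motions, mm.
#' @param seed RNG seed.
#' @return `list(a = list of A, b = list of B)`.
#' @export
synth_handeye_motions <- function(x, n = 20, sigma = 0, seed = 1) {
  set.seed(seed)
  a <- list(); b <- list()
  xi <- rt_invert(x)
  for (i in seq_len(n)) {
    bi <- rt_random(trans_range = 50)
    ai <- rt_compose(rt_compose(x, bi), xi)
    if (sigma > 0)
      bi$t <- bi$t + stats::rnorm(3, sd = sigma)
    a[[i]] <- ai; b[[i]] <- bi
  }
  list(a = a, b = b)
}

#' Write ground truth next to a session directory
#'
#' `truth/events.json` (scripted contact events) and
#' `truth/calibrations.json` (true hand-eye, tip offsets, registration).
#'
#' @param truth the truth component of [generate_session()].
#' @param path session directory.
#' @export
write_truth <- function(truth, path) {
  dir.create(file.path(path, "truth"), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(truth$contact_events, dataframe = "rows",
                              digits = NA, pretty = TRUE),
             file.path(path, "truth", "events.json"))
  tf <- function(x) list(q = x$q, t = x$t)
  cal <- list(hand_eye = tf(truth$true_hand_eye),
              tip_offsets = truth$true_tip_offsets,
              registration = tf(truth$true_registration))
  writeLines(jsonlite::toJSON(cal, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "truth", "calibrations.json"))
  invisible(path)
}
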