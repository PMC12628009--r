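# Distance series, kinematics, rule engine, aggregation, scoring.

test_that("rule_config validates its own invariants", {
  expect_error(rule_config(tau_enter = 5, tau_exit = 3), "tau_enter")
  expect_error(rule_config(min_duration = 0), "min_duration")
  expect_error(rule_config(kinematics_window = 4), "kinematics_window")
  cfg <- rule_config()
  expect_true(cfg$tau_enter < cfg$tau_exit && cfg$tau_exit < cfg$tau_far)
})

test_that("a missing verb-table entry fails at configuration time", {
  d <- data.frame(t = 0, frame = 1, instrument = "laser", structure = "s",
                  distance = 1, inside = FALSE, valid = TRUE)
  expect_error(infer_frame_state(d, NULL, rule_config()),
               class = "sl_error_config")
  bad <- rule_config()
  bad$verb_table$grasper$contact_fast <- NULL
  d2 <- d; d2$instrument <- "grasper"
  expect_error(infer_frame_state(d2, NULL, bad), class = "sl_error_config")
})

test_that("kinematics: closed forms and dense finite-difference oracle", {
  ts <- seq(0, 2, by = 1 / 30)
  # constant velocity 10 mm/s along a skew direction
  dirv <- c(2, -1, 2) / 3
  pos <- data.frame(t = ts, x = 10 * ts * dirv[1], y = 10 * ts * dirv[2],
                    z = 10 * ts * dirv[3], valid = TRUE)
  k <- compute_kinematics(pos, window = 5)
  expect_equal(k$speed, rep(10, length(ts)), tolerance = 1e-6)
  # stationary
  pos0 <- data.frame(t = ts, x = 1, y = 2, z = 3, valid = TRUE)
  k0 <- compute_kinematics(pos0, window = 5)
  expect_equal(k0$speed, rep(0, length(ts)), tolerance = 1e-12)
  expect_equal(k0$approach_rate, rep(0, length(ts)), tolerance = 1e-12)
  # smooth trajectory vs dense finite differences (interior, 2%)
  amp <- 20; om <- 2 * pi * 0.2
  poss <- data.frame(t = ts, x = amp * sin(om * ts), y = amp * cos(om * ts),
                     z = 0, valid = TRUE)
  ks <- compute_kinematics(poss, window = 5)
  tfine <- ts
  vtrue <- sqrt((amp * om * cos(om * tfine))^2 + (amp * om * sin(om * tfine))^2)
  interior <- 5:(length(ts) - 5)
  expect_lt(max(abs(ks$speed[interior] - vtrue[interior]) / vtrue[interior]),
            0.02)
  # invalid frames break spans
  posb <- pos; posb$valid[30] <- FALSE
  kb <- compute_kinematics(posb, window = 5)
  expect_true(is.na(kb$speed[30]))
  expect_false(anyNA(kb$speed[-30]))
  # approach_rate sign: positive when the distance is shrinking
  kd <- compute_kinematics(pos, window = 5,
                           nearest_distance = 50 - 4 * ts)
  expect_equal(kd$approach_rate, rep(4, length(ts)), tolerance = 1e-9)
  expect_error(compute_kinematics(pos, window = 4), "odd")
})

mk_dist <- function(ds, instrument = "grasper", structure = "mesentery",
                    fps = 30) {
  data.frame(t = (seq_along(ds) - 1) / fps, frame = seq_along(ds),
             instrument = instrument, structure = structure, distance = ds,
             inside = FALSE, valid = TRUE, stringsAsFactors = FALSE)
}

test_that("frame states: contact, verbs, confidence, hysteresis, ties", {
  cfg <- rule_config()
  # grasper 1 mm from mesentery at 0.5 mm/s -> grasp, confidence >= 2/3
  d <- mk_dist(rep(1, 5))
  kin <- list(grasper = data.frame(t = d$t[1:5], speed = 0.5,
                                   approach_rate = 0, valid = TRUE))
  fs <- infer_frame_state(d, kin, cfg)
  expect_true(all(fs$contact))
  expect_true(all(fs$verb == "grasp"))
  expect_true(all(fs$target == "mesentery"))
  expect_true(all(fs$confidence >= 2 / 3 - 1e-9))

  # hysteresis: distance oscillating 2.9 -> 4.0 -> 2.9 stays in contact
  # (no exit above tau_enter until the distance exceeds tau_exit)
  fh <- infer_frame_state(mk_dist(c(2.9, 4.0, 2.9)), NULL, cfg)
  expect_true(all(fh$contact))
  fh2 <- infer_frame_state(mk_dist(rep(c(2.9, 4.0), 10)), NULL,
                           rule_config(kinematics_window = 3))
  expect_true(all(fh2$contact))
  # and exit only above tau_exit
  fx <- infer_frame_state(mk_dist(c(rep(2.9, 5), rep(5.5, 6))), NULL,
                          rule_config(kinematics_window = 3))
  expect_equal(fx$contact, c(rep(TRUE, 5), FALSE, rep(FALSE, 5)))

  # beyond tau_far: null target, idle verb
  ff <- infer_frame_state(mk_dist(rep(30, 3)), NULL, cfg)
  expect_true(all(ff$target == "null_target"))
  expect_true(all(ff$verb == "idle"))

  # exact tie: structure_priority wins, then name order
  d2 <- rbind(mk_dist(rep(2, 3), structure = "omentum"),
              mk_dist(rep(2, 3), structure = "mesentery"))
  tie1 <- infer_frame_state(d2, NULL, rule_config(
    structure_priority = c("omentum", "mesentery")))
  expect_true(all(tie1$target == "omentum"))
  tie2 <- infer_frame_state(d2, NULL, cfg)   # no priority: name order
  expect_true(all(tie2$target == "mesentery"))

  # speed classes map through the verb table
  kinf <- list(grasper = data.frame(t = d$t[1:5], speed = 20,
                                    approach_rate = 0, valid = TRUE))
  ffast <- infer_frame_state(mk_dist(rep(1, 5)), kinf, cfg)
  expect_true(all(ffast$verb == "retract"))
})

test_that("hysteresis sandwich: stricter tau_enter gives a subset", {
  set.seed(53)
  ds <- abs(3.5 + cumsum(rnorm(400, sd = 0.6)))
  base <- infer_frame_state(mk_dist(ds), NULL, rule_config())
  strict <- infer_frame_state(mk_dist(ds), NULL, rule_config(tau_enter = 2))
  expect_true(all(!strict$contact | base$contact))
  expect_lt(sum(strict$contact), sum(base$contact))
})

test_that("aggregation: runs, blips, merging, invalid frames", {
  cfg <- rule_config()
  # scripted 2 s contact at 30 fps, noiseless
  ds <- c(rep(30, 30), rep(1, 60), rep(30, 30))
  fs <- infer_frame_state(mk_dist(ds), NULL, cfg)
  ev <- aggregate_triplets(fs, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$verb, "grasp")
  expect_equal(ev$target, "mesentery")
  expect_lt(abs(ev$t_start - 30 / 30), 1 / 30 + 1e-9)
  expect_lt(abs(ev$t_end - 90 / 30), 1 / 30 + 1e-9)
  expect_equal(ev$frames, 60)

  # 0.2 s blip < min_duration 0.5 s: no events
  blip <- c(rep(30, 30), rep(1, 6), rep(30, 30))
  evb <- aggregate_triplets(infer_frame_state(mk_dist(blip), NULL, cfg), cfg)
  expect_equal(nrow(evb), 0)

  # two 1 s contacts separated by a 0.1 s gap: merged into one event
  two <- c(rep(1, 30), rep(30, 3), rep(1, 30))
  # (distances of 30 for 3 frames exit contact via the smoothed metric only
  #  if the median crosses tau_exit; force it with a wider gap in distance)
  fs2 <- infer_frame_state(mk_dist(two), NULL,
                           rule_config(kinematics_window = 3))
  ev2 <- aggregate_triplets(fs2, cfg)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$frames, 60)

  # invalid frames break runs but short gaps still merge
  d3 <- mk_dist(rep(1, 60))
  d3$valid[30:31] <- FALSE
  fs3 <- infer_frame_state(d3, NULL, cfg)
  ev3 <- aggregate_triplets(fs3, cfg)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$frames, 58)
})

test_that("determinism: identical inputs give identical event lists", {
  gs <- get_demo()
  r1 <- compute_triplets(gs$session)
  r2 <- compute_triplets(gs$session)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$frame_states, r2$frame_states)
})

test_that("score_events: exact match, misses, closed-form IoU", {
  ev <- data.frame(instrument = "g", verb = "grasp", target = "s",
                   t_start = 0, t_end = 10, stringsAsFactors = FALSE)
  sc <- score_events(ev, ev)
  expect_equal(sc$precision, 1); expect_equal(sc$recall, 1)
  expect_equal(sc$mean_iou, 1)
  empty <- ev[0, ]
  expect_equal(score_events(empty, ev)$recall, 0)
  expect_equal(score_events(ev, empty)$precision, 0)
  # 10% duration offset: IoU = 9/11 exactly
  off <- ev; off$t_start <- 1; off$t_end <- 11
  sc2 <- score_events(off, ev, iou_threshold = 0.5)
  expect_equal(sc2$mean_iou, 9 / 11, tolerance = 1e-9)
  # label mismatch never matches
  wrong <- ev; wrong$verb <- "cut"
  expect_equal(score_events(wrong, ev)$recall, 0)
  expect_error(score_events(ev, ev, iou_threshold = 0), "iou_threshold")
})

test_that("distance series annotates off-screen instruments and dropouts", {
  gs <- get_demo()
  s <- gs$session
  dist <- compute_distance_series(s)
  expect_equal(nrow(dist), 1800 * 2 * 3)
  expect_true(all(dist$distance[dist$valid] >= 0))
  # the scripted off-screen contact (grasper on the ureter tube) is measured:
  ur <- dist[dist$instrument == "grasper" & dist$structure == "ureter", ]
  expect_lt(min(ur$distance), rule_config()$tau_enter - 1)
  # while the tip is off screen for the camera during that dwell
  ev <- gs$truth$contact_events
  evu <- ev[ev$target == "ureter", ]
  tmid <- (evu$t_start + evu$t_end) / 2
  tipc <- resolve_transform(s, "camera_optical", "grasper_tip", tmid)
  vis <- visibility(s$camera$model, tipc$transform$t)
  expect_equal(vis$state, "off_screen")

  # dropout in the instrument stream invalidates its records only
  s2 <- s
  k <- which(vapply(s2$dynamic_edges, function(e)
    e$child_frame == "grasper_array", TRUE))
  sm <- s2$dynamic_edges[[k]]$stream$samples
  sm$valid[sm$t >= 2 & sm$t < 3] <- FALSE
  s2$dynamic_edges[[k]]$stream <- transform_stream("tracker", "grasper_array", sm)
  d2 <- compute_distance_series(s2, s2$frame_clock$times[s2$frame_clock$times < 5])
  bad <- d2$t >= 2 & d2$t < 3 & d2$instrument == "grasper"
  expect_true(all(!d2$valid[bad]))
  expect_true(all(is.na(d2$distance[bad])))
  expect_true(all(d2$valid[d2$instrument == "scissors"]))
})

test_that("no event targets a structure farther than tau_far throughout", {
  gs <- get_demo()
  res <- compute_triplets(gs$session)
  cfg <- rule_config()
  for (i in seq_len(nrow(res$events))) {
    e <- res$events[i, ]
    di <- res$distances
    sel <- di$instrument == e$instrument & di$structure == e$target &
      di$t >= e$t_start & di$t <= e$t_end & di$valid
    expect_true(any(di$distance[sel] <= cfg$tau_far))
  }
})
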