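# Session format: write/load round-trips, invariants, validation.

# a tiny hand-built session exercising every manifest feature
tiny_session <- function(drop_start = NULL, drop_len = 0) {
  tv <- seq(0, 10, by = 1 / 20)
  valid <- rep(TRUE, length(tv))
  if (!is.null(drop_start))
    valid[tv >= drop_start & tv < drop_start + drop_len] <- FALSE
  qs <- t(vapply(tv, function(t) quat_axis_angle(c(0, 0, 1), 0.1 * t),
                 numeric(4)))
  st <- transform_stream("tracker", "scope_array", data.frame(
    t = tv, qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4],
    tx = 10 * tv, ty = 0, tz = -100, valid = valid))
  tab <- transform_stream("tracker", "table_array", data.frame(
    t = tv, qw = 1, qx = 0, qy = 0, qz = 0, tx = 0, ty = 0, tz = 0,
    valid = TRUE))
  new_session(
    session_id = "tiny",
    frames = c("tracker", "table_array", "patient", "scope_array",
               "camera_optical", "tool_array", "tool_tip"),
    dynamic_edges = list(
      list(stream_file = "streams/scope.csv", parent_frame = "tracker",
           child_frame = "scope_array", stream = st),
      list(stream_file = "streams/table.csv", parent_frame = "tracker",
           child_frame = "table_array", stream = tab),
      list(stream_file = "streams/tool.csv", parent_frame = "tracker",
           child_frame = "tool_array", stream = tab)),
    static_edges = list(
      list(name = "registration", parent_frame = "table_array",
           child_frame = "patient",
           transform = rt_axis_angle(c(1, 0, 0), 0.2, c(5, 6, 7))),
      list(name = "hand_eye", parent_frame = "scope_array",
           child_frame = "camera_optical",
           transform = rt_axis_angle(c(0, 1, 0), 0.4, c(1, -2, 30)))),
    camera = list(camera_frame = "camera_optical",
                  model = camera_model(800, 810, 319.5, 239.5, 640, 480,
                                       k1 = -0.1)),
    anatomies = list(list(name = "sphereA", label_id = 1L, frame = "patient",
                          mesh_file = "meshes/sphereA.ply",
                          mesh = mesh_icosphere(8, 2, name = "sphereA"))),
    instruments = list(list(name = "tool_grasper", array_frame = "tool_array",
                            tip_frame = "tool_tip",
                            tip_offset = c(0, 0, 150), tool_radius = 2.5,
                            shaft_length = 150,
                            verbs = c("grasp", "retract"))),
    frame_clock = list(times = seq(0, 10, by = 0.1), nominal_rate = 10))
}

test_that("write/load round-trips a session field for field", {
  s <- tiny_session()
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- load_session(dir)
  expect_identical(s2$session_id, s$session_id)
  expect_identical(s2$frames, s$frames)
  expect_equal(s2$frame_clock$times, s$frame_clock$times, tolerance = 1e-8)
  expect_equal(s2$camera$model, s$camera$model, tolerance = 1e-8)
  expect_equal(s2$anatomies[[1]]$mesh$vertices, s$anatomies[[1]]$mesh$vertices)
  expect_identical(s2$anatomies[[1]]$label_id, 1L)
  expect_equal(s2$instruments[[1]]$tip_offset, c(0, 0, 150))
  for (k in seq_along(s$dynamic_edges))
    expect_equal(s2$dynamic_edges[[k]]$stream$samples,
                 s$dynamic_edges[[k]]$stream$samples, tolerance = 1e-8)
  for (k in seq_along(s$static_edges)) {
    expect_equal(s2$static_edges[[k]]$transform$q,
                 s$static_edges[[k]]$transform$q, tolerance = 1e-8)
    expect_equal(s2$static_edges[[k]]$transform$t,
                 s$static_edges[[k]]$transform$t, tolerance = 1e-8)
  }
})

test_that("writing is deterministic: byte-identical directories", {
  s <- tiny_session()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(s, d1); write_session(s, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("a session with zero instruments is valid", {
  s <- tiny_session()
  s0 <- new_session(s$session_id, s$frames, s$dynamic_edges,
                    s$static_edges[1:2], s$camera, s$anatomies,
                    instruments = list(), frame_clock = s$frame_clock)
  dir <- withr::local_tempdir()
  write_session(s0, dir)
  expect_length(load_session(dir)$instruments, 0)
  rep <- validate_session(s0)
  expect_false(any(rep$issues$severity == "error"))
})

test_that("manifest invariants raise distinct named errors", {
  s <- tiny_session()
  # undeclared frame
  bad <- s; bad$frames <- setdiff(bad$frames, "tool_tip")
  expect_error(do.call(new_session, list(
    bad$session_id, bad$frames, bad$dynamic_edges, bad$static_edges,
    bad$camera, bad$anatomies, bad$instruments, bad$frame_clock)),
    class = "sl_error_unknown_frame")
  # duplicate label id
  a2 <- c(s$anatomies, list(modifyList(s$anatomies[[1]],
                                       list(name = "sphereB"))))
  expect_error(new_session(s$session_id, s$frames, s$dynamic_edges,
                           s$static_edges[1:2], s$camera, a2,
                           list(), s$frame_clock),
               class = "sl_error_duplicate_label")
  # duplicate edge between one frame pair
  dup <- c(s$static_edges[1:2], s$static_edges[1])
  expect_error(new_session(s$session_id, s$frames, s$dynamic_edges, dup,
                           s$camera, s$anatomies, s$instruments,
                           s$frame_clock),
               class = "sl_error_duplicate_edge")
  # redundant cycle
  cyc <- c(s$static_edges[1:2],
           list(list(name = "extra", parent_frame = "patient",
                     child_frame = "camera_optical",
                     transform = rt_identity())))
  expect_error(new_session(s$session_id, s$frames, s$dynamic_edges, cyc,
                           s$camera, s$anatomies, s$instruments,
                           s$frame_clock),
               class = "sl_error_cyclic_edges")
  # unsorted stream
  expect_error(transform_stream("a", "b", data.frame(
    t = c(0, 0.1, 0.1), qw = 1, qx = 0, qy = 0, qz = 0,
    tx = 0, ty = 0, tz = 0, valid = TRUE)),
    class = "sl_error_unsorted_stream")
  # missing file at load
  dir <- withr::local_tempdir()
  write_session(s, dir)
  unlink(file.path(dir, "meshes", "sphereA.ply"))
  expect_error(load_session(dir), class = "sl_error_missing_file")
})

test_that("validate_session reports gaps, coverage and connectivity", {
  clean <- validate_session(tiny_session())
  expect_equal(nrow(clean$issues), 0)
  expect_true(all(clean$coverage == 1))

  # 1 s dropout in a 10 s stream: coverage 0.9 +- one sample interval
  s <- tiny_session(drop_start = 4, drop_len = 1)
  rep <- validate_session(s, max_gap = 0.2)
  cov <- rep$coverage[["tracker->scope_array"]]
  expect_lt(abs(cov - 0.9), 1 / 20 + 1 / 100)
  expect_true(any(rep$issues$code == "tracking_gap"))
  expect_true(all(rep$issues$severity[rep$issues$code == "tracking_gap"] ==
                    "warning"))

  # camera frame disconnected from the patient frame
  s2 <- tiny_session()
  s2$static_edges <- s2$static_edges[
    vapply(s2$static_edges, function(e) e$name != "hand_eye", TRUE)]
  s2$dynamic_edges <- s2$dynamic_edges[
    vapply(s2$dynamic_edges, function(e) e$child_frame != "scope_array", TRUE)]
  rep2 <- validate_session(s2)
  expect_true(any(rep2$issues$code == "disconnected" &
                    rep2$issues$severity == "error"))

  # validation is pure: identical consecutive reports
  expect_identical(validate_session(s), validate_session(s))
})

test_that("generator sessions round-trip through the format", {
  gs <- get_demo()
  dir <- withr::local_tempdir()
  write_session(gs$session, dir)
  s2 <- load_session(dir)
  expect_identical(s2$frames, gs$session$frames)
  expect_equal(s2$dynamic_edges[[2]]$stream$samples$tx,
               gs$session$dynamic_edges[[2]]$stream$samples$tx,
               tolerance = 1e-8)
  expect_equal(s2$frame_clock$times, gs$session$frame_clock$times,
               tolerance = 1e-8)
})
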