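# Camera projection, PNG codec, label/depth rendering, masks, visibility,
# chromadepth.

cam0 <- function(...) camera_model(800, 800, 319.5, 239.5, 640, 480, ...)

test_that("project_point: closed forms and behind-camera flag", {
  cam <- camera_model(1000, 1000, 320, 240, 640, 480)
  p <- project_point(cam, c(0, 0, 100))
  expect_equal(c(p$u, p$v), c(320, 240))
  p2 <- project_point(cam, c(10, 0, 100))
  expect_equal(c(p2$u, p2$v), c(420, 240))
  expect_true(project_point(cam, c(0, 0, -50))$behind)
  expect_true(project_point(cam, c(0, 0, 0.05))$behind)  # z <= z_near
})

test_that("distortion matches an independently coded model and inverts", {
  cam <- cam0(k1 = -0.28, k2 = 0.07, p1 = 0.001, p2 = -0.0005, k3 = 0.002)
  # independent reimplementation of the radial-tangential model
  distort_oracle <- function(xn, yn) {
    r2 <- xn^2 + yn^2
    rad <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
    c(cam$fx * (xn * rad + 2 * cam$p1 * xn * yn + cam$p2 * (r2 + 2 * xn^2)) + cam$cx,
      cam$fy * (yn * rad + cam$p1 * (r2 + 2 * yn^2) + 2 * cam$p2 * xn * yn) + cam$cy)
  }
  undistort <- function(xd, yd) {      # fixed-point iteration
    x <- xd; y <- yd
    for (i in 1:50) {
      r2 <- x^2 + y^2
      rad <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
      x <- (xd - (2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2))) / rad
      y <- (yd - (cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y)) / rad
    }
    c(x, y)
  }
  set.seed(50)
  for (i in 1:100) {
    z <- runif(1, 50, 300)
    xy <- runif(2, -0.35, 0.35) * z
    got <- project_point(cam, c(xy, z))
    want <- distort_oracle(xy[1] / z, xy[2] / z)
    expect_lt(max(abs(c(got$u, got$v) - want)), 1e-6)
    # undistort o distort round-trip
    back <- undistort((got$u - cam$cx) / cam$fx, (got$v - cam$cy) / cam$fy)
    expect_lt(max(abs(back - xy / z)), 1e-6)
  }
})

test_that("PNG codec round-trips gray8, gray16 and RGB", {
  set.seed(51)
  m8 <- matrix(sample(0:255, 60 * 80, TRUE), 60, 80)
  p <- withr::local_tempfile(fileext = ".png")
  write_png_gray(m8, p)
  expect_identical(read_png(p), m8)
  m16 <- matrix(sample(0:65535, 60 * 80, TRUE), 60, 80)
  write_png_gray(m16, p, bitdepth = 16)
  expect_identical(read_png(p), m16)
  rgb <- array(sample(0:255, 30 * 40 * 3, TRUE), c(30, 40, 3))
  write_png_rgb(rgb, p)
  expect_identical(read_png(p), rgb)
  # depth quantization: 0.1 mm units
  d <- matrix(c(0, 12.34, 500.06, 1.01), 2, 2)
  write_depth_png(d, p)
  expect_equal(read_depth_png(p), matrix(c(0, 12.3, 500.1, 1.0), 2, 2),
               tolerance = 1e-9)
  expect_error(write_png_gray(matrix(-1, 2, 2), p), "out of range")
})

test_that("empty scene renders all background", {
  lm <- render_label_map(cam0(), list())
  expect_true(all(lm$labels == 0L))
  expect_true(all(lm$depth == 0))
})

test_that("sphere label area matches the analytic silhouette within 1%", {
  cam <- cam0()
  r <- 10; z <- 100
  sph <- mesh_icosphere(r, 4)
  lm <- render_label_map(cam, list(list(mesh = sph,
                                        transform = rigid_transform(t = c(0, 0, z)),
                                        label_id = 1L)))
  sil <- analytic_sphere_silhouette(cam, c(0, 0, z), r)
  expect_gt(sil$radius_px, 30)                 # regime the bound targets
  area <- sum(lm$labels == 1L)
  expect_lt(abs(area - sil$area_px2) / sil$area_px2, 0.01)
  # depth at the centre pixel is the near surface of the sphere
  expect_equal(lm$depth[240, 320], z - r, tolerance = 0.1)
  # label/depth consistency
  expect_identical(lm$labels > 0L, lm$depth > 0)
})

test_that("z-order: nearer surface wins everywhere in the overlap", {
  sq <- function(z, half) {
    v <- rbind(c(-half, -half, z), c(half, -half, z),
               c(half, half, z), c(-half, half, z))
    triangle_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
  }
  lm <- render_label_map(cam0(), list(
    list(mesh = sq(50, 10), transform = rt_identity(), label_id = 1L),
    list(mesh = sq(100, 30), transform = rt_identity(), label_id = 2L)))
  # the near square fully covers its projection; label 2 only outside it
  near_px <- lm$labels == 1L
  expect_gt(sum(near_px), 0)
  expect_gt(sum(lm$labels == 2L), 0)
  # inside the overlap the depth equals the near plane
  expect_true(all(lm$depth[near_px] == 50))
  # reversing the draw order changes nothing (z-buffer, not painter)
  lm2 <- render_label_map(cam0(), list(
    list(mesh = sq(100, 30), transform = rt_identity(), label_id = 2L),
    list(mesh = sq(50, 10), transform = rt_identity(), label_id = 1L)))
  expect_identical(lm$labels, lm2$labels)
})

test_that("rendering is deterministic and monotone under mesh shrink", {
  cam <- cam0()
  sph <- mesh_icosphere(10, 3, center = c(3, -2, 0))
  posed <- list(list(mesh = sph, transform = rigid_transform(t = c(0, 0, 90)),
                     label_id = 5L))
  a <- render_label_map(cam, posed)
  b <- render_label_map(cam, posed)
  expect_identical(a$labels, b$labels)
  expect_identical(a$depth, b$depth)
  # strict shrink about the centroid never increases coverage
  for (sc in c(0.9, 0.6, 0.3)) {
    ctr <- colMeans(sph$vertices)
    shr <- triangle_mesh(sweep(sweep(sph$vertices, 2, ctr), 2, ctr,
                               FUN = function(x, c) x * sc + c), sph$faces)
    lm2 <- render_label_map(cam, list(list(
      mesh = shr, transform = rigid_transform(t = c(0, 0, 90)),
      label_id = 5L)))
    expect_lte(sum(lm2$labels > 0), sum(a$labels > 0))
  }
})

test_that("instrument masks: silhouette oracle, occlusion, off-screen", {
  cam <- cam0()
  tip <- c(0, 0, 80); arr <- c(30, 20, 220)
  ins <- list(list(name = "grasper", tip_cam = tip, array_cam = arr,
                   tool_radius = 2.5, shaft_length = 150, valid = TRUE))
  masks <- render_instrument_masks(cam, ins, amodal = TRUE)
  m <- masks$grasper$mask
  # independent silhouette oracle: pixel in silhouette iff the camera ray
  # through it passes within tool_radius of the capsule axis segment
  d <- arr - tip; len <- sqrt(sum(d^2)); dirv <- d / len
  a <- tip + dirv * min(len, 150)      # truncated at shaft_length
  uu <- matrix((0:639 - cam$cx) / cam$fx, 480, 640, byrow = TRUE)
  vv <- matrix((0:479 - cam$cy) / cam$fy, 480, 640)
  inside <- matrix(FALSE, 480, 640)
  for (i in seq(0, 1, length.out = 200)) {   # sample the segment densely
    p <- tip + i * (a - tip)
    # distance from ray r(s)=s*(u,v,1) to point p
    rd2 <- uu^2 + vv^2 + 1
    s <- (uu * p[1] + vv * p[2] + p[3]) / rd2
    dx <- s * uu - p[1]; dy <- s * vv - p[2]; dz <- s - p[3]
    inside <- inside | (dx^2 + dy^2 + dz^2 <= 2.5^2)
  }
  expect_lt(abs(sum(m) - sum(inside)) / sum(inside), 0.05)

  # occlusion: a wall in front of the far half of the capsule
  wallv <- rbind(c(-100, -100, 120), c(100, -100, 120),
                 c(100, 100, 120), c(-100, 100, 120))
  wall <- triangle_mesh(wallv, rbind(c(1, 2, 3), c(1, 3, 4)))
  lm <- render_label_map(cam, list(list(mesh = wall,
                                        transform = rt_identity(),
                                        label_id = 1L)))
  vis <- render_instrument_masks(cam, ins, lm$depth, amodal = FALSE)
  amo <- render_instrument_masks(cam, ins, lm$depth, amodal = TRUE)
  expect_lt(sum(vis$grasper$mask), sum(amo$grasper$mask))
  expect_identical(amo$grasper$mask, m)  # amodal ignores the wall
  # the visible mask is a subset of the amodal one
  expect_true(all(!vis$grasper$mask | amo$grasper$mask))

  # fully outside the frustum: empty mask, off_screen
  far <- list(list(name = "g", tip_cam = c(500, 0, 100),
                   array_cam = c(900, 0, 300), tool_radius = 2.5,
                   shaft_length = 150, valid = TRUE))
  mf <- render_instrument_masks(cam, far, amodal = TRUE)
  expect_equal(sum(mf$g$mask), 0)
  expect_equal(mf$g$visibility$state, "off_screen")
  # invalid pose: mask flagged invalid
  mi <- render_instrument_masks(cam, list(list(name = "g", valid = FALSE)))
  expect_false(mi$g$valid)
  expect_equal(sum(mi$g$mask), 0)
})

test_that("visibility states and occlusion flag", {
  cam <- cam0()
  expect_equal(visibility(cam, c(0, 0, -50))$state, "behind_camera")
  expect_equal(visibility(cam, c(500, 0, 100))$state, "off_screen")
  sph <- mesh_icosphere(10, 3)
  lm <- render_label_map(cam, list(list(
    mesh = sph, transform = rigid_transform(t = c(0, 0, 100)), label_id = 1L)))
  behind <- visibility(cam, c(0, 0, 150), lm$depth)
  expect_equal(behind$state, "on_screen")
  expect_true(behind$occluded)
  before <- visibility(cam, c(0, 0, 50), lm$depth)
  expect_equal(before$state, "on_screen")
  expect_false(before$occluded)
})

test_that("chromadepth ramp: endpoints, midpoint, monotone red channel", {
  d <- matrix(c(0, 50, 100, 150, 75, 200), 2, 3)
  img <- render_chromadepth(d, 50, 150)
  expect_equal(img[1, 1, ], c(0L, 0L, 0L))          # background black
  expect_equal(img[2, 1, ], c(255L, 0L, 0L))        # z_min pure red
  expect_equal(img[1, 2, ], c(0L, 255L, 0L))        # midpoint (100) green
  expect_equal(img[2, 2, ], c(0L, 0L, 255L))        # z_max pure blue
  expect_equal(img[2, 3, ], c(0L, 0L, 255L))        # clamped beyond z_max
  set.seed(52)
  dm <- matrix(runif(200, 10, 300), 10, 20)
  im <- render_chromadepth(dm, 10, 300)
  o <- order(dm)
  red <- im[, , 1][o]
  expect_true(all(diff(red) <= 0))                  # deeper never redder
})
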