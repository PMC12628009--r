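# Rigid-transform algebra, pose interpolation, point-mesh queries.

test_that("compose matches the homogeneous matrix product and is associative", {
  set.seed(42)
  for (i in 1:50) {
    a <- rt_random(); b <- rt_random(); c <- rt_random()
    expect_lt(max(abs(rt_to_matrix(rt_compose(a, b)) -
                        rt_to_matrix(a) %*% rt_to_matrix(b))), 1e-9)
    # associativity
    expect_lt(max(abs(rt_to_matrix(rt_compose(rt_compose(a, b), c)) -
                        rt_to_matrix(rt_compose(a, rt_compose(b, c))))), 1e-9)
    # quaternion stays normalized
    expect_lt(abs(sum(rt_compose(a, b)$q^2) - 1), 1e-9)
  }
  t1 <- rt_random()
  expect_equal(rt_compose(rt_identity(), t1)$t, t1$t)
  expect_lt(max(abs(rt_to_matrix(rt_compose(rt_identity(), t1)) -
                      rt_to_matrix(t1))), 1e-12)
})

test_that("invert matches the matrix inverse and round-trips", {
  expect_equal(rt_invert(rt_identity())$t, c(0, 0, 0))
  tr <- rt_invert(rigid_transform(t = c(1, 2, 3)))
  expect_equal(tr$t, c(-1, -2, -3))
  set.seed(43)
  for (i in 1:50) {
    a <- rt_random()
    expect_lt(max(abs(rt_to_matrix(rt_invert(a)) - solve(rt_to_matrix(a)))),
              1e-9)
    expect_lt(max(abs(rt_to_matrix(rt_compose(a, rt_invert(a))) - diag(4))),
              1e-9)
  }
})

test_that("interpolate_pose: endpoints exact, symmetry, geodesic oracle", {
  p0 <- rt_identity()
  p1 <- rt_axis_angle(c(0, 0, 1), pi / 2, c(10, 0, 0))
  expect_identical(interpolate_pose(0, p0, 1, p1, 0)$q, p0$q)
  expect_identical(interpolate_pose(0, p0, 1, p1, 0)$t, p0$t)
  mid <- interpolate_pose(0, p0, 1, p1, 0.5)
  expect_lt(rt_rotation_angle(mid, rt_axis_angle(c(0, 0, 1), pi / 4)), 1e-9)
  expect_equal(mid$t, c(5, 0, 0))
  expect_error(interpolate_pose(0, p0, 1, p1, 1.5),
               class = "sl_error_out_of_range")

  set.seed(44)
  for (i in 1:20) {
    a <- rt_random(); b <- rt_random()
    u <- 0.3
    got <- interpolate_pose(0, a, 1, b, u)
    # matrix-log geodesic oracle: R(u) = Ra expm(u logm(Ra^T Rb))
    Ra <- rt_to_matrix(a)[1:3, 1:3]; Rb <- rt_to_matrix(b)[1:3, 1:3]
    Rex <- Ra %*% rot_exp(u * rot_log(t(Ra) %*% Rb))
    ang <- acos(pmin(1, (sum(diag(t(Rex) %*% quat_to_matrix_test(got$q))) - 1) / 2))
    expect_lt(ang, 1e-7)
    expect_equal(got$t, (1 - u) * a$t + u * b$t, tolerance = 1e-12)
    # symmetry under (p0,p1) swap and t -> t0+t1-t
    got2 <- interpolate_pose(0, b, 1, a, 1 - u)
    expect_lt(rt_rotation_angle(got, got2), 1e-9)
    expect_equal(got$t, got2$t, tolerance = 1e-9)
  }
})

test_that("point_triangle_distance is exact", {
  a <- c(0, 0, 0); b <- c(4, 0, 0); c3 <- c(0, 3, 0)
  expect_equal(point_triangle_distance(a, a, b, c3)$distance, 0)
  expect_equal(point_triangle_distance(a, a, b, c3)$closest_point, a)
  # right triangle in z = 0, point above the interior at height h
  expect_equal(point_triangle_distance(c(1, 1, 2.5), a, b, c3)$distance, 2.5)
  expect_error(point_triangle_distance(c(0, 0, 1), a, a, a),
               class = "sl_error_degenerate")

  set.seed(45)
  for (i in 1:1000) {
    v <- matrix(rnorm(9, sd = 10), 3, 3)
    p <- rnorm(3, sd = 15)
    got <- point_triangle_distance(p, v[1, ], v[2, ], v[3, ])
    expect_equal(got$distance, oracle_point_tri(p, v[1, ], v[2, ], v[3, ]),
                 tolerance = 1e-9)
    # returned closest point is consistent with the distance
    expect_equal(sqrt(sum((p - got$closest_point)^2)), got$distance,
                 tolerance = 1e-9)
  }
})

test_that("point_triangle_distance agrees with dense surface sampling", {
  # barycentric grid of ~10^4 samples per triangle; the sampling oracle
  # overestimates by at most the grid spacing, so the check is one-sided
  # plus a grid-derived bound
  set.seed(46)
  gr <- expand.grid(u = seq(0, 1, length.out = 100),
                    v = seq(0, 1, length.out = 100))
  gr <- gr[gr$u + gr$v <= 1, ]
  for (i in 1:40) {
    v <- matrix(rnorm(9, sd = 10), 3, 3)
    p <- rnorm(3, sd = 15)
    samp <- outer(1 - gr$u - gr$v, v[1, ]) + outer(gr$u, v[2, ]) +
      outer(gr$v, v[3, ])
    dmin <- sqrt(min(rowSums(sweep(samp, 2, p)^2)))
    got <- point_triangle_distance(p, v[1, ], v[2, ], v[3, ])$distance
    h <- max(dist(v)) / 99          # grid spacing bound
    expect_lte(got, dmin + 1e-9)
    expect_lte(dmin - got, h)
  }
})

test_that("mesh_distance: icosphere oracle and accel/brute equivalence", {
  r <- 10
  sph <- mesh_icosphere(r, 4)
  tol <- icosphere_chord_tolerance(sph, c(0, 0, 0), r)
  expect_lt(tol, 0.05)
  got <- mesh_distance(c(0, 0, 2 * r), sph)
  expect_lt(abs(got$distance - r), tol + 1e-12)
  # a vertex lies on the sphere: distance 0 there
  expect_equal(mesh_distance(sph$vertices[17, ], sph)$distance, 0,
               tolerance = 1e-12)
  expect_error(mesh_distance(c(0, 0, 0), triangle_mesh(matrix(0, 0, 3),
                                                       matrix(0L, 0, 3))),
               class = "sl_error_empty_mesh")

  set.seed(47)
  P <- matrix(rnorm(500 * 3, sd = 2 * r), ncol = 3)
  acc <- mesh_distance(P, sph, method = "accel")
  bru <- mesh_distance(P, sph, method = "brute")
  expect_true(all(acc$face == bru$face | abs(acc$distance - bru$distance) < 1e-9))
  expect_equal(acc$distance, bru$distance, tolerance = 1e-12)
})

test_that("mesh surface points have zero distance; off-surface do not", {
  sph <- mesh_icosphere(5, 2)
  set.seed(48)
  f <- sample(nrow(sph$faces), 50)
  w <- matrix(runif(150), ncol = 3); w <- w / rowSums(w)
  pts <- sapply(1:50, function(i) {
    v <- sph$vertices[sph$faces[f[i], ], ]
    colSums(v * w[i, ])
  })
  d <- mesh_distance(t(pts), sph)$distance
  expect_true(all(d < 1e-9))
  expect_gt(mesh_distance(c(0, 0, 5.5), sph)$distance, 0.4)
})

test_that("point_in_mesh matches the winding-number oracle", {
  sph <- mesh_icosphere(10, 3, center = c(1, 2, 3))
  expect_true(point_in_mesh(c(1, 2, 3), sph))
  expect_false(point_in_mesh(c(1, 2, 23), sph))
  set.seed(49)
  P <- matrix(rnorm(200 * 3, sd = 8), ncol = 3) +
    matrix(c(1, 2, 3), 200, 3, byrow = TRUE)
  got <- point_in_mesh(P, sph)
  wn <- apply(P, 1, function(p) winding_number(p, sph))
  expect_identical(got, wn > 0.5)

  # non-watertight mesh: containment unsupported
  open_mesh <- triangle_mesh(sph$vertices, sph$faces[-1, , drop = FALSE])
  expect_error(point_in_mesh(c(1, 2, 3), open_mesh),
               class = "sl_error_not_watertight")
})

test_that("collision predicate combines proximity and containment", {
  sph <- mesh_icosphere(10, 3)
  expect_true(check_collision(c(0, 0, 10.5), sph, tolerance = 1))   # near
  expect_true(check_collision(c(0, 0, 0), sph, tolerance = 1))      # inside
  expect_false(check_collision(c(0, 0, 15), sph, tolerance = 1))    # far
})

test_that("mesh construction rejects invalid geometry", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))),
               class = "sl_error_mesh_invalid")
  expect_error(triangle_mesh(v, rbind(c(1, 1, 2))),
               class = "sl_error_mesh_invalid")  # zero area
  m <- triangle_mesh(v, rbind(c(1, 2, 3)))
  expect_s3_class(m, "triangle_mesh")
})
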