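# Shared fixtures.  The demo session is expensive enough to build once and
# reuse across test files; everything is generated in code (no stored data).

demo_cache <- new.env(parent = emptyenv())

get_demo <- function() {
  if (is.null(demo_cache$gs))
    demo_cache$gs <- generate_session(synth_config(seed = 1))
  demo_cache$gs
}

get_demo_jitter <- function() {
  if (is.null(demo_cache$gsj))
    demo_cache$gsj <- generate_session(
      synth_config(seed = 7, noise = list(jitter_sigma_t = 1)))
  demo_cache$gsj
}

# independent rotation exp/log used as oracles (test-side only, written
# against the matrix definitions, not the package quaternion code)
rot_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(pmin(1, pmax(-1, ct)))
  if (th < 1e-12) return(c(0, 0, 0))
  (th / (2 * sin(th))) * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1],
                           R[2, 1] - R[1, 2])
}

rot_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# test-side quaternion -> matrix conversion (independent reimplementation,
# used by several oracle checks)
quat_to_matrix_test <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# independent closest-point-on-segment helper for distance oracles
seg_closest <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(1, max(0, t))
  a + t * ab
}

# independent exact point-triangle distance: min of (plane projection if its
# barycentrics are all nonnegative) and the three edge segments
oracle_point_tri <- function(p, a, b, c) {
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - a) * n) * n          # projection into the plane
  # barycentric coordinates of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  cands <- list(seg_closest(p, a, b), seg_closest(p, b, c),
                seg_closest(p, c, a))
  if (v >= 0 && w >= 0 && v + w <= 1) cands <- c(cands, list(q))
  min(vapply(cands, function(x) sqrt(sum((p - x)^2)), 0))
}
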