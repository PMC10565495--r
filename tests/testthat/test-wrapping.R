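test_that("path length and directions follow the polyline", {
  p <- rbind(c(0, 0, 0), c(0.3, 0.4, 0))
  pl <- path_length_and_direction(p)
  expect_equal(pl$lmt, 0.5)
  expect_vec_equal(pl$dir_origin, c(0.6, 0.8, 0), 1e-12)
  expect_vec_equal(pl$dir_insertion, -c(0.6, 0.8, 0), 1e-12)
  # via path: sum of segments
  p3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(path_length_and_direction(p3)$lmt, 2)
  expect_error(path_length_and_direction(rbind(c(0, 0, 0))), "2 points")
})

test_that("cylinder wrap matches the planar tangent-arc construction", {
  cyl <- list(center = c(0, 0, 0), axis = c(0, 0, 1), radius = 1)
  p0 <- c(-2, -0.5, 0); p1 <- c(2, -0.5, 0)
  w <- wrap_cylinder(p0, p1, cyl, n_arc = 64L)
  expect_false(is.null(w))
  len <- path_length_and_direction(rbind(p0, w, p1))$lmt
  # analytic 2D tangent construction (symmetric chord below the axis)
  n0 <- sqrt(sum(p0^2)); l0 <- sqrt(n0^2 - 1)
  a0 <- acos(1 / n0)
  phi0 <- atan2(p0[2], p0[1]); phi1 <- atan2(p1[2], p1[1])
  dpsi <- ((phi1 - a0) - (phi0 + a0)) %% (2 * pi)
  analytic <- 2 * l0 + dpsi
  expect_equal(len, analytic, tolerance = 1e-4)
  # wrapped path at least as long as the straight line
  expect_gte(len, sqrt(sum((p1 - p0)^2)))
  # segment missing the cylinder: no contact
  expect_null(wrap_cylinder(c(-2, 5, 0), c(2, 5, 0), cyl))
  # endpoint inside is an error
  expect_error(wrap_cylinder(c(0.2, 0, 0), c(2, 0, 0), cyl), "inside")
})

test_that("path length is continuous across grazing incidence", {
  cyl <- list(center = c(0, 0, 0), axis = c(0, 0, 1), radius = 1)
  p0 <- c(-3, -1.5, 0)
  lens <- vapply(seq(-1.2, -0.8, length.out = 41), function(y1) {
    p1 <- c(3, y1, 0)
    w <- wrap_cylinder(p0, p1, cyl, n_arc = 64L)
    if (is.null(w)) sqrt(sum((p1 - p0)^2)) else
      path_length_and_direction(rbind(p0, w, p1))$lmt
  }, numeric(1))
  # no jump at wrap engagement: successive samples move by at most the
  # geometric rate of the endpoint sweep, and the slope changes smoothly
  expect_lt(max(abs(diff(lens))), 0.02)
  expect_lt(max(abs(diff(lens, differences = 2))), 1e-3)
})

test_that("ellipsoid wrap reduces to the great-circle construction on a sphere", {
  ell <- list(center = c(0, 0, 0), R = diag(3), radii = c(1, 1, 1))
  p0 <- c(-2, -0.5, 0); p1 <- c(2, -0.5, 0)
  w <- wrap_ellipsoid(p0, p1, ell, n_chain = 31L, tol = 1e-7,
                      max_iter = 5000L)
  expect_false(is.null(w))
  len <- path_length_and_direction(rbind(p0, w, p1))$lmt
  n0 <- sqrt(sum(p0^2)); a0 <- acos(1 / n0)
  phi0 <- atan2(p0[2], p0[1]); phi1 <- atan2(p1[2], p1[1])
  dpsi <- ((phi1 - a0) - (phi0 + a0)) %% (2 * pi)
  analytic <- 2 * sqrt(n0^2 - 1) + dpsi
  expect_equal(len, analytic, tolerance = 0.01)
  expect_gte(len, sqrt(sum((p1 - p0)^2)))
  # miss: straight line
  expect_null(wrap_ellipsoid(c(-2, 3, 0), c(2, 3, 0), ell))
  expect_error(wrap_ellipsoid(c(0, 0, 0), c(2, 0, 0), ell), "inside")
})

test_that("lumbar wrap joints follow the extension and flexion ratios", {
  ref <- list(l1_pos = c(0.02, 0, 0.20), l2_pos = c(0.025, 0, 0.16),
              l4_pos = c(0.03, 0, 0.08), s1_pos = c(0, 0, 0),
              joint_center = c(-0.02, 0, 0.0345))
  # neutral: zero rotation and translation
  st0 <- list(l1_rot = 0, l1_pos = ref$l1_pos, l2_pos = ref$l2_pos,
              l4_pos = ref$l4_pos)
  lw0 <- update_lumbar_wrap(st0, ref)
  expect_equal(lw0$hinge_deg, 0)
  expect_equal(lw0$slider_m, 0)
  # extension: L2-S1 z-distance reduced 10 mm -> slider +5.4 mm
  st1 <- list(l1_rot = -5, l1_pos = ref$l1_pos,
              l2_pos = ref$l2_pos - c(0, 0, 0.010), l4_pos = ref$l4_pos)
  expect_equal(update_lumbar_wrap(st1, ref)$slider_m, 0.0054)
  # flexion: L4 anterior +10 mm -> slider +13 mm, hinge fixed
  st2 <- list(l1_rot = 5, l1_pos = ref$l1_pos, l2_pos = ref$l2_pos,
              l4_pos = ref$l4_pos + c(0.010, 0, 0))
  lw2 <- update_lumbar_wrap(st2, ref)
  expect_equal(lw2$slider_m, 0.013)
  expect_equal(lw2$hinge_deg, 0)
  # extension hinge keeps the angular sum to the S1 perpendicular constant
  ang <- function(v) atan2(v[1], v[3])
  st3 <- list(l1_rot = -5,
              l1_pos = ref$s1_pos +
                as.numeric(rot_y(-4) %*% (ref$l1_pos - ref$s1_pos)),
              l2_pos = ref$l2_pos, l4_pos = ref$l4_pos)
  lw3 <- update_lumbar_wrap(st3, ref)
  th_ref <- ang(ref$l1_pos - ref$s1_pos)
  th_cur <- ang(st3$l1_pos - ref$s1_pos)
  expect_equal(rad2deg(th_cur - th_ref) + lw3$hinge_deg, 0,
               tolerance = 1e-9)
})

test_that("tendon-excursion moment arm matches the path-force moment", {
  # one muscle from a fixed origin to a point on a body rotating about +y,
  # wrapped around a cylinder: d lMT / d theta equals the moment per unit
  # tension about the same axis
  cyl <- list(center = c(0, 0, 0), axis = c(0, 1, 0), radius = 0.05)
  origin <- c(-0.2, 0, -0.1)
  attach_local <- c(0.15, 0, 0.12)
  path_of <- function(theta) {
    pb <- as.numeric(rot_y(theta) %*% attach_local)
    w <- wrap_cylinder(origin, pb, cyl)
    rbind(origin, w, pb)
  }
  lmt_of <- function(theta) path_length_and_direction(path_of(theta))$lmt
  th <- 18
  h <- 0.01
  darm_num <- (lmt_of(th + h) - lmt_of(th - h)) / (2 * deg2rad(h))
  # moment about +y from unit tension at the moving attachment
  P <- path_of(th)
  pl <- path_length_and_direction(P)
  pb <- P[nrow(P), ]
  f <- pl$dir_insertion                     # unit force on the body
  mom <- cross3(pb, f)[2]
  expect_equal(-darm_num, mom, tolerance = abs(mom) * 0.01)
})
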