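test_that("chain coordinates follow the case-sensitive polynomials", {
  cc0 <- chain_coordinates(0, 0, 0)
  expect_true(all(cc0 == 0))
  # flexion branch at +30 deg
  cc <- chain_coordinates(0, 30, 0)
  expect_equal(unname(cc["theta1"]), 0.442 * 30 + 0.0116 * 900,
               tolerance = 1e-12)
  expect_equal(unname(cc["theta2"]), 0.2509 * 30)
  expect_equal(unname(cc["z"]), -0.1663 * 30)
  # extension branch at -10 deg (quadratic term dominates near zero)
  cc2 <- chain_coordinates(0, -10, 0)
  expect_equal(unname(cc2["theta1"]), 0.2437 * (-10) + 0.0144 * 100,
               tolerance = 1e-12)
  expect_equal(unname(cc2["theta2"]), 0.4236 * (-10))
  # lateral/axial arguments drive phi and theta3
  cc3 <- chain_coordinates(alpha_x = 8, alpha_y = 5, alpha_z = 3)
  expect_equal(unname(cc3["phi"]), 0.4406 * 11)
  expect_equal(unname(cc3["theta3"]), 0.815 * 8)
})

test_that("plate forward kinematics composes the elementary joint transforms", {
  cfg <- default_chain_config()
  # zero coordinates: plate at its build pose
  ap0 <- pose_plates(chain_coordinates(0, 0, 0), config = cfg)
  expect_vec_equal(ap0$origin, cfg$ap0$center, 1e-12)
  # pure theta1: the plate moves on a circle about the UJ center
  r0 <- sqrt(sum((cfg$ap0$center - cfg$uj$center)^2))
  for (t1 in c(5, 12)) {
    cc <- chain_coordinates(0, 0, 0)
    cc["theta1"] <- t1
    ap <- pose_plates(cc, config = cfg)
    expect_equal(sqrt(sum((ap$origin - cfg$uj$center)^2)), r0,
                 tolerance = 1e-10)
  }
  # composed pose equals a product of homogeneous transforms built
  # independently in the test
  hom <- function(R, t) rbind(cbind(R, t), c(0, 0, 0, 1))
  rot_about_h <- function(R, c0) hom(R, c0 - R %*% c0)
  cc <- c(theta1 = 7, theta2 = -4, theta3 = 3, phi = 6, z = -2)
  Ruj <- rot_x(90) %*% rot_z(10)
  Rhj <- rot_x(90)
  Rcj <- rot_x(90) %*% rot_z(10) %*% rot_y(90)
  Tuj <- rot_about_h(Ruj %*% rot_z(7) %*% rot_y(6) %*% t(Ruj),
                     cfg$uj$center)
  Thj <- rot_about_h(Rhj %*% rot_z(-4) %*% t(Rhj), cfg$hj$center)
  Tcj <- rot_about_h(Rcj %*% rot_z(3) %*% t(Rcj), cfg$cj$center)
  Tcj[1:3, 4] <- Tcj[1:3, 4] + as.numeric(Rcj %*% c(0, 0, -2 * cfg$z_scale_m))
  Tap <- hom(rot_y(7), cfg$ap0$center)
  M <- Tuj %*% Thj %*% Tcj %*% Tap
  ap <- pose_plates(cc, config = cfg)
  expect_vec_equal(ap$origin, M[1:3, 4], 1e-10)
  expect_vec_equal(ap$R, M[1:3, 1:3], 1e-10)
})

test_that("the six-dimensional plate spring produces the stated wrenches", {
  f1 <- new_frame()
  expect_vec_equal(frame_spring_wrench(f1, f1)$force_iap, c(0, 0, 0), 1e-12)
  # 1 mm offset along the plate normal: 90 N restoring force
  f2 <- new_frame(c(0.001, 0, 0))
  sw <- frame_spring_wrench(f1, f2)
  expect_equal(sqrt(sum(sw$force_iap^2)), 90)
  expect_vec_equal(sw$force_iap, c(-90, 0, 0), 1e-9)
  expect_vec_equal(sw$force_ap, -sw$force_iap, 1e-12)
  # posterior (compressive) displacement gives a positive F_AP
  f2b <- new_frame(c(-0.001, 0, 0))
  expect_equal(frame_spring_wrench(f1, f2b)$normal_force, 90)
  # 0.01 rad tilt: 5 Nm restoring moment
  f3 <- new_frame(R = rot_y(rad2deg(0.01)))
  expect_equal(sqrt(sum(frame_spring_wrench(f1, f3)$torque_iap^2)), 5,
               tolerance = 1e-9)
  # shear stiffness 1 MN/m
  f4 <- new_frame(c(0, 0.0005, 0))
  expect_equal(sqrt(sum(frame_spring_wrench(f1, f4)$force_iap^2)), 500)
})

test_that("intra-abdominal pressure follows the cavity relation with offset and cap", {
  # no muscle force: offset only
  expect_equal(compute_iap(0)$p_iap_mmhg, 4)
  # worked example: c_w = 0.6, d = 0.2 m, h = 0.3 m, F_AP = 120 N
  cav <- list(d_ac = 0.2, h_ac = 0.3, c_w = 0.6, offset_mmhg = 4,
              cap_mmhg = 200)
  r <- compute_iap(120, cav)
  expect_equal(r$f_iap, 100 / 3, tolerance = 1e-9)
  area <- pi * 0.2^2 / 4
  expect_equal(r$p_iap_mmhg - 4, (100 / 3) / area / 133.322387,
               tolerance = 1e-6)
  expect_equal(r$p_iap_mmhg - 4, 7.96, tolerance = 1e-3)
  # arbitrarily large force saturates at the 200 mmHg cap
  expect_equal(compute_iap(1e9, cav)$p_iap_mmhg, 200)
  # monotone non-decreasing in F_AP and continuous at the clamp
  ps <- vapply(seq(0, 5e4, length.out = 60), function(f)
    compute_iap(f, cav)$p_iap_mmhg, numeric(1))
  expect_true(all(diff(ps) >= 0))
  # continuity at the clamp: find the crossing and compare both sides
  fstar <- uniroot(function(f) compute_iap(f, cav)$p_iap_mmhg - 199.999,
                   c(1, 5e4))$root
  expect_lt(abs(compute_iap(fstar + 1, cav)$p_iap_mmhg -
                  compute_iap(fstar - 1, cav)$p_iap_mmhg), 0.1)
  # negative inputs are clamped at zero compression
  expect_equal(compute_iap(-50)$p_iap_mmhg, 4)
  expect_error(compute_iap(10, list(d_ac = -1, h_ac = 0.3, c_w = 0.6,
                                    offset_mmhg = 4, cap_mmhg = 200)),
               "cavity")
  # the applied force rotates with the thorax
  Rth <- rot_y(25)
  expect_vec_equal(compute_iap(120, cav, Rth)$force,
                   as.numeric(Rth %*% c(0, 0, compute_iap(120, cav)$force[3])),
                   1e-9)
})

test_that("DTW distance matches brute-force path enumeration", {
  a <- c(0, 1, 2, 3, 4)
  expect_equal(dtw_distance(a, a), 0)
  # constant offset on n samples: n * |delta| with L1 local cost
  expect_equal(dtw_distance(a, a + 0.5), 5 * 0.5)
  expect_error(dtw_distance(numeric(0), a), "empty")
  # exhaustive enumeration of monotone warping paths on 4x4 grids
  brute_dtw <- function(x, y) {
    n <- length(x); m <- length(y)
    best <- Inf
    walk <- function(i, j, cost) {
      cost <- cost + abs(x[i] - y[j])
      if (i == n && j == m) { best <<- min(best, cost); return() }
      if (i < n) walk(i + 1, j, cost)
      if (j < m) walk(i, j + 1, cost)
      if (i < n && j < m) walk(i + 1, j + 1, cost)
    }
    walk(1, 1, 0)
    best
  }
  set.seed(21)
  for (k in 1:6) {
    x <- rnorm(4); y <- rnorm(4)
    expect_equal(dtw_distance(x, y), brute_dtw(x, y), tolerance = 1e-12)
  }
  # symmetry
  x <- rnorm(5); y <- rnorm(4)
  expect_equal(dtw_distance(x, y), dtw_distance(y, x))
})

test_that("synthetic mocap is deterministic per seed with calibrated noise", {
  prof <- data.frame(alpha_x = 0, alpha_y = seq(0, 30, length.out = 40),
                     alpha_z = 0)
  m0 <- synth_mocap(prof, sigma = 0, seed = 3)
  # zero noise reproduces the exact chain kinematics
  ap_end <- pose_plates(chain_coordinates(0, 30, 0))
  expect_vec_equal(m0$LAL41[40, ],
                   as.numeric(frame_transform(ap_end, c(0.01, 0.05, 0))),
                   1e-10)
  # fixed seed: bit-identical repeat
  m1 <- synth_mocap(prof, sigma = 1e-3, seed = 7)
  m2 <- synth_mocap(prof, sigma = 1e-3, seed = 7)
  expect_identical(m1$LAL41, m2$LAL41)
  # noise RMS close to sigma at large n
  prof_big <- data.frame(alpha_x = 0, alpha_y = rep(10, 1000), alpha_z = 0)
  mb <- synth_mocap(prof_big, sigma = 2e-3, seed = 11)
  m0b <- synth_mocap(prof_big, sigma = 0, seed = 11)
  rms <- sqrt(mean((mb$LAL41 - m0b$LAL41)^2))
  expect_equal(rms, 2e-3, tolerance = 0.1)
})

test_that("marker trajectories round-trip through CSV", {
  prof <- data.frame(alpha_x = 0, alpha_y = seq(0, 10, length.out = 5),
                     alpha_z = 0)
  mk <- synth_mocap(prof, sigma = 0, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_markers_csv(mk, time = seq(0, 1, length.out = 5), f)
  rd <- read_markers(f)
  expect_equal(rd$LAL41, mk$LAL41, tolerance = 1e-9, ignore_attr = TRUE)
  unlink(f)
})
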