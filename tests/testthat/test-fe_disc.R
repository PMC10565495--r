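test_that("hyperelastic stresses vanish at identity and split cleanly", {
  expect_equal(max(abs(yeoh_stress(diag(3), 0.12e6, 0.03e6, 0.3e6))), 0)
  expect_equal(max(abs(mooney_rivlin_stress(diag(3), 0.18e6, 0.045e6))), 0)
  # pure volumetric deformation leaves only a pressure term
  s <- yeoh_stress(1.04 * diag(3), 0.12e6, 0.03e6, 0.3e6, kappa = 1e8)
  dev <- s - mean(diag(s)) * diag(3)
  expect_lt(max(abs(dev)), 1e-6 * max(abs(s)))
  s2 <- mooney_rivlin_stress(0.97 * diag(3), 0.18e6, 0.045e6, kappa = 1e7)
  expect_lt(max(abs(s2 - mean(diag(s2)) * diag(3))), 1e-6 * max(abs(s2)))
})

test_that("Cauchy stress matches the finite-difference energy derivative", {
  set.seed(42)
  mats <- list(list(type = "yeoh", c = c(0.12e6, 0.03e6, 0.3e6),
                    kappa = 1e8),
               list(type = "mooney", c10 = 0.18e6, c01 = 0.045e6,
                    kappa = 2e7))
  for (mat in mats) {
    for (rep in 1:3) {
      F <- diag(3) + matrix(rnorm(9, sd = 0.04), 3, 3)
      h <- 1e-6
      P_fd <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3) {
        Fp <- F; Fm <- F
        Fp[i, j] <- Fp[i, j] + h; Fm[i, j] <- Fm[i, j] - h
        P_fd[i, j] <- (hyper_energy(Fp, mat) - hyper_energy(Fm, mat)) /
          (2 * h)
      }
      sig_fd <- P_fd %*% t(F) / det(F)
      sig <- if (mat$type == "yeoh")
        yeoh_stress(F, mat$c[1], mat$c[2], mat$c[3], mat$kappa) else
        mooney_rivlin_stress(F, mat$c10, mat$c01, mat$kappa)
      expect_lt(max(abs(sig - sig_fd)) / max(abs(sig)), 1e-6)
    }
  }
})

test_that("Mooney-Rivlin uniaxial incompressible stretch matches closed form", {
  c10 <- 0.18e6; c01 <- 0.045e6
  for (lam in c(0.9, 1.05, 1.2)) {
    F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    s <- mooney_rivlin_stress(F, c10, c01, kappa = 5e7)
    closed <- 2 * (lam^2 - 1 / lam) * (c10 + c01 / lam)
    expect_equal(s[1, 1] - s[2, 2], closed, tolerance = 1e-9)
  }
})

test_that("strain energy is convex around the identity on sampled stretches", {
  mat <- list(type = "mooney", c10 = 0.18e6, c01 = 0.045e6, kappa = 2e7)
  lams <- seq(0.96, 1.04, length.out = 9)
  W <- vapply(lams, function(l) hyper_energy(diag(c(l, 1, 1 / l)), mat),
              numeric(1))
  d2 <- diff(diff(W))
  expect_true(all(d2 > 0))
  expect_equal(which.min(W), 5L)  # minimum at the identity
})

test_that("inverted deformation states are rejected with element identity", {
  expect_error(yeoh_stress(diag(c(-1, 1, 1)), 1e5), "det\\(F\\)")
  d <- get_disc()
  expect_error(
    assemble_disc_response(d, new_frame(),
                           new_frame(c(0, 0, -0.012)), want_stress = FALSE),
    "element")
})

test_that("fiber force is tension-only and interpolates the config curve", {
  crv <- default_fiber_curve()
  expect_equal(fiber_force(-0.05, crv), 0)
  expect_equal(fiber_force(0, crv), 0)
  # knots are reproduced exactly (the interpolant passes through them)
  for (k in 2:nrow(crv))
    expect_equal(unname(fiber_force(crv[k, 1], crv)),
                 unname(crv[k, 2]), tolerance = 1e-12)
  # monotone between knots
  ss <- seq(0, 0.4, by = 0.002)
  expect_true(all(diff(fiber_force(ss, crv)) >= -1e-12))
})

test_that("disc response is frame-indifferent and obeys Newton's third law", {
  d <- get_disc()
  r0 <- assemble_disc_response(d, want_stress = FALSE)
  expect_lt(max(abs(r0$f_nodal)), 1e-8)
  # rigid translation of both vertebrae
  sh <- c(0.013, -0.007, 0.021)
  r1 <- assemble_disc_response(d, new_frame(sh),
                               new_frame(c(0, 0, 0.011) + sh),
                               want_stress = FALSE)
  expect_lt(max(abs(r1$f_nodal)), 1e-7)
  # rigid rotation of the whole disc about an arbitrary point
  R <- rot_y(17) %*% rot_x(9)
  p0 <- c(0.05, 0.02, -0.01)
  mv <- function(f) new_frame(p0 + as.numeric(R %*% (f$origin - p0)),
                              R %*% f$R)
  r2 <- assemble_disc_response(d, mv(new_frame()),
                               mv(new_frame(c(0, 0, 0.011))),
                               want_stress = FALSE)
  expect_lt(max(abs(r2$f_nodal)), 1e-6)
  # loaded: wrenches on the two vertebrae are equal and opposite
  r3 <- assemble_disc_response(d, new_frame(),
                               new_frame(c(0.001, 0, 0.0102), rot_y(3)))
  expect_vec_equal(r3$wrench_lower$force + r3$wrench_upper$force,
                   c(0, 0, 0), tol = 1e-6)
  # total moment about a common point vanishes
  tq_low <- r3$wrench_lower$torque
  tq_up <- r3$wrench_upper$torque +
    cross3(c(0.001, 0, 0.0102), r3$wrench_upper$force)
  expect_vec_equal(tq_low + tq_up, c(0, 0, 0), tol = 1e-6)
})

test_that("axial compression of a single bound element matches the confined closed form", {
  # one-element disc built by hand: unit-square cross-section, all nodes
  # bound, uniform F = diag(1, 1, lambda)
  X0 <- as.matrix(expand.grid(x = c(0, 0.01), y = c(0, 0.01),
                              z = c(0, 0.01)))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  mat <- list(type = "yeoh", c = c(0.12e6, 0.03e6, 0.3e6), kappa = 1e7)
  disc <- structure(list(
    X0 = X0, elem = matrix(1:8, 1), region = "nucleus",
    caudal = 1:4, cranial = 5:8,
    local_caudal = X0[1:4, ], local_cranial = sweep(X0[5:8, ], 2,
                                                    c(0, 0, 0.01)),
    n_layers = 1L, nodes_per_layer = 4L,
    materials = list(nucleus = mat,
                     annulus = list(type = "mooney", c10 = 1, c01 = 1,
                                    kappa = 1)),
    pre = disc_precompute(X0, matrix(1:8, 1)),
    fibers = list(i = integer(0), j = integer(0), L0 = numeric(0),
                  curve = default_fiber_curve(), weight = numeric(0)),
    lower0 = new_frame(), upper0 = new_frame(c(0, 0, 0.01))),
    class = "ls_disc")
  lam <- 0.95
  r <- assemble_disc_response(disc, new_frame(),
                              new_frame(c(0, 0, 0.01 * lam)))
  sig <- yeoh_stress(diag(c(1, 1, lam)), mat$c[1], mat$c[2], mat$c[3],
                     mat$kappa)
  F_analytic <- sig[3, 3] * 0.01^2       # Cauchy stress x current area
  expect_equal(r$wrench_upper$force[3], -F_analytic,
               tolerance = 0.05 * abs(F_analytic))
})

test_that("IDP equals pressure for hydrostatic fields and hand-computed means", {
  d <- get_disc()
  ne <- nrow(d$elem)
  # uniform hydrostatic sigma = -p I over all elements
  p <- 0.73e6
  S <- matrix(0, ne, 9)
  S[, c(1, 5, 9)] <- -p
  expect_equal(compute_idp(d, S), p / 1e6, tolerance = 1e-12)
  expect_equal(compute_idp(d, S * 0), 0)
  # mixed field on a synthetic two-element fixture, volume-weighted
  fx <- list(region = c("nucleus", "nucleus"),
             elem = rbind(1:8, c(5:8, 9:12)),
             pre = list(elem_vol = c(2, 1)))
  class(fx) <- "ls_disc"
  S2 <- matrix(0, 2, 9)
  S2[1, c(1, 5, 9)] <- -1e6        # 1 MPa
  S2[2, c(1, 5, 9)] <- -4e6        # 4 MPa
  # nodes 1:4 see only el1 (1), nodes 5:8 see both (vol-weighted 2 MPa),
  # nodes 9:12 only el2 (4); mean = (4*1 + 4*2 + 4*4)/12
  expect_equal(compute_idp(fx, S2), (4 * 1 + 4 * 2 + 4 * 4) / 12,
               tolerance = 1e-12)
  expect_error(compute_idp(structure(list(region = "annulus"),
                                     class = "ls_disc"), S),
               "nucleus")
})

test_that("nucleus is quasi-incompressible under physiological compression", {
  d <- get_disc(gauss_order = 1L)
  # find the compression carrying ~500 N and check nucleus volume change
  fz <- function(dz) assemble_disc_response(
    d, upper = new_frame(c(0, 0, 0.011 - dz)),
    want_stress = FALSE)$wrench_upper$force[3] - 500
  dz <- uniroot(fz, c(1e-6, 2e-3))$root
  r <- assemble_disc_response(d, upper = new_frame(c(0, 0, 0.011 - dz)))
  nuc <- d$region == "nucleus"
  jn <- sum((r$Jbar * d$pre$elem_vol)[nuc]) / sum(d$pre$elem_vol[nuc])
  expect_lt(abs(1 - jn), 0.01)
})

test_that("disc IDP increases monotonically with compressive load", {
  d <- get_disc(gauss_order = 1L)
  idps <- vapply(seq(0, 8e-4, length.out = 5), function(dz)
    assemble_disc_response(d, upper = new_frame(c(0, 0, 0.011 - dz)))$idp_mpa,
    numeric(1))
  expect_true(all(diff(idps) > 0))
})

test_that("disc tangent is symmetric and consistent with nodal forces", {
  # small hand-built one-element disc keeps the FD tangent cheap
  X0 <- as.matrix(expand.grid(x = c(0, 0.01), y = c(0, 0.01),
                              z = c(0, 0.01)))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  disc <- structure(list(
    X0 = X0, elem = matrix(1:8, 1), region = "annulus",
    caudal = 1:4, cranial = 5:8,
    local_caudal = X0[1:4, ], local_cranial = sweep(X0[5:8, ], 2,
                                                    c(0, 0, 0.01)),
    n_layers = 1L, nodes_per_layer = 4L,
    materials = list(nucleus = list(type = "yeoh", c = c(1, 0, 0),
                                    kappa = 1),
                     annulus = list(type = "mooney", c10 = 0.18e6,
                                    c01 = 0.045e6, kappa = 2e7)),
    pre = disc_precompute(X0, matrix(1:8, 1)),
    fibers = list(i = integer(0), j = integer(0), L0 = numeric(0),
                  curve = default_fiber_curve(), weight = numeric(0)),
    lower0 = new_frame(), upper0 = new_frame(c(0, 0, 0.01))),
    class = "ls_disc")
  r <- assemble_disc_response(disc, new_frame(),
                              new_frame(c(2e-4, 0, 0.0098), rot_y(1)),
                              tangent = TRUE, want_stress = FALSE)
  K <- r$tangent
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-8)
})

test_that("facet contact is unilateral with an energy-consistent penalty", {
  fc <- list(point_upper = c(0, 0, 0.0005), plane_point = c(0, 0, 0),
             normal = c(0, 0, 1), k = 4e5)
  lower <- new_frame(); upper <- new_frame()
  # positive gap: no force
  r <- facet_force(fc, lower, upper)
  expect_equal(r$gap, 0.0005)
  expect_equal(max(abs(r$force_upper)), 0)
  # penetration delta -> k * delta along the normal
  up2 <- new_frame(c(0, 0, -0.0015))
  r2 <- facet_force(fc, lower, up2)
  expect_equal(r2$gap, -0.001)
  expect_vec_equal(r2$force_upper, c(0, 0, 4e5 * 0.001), tol = 1e-9)
  expect_vec_equal(r2$force_lower, -r2$force_upper, tol = 1e-12)
  # force equals the gradient of the 0.5 k delta^2 penalty energy
  en <- function(dz) {
    g <- min(fc$point_upper[3] + dz, 0)
    0.5 * fc$k * g^2
  }
  h <- 1e-8
  f_fd <- -(en(-0.0015 + h) - en(-0.0015 - h)) / (2 * h)
  expect_equal(r2$force_upper[3], f_fd, tolerance = 1e-4 * abs(f_fd))
})
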