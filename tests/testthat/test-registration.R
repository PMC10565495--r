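lm_df <- function(ids, pos, bone = "vert") {
  data.frame(bone = bone, landmark_id = ids, x = pos[, 1], y = pos[, 2],
             z = pos[, 3])
}

test_that("palpation repeatability is the mean squared distance to the mean", {
  base <- data.frame(bone = "vert", landmark_id = "tip",
                     x = 0, y = 0, z = 0, operator = "a", repetition = 1)
  # identical repeats
  d <- rbind(base, transform(base, repetition = 2))
  expect_equal(palpation_repeatability(d)$msd_m2, 0)
  # two points 2 mm apart: each 1 mm from the mean, MSD = 1e-6 m^2
  d2 <- rbind(base, transform(base, x = 0.002, repetition = 2))
  expect_equal(palpation_repeatability(d2)$msd_m2, 1e-6)
  # a single repetition is reported missing; an outlier inflates only its
  # own landmark
  d3 <- rbind(d2, transform(base, landmark_id = "base"),
              transform(base, landmark_id = "spst"),
              transform(base, landmark_id = "spst", x = 0.02,
                        repetition = 2))
  r <- palpation_repeatability(d3)
  expect_true(is.na(r$msd_m2[r$landmark_id == "base"]))
  expect_equal(r$msd_m2[r$landmark_id == "tip"], 1e-6)
  expect_equal(r$msd_m2[r$landmark_id == "spst"], 1e-4)
})

test_that("affine registration recovers exact transforms and reports residuals", {
  set.seed(11)
  ids <- paste0("lm", 1:8)
  S <- matrix(rnorm(24), 8, 3)
  src <- lm_df(ids, S)
  # identity
  f0 <- affine_fit(src, src)
  expect_vec_equal(f0$A, diag(3), 1e-12)
  expect_vec_equal(f0$t, c(0, 0, 0), 1e-12)
  expect_equal(f0$rms, 0, tolerance = 1e-12)
  # exact synthetic affine recovered to 1e-9
  A <- matrix(c(1.1, 0.2, -0.1, 0, 0.9, 0.05, 0.1, -0.3, 1.2), 3, 3)
  tt <- c(0.01, -0.02, 0.005)
  G <- t(A %*% t(S) + tt)
  f1 <- affine_fit(src, lm_df(ids, G))
  expect_vec_equal(f1$A, A, 1e-9)
  expect_vec_equal(f1$t, tt, 1e-9)
  # noisy correspondences: residual equals the normal-equations oracle
  Gn <- G + matrix(rnorm(24, sd = 1e-3), 8, 3)
  f2 <- affine_fit(src, lm_df(ids, Gn))
  X <- cbind(S, 1)
  beta <- solve(crossprod(X), crossprod(X, Gn))
  res <- X %*% beta - Gn
  expect_equal(f2$rms, sqrt(mean(rowSums(res^2))), tolerance = 1e-10)
  # degenerate (coplanar) source is rejected
  Sp <- cbind(S[, 1:2], 0)
  expect_error(affine_fit(lm_df(ids, Sp), lm_df(ids, G)), "degenerate")
  # residuals grow monotonically with injected noise
  rmss <- vapply(c(1e-4, 1e-3, 1e-2), function(sg) {
    set.seed(5)
    affine_fit(src, lm_df(ids, G + matrix(rnorm(24, sd = sg), 8, 3)))$rms
  }, numeric(1))
  expect_true(all(diff(rmss) > 0))
})

test_that("surface projection moves non-via points to the nearest surface point", {
  box <- mesh_box(half = c(0.05, 0.05, 0.05))
  # point already on the surface is unchanged
  on <- matrix(c(0.05, 0.01, 0.02), 1)
  pr <- project_to_surface(on, box)
  expect_vec_equal(pr$points, on, 1e-12)
  expect_equal(pr$displacement, 0)
  # via points are untouched
  off <- matrix(c(0.2, 0, 0), 1)
  pr2 <- project_to_surface(off, box, via_flags = TRUE)
  expect_vec_equal(pr2$points, off, 1e-12)
  # projection lands at the closest face with the right distance
  pr3 <- project_to_surface(off, box)
  expect_vec_equal(pr3$points, c(0.05, 0, 0), 1e-12)
  expect_equal(pr3$displacement, 0.15)
  # a point at the center of a sphere projects to radius r
  sph <- mesh_ellipsoid(radii = c(0.03, 0.03, 0.03), n = 16)
  prc <- project_to_surface(matrix(0, 1, 3), sph)
  expect_equal(prc$displacement, 0.03, tolerance = 0.02)
  expect_error(project_to_surface(off, new_mesh(matrix(0, 0, 3),
                                                matrix(0L, 0, 3))),
               "empty")
})

test_that("muscle registration transfers point sets bone-by-bone", {
  set.seed(3)
  ids <- paste0("lm", 1:6)
  Sv <- matrix(rnorm(18, sd = 0.03), 6, 3)
  Sp <- matrix(rnorm(18, sd = 0.05), 6, 3)
  muscles <- data.frame(
    bone = c("vert", "vert", "pelvis"),
    fascicle = c("f1", "f1", "f2"), ord = c(1, 2, 1),
    x = c(0.01, 0.02, 0), y = c(0, 0.01, 0.02), z = c(0, 0.005, 0.01),
    via = c(FALSE, TRUE, FALSE))
  reference <- list(landmarks = rbind(lm_df(ids, Sv, "vert"),
                                      lm_df(ids, Sp, "pelvis")),
                    muscles = muscles)
  # target equal to the reference: identity round trip
  tgt_same <- list(landmarks = reference$landmarks, meshes = NULL)
  out <- register_muscles(reference, tgt_same)
  m0 <- out$muscles[order(out$muscles$fascicle, out$muscles$ord), ]
  mref <- muscles[order(muscles$fascicle, muscles$ord), ]
  expect_vec_equal(as.matrix(m0[, c("x", "y", "z")]),
                   as.matrix(mref[, c("x", "y", "z")]), 1e-10)
  # uniformly scaled target: registered points match the scaled originals
  sc <- 1.1
  tgt_scaled <- list(landmarks = rbind(lm_df(ids, Sv * sc, "vert"),
                                       lm_df(ids, Sp * sc, "pelvis")))
  out2 <- register_muscles(reference, tgt_scaled)
  m2 <- out2$muscles[order(out2$muscles$fascicle, out2$muscles$ord), ]
  expect_vec_equal(as.matrix(m2[, c("x", "y", "z")]),
                   sc * as.matrix(mref[, c("x", "y", "z")]), 1e-9)
  # fascicle ordering preserved
  expect_equal(m2$ord[m2$fascicle == "f1"], c(1, 2))
  # missing bone correspondence is skipped with a warning
  ref_extra <- reference
  ref_extra$muscles <- rbind(reference$muscles,
                             data.frame(bone = "rib", fascicle = "f3",
                                        ord = 1, x = 0, y = 0, z = 0,
                                        via = FALSE))
  expect_warning(out3 <- register_muscles(ref_extra, tgt_scaled),
                 "rib")
  expect_equal(out3$skipped, "rib")
})

test_that("registration QA flags bone-piercing path segments", {
  box <- mesh_box(half = c(0.02, 0.02, 0.02))
  expect_true(segment_pierces_mesh(c(-0.1, 0, 0), c(0.1, 0, 0), box))
  expect_false(segment_pierces_mesh(c(-0.1, 0.05, 0), c(0.1, 0.05, 0), box))
  reg <- list(muscles = data.frame(
    bone = "vert", fascicle = "f1", ord = c(1, 2),
    x = c(-0.1, 0.1), y = 0, z = 0, via = FALSE),
    qa = list(vert = list(affine_rms = 0, displacement = c(0, 0))))
  qa <- registration_qa(reg, meshes = list(vert = box))
  expect_equal(nrow(qa$piercing), 1)
})

test_that("mesh I/O round-trips OBJ files", {
  box <- mesh_box(half = c(0.05, 0.04, 0.03))
  f <- tempfile(fileext = ".obj")
  write_obj(box, f)
  rd <- read_mesh(f)
  expect_equal(rd$vertices, box$vertices, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rd$faces, box$faces, ignore_attr = TRUE)
  unlink(f)
})
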