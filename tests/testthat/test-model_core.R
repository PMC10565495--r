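test_that("the synthetic spine reproduces the configured lordosis and inventory", {
  m <- get_model()
  expect_equal(model_lordosis(m), 47.5, tolerance = 0.5 / 47.5)
  expect_equal(length(m$discs), 5L)
  expect_equal(length(m$facets), 10L)
  # fascicle inventory: 129 per side, 258 total, counts per group
  tab <- table(m$muscles$fasc$group, m$muscles$fasc$side)
  expect_equal(sum(m$muscles$fasc$side == "R"), 129L)
  expect_equal(nrow(m$muscles$fasc), 258L)
  inv <- muscle_group_table()
  for (g in inv$group) {
    expect_equal(unname(tab[g, "R"]), inv$fascicles[inv$group == g])
    expect_equal(unname(tab[g, "L"]), inv$fascicles[inv$group == g])
  }
  expect_equal(sum(m$muscles$fasc$side == "R" &
                     m$muscles$fasc$group != "TA"), 119L)
})

test_that("zero lordosis with equal spacing stacks vertebral centers collinearly", {
  cfg <- default_spine_config(lordosis = 0)
  cfg$sacral_slope <- 0
  cfg$wedge_fractions <- rep(0.2, 5)
  m <- build_synthetic_lss(cfg)
  ctrs <- t(vapply(m$vertebrae, function(v) v$center$origin, numeric(3)))
  expect_lt(max(abs(ctrs[, 1])), 1e-12)     # all on the global z axis
  expect_lt(max(abs(ctrs[, 2])), 1e-12)
  expect_true(all(diff(ctrs[, 3]) > 0))
  expect_equal(model_lordosis(m), 0, tolerance = 1e-10)
})

test_that("invalid configurations are rejected naming the offending field", {
  cfg <- default_spine_config()
  cfg$disc_height <- -0.01
  expect_error(build_synthetic_lss(cfg), "disc_height")
  cfg2 <- default_spine_config()
  cfg2$wedge_fractions <- cfg2$wedge_fractions[1:4]
  expect_error(build_synthetic_lss(cfg2), "wedge_fractions")
  cfg3 <- default_spine_config()
  cfg3$disc$r_nucleus <- 0.03           # larger than the outer radius
  expect_error(build_synthetic_lss(cfg3), "disc radii")
})

test_that("lumped segment parameters conserve mass and combine COMs", {
  # a single 10 kg cranial segment is carried entirely by the thorax
  t1 <- data.frame(segment = "T7", mass = 10, x = 0.01, y = 0, z = 0.3)
  p1 <- lumped_segment_parameters(t1)
  expect_equal(p1$thorax$mass, 10)
  expect_vec_equal(p1$thorax$com, c(0.01, 0, 0.3), 1e-12)
  # two segments combine at the mass-weighted mean position
  t2 <- data.frame(segment = c("head", "T7"), mass = c(4, 6),
                   x = c(0, 0.02), y = 0, z = c(0.5, 0.3))
  p2 <- lumped_segment_parameters(t2)
  expect_equal(p2$thorax$mass, 10)
  expect_vec_equal(p2$thorax$com,
                   (4 * c(0, 0, 0.5) + 6 * c(0.02, 0, 0.3)) / 10, 1e-12)
  # full table conserves total mass, lumbar levels kept separate
  t3 <- rbind(t2, data.frame(segment = c("L1", "L2"), mass = c(2, 2.5),
                             x = 0, y = 0, z = c(0.2, 0.16)))
  p3 <- lumped_segment_parameters(t3)
  expect_equal(p3$thorax$mass + p3$L1$mass + p3$L2$mass, sum(t3$mass))
  expect_error(lumped_segment_parameters(
    data.frame(segment = "T7", mass = -1, x = 0, y = 0, z = 0)), "mass")
})

test_that("sagittal mirroring is an involution and maps points correctly", {
  m <- get_model()
  f <- m$muscles$fasc
  pts <- m$muscles$pts
  # every right fascicle has a left twin with identical parameters
  rids <- f$id[f$side == "R"]
  lids <- sub("_R$", "_L", rids)
  expect_true(all(lids %in% f$id))
  expect_equal(f$pcsa[match(rids, f$id)], f$pcsa[match(lids, f$id)])
  expect_equal(f$f0[match(rids, f$id)], f$f0[match(lids, f$id)])
  # mirrored points have negated y
  for (id in rids[c(1, 50, 129)]) {
    pr <- pts[pts$fascicle == id, ]
    plft <- pts[pts$fascicle == sub("_R$", "_L", id), ]
    expect_vec_equal(plft$y[order(plft$ord)], -pr$y[order(pr$ord)], 1e-12)
    expect_vec_equal(plft$x[order(plft$ord)], pr$x[order(pr$ord)], 1e-12)
  }
  # a point on the mid-sagittal plane maps to itself
  expect_vec_equal(mirror_points_sagittal(matrix(c(0.1, 0, 0.2), 1)),
                   c(0.1, 0, 0.2), 1e-15)
  # mirroring twice returns an identical muscle set
  m2 <- mirror_sagittal(mirror_sagittal(m))
  expect_equal(m2$muscles$fasc$id, m$muscles$fasc$id)
  expect_equal(as.matrix(m2$muscles$pts[, c("x", "y", "z")]),
               as.matrix(m$muscles$pts[, c("x", "y", "z")]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("build is deterministic and conserves mass through assembly", {
  ma <- build_synthetic_lss()
  mb <- build_synthetic_lss()
  expect_identical(ma$muscles$fasc$f0, mb$muscles$fasc$f0)
  expect_identical(vapply(ma$vertebrae, function(v) v$center$origin[3],
                          numeric(1)),
                   vapply(mb$vertebrae, function(v) v$center$origin[3],
                          numeric(1)))
  # total mass equals the configured body mass before and after mirroring
  tot <- sum(vapply(ma$bodies, `[[`, 0, "mass")) - ma$bodies$ap_iap$mass
  expect_equal(tot, ma$config$body_mass, tolerance = 1e-9)
})

test_that("segment angles report thorax rotation and IVRs consistently", {
  m <- get_model()
  s <- neutral_state(m)
  ang0 <- measure_angles(m, s)
  expect_vec_equal(ang0$alpha, c(0, 0, 0), 1e-12)
  expect_vec_equal(ang0$ivr, rep(0, 5), 1e-12)
  # impose a pure 10 deg sagittal rotation of thorax+L1 about its center
  s2 <- s
  f0 <- m$bodies$thorax$frame0
  s2$frames$thorax <- new_frame(f0$origin, rot_y(10) %*% f0$R)
  ang2 <- measure_angles(m, s2)
  expect_equal(unname(ang2$alpha["y"]), 10, tolerance = 1e-9)
  expect_equal(unname(ang2$ivr["L1L2"]), 10, tolerance = 1e-9)
  expect_equal(unname(ang2$ivr["L2L3"]), 0, tolerance = 1e-12)
  # sagittal IVRs sum to the total lumbar rotation
  s3 <- s2
  for (b in c("L2", "L3", "L4", "L5")) {
    fb <- m$bodies[[b]]$frame0
    s3$frames[[b]] <- new_frame(fb$origin, rot_y(2) %*% fb$R)
  }
  ang3 <- measure_angles(m, s3)
  expect_equal(sum(ang3$ivr), unname(ang3$rotation["L1"]),
               tolerance = 1e-9)
})

test_that("model dump and restore round-trips through JSON", {
  m <- get_model()
  f <- tempfile(fileext = ".json")
  model_to_json(m, f)
  m2 <- model_from_json(f)
  expect_equal(model_lordosis(m2), model_lordosis(m), tolerance = 1e-9)
  expect_equal(nrow(m2$muscles$fasc), nrow(m$muscles$fasc))
  expect_equal(m2$muscles$fasc$f0, m$muscles$fasc$f0, tolerance = 1e-9)
  unlink(f)
})

test_that("YAML configurations override defaults field-wise", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("lordosis: 40.0", "body_mass: 75"), f)
  cfg <- read_spine_config(f)
  expect_equal(cfg$lordosis, 40)
  expect_equal(cfg$body_mass, 75)
  expect_equal(cfg$disc$r_outer, default_spine_config()$disc$r_outer)
  m <- build_synthetic_lss(cfg)
  expect_equal(model_lordosis(m), 40, tolerance = 0.5 / 40)
  unlink(f)
})
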