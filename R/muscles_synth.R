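#' Synthetic trunk musculature
#'
#' Generates the right-side muscle fascicles of the 12 trunk muscle groups
#' on the synthetic skeleton (counts per group from the shipped inventory
#' table), then mirrors them to the left side. Attachment coordinates are
#' parametric archetypes of the anatomical courses; they are synthetic
#' stand-ins, not digitized anatomy.
#'
#' @name synthetic-muscles
NULL

muscle_group_table <- function() {
  path <- system.file("extdata", "muscle_groups.csv", package = "lumbosim")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# linear deterministic spread in [-h, h]
spread <- function(i, n, h) if (n == 1L) 0 else -h + 2 * h * (i - 1) / (n - 1)

add_synthetic_muscles <- function(model) {
  cfg <- model$config
  verts <- model$vertebrae
  tab <- muscle_group_table()
  nlev <- cfg$n_lumbar
  vnames <- paste0("L", seq_len(nlev))
  pts <- list(); fasc <- list()
  thorax_f0 <- model$bodies$thorax$frame0
  vert_global <- function(v, local) {
    as.numeric(frame_transform(verts[[v]]$center, local))
  }
  add_f <- function(group, i, plist, wrapL = FALSE, wrapT = FALSE) {
    id <- sprintf("%s%02d_R", group, i)
    for (k in seq_along(plist)) {
      p <- plist[[k]]
      owner <- p$owner
      loc <- if (owner == "AP") p$p else
        point_in_body(p$p, model$bodies[[owner]]$frame0)
      pts[[length(pts) + 1L]] <<- data.frame(
        fascicle = id, ord = k, owner = owner,
        x = loc[1], y = loc[2], z = loc[3],
        via = isTRUE(p$via))
    }
    fasc[[length(fasc) + 1L]] <<- data.frame(
      id = id, group = group, side = "R",
      wrap_lumbar = wrapL, wrap_thoracic = wrapT,
      pcsa = tab$pcsa_total_cm2[tab$group == group] /
        tab$fascicles[tab$group == group])
  }
  th_pt <- function(local) list(owner = "thorax",
                                p = as.numeric(frame_transform(thorax_f0,
                                                               local)))
  vert_pt <- function(v, local)
    list(owner = model$vert_owner[[v]], p = vert_global(v, local))
  sac_pt <- function(p) list(owner = "sacrum", p = p)
  plate_pt <- function(local, dynamic = TRUE, via = FALSE)
    if (dynamic) list(owner = "ap_iap",
                      p = as.numeric(frame_transform(model$ap0, local)))
    else list(owner = "AP", p = local, via = via)

  # QL: iliac crest to L1-L4 transverse processes and 12th rib
  targets <- c(vnames[seq_len(min(4L, nlev))], "rib12")
  for (i in 1:18) {
    tg <- targets[((i - 1L) %% length(targets)) + 1L]
    orig <- sac_pt(c(-0.028 + spread(i, 18, 0.012), -0.055 - spread(i, 18, 0.015),
                     -0.030))
    ins <- if (tg == "rib12") th_pt(c(-0.005, -0.075, 0.055)) else
      vert_pt(tg, c(-0.005, -0.036, 0))
    add_f("QL", i, list(orig, ins))
  }
  # PM: vertebral bodies to the pelvis, redirected at the pelvic brim
  for (i in 1:11) {
    lv <- vnames[((i - 1L) %% nlev) + 1L]
    orig <- vert_pt(lv, c(0.012, -0.028, spread(i, 11, 0.008)))
    via <- sac_pt(c(0.045, -0.05, -0.075)); via$via <- TRUE
    ins <- sac_pt(c(0.02, -0.06, -0.13))
    add_f("PM", i, list(orig, via, ins))
  }
  # MF: sacrum / vertebra origins to spinous processes 2-3 levels cranial
  for (i in 1:25) {
    lower <- c("S1", "S1", "L5", "L4", "L3")[((i - 1L) %% 5L) + 1L]
    span <- 2L + (i %% 2L)
    orig <- if (lower == "S1")
      sac_pt(c(-0.052 - spread(i, 25, 0.008), -0.012 - spread(i, 25, 0.01),
               -0.025 - spread(i, 25, 0.02))) else
      vert_pt(lower, c(-0.040, -0.012, 0))
    lower_idx <- if (lower == "S1") nlev + 1L else
      as.integer(sub("L", "", lower))
    up_idx <- max(1L, lower_idx - span)
    ins <- vert_pt(vnames[up_idx], c(-0.046, -0.004, 0))
    add_f("MF", i, list(orig, ins), wrapL = (i == 1L))
  }
  # IT: ilium to upper thoracic ribs, wrapped on the lumbar body
  for (i in 1:8) {
    orig <- sac_pt(c(-0.050, -0.042 - spread(i, 8, 0.008), -0.035))
    ins <- th_pt(c(-0.050, -0.052 - spread(i, 8, 0.012), 0.21))
    add_f("IT", i, list(orig, ins), wrapL = (i <= 7L))
  }
  # IL: ilium to the caudal ribs
  for (i in 1:4) {
    orig <- sac_pt(c(-0.048, -0.050 - spread(i, 4, 0.006), -0.038))
    ins <- th_pt(c(-0.040, -0.068 - spread(i, 4, 0.008), 0.11))
    add_f("IL", i, list(orig, ins), wrapL = TRUE)
  }
  # LT: sacrum/spinous origins to the posterior thorax
  for (i in 1:21) {
    orig <- sac_pt(c(-0.054, -0.016 - spread(i, 21, 0.012),
                     -0.030 - spread(i, 21, 0.015)))
    ins <- th_pt(c(-0.054, -0.030 - spread(i, 21, 0.02),
                   0.12 + 0.12 * (i - 1) / 20))
    add_f("LT", i, list(orig, ins), wrapL = (i <= 2L),
          wrapT = (i > 16L))
  }
  # LL: sacrum to lumbar accessory processes
  for (i in 1:5) {
    orig <- sac_pt(c(-0.052, -0.020 - spread(i, 5, 0.006), -0.035))
    ins <- vert_pt(vnames[i], c(-0.030, -0.024, 0))
    add_f("LL", i, list(orig, ins), wrapL = (i == 5L))
  }
  # RA: pubis to sternum, redirected via the kinematic abdominal plate
  add_f("RA", 1, list(sac_pt(c(0.055, -0.030, -0.100)),
                      plate_pt(c(0.004, -0.030, -0.01), dynamic = FALSE,
                               via = TRUE),
                      th_pt(c(0.095, -0.030, 0.13))))
  # IO: iliac crest to the dynamic abdominal plate
  for (i in 1:6) {
    orig <- sac_pt(c(-0.005, -0.075, -0.030 - spread(i, 6, 0.01)))
    ins <- plate_pt(c(0, -0.020 - spread(i, 6, 0.012),
                      -0.035 + 0.012 * (i - 1)))
    add_f("IO", i, list(orig, ins))
  }
  # EO: caudal ribs to the dynamic abdominal plate
  for (i in 1:6) {
    orig <- th_pt(c(0.010, -0.092, 0.045 + spread(i, 6, 0.02)))
    ins <- plate_pt(c(0, -0.022 - spread(i, 6, 0.014),
                      0.010 + 0.008 * (i - 1)))
    add_f("EO", i, list(orig, ins))
  }
  # LD: spinous/iliac origins over the thoracic wrapping body to the humerus
  for (i in 1:14) {
    orig <- if (i <= 5L) vert_pt(vnames[i], c(-0.047, -0.003, 0)) else
      if (i <= 8L) sac_pt(c(-0.055, -0.012 - spread(i - 5, 3, 0.01), -0.03))
      else th_pt(c(-0.058, -0.004, 0.02 + 0.02 * (i - 9L)))
    ins <- th_pt(c(0.00, -0.165, 0.26))
    add_f("LD", i, list(orig, ins), wrapL = (i %in% 6:8), wrapT = TRUE)
  }
  # TA: transverse belts from the vertebrae to the dynamic plate
  for (i in 1:10) {
    lv <- vnames[((i - 1L) %% nlev) + 1L]
    orig <- vert_pt(lv, c(-0.005, -0.038, 0))
    belt <- vert_pt(lv, c(0.012, -0.105, 0)); belt$via <- TRUE
    ins <- plate_pt(c(0, -0.012 - 0.004 * (i - 1),
                      0.045 - 0.010 * (i - 1)))
    add_f("TA", i, list(orig, belt, ins))
  }
  model$muscles <- list(pts = do.call(rbind, pts),
                        fasc = do.call(rbind, fasc),
                        group_names = NULL)
  mirror_sagittal(model)
}

# Build per-fascicle Hill parameters from the neutral-pose path lengths and
# cache vectorized force-model columns.
finalize_muscles <- function(model) {
  m <- model$muscles
  groups <- unique(m$fasc$group)
  m$group_names <- as.vector(outer(groups, c("R", "L"), paste, sep = "_"))
  m$fasc$group_side <- paste(m$fasc$group, m$fasc$side, sep = "_")
  model$muscles <- m
  state <- neutral_state(model)
  geo <- muscle_geometry(model, state)
  mus <- model$config$muscles
  lmt0 <- geo$lmt[m$fasc$id]
  l_opt <- mus$fiber_fraction * lmt0
  m$fasc$lmt0 <- lmt0
  m$fasc$l_opt <- l_opt
  m$fasc$pennation <- ifelse(m$fasc$group == "MF", 14, 0)
  m$fasc$tendon_slack <- pmax(lmt0 - l_opt *
                                cos(deg2rad(m$fasc$pennation)), 0)
  m$fasc$f0 <- m$fasc$pcsa * mus$k_spec *
    (model$config$body_mass / mus$b_ref)   # lmt_ref = lmt0 for the synthetic build
  m$fasc$vmax <- mus$vmax
  m$fasc$damping <- mus$damping
  model$muscles <- m
  model$muscles$plate_plan <- make_plate_plan(model)
  model
}
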