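#' Default configuration of the synthetic parametric lumbosacral spine
#'
#' All geometric, inertial, material and muscle parameters of the bundled
#' synthetic spine. Values are plausible mid-size-male defaults chosen for
#' the synthetic anatomy (see the methods vignette); they are configuration
#' inputs, not measurements.
#'
#' @param body_mass total body mass b (kg).
#' @param lordosis target L1-S1 superior-endplate lordosis (deg).
#' @param sacral_slope sacral slope of the S1 superior endplate (deg).
#' @return nested configuration list understood by [build_synthetic_lss()].
#' @export
default_spine_config <- function(body_mass = 90, lordosis = 47.5,
                                 sacral_slope = 36.3) {
  list(
    n_lumbar = 5L,
    body_mass = body_mass,
    lordosis = lordosis,
    sacral_slope = sacral_slope,
    pelvic_incidence = 45.36, pelvic_tilt = 9.06,
    vertebra_height = 0.028,
    disc_height = 0.011,
    # caudally increasing share of the lordotic wedge per disc (L1/L2 first)
    wedge_fractions = c(0.12, 0.17, 0.20, 0.24, 0.27),
    disc = list(r_nucleus = 0.012, r_outer = 0.021, n_layers = 1L,
                gauss_order = 1L,
                materials = list(
                  nucleus = list(type = "yeoh",
                                 c = c(0.12e6, 0.03e6, 0.30e6), kappa = 2e8),
                  annulus = list(type = "mooney", c10 = 0.18e6,
                                 c01 = 0.045e6, kappa = 6e6))),
    masses = list(thorax = 0.40 * body_mass,       # all mass cranial to L1
                  vertebra = c(1.6, 1.7, 1.8, 1.9, 2.0)),
    com_ub = c(0.02, 0, 0.20),          # COM_UB relative to L1 center
    thorax_inertia = diag(c(1.2, 1.0, 0.6)),
    vertebra_inertia = diag(c(2e-4, 2e-4, 3e-4)),
    facet = list(k = 4e5, gap = 0.0015, x = -0.035, y = 0.020),
    ligaments = list(pretension = 0.01,
                     shape = cbind(strain = c(0, 0.05, 0.10, 0.20, 0.40),
                                   force = c(0, 5, 20, 80, 250)),
                     types = c(ALL = 1.0, PLL = 0.5, LF = 0.8, ISL = 0.4,
                               SSL = 0.6),
                     x = c(ALL = 0.022, PLL = -0.022, LF = -0.035,
                           ISL = -0.050, SSL = -0.062)),
    muscles = list(k_spec = 100, b_ref = 90, fiber_fraction = 0.5,
                   vmax = 10, damping = 0.01),
    gravity = c(0, 0, -9.81),
    resting_tone = 0.001,
    cavity = default_cavity(),
    chain = default_chain_config(),
    spring = list(k_normal = 90e3, k_shear = 1e6, k_rot = 500),
    wraps = list(
      lumbar = list(center = c(-0.13935 + 0.085, 0, 0.1057), radius = 0.085,
                    length = 0.3, axis = c(0, 1, 0),
                    joint_center = c(-0.02, 0, 0.0345)),
      thoracic_L = list(center = c(0.04287, 0.02059, 0.2788),
                        radii = c(0.1, 0.14, 0.21) / 2,
                        rot = c(rx = -4.5, ry = -9.4, rz = 36.4)),
      thoracic_R = list(center = c(0.04287, -0.02059, 0.2788),
                        radii = c(0.1, 0.14, 0.21) / 2,
                        rot = c(rx = 4.5, ry = -9.4, rz = -36.4))),
    controller = list(w_thorax = 15, w_vertebra = 1, w_excitation = 0.667,
                      w_rate = 0.3e-4,
                      cor = c(-0.015, 0, 0.1),
                      ramp_duration = 2, max_step_deg = 5),
    load = list(shoulder_z = 0.30, t7_z = 0.20, sternum = c(0.10, 0, 0.22))
  )
}

#' Validate a spine configuration
#' @param config configuration list.
#' @keywords internal
validate_spine_config <- function(config) {
  chk <- function(ok, field)
    if (!ok) stop("invalid config field: ", field, call. = FALSE)
  chk(config$n_lumbar >= 1, "n_lumbar")
  chk(config$vertebra_height > 0, "vertebra_height")
  chk(config$disc_height > 0, "disc_height")
  chk(length(config$wedge_fractions) == config$n_lumbar, "wedge_fractions")
  chk(abs(sum(config$wedge_fractions) - 1) < 1e-9, "wedge_fractions")
  chk(config$body_mass > 0, "body_mass")
  chk(all(unlist(config$masses) > 0), "masses")
  chk(config$disc$r_nucleus > 0 &&
        config$disc$r_outer > config$disc$r_nucleus, "disc radii")
  invisible(TRUE)
}

#' Lumped upper-body segment parameters
#'
#' Combines a per-level mass table into the model's rigid segments: every
#' entry cranial to L1 is concentrated at the upper-body center of mass
#' COM_UB carried by the thorax. Total mass is conserved; combined COM is
#' the mass-weighted mean and inertias are combined with the parallel-axis
#' theorem.
#'
#' @param mass_table data frame with columns `segment` (e.g. "head", "T7",
#'   "L3"), `mass` (kg), `x, y, z` (COM, m) and optionally `ixx, iyy, izz`.
#' @return list with `thorax` (mass, com, inertia) and one entry per lumbar
#'   vertebra present in the table.
#' @export
lumped_segment_parameters <- function(mass_table) {
  if (sum(mass_table$mass) <= 0) stop("total mass must be positive")
  lumbar <- grepl("^L[1-5]$", mass_table$segment)
  combine <- function(d) {
    m <- sum(d$mass)
    com <- colSums(d$mass * as.matrix(d[, c("x", "y", "z")])) / m
    inert <- diag(3) * 0
    for (i in seq_len(nrow(d))) {
      I0 <- if (all(c("ixx", "iyy", "izz") %in% names(d)))
        diag(c(d$ixx[i], d$iyy[i], d$izz[i])) else diag(3) * 0
      r <- as.numeric(d[i, c("x", "y", "z")]) - com
      inert <- inert + I0 + d$mass[i] * (sum(r^2) * diag(3) - r %o% r)
    }
    list(mass = m, com = as.numeric(com), inertia = inert)
  }
  out <- list(thorax = combine(mass_table[!lumbar, , drop = FALSE]))
  for (lv in mass_table$segment[lumbar])
    out[[lv]] <- combine(mass_table[mass_table$segment == lv, ,
                                    drop = FALSE])
  out
}

endplate_advance <- function(f, height, wedge_deg) {
  # advance a frame through a wedge-shaped slab (extension sense about +y)
  Rmid <- f$R %*% rot_y(-wedge_deg / 2)
  new_frame(f$origin + as.numeric(Rmid %*% c(0, 0, height)),
            f$R %*% rot_y(-wedge_deg))
}

#' Build the synthetic parametric lumbosacral spine model
#'
#' Assembles the full mechanism from a configuration list: rigid sacrum
#' (with pelvis) fixed in space, five lumbar vertebrae and the lumped
#' thorax (rigid with L1) as dynamic bodies, fiber-reinforced FE discs at
#' every level, pre-tensioned ligaments, unilateral facet contacts, the
#' mirrored Hill-type trunk musculature, the abdominal plate pair, and the
#' muscle wrapping bodies. The model is mirror-symmetric about the
#' mid-sagittal plane y = 0 and its L1-S1 endplate lordosis matches the
#' configured value.
#'
#' @param config configuration list, see [default_spine_config()].
#' @return object of class `spine_model`.
#' @export
build_synthetic_lss <- function(config = default_spine_config()) {
  validate_spine_config(config)
  nv <- config$n_lumbar
  hv <- config$vertebra_height; hd <- config$disc_height
  wedges <- config$lordosis * config$wedge_fractions
  # walk cranially from the S1 superior endplate (global origin)
  s1_sup <- new_frame(c(0, 0, 0), rot_y(config$sacral_slope))
  vert_names <- paste0("L", rev(seq_len(nv)))     # caudal to cranial: L5..L1
  sup <- s1_sup
  verts <- list()
  disc_frames <- list()
  for (k in seq_len(nv)) {   # k = 1 is L5/S1 disc
    wedge <- wedges[nv - k + 1L]
    lower_ep <- sup
    upper_ep <- endplate_advance(lower_ep, hd, wedge)
    inf_ep <- upper_ep
    center <- new_frame(inf_ep$origin + as.numeric(inf_ep$R %*% c(0, 0,
                                                                  hv / 2)),
                        inf_ep$R)
    sup <- new_frame(inf_ep$origin + as.numeric(inf_ep$R %*% c(0, 0, hv)),
                     inf_ep$R)
    verts[[vert_names[k]]] <- list(center = center, inferior = inf_ep,
                                   superior = sup)
    disc_frames[[k]] <- list(lower = lower_ep, upper = inf_ep)
  }
  # bodies: thorax (frame at L1 center, includes L1), L2..L5 dynamic,
  # sacrum+pelvis static at the global origin
  l1 <- verts$L1
  bodies <- list()
  bodies$thorax <- list(
    name = "thorax", frame0 = l1$center, dynamic = TRUE,
    mass = config$masses$thorax + config$masses$vertebra[1],
    com = (config$masses$thorax * config$com_ub +
             config$masses$vertebra[1] * c(0, 0, 0)) /
      (config$masses$thorax + config$masses$vertebra[1]),
    inertia = config$thorax_inertia)
  for (i in 2:nv) {
    nm <- paste0("L", i)
    bodies[[nm]] <- list(name = nm, frame0 = verts[[nm]]$center,
                         dynamic = TRUE, mass = config$masses$vertebra[i],
                         com = c(0, 0, 0),
                         inertia = config$vertebra_inertia)
  }
  bodies$sacrum <- list(name = "sacrum", frame0 = new_frame(), dynamic = FALSE,
                        mass = config$body_mass -
                          config$masses$thorax -
                          sum(config$masses$vertebra),
                        com = c(0, 0, -0.08), inertia = diag(3) * 0.1)
  # owner body of each vertebra (L1 belongs to the thorax body)
  vert_owner <- c(L1 = "thorax", stats::setNames(paste0("L", 2:nv),
                                                 paste0("L", 2:nv)))
  # discs
  discs <- list()
  for (k in seq_len(nv)) {
    lower_name <- if (k == 1L) "S1" else vert_names[k - 1L]
    upper_name <- vert_names[k]
    d <- build_disc(disc_frames[[k]]$lower, disc_frames[[k]]$upper,
                    r_nucleus = config$disc$r_nucleus,
                    r_outer = config$disc$r_outer,
                    n_layers = config$disc$n_layers,
                    gauss_order = if (is.null(config$disc$gauss_order)) 2L
                      else config$disc$gauss_order,
                    materials = config$disc$materials)
    discs[[paste0(upper_name, lower_name)]] <- list(
      fe = d, level = paste0(lower_name, "/", upper_name),
      body_lower = if (k == 1L) "sacrum" else
        vert_owner[[vert_names[k - 1L]]],
      body_upper = vert_owner[[upper_name]],
      lower_local = frame_in_body(disc_frames[[k]]$lower,
                                  if (k == 1L) bodies$sacrum$frame0 else
                                    bodies_frame(bodies, vert_owner[[vert_names[k - 1L]]])),
      upper_local = frame_in_body(disc_frames[[k]]$upper,
                                  bodies_frame(bodies,
                                               vert_owner[[upper_name]])))
  }
  # facets: one left/right pair per level
  facets <- list()
  for (k in seq_len(nv)) {
    lower_name <- if (k == 1L) "sacrum" else
      vert_owner[[vert_names[k - 1L]]]
    upper_name <- vert_owner[[vert_names[k]]]
    lower_f0 <- bodies_frame(bodies, lower_name)
    upper_f0 <- bodies_frame(bodies, upper_name)
    base <- if (k == 1L) s1_sup else verts[[vert_names[k - 1L]]]$superior
    for (sdy in c(-1, 1)) {
      pp_global <- as.numeric(frame_transform(
        base, c(config$facet$x, sdy * config$facet$y, 0.002)))
      n_global <- as.numeric(base$R %*% c(0, 0, 1))
      pu_global <- pp_global + config$facet$gap * n_global
      facets[[length(facets) + 1L]] <- list(
        level = names(discs)[k], side = if (sdy < 0) "R" else "L",
        body_lower = lower_name, body_upper = upper_name,
        plane_point = point_in_body(pp_global, lower_f0),
        normal = as.numeric(t(lower_f0$R) %*% n_global),
        point_upper = point_in_body(pu_global, upper_f0),
        k = config$facet$k)
    }
  }
  # ligaments: five mid-sagittal bands per level
  lig <- list()
  lcfg <- config$ligaments
  for (k in seq_len(nv)) {
    lower_name <- if (k == 1L) "sacrum" else vert_owner[[vert_names[k - 1L]]]
    upper_name <- vert_owner[[vert_names[k]]]
    lower_f0 <- bodies_frame(bodies, lower_name)
    upper_f0 <- bodies_frame(bodies, upper_name)
    lo_ep <- disc_frames[[k]]$lower; up_ep <- disc_frames[[k]]$upper
    for (ty in names(lcfg$types)) {
      p_lo <- as.numeric(frame_transform(lo_ep, c(lcfg$x[[ty]], 0, -0.002)))
      p_up <- as.numeric(frame_transform(up_ep, c(lcfg$x[[ty]], 0, 0.002)))
      L_build <- sqrt(sum((p_up - p_lo)^2))
      lig[[length(lig) + 1L]] <- list(
        name = paste0(ty, "_", names(discs)[k]), type = ty,
        body_lower = lower_name, body_upper = upper_name,
        p_lower = point_in_body(p_lo, lower_f0),
        p_upper = point_in_body(p_up, upper_f0),
        slack = L_build / (1 + lcfg$pretension),
        curve = cbind(strain = lcfg$shape[, "strain"],
                      force = lcfg$shape[, "force"] * lcfg$types[[ty]]))
    }
  }
  lig_vec <- list(
    body_lower = vapply(lig, `[[`, "", "body_lower"),
    body_upper = vapply(lig, `[[`, "", "body_upper"),
    p_lower = do.call(rbind, lapply(lig, `[[`, "p_lower")),
    p_upper = do.call(rbind, lapply(lig, `[[`, "p_upper")),
    slack = vapply(lig, `[[`, 0, "slack"),
    scale = vapply(lig, function(l) lcfg$types[[l$type]], 0),
    shape = lcfg$shape)
  model <- structure(list(
    lig_vec = lig_vec,
    config = config, bodies = bodies, vertebrae = verts,
    vert_owner = vert_owner, discs = discs, facets = facets,
    ligaments = lig, s1_sup = s1_sup,
    gravity = config$gravity, resting_tone = config$resting_tone,
    cavity = config$cavity, chain = config$chain, spring = config$spring,
    wraps = config$wraps), class = "spine_model")
  model <- add_abdominal_plates(model)
  model <- add_synthetic_muscles(model)
  model$reference <- NULL
  model
}

bodies_frame <- function(bodies, name) {
  if (name == "S1") name <- "sacrum"
  bodies[[name]]$frame0
}

frame_in_body <- function(frame, body_frame) {
  # express a world frame in body coordinates
  list(origin = as.numeric(t(body_frame$R) %*% (frame$origin -
                                                  body_frame$origin)),
       R = t(body_frame$R) %*% frame$R)
}

point_in_body <- function(p, body_frame) {
  as.numeric(t(body_frame$R) %*% (p - body_frame$origin))
}

local_frame_to_world <- function(local, body_frame) {
  new_frame(body_frame$origin + as.numeric(body_frame$R %*% local$origin),
            body_frame$R %*% local$R)
}

add_abdominal_plates <- function(model) {
  cfg <- model$config
  ap0 <- pose_plates(chain_coordinates(0, 0, 0, model$chain),
                     sacrum = model$bodies$sacrum$frame0,
                     config = model$chain)
  # The dynamically active plate is quasi-massless: it is kept in exact
  # static equilibrium by an inner solve inside the residual rather than
  # carried as a global degree of freedom.
  model$bodies$ap_iap <- list(name = "ap_iap", frame0 = ap0,
                              dynamic = FALSE, slaved = TRUE,
                              mass = 1e-3, com = c(0, 0, 0),
                              inertia = diag(3) * 1e-6)
  model$plate_env <- new.env(parent = emptyenv())
  # diaphragm force application point A_D: 5.1 cm anterior of T12
  t12_local <- c(0, 0, cfg$vertebra_height / 2 + 0.01)
  model$a_d_local <- t12_local + c(model$cavity$a_d_anterior, 0, 0)
  model$ap0 <- ap0
  model
}

#' Mirror the right-side musculature across the mid-sagittal plane
#'
#' Every right-side fascicle gets a left twin with y-negated path points
#' and identical parameters; applying the operation twice returns an
#' identical model (involution). Fascicles whose mirrored name would
#' collide with an existing one raise an error.
#'
#' @param model a `spine_model` with right-side muscles.
#' @return the model with both sides present.
#' @export
mirror_sagittal <- function(model) {
  m <- model$muscles
  keep <- m$fasc$side == "R"
  if (any(m$fasc$side == "L")) {
    # drop previous mirror images so the operation is an involution
    drop_ids <- m$fasc$id[m$fasc$side == "L"]
    m$pts <- m$pts[!(m$pts$fascicle %in% drop_ids), , drop = FALSE]
    m$fasc <- m$fasc[keep, , drop = FALSE]
  }
  fr <- m$fasc
  fl <- fr
  fl$id <- sub("_R$", "_L", fr$id)
  fl$side <- "L"
  if (any(fl$id %in% fr$id))
    stop("mirrored fascicle name collision: ",
         paste(utils::head(intersect(fl$id, fr$id)), collapse = ", "))
  pl <- m$pts[m$pts$fascicle %in% fr$id, , drop = FALSE]
  pl$fascicle <- sub("_R$", "_L", pl$fascicle)
  pl$y <- -pl$y
  m$fasc <- rbind(fr, fl)
  m$pts <- rbind(m$pts[m$pts$fascicle %in% fr$id, , drop = FALSE], pl)
  model$muscles <- m
  model <- finalize_muscles(model)
  model
}

#' Intervertebral and thorax-pelvis angles of a model state
#'
#' Sagittal rotations are measured relative to the stored reference posture
#' (or the build state when no reference is set). IVRs are differences of
#' adjacent absolute rotations; the thorax angle equals the absolute L1
#' rotation because thorax and L1 are rigidly connected.
#'
#' @param model a `spine_model`.
#' @param state a simulation state (see [neutral_state()]).
#' @return list with `alpha` (thorax rotation vector rel. pelvis, deg),
#'   `rotation` (named absolute sagittal rotations L1..L5, deg), `ivr`
#'   (named L1L2..L5S1, deg).
#' @export
measure_angles <- function(model, state) {
  ref <- model$reference
  rot_of <- function(body) {
    R <- state$frames[[body]]$R
    R0 <- if (!is.null(ref)) ref$frames[[body]]$R else
      model$bodies[[body]]$frame0$R
    rad2deg(matrix_to_rotvec(R %*% t(R0)))
  }
  nv <- model$config$n_lumbar
  vnames <- paste0("L", seq_len(nv))
  rot <- vapply(vnames, function(v) rot_of(model$vert_owner[[v]])[2],
                numeric(1))
  alpha <- rot_of("thorax")
  # IVR = rotation(upper) - rotation(lower); the sacrum is fixed at 0
  ivr <- c(rot[-nv] - rot[-1], rot[nv])
  names(ivr) <- c(paste0(vnames[-nv], vnames[-1]), paste0("L", nv, "S1"))
  list(alpha = c(x = alpha[1], y = alpha[2], z = alpha[3]),
       rotation = stats::setNames(rot, vnames), ivr = ivr)
}

#' Neutral (build) simulation state
#' @param model a `spine_model`.
#' @param excitations optional named group excitation vector.
#' @export
neutral_state <- function(model, excitations = NULL) {
  frames <- lapply(model$bodies, function(b) b$frame0)
  e <- excitations
  if (is.null(e)) {
    e <- stats::setNames(rep(0, length(model$muscles$group_names)),
                         model$muscles$group_names)
  }
  list(frames = frames, e = e, time = 0,
       vel = lapply(model$bodies, function(b) list(v = c(0, 0, 0),
                                                   w = c(0, 0, 0))),
       gravity_scale = 1)
}

#' Measured lordosis of the built model (deg)
#' @param model a `spine_model`.
#' @export
model_lordosis <- function(model) {
  zs1 <- model$s1_sup$R[, 3]
  zl1 <- model$vertebrae$L1$superior$R[, 3]
  rad2deg(acos(min(1, max(-1, sum(zs1 * zl1)))))
}

#' @exportS3Method base::print
print.spine_model <- function(x, ...) {
  nf <- nrow(x$muscles$fasc)
  cat("Synthetic lumbosacral spine model\n")
  cat(sprintf("  lumbar vertebrae: %d (thorax rigid with L1; sacrum fixed)\n",
              x$config$n_lumbar))
  cat(sprintf("  lordosis L1-S1: %.1f deg (target %.1f)\n",
              model_lordosis(x), x$config$lordosis))
  cat(sprintf("  discs: %d  facets: %d  ligaments: %d\n",
              length(x$discs), length(x$facets), length(x$ligaments)))
  cat(sprintf("  muscle fascicles: %d (%d per side, %d groups)\n", nf,
              nf %/% 2L, length(unique(x$muscles$fasc$group))))
  invisible(x)
}

#' @exportS3Method base::summary
summary.spine_model <- function(object, ...) {
  tab <- table(object$muscles$fasc$group, object$muscles$fasc$side)
  print(object)
  cat("\nFascicles per group and side:\n")
  print(tab)
  invisible(list(groups = tab, lordosis = model_lordosis(object)))
}
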