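#' Internal force assembly for the assembled spine model
#'
#' The quasi-static residual collects, for every dynamic body, the net
#' force and torque from gravity, FE disc responses, collagen fiber rings,
#' ligaments, facet contacts, muscle fascicle tensions, the abdominal plate
#' spring, the intra-abdominal pressure, and external loads.
#'
#' @name forces
NULL

dynamic_body_names <- function(model) {
  names(model$bodies)[vapply(model$bodies, `[[`, TRUE, "dynamic")]
}

# thorax rotation relative to the pelvis/reference (deg, rotation vector)
thorax_alpha <- function(model, state) {
  R0 <- if (!is.null(model$reference)) model$reference$frames$thorax$R else
    model$bodies$thorax$frame0$R
  rad2deg(matrix_to_rotvec(state$frames$thorax$R %*% t(R0)))
}

current_ap_frame <- function(model, state) {
  al <- thorax_alpha(model, state)
  pose_plates(chain_coordinates(al[1], al[2], al[3], model$chain),
              sacrum = model$bodies$sacrum$frame0, config = model$chain)
}

# current pose of the named wrap obstacle
wrap_obstacles <- function(model, state) {
  ref <- if (!is.null(model$reference)) model$reference else
    list(frames = lapply(model$bodies, `[[`, "frame0"))
  l1c <- model$vertebrae$L1$center
  l1_local <- point_in_body(l1c$origin, model$bodies$thorax$frame0)
  pos_of <- function(body, frames) {
    f <- frames[[body]]
    if (body == "thorax") as.numeric(frame_transform(f, l1_local)) else
      f$origin
  }
  st <- list(l1_rot = thorax_alpha(model, state)[2],
             l1_pos = pos_of("thorax", state$frames),
             l2_pos = state$frames$L2$origin,
             l4_pos = state$frames$L4$origin)
  rf <- list(l1_pos = pos_of("thorax", ref$frames),
             l2_pos = ref$frames$L2$origin,
             l4_pos = ref$frames$L4$origin,
             s1_pos = c(0, 0, 0))
  lw <- update_lumbar_wrap(st, rf)
  wl <- model$wraps$lumbar
  lum <- lumbar_wrap_pose(list(center = wl$center, axis = wl$axis,
                               radius = wl$radius),
                          wl$joint_center, lw$hinge_deg, lw$slider_m)
  th <- state$frames$thorax
  th0 <- model$bodies$thorax$frame0
  ell <- lapply(model$wraps[c("thoracic_L", "thoracic_R")], function(w) {
    ctr_local <- point_in_body(w$center, th0)
    R_local <- t(th0$R) %*% joint_rot(w$rot)
    list(center = as.numeric(frame_transform(th, ctr_local)),
         R = th$R %*% R_local, radii = w$radii)
  })
  list(lumbar = lum, thoracic_L = ell$thoracic_L, thoracic_R = ell$thoracic_R,
       lumbar_state = lw)
}

# Precompute the static index structure for fast muscle geometry
# evaluation: point ordering with wrap points interleaved, per-owner row
# groups with local coordinates, and segment index arrays.
make_geometry_plan <- function(model, wrap_segs) {
  fasc <- model$muscles$fasc
  pts <- model$muscles$pts
  fid_b <- match(pts$fascicle, fasc$id)
  o <- order(fid_b, pts$ord)
  pts <- pts[o, , drop = FALSE]; fid_b <- fid_b[o]
  owner <- character(0); fid <- integer(0)
  loc <- list()
  for (k in seq_len(nrow(fasc))) {
    ix <- which(fid_b == k)
    segs <- wrap_segs[[fasc$id[k]]]
    after <- if (is.null(segs)) integer(0) else
      vapply(segs, `[[`, 0L, "after")
    pos <- 0L
    for (j in seq_along(ix)) {
      owner <- c(owner, pts$owner[ix[j]]); fid <- c(fid, k)
      loc[[length(loc) + 1L]] <-
        as.numeric(pts[ix[j], c("x", "y", "z")])
      hit <- which(after == j)
      for (hh in hit) {
        s <- segs[[hh]]
        owner <- c(owner, rep(s$owner, nrow(s$local)))
        fid <- c(fid, rep(k, nrow(s$local)))
        for (rr in seq_len(nrow(s$local)))
          loc[[length(loc) + 1L]] <- s$local[rr, ]
      }
    }
  }
  L <- do.call(rbind, loc)
  n <- nrow(L)
  last <- c(fid[-1] != fid[-n], TRUE)
  i0 <- which(!last); i1 <- i0 + 1L
  seg_fid <- fid[i0]
  # cumulative-sum boundaries for per-fascicle length sums
  lastseg <- cumsum(as.numeric(table(seg_fid)))
  list(L = L, owner = owner, fid = fid, i0 = i0, i1 = i1,
       seg_fid = seg_fid, lastseg = lastseg,
       owner_rows = split(seq_len(n), owner))
}

# Resolve wrap contact points for all wrapped fascicles at the given state.
# Returns a list with `segs` per fascicle id (points expressed in the
# wrap-carrier body frame: sacrum for the lumbar cylinder, thorax for the
# ellipsoids) and the geometry `plan` built from them.
resolve_wrap_points <- function(model, state) {
  obs <- wrap_obstacles(model, state)
  fasc <- model$muscles$fasc
  wrapped <- which(fasc$wrap_lumbar | fasc$wrap_thoracic)
  if (!length(wrapped))
    return(list(segs = list(), plan = make_geometry_plan(model, list())))
  geo <- muscle_world_points(model, state)
  out <- list()
  th0 <- model$bodies$thorax$frame0
  thf <- state$frames$thorax
  for (k in wrapped) {
    id <- fasc$id[k]
    P <- geo$points[geo$fascicle_idx == k, , drop = FALSE]
    path <- P
    segs <- list()
    if (fasc$wrap_lumbar[k]) {
      w <- tryCatch(wrap_cylinder(path[1, ], path[2, ], obs$lumbar),
                    error = function(e) NULL)
      if (!is.null(w))
        segs$lumbar <- list(owner = "sacrum", after = 1L,
                            local = t(apply(w, 1, point_in_body,
                                            body_frame = model$bodies$sacrum$frame0)),
                            world = w)
      if (!is.null(w)) path <- rbind(path[1, ], w[nrow(w), ],
                                     path[-1, , drop = FALSE])
    }
    if (fasc$wrap_thoracic[k]) {
      ell <- if (fasc$side[k] == "R") obs$thoracic_R else obs$thoracic_L
      n <- nrow(path)
      w <- tryCatch(wrap_ellipsoid(path[n - 1L, ], path[n, ], ell,
                                   n_chain = 9L, max_iter = 400L,
                                   tol = 1e-5),
                    error = function(e) NULL)
      if (!is.null(w) && nrow(w))
        segs$thoracic <- list(owner = "thorax", after = n - 1L,
                              local = t(apply(w, 1, function(p)
                                point_in_body(p, thf))),
                              world = w)
    }
    out[[id]] <- segs
  }
  list(segs = out, plan = make_geometry_plan(model, out))
}

# world coordinates of the base (non-wrap) muscle points
muscle_world_points <- function(model, state) {
  pts <- model$muscles$pts
  P <- matrix(0, nrow(pts), 3)
  owners <- unique(pts$owner)
  ap <- NULL
  for (ow in owners) {
    ix <- which(pts$owner == ow)
    loc <- as.matrix(pts[ix, c("x", "y", "z")])
    f <- if (ow == "AP") {
      if (is.null(ap)) ap <- current_ap_frame(model, state)
      ap
    } else state$frames[[ow]]
    P[ix, ] <- frame_transform(f, loc)
  }
  fid <- match(pts$fascicle, model$muscles$fasc$id)
  ord <- order(fid, pts$ord)
  list(points = P[ord, , drop = FALSE],
       owner = pts$owner[ord],
       fascicle_idx = fid[ord])
}

# Full muscle geometry with wrap points inserted, evaluated through the
# precomputed plan. Returns the expanded point table and per-fascicle path
# lengths.
muscle_geometry <- function(model, state, wrap_cache = NULL) {
  if (is.null(wrap_cache)) wrap_cache <- resolve_wrap_points(model, state)
  plan <- wrap_cache$plan
  P <- matrix(0, nrow(plan$L), 3L)
  ap <- NULL
  for (ow in names(plan$owner_rows)) {
    rows <- plan$owner_rows[[ow]]
    f <- if (ow == "AP") {
      if (is.null(ap)) ap <- current_ap_frame(model, state)
      ap
    } else state$frames[[ow]]
    P[rows, ] <- frame_transform(f, plan$L[rows, , drop = FALSE])
  }
  seg <- P[plan$i1, , drop = FALSE] - P[plan$i0, , drop = FALSE]
  slen <- sqrt(rowSums(seg^2))
  cs <- cumsum(slen)
  tot <- cs[plan$lastseg]
  lmt <- c(tot[1], diff(tot))
  names(lmt) <- model$muscles$fasc$id
  list(P = P, owner = plan$owner, fid = plan$fid, i0 = plan$i0,
       i1 = plan$i1, seg = seg, slen = slen, lmt = lmt)
}

# vectorized rigid-tendon Hill tension for all fascicles
muscle_tensions <- function(model, lmt, a) {
  f <- model$muscles$fasc
  h <- f$l_opt * sin(deg2rad(f$pennation))
  lproj <- pmax(lmt - f$tendon_slack, 0.01 * f$l_opt)
  lM <- sqrt(lproj^2 + h^2)
  cosp <- lproj / lM
  lt <- lM / f$l_opt
  act <- active_fl(lt)
  Fn <- a * act + passive_fl(lt)
  list(T = f$f0 * pmax(Fn, 0) * cosp,
       dT_da = f$f0 * act * cosp)
}

# per-body wrench accumulation from point forces
accumulate_wrench <- function(wrench, body, force, point, origin) {
  if (is.null(wrench[[body]]))
    wrench[[body]] <- list(force = c(0, 0, 0), torque = c(0, 0, 0))
  wrench[[body]]$force <- wrench[[body]]$force + force
  wrench[[body]]$torque <- wrench[[body]]$torque +
    cross3(point - origin, force)
  wrench
}

#' Quasi-static residual of the assembled model
#'
#' Net force and torque on every dynamic body under the current state and
#' group excitations. The residual is zero at static equilibrium.
#'
#' @param model a `spine_model`.
#' @param state simulation state.
#' @param wrap_cache optional frozen wrap-point cache
#'   (see `resolve_wrap_points`); resolved fresh when `NULL`.
#' @param loads optional list of external loads, each
#'   `list(body, point_local, force)` with `force` a function
#'   `(state) -> global force vector` or a fixed vector.
#' @param detail return per-component diagnostics (muscle forces, IAP, IDP
#'   inputs).
#' @return list with `r` (length 6 x n_dynamic residual, N and Nm), `aux`.
#' @export
spine_residual <- function(model, state, wrap_cache = NULL, loads = list(),
                           detail = FALSE) {
  dyn <- dynamic_body_names(model)
  # quasi-massless dynamic plate: solved to static equilibrium here
  fasc <- model$muscles$fasc
  tone <- model$resting_tone
  a <- pmax(as.numeric(state$e[fasc$group_side]), tone)
  a[is.na(a)] <- tone
  ap_frame <- current_ap_frame(model, state)
  state$frames$ap_iap <- solve_plate(model, state, a, ap_frame)
  wr <- stats::setNames(vector("list", length(dyn)), dyn)
  origins <- lapply(state$frames, `[[`, "origin")
  gs <- if (is.null(state$gravity_scale)) 1 else state$gravity_scale
  # gravity
  for (b in dyn) {
    bd <- model$bodies[[b]]
    com_w <- as.numeric(frame_transform(state$frames[[b]], bd$com))
    Fg <- bd$mass * model$gravity * gs
    wr <- accumulate_wrench(wr, b, Fg, com_w, origins[[b]])
  }
  # discs (+ fiber rings)
  disc_aux <- list()
  for (dn in names(model$discs)) {
    dc <- model$discs[[dn]]
    lf <- local_frame_to_world(dc$lower_local, state$frames[[dc$body_lower]])
    uf <- local_frame_to_world(dc$upper_local, state$frames[[dc$body_upper]])
    xcur <- disc_current_nodes(dc$fe, lf, uf)
    o <- disc_internal(dc$fe, xcur, want_stress = detail)
    f_nodal <- -o$fint + disc_fiber_forces(dc$fe, xcur)
    for (side in c("lower", "upper")) {
      body <- dc[[paste0("body_", side)]]
      if (!(body %in% dyn)) next
      nodes <- if (side == "lower") dc$fe$caudal else dc$fe$cranial
      w <- node_wrench(f_nodal, xcur, nodes, origins[[body]])
      if (is.null(wr[[body]]))
        wr[[body]] <- list(force = c(0, 0, 0), torque = c(0, 0, 0))
      wr[[body]]$force <- wr[[body]]$force + w$force
      wr[[body]]$torque <- wr[[body]]$torque + w$torque
    }
    if (detail)
      disc_aux[[dn]] <- list(idp = compute_idp(dc$fe, o$stress_elem),
                             energy = o$energy)
  }
  # ligaments (tension-only, vectorized over the stacked attachment table)
  lv <- model$lig_vec
  if (!is.null(lv)) {
    PL <- matrix(0, nrow(lv$p_lower), 3)
    PU <- PL
    for (b in unique(lv$body_lower)) {
      ix <- lv$body_lower == b
      PL[ix, ] <- frame_transform(state$frames[[b]],
                                  lv$p_lower[ix, , drop = FALSE])
    }
    for (b in unique(lv$body_upper)) {
      ix <- lv$body_upper == b
      PU[ix, ] <- frame_transform(state$frames[[b]],
                                  lv$p_upper[ix, , drop = FALSE])
    }
    d <- PU - PL
    len <- sqrt(rowSums(d^2))
    strain <- len / lv$slack - 1
    Tl <- fiber_force(strain, lv$shape) * lv$scale
    act <- which(Tl > 0)
    for (i in act) {
      u <- d[i, ] / len[i]
      if (lv$body_upper[i] %in% dyn)
        wr <- accumulate_wrench(wr, lv$body_upper[i], -Tl[i] * u, PU[i, ],
                                origins[[lv$body_upper[i]]])
      if (lv$body_lower[i] %in% dyn)
        wr <- accumulate_wrench(wr, lv$body_lower[i], Tl[i] * u, PL[i, ],
                                origins[[lv$body_lower[i]]])
    }
  }
  # facet contacts (forces act at the upper body's contact point)
  for (fc in model$facets) {
    lf <- state$frames[[fc$body_lower]]; uf <- state$frames[[fc$body_upper]]
    ff <- facet_force(fc, lf, uf)
    if (ff$gap >= 0) next
    cp <- as.numeric(frame_transform(uf, fc$point_upper))
    if (fc$body_upper %in% dyn)
      wr <- accumulate_wrench(wr, fc$body_upper, ff$force_upper, cp,
                              origins[[fc$body_upper]])
    if (fc$body_lower %in% dyn)
      wr <- accumulate_wrench(wr, fc$body_lower, ff$force_lower, cp,
                              origins[[fc$body_lower]])
  }
  # muscles
  geo <- muscle_geometry(model, state, wrap_cache)
  mt <- muscle_tensions(model, geo$lmt, a)
  Tseg <- mt$T[geo$fid[geo$i0]]
  u <- geo$seg / geo$slen
  fv <- u * Tseg
  # per-point force: +T u at segment start, -T u at segment end
  fpt <- matrix(0, nrow(geo$P), 3)
  fpt[geo$i0, ] <- fpt[geo$i0, ] + fv
  add <- rowsum(-fv, geo$i1)
  ri <- as.integer(rownames(add))
  fpt[ri, ] <- fpt[ri, ] + add
  for (b in unique(geo$owner)) {
    if (!(b %in% dyn)) next
    ix <- which(geo$owner == b)
    fs <- fpt[ix, , drop = FALSE]
    ps <- geo$P[ix, , drop = FALSE]
    org <- origins[[b]]
    if (is.null(wr[[b]]))
      wr[[b]] <- list(force = c(0, 0, 0), torque = c(0, 0, 0))
    wr[[b]]$force <- wr[[b]]$force + colSums(fs)
    rvec <- sweep(ps, 2, org)
    wr[[b]]$torque <- wr[[b]]$torque +
      colSums(cbind(rvec[, 2] * fs[, 3] - rvec[, 3] * fs[, 2],
                    rvec[, 3] * fs[, 1] - rvec[, 1] * fs[, 3],
                    rvec[, 1] * fs[, 2] - rvec[, 2] * fs[, 1]))
  }
  # abdominal plate spring (at the plate's solved equilibrium) + IAP
  spw <- frame_spring_wrench(ap_frame, state$frames$ap_iap,
                             model$spring$k_normal, model$spring$k_shear,
                             model$spring$k_rot)
  f_ap <- max(spw$normal_force, 0)
  iap <- compute_iap(f_ap, model$cavity, state$frames$thorax$R)
  a_d_world <- as.numeric(frame_transform(state$frames$thorax,
                                          model$a_d_local))
  wr <- accumulate_wrench(wr, "thorax", iap$force, a_d_world,
                          origins$thorax)
  # external loads
  for (ld in loads) {
    f <- if (is.function(ld$force)) ld$force(state) else ld$force
    pw <- as.numeric(frame_transform(state$frames[[ld$body]],
                                     ld$point_local))
    wr <- accumulate_wrench(wr, ld$body, f, pw, origins[[ld$body]])
  }
  r <- unlist(lapply(dyn, function(b) c(wr[[b]]$force, wr[[b]]$torque)))
  out <- list(r = r, wrench = wr, plate_frame = state$frames$ap_iap)
  if (detail) {
    out$aux <- list(
      discs = disc_aux, iap = iap, f_ap = f_ap,
      lmt = geo$lmt, tension = mt$T,
      activation = stats::setNames(a, fasc$id))
  }
  out
}

# ---- quasi-massless abdominal plate ------------------------------------

# Precompute the reduced structure of all fascicles touching the dynamic
# plate: point table, segment indices and Hill parameters.
make_plate_plan <- function(model) {
  pts <- model$muscles$pts
  fasc <- model$muscles$fasc
  plate_f <- unique(pts$fascicle[pts$owner == "ap_iap"])
  if (!length(plate_f)) return(NULL)
  k <- match(plate_f, fasc$id)
  sub <- pts[pts$fascicle %in% plate_f, , drop = FALSE]
  fid <- match(sub$fascicle, plate_f)
  o <- order(fid, sub$ord)
  sub <- sub[o, , drop = FALSE]; fid <- fid[o]
  n <- nrow(sub)
  last <- c(fid[-1] != fid[-n], TRUE)
  i0 <- which(!last); i1 <- i0 + 1L
  lastseg <- cumsum(as.numeric(table(fid[i0])))
  list(local = as.matrix(sub[, c("x", "y", "z")]),
       owner = sub$owner, fid = fid, ids = plate_f, fasc_row = k,
       i0 = i0, i1 = i1, lastseg = lastseg,
       plate_rows = which(sub$owner == "ap_iap"))
}

# Static equilibrium pose of the quasi-massless plate AP_IAP: balances the
# six-dimensional frame spring against the attached abdominal muscle pulls
# at fixed poses of all other bodies.
solve_plate <- function(model, state, a, ap_frame) {
  pp <- model$muscles$plate_plan
  if (is.null(pp)) return(ap_frame)
  fr <- model$muscles$fasc[pp$fasc_row, ]
  a_sub <- a[pp$fasc_row]
  # fixed-world part of the point table
  P <- matrix(0, nrow(pp$local), 3)
  for (ow in unique(pp$owner)) {
    if (ow == "ap_iap") next
    rows <- which(pp$owner == ow)
    P[rows, ] <- frame_transform(state$frames[[ow]],
                                 pp$local[rows, , drop = FALSE])
  }
  sp <- model$spring
  wrench_of <- function(p) {
    f <- new_frame(ap_frame$origin + p[1:3],
                   rotvec_to_matrix(p[4:6]) %*% ap_frame$R)
    P[pp$plate_rows, ] <- frame_transform(f,
                                          pp$local[pp$plate_rows, ,
                                                   drop = FALSE])
    seg <- P[pp$i1, , drop = FALSE] - P[pp$i0, , drop = FALSE]
    slen <- sqrt(rowSums(seg^2))
    cs <- cumsum(slen); tot <- cs[pp$lastseg]
    lmt <- c(tot[1], diff(tot))
    lproj <- pmax(lmt - fr$tendon_slack, 0.01 * fr$l_opt)
    lt <- lproj / fr$l_opt
    Tf <- fr$f0 * pmax(a_sub * active_fl(lt) + passive_fl(lt), 0)
    Tseg <- Tf[pp$fid[pp$i0]]
    u <- seg / slen
    fv <- u * Tseg
    fpt <- matrix(0, nrow(P), 3)
    fpt[pp$i0, ] <- fpt[pp$i0, ] + fv
    fpt[pp$i1, ] <- fpt[pp$i1, ] - fv
    rows <- pp$plate_rows
    fs <- fpt[rows, , drop = FALSE]
    rvec <- sweep(P[rows, , drop = FALSE], 2, f$origin)
    spw <- frame_spring_wrench(ap_frame, f, sp$k_normal, sp$k_shear,
                               sp$k_rot)
    c(colSums(fs) + spw$force_iap,
      colSums(cbind(rvec[, 2] * fs[, 3] - rvec[, 3] * fs[, 2],
                    rvec[, 3] * fs[, 1] - rvec[, 1] * fs[, 3],
                    rvec[, 1] * fs[, 2] - rvec[, 2] * fs[, 1])) +
        spw$torque_iap)
  }
  p <- model$plate_env$p
  if (is.null(p) || length(p) != 6L) p <- numeric(6)
  for (it in 1:15) {
    r <- wrench_of(p)
    if (max(abs(r[1:3])) < 1e-3 && max(abs(r[4:6])) < 1e-4) break
    J <- fd_jacobian(wrench_of, p, h = 1e-8)
    dp <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dp)) { p <- numeric(6); next }
    # plate excursions are millimetric; clamp runaway steps
    dp[1:3] <- pmin(pmax(dp[1:3], -0.02), 0.02)
    dp[4:6] <- pmin(pmax(dp[4:6], -0.2), 0.2)
    p <- p + dp
  }
  model$plate_env$p <- p
  new_frame(ap_frame$origin + p[1:3],
            rotvec_to_matrix(p[4:6]) %*% ap_frame$R)
}

# analytic d(residual)/d(group excitation) at fixed kinematics
residual_excitation_jacobian <- function(model, state, wrap_cache = NULL) {
  dyn <- dynamic_body_names(model)
  geo <- muscle_geometry(model, state, wrap_cache)
  fasc <- model$muscles$fasc
  tone <- model$resting_tone
  e <- as.numeric(state$e[fasc$group_side])
  # upward one-sided derivative through the max(e, tone) rule: excitations
  # at/below tone still respond to increases, so keep their sensitivity
  active <- rep(TRUE, length(e))
  mt <- muscle_tensions(model, geo$lmt, pmax(e, tone))
  groups <- model$muscles$group_names
  B <- matrix(0, 6L * length(dyn), length(groups),
              dimnames = list(NULL, groups))
  origins <- lapply(state$frames, `[[`, "origin")
  u <- geo$seg / geo$slen
  fidseg <- geo$fid[geo$i0]
  for (gi in seq_along(groups)) {
    sel <- which(fasc$group_side == groups[gi] & active)
    if (!length(sel)) next
    segsel <- which(fidseg %in% sel)
    if (!length(segsel)) next
    dT <- mt$dT_da[fidseg[segsel]]
    fv <- u[segsel, , drop = FALSE] * dT
    fpt <- matrix(0, nrow(geo$P), 3)
    i0 <- geo$i0[segsel]; i1 <- geo$i1[segsel]
    ad0 <- rowsum(fv, i0); fpt[as.integer(rownames(ad0)), ] <- ad0
    ad1 <- rowsum(-fv, i1)
    ri <- as.integer(rownames(ad1))
    fpt[ri, ] <- fpt[ri, ] + ad1
    col <- numeric(6L * length(dyn))
    for (bi in seq_along(dyn)) {
      b <- dyn[bi]
      ix <- which(geo$owner == b)
      if (!length(ix)) next
      fs <- fpt[ix, , drop = FALSE]
      if (!any(fs != 0)) next
      ps <- geo$P[ix, , drop = FALSE]
      rvec <- sweep(ps, 2, origins[[b]])
      col[(6 * bi - 5):(6 * bi - 3)] <- colSums(fs)
      col[(6 * bi - 2):(6 * bi)] <-
        colSums(cbind(rvec[, 2] * fs[, 3] - rvec[, 3] * fs[, 2],
                      rvec[, 3] * fs[, 1] - rvec[, 1] * fs[, 3],
                      rvec[, 1] * fs[, 2] - rvec[, 2] * fs[, 1]))
    }
    B[, gi] <- col
  }
  # groups acting through the slaved plate (their force path includes the
  # plate equilibrium and the IAP) get finite-difference columns
  plate_groups <- intersect(groups, as.vector(outer(c("IO", "EO", "TA"),
                                                    c("R", "L"), paste,
                                                    sep = "_")))
  if (length(plate_groups)) {
    r0 <- spine_residual(model, state, wrap_cache)$r
    h <- 1e-3
    for (g in plate_groups) {
      st <- state
      st$e[g] <- st$e[g] + h
      B[, g] <- (spine_residual(model, st, wrap_cache)$r - r0) / h
    }
  }
  B
}
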