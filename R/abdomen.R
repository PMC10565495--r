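#' Abdominal kinematic chain, plates, and intra-abdominal pressure
#'
#' The abdominal plate (AP) is connected to the sacrum by an open kinematic
#' chain Sacrum - UJ - auxiliary body 1 - HJ - auxiliary body 2 - CJ - AP
#' whose five joint coordinates follow the thorax-relative-to-pelvis angles
#' through quadratic polynomials. A second, dynamically active and
#' quasi-massless plate (AP_IAP) carries the attachments of the abdominal
#' wall muscles and is tied to AP by a six-dimensional frame spring; the net
#' compressive muscle force on AP_IAP sets the intra-abdominal pressure.
#'
#' @name abdomen
NULL

#' Default abdominal chain configuration
#'
#' Joint centers, joint-frame rotations, and the case-sensitive polynomial
#' coefficients for the five controlled coordinates (flexion branch for
#' sagittal angle > 0, extension branch otherwise).
#' @export
default_chain_config <- function() {
  list(
    uj = list(center = c(0.0080, 0.0, 0.02314), rot = c(rx = 90, rz = 10)),
    hj = list(center = c(0.1347, 0.0, 0.0492), rot = c(rx = 90)),
    cj = list(center = c(0.0539, 0.0, -0.0308), rot = c(rx = 90, rz = 10,
                                                        ry = 90)),
    coef = list(
      theta1 = list(flexion = c(p1 = 0.442, p2 = 0.0116),
                    extension = c(p1 = 0.2437, p2 = 0.0144)),
      phi    = list(flexion = c(p1 = 0.4406, p2 = 0),
                    extension = c(p1 = 0.4406, p2 = 0)),
      theta2 = list(flexion = c(p1 = 0.2509, p2 = 0),
                    extension = c(p1 = 0.4236, p2 = 0)),
      z      = list(flexion = c(p1 = -0.1663, p2 = 0),
                    extension = c(p1 = -0.4236, p2 = 0)),
      theta3 = list(flexion = c(p1 = 0.815, p2 = 0),
                    extension = c(p1 = 0.815, p2 = 0))),
    # Z polynomial output is in degrees-driven centimeters (see vignette);
    # converted to meters by this scale factor
    z_scale_m = 0.01,
    ap0 = list(center = c(0.1345, 0.0, 0.0488), rot = c(ry = 7))
  )
}

poly2 <- function(coefs, a) coefs[["p1"]] * a + coefs[["p2"]] * a^2

#' Abdominal chain joint coordinates from thorax-pelvis angles
#'
#' Each controlled coordinate is a quadratic polynomial of its governing
#' thorax angle: theta1(alpha_y), phi(alpha_x + alpha_z), theta2(alpha_y),
#' theta3(alpha_x), Z(alpha_y). The flexion branch is used for
#' `alpha_y >= 0`, the extension branch otherwise (both give 0 at 0).
#'
#' @param alpha_x,alpha_y,alpha_z thorax rotations relative to the pelvis
#'   about the global axes (deg).
#' @param config chain configuration (see [default_chain_config()]).
#' @return named vector `theta1, theta2, theta3, phi, z` (rotations deg,
#'   `z` in the polynomial's native units; multiply by `config$z_scale_m`
#'   for meters).
#' @export
chain_coordinates <- function(alpha_x = 0, alpha_y = 0, alpha_z = 0,
                              config = default_chain_config()) {
  cf <- config$coef
  eval_br <- function(br) {
    c(theta1 = poly2(cf$theta1[[br]], alpha_y),
      theta2 = poly2(cf$theta2[[br]], alpha_y),
      theta3 = poly2(cf$theta3[[br]], alpha_x),
      phi = poly2(cf$phi[[br]], alpha_x + alpha_z),
      z = poly2(cf$z[[br]], alpha_y))
  }
  # C1 blend of the two branches in a narrow band about alpha_y = 0 (both
  # give 0 there); keeps static solvers off the derivative kink
  eps <- 0.5
  if (alpha_y >= eps) return(eval_br("flexion"))
  if (alpha_y <= -eps) return(eval_br("extension"))
  s <- (alpha_y + eps) / (2 * eps)
  w <- 3 * s^2 - 2 * s^3
  w * eval_br("flexion") + (1 - w) * eval_br("extension")
}

joint_rot <- function(rot) {
  R <- diag(3)
  for (nm in names(rot)) {
    R <- R %*% switch(substr(nm, 1, 2),
                      rx = rot_x(rot[[nm]]),
                      ry = rot_y(rot[[nm]]),
                      rz = rot_z(rot[[nm]]))
  }
  R
}

#' Forward kinematics of the abdominal plate
#'
#' Composes the UJ (rotations theta1 about its z''-axis and phi about the
#' rotated y''-axis), HJ (theta2 about z'), and CJ (translation Z along and
#' rotation theta3 about its z'''-axis) transforms to pose AP relative to
#' the sacrum frame.
#'
#' @param coords joint coordinates from [chain_coordinates()].
#' @param sacrum sacrum `ls_frame` (chain base).
#' @param config chain configuration.
#' @return `ls_frame` of the abdominal plate.
#' @export
pose_plates <- function(coords, sacrum = new_frame(),
                        config = default_chain_config()) {
  world <- function(f) frame_compose(sacrum, f)
  # joint frames at build
  Ruj <- joint_rot(config$uj$rot)
  Rhj <- joint_rot(config$hj$rot)
  Rcj <- joint_rot(config$cj$rot)
  # motion of each joint expressed in its joint frame
  Muj <- Ruj %*% rot_z(coords[["theta1"]]) %*% rot_y(coords[["phi"]]) %*%
    t(Ruj)
  Mhj <- Rhj %*% rot_z(coords[["theta2"]]) %*% t(Rhj)
  zvec <- as.numeric(Rcj %*% c(0, 0, coords[["z"]] * config$z_scale_m))
  Mcj <- Rcj %*% rot_z(coords[["theta3"]]) %*% t(Rcj)
  rot_about <- function(R, c0) {
    # frame motion: rotate about point c0
    list(R = R, t = as.numeric(c0 - R %*% c0))
  }
  Tuj <- rot_about(Muj, config$uj$center)
  Thj <- rot_about(Mhj, config$hj$center)
  Tcj <- rot_about(Mcj, config$cj$center)
  Tcj$t <- Tcj$t + zvec
  ap_c <- config$ap0$center
  ap_R <- joint_rot(config$ap0$rot)
  # apply CJ, then HJ, then UJ (chain from plate to base)
  app <- function(Tr, p) as.numeric(Tr$R %*% p + Tr$t)
  ctr <- app(Tuj, app(Thj, app(Tcj, ap_c)))
  Rw <- Tuj$R %*% Thj$R %*% Tcj$R %*% ap_R
  world(new_frame(ctr, Rw))
}

#' Restoring wrench of the six-dimensional plate spring
#'
#' Linear diagonal stiffness between two frames: translational stiffness
#' `k_normal` along the plate normal (local x), `k_shear` in the other two
#' translations, rotational stiffness `k_rot` about all axes. Defaults are
#' 90 kN/m, 1 MN/m and 500 Nm/rad.
#'
#' @param f_ap,f_iap `ls_frame`s of the kinematic and dynamic plates.
#' @param k_normal,k_shear,k_rot stiffnesses (N/m, N/m, Nm/rad).
#' @return list with `force_iap`, `torque_iap` (on AP_IAP, global),
#'   `force_ap`, `torque_ap` (equal and opposite), and `normal_force`
#'   (signed spring force along the plate normal; positive = AP_IAP pushed
#'   posteriorly, i.e. the abdominal compression F_AP).
#' @export
frame_spring_wrench <- function(f_ap, f_iap, k_normal = 90e3, k_shear = 1e6,
                                k_rot = 500) {
  dp_local <- as.numeric(t(f_ap$R) %*% (f_iap$origin - f_ap$origin))
  kdiag <- c(k_normal, k_shear, k_shear)
  f_local <- -kdiag * dp_local
  force <- as.numeric(f_ap$R %*% f_local)
  w <- matrix_to_rotvec(t(f_ap$R) %*% f_iap$R)
  torque <- as.numeric(f_ap$R %*% (-k_rot * w))
  # posterior plate displacement (muscle compression of the cavity) makes
  # the restoring force point anteriorly: that magnitude is F_AP
  list(force_iap = force, torque_iap = torque,
       force_ap = -force, torque_ap = -torque,
       normal_force = f_local[1])
}

MMHG_PA <- 133.322387415

#' Intra-abdominal pressure from the abdominal plate force
#'
#' The abdominal cavity is an idealized constant-volume cylinder of
#' diameter `d_ac` and height `h_ac` whose barrel is entwined by the
#' abdominal wall muscles with effectiveness `c_w`. The compressive muscle
#' force `F_AP` on the dynamic plate maps to the cranial diaphragm force
#' \eqn{F_{IAP} = (1/c_w)\, d_{AC}/(4 h_{AC})\, F_{AP}} and the pressure
#' \eqn{p_{IAP} = F_{IAP} / (\pi d_{AC}^2/4)} plus a 4 mmHg resting offset,
#' capped at 200 mmHg. The force acts cranially at the diaphragm center
#' `A_D` and rotates with the thorax.
#'
#' @param f_ap net compressive abdominal muscle force on the plate (N),
#'   clamped at 0 from below.
#' @param cavity list with `d_ac`, `h_ac` (m), `c_w` entwinement fraction,
#'   `offset_mmhg`, `cap_mmhg`.
#' @param thorax_R current thorax rotation matrix (the force direction is
#'   the thorax +z axis).
#' @return list with `p_iap_mmhg`, `f_iap` (N magnitude), `force` (global
#'   force vector on the thorax).
#' @export
compute_iap <- function(f_ap, cavity = default_cavity(), thorax_R = diag(3)) {
  if (cavity$d_ac <= 0 || cavity$h_ac <= 0 || cavity$c_w <= 0 ||
      cavity$c_w > 1)
    stop("invalid abdominal cavity geometry")
  f_ap <- max(f_ap, 0)
  f_iap <- (1 / cavity$c_w) * cavity$d_ac / (4 * cavity$h_ac) * f_ap
  area <- pi * cavity$d_ac^2 / 4
  p <- min(f_iap / area / MMHG_PA + cavity$offset_mmhg, cavity$cap_mmhg)
  # applied diaphragm force is consistent with the total (capped) pressure
  f_applied <- p * MMHG_PA * area
  list(p_iap_mmhg = p, f_iap = min(f_iap, cavity$cap_mmhg * MMHG_PA * area),
       force = as.numeric(thorax_R %*% c(0, 0, f_applied)))
}

#' @rdname compute_iap
#' @export
default_cavity <- function() {
  list(d_ac = 0.24, h_ac = 0.26, c_w = 0.6, offset_mmhg = 4, cap_mmhg = 200,
       a_d_anterior = 0.051)   # A_D application point 5.1 cm anterior of T12
}

#' Unnormalized dynamic time warping distance between two curves
#'
#' Monotone dynamic-programming alignment with L1 local cost and anchored
#' endpoints; the unnormalized distance is the sum of local costs along the
#' optimal warping path.
#'
#' @param a,b numeric vectors (sampled 1-D trajectories).
#' @return non-negative scalar; 0 iff the curves are identical up to
#'   warping.
#' @export
dtw_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 1L) a <- t(a)
  if (nrow(b) == 1L) b <- t(b)
  n <- nrow(a); m <- nrow(b)
  if (!n || !m) stop("empty curve")
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    # L1 local cost; multivariate rows share one warping path
    cost_i <- colSums(abs(a[i, ] - t(b)))
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- cost_i[j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' Synthetic motion-capture marker trajectories of the abdominal plate
#'
#' Drives the abdominal chain with a thorax-angle profile and records the
#' plate marker (and a 60 mm triangle of auxiliary markers around it),
#' optionally adding Gaussian noise. Stands in for skin-marker recordings.
#'
#' @param profile data frame with columns `alpha_x, alpha_y, alpha_z` (deg),
#'   one row per frame.
#' @param config chain configuration (its `coef` are the ground truth).
#' @param sigma marker noise standard deviation (m).
#' @param seed RNG seed (deterministic trajectories per seed).
#' @param marker_local local plate coordinates of the primary marker.
#' @return list of marker trajectories (`LAL41`, `TRI1..3`), each an
#'   n x 3 matrix, plus the input profile.
#' @export
synth_mocap <- function(profile, config = default_chain_config(),
                        sigma = 0, seed = 1,
                        marker_local = c(0.01, 0.05, 0)) {
  set.seed(seed)
  tri <- rbind(TRI1 = marker_local + c(0, 0.06, 0),
               TRI2 = marker_local + c(0, -0.03, 0.052),
               TRI3 = marker_local + c(0, -0.03, -0.052))
  out <- list(LAL41 = matrix(0, nrow(profile), 3),
              TRI1 = matrix(0, nrow(profile), 3),
              TRI2 = matrix(0, nrow(profile), 3),
              TRI3 = matrix(0, nrow(profile), 3))
  for (i in seq_len(nrow(profile))) {
    cc <- chain_coordinates(profile$alpha_x[i], profile$alpha_y[i],
                            profile$alpha_z[i], config)
    ap <- pose_plates(cc, config = config)
    out$LAL41[i, ] <- frame_transform(ap, marker_local)
    for (k in 1:3)
      out[[paste0("TRI", k)]][i, ] <- frame_transform(ap, tri[k, ])
  }
  if (sigma > 0)
    for (nm in names(out))
      out[[nm]] <- out[[nm]] + matrix(stats::rnorm(3 * nrow(profile),
                                                   sd = sigma),
                                      ncol = 3)
  out$profile <- profile
  out
}

#' Fit the abdominal chain polynomial coefficients to marker curves
#'
#' Reproduces the coefficient-fitting protocol: per-direction
#' derivative-free fits (pattern search) of the coefficients governing each
#' motion direction, minimizing the summed unnormalized DTW distances
#' between reference and simulated plate-marker coordinate curves, followed
#' by a combined refinement over all directions.
#'
#' @param curves list of reference marker trajectories per direction:
#'   `flexion`, `extension`, `lateral`, `axial`, each a list with `profile`
#'   and `LAL41` as from [synth_mocap()].
#' @param config starting chain configuration; its coefficients are the
#'   initial values.
#' @param max_iter pattern-search iterations per stage.
#' @param markers marker names entering the cost. The plate marker alone
#'   leaves the rotational joint split unidentifiable under time warping;
#'   the default adds the rigid marker triangle, which pins the plate pose
#'   (see the methods vignette).
#' @return list with fitted `config`, `cost`, and the coefficient table.
#' @export
fit_abdominal_polynomials <- function(curves, config = default_chain_config(),
                                      max_iter = 400L,
                                      markers = c("LAL41", "TRI1", "TRI2",
                                                  "TRI3")) {
  stopifnot(all(c("flexion", "extension", "lateral", "axial") %in%
                  names(curves)))
  coef_vec <- function(cfg) {
    c(t1f1 = cfg$coef$theta1$flexion[["p1"]],
      t1f2 = cfg$coef$theta1$flexion[["p2"]],
      t1e1 = cfg$coef$theta1$extension[["p1"]],
      t1e2 = cfg$coef$theta1$extension[["p2"]],
      phi1 = cfg$coef$phi$flexion[["p1"]],
      t2f1 = cfg$coef$theta2$flexion[["p1"]],
      t2e1 = cfg$coef$theta2$extension[["p1"]],
      zf1 = cfg$coef$z$flexion[["p1"]],
      ze1 = cfg$coef$z$extension[["p1"]],
      t31 = cfg$coef$theta3$flexion[["p1"]])
  }
  vec_coef <- function(v, cfg) {
    cfg$coef$theta1$flexion[["p1"]] <- v[["t1f1"]]
    cfg$coef$theta1$flexion[["p2"]] <- v[["t1f2"]]
    cfg$coef$theta1$extension[["p1"]] <- v[["t1e1"]]
    cfg$coef$theta1$extension[["p2"]] <- v[["t1e2"]]
    cfg$coef$phi$flexion[["p1"]] <- cfg$coef$phi$extension[["p1"]] <-
      v[["phi1"]]
    cfg$coef$theta2$flexion[["p1"]] <- v[["t2f1"]]
    cfg$coef$theta2$extension[["p1"]] <- v[["t2e1"]]
    cfg$coef$z$flexion[["p1"]] <- v[["zf1"]]
    cfg$coef$z$extension[["p1"]] <- v[["ze1"]]
    cfg$coef$theta3$flexion[["p1"]] <- cfg$coef$theta3$extension[["p1"]] <-
      v[["t31"]]
    cfg
  }
  dir_cost <- function(cfg, direction) {
    ref <- curves[[direction]]
    sim <- synth_mocap(ref$profile, cfg, sigma = 0)
    cols <- if (direction %in% c("flexion", "extension")) c(1, 3)
            else 1:3
    mks <- intersect(markers, names(ref))
    # dependent multivariate DTW: all marker components share one warp,
    # so the pacing along the motion constrains the polynomial shape
    A <- do.call(cbind, lapply(mks, function(mk) ref[[mk]][, cols]))
    Bm <- do.call(cbind, lapply(mks, function(mk) sim[[mk]][, cols]))
    s <- dtw_distance(A, Bm)
    if (!is.finite(s)) stop("non-finite DTW cost")
    s
  }
  param_sets <- list(flexion = c("t1f1", "t1f2", "t2f1", "zf1"),
                     extension = c("t1e1", "t1e2", "t2e1", "ze1"),
                     lateral = c("phi1", "t31"),
                     axial = c("phi1"))
  v <- coef_vec(config)
  for (d in names(param_sets)) {
    ps <- param_sets[[d]]
    fn <- function(x) {
      vv <- v; vv[ps] <- x
      dir_cost(vec_coef(vv, config), d)
    }
    # the DTW landscape is rugged: a factorial grid scan locates the
    # global basin before the local pattern search refines within it
    levels <- c(0.7, 0.85, 1, 1.15, 1.3)
    grid <- as.matrix(do.call(expand.grid,
                              rep(list(levels), length(ps))))
    best <- v[ps]; bestc <- fn(best)
    for (gi in seq_len(nrow(grid))) {
      cand <- v[ps] * grid[gi, ]
      cc <- fn(cand)
      if (cc < bestc) { best <- cand; bestc <- cc }
    }
    v[ps] <- nm_rounds(fn, best, max_iter)
  }
  total_cost <- function(x) {
    cfg <- vec_coef(stats::setNames(x, names(v)), config)
    sum(vapply(names(param_sets), function(d) dir_cost(cfg, d), numeric(1)))
  }
  vfit <- nm_rounds(total_cost, v, max_iter)
  v <- stats::setNames(vfit, names(v))
  list(config = vec_coef(v, config), coefficients = v,
       cost = total_cost(v))
}

# restarted Nelder-Mead polish: the DTW cost has narrow curved valleys on
# which coordinate-wise searches stall; a simplex restart from the first
# optimum reliably reaches the basin floor
nm_rounds <- function(fn, x0, max_iter = 400L, rounds = 2L) {
  x <- x0
  if (length(x) == 1L) {
    lo <- min(x * 0.5, x * 1.5); hi <- max(x * 0.5, x * 1.5)
    return(stats::optimize(function(z) fn(z), c(lo, hi),
                           tol = 1e-10)$minimum)
  }
  for (r in seq_len(rounds)) {
    x <- stats::optim(x, fn, method = "Nelder-Mead",
                      control = list(maxit = 5L * max_iter,
                                     reltol = 1e-12))$par
  }
  x
}

# deterministic Hooke-Jeeves pattern search: exploratory coordinate moves
# followed by accelerated pattern moves, with step shrinking on failure
pattern_search <- function(fn, x0, step, max_iter = 200L, shrink = 0.5,
                           tol = 1e-9) {
  x <- x0; f <- fn(x)
  step <- rep(step, length.out = length(x))
  explore <- function(xb, fb) {
    for (k in seq_along(xb)) {
      for (s in c(1, -1)) {
        xt <- xb; xt[k] <- xt[k] + s * step[k]
        ft <- fn(xt)
        if (ft < fb - 1e-15) { xb <- xt; fb <- ft; break }
      }
    }
    list(x = xb, f = fb)
  }
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ex <- explore(x, f)
    if (ex$f < f - 1e-15) {
      # pattern move: keep stepping along the successful direction
      repeat {
        xp <- ex$x + (ex$x - x)
        x <- ex$x; f <- ex$f
        ex2 <- explore(xp, fn(xp))
        if (ex2$f < f - 1e-15) { ex <- ex2 } else break
        it <- it + 1L
        if (it >= max_iter) break
      }
    } else {
      step <- step * shrink
      if (max(abs(step)) < tol) break
    }
  }
  list(par = x, value = f, iterations = it)
}

#' Read / write marker trajectories (TRC and plain CSV)
#'
#' The CSV layout is `time, marker, x, y, z` (long). TRC follows the
#' conventional tab-separated layout with a 5-line header.
#'
#' @param path file path; format by extension (.trc, .csv).
#' @return named list of n x 3 marker matrices plus `time`.
#' @export
read_markers <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path)
    out <- lapply(split(d, d$marker), function(m)
      as.matrix(m[order(m$time), c("x", "y", "z")]))
    out$time <- sort(unique(d$time))
    return(out)
  }
  if (ext == "trc") {
    lines <- readLines(path, warn = FALSE)
    hdr <- strsplit(lines[4], "\t")[[1]]
    markers <- hdr[seq(3, length(hdr), by = 3)]
    markers <- markers[nzchar(markers)]
    dat <- utils::read.delim(text = paste(lines[-(1:5)], collapse = "\n"),
                             header = FALSE)
    out <- list(time = dat[[2]])
    for (k in seq_along(markers)) {
      out[[markers[k]]] <- as.matrix(dat[, (3 * k):(3 * k + 2)])
    }
    return(out)
  }
  stop("unsupported marker format: ", ext)
}

#' @rdname read_markers
#' @param markers named list of n x 3 matrices.
#' @param time time vector (s).
#' @export
write_markers_csv <- function(markers, time, path) {
  nms <- setdiff(names(markers), c("time", "profile"))
  rows <- do.call(rbind, lapply(nms, function(nm)
    data.frame(time = time, marker = nm, x = markers[[nm]][, 1],
               y = markers[[nm]][, 2], z = markers[[nm]][, 3])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
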