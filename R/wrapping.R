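#' Muscle path geometry: via points and obstacle wrapping
#'
#' Muscle fascicle paths are polylines through attachment and via points;
#' designated segments may wrap around smooth auxiliary bodies (cylinders,
#' ellipsoids). Wrapped paths are C0 polylines whose length varies
#' continuously with the body poses.
#'
#' @name paths-wrapping
NULL

#' Tangent-arc-tangent wrap of a path segment around a cylinder
#'
#' Both endpoints must lie outside the cylinder. If the straight segment
#' misses the surface, `NULL` is returned (no contact); otherwise the
#' shortest tangent-arc-tangent geodesic path on the requested side is
#' returned as intermediate points.
#'
#' @param p0,p1 segment endpoints (global, m).
#' @param cylinder list with `center`, `axis` (unit), `radius`, optional
#'   `side` (+1/-1, wrap handedness about the axis; default picks the
#'   shorter path).
#' @param n_arc number of arc points returned.
#' @return matrix of intermediate points (possibly 0 rows) or `NULL` if no
#'   contact.
#' @export
wrap_cylinder <- function(p0, p1, cylinder, n_arc = 8L) {
  a <- cylinder$axis / sqrt(sum(cylinder$axis^2))
  r <- cylinder$radius
  if (r <= 0) stop("cylinder radius must be positive")
  # orthonormal frame perpendicular to the axis
  e1 <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(a, e1)
  to2d <- function(p) {
    d <- p - cylinder$center
    c(sum(d * e1), sum(d * e2), sum(d * a))
  }
  q0 <- to2d(p0); q1 <- to2d(p1)
  n0 <- sqrt(sum(q0[1:2]^2)); n1 <- sqrt(sum(q1[1:2]^2))
  if (n0 <= r || n1 <= r) stop("path endpoint inside wrap cylinder")
  # does the planar segment intersect the circle?
  d2 <- q1[1:2] - q0[1:2]
  tproj <- -sum(q0[1:2] * d2) / sum(d2^2)
  tproj <- min(max(tproj, 0), 1)
  closest <- q0[1:2] + tproj * d2
  if (sqrt(sum(closest^2)) >= r) return(NULL)
  sides <- if (is.null(cylinder$side)) c(1, -1) else cylinder$side
  best <- NULL; bestlen <- Inf
  for (s in sides) {
    phi0 <- atan2(q0[2], q0[1]); phi1 <- atan2(q1[2], q1[1])
    a0 <- acos(min(max(r / n0, -1), 1)); a1 <- acos(min(max(r / n1, -1), 1))
    # departure/arrival tangent points for wrap direction s (+1 = CCW)
    psi0 <- phi0 + s * a0
    psi1 <- phi1 - s * a1
    dpsi <- (s * (psi1 - psi0)) %% (2 * pi)
    arc <- r * dpsi
    l0 <- sqrt(n0^2 - r^2); l1 <- sqrt(n1^2 - r^2)
    len <- l0 + arc + l1
    if (len < bestlen) {
      bestlen <- len
      psis <- psi0 + s * seq(0, dpsi, length.out = n_arc)
      # axial coordinate varies linearly with unrolled path length
      cum <- l0 + r * seq(0, dpsi, length.out = n_arc)
      zfrac <- cum / len
      z <- q0[3] + zfrac * (q1[3] - q0[3])
      pts2 <- cbind(r * cos(psis), r * sin(psis), z)
      best <- sweep(pts2[, 1] %o% e1 + pts2[, 2] %o% e2 + pts2[, 3] %o% a,
                    2, cylinder$center, `+`)
    }
  }
  best
}

inside_ellipsoid <- function(p, ell) {
  q <- as.numeric(t(ell$R) %*% (p - ell$center)) / ell$radii
  sum(q^2) < 1
}

project_ellipsoid <- function(p, ell) {
  # radial projection in the normalized (unit-sphere) space
  q <- as.numeric(t(ell$R) %*% (p - ell$center)) / ell$radii
  q <- q / sqrt(sum(q^2))
  as.numeric(ell$center + ell$R %*% (q * ell$radii))
}

#' Iterative shortest-path wrap of a segment over an ellipsoid
#'
#' Taut-string approximation: a point chain between the endpoints is
#' repeatedly midpoint-smoothed, with points falling inside the ellipsoid
#' projected back to the surface, until displacement per sweep is below
#' `tol`. Returns `NULL` when the straight segment misses the surface.
#'
#' @param p0,p1 endpoints (outside the ellipsoid).
#' @param ellipsoid list with `center`, `R` (3x3 orientation), `radii`.
#' @param n_chain interior chain points.
#' @param tol convergence tolerance (m).
#' @param max_iter sweep limit.
#' @export
wrap_ellipsoid <- function(p0, p1, ellipsoid, n_chain = 15L, tol = 1e-6,
                           max_iter = 2000L) {
  if (inside_ellipsoid(p0, ellipsoid) || inside_ellipsoid(p1, ellipsoid))
    stop("path endpoint inside wrap ellipsoid")
  tt <- seq(0, 1, length.out = n_chain + 2L)[2:(n_chain + 1L)]
  chain <- outer(1 - tt, p0) + outer(tt, p1)
  touches <- apply(chain, 1, inside_ellipsoid, ell = ellipsoid)
  if (!any(touches)) return(NULL)
  for (it in seq_len(max_iter)) {
    moved <- 0
    full <- rbind(p0, chain, p1)
    for (i in seq_len(n_chain)) {
      new <- 0.5 * (full[i, ] + full[i + 2L, ])
      if (inside_ellipsoid(new, ellipsoid))
        new <- project_ellipsoid(new, ellipsoid)
      moved <- max(moved, sqrt(sum((new - chain[i, ])^2)))
      chain[i, ] <- new
      full[i + 1L, ] <- new
    }
    if (moved < tol) break
  }
  on_surface <- apply(chain, 1, function(p) {
    q <- as.numeric(t(ellipsoid$R) %*% (p - ellipsoid$center)) /
      ellipsoid$radii
    abs(sqrt(sum(q^2)) - 1) < 1e-4
  })
  if (!any(on_surface)) return(NULL)
  chain[on_surface, , drop = FALSE]
}

#' Length and endpoint force directions of a fascicle path
#'
#' @param path n x 3 matrix of resolved path points (attachments, via and
#'   wrap points) in order.
#' @return list with `lmt` (m), `dir_origin`, `dir_insertion` (unit vectors
#'   along which tension pulls each attachment, pointing into the path), and
#'   per-segment lengths.
#' @export
path_length_and_direction <- function(path) {
  path <- rbind(path)
  if (nrow(path) < 2L) stop("a path needs at least 2 points")
  seg <- diff(path)
  lens <- sqrt(rowSums(seg^2))
  u1 <- seg[1, ] / lens[1]
  un <- -seg[nrow(seg), ] / lens[length(lens)]
  list(lmt = sum(lens), dir_origin = u1, dir_insertion = un,
       segment_lengths = lens)
}

#' Kinematically slaved pose of the lumbar wrapping body
#'
#' The lumbar wrapping cylinder hangs on a linked hinge + slider joint at
#' the L5 superior articular process. In extension (sagittal L1 rotation
#' < 0) the hinge keeps the angular sum of the vectors S1-L1 and
#' S1-wrapping-body relative to the S1 perpendicular constant, and the
#' slider advances anteriorly 0.54 m per 1 m reduction of the L2-S1
#' z-distance. In flexion the hinge is fixed and the slider advances
#' anteriorly 1.3 m per 1 m anterior displacement of L4.
#'
#' @param state list with current `l1_rot` (sagittal L1 rotation, deg,
#'   relative to reference), `l1_pos`, `l2_pos`, `l4_pos` (global, m).
#' @param ref reference (build) values: `l1_pos`, `l2_pos`, `l4_pos`,
#'   `s1_pos` (joint-relevant sacrum point), `joint_center`.
#' @return list with `hinge_deg` and `slider_m` (anterior +x translation in
#'   the hinge-rotated slider frame).
#' @export
update_lumbar_wrap <- function(state, ref) {
  if (state$l1_rot > 0) {                      # flexion
    hinge <- 0
    slider <- 1.3 * (state$l4_pos[1] - ref$l4_pos[1])
  } else {                                     # extension (or neutral)
    sag_angle <- function(v) atan2(v[1], v[3])  # angle to S1 perpendicular
    th_ref <- sag_angle(ref$l1_pos - ref$s1_pos)
    th_cur <- sag_angle(state$l1_pos - ref$s1_pos)
    # angular sum constant: wrap-body angle compensates the L1 change
    hinge <- -rad2deg(th_cur - th_ref)
    dz <- (ref$l2_pos[3] - ref$s1_pos[3]) - (state$l2_pos[3] - ref$s1_pos[3])
    slider <- 0.54 * dz
  }
  list(hinge_deg = hinge, slider_m = slider)
}

# world pose of the lumbar wrap cylinder given hinge/slider values
lumbar_wrap_pose <- function(wrap0, joint_center, hinge_deg, slider_m) {
  Rh <- rot_y(hinge_deg)
  ctr <- joint_center + as.numeric(Rh %*% (wrap0$center - joint_center)) +
    as.numeric(Rh %*% c(slider_m, 0, 0))
  list(center = ctr, axis = as.numeric(Rh %*% wrap0$axis),
       radius = wrap0$radius)
}
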