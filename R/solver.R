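#' Tracking controller and quasi-static / transient solvers
#'
#' The muscle redundancy problem is solved per step by a bounded quadratic
#' program over the 24 excitation groups (12 per side): minimize the
#' weighted tracked-coordinate error plus the squared group excitations
#' (weight 0.667 relative to the thorax target) plus the excitation rate
#' term (weight 0.3e-4), subject to 0 <= e <= 1. In quasi-static mode the
#' model is driven through target increments, solving full static
#' equilibrium (Newton on the residual) and re-linearizing the excitation
#' sensitivities at each iteration.
#'
#' @name controller
NULL

# ---- bounded quadratic programming -------------------------------------

#' Solve a strictly convex box-constrained QP
#'
#' Minimizes `0.5 t(x) H x + t(g) x` subject to `lb <= x <= ub` with a
#' primal active-set iteration (exact solves on the free set).
#'
#' @param H symmetric positive-definite matrix.
#' @param g linear term.
#' @param lb,ub bounds.
#' @param tol bound/multiplier tolerance.
#' @export
solve_box_qp <- function(H, g, lb = 0, ub = 1, tol = 1e-10) {
  n <- length(g)
  lb <- rep(lb, length.out = n); ub <- rep(ub, length.out = n)
  x <- pmin(pmax(rep(0, n), lb), ub)
  status <- integer(n)               # 0 free, -1 at lower, +1 at upper
  status[x <= lb] <- -1L; status[x >= ub] <- 1L
  for (it in seq_len(20L * n + 20L)) {
    free <- status == 0L
    if (any(free)) {
      xf <- x
      rhs <- -g[free] - if (any(!free))
        as.numeric(H[free, !free, drop = FALSE] %*% x[!free]) else 0
      xf[free] <- solve(H[free, free, drop = FALSE], rhs)
      inside <- xf[free] >= lb[free] - tol & xf[free] <= ub[free] + tol
      if (!all(inside)) {
        # partial step to the first blocking bound
        d <- xf - x
        alpha <- 1; blk <- 0L; side <- 0L
        for (k in which(free)) {
          if (d[k] > tol) {
            a <- (ub[k] - x[k]) / d[k]
            if (a < alpha) { alpha <- a; blk <- k; side <- 1L }
          } else if (d[k] < -tol) {
            a <- (lb[k] - x[k]) / d[k]
            if (a < alpha) { alpha <- a; blk <- k; side <- -1L }
          }
        }
        x <- x + alpha * d
        if (blk > 0L) {
          x[blk] <- if (side > 0L) ub[blk] else lb[blk]
          status[blk] <- side
        }
        next
      }
      x[free] <- pmin(pmax(xf[free], lb[free]), ub[free])
    }
    # KKT check on the bound multipliers; release the worst violator
    grad <- as.numeric(H %*% x + g)
    viol_lb <- status == -1L & grad < -tol
    viol_ub <- status == 1L & grad > tol
    if (!any(viol_lb) && !any(viol_ub)) break
    cand <- which(viol_lb | viol_ub)
    worst <- cand[which.max(abs(grad[cand]))]
    status[worst] <- 0L
  }
  x
}

#' Tracking QP for the muscle excitation groups
#'
#' One controller update: given the linearized sensitivity `S` of the
#' tracked coordinates to the group excitations, returns the excitations
#' minimizing
#' `sum w_i (c_i + S (e - e_prev) - c*_i)^2 + w_exc ||e||^2 +
#'  w_rate ||(e - e_prev)/dt||^2` subject to `0 <= e <= 1`.
#'
#' @param S n_coord x n_group sensitivity matrix.
#' @param c_now,c_target current and target tracked coordinates.
#' @param e_prev previous excitations.
#' @param w coordinate weights (thorax components 15, vertebrae 1).
#' @param w_exc,w_rate excitation and rate-term weights.
#' @param dt step duration (s) for the rate term.
#' @export
tracking_qp <- function(S, c_now, c_target, e_prev, w,
                        w_exc = 0.667, w_rate = 0.3e-4, dt = 0.01) {
  Wd <- w
  d <- c_now - c_target - as.numeric(S %*% e_prev)
  H <- 2 * (crossprod(S * sqrt(Wd)) + diag(w_exc + w_rate / dt^2,
                                           ncol(S)))
  g <- 2 * (as.numeric(crossprod(S, Wd * d)) - (w_rate / dt^2) * e_prev)
  e <- solve_box_qp(H, g, 0, 1)
  stats::setNames(e, colnames(S))
}

#' C1 smoothstep load ramp
#'
#' `3 t^2 - 2 t^3` interpolation of a force magnitude between `t0` and
#' `t1`.
#' @param t time (s).
#' @param t0,t1 ramp start and end (`t0 < t1`).
#' @param f_final final magnitude.
#' @export
smoothstep_load <- function(t, t0, t1, f_final) {
  if (t0 >= t1) stop("t0 must be < t1")
  s <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  f_final * (3 * s^2 - 2 * s^3)
}

#' Distribute a thorax target rotation over the vertebral target frames
#'
#' Fixed segmental rotation contributions (a spinal rhythm) assign each
#' tracked vertebra the cumulative caudal share of the thorax target
#' rotation.
#'
#' @param alpha_y_star thorax target rotation (deg).
#' @param contributions named or ordered shares (%) for levels L1L2..L5S1;
#'   must sum to 100 +- 0.1.
#' @return named vector of absolute target rotations for L1 (= thorax) to
#'   L5 (deg).
#' @export
distribute_rhythm <- function(alpha_y_star, contributions) {
  if (abs(sum(contributions) - 100) > 0.1)
    stop("rhythm contributions must sum to 100% (got ",
         round(sum(contributions), 3), ")")
  cum <- cumsum(contributions) / 100
  nlev <- length(contributions)
  # vertebra k carries the share below level k-1/k
  rots <- alpha_y_star * c(1, 1 - cum[-nlev])
  stats::setNames(rots, paste0("L", seq_len(nlev)))
}

# ---- state / DOF plumbing ----------------------------------------------

state_get_q <- function(model, state) {
  dyn <- dynamic_body_names(model)
  unlist(lapply(dyn, function(b) {
    f0 <- model$bodies[[b]]$frame0; f <- state$frames[[b]]
    c(f$origin - f0$origin, matrix_to_rotvec(f$R %*% t(f0$R)))
  }))
}

state_set_q <- function(model, state, q) {
  dyn <- dynamic_body_names(model)
  for (bi in seq_along(dyn)) {
    b <- dyn[bi]
    f0 <- model$bodies[[b]]$frame0
    tq <- q[(6 * bi - 5):(6 * bi - 3)]
    wq <- q[(6 * bi - 2):(6 * bi)]
    state$frames[[b]] <- new_frame(f0$origin + tq,
                                   rotvec_to_matrix(wq) %*% f0$R)
  }
  state
}

# tracked coordinates: thorax sagittal rotation (deg), thorax CoR
# x-translation (cm), L2..L5 sagittal rotations (deg)
tracked_coords <- function(model, state) {
  ang <- measure_angles(model, state)
  ref <- model$reference
  cor_local <- model$tracking$cor_local
  if (is.null(cor_local)) {
    corg <- model$config$controller$cor
    cor_local <- point_in_body(corg, model$bodies$thorax$frame0)
  }
  x_ref <- if (!is.null(ref)) ref$cor_x else
    frame_transform(model$bodies$thorax$frame0, cor_local)[1]
  x_now <- frame_transform(state$frames$thorax, cor_local)[1]
  c(thorax_rot = unname(ang$alpha["y"]),
    thorax_x = 100 * (x_now - x_ref),
    L2 = unname(ang$rotation["L2"]), L3 = unname(ang$rotation["L3"]),
    L4 = unname(ang$rotation["L4"]), L5 = unname(ang$rotation["L5"]))
}

tracked_weights <- function(model) {
  ct <- model$config$controller
  c(ct$w_thorax, ct$w_thorax, rep(ct$w_vertebra, 4))
}

# ---- quasi-static equilibrium ------------------------------------------

# forward-difference stiffness of the residual w.r.t. the rigid DOFs
residual_stiffness <- function(model, state, wrap_cache, loads, r0 = NULL,
                               h_t = 1e-6, h_r = 1e-6) {
  q0 <- state_get_q(model, state)
  if (is.null(r0)) r0 <- spine_residual(model, state, wrap_cache, loads)$r
  n <- length(q0)
  K <- matrix(0, n, n)
  for (k in seq_len(n)) {
    h <- if ((k - 1) %% 6 < 3) h_t else h_r
    qp <- q0; qp[k] <- qp[k] + h
    rp <- spine_residual(model, state_set_q(model, state, qp), wrap_cache,
                         loads)$r
    K[, k] <- -(rp - r0) / h
  }
  K
}

#' Solve the model to a static state at fixed excitations
#'
#' Damped Newton iteration on the quasi-static residual. Convergence
#' requires the net wrench on every dynamic body below `tol_force` /
#' `tol_torque`.
#'
#' @param model a `spine_model`.
#' @param state starting state (its excitations are held fixed).
#' @param loads external load list (see [spine_residual()]).
#' @param tol_force,tol_torque static-state tolerances (N, Nm).
#' @param max_iter Newton iteration limit.
#' @param wrap_cache frozen wrap-point cache; resolved at entry when `NULL`.
#' @return list with converged `state`, `K` (last stiffness), `residual`,
#'   `converged`.
#' @export
run_to_static <- function(model, state, loads = list(), tol_force = 0.5,
                          tol_torque = 0.05, max_iter = 40L,
                          wrap_cache = NULL, K = NULL) {
  if (is.null(wrap_cache)) wrap_cache <- resolve_wrap_points(model, state)
  q <- state_get_q(model, state)
  res <- spine_residual(model, state, wrap_cache, loads)
  rnorm_of <- function(r) {
    if (any(!is.finite(r))) return(Inf)
    rf <- matrix(r, nrow = 6)
    max(apply(rf, 2, function(col) max(abs(col[1:3]) / tol_force,
                                       abs(col[4:6]) / tol_torque)))
  }
  best <- rnorm_of(res$r)
  # row scaling makes forces and torques commensurate in the merit norm
  nscale <- rep(c(1, 1, 1, tol_force / tol_torque, tol_force / tol_torque,
                  tol_force / tol_torque), length.out = length(res$r))
  merit <- function(r) sum((r * nscale)^2)
  mbest <- merit(res$r)
  lambda <- 1e-4
  fresh <- FALSE
  for (it in seq_len(max_iter)) {
    if (best < 1) break
    if (is.null(K)) {
      K <- residual_stiffness(model, state, wrap_cache, loads, res$r)
      fresh <- TRUE
    }
    # Levenberg-Marquardt on 0.5 ||scaled r||^2: guaranteed descent even
    # where the tangent stiffness is indefinite (saddle equilibria under
    # compressive muscle preload)
    A <- nscale * K                      # row-scaled Jacobian (of -r)
    AtA <- crossprod(A)
    g <- as.numeric(crossprod(A, nscale * res$r))
    D <- diag(pmax(diag(AtA), 1e-8))
    improved <- FALSE
    for (ls in 1:10) {
      dq <- tryCatch(solve(AtA + lambda * D, g), error = function(e) NULL)
      if (!is.null(dq)) {
        st <- state_set_q(model, state, q + dq)
        rt <- tryCatch(spine_residual(model, st, wrap_cache, loads),
                       error = function(e) NULL)
        if (!is.null(rt) && all(is.finite(rt$r)) &&
            merit(rt$r) < mbest * (1 - 1e-6)) {
          q <- q + dq; state <- st; res <- rt
          mbest <- merit(rt$r); best <- rnorm_of(rt$r)
          lambda <- max(lambda / 3, 1e-8)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * 8
      if (lambda > 1e12) break
    }
    if (!improved) {
      if (!fresh) { K <- NULL; next }  # refresh a reused stiffness
      break
    }
    if (it %% 6L == 0L && best > 10) { K <- NULL; fresh <- FALSE }
  }
  if (is.null(K))
    K <- residual_stiffness(model, state, wrap_cache, loads, res$r)
  if (!is.null(res$plate_frame)) state$frames$ap_iap <- res$plate_frame
  list(state = state, K = K, residual = res, converged = best < 1,
       rnorm = best)
}

#' One quasi-static controller increment
#'
#' Joint Newton iteration on body poses and group excitations. At fixed
#' excitations the upright spine is buckling-unstable (the tangent
#' stiffness is indefinite), so poses and excitations must be advanced
#' together, exactly as the closed-loop forward dynamics does: each
#' iteration linearizes the force balance, eliminates the pose step
#' through the stiffness, solves the tracking box-QP for the excitation
#' step, and applies both under a trust region. Converged when the net
#' wrench on every body is below tolerance and the excitations are
#' stationary.
#'
#' @param model a `spine_model`.
#' @param state current state.
#' @param targets named tracked-coordinate targets (see
#'   `tracked_coords`).
#' @param loads external loads.
#' @param dt pseudo time step for the controller rate term (s).
#' @param max_outer iteration limit.
#' @param K optional starting stiffness (reused across increments).
#' @return list with `state`, `converged`, `e`, `K`, `residual`.
#' @export
controller_increment <- function(model, state, targets, loads = list(),
                                 dt = 0.1, max_outer = 30L, K = NULL) {
  wrap_cache <- resolve_wrap_points(model, state)
  w <- tracked_weights(model)
  ct <- model$config$controller
  tol_force <- 0.5; tol_torque <- 0.05
  rnorm_of <- function(r) {
    if (any(!is.finite(r))) return(Inf)
    rf <- matrix(r, nrow = 6)
    max(apply(rf, 2, function(col) max(abs(col[1:3]) / tol_force,
                                       abs(col[4:6]) / tol_torque)))
  }
  res <- spine_residual(model, state, wrap_cache, loads)
  nscale <- rep(c(1, 1, 1, 10, 10, 10), length.out = length(res$r))
  merit_of <- function(r, st) {
    cerr <- tracked_coords(model, st) - targets[names(tracked_coords(model,
                                                                     st))]
    sum((nscale * r)^2) + 100 * sum(w * cerr^2)
  }
  mcur <- merit_of(res$r, state)
  fresh <- FALSE
  delta <- Inf
  for (it in seq_len(max_outer)) {
    if (rnorm_of(res$r) < 1 && delta < 2e-4) break
    if (is.null(K)) {
      K <- residual_stiffness(model, state, wrap_cache, loads, res$r)
      fresh <- TRUE
    }
    B <- residual_excitation_jacobian(model, state, wrap_cache)
    Ki <- tryCatch(solve(K), error = function(e)
      solve(K + diag(1e-2, nrow(K))))
    dq0 <- as.numeric(Ki %*% res$r)
    X <- Ki %*% B
    q <- state_get_q(model, state)
    Jc <- fd_jacobian(function(qv)
      tracked_coords(model, state_set_q(model, state, qv)), q, h = 1e-7)
    S <- Jc %*% X
    # mirror-symmetric model + mirror-even tracked coordinates: paired
    # left/right sensitivity columns are theoretically equal; averaging
    # removes finite-difference noise that would otherwise excite the
    # soft left-minus-right excitation direction
    if (!identical(model$config$controller$symmetrize, FALSE)) {
      cn <- colnames(B)
      rgt <- grep("_R$", cn)
      lft <- match(sub("_R$", "_L", cn[rgt]), cn)
      if (!anyNA(lft)) {
        avg <- (S[, rgt, drop = FALSE] + S[, lft, drop = FALSE]) / 2
        S[, rgt] <- avg; S[, lft] <- avg
      }
    }
    # predicted tracked coordinates after the pure force-balance step
    c0 <- tracked_coords(model, state) + as.numeric(Jc %*% dq0)
    e_now <- state$e[colnames(B)]
    e_new <- tracking_qp(S, c0, targets[names(c0)], as.numeric(e_now), w,
                         ct$w_excitation, ct$w_rate, dt)
    de <- e_new - e_now
    dq <- dq0 + as.numeric(X %*% de)
    # trust region on the combined step
    dqm <- matrix(dq, nrow = 6)
    tt <- min(1,
              0.02 / max(abs(dqm[1:3, ]), 1e-12),
              0.10 / max(abs(dqm[4:6, ]), 1e-12),
              0.30 / max(abs(de), 1e-12))
    accepted <- FALSE
    for (ls in 1:8) {
      st <- state_set_q(model, state, q + tt * dq)
      st$e[names(e_new)] <- e_now + tt * de
      rt <- tryCatch(spine_residual(model, st, wrap_cache, loads),
                     error = function(e) NULL)
      if (!is.null(rt) && all(is.finite(rt$r))) {
        mt <- merit_of(rt$r, st)
        if (mt < mcur * (1 + 1e-9) || ls == 8L) {
          state <- st; res <- rt; mcur <- mt
          delta <- max(abs(tt * de))
          accepted <- TRUE
          break
        }
      }
      tt <- tt / 2
    }
    if (!accepted) {
      if (!fresh) { K <- NULL; next }
      break
    }
    if (it %% 5L == 0L) {
      K <- NULL
      wrap_cache <- resolve_wrap_points(model, state)
      res <- spine_residual(model, state, wrap_cache, loads)
      mcur <- merit_of(res$r, state)
    }
  }
  if (!is.null(res$plate_frame)) state$frames$ap_iap <- res$plate_frame
  conv <- rnorm_of(res$r) < 1 && delta < 2e-3
  if (is.null(K))
    K <- residual_stiffness(model, state, wrap_cache, loads, res$r)
  list(state = state, converged = conv, e = state$e, K = K,
       residual = res, rnorm = rnorm_of(res$r))
}

#' Establish the gravity-settled upright reference posture
#'
#' Ramps gravity to its full value under controller action, performs the
#' small 2 degree thorax excursion and return, and stores the resulting
#' vertebral orientations as the upright reference (alpha_y = 0).
#'
#' @param model a `spine_model`.
#' @param gravity_steps gravity ramp fractions.
#' @param excursion_deg excursion amplitude (deg).
#' @return list with updated `model` (reference set) and settled `state`.
#' @export
settle <- function(model, gravity_steps = c(0.4, 1), excursion_deg = 2) {
  state <- neutral_state(model)
  targets0 <- c(thorax_rot = 0, thorax_x = 0, L2 = 0, L3 = 0, L4 = 0,
                L5 = 0)
  K <- NULL
  for (gsc in gravity_steps) {
    state$gravity_scale <- gsc
    inc <- controller_increment(model, state, targets0, K = K)
    state <- inc$state; K <- inc$K
  }
  if (excursion_deg != 0) {
    rhythm <- rep(20, 5)
    for (a in c(excursion_deg, 0)) {
      tg <- rhythm_targets(a, rhythm)
      inc <- controller_increment(model, state, tg, K = K)
      state <- inc$state; K <- inc$K
    }
  }
  cor_local <- point_in_body(model$config$controller$cor,
                             model$bodies$thorax$frame0)
  model$tracking <- list(cor_local = cor_local)
  model$reference <- list(frames = state$frames,
                          cor_x = frame_transform(state$frames$thorax,
                                                  cor_local)[1],
                          e = state$e)
  list(model = model, state = state)
}

#' Tracked-coordinate targets for a thorax rotation under a rhythm
#'
#' Builds the named target vector (thorax rotation and x-translation plus
#' the L2..L5 rotations) for a thorax target angle distributed over the
#' vertebral target frames by the given segmental contributions.
#' @param alpha_y_star thorax target rotation (deg).
#' @param contributions level shares (%), length 5, summing to 100.
#' @export
rhythm_targets <- function(alpha_y_star, contributions) {
  rots <- distribute_rhythm(alpha_y_star, contributions)
  c(thorax_rot = alpha_y_star, thorax_x = 0,
    L2 = unname(rots["L2"]), L3 = unname(rots["L3"]),
    L4 = unname(rots["L4"]), L5 = unname(rots["L5"]))
}

# ---- transient integration ---------------------------------------------

#' First-order implicit (backward Euler) transient step
#'
#' Updates body velocities and poses of the dynamic bodies with an implicit
#' first-order scheme: velocities solve
#' `M (v+ - v)/dt = f(q + dt v+, v+)` by Newton iteration on the combined
#' update, then poses advance with the new velocities. With all rigid
#' couplings composed kinematically there are no bilateral constraint
#' multipliers.
#'
#' @param model a `spine_model`.
#' @param state current state (with `vel`).
#' @param dt step size (s), `<= 0.01`.
#' @param loads external loads.
#' @param damping artificial uniform viscous damping (Ns/m and Nms/rad) on
#'   body velocities, stabilizing the stiff muscle-FE coupling.
#' @return advanced state.
#' @export
step <- function(model, state, dt = 0.01, loads = list(), damping = 20) {
  if (dt > 0.01 + 1e-12) stop("maximum step size is 0.01 s")
  dyn <- dynamic_body_names(model)
  nb <- length(dyn)
  Mdiag <- unlist(lapply(dyn, function(b) {
    bd <- model$bodies[[b]]
    c(rep(max(bd$mass, 1e-4), 3), pmax(diag(bd$inertia), 1e-7))
  }))
  v0 <- unlist(lapply(dyn, function(b) c(state$vel[[b]]$v,
                                         state$vel[[b]]$w)))
  q0 <- state_get_q(model, state)
  wrap_cache <- resolve_wrap_points(model, state)
  g <- function(v) {
    qn <- q0 + dt * v
    st <- state_set_q(model, state, qn)
    r <- spine_residual(model, st, wrap_cache, loads)$r
    Mdiag * (v - v0) / dt - r + damping * v
  }
  v <- v0
  for (it in 1:30) {
    gv <- g(v)
    if (max(abs(gv)) < 1e-6) break
    J <- fd_jacobian(g, v, h = 1e-7)
    dv <- tryCatch(solve(J, -gv), error = function(e) NULL)
    if (is.null(dv)) dv <- -gv / (Mdiag / dt + damping)
    # backtracking on the implicit residual
    stp <- 1; g0 <- max(abs(gv))
    repeat {
      vn <- v + stp * dv
      if (max(abs(g(vn))) < g0 || stp < 1 / 64) { v <- vn; break }
      stp <- stp / 2
    }
  }
  state <- state_set_q(model, state, q0 + dt * v)
  for (bi in seq_along(dyn)) {
    b <- dyn[bi]
    state$vel[[b]] <- list(v = v[(6 * bi - 5):(6 * bi - 3)],
                           w = v[(6 * bi - 2):(6 * bi)])
  }
  state$time <- state$time + dt
  state
}
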