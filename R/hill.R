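#' Hill-type musculotendon model with rigid tendons
#'
#' Muscle fascicles are tension-only force actuators with normalized
#' active/passive force-length and force-velocity curves and a rigid
#' (inextensible) tendon, so the fiber state is algebraic in the
#' musculotendon length. The standard closed-form curve set is used
#' (tri-Gaussian active force-length, exponential passive force-length,
#' logarithmic force-velocity), normalized so that `active_fl(1) = 1` and
#' `force_velocity(0) = 1` exactly.
#'
#' @name hill-curves
NULL

afl_raw <- function(lt) {
  b1 <- c(0.814483478343008, 0.433004984392647, 0.1)
  b2 <- c(1.055033428970575, 0.716775413397760, 1.0)
  b3 <- c(0.162384573599574, -0.029947116970696, 0.353553390593274)
  b4 <- c(0.063303448465465, 0.200356847296188, 0.0)
  out <- 0
  for (i in 1:3) out <- out + b1[i] * exp(-0.5 * (lt - b2[i])^2 /
                                            (b3[i] + b4[i] * lt)^2)
  out
}

fv_raw <- function(vt) {
  d1 <- -0.318323436899127; d2 <- -8.149156043475250
  d3 <- -0.374121508647863; d4 <- 0.885644059915004
  d1 * log((d2 * vt + d3) + sqrt((d2 * vt + d3)^2 + 1)) + d4
}

#' @rdname hill-curves
#' @param l_tilde fiber length normalized by optimal fiber length.
#' @return normalized force factor (dimensionless, >= 0).
#' @export
active_fl <- function(l_tilde) pmax(afl_raw(l_tilde) / afl_raw(1), 0)

#' @rdname hill-curves
#' @param v_tilde fiber velocity normalized by the maximum contraction
#'   velocity (positive = lengthening).
#' @export
force_velocity <- function(v_tilde) pmax(fv_raw(v_tilde) / fv_raw(0), 0)

#' @rdname hill-curves
#' @param kpe,e0 passive curve shape and reference strain; defaults give an
#'   exponential toe reaching 1 at 60 % fiber strain. The curve is C1 with
#'   zero slope at slack (`l_tilde = 1`), so force and stiffness vanish
#'   together at engagement.
#' @export
passive_fl <- function(l_tilde, kpe = 4, e0 = 0.6) {
  g <- pmax((l_tilde - 1) / e0, 0)
  (exp(kpe * g) - 1 - kpe * g) / (exp(kpe) - 1 - kpe)
}

#' Musculotendon parameter set
#'
#' @param pcsa_ref reference physiological cross-sectional area (cm^2).
#' @param k_spec maximum specific muscle tension K (N/cm^2).
#' @param b,b_ref subject and reference body mass (kg).
#' @param lmt,lmt_ref musculotendon length in the neutral posture of the
#'   subject and reference model (m).
#' @param l_opt optimal fiber length (m).
#' @param pennation pennation angle (deg), `0 <= pennation < 90`.
#' @param tendon_slack tendon slack length (m).
#' @param vmax maximum contraction velocity (optimal lengths / s).
#' @param damping parallel viscosity on normalized fiber velocity.
#' @return list of class `mt_params` including the scaled maximum isometric
#'   force `f0`.
#' @export
mt_params <- function(pcsa_ref, k_spec = 100, b = 90, b_ref = 90,
                      lmt, lmt_ref = lmt, l_opt, pennation = 0,
                      tendon_slack = max(lmt - l_opt * cos(deg2rad(pennation)),
                                         0),
                      vmax = 10, damping = 0.01) {
  if (pcsa_ref <= 0) stop("pcsa_ref must be > 0")
  if (pennation < 0 || pennation >= 90) stop("pennation must be in [0, 90)")
  if (l_opt <= 0 || lmt <= 0 || lmt_ref <= 0) stop("lengths must be > 0")
  p <- list(pcsa_ref = pcsa_ref, k_spec = k_spec, f0_ref = pcsa_ref * k_spec,
            b = b, b_ref = b_ref, lmt_neutral = lmt, lmt_ref = lmt_ref,
            l_opt = l_opt, pennation = pennation,
            tendon_slack = tendon_slack, vmax = vmax, damping = damping)
  p$f0 <- scale_f0(p)
  class(p) <- "mt_params"
  p
}

#' Scale the maximum isometric muscle force to the subject
#'
#' Muscle volume is taken proportional to body mass and fiber length
#' proportional to musculotendon length, giving
#' \eqn{F_0 = F_{0,ref} (b/b_{ref}) (l^{MT}_{ref}/l^{MT})}.
#'
#' @param params an `mt_params` list (uses `f0_ref`, `b`, `b_ref`,
#'   `lmt_neutral`, `lmt_ref`).
#' @return scaled maximum isometric force (N).
#' @export
scale_f0 <- function(params) {
  if (params$lmt_neutral == 0) stop("musculotendon length must be non-zero")
  params$f0_ref * (params$b / params$b_ref) *
    (params$lmt_ref / params$lmt_neutral)
}

#' Tension of one fascicle from activation and musculotendon kinematics
#'
#' Rigid-tendon fiber kinematics with a fixed-width pennation model:
#' the projected fiber length is `lmt - tendon_slack`, and
#' \eqn{F = F_0 (a\,f_l(\tilde l) f_v(\tilde v) + f_p(\tilde l) +
#' \beta \tilde v) \cos\alpha}, clamped tension-only.
#'
#' @param a activation in `[0, 1]` (resting tone already applied).
#' @param lmt current musculotendon length (m).
#' @param vmt current lengthening velocity (m/s).
#' @param params an `mt_params`.
#' @return scalar tension (N), always `>= 0`.
#' @export
fascicle_force <- function(a, lmt, vmt = 0, params) {
  h <- params$l_opt * sin(deg2rad(params$pennation))   # fixed fiber width
  lproj <- lmt - params$tendon_slack
  lmin <- 0.01 * params$l_opt
  clamped <- lproj < lmin
  lproj <- pmax(lproj, lmin)
  lM <- sqrt(lproj^2 + h^2)
  cosp <- lproj / lM
  lt <- lM / params$l_opt
  vt <- (vmt * cosp) / (params$l_opt * params$vmax)
  Fn <- a * active_fl(lt) * force_velocity(vt) + passive_fl(lt) +
    params$damping * vt
  F <- params$f0 * pmax(Fn, 0) * cosp
  attr(F, "fiber_clamped") <- clamped
  F
}

#' Apply a resting muscle tone to a model
#'
#' The effective excitation of every fascicle group is
#' `max(controller excitation, tone)`; a small tone (default 0.1 %)
#' stabilizes the unloaded model.
#'
#' @param model a `spine_model`.
#' @param tone resting tone in `[0, 0.05]`.
#' @export
apply_resting_tone <- function(model, tone = 0.001) {
  if (tone < 0 || tone > 0.05) stop("tone must be in [0, 0.05]")
  model$resting_tone <- tone
  model
}
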