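#' Calibration and validation experiment protocols
#'
#' The validation plan drives the settled model through 13 sagittal load
#' cases (upright to 30 degree flexion and 10 degree extension, with hand
#' loads up to 200 N), extracting intradiscal pressures of the three caudal
#' levels, the intra-abdominal pressure, muscle group forces, and
#' intervertebral rotations at each converged static state.
#'
#' @name experiments
NULL

#' The validation load-case table
#'
#' 13 sagittal load cases: thorax target angle (deg), external load (N)
#' and its lever arm from the origin (cm) in the loaded static posture.
#' @return data frame with `id`, `alpha`, `f_load`, `l_load`, `with_ta`.
#' @export
load_case_table <- function() {
  data.frame(
    id = c("N0_1", "N0_2", "N0_3", "N0_4", "N0_5",
           "F10_1", "F10_2", "F20_1", "F20_2",
           "F30_1", "F30_2", "F30_3", "E10_1"),
    alpha = c(0, 0, 0, 0, 0, 10, 10, 20, 20, 30, 30, 30, -10),
    f_load = c(0, 80, 100, 200, 200, 0, 100, 0, 100, 0, 80, 100, 0),
    l_load = c(NA, 62, 4, 19, 44, NA, 10.5, NA, 16.6, NA, 70, 22.8, NA),
    stringsAsFactors = FALSE)
}

#' Segmental rhythm tables R1-R7
#'
#' Fixed segmental target-frame rotation contributions (% of the thorax
#' rotation per level, L1L2..L5S1). R1 is the equal-share rhythm and R5 the
#' rhythm used for validation; the remaining rows are synthetic stand-ins
#' following reported in vivo distributions' qualitative shapes (see the
#' `note` column of the shipped CSV).
#' @return named list of length-5 contribution vectors.
#' @export
rhythm_tables <- function() {
  d <- utils::read.csv(system.file("extdata", "rhythms.csv",
                                   package = "lumbosim"))
  out <- lapply(seq_len(nrow(d)), function(i)
    unlist(d[i, c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1")]))
  names(out) <- d$rhythm
  out
}

#' Sagittal tracking error
#'
#' \eqn{\Delta\alpha_y = |\alpha_y^* - \alpha_y|}: absolute rotational
#' deviation between the thorax target frame and the thorax, both relative
#' to the settled upright reference.
#' @param alpha_star target rotation (deg).
#' @param alpha achieved rotation (deg).
#' @export
tracking_error <- function(alpha_star, alpha) abs(alpha_star - alpha)

muscle_group_forces <- function(model, aux) {
  f <- model$muscles$fasc
  byg <- rowsum(aux$tension, f$group)
  g <- stats::setNames(as.numeric(byg), rownames(byg))
  c(g, ES = sum(g[c("IT", "IL", "LT", "LL")], na.rm = TRUE),
    AM = sum(g[c("IO", "EO", "RA")], na.rm = TRUE))
}

# thorax-fixed application point for a vertical hand load: placed so that
# its global lever from the origin equals l_load (cm) in the target posture
load_point_local <- function(model, alpha_star, l_load_cm) {
  ref <- model$reference
  Rstar <- rot_y(alpha_star) %*% ref$frames$thorax$R
  cor_w <- c(ref$cor_x, 0, model$config$controller$cor[3])
  org_star <- cor_w + as.numeric((Rstar %*% t(ref$frames$thorax$R)) %*%
                                   (ref$frames$thorax$origin - cor_w))
  p_world <- c(l_load_cm / 100, 0, model$config$load$shoulder_z)
  as.numeric(t(Rstar) %*% (p_world - org_star))
}

#' Run one validation load case on a settled model
#'
#' Ramps the thorax target to the case angle (distributed over the
#' vertebral targets by the validation rhythm), then ramps the external
#' load with a smoothstep, and extracts the biomechanical responses at the
#' converged static state.
#'
#' @param model settled `spine_model` (see [settle()]).
#' @param state settled state.
#' @param case one row of [load_case_table()] (or a list with the same
#'   fields).
#' @param rhythm level contributions (%), default the validation rhythm R5.
#' @param with_ta include the transversus abdominis group; `FALSE` removes
#'   TA from the recruitable set (its excitation is fixed at zero).
#' @param max_step_deg target ramp increment (deg).
#' @param K optional starting stiffness (reused across cases).
#' @return a `case_result` list: `idp_mpa` (all levels), `iap_mmhg`,
#'   `group_forces_n`, `ivr_deg`, `tracking_error_deg`, `converged`.
#' @export
run_load_case <- function(model, state, case, rhythm = rhythm_tables()$R5,
                          with_ta = TRUE, max_step_deg = 5, K = NULL) {
  if (is.null(model$reference)) stop("model must be settled first")
  if (!with_ta) model <- drop_ta(model)
  state$e <- state$e[model$muscles$group_names]
  state$e[is.na(state$e)] <- 0
  names(state$e) <- model$muscles$group_names
  alpha <- case$alpha
  steps <- if (alpha == 0) numeric(0) else
    seq(0, alpha, by = sign(alpha) * max_step_deg)[-1]
  if (length(steps) && steps[length(steps)] != alpha)
    steps <- c(steps, alpha)
  if (!length(steps)) steps <- 0
  inc <- NULL
  for (a in steps) {
    tg <- rhythm_targets(a, rhythm)
    inc <- controller_increment(model, state, tg, K = K)
    state <- inc$state; K <- inc$K
  }
  tg <- rhythm_targets(alpha, rhythm)
  loads <- list()
  if (!is.na(case$l_load) && case$f_load > 0) {
    pl <- load_point_local(model, alpha, case$l_load)
    # ramp the load with smoothstep sampling; more increments for larger
    # applied moments
    moment <- case$f_load * case$l_load / 100
    nstep <- max(2L, ceiling(moment / 25))
    for (frac in smoothstep_load(seq_len(nstep) / nstep, 0, 1, 1)) {
      loads <- list(list(body = "thorax", point_local = pl,
                         force = c(0, 0, -case$f_load * frac)))
      inc <- controller_increment(model, state, tg, loads = loads, K = K)
      state <- inc$state; K <- inc$K
    }
  }
  res <- spine_residual(model, state, loads = loads, detail = TRUE)
  ang <- measure_angles(model, state)
  idp <- vapply(res$aux$discs, `[[`, 0, "idp")
  structure(list(
    id = if (!is.null(case$id)) case$id else NA_character_,
    alpha_star = alpha,
    alpha = unname(ang$alpha["y"]),
    tracking_error_deg = tracking_error(alpha, unname(ang$alpha["y"])),
    idp_mpa = idp,
    iap_mmhg = res$aux$iap$p_iap_mmhg,
    group_forces_n = muscle_group_forces(model, res$aux),
    ivr_deg = ang$ivr,
    excitations = state$e,
    with_ta = with_ta,
    converged = if (is.null(inc)) NA else inc$converged,
    state = state, K = K), class = "case_result")
}

#' @exportS3Method base::print
print.case_result <- function(x, ...) {
  cat(sprintf("Load case %s: alpha* = %g deg -> alpha = %.3f deg (error %.3f)\n",
              x$id, x$alpha_star, x$alpha, x$tracking_error_deg))
  cat("  IDP (MPa):", paste(sprintf("%s %.3f", names(x$idp_mpa), x$idp_mpa),
                            collapse = ", "), "\n")
  cat(sprintf("  IAP: %.2f mmHg\n", x$iap_mmhg))
  invisible(x)
}

# remove the TA group from the recruitable muscle set entirely
drop_ta <- function(model) {
  m <- model$muscles
  keep <- m$fasc$group != "TA"
  ids <- m$fasc$id[keep]
  m$fasc <- m$fasc[keep, , drop = FALSE]
  m$pts <- m$pts[m$pts$fascicle %in% ids, , drop = FALSE]
  m$group_names <- setdiff(m$group_names, c("TA_R", "TA_L"))
  model$muscles <- m
  model$muscles$plate_plan <- make_plate_plan(model)
  model$plate_env <- new.env(parent = emptyenv())
  model
}

#' Calibrate the maximum specific muscle tension
#'
#' Maximum isometric back-extension protocol: gravity off, a horizontal
#' force at T7 rotating with the thorax (700 N at -10 degrees extension,
#' 870 N at +10 degrees flexion), solved for each candidate specific
#' tension K. Equilibrium is accepted when the tracking error stays below
#' 1 degree and no muscle group saturates.
#'
#' @param k_values candidate specific tensions (N/cm^2).
#' @param config model configuration to rebuild with each K.
#' @param forces named forces (N) per posture.
#' @return data frame with one row per (K, posture): `delta_alpha_deg`,
#'   `equilibrium`, `max_activation`.
#' @export
calibrate_specific_tension <- function(k_values = c(46, 73, 100),
                                       config = default_spine_config(),
                                       forces = c(extension = 700,
                                                  flexion = 870)) {
  rows <- list()
  for (K in k_values) {
    cfg <- config
    cfg$muscles$k_spec <- K
    cfg$gravity <- c(0, 0, 0)
    model <- build_synthetic_lss(cfg)
    st <- settle(model, gravity_steps = numeric(0), excursion_deg = 0)
    model <- st$model
    for (post in names(forces)) {
      alpha <- if (post == "extension") -10 else 10
      state <- st$state
      Kmat <- NULL
      ok <- TRUE
      t7 <- c(0, 0, model$config$load$t7_z)
      loads <- list(list(body = "thorax", point_local = t7,
                         force = function(s)
                           as.numeric(s$frames$thorax$R %*%
                                        c(forces[[post]], 0, 0))))
      res <- tryCatch({
        for (a in seq(0, alpha, by = sign(alpha) * 5)[-1]) {
          inc <- controller_increment(model, state,
                                      rhythm_targets(a, rep(20, 5)),
                                      loads = loads, K = Kmat)
          state <- inc$state; Kmat <- inc$K
        }
        inc
      }, error = function(e) NULL)
      if (is.null(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          k = K, posture = post, delta_alpha_deg = NA, equilibrium = FALSE,
          max_activation = NA)
        next
      }
      ang <- measure_angles(model, state)
      err <- tracking_error(alpha, unname(ang$alpha["y"]))
      amax <- max(state$e)
      rows[[length(rows) + 1L]] <- data.frame(
        k = K, posture = post, delta_alpha_deg = err,
        equilibrium = isTRUE(res$converged) && err <= 1.0 && amax < 1,
        max_activation = amax)
    }
  }
  do.call(rbind, rows)
}

#' Segmental rhythm calibration experiment
#'
#' Runs the settled model to thorax tilts of -10, +15 and +30 degrees under
#' each rhythm table and reports, per rhythm: the per-level deviations
#' between target contributions and resulting IVRs, their RMSE (in % of
#' the thorax rotation), and the L4/5 IDP change versus upright.
#'
#' @param model settled model.
#' @param state settled state.
#' @param rhythms named list of contribution vectors (default R1-R7).
#' @param tilts thorax target angles (deg).
#' @return list with `summary` data frame and per-run details.
#' @export
rhythm_experiment <- function(model, state, rhythms = rhythm_tables(),
                              tilts = c(-10, 15, 30)) {
  for (r in rhythms)
    if (abs(sum(r) - 100) > 0.1)
      stop("rhythm contributions must be normalized to 100%")
  res0 <- spine_residual(model, state, detail = TRUE)
  idp0 <- res0$aux$discs$L4L5$idp
  rows <- list(); details <- list()
  for (rn in names(rhythms)) {
    errs <- c()
    for (tl in tilts) {
      cr <- run_load_case(model, state,
                          list(id = sprintf("%s_t%g", rn, tl), alpha = tl,
                               f_load = 0, l_load = NA),
                          rhythm = rhythms[[rn]])
      # realized contributions (% of thorax rotation, caudal levels)
      contrib <- 100 * cr$ivr_deg / sum(cr$ivr_deg)
      dev <- contrib - rhythms[[rn]]
      errs <- c(errs, dev[-1])            # L1-L2 is rigid with the thorax
      details[[cr$id]] <- list(case = cr, contrib = contrib, dev = dev)
    }
    up <- run_load_case(model, state,
                        list(id = paste0(rn, "_up"), alpha = 0,
                             f_load = 0, l_load = NA),
                        rhythm = rhythms[[rn]])
    rows[[rn]] <- data.frame(
      rhythm = rn, rmse_pct = sqrt(mean(errs^2)),
      idp_l45_upright = up$idp_mpa[["L4L5"]],
      idp_l45_change_pct = 100 * (up$idp_mpa[["L4L5"]] - idp0) / idp0)
  }
  list(summary = do.call(rbind, rows), details = details,
       idp0_l45 = idp0)
}

#' Tabulate and export case results
#'
#' Writes a per-case CSV of the biomechanical responses and, when paired
#' with/without-TA results are given, the percentage-change table.
#'
#' @param results list of `case_result` objects (w/TA).
#' @param results_wota optional matching list without TA.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return list with `cases` (data frame) and `ta_change` (percent change
#'   w/oTA vs w/TA, or `NULL`).
#' @export
report_cases <- function(results, results_wota = NULL, out_dir = NULL) {
  row_of <- function(cr) {
    data.frame(id = cr$id, alpha_star = cr$alpha_star, alpha = cr$alpha,
               tracking_error_deg = cr$tracking_error_deg,
               idp_l34 = cr$idp_mpa[["L3L4"]],
               idp_l45 = cr$idp_mpa[["L4L5"]],
               idp_l5s1 = cr$idp_mpa[["L5S1"]],
               iap_mmhg = cr$iap_mmhg,
               f_es = cr$group_forces_n[["ES"]],
               f_am = cr$group_forces_n[["AM"]],
               f_mf = cr$group_forces_n[["MF"]],
               f_ta = if ("TA" %in% names(cr$group_forces_n))
                 cr$group_forces_n[["TA"]] else NA,
               converged = cr$converged)
  }
  cases <- do.call(rbind, lapply(results, row_of))
  ta_change <- NULL
  if (!is.null(results_wota)) {
    co <- do.call(rbind, lapply(results_wota, row_of))
    pc <- function(x, ref) ifelse(is.na(ref) | ref == 0, NA,
                                  (x - ref) / ref * 100)
    ta_change <- data.frame(
      id = cases$id,
      idp_l45_pct = pc(co$idp_l45, cases$idp_l45),
      iap_pct = pc(co$iap_mmhg, cases$iap_mmhg),
      f_es_pct = pc(co$f_es, cases$f_es),
      f_am_pct = pc(co$f_am, cases$f_am),
      f_mf_pct = pc(co$f_mf, cases$f_mf))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cases, file.path(out_dir, "case_results.csv"),
                     row.names = FALSE)
    if (!is.null(ta_change))
      utils::write.csv(ta_change, file.path(out_dir, "ta_change.csv"),
                       row.names = FALSE)
    litf <- system.file("extdata", "literature_idp_iap.csv",
                        package = "lumbosim")
    if (nzchar(litf))
      file.copy(litf, file.path(out_dir, "literature_reference.csv"),
                overwrite = TRUE)
  }
  list(cases = cases, ta_change = ta_change)
}
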