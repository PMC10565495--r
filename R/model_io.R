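#' Model configuration and state I/O
#'
#' Configurations are plain YAML mirroring [default_spine_config()]; any
#' field not present falls back to the default. Models dump to JSON as
#' configuration + settled reference, and are restored by deterministic
#' rebuild.
#'
#' @param path YAML file path.
#' @return a full configuration list.
#' @export
read_spine_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_spine_config(), user)
  # matrix-valued fields arrive as lists of rows
  fix_mat <- function(x, cols) {
    if (is.matrix(x)) return(x)
    m <- do.call(rbind, lapply(x, unlist))
    colnames(m) <- cols
    m
  }
  if (!is.null(user$ligaments$shape))
    cfg$ligaments$shape <- fix_mat(user$ligaments$shape,
                                   c("strain", "force"))
  cfg
}

#' @rdname read_spine_config
#' @param config configuration list.
#' @export
write_spine_config <- function(config, path) {
  cfg <- config
  cfg$ligaments$shape <- apply(cfg$ligaments$shape, 1, as.list)
  cfg$thorax_inertia <- diag(cfg$thorax_inertia)
  cfg$vertebra_inertia <- diag(cfg$vertebra_inertia)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

frame_to_list <- function(f) list(origin = f$origin, R = as.numeric(f$R))
list_to_frame <- function(l) new_frame(unlist(l$origin),
                                       matrix(unlist(l$R), 3, 3))

#' Dump / restore an assembled model (JSON)
#'
#' The dump stores the configuration, the muscle inventory summary, the
#' measured lordosis and (when settled) the reference posture; restoring
#' rebuilds the model deterministically from the configuration and
#' re-attaches the reference.
#'
#' @param model a `spine_model`.
#' @param path JSON path.
#' @export
model_to_json <- function(model, path) {
  obj <- list(
    config = model$config,
    inventory = as.list(table(model$muscles$fasc$group)),
    n_fascicles = nrow(model$muscles$fasc),
    lordosis_deg = model_lordosis(model),
    reference = if (!is.null(model$reference))
      list(frames = lapply(model$reference$frames[
        vapply(model$reference$frames, inherits, TRUE, "ls_frame")],
        frame_to_list),
        cor_x = model$reference$cor_x,
        e = as.list(model$reference$e)) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  cfg <- utils::modifyList(default_spine_config(), obj$config)
  cfg$ligaments$shape <- do.call(cbind, obj$config$ligaments$shape)
  cfg$thorax_inertia <- matrix(unlist(obj$config$thorax_inertia), 3, 3)
  cfg$vertebra_inertia <- matrix(unlist(obj$config$vertebra_inertia), 3, 3)
  # JSON simplification drops the polynomial coefficient names
  cfg$chain$coef <- lapply(cfg$chain$coef, function(cc)
    lapply(cc, function(v) stats::setNames(as.numeric(v)[1:2],
                                           c("p1", "p2"))))
  for (nm in c("types", "x"))
    cfg$ligaments[[nm]] <- unlist(cfg$ligaments[[nm]])
  model <- build_synthetic_lss(cfg)
  if (!is.null(obj$reference)) {
    frames <- lapply(obj$reference$frames, list_to_frame)
    model$reference <- list(frames = frames,
                            cor_x = obj$reference$cor_x,
                            e = unlist(obj$reference$e))
    model$tracking <- list(
      cor_local = point_in_body(model$config$controller$cor,
                                model$bodies$thorax$frame0))
  }
  model
}
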