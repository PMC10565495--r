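#' Landmark-based muscle morphology registration
#'
#' Reference muscle attachment/via points are transferred onto a target
#' skeleton bone-by-bone: matched landmark clouds define a least-squares
#' affine transform, transformed muscle points are then projected onto the
#' target bone surface (via points excluded), and a QA report replaces the
#' manual path check.
#'
#' Landmark tables are data frames with columns
#' `bone, landmark_id, x, y, z` and optionally `operator, repetition`.
#' Muscle point sets are data frames with columns
#' `bone, fascicle, ord, x, y, z, via`.
#'
#' @name registration
NULL

#' Per-landmark palpation repeatability
#'
#' Mean squared distance of repeated palpations from the per-landmark mean
#' position.
#'
#' @param clouds landmark data frame with `operator`/`repetition` columns;
#'   each (bone, landmark_id) should appear at least twice.
#' @return data frame with `bone`, `landmark_id`, `n`, `msd_m2` (m^2; `NA`
#'   for landmarks with a single repetition).
#' @export
palpation_repeatability <- function(clouds) {
  key <- interaction(clouds$bone, clouds$landmark_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(clouds, key), function(d) {
    n <- nrow(d)
    msd <- if (n < 2L) NA_real_ else {
      ctr <- colMeans(d[, c("x", "y", "z")])
      mean(rowSums(sweep(as.matrix(d[, c("x", "y", "z")]), 2, ctr)^2))
    }
    data.frame(bone = d$bone[1], landmark_id = d$landmark_id[1],
               n = n, msd_m2 = msd)
  }))
  rownames(out) <- NULL
  out
}

#' Least-squares affine registration of matched landmark clouds
#'
#' Finds the 3x4 affine transform `[A | t]` minimizing
#' `sum ||A s_i + t - g_i||^2` over matched landmark pairs.
#'
#' @param source,target landmark data frames (`landmark_id, x, y, z`);
#'   only shared ids are used, and at least 4 non-coplanar pairs are needed.
#' @return list with `A` (3x3), `t` (length 3), `rms` residual (m) and the
#'   ids used.
#' @export
affine_fit <- function(source, target) {
  ids <- intersect(source$landmark_id, target$landmark_id)
  if (length(ids) < 4L) stop("need >= 4 matched landmarks, got ", length(ids))
  S <- as.matrix(source[match(ids, source$landmark_id), c("x", "y", "z")])
  G <- as.matrix(target[match(ids, target$landmark_id), c("x", "y", "z")])
  X <- cbind(S, 1)
  if (qr(X)$rank < 4L)
    stop("landmark cloud is degenerate (coplanar or collinear)")
  # rows of [A | t] solve the normal equations of X beta = G
  beta <- qr.solve(X, G)                  # 4 x 3
  A <- t(beta[1:3, , drop = FALSE])
  tt <- as.numeric(beta[4, ])
  res <- X %*% beta - G
  list(A = A, t = tt, rms = sqrt(mean(rowSums(res^2))), ids = ids)
}

apply_affine <- function(af, pts) {
  sweep(rbind(pts) %*% t(af$A), 2, af$t, `+`)
}

#' Project muscle points onto a bone surface
#'
#' Every non-via point is replaced by its nearest point on the mesh
#' (first-triangle tie break); via points are left untouched.
#'
#' @param points n x 3 matrix.
#' @param mesh an `ls_mesh`.
#' @param via_flags logical length n; `TRUE` points are not moved.
#' @return list with `points` (corrected) and `displacement` (m per point;
#'   0 for via points).
#' @export
project_to_surface <- function(points, mesh, via_flags = rep(FALSE,
                                                             nrow(points))) {
  if (!nrow(mesh$faces)) stop("empty mesh")
  points <- rbind(points)
  disp <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    if (via_flags[i]) next
    np <- mesh_nearest_point(points[i, ], mesh)
    disp[i] <- np$distance
    points[i, ] <- np$point
  }
  list(points = points, displacement = disp)
}

#' Transfer a reference muscle point set onto a target skeleton
#'
#' For each bone present in the dictionary: fit the affine transform from
#' reference to target landmark cloud, transform the bone's muscle points,
#' and project non-via points to the target bone surface. Fascicle point
#' ordering is preserved. Bones without a landmark correspondence are
#' skipped with a warning and listed in the output.
#'
#' @param reference list with `landmarks` (landmark data frame), `muscles`
#'   (muscle point data frame) per the format in [registration].
#' @param target list with `landmarks` and `meshes` (named list of
#'   `ls_mesh` per bone; optional).
#' @return list with `muscles` (registered point set), `qa` (per-point
#'   displacements, per-bone affine RMS), `skipped` bones.
#' @export
register_muscles <- function(reference, target) {
  bones <- unique(reference$muscles$bone)
  out <- list(); qa <- list(); skipped <- character(0)
  for (b in bones) {
    src <- reference$landmarks[reference$landmarks$bone == b, ]
    tgt <- target$landmarks[target$landmarks$bone == b, ]
    if (!nrow(src) || !nrow(tgt)) {
      skipped <- c(skipped, b)
      warning("no landmark correspondence for bone ", b, "; skipped")
      next
    }
    af <- affine_fit(src, tgt)
    mp <- reference$muscles[reference$muscles$bone == b, , drop = FALSE]
    mp <- mp[order(mp$fascicle, mp$ord), , drop = FALSE]
    pts <- apply_affine(af, as.matrix(mp[, c("x", "y", "z")]))
    disp <- numeric(nrow(pts))
    if (!is.null(target$meshes[[b]])) {
      pr <- project_to_surface(pts, target$meshes[[b]], mp$via)
      pts <- pr$points; disp <- pr$displacement
    }
    mp$x <- pts[, 1]; mp$y <- pts[, 2]; mp$z <- pts[, 3]
    out[[b]] <- mp
    qa[[b]] <- list(affine_rms = af$rms, displacement = disp)
  }
  muscles <- do.call(rbind, out)
  rownames(muscles) <- NULL
  list(muscles = muscles, qa = qa, skipped = skipped)
}

#' Registration QA report
#'
#' Summarizes per-fascicle projection displacements and checks straight
#' path segments for bone piercing, replacing the manual verification step
#' of the registration pipeline.
#'
#' @param registered output of [register_muscles()].
#' @param meshes named list of bone meshes to test piercing against
#'   (optional).
#' @return list with `displacement_summary` (per fascicle) and
#'   `piercing` data frame.
#' @export
registration_qa <- function(registered, meshes = NULL) {
  m <- registered$muscles
  # per-bone displacement vectors follow the registered row order per bone
  m$displacement <- NA_real_
  for (b in names(registered$qa)) {
    rows <- which(m$bone == b)
    d <- registered$qa[[b]]$displacement
    if (length(rows) == length(d)) m$displacement[rows] <- d
  }
  ds <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$fascicle),
                              function(ix) {
    data.frame(fascicle = m$fascicle[ix[1]], n_points = length(ix),
               mean_displacement = mean(m$displacement[ix], na.rm = TRUE),
               max_displacement = suppressWarnings(
                 max(m$displacement[ix], na.rm = TRUE)))
  }))
  pierce <- NULL
  if (!is.null(meshes)) {
    rows <- list()
    for (f in unique(m$fascicle)) {
      mp <- m[m$fascicle == f, , drop = FALSE]
      mp <- mp[order(mp$ord), ]
      P <- as.matrix(mp[, c("x", "y", "z")])
      if (nrow(P) < 2L) next
      for (s in seq_len(nrow(P) - 1L)) {
        for (b in names(meshes)) {
          if (segment_pierces_mesh(P[s, ], P[s + 1L, ], meshes[[b]]))
            rows[[length(rows) + 1L]] <-
              data.frame(fascicle = f, segment = s, bone = b)
        }
      }
    }
    pierce <- if (length(rows)) do.call(rbind, rows) else
      data.frame(fascicle = character(0), segment = integer(0),
                 bone = character(0))
  }
  list(displacement_summary = ds, piercing = pierce)
}

#' Mirror a muscle point set across the mid-sagittal plane
#'
#' The mid-sagittal plane is y = 0; mirrored points have negated y.
#' @param points n x 3 matrix.
#' @export
mirror_points_sagittal <- function(points) {
  points <- rbind(points)
  points[, 2] <- -points[, 2]
  points
}
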