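#' @importFrom Matrix sparseMatrix crossprod t
NULL

# ---- batched 3x3 algebra -----------------------------------------------
# 3x3 tensors are stored as n x 9 matrices in column-major component order
# (A11, A21, A31, A12, A22, A32, A13, A23, A33). The sparse map D is built
# component-major (rows grouped by tensor component, then Gauss point) so
# that matrix(D %*% x, ncol = 9) lands in this layout without transposes.

bm_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 8] * A[, 6]) -
    A[, 4] * (A[, 2] * A[, 9] - A[, 8] * A[, 3]) +
    A[, 7] * (A[, 2] * A[, 6] - A[, 5] * A[, 3])
}

# cofactor matrix (so that inv(A) = t(cof)/det, Ainv^T = cof/det)
bm_cof <- function(A) {
  M <- matrix(0, nrow(A), 9L)
  M[, 1] <- A[, 5] * A[, 9] - A[, 8] * A[, 6]
  M[, 2] <- -(A[, 4] * A[, 9] - A[, 7] * A[, 6])
  M[, 3] <- A[, 4] * A[, 8] - A[, 7] * A[, 5]
  M[, 4] <- -(A[, 2] * A[, 9] - A[, 8] * A[, 3])
  M[, 5] <- A[, 1] * A[, 9] - A[, 7] * A[, 3]
  M[, 6] <- -(A[, 1] * A[, 8] - A[, 7] * A[, 2])
  M[, 7] <- A[, 2] * A[, 6] - A[, 5] * A[, 3]
  M[, 8] <- -(A[, 1] * A[, 6] - A[, 4] * A[, 3])
  M[, 9] <- A[, 1] * A[, 5] - A[, 4] * A[, 2]
  M
}

bm_mul <- function(A, B) {
  M <- matrix(0, nrow(A), 9L)
  M[, 1] <- A[, 1] * B[, 1] + A[, 4] * B[, 2] + A[, 7] * B[, 3]
  M[, 2] <- A[, 2] * B[, 1] + A[, 5] * B[, 2] + A[, 8] * B[, 3]
  M[, 3] <- A[, 3] * B[, 1] + A[, 6] * B[, 2] + A[, 9] * B[, 3]
  M[, 4] <- A[, 1] * B[, 4] + A[, 4] * B[, 5] + A[, 7] * B[, 6]
  M[, 5] <- A[, 2] * B[, 4] + A[, 5] * B[, 5] + A[, 8] * B[, 6]
  M[, 6] <- A[, 3] * B[, 4] + A[, 6] * B[, 5] + A[, 9] * B[, 6]
  M[, 7] <- A[, 1] * B[, 7] + A[, 4] * B[, 8] + A[, 7] * B[, 9]
  M[, 8] <- A[, 2] * B[, 7] + A[, 5] * B[, 8] + A[, 8] * B[, 9]
  M[, 9] <- A[, 3] * B[, 7] + A[, 6] * B[, 8] + A[, 9] * B[, 9]
  M
}

# left Cauchy-Green B = F F^T (symmetric, returned in full 9-col layout)
bm_bten <- function(F) {
  M <- matrix(0, nrow(F), 9L)
  M[, 1] <- F[, 1]^2 + F[, 4]^2 + F[, 7]^2
  M[, 5] <- F[, 2]^2 + F[, 5]^2 + F[, 8]^2
  M[, 9] <- F[, 3]^2 + F[, 6]^2 + F[, 9]^2
  M[, 2] <- M[, 4] <- F[, 1] * F[, 2] + F[, 4] * F[, 5] + F[, 7] * F[, 8]
  M[, 3] <- M[, 7] <- F[, 1] * F[, 3] + F[, 4] * F[, 6] + F[, 7] * F[, 9]
  M[, 6] <- M[, 8] <- F[, 2] * F[, 3] + F[, 5] * F[, 6] + F[, 8] * F[, 9]
  M
}

# ---- hyperelastic constitutive laws ------------------------------------
# Isochoric/volumetric split: W = W_iso(I1bar, I2bar) + kappa/2 (J-1)^2 with
# I1bar = J^{-2/3} tr(B), I2bar from the isochoric B. Cauchy stress
#   sigma = (2/J) dev[(W1 + I1bar W2) Bbar - W2 Bbar^2] + p I,  p = kappa(J-1)
# `pbar` optionally overrides the pointwise pressure (mean-dilatation).

hyper_cauchy_batch <- function(F, material, pbar = NULL) {
  J <- bm_det(F)
  if (any(J <= 0)) {
    bad <- which(J <= 0)
    stop("inverted element state: det(F) <= 0 at integration point(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  B <- bm_bten(F)
  Jm23 <- J^(-2 / 3)
  Bb <- B * Jm23
  I1b <- Bb[, 1] + Bb[, 5] + Bb[, 9]
  Bb2 <- bm_mul(Bb, Bb)
  trBb2 <- Bb2[, 1] + Bb2[, 5] + Bb2[, 9]
  if (material$type == "yeoh") {
    cc <- material$c  # c1, c2, c3
    x <- I1b - 3
    W1 <- cc[1] + 2 * cc[2] * x + 3 * cc[3] * x^2
    W2 <- 0
    Wiso <- cc[1] * x + cc[2] * x^2 + cc[3] * x^3
  } else if (material$type == "mooney") {
    I2b <- 0.5 * (I1b^2 - trBb2)
    W1 <- rep(material$c10, length(J))
    W2 <- rep(material$c01, length(J))
    Wiso <- material$c10 * (I1b - 3) + material$c01 * (I2b - 3)
  } else stop("unknown material type: ", material$type)
  A <- (W1 + I1b * W2) * Bb - W2 * Bb2
  trA <- A[, 1] + A[, 5] + A[, 9]
  p <- if (is.null(pbar)) material$kappa * (J - 1) else pbar
  sig <- (2 / J) * A
  sig[, c(1, 5, 9)] <- sig[, c(1, 5, 9)] - (2 / J) * trA / 3 + p
  Wvol <- if (is.null(pbar)) 0.5 * material$kappa * (J - 1)^2 else NULL
  list(sigma = sig, J = J, Wiso = Wiso, Wvol = Wvol, p = p)
}

mat3_to_row <- function(M) matrix(as.numeric(M), 1, 9)
row_to_mat3 <- function(r) matrix(as.numeric(r), 3, 3)

#' Cauchy stress of the isochoric Yeoh solid with volumetric penalty
#'
#' Strain energy \eqn{W = \sum_{i=1}^{3} c_i(\bar I_1-3)^i + \kappa/2 (J-1)^2}
#' with \eqn{\bar I_1} the isochoric first invariant. Used for the
#' quasi-incompressible nucleus pulposus.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param c1,c2,c3 Yeoh coefficients (Pa).
#' @param kappa bulk penalty modulus (Pa).
#' @return symmetric 3x3 Cauchy stress (Pa).
#' @export
yeoh_stress <- function(F, c1, c2 = 0, c3 = 0, kappa = 1e8) {
  out <- hyper_cauchy_batch(mat3_to_row(F),
                            list(type = "yeoh", c = c(c1, c2, c3),
                                 kappa = kappa))
  row_to_mat3(out$sigma)
}

#' Cauchy stress of the isochoric Mooney-Rivlin solid
#'
#' Strain energy \eqn{W = c_{10}(\bar I_1-3) + c_{01}(\bar I_2-3) +
#' \kappa/2 (J-1)^2}. Used for the annulus fibrosus ground substance.
#'
#' @inheritParams yeoh_stress
#' @param c10,c01 Mooney-Rivlin coefficients (Pa).
#' @export
mooney_rivlin_stress <- function(F, c10, c01, kappa = 1e8) {
  out <- hyper_cauchy_batch(mat3_to_row(F),
                            list(type = "mooney", c10 = c10, c01 = c01,
                                 kappa = kappa))
  row_to_mat3(out$sigma)
}

#' Strain energy density of the single-point hyperelastic laws
#' @inheritParams yeoh_stress
#' @param material list with `type` ("yeoh"/"mooney"), coefficients and
#'   `kappa`, as stored in a disc's material table.
#' @export
hyper_energy <- function(F, material) {
  out <- hyper_cauchy_batch(mat3_to_row(F), material)
  as.numeric(out$Wiso + out$Wvol)
}

# ---- hexahedral disc mesh ----------------------------------------------

hex_gauss <- function(order = 2L) {
  if (order == 1L)
    return(list(points = matrix(0, 1, 3), weights = 8))
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  list(points = gp, weights = rep(1, 8))
}

# trilinear shape function derivatives at (xi, eta, zeta); node order:
# bottom face CCW (-,-,-), (+,-,-), (+,+,-), (-,+,-) then top face likewise
hex_dN <- function(xi, eta, zeta) {
  s <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
              ncol = 3, byrow = TRUE)
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    dN[a, 1] <- 0.125 * s[a, 1] * (1 + s[a, 2] * eta) * (1 + s[a, 3] * zeta)
    dN[a, 2] <- 0.125 * s[a, 2] * (1 + s[a, 1] * xi) * (1 + s[a, 3] * zeta)
    dN[a, 3] <- 0.125 * s[a, 3] * (1 + s[a, 1] * xi) * (1 + s[a, 2] * eta)
  }
  dN
}

# Precompute the sparse linear map D with F(gp) = reshape(D %*% x) and the
# integration weights w = gauss_w * detJ0. x is the length-3n vector of
# nodal coordinates (node-major: x1 y1 z1 x2 ...).
disc_precompute <- function(X0, elem, gauss_order = 2L) {
  gq <- hex_gauss(gauss_order)
  npe <- length(gq$weights)
  ne <- nrow(elem)
  ngp <- npe * ne
  ii <- jj <- vv <- vector("list", ngp)
  w <- numeric(ngp)
  gp_elem <- rep(seq_len(ne), each = npe)
  idx <- 1L
  for (e in seq_len(ne)) {
    en <- elem[e, ]
    Xe <- X0[en, , drop = FALSE]
    for (g in seq_len(npe)) {
      dN <- hex_dN(gq$points[g, 1], gq$points[g, 2], gq$points[g, 3])
      J0 <- t(Xe) %*% dN            # dX/dxi
      dJ <- det(J0)
      if (dJ <= 0) stop("degenerate reference element ", e)
      gradN <- dN %*% solve(J0)     # dN/dX, 8 x 3
      w[idx] <- gq$weights[g] * dJ
      # component-major rows: F component (i,j) lives in row
      # (i + 3(j-1) - 1) * ngp + idx, so matrix(D %*% x, ncol = 9) is the
      # batched tensor layout directly
      rows <- integer(0); cols <- integer(0); vals <- numeric(0)
      for (j in 1:3) for (i in 1:3) {
        comp <- i + 3L * (j - 1L)
        r <- (comp - 1L) * ngp + idx
        rows <- c(rows, rep(r, 8L))
        cols <- c(cols, 3L * (en - 1L) + i)
        vals <- c(vals, gradN[, j])
      }
      ii[[idx]] <- rows; jj[[idx]] <- cols; vv[[idx]] <- vals
      idx <- idx + 1L
    }
  }
  D <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(9L * ngp, 3L * nrow(X0)))
  elem_vol <- as.numeric(rowsum(w, gp_elem))
  list(D = D, Dt = Matrix::t(D), w = w, gp_elem = gp_elem,
       elem_vol = elem_vol)
}

# O-grid (butterfly) cross-section node layout for one layer.
# Returns list(xy = n x 2, nucleus_ring_max): core 4x4 grid + ring circles.
disc_section <- function(r_nucleus, r_outer, n_annulus_rings = 5L) {
  m <- 3L                              # core elements per side -> 12 sectors
  s <- 0.5 * r_nucleus
  gxy <- as.matrix(expand.grid(x = seq(-s, s, length.out = m + 1L),
                               y = seq(-s, s, length.out = m + 1L)))
  # core boundary nodes in CCW order starting at (+s, -s) corner region
  bidx <- integer(0)
  bx <- gxy[, 1]; by <- gxy[, 2]
  on_b <- abs(abs(bx) - s) < 1e-12 | abs(abs(by) - s) < 1e-12
  bpts <- which(on_b)
  ang <- atan2(by[bpts], bx[bpts])
  bidx <- bpts[order(ang)]
  nb <- length(bidx)                   # 12
  th <- atan2(by[bidx], bx[bidx])
  radii <- c(r_nucleus,
             r_nucleus + (r_outer - r_nucleus) * seq_len(n_annulus_rings) /
               n_annulus_rings)
  ring_xy <- do.call(rbind, lapply(radii, function(r)
    cbind(r * cos(th), r * sin(th))))
  xy <- rbind(gxy, ring_xy)
  ring_start <- nrow(gxy) + (seq_along(radii) - 1L) * nb
  list(xy = xy, core_n = nrow(gxy), core_m = m, boundary = bidx,
       ring_start = ring_start, nb = nb, n_rings = length(radii))
}

# quad connectivity (1-layer cross-section) with region labels
disc_section_quads <- function(sec) {
  m <- sec$core_m
  quads <- list(); region <- character(0)
  id <- function(i, j) (j - 1L) * (m + 1L) + i
  for (j in seq_len(m)) for (i in seq_len(m)) {
    quads[[length(quads) + 1L]] <- c(id(i, j), id(i + 1L, j),
                                     id(i + 1L, j + 1L), id(i, j + 1L))
    region <- c(region, "nucleus")
  }
  nb <- sec$nb
  prev <- sec$boundary                      # core boundary node ids (CCW)
  for (k in seq_len(sec$n_rings)) {
    cur <- sec$ring_start[k] + seq_len(nb)
    for (i in seq_len(nb)) {
      i2 <- if (i == nb) 1L else i + 1L
      quads[[length(quads) + 1L]] <- c(prev[i], cur[i], cur[i2], prev[i2])
      region <- c(region, if (k == 1L) "nucleus" else "annulus")
    }
    prev <- cur
  }
  list(quads = do.call(rbind, quads), region = region)
}

default_fiber_curve <- function() {
  cbind(strain = c(0, 0.02, 0.05, 0.10, 0.20, 0.40),
        force = c(0, 0.5, 3, 12.5, 45, 150))
}

#' Build a fiber-reinforced hyperelastic FE intervertebral disc
#'
#' Creates an 8-node hexahedral disc between two endplate frames: a
#' quasi-incompressible Yeoh nucleus pulposus surrounded by a Mooney-Rivlin
#' annulus fibrosus carrying five concentric rings of criss-crossed
#' tension-only collagen fibers. Cranial/caudal node layers are bound to the
#' adjacent vertebra frames; the mesh is built in situ and stress-free.
#'
#' @param lower,upper `ls_frame` endplate frames (z-axis = endplate normal).
#' @param r_nucleus,r_outer nucleus and outer annulus radii (m).
#' @param n_layers element layers through the disc height.
#' @param materials list with `nucleus` (type "yeoh") and `annulus`
#'   (type "mooney") entries; Pa units.
#' @param fiber_curve two-column matrix (strain, force N) for one fiber,
#'   linearly interpolated, tension-only.
#' @param gauss_order 2 for full 2x2x2 integration, 1 for reduced
#'   single-point integration (adequate when all nodes are bound to the
#'   endplates, as in the default one-layer disc).
#' @return an object of class `ls_disc`.
#' @export
build_disc <- function(lower, upper, r_nucleus = 0.012, r_outer = 0.021,
                       n_layers = 1L, gauss_order = 2L,
                       materials = list(
                         nucleus = list(type = "yeoh",
                                        c = c(0.12e6, 0.03e6, 0.30e6),
                                        kappa = 2e8),
                         annulus = list(type = "mooney", c10 = 0.18e6,
                                        c01 = 0.045e6, kappa = 6e6)),
                       fiber_curve = default_fiber_curve()) {
  if (r_nucleus <= 0 || r_outer <= r_nucleus)
    stop("disc radii must satisfy 0 < r_nucleus < r_outer")
  sec <- disc_section(r_nucleus, r_outer)
  sq <- disc_section_quads(sec)
  npl <- nrow(sec$xy)                       # nodes per layer
  nl <- n_layers + 1L                       # node layers
  bot <- frame_transform(lower, cbind(sec$xy, 0))
  top <- frame_transform(upper, cbind(sec$xy, 0))
  X0 <- do.call(rbind, lapply(seq_len(nl), function(k) {
    t <- (k - 1) / n_layers
    (1 - t) * bot + t * top
  }))
  elem <- do.call(rbind, lapply(seq_len(n_layers), function(k) {
    off_b <- (k - 1L) * npl; off_t <- k * npl
    cbind(sq$quads + off_b, sq$quads + off_t)
  }))
  region <- rep(sq$region, n_layers)
  caudal <- seq_len(npl)
  cranial <- (nl - 1L) * npl + seq_len(npl)
  pre <- disc_precompute(X0, elem, gauss_order)
  # fibers on the 5 outer annulus ring circles, endplate to endplate
  nb <- sec$nb
  fib_i <- fib_j <- integer(0)
  for (k in 2:sec$n_rings) {               # skip nucleus boundary ring
    ring <- sec$ring_start[k] + seq_len(nb)
    ring_top <- (nl - 1L) * npl + ring
    nxt <- c(ring[-1], ring[1]); prv <- c(ring[nb], ring[-nb])
    fib_i <- c(fib_i, ring, ring)
    fib_j <- c(fib_j, (nl - 1L) * npl + c(ring[-1], ring[1]),
               (nl - 1L) * npl + c(ring[nb], ring[-nb]))
  }
  L0 <- sqrt(rowSums((X0[fib_j, , drop = FALSE] -
                        X0[fib_i, , drop = FALSE])^2))
  disc <- list(X0 = X0, elem = elem, region = region,
               caudal = caudal, cranial = cranial,
               local_caudal = cbind(sec$xy, 0),
               local_cranial = cbind(sec$xy, 0),
               n_layers = n_layers, nodes_per_layer = npl,
               materials = materials, pre = pre,
               fibers = list(i = fib_i, j = fib_j, L0 = L0,
                             curve = fiber_curve,
                             weight = rep(1 / (2 * nb), length(fib_i))),
               lower0 = lower, upper0 = upper)
  class(disc) <- "ls_disc"
  disc
}

disc_current_nodes <- function(disc, lower, upper) {
  npl <- disc$nodes_per_layer
  nl <- disc$n_layers + 1L
  bot <- frame_transform(lower, disc$local_caudal)
  top <- frame_transform(upper, disc$local_cranial)
  if (nl == 2L) return(rbind(bot, top))
  out <- matrix(0, nl * npl, 3L)
  for (k in seq_len(nl)) {
    t <- (k - 1) / disc$n_layers
    out[((k - 1L) * npl + 1L):(k * npl), ] <- (1 - t) * bot + t * top
  }
  out
}

# internal nodal forces + stresses for given current nodal coordinates
disc_internal <- function(disc, xcur, want_stress = FALSE) {
  Fm <- matrix(as.numeric(disc$pre$D %*% as.numeric(t(xcur))), ncol = 9)
  ge <- disc$pre$gp_elem
  # pointwise J for mean dilatation
  J <- bm_det(Fm)
  if (any(J <= 0)) {
    stop("inverted element: det(F) <= 0 in element ",
         ge[which(J <= 0)[1]])
  }
  Jbar_e <- as.numeric(rowsum(disc$pre$w * J, ge)) / disc$pre$elem_vol
  kap <- ifelse(disc$region == "nucleus",
                disc$materials$nucleus$kappa, disc$materials$annulus$kappa)
  # The nucleus pulposus behaves as an incompressible fluid: its volumetric
  # constraint acts on the REGION volume (one hydrostatic pressure for the
  # whole nucleus), so bending redistributes nucleus volume freely while
  # net compression is penalized. The solid annulus keeps element-level
  # mean dilatation.
  nuc_e <- disc$region == "nucleus"
  Jbar_nuc <- sum((Jbar_e * disc$pre$elem_vol)[nuc_e]) /
    sum(disc$pre$elem_vol[nuc_e])
  p_e <- kap * (Jbar_e - 1)
  p_e[nuc_e] <- disc$materials$nucleus$kappa * (Jbar_nuc - 1)
  pbar <- p_e[ge]
  is_nuc <- disc$region[ge] == "nucleus"
  sig <- matrix(0, nrow(Fm), 9)
  Wiso <- numeric(nrow(Fm))
  if (any(is_nuc)) {
    o <- hyper_cauchy_batch(Fm[is_nuc, , drop = FALSE],
                            disc$materials$nucleus, pbar = pbar[is_nuc])
    sig[is_nuc, ] <- o$sigma; Wiso[is_nuc] <- o$Wiso
  }
  if (any(!is_nuc)) {
    o <- hyper_cauchy_batch(Fm[!is_nuc, , drop = FALSE],
                            disc$materials$annulus, pbar = pbar[!is_nuc])
    sig[!is_nuc, ] <- o$sigma; Wiso[!is_nuc] <- o$Wiso
  }
  # P = J sigma F^{-T} = sigma %*% cof(F)
  P <- bm_mul(sig, bm_cof(Fm))
  f <- as.numeric(disc$pre$Dt %*% as.numeric(P * disc$pre$w))
  fint <- matrix(f, ncol = 3, byrow = TRUE)     # internal force conjugate
  energy <- sum(disc$pre$w * Wiso) +
    sum((0.5 * kap * (Jbar_e - 1)^2 * disc$pre$elem_vol)[!nuc_e]) +
    0.5 * disc$materials$nucleus$kappa * (Jbar_nuc - 1)^2 *
      sum(disc$pre$elem_vol[nuc_e])
  out <- list(fint = fint, energy = energy, Jbar = Jbar_e,
              Jbar_nucleus = Jbar_nuc)
  if (want_stress) {
    selem <- rowsum(sig * disc$pre$w, ge) / disc$pre$elem_vol
    out$stress_elem <- selem
  }
  out
}

#' Piecewise-linear tension-only fiber force
#'
#' @param strain axial engineering strain of a fiber segment.
#' @param curve two-column (strain, force) matrix; monotone non-decreasing,
#'   zero at and below zero strain. Extrapolates with the last slope.
#' @return force in N, `>= 0`; zero for compressive strain.
#' @export
fiber_force <- function(strain, curve = default_fiber_curve()) {
  s <- curve[, 1]; f <- curve[, 2]
  n <- length(s)
  # monotone C1 Hermite interpolation through the table knots with zero
  # slope at the slack knot: force and stiffness engage together, keeping
  # Newton-type solvers off slope kinks at the operating point
  d <- diff(f) / diff(s)
  m <- c(0, (d[-1] + d[-(n - 1)]) / 2, d[n - 1])
  for (k in 2:(n - 1))
    m[k] <- min(m[k], 3 * d[k - 1], 3 * d[k])
  m <- pmax(m, 0)
  x <- pmin(pmax(strain, s[1]), s[n])
  iv <- pmin(pmax(findInterval(x, s), 1L), n - 1L)
  h <- s[iv + 1L] - s[iv]
  t <- (x - s[iv]) / h
  h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2;    h11 <- t^3 - t^2
  val <- h00 * f[iv] + h10 * h * m[iv] + h01 * f[iv + 1L] +
    h11 * h * m[iv + 1L]
  out <- ifelse(strain <= s[1], 0,
                ifelse(strain >= s[n],
                       f[n] + m[n] * (strain - s[n]), val))
  pmax(out, 0)
}

# fiber nodal forces given current node positions; returns n x 3 matrix
disc_fiber_forces <- function(disc, xcur) {
  fb <- disc$fibers
  d <- xcur[fb$j, , drop = FALSE] - xcur[fb$i, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  eps <- len / fb$L0 - 1
  Tf <- fiber_force(eps, fb$curve)
  u <- d / len
  fv <- u * Tf
  f <- matrix(0, nrow(xcur), 3)
  fi <- rowsum(fv, fb$i); f[as.integer(rownames(fi)), ] <- fi
  fj <- rowsum(-fv, fb$j)
  f[as.integer(rownames(fj)), ] <- f[as.integer(rownames(fj)), ] + fj
  f   # force applied ON nodes (pulling i toward j and vice versa)
}

#' Quasi-static response of a disc bound to two vertebra frames
#'
#' Bound cranial/caudal node layers follow the vertebra frames; any interior
#' node layers are equilibrated by Newton iteration. Returns nodal forces,
#' the wrench transmitted to each vertebra, element Cauchy stresses, and the
#' intradiscal pressure.
#'
#' @param disc an `ls_disc`.
#' @param lower,upper current `ls_frame`s of the caudal and cranial vertebrae.
#' @param tangent if `TRUE`, also return the symmetric stiffness (finite
#'   difference of nodal forces; intended for small test meshes).
#' @param want_stress compute element stresses / IDP (skippable in inner
#'   solver loops).
#' @return list with `f_nodal` (n x 3, force exerted BY the disc ON whatever
#'   holds each node), `wrench_lower`/`wrench_upper` (`force`, `torque` about
#'   each frame origin), `stress_elem`, `idp_mpa`, `energy`.
#' @export
assemble_disc_response <- function(disc, lower = disc$lower0,
                                   upper = disc$upper0, tangent = FALSE,
                                   want_stress = TRUE) {
  xcur <- disc_current_nodes(disc, lower, upper)
  free <- setdiff(seq_len(nrow(xcur)), c(disc$caudal, disc$cranial))
  if (length(free)) {
    # equilibrate interior nodes: residual = -fint + fiber forces
    xf <- as.numeric(t(xcur[free, , drop = FALSE]))
    resfun <- function(v) {
      xcur[free, ] <- matrix(v, ncol = 3, byrow = TRUE)
      o <- disc_internal(disc, xcur)
      r <- -o$fint[free, , drop = FALSE] + disc_fiber_forces(disc, xcur)[free, , drop = FALSE]
      as.numeric(t(r))
    }
    for (it in 1:50) {
      r <- resfun(xf)
      if (max(abs(r)) < 1e-6) break
      Jm <- fd_jacobian(resfun, xf, h = 1e-8)
      dx <- tryCatch(solve(Jm, -r), error = function(e) NULL)
      if (is.null(dx)) stop("interior disc solve failed (singular tangent)")
      xf <- xf + dx
    }
    if (max(abs(resfun(xf))) > 1e-4)
      stop("non-convergent interior element state in disc")
    xcur[free, ] <- matrix(xf, ncol = 3, byrow = TRUE)
  }
  o <- disc_internal(disc, xcur, want_stress = want_stress)
  f_nodal <- -o$fint + disc_fiber_forces(disc, xcur)
  wl <- node_wrench(f_nodal, xcur, disc$caudal, lower$origin)
  wu <- node_wrench(f_nodal, xcur, disc$cranial, upper$origin)
  out <- list(f_nodal = f_nodal, wrench_lower = wl, wrench_upper = wu,
              energy = o$energy, Jbar = o$Jbar, x = xcur)
  if (want_stress) {
    out$stress_elem <- o$stress_elem
    out$idp_mpa <- compute_idp(disc, o$stress_elem)
  }
  if (tangent) {
    dof <- as.numeric(t(xcur))
    ffun <- function(v) {
      xm <- matrix(v, ncol = 3, byrow = TRUE)
      as.numeric(t(-disc_internal(disc, xm)$fint + disc_fiber_forces(disc, xm)))
    }
    K <- -fd_jacobian(ffun, dof, h = 1e-7)
    out$tangent <- (K + t(K)) / 2
  }
  out
}

node_wrench <- function(f_nodal, xcur, nodes, origin) {
  fs <- f_nodal[nodes, , drop = FALSE]
  r <- sweep(xcur[nodes, , drop = FALSE], 2, origin, `-`)
  list(force = colSums(fs),
       torque = colSums(cbind(r[, 2] * fs[, 3] - r[, 3] * fs[, 2],
                              r[, 3] * fs[, 1] - r[, 1] * fs[, 3],
                              r[, 1] * fs[, 2] - r[, 2] * fs[, 1])))
}

fd_jacobian <- function(fn, x, h = 1e-7) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    J[, k] <- (fn(xp) - f0) / h
  }
  J
}

#' Intradiscal pressure from element stresses
#'
#' The nucleus pulposus is assumed hydrostatic: IDP is the negative mean over
#' all nucleus FE nodes of the mean normal stress tr(sigma)/3, with
#' volume-weighted element-to-node stress averaging. Reported in MPa,
#' positive in compression.
#'
#' @param disc an `ls_disc`.
#' @param stress_elem ne x 9 element Cauchy stresses (Pa) as returned by
#'   [assemble_disc_response()].
#' @export
compute_idp <- function(disc, stress_elem) {
  nuc <- which(disc$region == "nucleus")
  if (!length(nuc)) stop("disc has no nucleus elements")
  p_el <- -(stress_elem[nuc, 1] + stress_elem[nuc, 5] + stress_elem[nuc, 9]) / 3
  vol <- disc$pre$elem_vol[nuc]
  # scatter element values to their nodes with volume weights
  nodes <- as.integer(disc$elem[nuc, ])
  wts <- rep(vol, times = 8L)
  vals <- rep(p_el, times = 8L)
  num <- rowsum(wts * vals, nodes)
  den <- rowsum(wts, nodes)
  mean(num / den) / 1e6
}

#' Unilateral frictionless facet contact force
#'
#' Node-to-plane penalty: the contact point fixed on the upper vertebra is
#' checked against a plane patch fixed on the lower vertebra. Zero force when
#' separated; a compressive-only penalty force `k * penetration` along the
#' plane normal when penetrating; wrenches are equal and opposite.
#'
#' @param contact list with `point_upper` (local coords on upper body),
#'   `plane_point`, `normal` (local on lower body), stiffness `k` (N/m).
#' @param lower,upper current vertebra frames.
#' @return list `force_upper`, `torque_upper`, `force_lower`, `torque_lower`
#'   (global, torques about the respective frame origins), and `gap` (m).
#' @export
facet_force <- function(contact, lower, upper) {
  p <- as.numeric(frame_transform(upper, contact$point_upper))
  q <- as.numeric(frame_transform(lower, contact$plane_point))
  n <- as.numeric(lower$R %*% contact$normal)
  gap <- sum((p - q) * n)
  Fm <- if (gap < 0) contact$k * (-gap) else 0
  fu <- Fm * n
  ru <- p - upper$origin; rl <- p - lower$origin
  list(force_upper = fu, torque_upper = cross3(ru, fu),
       force_lower = -fu, torque_lower = cross3(rl, -fu), gap = gap)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
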