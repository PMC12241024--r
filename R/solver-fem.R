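# Axisymmetric nonlinear finite-element engine.
#
# Formulation: displacement-based 4-node quadrilaterals in the (r, z) plane,
# total-Lagrangian kinematics with the stress evaluated in the spatial
# configuration, nearly incompressible Ogden material (isochoric principal
# stretches + quadratic volumetric penalty), and an F-bar treatment of the
# volumetric part (deformation gradient scaled to the centroid Jacobian) to
# prevent volumetric locking. The tangent stiffness is a central
# finite-difference of the analytic element internal force, which is exact
# enough for Newton at 0.1 mm load increments and sidesteps the coalescent
# principal-stretch cases of hand-derived Ogden tangents.

# Bilinear shape functions and parametric derivatives at one gauss point.
shape_q4 <- function(xi, eta) {
  list(N = c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
             (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4,
       dxi = c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
       deta = c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
}

gauss_q4 <- local({
  g <- 1 / sqrt(3)
  pts <- rbind(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  lapply(seq_len(4), function(k)
    c(shape_q4(pts[k, 1], pts[k, 2]), w = 1))
})
centroid_q4 <- c(shape_q4(0, 0), w = 4)

# Precompute per-element reference geometry factors at each quadrature point.
fem_precompute <- function(mesh) {
  Rn <- matrix(mesh$nodes[mesh$elems, 1], ncol = 4)
  Zn <- matrix(mesh$nodes[mesh$elems, 2], ncol = 4)
  prep_gp <- function(sh) {
    J11 <- Rn %*% sh$dxi; J12 <- Zn %*% sh$dxi
    J21 <- Rn %*% sh$deta; J22 <- Zn %*% sh$deta
    det <- as.vector(J11 * J22 - J12 * J21)
    if (any(det <= 0)) stop("non-positive element Jacobian in reference mesh")
    dNdR <- (outer(as.vector(J22), sh$dxi) - outer(as.vector(J21), sh$deta)) / det
    dNdZ <- (outer(as.vector(J11), sh$deta) - outer(as.vector(J12), sh$dxi)) / det
    Rgp <- as.vector(Rn %*% sh$N)
    list(N = sh$N, dNdR = dNdR, dNdZ = dNdZ, Rgp = Rgp,
         dV0 = sh$w * det * 2 * pi * Rgp)
  }
  list(Rn = Rn, Zn = Zn,
       gp = lapply(gauss_q4, prep_gp),
       c0 = prep_gp(centroid_q4),
       edof = cbind(2L * mesh$elems[, 1] - 1L, 2L * mesh$elems[, 1],
                    2L * mesh$elems[, 2] - 1L, 2L * mesh$elems[, 2],
                    2L * mesh$elems[, 3] - 1L, 2L * mesh$elems[, 3],
                    2L * mesh$elems[, 4] - 1L, 2L * mesh$elems[, 4]))
}

# Deformation kinematics at a quadrature point, vectorised over elements.
# ur, uz: ne x 4 gathered nodal displacements.
fem_kinematics <- function(gp, ur, uz) {
  F11 <- 1 + rowSums(ur * gp$dNdR); F12 <- rowSums(ur * gp$dNdZ)
  F21 <- rowSums(uz * gp$dNdR);     F22 <- 1 + rowSums(uz * gp$dNdZ)
  urg <- as.vector(ur %*% gp$N)
  lth <- 1 + urg / gp$Rgp
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22,
       J2 = F11 * F22 - F12 * F21, lth = lth, urg = urg)
}

# Cauchy stress (vectorised over elements) from in-plane deformation
# gradient and hoop stretch, after F-bar volumetric scaling to Jbar.
# paug is the augmented-Lagrangian pressure carried between solves (the
# Uzawa update that enforces incompressibility without raising the penalty).
ogden_cauchy_axisym <- function(mat, kin, scale, paug = 0) {
  F11 <- kin$F11 * scale; F12 <- kin$F12 * scale
  F21 <- kin$F21 * scale; F22 <- kin$F22 * scale
  lth <- kin$lth * scale
  b11 <- F11^2 + F12^2
  b22 <- F21^2 + F22^2
  b12 <- F11 * F21 + F12 * F22
  tr <- b11 + b22
  dd <- sqrt(pmax(((b11 - b22) / 2)^2 + b12^2, 0))
  le1 <- tr / 2 + dd
  le2 <- pmax(tr / 2 - dd, 1e-12)
  l1 <- sqrt(le1); l2 <- sqrt(le2); l3 <- lth
  J <- l1 * l2 * l3
  Jm13 <- J^(-1 / 3)
  lb1 <- Jm13 * l1; lb2 <- Jm13 * l2; lb3 <- Jm13 * l3
  s1 <- s2 <- s3 <- 0
  for (p in seq_along(mat$mu)) {
    w1 <- mat$mu[p] * lb1^mat$alpha[p]
    w2 <- mat$mu[p] * lb2^mat$alpha[p]
    w3 <- mat$mu[p] * lb3^mat$alpha[p]
    m <- (w1 + w2 + w3) / 3
    s1 <- s1 + (w1 - m); s2 <- s2 + (w2 - m); s3 <- s3 + (w3 - m)
  }
  pv <- paug + mat$penalty_bulk * (J - 1)
  sig1 <- s1 / J + pv; sig2 <- s2 / J + pv; sig3 <- s3 / J + pv
  # principal direction of b for eigenvalue le1 (in-plane rotation)
  v1 <- b12; v2 <- le1 - b11
  # trial states from a rejected line-search step may carry NaN; keep them
  # NaN (the caller rejects on a non-finite residual) but never subscript
  # with NA
  alt <- abs(v1) + abs(v2) < 1e-12 * pmax(tr, 1)
  alt[is.na(alt)] <- FALSE
  v1[alt] <- (le1 - b22)[alt]; v2[alt] <- b12[alt]
  iso <- abs(v1) + abs(v2) < 1e-12 * pmax(tr, 1)
  iso[is.na(iso)] <- FALSE
  v1[iso] <- 1; v2[iso] <- 0
  nv <- sqrt(v1^2 + v2^2)
  cth <- v1 / nv; sth <- v2 / nv
  list(s_rr = cth^2 * sig1 + sth^2 * sig2,
       s_zz = sth^2 * sig1 + cth^2 * sig2,
       s_rz = cth * sth * (sig1 - sig2),
       s_tt = sig3, J = J)
}

# Element internal force vectors (ne x 8, dof order r1 z1 r2 z2 r3 z3 r4 z4).
fem_internal_force <- function(mat, pre, ur, uz, paug = 0) {
  ne <- nrow(ur)
  kin0 <- fem_kinematics(pre$c0, ur, uz)
  J0 <- kin0$J2 * kin0$lth
  f <- matrix(0, ne, 8)
  for (gp in pre$gp) {
    kin <- fem_kinematics(gp, ur, uz)
    Jgp <- kin$J2 * kin$lth
    s <- (J0 / Jgp)^(1 / 3)
    st <- ogden_cauchy_axisym(mat, kin, s, paug)
    # spatial shape-function gradients via actual F^{-T}
    dNdx <- (kin$F22 * gp$dNdR - kin$F21 * gp$dNdZ) / kin$J2
    dNdz <- (-kin$F12 * gp$dNdR + kin$F11 * gp$dNdZ) / kin$J2
    rcur <- gp$Rgp + kin$urg
    dv <- gp$dV0 * Jgp
    Nor <- outer(1 / rcur, gp$N)
    fr <- (dNdx * st$s_rr + dNdz * st$s_rz + Nor * st$s_tt) * dv
    fz <- (dNdx * st$s_rz + dNdz * st$s_zz) * dv
    f[, c(1, 3, 5, 7)] <- f[, c(1, 3, 5, 7)] + fr
    f[, c(2, 4, 6, 8)] <- f[, c(2, 4, 6, 8)] + fz
  }
  f
}

# Global residual: assembled internal force, two-sided tie springs,
# one-sided platen contact springs, and optional stabilization anchors.
fem_residual <- function(mat, pre, u, pen, paug = 0) {
  ur <- matrix(u[pre$edof[, c(1, 3, 5, 7)]], ncol = 4)
  uz <- matrix(u[pre$edof[, c(2, 4, 6, 8)]], ncol = 4)
  fe <- fem_internal_force(mat, pre, ur, uz, paug)
  r <- numeric(length(u))
  for (a in 1:8) {
    acc <- rowsum(fe[, a], pre$edof[, a])
    idx <- as.integer(rownames(acc))
    r[idx] <- r[idx] + acc[, 1]
  }
  if (length(pen$dof))
    r[pen$dof] <- r[pen$dof] + pen$k * (u[pen$dof] - pen$target)
  if (length(pen$cdof)) {
    g <- pen$csign * (u[pen$cdof] - pen$ctarget)  # >= 0 means separated
    r[pen$cdof] <- r[pen$cdof] + pen$csign * pen$ck * pmin(g, 0)
  }
  if (length(pen$sdof))
    r[pen$sdof] <- r[pen$sdof] + pen$sk * (u[pen$sdof] - pen$starget)
  r
}

# Tangent stiffness by central finite differences of the element force.
fem_tangent <- function(mat, pre, u, pen, paug = 0, h = 1e-6) {
  ur <- matrix(u[pre$edof[, c(1, 3, 5, 7)]], ncol = 4)
  uz <- matrix(u[pre$edof[, c(2, 4, 6, 8)]], ncol = 4)
  ne <- nrow(ur)
  xs <- matrix(0, ne, 64)
  rc <- c(1, 3, 5, 7); zc <- c(2, 4, 6, 8)
  for (k in 1:8) {
    urp <- ur; uzp <- uz; urm <- ur; uzm <- uz
    if (k %% 2 == 1) { j <- (k + 1) / 2; urp[, j] <- ur[, j] + h; urm[, j] <- ur[, j] - h }
    else { j <- k / 2; uzp[, j] <- uz[, j] + h; uzm[, j] <- uz[, j] - h }
    dk <- (fem_internal_force(mat, pre, urp, uzp, paug) -
             fem_internal_force(mat, pre, urm, uzm, paug)) / (2 * h)
    xs[, (k - 1) * 8 + (1:8)] <- dk
  }
  ii <- pre$edof[, rep(1:8, times = 8)]
  jj <- pre$edof[, rep(1:8, each = 8)]
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xs),
                            dims = c(length(u), length(u)))
  di <- integer(0); dx <- numeric(0)
  if (length(pen$dof)) { di <- c(di, pen$dof); dx <- c(dx, pen$k) }
  if (length(pen$cdof)) {
    act <- pen$csign * (u[pen$cdof] - pen$ctarget) < 0
    if (any(act)) { di <- c(di, pen$cdof[act]); dx <- c(dx, pen$ck[act]) }
  }
  if (length(pen$sdof)) { di <- c(di, pen$sdof); dx <- c(dx, pen$sk) }
  if (length(di))
    K <- K + Matrix::sparseMatrix(i = di, j = di, x = dx,
                                  dims = c(length(u), length(u)))
  K
}

# Build boundary conditions for a target anvil displacement d.
# Returns fixed dof indices + values and penalty spring definitions.
fem_bcs <- function(mesh, footprints, d, contact, mu0, k_tie = 1e3) {
  tol <- 1e-8
  nds <- mesh$nodes
  top <- which(abs(nds[, 2] - mesh$stack$total) < tol)
  bot <- which(abs(nds[, 2]) < tol)
  outer_n <- which(abs(nds[, 1] - mesh$stack$r_outer) < tol)
  fixed <- integer(0); fval <- numeric(0)
  pdof <- integer(0); pk <- numeric(0); ptar <- numeric(0)
  cdof <- integer(0); ck <- numeric(0); ctar <- numeric(0); csgn <- numeric(0)
  add_fix <- function(dofs, vals) {
    fixed <<- c(fixed, dofs); fval <<- c(fval, vals)
  }
  if (contact == "full_frictionless") {
    add_fix(2L * top, rep(-d, length(top)))
    add_fix(2L * bot, rep(0, length(bot)))
  } else {
    dr <- (mesh$stack$r_outer - mesh$stack$r_inner) / mesh$nr
    kbase <- k_tie * mu0 / mesh$element_size
    apply_fp <- function(fp, nodeset, uz_target) {
      for (b in seq_len(nrow(fp$bands))) {
        bb <- fp$bands[b, ]
        sel <- nodeset[nds[nodeset, 1] >= bb$r_in - tol &
                         nds[nodeset, 1] <= bb$r_out + tol]
        if (!length(sel)) next
        if (bb$area_fraction >= 0.999) {
          add_fix(2L * sel - 1L, rep(0, length(sel)))
          add_fix(2L * sel, rep(uz_target, length(sel)))
        } else {
          atrib <- 2 * pi * nds[sel, 1] * dr
          kk <- bb$area_fraction * kbase * atrib
          pdof <<- c(pdof, 2L * sel - 1L, 2L * sel)
          pk <<- c(pk, kk, kk)
          ptar <<- c(ptar, rep(0, length(sel)), rep(uz_target, length(sel)))
        }
      }
    }
    apply_fp(footprints$anvil, top, -d)
    apply_fp(footprints$cartridge, bot, 0)
    # outer tissue surface: radially constrained, free along the axis
    add_fix(2L * outer_n - 1L, rep(0, length(outer_n)))
    # one-sided (unilateral) contact of untied surface nodes against the
    # rigid platen planes: tissue outside the contact lands may separate
    # from a platen but cannot pass through it
    kcont <- 100 * mu0 / mesh$element_size  # softer than ties: smoother
                                            # active-set transitions
    tied <- unique(c((fixed + 1L) %/% 2L, (pdof + 1L) %/% 2L))
    bot_free <- setdiff(bot, tied)
    top_free <- setdiff(top, tied)
    if (length(bot_free)) {
      kk <- kcont * 2 * pi * nds[bot_free, 1] * dr
      cdof <- c(cdof, 2L * bot_free); ck <- c(ck, kk)
      ctar <- c(ctar, rep(0, length(bot_free)))
      csgn <- c(csgn, rep(1, length(bot_free)))   # u_z >= 0
    }
    if (length(top_free)) {
      kk <- kcont * 2 * pi * nds[top_free, 1] * dr
      cdof <- c(cdof, 2L * top_free); ck <- c(ck, kk)
      ctar <- c(ctar, rep(-d, length(top_free)))
      csgn <- c(csgn, rep(-1, length(top_free)))  # u_z <= -d
    }
  }
  keep <- !duplicated(fixed)
  list(fixed = fixed[keep], fval = fval[keep],
       pen = list(dof = pdof, k = pk, target = ptar,
                  cdof = cdof, ck = ck, ctarget = ctar, csign = csgn,
                  sdof = integer(0), sk = numeric(0), starget = numeric(0)),
       anvil_nodes = top)
}

# Newton solve from state u0 (equilibrium at d0) to anvil displacement d1.
# Bisects the increment on non-convergence, up to max_bisect levels.
fem_increment <- function(mat, mesh, pre, footprints, u0, d0, d1, contact,
                          mu0, max_iter, tol_rel, max_bisect, level = 0,
                          stab = 0, k_tie = 1e3, paug = 0) {
  bc <- fem_bcs(mesh, footprints, d1, contact, mu0, k_tie)
  # predictor: add a linear through-thickness ramp of the increment
  u <- u0
  zdofs <- 2L * seq_len(nrow(mesh$nodes))
  u[zdofs] <- u[zdofs] -
    (d1 - d0) * mesh$nodes[, 2] / mesh$stack$total
  u[bc$fixed] <- bc$fval
  free <- setdiff(seq_along(u), bc$fixed)
  if (stab > 0) {
    # adaptive stabilization: weak anchors toward the predictor state,
    # engaged only when the plain increment hits a limit point (local
    # snap-through); spring scale stab * mu0 * h is orders of magnitude
    # below the tissue stiffness, so the equilibrium perturbation is
    # negligible
    bc$pen$sdof <- free
    bc$pen$sk <- rep(stab * mu0 * mesh$element_size, length(free))
    bc$pen$starget <- u[free]
  }
  resnorm <- function(uu) {
    r <- fem_residual(mat, pre, uu, bc$pen, paug)
    list(r = r, rn = sqrt(sum(r[free]^2)), ref = max(sqrt(sum(r^2)), 1e-6))
  }
  conv <- FALSE; it <- 0L
  st <- resnorm(u)
  rn_hist <- st$rn
  while (it < max_iter) {
    it <- it + 1L
    if (is.finite(st$rn) && st$rn <= tol_rel * st$ref) { conv <- TRUE; break }
    K <- fem_tangent(mat, pre, u, bc$pen, paug)
    du <- tryCatch(
      as.vector(Matrix::solve(K[free, free, drop = FALSE], -st$r[free])),
      error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du))) break
    # cap the Newton step (near-singular tangents at snapping free-edge
    # elements otherwise throw the iterate far away)
    dmax <- max(abs(du))
    if (dmax > 2 * mesh$element_size)
      du <- du * (2 * mesh$element_size / dmax)
    # non-monotone backtracking line search: accept a step that improves on
    # the worst of the recent residual norms (a strictly monotone search
    # stagnates in local basins of the residual norm near snapping states);
    # otherwise take the best finite trial
    rmax <- max(utils::tail(rn_hist, 5))
    best <- NULL
    step <- 1; ok <- FALSE
    for (ls in 1:10) {
      u_try <- u
      u_try[free] <- u[free] + step * du
      st_try <- resnorm(u_try)
      if (is.finite(st_try$rn)) {
        if (st_try$rn < 0.999 * rmax || st_try$rn <= tol_rel * st_try$ref) {
          u <- u_try; st <- st_try; ok <- TRUE; break
        }
        if (is.null(best) || st_try$rn < best$st$rn)
          best <- list(u = u_try, st = st_try)
      }
      step <- step / 2
    }
    if (!ok) {
      if (is.null(best)) break
      u <- best$u; st <- best$st
    }
    rn_hist <- c(rn_hist, st$rn)
  }
  if (!conv && is.finite(st$rn) && st$rn <= tol_rel * st$ref) conv <- TRUE
  if (!conv) {
    if (level >= max_bisect) {
      if (stab < 1)
        return(fem_increment(mat, mesh, pre, footprints, u0, d0, d1,
                             contact, mu0, max_iter, tol_rel, max_bisect,
                             level, stab = if (stab == 0) 0.01 else 10 * stab,
                             k_tie = k_tie, paug = paug))
      stop(sprintf(
        "Newton failed to converge at anvil displacement %.4g mm (after %d bisection levels)",
        d1, level))
    }
    dm <- (d0 + d1) / 2
    mid <- fem_increment(mat, mesh, pre, footprints, u0, d0, dm, contact,
                         mu0, max_iter, tol_rel, max_bisect, level + 1, stab,
                         k_tie, paug)
    return(fem_increment(mat, mesh, pre, footprints, mid$u, dm, d1, contact,
                         mu0, max_iter, tol_rel, max_bisect, level + 1, stab,
                         k_tie, paug))
  }
  # reaction on the anvil: internal force at tied dofs + spring forces
  r_full <- fem_residual(mat, pre, u, list(dof = integer(0)), paug)
  anvil_z <- 2L * bc$anvil_nodes
  f_dir <- sum(r_full[intersect(anvil_z, bc$fixed)])
  f_pen <- 0
  if (length(bc$pen$dof)) {
    on_anvil <- bc$pen$dof %in% anvil_z
    f_pen <- -sum(bc$pen$k[on_anvil] *
                    (u[bc$pen$dof[on_anvil]] - bc$pen$target[on_anvil]))
  }
  list(u = u, force = abs(f_dir + f_pen), n_iter = it)
}

#' Axisymmetric finite-element compression engine
#'
#' Quasi-static displacement-controlled compression of the two-layer annular
#' stack between rigid platens. Per load step (default 0.1 mm) an
#' incremental Newton solution is computed; nodes under the anvil footprint
#' follow the platen rigidly (bonded contact), nodes under the cartridge
#' footprint are held fixed, the layer interface shares nodes, and the outer
#' tissue surface is radially constrained but free axially. Footprint bands
#' with `area_fraction < 1` are tied through penalty springs scaled by the
#' fraction. Stresses are reported at element centroids; the current element
#' volume is the reference volume times the centroid Jacobian.
#'
#' @param mat an [ogden_material()].
#' @param stack a [tissue_stack()].
#' @param footprints list with `anvil` and `cartridge`
#'   [contact_footprint()]s; default [default_footprints()].
#' @param program a [load_program()].
#' @param mesh an [axisym_mesh][build_mesh()] for `stack`; default built at
#'   `element_size = 0.5` mm.
#' @param options list: `contact` (`"footprints"` or `"full_frictionless"`,
#'   the validation switch that reproduces the homogeneous uniaxial state),
#'   `max_iter` (Newton iterations per step, default 60), `tol_rel`
#'   (residual tolerance relative to the force norm, default 1e-6),
#'   `max_bisect` (step bisection levels, default 3), `verbose`.
#' @return list of `step_result` objects (one per converged step) with
#'   per-element centroid stresses, von Mises values, current volumes, layer
#'   tags, per-layer max/mean von Mises and the anvil reaction force in N.
#' @export
run_fem <- function(mat, stack, footprints = default_footprints(stack),
                    program = load_program(stack),
                    mesh = build_mesh(stack, 0.5),
                    options = list()) {
  stopifnot(inherits(mat, "ogden_material"), inherits(stack, "tissue_stack"),
            inherits(mesh, "axisym_mesh"), inherits(program, "load_program"))
  if (!isTRUE(all.equal(mesh$stack$total, stack$total)))
    stop("mesh does not conform to the stack")
  opt <- utils::modifyList(list(contact = "footprints", max_iter = 60L,
                                tol_rel = 1e-6, max_bisect = 3L,
                                k_tie = 300, augmentations = 3L,
                                tol_j = 0.005, verbose = FALSE), options)
  mu0 <- initial_shear_modulus(mat)
  pre <- fem_precompute(mesh)
  u <- numeric(2L * nrow(mesh$nodes))
  paug <- numeric(nrow(mesh$elems))
  d_prev <- 0
  out <- vector("list", program$n_steps)
  for (k in seq_len(program$n_steps)) {
    d <- program$d[k]
    sol <- fem_increment(mat, mesh, pre, footprints, u, d_prev, d,
                         opt$contact, mu0, opt$max_iter, opt$tol_rel,
                         opt$max_bisect, stab = 0, k_tie = opt$k_tie,
                         paug = paug)
    u <- sol$u
    # augmented-Lagrangian (Uzawa) passes: fold the penalty pressure into
    # the element multipliers and re-solve until the centroid Jacobians are
    # within tol_j of unity
    for (aug in seq_len(opt$augmentations)) {
      ur <- matrix(u[pre$edof[, c(1, 3, 5, 7)]], ncol = 4)
      uz <- matrix(u[pre$edof[, c(2, 4, 6, 8)]], ncol = 4)
      kin <- fem_kinematics(pre$c0, ur, uz)
      J0 <- kin$J2 * kin$lth
      if (max(abs(J0 - 1)) <= opt$tol_j) break
      paug <- paug + mat$penalty_bulk * (J0 - 1)
      sol <- fem_increment(mat, mesh, pre, footprints, u, d, d,
                           opt$contact, mu0, opt$max_iter, opt$tol_rel,
                           opt$max_bisect, stab = 0, k_tie = opt$k_tie,
                           paug = paug)
      u <- sol$u
    }
    d_prev <- d
    ur <- matrix(u[pre$edof[, c(1, 3, 5, 7)]], ncol = 4)
    uz <- matrix(u[pre$edof[, c(2, 4, 6, 8)]], ncol = 4)
    kin <- fem_kinematics(pre$c0, ur, uz)
    st <- ogden_cauchy_axisym(mat, kin, 1, paug)
    stress <- cauchy_axisym(s_rr = st$s_rr, s_zz = st$s_zz,
                            s_tt = st$s_tt, s_rz = st$s_rz)
    out[[k]] <- new_step_result(step = k, d = d, stack = stack,
                                stress = stress,
                                vol_cur = mesh$vol_ref * st$J,
                                vol_ref = mesh$vol_ref,
                                layer = mesh$layer, force = sol$force,
                                n_iter = sol$n_iter)
    if (isTRUE(opt$verbose))
      message(sprintf(
        "step %d: d = %.2f mm (ratio %.2f), %d Newton iters, force %.4g N, max vM upper %.3g lower %.3g MPa",
        k, d, d / stack$total, sol$n_iter, sol$force,
        out[[k]]$layer_stats$max_vm[1], out[[k]]$layer_stats$max_vm[2]))
  }
  out
}
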