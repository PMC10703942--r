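# Quasi-static total-Lagrangian finite elements on linear tetrahedra (C3D4):
# follower surface pressure, prescribed displacements, optional rigid-obstacle
# penalty contact, full Newton with increment cutback.

#' Piecewise-linear amplitude schedule
#'
#' Scales loads and prescribed displacements over pseudo-time.  The default
#' knots (0,0) -> (2,1) -> (5,0) describe one breathing cycle: pressure ramps
#' up during exhalation (0-2 s) and back down during inhalation (2-5 s).
#'
#' @param times knot times (s), strictly increasing, starting at 0.
#' @param factors knot factors (dimensionless, finite).
#' @return object of class \code{"amplitude_schedule"}; evaluate with
#'   \code{schedule_factor()}.
#' @export
amplitude_schedule <- function(times = c(0, 2, 5), factors = c(0, 1, 0)) {
  if (length(times) != length(factors) || length(times) < 2)
    rm_stop("schedule needs matching times and factors (>= 2 knots)",
            "respmech_config")
  if (times[1] != 0) rm_stop("schedule must start at t = 0", "respmech_config")
  if (any(diff(times) <= 0)) rm_stop("schedule times must be strictly increasing",
                                     "respmech_config")
  if (any(!is.finite(factors))) rm_stop("schedule factors must be finite",
                                        "respmech_config")
  structure(list(times = times, factors = factors),
            class = "amplitude_schedule")
}

#' @rdname amplitude_schedule
#' @param schedule an \code{amplitude_schedule}.
#' @param t time (s), clamped to the knot range.
#' @export
schedule_factor <- function(schedule, t) {
  stats::approx(schedule$times, schedule$factors, xout = t, rule = 2)$y
}

#' Follower (or dead) surface pressure load
#'
#' @param facet_set name of the loaded boundary facet set.
#' @param magnitude peak pressure (kPa), >= 0; positive pushes against the
#'   outward normal (compression).  The transpulmonary load of quiet
#'   breathing peaks at 10 cmH2O = 0.98 kPa.
#' @param follower evaluate areas and normals on the deformed surface
#'   (default TRUE); FALSE gives a dead load on the reference surface.
#' @param schedule optional \code{amplitude_schedule}; defaults to the
#'   simulation schedule.
#' @return object of class \code{"pressure_load"}.
#' @export
pressure_load <- function(facet_set = "outer_surface", magnitude = 0.98,
                          follower = TRUE, schedule = NULL) {
  if (magnitude < 0) rm_stop("pressure magnitude must be >= 0",
                             "respmech_config")
  structure(list(facet_set = facet_set, magnitude = magnitude,
                 follower = follower, schedule = schedule),
            class = "pressure_load")
}

#' Displacement boundary condition on a node set
#'
#' Axes with \code{fix = TRUE} are constrained; they follow
#' \code{displacement} scaled by the schedule (zero displacement by
#' default).  The tracheal fixation (BC-1) fixes all three axes; the
#' diaphragm condition fixes X and Y and prescribes the scheduled
#' superior-inferior motion on Z.
#'
#' @param node_set name of the constrained node set.
#' @param fix logical length-3 mask (x, y, z).
#' @param displacement length-3 prescribed displacement (mm) reached at
#'   schedule factor 1; entries on non-fixed axes must be zero.
#' @param schedule optional \code{amplitude_schedule}; defaults to the
#'   simulation schedule.
#' @return object of class \code{"boundary_condition"}.
#' @export
boundary_condition <- function(node_set, fix = c(TRUE, TRUE, TRUE),
                               displacement = c(0, 0, 0), schedule = NULL) {
  fix <- as.logical(fix)
  if (length(fix) != 3 || anyNA(fix))
    rm_stop("fix must be 3 logicals", "respmech_config")
  if (length(displacement) != 3 || any(displacement[!fix] != 0))
    rm_stop("prescribed displacement only on fixed axes", "respmech_config")
  structure(list(node_set = node_set, fix = fix,
                 displacement = as.numeric(displacement), schedule = schedule),
            class = "boundary_condition")
}

#' Rigid obstacle for frictionless penalty contact
#'
#' @param surface a \code{tri_surface}, oriented with outward normals (nodes
#'   are pushed back along the local outward normal).
#' @param stiffness penalty stiffness (kPa/mm per unit nodal area
#'   equivalent, i.e. mN/mm of penetration per node), > 0.
#' @param active logical.
#' @return object of class \code{"rigid_obstacle"}.
#' @export
rigid_obstacle <- function(surface, stiffness, active = TRUE) {
  if (!inherits(surface, "tri_surface"))
    rm_stop("obstacle needs a tri_surface", "respmech_config")
  if (active && stiffness <= 0) rm_stop("penalty stiffness must be > 0",
                                        "respmech_config")
  structure(list(surface = surface, stiffness = stiffness, active = active),
            class = "rigid_obstacle")
}

#' Solver configuration
#'
#' @param n_increments pseudo-time increments over the schedule (default 50).
#' @param tol_rel relative residual tolerance (default 1e-6).
#' @param tol_abs absolute residual tolerance (mN, default 1e-8).
#' @param max_iter Newton iterations per increment (default 25).
#' @param max_cutbacks increment halvings on failure (default 4).
#' @param tangent \code{"analytic"} or \code{"finite_difference"} element
#'   material tangent.
#' @param load_stiffness include the follower-pressure configuration
#'   derivative in the tangent (default TRUE; disabling recovers a
#'   material-tangent-only Newton whose convergence degrades at breathing
#'   pressures).
#' @return object of class \code{"solver_config"}.
#' @export
solver_config <- function(n_increments = 50L, tol_rel = 1e-6, tol_abs = 1e-8,
                          max_iter = 25L, max_cutbacks = 4L,
                          tangent = c("analytic", "finite_difference"),
                          load_stiffness = TRUE) {
  if (n_increments < 1 || tol_rel <= 0 || tol_abs <= 0 || max_iter < 1 ||
      max_cutbacks < 0)
    rm_stop("invalid solver configuration", "respmech_config")
  structure(list(n_increments = as.integer(n_increments), tol_rel = tol_rel,
                 tol_abs = tol_abs, max_iter = as.integer(max_iter),
                 max_cutbacks = as.integer(max_cutbacks),
                 tangent = match.arg(tangent),
                 load_stiffness = isTRUE(load_stiffness)),
            class = "solver_config")
}

# ---- element level ----

# reference shape-function gradients G (4 x 3) and volumes for all elements
precompute_elements <- function(mesh) {
  E <- nrow(mesh$tets)
  G <- vector("list", E)
  V <- numeric(E)
  for (e in seq_len(E)) {
    X <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    B <- t(X[2:4, , drop = FALSE]) - X[1, ]     # 3x3 edge matrix
    Binv <- solve(B)                            # rows: grad N2..N4
    G[[e]] <- rbind(-colSums(Binv), Binv)
    V[e] <- det(B) / 6
  }
  list(G = G, V = V)
}

#' Deformation state of one element
#'
#' Constant deformation gradient of a linear tetrahedron,
#' F = I + (du/dX) from the reference shape-function gradients.
#'
#' @param mesh a \code{tet_mesh}.
#' @param element element index.
#' @param u nodal displacement matrix (n x 3, mm).
#' @return a \code{\link{deformation_state}}; errors with class
#'   \code{respmech_state} if the element is inverted.
#' @export
element_kinematics <- function(mesh, element, u) {
  X <- mesh$nodes[mesh$tets[element, ], , drop = FALSE]
  B <- t(X[2:4, , drop = FALSE]) - X[1, ]
  Binv <- solve(B)
  G <- rbind(-colSums(Binv), Binv)                 # 4x3 shape gradients
  ue <- u[mesh$tets[element, ], , drop = FALSE]
  deformation_state(diag(3) + t(ue) %*% G)
}

# element force (4x3) and optional 12x12 stiffness for one element
element_force_stiff <- function(model, G, V, ue, tangent = TRUE,
                                fd = FALSE) {
  Fg <- diag(3) + t(ue) %*% G
  st <- deformation_state(Fg)
  P <- pk1_stress(model, st)
  f <- V * G %*% t(P)                     # f[a, i]
  if (!tangent) return(list(f = f))
  A <- if (fd) fd_material_tangent(model, Fg) else material_tangent(model, st)
  K <- matrix(0, 12, 12)
  for (i in 1:3) for (k in 1:3) {
    Kik <- V * G %*% A[i, , k, ] %*% t(G) # 4x4
    K[seq(i, 12, by = 3), seq(k, 12, by = 3)] <- Kik
  }
  list(f = f, K = K)
}

fd_material_tangent <- function(model, Fg, h = 1e-7) {
  A <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (L in 1:3) {
    Fp <- Fg; Fp[k, L] <- Fp[k, L] + h
    Fm <- Fg; Fm[k, L] <- Fm[k, L] - h
    A[, , k, L] <- (pk1_stress(model, Fp) - pk1_stress(model, Fm)) / (2 * h)
  }
  A
}

#' Internal nodal forces (and tangent) of the assembled mesh
#'
#' Total-Lagrangian internal force vector \eqn{f = \sum_e V_e P_e \nabla N}
#' and, optionally, the assembled tangent stiffness (material + geometric).
#'
#' @param mesh a \code{tet_mesh}.
#' @param material a hyperelastic model (applied to every element) or a list
#'   \code{list(default = , <element_set> = )} keyed by \code{mesh$element_sets}.
#' @param u nodal displacements (n x 3, mm).
#' @param tangent also assemble the sparse tangent (default FALSE).
#' @param fd_tangent use finite-difference element tangents.
#' @return list with \code{f} (n x 3 internal forces, mN) and, when
#'   requested, sparse \code{K} (3n x 3n, mN/mm).
#' @export
internal_forces <- function(mesh, material, u, tangent = FALSE,
                            fd_tangent = FALSE) {
  pre <- precompute_elements(mesh)
  mats <- material_map(mesh, material)
  asm <- assemble_internal(mesh, mats, pre, u, tangent, fd_tangent)
  if (tangent) asm else list(f = asm$f)
}

material_map <- function(mesh, material) {
  E <- nrow(mesh$tets)
  if (inherits(material, "hyperelastic_model") ||
      inherits(material, "elastic_surrogate")) {
    m <- as_hyperelastic(material)
    if (all(m$D == 0))
      rm_stop("displacement-based FEM needs a compressible material (D1 > 0)",
              "respmech_config")
    return(rep(list(m), E))
  }
  if (!is.list(material) || is.null(material$default))
    rm_stop("material must be a model or list with a 'default'",
            "respmech_config")
  out <- rep(list(as_hyperelastic(material$default)), E)
  for (nm in setdiff(names(material), "default")) {
    idx <- mesh$element_sets[[nm]]
    if (is.null(idx)) rm_stop(sprintf("no element set '%s'", nm),
                              "respmech_config")
    out[idx] <- list(as_hyperelastic(material[[nm]]))
  }
  for (m in unique(out)) if (all(m$D == 0))
    rm_stop("displacement-based FEM needs compressible materials (D1 > 0)",
            "respmech_config")
  out
}

assemble_internal <- function(mesh, mats, pre, u, tangent, fd = FALSE) {
  E <- nrow(mesh$tets)
  n <- nrow(mesh$nodes)
  f <- matrix(0, n, 3)
  if (tangent) {
    vals <- numeric(144 * E)
    rows <- integer(144 * E); cols <- integer(144 * E)
  }
  for (e in seq_len(E)) {
    en <- mesh$tets[e, ]
    ue <- u[en, , drop = FALSE]
    efs <- element_force_stiff(mats[[e]], pre$G[[e]], pre$V[e], ue,
                               tangent = tangent, fd = fd)
    f[en, ] <- f[en, ] + efs$f
    if (tangent) {
      idx <- rep((en - 1L) * 3L, each = 3L) + rep(1:3, 4)
      o <- (e - 1L) * 144L
      rows[o + seq_len(144)] <- rep(idx, times = 12)
      cols[o + seq_len(144)] <- rep(idx, each = 12)
      vals[o + seq_len(144)] <- as.numeric(efs$K)
    }
  }
  if (!tangent) return(list(f = f))
  K <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(3 * n, 3 * n))
  list(f = f, K = K)
}

#' Nodal forces of a uniform surface pressure
#'
#' Per facet: force = p x (current facet area) x (inward normal), lumped
#' equally onto the three facet nodes.  With \code{x} the deformed
#' coordinates this is the follower load; with reference coordinates it is a
#' dead load.
#'
#' @param mesh a \code{tet_mesh}.
#' @param facets boundary facet row indices (e.g.
#'   \code{mesh$facet_sets$outer_surface}).
#' @param x coordinates to evaluate areas/normals on (n x 3, mm).
#' @param p pressure (kPa); positive compresses (force opposite the outward
#'   normal).
#' @return n x 3 nodal force matrix (mN).
#' @export
follower_pressure_forces <- function(mesh, facets, x, p) {
  tris <- mesh$boundary[facets, , drop = FALSE]
  a <- x[tris[, 1], , drop = FALSE]
  b <- x[tris[, 2], , drop = FALSE]
  c_ <- x[tris[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  An <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2  # outward area vectors
  if (any(!is.finite(An))) warning("degenerate deformed facet: zero contribution")
  An[!is.finite(An)] <- 0
  f <- matrix(0, nrow(x), 3)
  contrib <- -p * An / 3
  for (k in 1:3) {
    agg <- rowsum(contrib, tris[, k], reorder = FALSE)
    f[as.integer(rownames(agg)), ] <- f[as.integer(rownames(agg)), ] + agg
  }
  f
}

# Load-stiffness (configuration derivative) of the follower pressure:
# d f_ext / d x as sparse triplets.  Per facet, f_node = -(p/3) An with
# An = (a x b + b x c + c x a)/2, so dAn/da = [c - b]_x / 2 etc.
follower_pressure_stiffness <- function(mesh, facets, x, p) {
  tris <- mesh$boundary[facets, , drop = FALSE]
  nt <- nrow(tris)
  rows <- integer(81 * nt); cols <- integer(81 * nt); vals <- numeric(81 * nt)
  crossmat <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1],
                                   v[2], -v[1], 0), 3, 3)
  o <- 0L
  for (t in seq_len(nt)) {
    nd <- tris[t, ]
    a <- x[nd[1], ]; b <- x[nd[2], ]; c_ <- x[nd[3], ]
    dAn <- list(crossmat(c_ - b) / 2, crossmat(a - c_) / 2,
                crossmat(b - a) / 2)
    for (k in 1:3) for (m in 1:3) {
      blk <- -(p / 3) * dAn[[m]]
      rows[o + 1:9] <- rep((nd[k] - 1L) * 3L + 1:3, 3)
      cols[o + 1:9] <- rep((nd[m] - 1L) * 3L + 1:3, each = 3)
      vals[o + 1:9] <- as.numeric(blk)
      o <- o + 9L
    }
  }
  list(i = rows, j = cols, x = vals)
}

#' Frictionless rigid-obstacle penalty forces
#'
#' Nodes penetrating the obstacle (negative signed distance along the local
#' outward normal of the closest triangle) receive a restoring force
#' k x depth along that normal; non-penetrating nodes get zero.
#'
#' @param x node positions (n x 3, mm).
#' @param obstacle a \code{\link{rigid_obstacle}}.
#' @return list: \code{f} (n x 3, mN), \code{depth} (n penetration depths,
#'   mm, 0 when clear), \code{normal} (n x 3 obstacle normals).
#' @export
rigid_contact_forces <- function(x, obstacle) {
  n <- nrow(x)
  out <- list(f = matrix(0, n, 3), depth = numeric(n),
              normal = matrix(0, n, 3))
  if (!obstacle$active) return(out)
  sv <- obstacle$surface$vertices
  sf <- obstacle$surface$faces
  for (i in seq_len(n)) {
    cp <- closest_point_on_surface(x[i, ], sv, sf)
    d <- sum((x[i, ] - cp$point) * cp$normal)
    if (d < 0) {
      out$depth[i] <- -d
      out$normal[i, ] <- cp$normal
      out$f[i, ] <- obstacle$stiffness * (-d) * cp$normal
    }
  }
  out
}

closest_point_on_surface <- function(p, verts, faces) {
  best <- list(d2 = Inf)
  for (t in seq_len(nrow(faces))) {
    tri <- verts[faces[t, ], , drop = FALSE]
    q <- closest_point_on_triangle(p, tri)
    d2 <- sum((p - q)^2)
    if (d2 < best$d2) {
      nrm <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      best <- list(d2 = d2, point = q, normal = nrm / sqrt(sum(nrm^2)))
    }
  }
  best
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Ericson-style closest point on triangle
closest_point_on_triangle <- function(p, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c_ <- tri[3, ]
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c_; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c_)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c_ - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

# ---- quasi-static solve ----

#' Quasi-static breathing simulation
#'
#' Solves static equilibrium at each pseudo-time increment of the schedule
#' by full Newton iteration on the total-Lagrangian residual: internal
#' forces from the hyperelastic material minus follower pressure, contact
#' and prescribed-displacement reactions.  Failed increments are retried at
#' half the step (up to \code{max_cutbacks} halvings).  The tangent includes
#' the follower-pressure load stiffness by default (see
#' \code{\link{solver_config}}); at breathing pressures the soft lung
#' material makes this term necessary for Newton convergence.
#'
#' @param mesh a \code{tet_mesh} with the sets referenced by BCs and loads.
#' @param material hyperelastic model (or per-element-set list); must be
#'   compressible (D1 > 0).
#' @param bcs list of \code{\link{boundary_condition}}.
#' @param loads list of \code{\link{pressure_load}}.
#' @param obstacle optional \code{\link{rigid_obstacle}}.
#' @param schedule an \code{\link{amplitude_schedule}} (default one
#'   breathing cycle, exhalation 0-2 s then inhalation 2-5 s).
#' @param config a \code{\link{solver_config}}.
#' @return object of class \code{"breath_sim"}: \code{times} (s),
#'   \code{U} (list of n x 3 displacement fields, mm), \code{volumes} (L),
#'   \code{log} (data.frame: increment, time, iterations, residual,
#'   cutbacks), \code{converged}, and the input \code{mesh}.
#' @export
solve_quasistatic <- function(mesh, material, bcs = list(), loads = list(),
                              obstacle = NULL,
                              schedule = amplitude_schedule(),
                              config = solver_config()) {
  n <- nrow(mesh$nodes)
  pre <- precompute_elements(mesh)
  mats <- material_map(mesh, material)
  for (bc in bcs) if (is.null(mesh$node_sets[[bc$node_set]]))
    rm_stop(sprintf("no node set '%s'", bc$node_set), "respmech_config")
  for (ld in loads) if (is.null(mesh$facet_sets[[ld$facet_set]]))
    rm_stop(sprintf("no facet set '%s'", ld$facet_set), "respmech_config")

  # constrained dof bookkeeping
  fixed <- matrix(FALSE, n, 3)
  for (bc in bcs) fixed[mesh$node_sets[[bc$node_set]], bc$fix] <- TRUE
  free <- which(!t(fixed))      # dof order (node-major, axis fastest)
  if (!length(free)) rm_stop("no free degrees of freedom", "respmech_config")

  prescribed_u <- function(t) {
    u <- matrix(0, n, 3)
    for (bc in bcs) {
      s <- schedule_factor(bc$schedule %||% schedule, t)
      set <- mesh$node_sets[[bc$node_set]]
      for (ax in which(bc$fix))
        u[set, ax] <- s * bc$displacement[ax]
    }
    u
  }
  external <- function(x, t) {
    f <- matrix(0, n, 3)
    for (ld in loads) {
      s <- schedule_factor(ld$schedule %||% schedule, t)
      xs <- if (ld$follower) x else mesh$nodes
      f <- f + follower_pressure_forces(mesh, mesh$facet_sets[[ld$facet_set]],
                                        xs, s * ld$magnitude)
    }
    contact <- NULL
    if (!is.null(obstacle) && obstacle$active) {
      contact <- rigid_contact_forces(x, obstacle)
      f <- f + contact$f
    }
    list(f = f, contact = contact)
  }

  u <- matrix(0, n, 3)
  t_end <- max(schedule$times)
  targets <- seq(0, t_end, length.out = config$n_increments + 1)[-1]
  times <- numeric(0); Us <- list(); vols <- numeric(0)
  log <- data.frame(); histories <- list()
  t_now <- 0; inc <- 0L; converged_all <- TRUE

  solve_to <- function(t_target, u0) {
    # returns list(u, iters, res) or condition of class respmech_noconv
    uk <- u0
    up <- prescribed_u(t_target)
    uk[fixed] <- up[fixed]                  # impose prescribed values
    hist <- numeric(0)
    for (it in seq_len(config$max_iter)) {
      asm <- assemble_internal(mesh, mats, pre, uk, tangent = TRUE,
                               fd = config$tangent == "finite_difference")
      ext <- external(mesh$nodes + uk, t_target)
      R <- as.numeric(t(asm$f - ext$f))     # dof vector, axis fastest
      ref <- max(sqrt(sum(as.numeric(t(ext$f))[free]^2)),
                 sqrt(sum(as.numeric(t(asm$f))[free]^2)), config$tol_abs)
      rnorm_ <- sqrt(sum(R[free]^2))
      hist <- c(hist, rnorm_)
      if (rnorm_ <= max(config$tol_rel * ref, config$tol_abs))
        return(list(u = uk, iters = it - 1L, res = rnorm_, hist = hist))
      K <- asm$K
      if (config$load_stiffness) {
        for (ld in loads) {
          if (!ld$follower) next
          s <- schedule_factor(ld$schedule %||% schedule, t_target)
          if (s * ld$magnitude == 0) next
          tr <- follower_pressure_stiffness(mesh,
                                            mesh$facet_sets[[ld$facet_set]],
                                            mesh$nodes + uk, s * ld$magnitude)
          K <- K - Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                        dims = dim(K))
        }
      }
      if (!is.null(ext$contact) && any(ext$contact$depth > 0)) {
        pen <- which(ext$contact$depth > 0)
        trip <- do.call(rbind, lapply(pen, function(i) {
          nrm <- ext$contact$normal[i, ]
          blk <- obstacle$stiffness * outer(nrm, nrm)
          cbind(rep((i - 1) * 3 + 1:3, 3), rep((i - 1) * 3 + 1:3, each = 3),
                as.numeric(blk))
        }))
        K <- K + Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2],
                                      x = trip[, 3], dims = dim(K))
      }
      du <- Matrix::solve(K[free, free, drop = FALSE], -R[free])
      ut <- t(uk); ut[free] <- ut[free] + as.numeric(du); uk <- t(ut)
    }
    rm_stop("Newton did not converge", "respmech_noconv")
  }

  while (t_now < t_end - 1e-12) {
    rem <- targets[targets > t_now + 1e-12]
    t_target <- if (length(rem)) rem[1] else t_end
    dt <- t_target - t_now
    cutbacks <- 0L
    repeat {
      res <- tryCatch(solve_to(t_now + dt, u),
                      respmech_noconv = function(e) e,
                      respmech_state = function(e) e)
      if (!inherits(res, "condition")) break
      cutbacks <- cutbacks + 1L
      if (cutbacks > config$max_cutbacks) {
        warning(sprintf("increment at t=%.3f s failed after %d cutbacks; partial result",
                        t_now + dt, config$max_cutbacks))
        converged_all <- FALSE
        break
      }
      dt <- dt / 2
    }
    if (inherits(res, "condition")) break
    u <- res$u
    t_now <- t_now + dt
    inc <- inc + 1L
    times <- c(times, t_now)
    Us[[length(Us) + 1L]] <- u
    vols <- c(vols, sum(signed_tet_volumes(mesh$nodes + u, mesh$tets)) / 1e6)
    log <- rbind(log, data.frame(increment = inc, time = t_now,
                                 iterations = res$iters, residual = res$res,
                                 cutbacks = cutbacks))
    histories[[length(histories) + 1L]] <- res$hist
  }
  structure(list(times = times, U = Us, volumes = vols, log = log,
                 newton_history = histories,
                 converged = converged_all, mesh = mesh,
                 schedule = schedule, config = config),
            class = "breath_sim")
}

#' @export
print.breath_sim <- function(x, ...) {
  cat(sprintf("breath_sim: %d accepted increments to t = %.3g s (%s)\n",
              nrow(x$log), if (length(x$times)) max(x$times) else 0,
              if (x$converged) "converged" else "PARTIAL"))
  if (length(x$volumes))
    cat(sprintf("  volume: %.4g L initial -> %.4g L final (min %.4g L)\n",
                mesh_volume(x$mesh, units = "L"), x$volumes[length(x$volumes)],
                min(x$volumes)))
  cat(sprintf("  Newton iterations: %s\n",
              paste(x$log$iterations, collapse = " ")))
  invisible(x)
}

#' @export
plot.breath_sim <- function(x, ...) {
  graphics::plot(c(0, x$times), c(mesh_volume(x$mesh, units = "L"), x$volumes),
                 type = "b", xlab = "time [s]", ylab = "volume [L]",
                 main = "deformed lung volume", ...)
  invisible(x)
}

#' Total stored strain energy of a displaced mesh
#'
#' @inheritParams internal_forces
#' @return scalar energy (kPa mm^3 = nJ... in this unit system, mN mm).
#' @export
total_strain_energy <- function(mesh, material, u) {
  pre <- precompute_elements(mesh)
  mats <- material_map(mesh, material)
  tot <- 0
  for (e in seq_len(nrow(mesh$tets))) {
    ue <- u[mesh$tets[e, ], , drop = FALSE]
    Fg <- diag(3) + t(ue) %*% pre$G[[e]]
    tot <- tot + pre$V[e] * strain_energy(mats[[e]], Fg)
  }
  tot
}

#' Structured tetrahedral ball mesh (validation geometry)
#'
#' Cube-to-ball mapped structured mesh of the full ball of given radius,
#' with the whole boundary as facet set \code{"surface"} and node sets
#' \code{"center"}, \code{"xaxis"}, \code{"z0plane"} for minimal rigid-mode
#' suppression (3-2-1 support).
#'
#' @param radius mm.
#' @param edge target edge length (mm).
#' @return a \code{\link{tet_mesh}}.
#' @export
build_ball_mesh <- function(radius = 20, edge = 8) {
  nr <- 2L * max(2L, as.integer(ceiling(radius / edge)))
  g <- seq(-1, 1, length.out = nr + 1)
  idx <- function(i, j, k) i + (nr + 1L) * (j - 1L + (nr + 1L) * (k - 1L))
  p <- as.matrix(expand.grid(x = g, y = g, z = g))
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  nodes <- cbind(x * sqrt(pmax(0, 1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3)),
                 y * sqrt(pmax(0, 1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3)),
                 z * sqrt(pmax(0, 1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3))) *
    radius
  cells <- expand.grid(i = seq_len(nr), j = seq_len(nr), k = seq_len(nr))
  ncell <- nrow(cells)
  ei <- diag(3)
  corner <- function(off) idx(cells$i + off[1], cells$j + off[2],
                              cells$k + off[3])
  tets <- matrix(0L, 6L * ncell, 4L)
  row <- 0L
  for (pm in seq_len(6)) {
    o0 <- c(0L, 0L, 0L)
    o1 <- o0 + ei[kuhn_perms[pm, 1], ]
    o2 <- o1 + ei[kuhn_perms[pm, 2], ]
    tets[row + seq_len(ncell), ] <- cbind(corner(o0), corner(o1), corner(o2),
                                          corner(c(1L, 1L, 1L)))
    row <- row + ncell
  }
  mesh <- tet_mesh(nodes, tets)
  tol <- 1e-9 * radius
  center <- which(rowSums(mesh$nodes^2) < tol^2)
  xaxis <- which(abs(mesh$nodes[, 2]) < tol & abs(mesh$nodes[, 3]) < tol &
                   mesh$nodes[, 1] > tol)
  z0 <- which(abs(mesh$nodes[, 3]) < tol)
  mesh$node_sets <- list(center = center,
                         xaxis = xaxis[which.max(mesh$nodes[xaxis, 1])],
                         z0plane = setdiff(z0, c(center, xaxis))[1])
  mesh$facet_sets <- list(surface = seq_len(nrow(mesh$boundary)))
  mesh
}
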