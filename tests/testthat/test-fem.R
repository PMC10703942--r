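# 6-tet unit cube with roller supports and a loaded top face, built in code
unit_cube_mesh <- function() {
  g <- c(0, 1)
  nodes <- unname(as.matrix(expand.grid(g, g, g)))
  idx <- function(i, j, k) i + 2 * (j - 1 + 2 * (k - 1))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ei <- diag(3)
  tets <- t(apply(perms, 1, function(pm) {
    o0 <- c(0, 0, 0); o1 <- o0 + ei[pm[1], ]; o2 <- o1 + ei[pm[2], ]
    c(idx(1 + o0[1], 1 + o0[2], 1 + o0[3]),
      idx(1 + o1[1], 1 + o1[2], 1 + o1[3]),
      idx(1 + o2[1], 1 + o2[2], 1 + o2[3]), idx(2, 2, 2))
  }))
  m <- tet_mesh(nodes, tets)
  fz <- matrix(m$nodes[m$boundary, 3], ncol = 3)
  m$facet_sets <- list(top = which(rowSums(fz == 1) == 3))
  m$node_sets <- list(x0 = which(nodes[, 1] == 0), y0 = which(nodes[, 2] == 0),
                      z0 = which(nodes[, 3] == 0))
  m
}

nh_surrogate <- function() as_hyperelastic(elastic_surrogate(E = 5, nu = 0.3))

test_that("element kinematics: identity, affine completeness, FD oracle", {
  m <- unit_cube_mesh()
  u0 <- matrix(0, nrow(m$nodes), 3)
  st <- element_kinematics(m, 1, u0)
  expect_equal(st$F, diag(3), tolerance = 1e-14)
  expect_equal(st$J, 1, tolerance = 1e-14)
  set.seed(8)
  A <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
  if (det(A) <= 0) A <- diag(3)
  uA <- m$nodes %*% t(A - diag(3))
  for (e in seq_len(nrow(m$tets)))
    expect_equal(element_kinematics(m, e, uA)$F, A, tolerance = 1e-12)
  # direct oracle: F maps reference edges to deformed edges
  u <- matrix(rnorm(nrow(m$nodes) * 3, 0, 0.02), ncol = 3)
  e <- 3
  Fk <- element_kinematics(m, e, u)$F
  X <- m$nodes[m$tets[e, ], ]; xdef <- X + u[m$tets[e, ], ]
  Eref <- t(X[2:4, ]) - X[1, ]; Edef <- t(xdef[2:4, ]) - xdef[1, ]
  expect_equal(Fk, Edef %*% solve(Eref), tolerance = 1e-12)
  # inverted element signals an invalid state
  ubad <- m$nodes %*% t(diag(c(-0.5, 1, 1)) - diag(3))
  expect_error(element_kinematics(m, 1, ubad), class = "respmech_state")
})

test_that("internal forces: zero at rest, frame-invariant, single-tet oracle", {
  m <- unit_cube_mesh()
  mat <- nh_surrogate()
  n <- nrow(m$nodes)
  expect_equal(internal_forces(m, mat, matrix(0, n, 3))$f,
               matrix(0, n, 3), tolerance = 1e-12)
  trans <- matrix(rep(c(3, -2, 7), each = n), n, 3)
  expect_equal(internal_forces(m, mat, trans)$f, matrix(0, n, 3),
               tolerance = 1e-9)
  # single regular tet: nodal force equals -P S_a / 3 with S_a the outward
  # area vector of the face opposite node a (hand-integrated oracle)
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tt <- tet_mesh(nodes, matrix(1:4, 1))
  A <- diag(c(1.2, 0.95, 0.9))
  u <- nodes %*% t(A - diag(3))
  P <- pk1_stress(mat, A)
  f <- internal_forces(tt, mat, u)$f
  faces <- list(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2)) # opp. 1..4, outward
  for (a in 1:4) {
    v <- nodes[faces[[a]], ]
    S <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ]) / 2
    expect_equal(f[a, ], as.numeric(-P %*% S) / 3, tolerance = 1e-10)
  }
})

test_that("assembled tangent matches finite differences of the forces", {
  m <- unit_cube_mesh()
  mat <- nh_surrogate()
  n <- nrow(m$nodes)
  set.seed(3)
  u <- matrix(rnorm(3 * n, 0, 0.02), n, 3)
  asm <- internal_forces(m, mat, u, tangent = TRUE)
  h <- 1e-6
  for (trial in 1:5) {
    d <- matrix(rnorm(3 * n), n, 3); d <- d / sqrt(sum(d^2))
    fp <- internal_forces(m, mat, u + h * d)$f
    fm <- internal_forces(m, mat, u - h * d)$f
    fd <- as.numeric(t(fp - fm)) / (2 * h)
    Kd <- as.numeric(asm$K %*% as.numeric(t(d)))
    expect_equal(Kd, fd, tolerance = 1e-4 * max(abs(fd)))
  }
})

test_that("residual is the gradient of the total potential for dead loads", {
  m <- unit_cube_mesh()
  mat <- nh_surrogate()
  n <- nrow(m$nodes)
  fext <- matrix(0, n, 3); fext[m$nodes[, 3] == 1, 3] <- 0.25 # dead nodal load
  set.seed(9)
  u <- matrix(rnorm(3 * n, 0, 0.01), n, 3)
  pot <- function(uu) total_strain_energy(m, mat, uu) - sum(fext * uu)
  R <- internal_forces(m, mat, u)$f - fext
  h <- 1e-6
  for (trial in 1:3) {
    d <- matrix(rnorm(3 * n), n, 3); d <- d / sqrt(sum(d^2))
    fd <- (pot(u + h * d) - pot(u - h * d)) / (2 * h)
    expect_equal(sum(R * d), fd, tolerance = 1e-6 * max(1, abs(fd)))
  }
})

test_that("follower pressure: definition, closed-surface balance, area scaling", {
  # two triangles tiling the unit square in the x-y plane, outward +z
  m <- unit_cube_mesh()
  top <- m$facet_sets$top
  x <- m$nodes
  f <- follower_pressure_forces(m, top, x, p = 1)
  tot <- colSums(f)
  expect_equal(tot, c(0, 0, -1), tolerance = 1e-12)  # 1 kPa x 1 mm^2 = 1 mN
  # closed surface, uniform p: net force vanishes
  all_facets <- seq_len(nrow(m$boundary))
  fc <- follower_pressure_forces(m, all_facets, x, p = 0.7)
  expect_equal(colSums(fc), c(0, 0, 0), tolerance = 1e-12)
  # scaling deformed coordinates by 2 scales forces by 4
  f2 <- follower_pressure_forces(m, top, 2 * x, p = 1)
  expect_equal(colSums(f2), 4 * tot, tolerance = 1e-12)
})

test_that("rigid contact: clearance, penalty law, frictionless direction", {
  # obstacle: floor z = 0 (two large triangles, outward +z)
  floor_s <- tri_surface(rbind(c(-10, -10, 0), c(10, -10, 0),
                               c(10, 10, 0), c(-10, 10, 0)),
                         rbind(c(1, 2, 3), c(1, 3, 4)), check = FALSE)
  obs <- rigid_obstacle(floor_s, stiffness = 100)
  x <- rbind(c(0, 0, 1), c(1, 2, -0.1), c(-3, 1, -0.02))
  rc <- rigid_contact_forces(x, obs)
  expect_equal(rc$f[1, ], c(0, 0, 0))
  expect_equal(rc$f[2, ], c(0, 0, 10), tolerance = 1e-12) # 100 * 0.1
  expect_equal(rc$depth[3], 0.02, tolerance = 1e-12)
  # frictionless: no tangential component for random penetrating nodes
  set.seed(4)
  xr <- cbind(runif(5, -5, 5), runif(5, -5, 5), -runif(5, 0.01, 0.2))
  rr <- rigid_contact_forces(xr, obs)
  expect_equal(rr$f[, 1:2], matrix(0, 5, 2), tolerance = 1e-12)
  inact <- rigid_obstacle(floor_s, stiffness = 100, active = FALSE)
  expect_equal(rigid_contact_forces(x, inact)$f, matrix(0, 3, 3))
})

test_that("zero load gives zero displacement in at most one iteration", {
  m <- unit_cube_mesh()
  sim <- solve_quasistatic(m, nh_surrogate(),
                           bcs = list(boundary_condition("z0",
                                                         fix = c(TRUE, TRUE, TRUE))),
                           loads = list(),
                           schedule = amplitude_schedule(c(0, 1), c(0, 1)),
                           config = solver_config(n_increments = 2))
  expect_true(sim$converged)
  expect_true(all(sim$log$iterations <= 1))
  expect_equal(sim$U[[length(sim$U)]], matrix(0, nrow(m$nodes), 3),
               tolerance = 1e-10)
})

test_that("single-element uniaxial traction matches the scalar bisection oracle", {
  m <- unit_cube_mesh()
  mat <- nh_surrogate()
  traction <- 1.2 # kPa, dead, +z on the top face
  bcs <- list(boundary_condition("x0", fix = c(TRUE, FALSE, FALSE)),
              boundary_condition("y0", fix = c(FALSE, TRUE, FALSE)),
              boundary_condition("z0", fix = c(FALSE, FALSE, TRUE)))
  loads <- list(pressure_load("top", magnitude = traction, follower = FALSE))
  # dead "pressure" of +magnitude pushes against outward normal (-z); the
  # pull is modelled by reversing the schedule sign
  sim <- solve_quasistatic(m, mat, bcs, loads,
                           schedule = amplitude_schedule(c(0, 1), c(0, -1)),
                           config = solver_config(n_increments = 4,
                                                  tol_rel = 1e-10))
  u <- sim$U[[length(sim$U)]]
  lam_z <- 1 + max(u[, 3])
  # oracle: P33(diag(l_lat, l_lat, l_z)) = t with P11 = 0, nested root solves
  lat_of <- function(lz) {
    stats::uniroot(function(ll)
      pk1_stress(mat, diag(c(ll, ll, lz)))[1, 1], c(0.3, 3), tol = 1e-12)$root
  }
  res_z <- function(lz) pk1_stress(mat, diag(c(lat_of(lz), lat_of(lz), lz)))[3, 3] - traction
  lam_star <- stats::uniroot(res_z, c(1.0001, 2), tol = 1e-12)$root
  expect_equal(lam_z, lam_star, tolerance = 1e-6)
  # homogeneity: every element shares the same F
  Fs <- lapply(seq_len(nrow(m$tets)), function(e) element_kinematics(m, e, u)$F)
  for (Fk in Fs[-1]) expect_equal(Fk, Fs[[1]], tolerance = 1e-7)
  # Newton converges superlinearly near the solution (dead load, analytic tangent)
  hist <- sim$newton_history[[length(sim$newton_history)]]
  if (length(hist) >= 3) {
    ratios <- hist[-1] / hist[-length(hist)]
    expect_lt(ratios[length(ratios)], ratios[1])
  }
})

test_that("hydrostatic sphere under follower pressure reaches J = 1 - p D1/2", {
  ball <- build_ball_mesh(radius = 20, edge = 10)
  lung <- ogden_table_lung()
  bcs <- list(boundary_condition("center"),
              boundary_condition("xaxis", fix = c(FALSE, TRUE, TRUE)),
              boundary_condition("z0plane", fix = c(FALSE, FALSE, TRUE)))
  sim <- solve_quasistatic(ball, lung, bcs,
                           loads = list(pressure_load("surface", 0.98)),
                           schedule = amplitude_schedule(c(0, 2), c(0, 1)),
                           config = solver_config(n_increments = 4))
  expect_true(sim$converged)
  J_star <- 1 - 0.98 * 0.289 / 2
  u <- sim$U[[length(sim$U)]]
  Js <- vapply(seq_len(nrow(ball$tets)),
               function(e) element_kinematics(ball, e, u)$J, numeric(1))
  expect_true(all(abs(Js - J_star) / J_star < 0.01))
  expect_equal(sim$volumes[length(sim$volumes)] /
                 mesh_volume(ball, units = "L"), J_star, tolerance = 0.01)
})

test_that("breathing cycle: volume dips at peak exhalation and returns", {
  ph <- build_phantom(phantom_spec(semi_axes = c(30, 30, 60), edge = 15))
  lung <- ogden_table_lung()
  bcs <- list(boundary_condition("trachea_top"),
              boundary_condition("diaphragm_base",
                                 displacement = c(0, 0, 4)))
  sim <- solve_quasistatic(ph, lung, bcs,
                           loads = list(pressure_load("outer_surface", 0.98)),
                           config = solver_config(n_increments = 10))
  expect_true(sim$converged)
  v0 <- mesh_volume(ph, units = "L")
  i2 <- which.min(abs(sim$times - 2))
  expect_lt(sim$volumes[i2], v0)
  expect_lt(abs(sim$volumes[length(sim$volumes)] - v0) / v0, 0.005)
  # prescribed diaphragm displacement honoured exactly at every increment
  base <- ph$node_sets$diaphragm_base
  for (k in seq_along(sim$times)) {
    s <- schedule_factor(sim$schedule, sim$times[k])
    expect_equal(sim$U[[k]][base, 3], rep(4 * s, length(base)),
                 tolerance = 1e-12)
    expect_equal(sim$U[[k]][ph$node_sets$trachea_top, , drop = FALSE],
                 matrix(0, length(ph$node_sets$trachea_top), 3),
                 tolerance = 1e-12)
  }
  # schedule default knots: one breathing cycle
  sc <- amplitude_schedule()
  expect_equal(sc$times, c(0, 2, 5))
  expect_equal(sc$factors, c(0, 1, 0))
  expect_equal(schedule_factor(sc, c(1, 2, 3.5, 7)), c(0.5, 1, 0.5, 0))
})

test_that("incompressible materials and missing sets are rejected", {
  m <- unit_cube_mesh()
  incom <- hyperelastic("ogden", mu = 2, alpha = 2) # all D = 0
  expect_error(solve_quasistatic(m, incom), class = "respmech_config")
  expect_error(solve_quasistatic(m, nh_surrogate(),
                                 bcs = list(boundary_condition("nope"))),
               class = "respmech_config")
  expect_error(solve_quasistatic(m, nh_surrogate(),
                                 loads = list(pressure_load("nope"))),
               class = "respmech_config")
  expect_error(amplitude_schedule(c(1, 2), c(0, 1)), class = "respmech_config")
  expect_error(boundary_condition("a", fix = c(TRUE, FALSE, FALSE),
                                  displacement = c(0, 1, 0)),
               class = "respmech_config")
})

test_that("finite-difference tangent mode reproduces the analytic solution", {
  m <- unit_cube_mesh()
  mat <- nh_surrogate()
  bcs <- list(boundary_condition("z0", fix = c(TRUE, TRUE, TRUE)))
  loads <- list(pressure_load("top", magnitude = 0.4))
  base <- solve_quasistatic(m, mat, bcs, loads,
                            schedule = amplitude_schedule(c(0, 1), c(0, 1)),
                            config = solver_config(n_increments = 2))
  fd <- solve_quasistatic(m, mat, bcs, loads,
                          schedule = amplitude_schedule(c(0, 1), c(0, 1)),
                          config = solver_config(n_increments = 2,
                                                 tangent = "finite_difference"))
  expect_equal(fd$U[[length(fd$U)]], base$U[[length(base$U)]],
               tolerance = 1e-6)
})
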