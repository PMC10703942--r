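# a minimal simulation-result stand-in: the trajectory/displacement code
# only touches $mesh, $times, $U and $schedule
fake_sim <- function(mesh, U, times = seq_along(U),
                     schedule = amplitude_schedule(c(0, max(times)), c(0, 1))) {
  structure(list(mesh = mesh, times = times, U = U, schedule = schedule),
            class = "breath_sim")
}

test_that("truncated relative error reproduces the printed convention", {
  expect_equal(relative_error_truncated(38.00, 38.70, 1), 1.8)
  # truncation, not rounding (rounding would give 3.0)
  expect_equal(relative_error_truncated(15.55, 15.10, 1), 2.9)
  expect_equal(relative_error_truncated(c(3.14, 42), c(3.10, 42), 2),
               c(1.29, 0))
  # magnitudes are compared when signs disagree
  expect_equal(relative_error_truncated(1.22, -1.27, 1), 3.9)
  expect_error(relative_error_truncated(1, 0), class = "respmech_domain")
})

test_that("landmark error table reproduces the nine-case directional errors", {
  cc <- clinical_cases()
  ct <- data.frame(case = cc$landmarks$case, lr = cc$landmarks$ct_lr,
                   ap = cc$landmarks$ct_ap, si = cc$landmarks$ct_si)
  sm <- data.frame(case = cc$landmarks$case, lr = cc$landmarks$sim_lr,
                   ap = cc$landmarks$sim_ap, si = cc$landmarks$sim_si)
  et <- landmark_error_table(ct, sm)
  expect_equal(nrow(et), 27)
  printed <- as.numeric(t(as.matrix(
    cc$landmarks[, c("printed_err_lr", "printed_err_ap", "printed_err_si")])))
  # every printed cell reproduces except Case 4 A/P, where the published
  # error (1.7) is inconsistent with the published displacements
  # (|9.35 - 9.50|/9.50 * 100 = 1.578 -> 1.5)
  mismatch <- which(et$error_pct != printed)
  expect_equal(mismatch, 11L)
  expect_equal(et$case[11], 4)
  expect_equal(as.character(et$direction[11]), "AP")
  expect_equal(et$error_pct[11], 1.5)
  # identical inputs give all-zero errors; mismatched case lists error out
  expect_true(all(landmark_error_table(ct, ct)$error_pct == 0))
  expect_error(landmark_error_table(ct, sm[c(2:9, 1), ]),
               class = "respmech_input")
})

test_that("volume report reproduces the nine-case errors and summaries", {
  cc <- clinical_cases()
  vr <- volume_report(cc$volumes)
  expect_equal(vr$rows$error_pct,
               c(1.29, 8.53, 5.51, 9.23, 7.25, 5.77, 1.35, 8.71, 7.64))
  s <- vr$summary
  expect_equal(s$mean[s$column == "error_pct"], 6.14)
  expect_equal(s$sd[s$column == "error_pct"], 2.83)
  expect_equal(s$mean[s$column == "fem_expiration_L"], 2.39)
  expect_equal(s$sd[s$column == "fem_expiration_L"], 0.48)
  expect_equal(s$sd[s$column == "inspiration_L"], 0.68)
  expect_equal(s$sd[s$column == "ct_expiration_L"], 0.56)
  # summary is recomputable from the rows (population SD, divide by n)
  expect_equal(s$mean[s$column == "error_pct"],
               trunc(mean(vr$rows$error_pct) * 100) / 100)
  expect_equal(s$sd[s$column == "error_pct"],
               trunc(sqrt(mean((vr$rows$error_pct -
                                  mean(vr$rows$error_pct))^2)) * 100) / 100)
  same <- cc$volumes; same$fem_expiration_L <- same$ct_expiration_L
  expect_true(all(volume_report(same)$rows$error_pct == 0))
  expect_error(volume_report(data.frame()), class = "respmech_input")
})

test_that("landmark census sums the per-case counts", {
  cc <- clinical_cases()
  expect_identical(landmark_census(cc$counts$n_landmarks), 258L)
  expect_identical(landmark_census(integer(0)), 0L)
  expect_identical(landmark_census(29), 29L)
  expect_error(landmark_census(c(3, -1)), class = "respmech_input")
})

test_that("landmark trajectories: constant, affine, interpolation oracle", {
  ph <- build_phantom(phantom_spec(semi_axes = c(30, 30, 60), edge = 12))
  lm <- seed_landmarks(ph, c(-15, 15, -15, 15, 10, 40), n = 8, seed = 2)
  n <- nrow(ph$nodes)
  zero <- matrix(0, n, 3)
  tr <- landmark_trajectories(fake_sim(ph, list(zero)), lm)
  expect_equal(tr[, , 2], tr[, , 1], tolerance = 1e-12)
  expect_equal(unname(tr[, , 1]), cbind(lm$x, lm$y, lm$z), tolerance = 1e-9)
  # affine displacement field: trajectory is the affine image of the point
  A <- diag(c(0.9, 1.1, 0.95)); b <- c(2, -1, 3)
  uA <- ph$nodes %*% t(A - diag(3)) + matrix(b, n, 3, byrow = TRUE)
  trA <- landmark_trajectories(fake_sim(ph, list(uA)), lm)
  expect_equal(unname(trA[, , 2]),
               unname(cbind(lm$x, lm$y, lm$z) %*% t(A) +
                        matrix(b, nrow(lm), 3, byrow = TRUE)),
               tolerance = 1e-9)
  # random field: matches direct barycentric evaluation of nodal values
  set.seed(5)
  u <- matrix(rnorm(3 * n), n, 3)
  tru <- landmark_trajectories(fake_sim(ph, list(u)), lm)
  for (k in seq_len(nrow(lm))) {
    w <- as.numeric(lm[k, c("w1", "w2", "w3", "w4")])
    nodes_k <- ph$tets[lm$element[k], ]
    expect_equal(unname(tru[k, , 2] - tru[k, , 1]),
                 as.numeric(t(u[nodes_k, ]) %*% w), tolerance = 1e-10)
  }
  # directional displacements: means equal arithmetic averages
  dd <- directional_displacements(fake_sim(ph, list(u)), lm, time = 1)
  expect_equal(attr(dd, "means"),
               c(lr = mean(dd$lr), ap = mean(dd$ap), si = mean(dd$si)),
               tolerance = 1e-12)
  bad <- lm; bad$element[1] <- nrow(ph$tets) + 50L
  expect_error(landmark_trajectories(fake_sim(ph, list(u)), bad),
               class = "respmech_input")
})

test_that("slice areas: cylinder analytic, plane misses, sphere cap profile", {
  cyl <- cylinder_surface(r = 10, h = 30, n = 128)
  pr <- slice_cross_sections(cyl, n_planes = 3, spacing = 7, anchor = 22)
  expect_equal(pr$z, c(22, 15, 8))
  expect_equal(pr$area_total, rep(pi * 100, 3), tolerance = 0.005 * pi * 100)
  # a plane outside the bounding box reports zero area with a warning
  expect_warning(pr0 <- slice_cross_sections(cyl, n_planes = 1, spacing = 1,
                                             anchor = 99))
  expect_equal(pr0$area_total, 0)
  # sphere: superior cap slice areas decrease monotonically toward the pole
  sph <- icosphere(10, 4)
  prs <- slice_cross_sections(sph, n_planes = 4, spacing = 2, anchor = 8)
  # planes at z = 8, 6, 4, 2: cap areas shrink toward the superior pole
  expect_true(all(diff(prs$area_total) > 0))
  a_analytic <- pi * (100 - prs$z^2)
  expect_equal(prs$area_total, a_analytic, tolerance = 0.01 * max(a_analytic))
})

test_that("slice areas are invariant to in-plane rigid motion; slabs sum to volume", {
  sph <- icosphere(10, 3)
  pr <- slice_cross_sections(sph, n_planes = 3, spacing = 4, anchor = 4)
  th <- 0.7; Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                        c(0, 0, 1))
  moved <- tri_surface(sweep(sph$vertices %*% t(Q), 2, c(5, -3, 0), "+"),
                       sph$faces, check = FALSE)
  prm <- slice_cross_sections(moved, n_planes = 3, spacing = 4, anchor = 4)
  expect_equal(prm$area_total, pr$area_total, tolerance = 1e-9)
  # midpoint-rule slab volumes approach the enclosed volume on a convex body
  np <- 40; sp <- 20 / np
  prf <- slice_cross_sections(sph, n_planes = np, spacing = sp,
                              anchor = 10 - sp / 2)
  expect_equal(sum(prf$area_total) * sp, mesh_volume(sph),
               tolerance = 0.01 * mesh_volume(sph))
})

test_that("left/right components split by centroid x and errors compare", {
  # two disjoint cylinders, one per side
  c1 <- cylinder_surface(r = 5, h = 20, n = 64)
  v1 <- sweep(c1$vertices, 2, c(15, 0, 0), "+")
  v2 <- sweep(c1$vertices, 2, c(-15, 0, 0), "+")
  nv <- nrow(v1)
  both <- tri_surface(rbind(v1, v2), rbind(c1$faces, c1$faces + nv),
                      check = FALSE)
  pr <- slice_cross_sections(both, n_planes = 1, spacing = 1, anchor = 10)
  expect_equal(pr$area_left, pi * 25, tolerance = 0.01 * pi * 25)
  expect_equal(pr$area_right, pi * 25, tolerance = 0.01 * pi * 25)
  # area error comparison between two tessellations of the same body
  prA <- slice_cross_sections(cylinder_surface(10, 30, 96), n_planes = 2,
                              spacing = 10, anchor = 20)
  prB <- slice_cross_sections(cylinder_surface(10, 30, 192), n_planes = 2,
                              spacing = 10, anchor = 20)
  er <- slice_area_errors(prA, prB)
  expect_true(all(er$error_total < 1))
  expect_error(slice_area_errors(prA, slice_cross_sections(
    cylinder_surface(10, 30, 96), n_planes = 2, spacing = 9, anchor = 20)),
    class = "respmech_input")
})
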