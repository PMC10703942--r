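# Shared finite-difference oracles and small fixtures built in code.

# central-difference gradient of strain energy wrt F -> PK1 oracle
fd_pk1 <- function(model, F, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(model, Fp) - strain_energy(model, Fm)) / (2 * h)
  }
  P
}

# central-difference tangent dP/dF oracle
fd_tangent <- function(model, F, h = 1e-6) {
  A <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (L in 1:3) {
    Fp <- F; Fp[k, L] <- Fp[k, L] + h
    Fm <- F; Fm[k, L] <- Fm[k, L] - h
    A[, , k, L] <- (pk1_stress(model, Fp) - pk1_stress(model, Fm)) / (2 * h)
  }
  A
}

# random deformation gradient with J > 0, bounded distortion
random_F <- function(scale = 0.2) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, scale), 3)
    if (det(F) > 0.3) return(F)
  }
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# icosphere built in code: subdivided icosahedron projected to radius r
icosphere <- function(r = 10, subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    env <- new.env(); assign("v", v, env); assign("mid", list(), env)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- get("mid", env)
      if (!is.null(m[[key]])) return(m[[key]])
      vv <- get("v", env)
      vv <- rbind(vv, (vv[i, ] + vv[j, ]) / 2)
      assign("v", vv, env)
      m[[key]] <- nrow(vv); assign("mid", m, env)
      nrow(vv)
    }
    f2 <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- get("v", env); f <- f2
  }
  v <- v / sqrt(rowSums(v^2)) * r
  tri_surface(v, f)
}

# closed triangulated cylinder, radius r, height h, axis z from 0 to h
cylinder_surface <- function(r = 10, h = 30, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring0 <- cbind(r * cos(th), r * sin(th), 0)
  ring1 <- cbind(r * cos(th), r * sin(th), h)
  v <- rbind(ring0, ring1, c(0, 0, 0), c(0, 0, h))
  c0 <- 2 * n + 1; c1 <- 2 * n + 2
  f <- matrix(0L, 0, 3)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    f <- rbind(f,
               c(i, j, n + i), c(j, n + j, n + i),   # side (outward)
               c(c0, j, i),                           # bottom cap (outward -z)
               c(c1, n + i, n + j))                   # top cap (outward +z)
  }
  tri_surface(v, f)
}

# the model roster used across calibration tests
roster_models <- function() {
  list(
    hyperelastic("ogden", mu = c(1.5, -0.4), alpha = c(2.8, -2.0)),
    hyperelastic("polynomial", C = c(C10 = 0.7, C01 = 0.25)),
    hyperelastic("reduced_polynomial", C = c(C10 = 1.0, C20 = 0.2)),
    hyperelastic("van_der_waals", mu = 1.5, lambda_m = 4, a = 0.3, beta = 0.1),
    ogden_table_lung()
  )
}
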