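# Isotropic hyperelastic constitutive models in principal-stretch form.
#
# Unit contract (package-wide): lengths mm, stresses/moduli kPa, pressures kPa,
# forces mN (kPa.mm^2), times s.
#
# Ogden convention: W = sum_i (2 mu_i / alpha_i^2) (lb1^a_i + lb2^a_i + lb3^a_i - 3)
# with isochoric stretches lb_a = J^(-1/3) lambda_a, plus volumetric terms
# sum_{D_i > 0} (1/D_i) (J - 1)^(2i).  Other conventions for (mu_i, alpha_i)
# exist in the literature; coefficients are NOT interchangeable between them.

rm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "respmech_error")))
}

#' Construct an isotropic hyperelastic material model
#'
#' Builds a model of one of four families used for lung parenchyma and
#' comparable soft tissue: \code{"ogden"} (principal-stretch series),
#' \code{"polynomial"} (Mooney-Rivlin and higher invariant series),
#' \code{"reduced_polynomial"} (first-invariant-only series, order 1 being
#' neo-Hookean), and \code{"van_der_waals"} (finite-extensibility model).
#' All deviatoric coefficients are in kPa (dimensionless exponents excepted);
#' volumetric compliances \code{D} are in 1/kPa.
#'
#' @param family one of \code{"ogden"}, \code{"polynomial"},
#'   \code{"reduced_polynomial"}, \code{"van_der_waals"}.
#' @param mu,alpha Ogden pairs (numeric vectors of equal length \eqn{N}), or
#'   for \code{van_der_waals} \code{mu} is the single shear modulus.
#' @param C named numeric vector of polynomial coefficients, names like
#'   \code{"C10"}, \code{"C01"}, \code{"C20"}, ... (kPa).  Reduced polynomial
#'   accepts only \code{Ci0} terms.
#' @param lambda_m,a,beta van der Waals locking stretch (> sqrt(3)),
#'   interaction parameter and invariant mixture parameter (0 <= beta <= 1).
#' @param D volumetric compliances \eqn{D_i \ge 0} (1/kPa); \code{D[i] = 0}
#'   omits the i-th volumetric term.  All zero means fully incompressible
#'   (legal here, rejected by the displacement-based FE solver).
#' @param label optional identifier used in rankings and reports.
#' @return object of class \code{"hyperelastic_model"} with fields
#'   \code{family}, \code{order}, the family coefficients, \code{D}, and the
#'   initial shear modulus \code{mu0} (kPa).
#' @examples
#' lung <- ogden_table_lung()           # bundled 6-term Ogden lung model
#' nh   <- hyperelastic("reduced_polynomial", C = c(C10 = 1))
#' nominal_stress(nh, "uniaxial", c(1, 1.5, 2))
#' @export
hyperelastic <- function(family = c("ogden", "polynomial", "reduced_polynomial",
                                    "van_der_waals"),
                         mu = NULL, alpha = NULL, C = NULL,
                         lambda_m = NULL, a = NULL, beta = 0,
                         D = 0, label = NULL) {
  family <- match.arg(family)
  m <- list(family = family, D = as.numeric(D))
  if (any(m$D < 0)) rm_stop("volumetric compliances D must be >= 0", "respmech_config")

  if (family == "ogden") {
    if (is.null(mu) || is.null(alpha) || length(mu) != length(alpha) || !length(mu))
      rm_stop("ogden needs mu and alpha vectors of equal positive length",
              "respmech_config")
    if (any(alpha == 0)) rm_stop("ogden exponents alpha must be nonzero",
                                 "respmech_config")
    m$mu <- as.numeric(mu); m$alpha <- as.numeric(alpha)
    m$order <- length(mu)
    m$mu0 <- sum(m$mu)
  } else if (family %in% c("polynomial", "reduced_polynomial")) {
    if (is.null(C) || is.null(names(C)) || !all(grepl("^C[0-9][0-9]$", names(C))))
      rm_stop("polynomial families need a named coefficient vector like c(C10=, C01=)",
              "respmech_config")
    i <- as.integer(substr(names(C), 2, 2)); j <- as.integer(substr(names(C), 3, 3))
    if (any(i + j < 1)) rm_stop("coefficient indices must satisfy i + j >= 1",
                                "respmech_config")
    if (family == "reduced_polynomial" && any(j != 0))
      rm_stop("reduced polynomial admits only Ci0 terms", "respmech_config")
    m$C <- as.numeric(C); m$i <- i; m$j <- j
    m$order <- max(i + j)
    m$mu0 <- 2 * (sum(m$C[i == 1 & j == 0]) + sum(m$C[i == 0 & j == 1]))
  } else { # van der Waals
    if (is.null(mu) || is.null(lambda_m) || is.null(a))
      rm_stop("van_der_waals needs mu, lambda_m and a", "respmech_config")
    if (lambda_m <= sqrt(3)) rm_stop("van der Waals needs lambda_m > sqrt(3)",
                                     "respmech_config")
    if (beta < 0 || beta > 1) rm_stop("beta must lie in [0, 1]", "respmech_config")
    m$mu <- as.numeric(mu); m$lambda_m <- as.numeric(lambda_m)
    m$a <- as.numeric(a); m$beta <- as.numeric(beta)
    m$order <- 1L
    m$mu0 <- m$mu
  }
  if (!is.finite(m$mu0)) rm_stop("initial shear modulus is not finite",
                                 "respmech_config")
  m$label <- label %||% default_label(m)
  class(m) <- "hyperelastic_model"
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

default_label <- function(m) {
  switch(m$family,
         ogden = paste0("ogden_", m$order),
         polynomial = paste0("polynomial_", m$order),
         reduced_polynomial = paste0("reduced_polynomial_", m$order),
         van_der_waals = "van_der_waals")
}

#' @export
print.hyperelastic_model <- function(x, ...) {
  cat(sprintf("Hyperelastic model: %s (family %s, order %d)\n",
              x$label, x$family, x$order))
  if (x$family == "ogden") {
    for (k in seq_len(x$order))
      cat(sprintf("  mu_%d = %10.4g kPa   alpha_%d = %8.4g\n",
                  k, x$mu[k], k, x$alpha[k]))
  } else if (x$family %in% c("polynomial", "reduced_polynomial")) {
    for (k in seq_along(x$C))
      cat(sprintf("  C%d%d = %10.4g kPa\n", x$i[k], x$j[k], x$C[k]))
  } else {
    cat(sprintf("  mu = %.4g kPa  lambda_m = %.4g  a = %.4g  beta = %.4g\n",
                x$mu, x$lambda_m, x$a, x$beta))
  }
  Dn <- which(x$D > 0)
  if (length(Dn)) cat(sprintf("  D_%d = %.4g 1/kPa\n", Dn, x$D[Dn]), sep = "")
  else cat("  incompressible (all D_i = 0)\n")
  cat(sprintf("  initial shear modulus mu0 = %.4g kPa\n", x$mu0))
  invisible(x)
}

#' Six-term Ogden lung parenchyma model
#'
#' The nearly-incompressible 6-term Ogden model used for lung parenchyma in
#' the breathing simulations: pairs (mu_i kPa, alpha_i) =
#' (2.801, 1.827), (-3.480, 2.393), (1.135, 2.918), (1.396, -5.631),
#' (-1.304, -6.082), (0.167, -7.007) with D1 = 0.289 1/kPa.
#'
#' @return a \code{"hyperelastic_model"} of family ogden, order 6.
#' @export
ogden_table_lung <- function() {
  hyperelastic("ogden",
               mu    = c(2.801, -3.480, 1.135, 1.396, -1.304, 0.167),
               alpha = c(1.827, 2.393, 2.918, -5.631, -6.082, -7.007),
               D = c(0.289, 0, 0, 0, 0, 0), label = "ogden_6_lung")
}

#' Linear-elastic surrogate for airway/mediastinum/rib regions
#'
#' Small-strain elastic constants mapped to a compressible neo-Hookean model
#' (C10 = E / (4(1+nu)), D1 = 6(1-2 nu)/E) so the surrogate remains
#' consistent under large deformation.
#'
#' @param E Young's modulus (kPa), positive.
#' @param nu Poisson ratio in [0, 0.5).
#' @param label optional identifier.
#' @return object of class \code{"elastic_surrogate"}; coerce with
#'   \code{as_hyperelastic()}.
#' @export
elastic_surrogate <- function(E, nu, label = NULL) {
  if (E <= 0) rm_stop("Young's modulus must be positive", "respmech_config")
  if (nu < 0 || nu >= 0.5) rm_stop("Poisson ratio must lie in [0, 0.5)",
                                   "respmech_config")
  structure(list(E = E, nu = nu, label = label %||% "elastic_surrogate"),
            class = "elastic_surrogate")
}

#' Coerce to a hyperelastic model
#' @param x model-like object.
#' @param ... unused.
#' @export
as_hyperelastic <- function(x, ...) UseMethod("as_hyperelastic")

#' @export
as_hyperelastic.hyperelastic_model <- function(x, ...) x

#' @export
as_hyperelastic.elastic_surrogate <- function(x, ...) {
  hyperelastic("reduced_polynomial",
               C = c(C10 = x$E / (4 * (1 + x$nu))),
               D = 6 * (1 - 2 * x$nu) / x$E, label = x$label)
}

#' Kinematic state from a deformation gradient
#'
#' @param F 3x3 deformation gradient with det F > 0.
#' @return object of class \code{"deformation_state"}: \code{F}, \code{J},
#'   principal stretches \code{lambda} (descending), isochoric stretches
#'   \code{lbar} and principal directions \code{N} (columns, reference frame).
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3)) || any(!is.finite(F)))
    rm_stop("F must be a finite 3x3 matrix", "respmech_state")
  J <- det(F)
  if (J <= 0) rm_stop(sprintf("deformation gradient has J = %.3g <= 0", J),
                      "respmech_state")
  Cmat <- crossprod(F)
  e <- eigen(Cmat, symmetric = TRUE)
  lambda <- sqrt(pmax(e$values, 0))
  structure(list(F = F, J = J, lambda = lambda,
                 lbar = J^(-1 / 3) * lambda, N = e$vectors),
            class = "deformation_state")
}

# ---- deviatoric energy: value / gradient / Hessian wrt isochoric stretches ----

# Returns list(W, g, H): energy (kPa), dW/dlbar (3), d2W/dlbar2 (3x3).
# Infinite values signal the van der Waals extensibility limit.
dev_energy <- function(model, lbar, hess = TRUE) {
  lb <- lbar
  if (model$family == "ogden") {
    W <- 0; g <- numeric(3); H <- diag(0, 3)
    for (k in seq_len(model$order)) {
      mu <- model$mu[k]; al <- model$alpha[k]
      W <- W + (2 * mu / al^2) * (sum(lb^al) - 3)
      g <- g + (2 * mu / al) * lb^(al - 1)
      if (hess) diag(H) <- diag(H) + 2 * mu * (al - 1) / al * lb^(al - 2)
    }
    return(list(W = W, g = g, H = H))
  }
  # invariant-based families
  I1 <- sum(lb^2)
  I2 <- lb[1]^2 * lb[2]^2 + lb[2]^2 * lb[3]^2 + lb[3]^2 * lb[1]^2
  dI1 <- 2 * lb
  dI2 <- 2 * lb * (I1 - lb^2)
  f <- inv_energy(model, I1, I2)
  if (!is.finite(f$W)) return(list(W = Inf, g = rep(Inf, 3), H = diag(Inf, 3)))
  g <- f$f1 * dI1 + f$f2 * dI2
  H <- NULL
  if (hess) {
    d2I1 <- diag(2, 3)
    d2I2 <- 4 * outer(lb, lb)
    diag(d2I2) <- 2 * (I1 - 3 * lb^2) + 4 * lb^2
    H <- f$f11 * outer(dI1, dI1) +
      f$f12 * (outer(dI1, dI2) + outer(dI2, dI1)) +
      f$f22 * outer(dI2, dI2) +
      f$f1 * d2I1 + f$f2 * d2I2
  }
  list(W = f$W, g = g, H = H)
}

# Invariant-space energy f(I1, I2) and partials f1, f2, f11, f12, f22.
inv_energy <- function(model, I1, I2) {
  if (model$family %in% c("polynomial", "reduced_polynomial")) {
    x <- I1 - 3; y <- I2 - 3
    W <- f1 <- f2 <- f11 <- f12 <- f22 <- 0
    pw <- function(b, e) if (e < 0) 0 else if (e == 0) 1 else b^e
    for (k in seq_along(model$C)) {
      Ck <- model$C[k]; i <- model$i[k]; j <- model$j[k]
      W   <- W   + Ck * pw(x, i) * pw(y, j)
      f1  <- f1  + Ck * i * pw(x, i - 1) * pw(y, j)
      f2  <- f2  + Ck * j * pw(x, i) * pw(y, j - 1)
      f11 <- f11 + Ck * i * (i - 1) * pw(x, i - 2) * pw(y, j)
      f12 <- f12 + Ck * i * j * pw(x, i - 1) * pw(y, j - 1)
      f22 <- f22 + Ck * j * (j - 1) * pw(x, i) * pw(y, j - 2)
    }
    return(list(W = W, f1 = f1, f2 = f2, f11 = f11, f12 = f12, f22 = f22))
  }
  # van der Waals with mixed invariant Itil = (1-beta) I1 + beta I2
  mu <- model$mu; lm2 <- model$lambda_m^2; a <- model$a; be <- model$beta
  It <- (1 - be) * I1 + be * I2
  den <- lm2 - 3
  s <- It - 3
  if (s >= den) # beyond the locking stretch
    return(list(W = Inf, f1 = Inf, f2 = Inf, f11 = Inf, f12 = Inf, f22 = Inf))
  s <- max(s, 0)
  eta <- sqrt(s / den)
  W <- -mu * (den * (log(1 - eta) + eta) + (2 / 3) * a * (s / 2)^1.5)
  fp <- mu / (2 * (1 - eta)) - (mu * a / 2) * sqrt(s / 2)
  seps <- max(s, 1e-12)  # curvature is singular at the undeformed state
  etap <- 1 / (2 * sqrt(seps / den) * den)
  fpp <- mu / 2 * etap / (1 - eta)^2 - mu * a / 8 * sqrt(2 / seps)
  list(W = W, f1 = fp * (1 - be), f2 = fp * be,
       f11 = fpp * (1 - be)^2, f12 = fpp * (1 - be) * be, f22 = fpp * be^2)
}

# Volumetric energy U(J), U'(J), U''(J) from compliances D_i (terms D_i = 0 absent).
vol_energy <- function(D, J) {
  U <- Up <- Upp <- 0
  for (i in seq_along(D)) {
    if (D[i] <= 0) next
    U   <- U + (J - 1)^(2 * i) / D[i]
    Up  <- Up + 2 * i * (J - 1)^(2 * i - 1) / D[i]
    Upp <- Upp + 2 * i * (2 * i - 1) * (J - 1)^(2 * i - 2) / D[i]
  }
  list(U = U, Up = Up, Upp = Upp)
}

#' Strain-energy density
#'
#' Evaluates the stored energy per reference volume, deviatoric part on the
#' isochoric stretches plus the volumetric terms in \eqn{(J-1)^{2i}}.
#'
#' @param model a \code{hyperelastic_model} (or \code{elastic_surrogate}).
#' @param state a \code{deformation_state} (or a 3x3 deformation gradient).
#' @return energy density in kPa; exactly 0 at the identity.
#' @export
strain_energy <- function(model, state) {
  model <- as_hyperelastic(model)
  if (!inherits(state, "deformation_state")) state <- deformation_state(state)
  dev_energy(model, state$lbar, hess = FALSE)$W + vol_energy(model$D, state$J)$U
}

# ---- nominal stress on the incompressible homogeneous test paths ----

path_def <- function(mode) {
  switch(mode,
         uniaxial    = list(lam = function(l) cbind(l, l^-0.5, l^-0.5),
                            dlam = function(l) cbind(1, -0.5 * l^-1.5, -0.5 * l^-1.5),
                            m = 1),
         equibiaxial = list(lam = function(l) cbind(l, l, l^-2),
                            dlam = function(l) cbind(1, 1, -2 * l^-3),
                            m = 2),
         planar      = list(lam = function(l) cbind(l, 1, 1 / l),
                            dlam = function(l) cbind(1, 0, -l^-2),
                            m = 1),
         rm_stop(sprintf("unknown test mode '%s'", mode), "respmech_config"))
}

#' Nominal stress along a homogeneous incompressible test path
#'
#' Closed-form engineering (first Piola-Kirchhoff) stress per loaded
#' direction for uniaxial, equibiaxial or planar (pure shear) tension or
#' compression under the incompressibility constraint, with the lateral
#' traction-free condition eliminated.  For the Ogden family the uniaxial
#' form is \eqn{T = \sum_i (2\mu_i/\alpha_i)(\lambda^{\alpha_i-1} -
#' \lambda^{-\alpha_i/2-1})}.
#'
#' @param model a \code{hyperelastic_model} or \code{elastic_surrogate}.
#' @param mode \code{"uniaxial"}, \code{"equibiaxial"} or \code{"planar"}.
#' @param stretch principal stretch(es) in the loaded direction, > 0.
#' @return nominal stress in kPa (vectorised over \code{stretch}); tension
#'   positive; exactly 0 at stretch 1.
#' @export
nominal_stress <- function(model, mode = c("uniaxial", "equibiaxial", "planar"),
                           stretch) {
  model <- as_hyperelastic(model)
  mode <- match.arg(mode)
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    rm_stop("stretches must be positive and finite", "respmech_domain")
  p <- path_def(mode)
  L <- p$lam(stretch); dL <- p$dlam(stretch)
  vapply(seq_along(stretch), function(k) {
    g <- dev_energy(model, L[k, ], hess = FALSE)$g
    sum(g * dL[k, ]) / p$m
  }, numeric(1))
}

# ---- full stress and tangent ----

# dW/dlambda (3) and d2W/dlambda2 (3x3) of the full energy (dev + vol)
# as a function of the principal stretches.
full_energy_derivs <- function(model, lambda, hess = TRUE) {
  J <- prod(lambda)
  lb <- J^(-1 / 3) * lambda
  de <- dev_energy(model, lb, hess = hess)
  vo <- vol_energy(model$D, J)
  # dlb_b / dlam_a = J^(-1/3) delta_ab - (1/3) lb_b / lam_a
  Jfac <- J^(-1 / 3)
  Dl <- diag(Jfac, 3) - (1 / 3) * outer(1 / lambda, lb, function(il, l) l * il)
  # Dl[a, b] = dlb_b/dlam_a
  dJ <- J / lambda
  g <- as.numeric(Dl %*% de$g) + vo$Up * dJ
  if (!hess) return(list(g = g))
  H <- Dl %*% de$H %*% t(Dl)
  # second derivatives of lb_b wrt (lam_a, lam_c):
  # d/dlam_c [ J^(-1/3) d_ab ] = -(1/3) J^(-1/3)/lam_c d_ab
  # d/dlam_c [ -(1/3) lb_b/lam_a ] = -(1/3) ( Dl[c,b]/lam_a - lb_b/lam_a^2 d_ac )
  for (a in 1:3) for (c in 1:3) {
    d2 <- numeric(3)
    for (b in 1:3) {
      d2[b] <- -(1 / 3) * Jfac / lambda[c] * (a == b) -
        (1 / 3) * (Dl[c, b] / lambda[a] - (a == c) * lb[b] / lambda[a]^2)
    }
    H[a, c] <- H[a, c] + sum(de$g * d2)
  }
  # volumetric: d2U/dlam_a dlam_c = Upp dJ_a dJ_c + Up * J/(lam_a lam_c) (1 - d_ac)
  H <- H + vo$Upp * outer(dJ, dJ) +
    vo$Up * (outer(dJ, 1 / lambda) * (1 - diag(3)))
  list(g = g, H = H)
}

#' First Piola-Kirchhoff stress
#'
#' Unconstrained stress from the stored energy.  For fully incompressible
#' models (all \code{D = 0}) the energy carries no volumetric part, so the
#' returned stress is the isochoric (deviatoric) contribution only; the
#' hydrostatic pressure of a constrained problem must then come from the
#' boundary conditions (as in \code{\link{nominal_stress}}).
#'
#' @param model a \code{hyperelastic_model} or \code{elastic_surrogate}.
#' @param F 3x3 deformation gradient (det F > 0).
#' @return 3x3 first Piola-Kirchhoff stress (kPa); the zero matrix at F = I.
#' @export
pk1_stress <- function(model, F) {
  model <- as_hyperelastic(model)
  st <- if (inherits(F, "deformation_state")) F else deformation_state(F)
  d <- full_energy_derivs(model, st$lambda, hess = FALSE)
  Sa <- d$g / st$lambda                      # principal 2nd PK values
  S <- st$N %*% (Sa * t(st$N))
  st$F %*% S
}

#' Material tangent dP/dF
#'
#' Fourth-order tangent of the first Piola-Kirchhoff stress with respect to
#' the deformation gradient, assembled from the spectral form of the material
#' elasticity tensor (analytic stretch derivatives; coincident-stretch limits
#' handled by the l'Hopital branch).
#'
#' @inheritParams pk1_stress
#' @return numeric array \code{[3,3,3,3]}, \code{A[i,J,k,L] = dP_iJ / dF_kL}
#'   (kPa).
#' @export
material_tangent <- function(model, F) {
  model <- as_hyperelastic(model)
  st <- if (inherits(F, "deformation_state")) F else deformation_state(F)
  lam <- st$lambda; N <- st$N
  d <- full_energy_derivs(model, lam, hess = TRUE)
  Sa <- d$g / lam
  # dS_a/dlam_b = W_ab / lam_a - delta_ab W_a / lam_a^2
  dS <- sweep(d$H, 1, lam, "/") - diag(d$g / lam^2)
  cab <- sweep(dS, 2, lam, "/")              # (1/lam_b) dS_a/dlam_b
  cab <- (cab + t(cab)) / 2                  # analytic symmetry, enforce numerically
  # material elasticity tensor in the principal frame
  CC <- array(0, c(3, 3, 3, 3))
  M <- lapply(1:3, function(a) tcrossprod(N[, a]))
  for (a in 1:3) for (b in 1:3) {
    CC <- CC + cab[a, b] * outer(M[[a]], M[[b]])
    if (a != b) {
      if (abs(lam[a]^2 - lam[b]^2) > 1e-8 * max(lam^2)) {
        Gab <- (Sa[b] - Sa[a]) / (lam[b]^2 - lam[a]^2)
      } else {
        Gab <- (dS[b, b] - dS[a, b]) / (2 * lam[b])
      }
      Mab <- tcrossprod(N[, a], N[, b]); Mba <- t(Mab)
      CC <- CC + Gab * (outer(Mab, Mab) + outer(Mab, Mba))
    }
  }
  # A_iJkL = d_ik S_JL + F_iA CC_AJLQ F_kQ  (two 3x27 contractions)
  S <- N %*% (Sa * t(N))
  Fm <- st$F
  T1 <- Fm %*% matrix(CC, 3, 27)                   # [i, (J,L,Q)]
  T1 <- array(T1, c(3, 3, 3, 3))                   # [i, J, L, Q]
  T2 <- matrix(aperm(T1, c(4, 1, 2, 3)), 3, 27)    # [Q, (i,J,L)]
  T3 <- array(Fm %*% T2, c(3, 3, 3, 3))            # [k, i, J, L]
  A <- aperm(T3, c(2, 3, 1, 4))                    # [i, J, k, L]
  for (i in 1:3) A[i, , i, ] <- A[i, , i, ] + S
  A
}

# ---- serialization ----

#' Read / write hyperelastic models as JSON or YAML
#'
#' Files carry an explicit \code{family}, \code{order}, named coefficients
#' and a \code{units} field fixed to \code{"kPa"}.
#'
#' @param model a \code{hyperelastic_model}.
#' @param path file path ending in \code{.json}, \code{.yaml} or \code{.yml}.
#' @return \code{write_material} returns \code{path} invisibly;
#'   \code{read_material} returns a \code{hyperelastic_model}.
#' @export
write_material <- function(model, path) {
  model <- as_hyperelastic(model)
  x <- list(family = model$family, order = model$order, units = "kPa",
            label = model$label, D = model$D)
  if (model$family == "ogden") {
    x$mu <- model$mu; x$alpha <- model$alpha
  } else if (model$family %in% c("polynomial", "reduced_polynomial")) {
    x$C <- as.list(stats::setNames(model$C, sprintf("C%d%d", model$i, model$j)))
  } else {
    x$mu <- model$mu; x$lambda_m <- model$lambda_m
    x$a <- model$a; x$beta <- model$beta
  }
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material
#' @export
read_material <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$units, "kPa"))
    rm_stop("material file must declare units 'kPa'", "respmech_config")
  D <- as.numeric(x$D %||% 0)
  if (x$family == "ogden") {
    hyperelastic("ogden", mu = as.numeric(x$mu), alpha = as.numeric(x$alpha),
                 D = D, label = x$label)
  } else if (x$family %in% c("polynomial", "reduced_polynomial")) {
    hyperelastic(x$family, C = unlist(x$C), D = D, label = x$label)
  } else if (x$family == "van_der_waals") {
    hyperelastic("van_der_waals", mu = x$mu, lambda_m = x$lambda_m,
                 a = x$a, beta = x$beta, D = D, label = x$label)
  } else rm_stop(sprintf("unsupported material family '%s'", x$family),
                 "respmech_config")
}
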