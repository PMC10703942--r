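# Least-squares calibration of hyperelastic models to nominal stress-strain
# test curves, Drucker stability screening, and roster ranking.

#' Nominal stress-strain test dataset
#'
#' @param mode test mode: \code{"uniaxial"}, \code{"equibiaxial"} or
#'   \code{"planar"}.
#' @param strain nominal strains \eqn{e_k > -1}, strictly increasing.
#' @param stress nominal stresses (kPa), same length.
#' @param provenance free-text tag recording where the curve came from.
#' @return object of class \code{"test_dataset"} (a data.frame with columns
#'   \code{strain}, \code{stress} and attributes \code{mode},
#'   \code{provenance}).
#' @export
test_dataset <- function(mode = c("uniaxial", "equibiaxial", "planar"),
                         strain, stress, provenance = "unspecified") {
  mode <- match.arg(mode)
  if (length(strain) != length(stress) || !length(strain))
    rm_stop("strain and stress must be non-empty and of equal length",
            "respmech_input")
  if (any(strain <= -1)) rm_stop("nominal strains must exceed -1",
                                 "respmech_input")
  if (any(diff(strain) <= 0)) rm_stop("strains must be strictly increasing",
                                      "respmech_input")
  structure(data.frame(strain = as.numeric(strain),
                       stress = as.numeric(stress)),
            mode = mode, provenance = provenance,
            class = c("test_dataset", "data.frame"))
}

as_dataset_list <- function(data) {
  if (inherits(data, "test_dataset")) return(list(data))
  if (is.list(data) && all(vapply(data, inherits, logical(1), "test_dataset")))
    return(data)
  rm_stop("data must be a test_dataset or a list of them", "respmech_input")
}

#' Generate synthetic test data from a reference model
#'
#' Evaluates the closed-form nominal stress of \code{model} on a strain grid
#' and adds i.i.d. Gaussian noise, standing in for a laboratory curve.
#'
#' @param model a \code{hyperelastic_model}.
#' @param mode test mode.
#' @param strain nominal strain grid (strictly increasing, > -1).
#' @param noise_sd Gaussian noise standard deviation (kPa); 0 reproduces the
#'   closed form exactly.
#' @param seed integer seed; fixed seed gives identical output.
#' @return a \code{\link{test_dataset}}.
#' @export
generate_test_data <- function(model, mode, strain, noise_sd = 0, seed = NULL) {
  model <- as_hyperelastic(model)
  if (any(1 + strain <= 0)) rm_stop("strain grid crosses lambda <= 0",
                                    "respmech_domain")
  T <- nominal_stress(model, mode, 1 + strain)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    T <- T + stats::rnorm(length(T), 0, noise_sd)
  }
  test_dataset(mode, strain, T,
               provenance = sprintf("synthetic from %s (noise_sd=%g)",
                                    model$label, noise_sd))
}

#' Synthetic biaxial tension-compression lung parenchyma curve
#'
#' Stand-in for an equibiaxial tension-compression test of lung parenchyma:
#' the bundled 6-term Ogden lung model evaluated on a nominal-strain grid
#' from -0.3 (compression) to 0.7 (tension), 51 points, with optional noise.
#'
#' @param noise_sd Gaussian noise sd (kPa), default 0.
#' @param seed integer seed for the noise.
#' @return a \code{\link{test_dataset}} (mode equibiaxial).
#' @export
lung_test_dataset <- function(noise_sd = 0, seed = NULL) {
  generate_test_data(ogden_table_lung(), "equibiaxial",
                     seq(-0.3, 0.7, length.out = 51),
                     noise_sd = noise_sd, seed = seed)
}

# ---- objective ----

# Relative least squares: sum_k (T_model/T_k - 1)^2 over points with
# |T_k| >= floor (typically this drops only the zero-stress point at e = 0).
STRESS_FLOOR <- 1e-6

fit_points <- function(datasets) {
  pts <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(mode = attr(d, "mode"), lambda = 1 + d$strain, stress = d$stress)
  }))
  pts[abs(pts$stress) >= STRESS_FLOOR, , drop = FALSE]
}

# model stresses at the fit points
predict_points <- function(model, pts) {
  out <- numeric(nrow(pts))
  for (mode in unique(pts$mode)) {
    i <- pts$mode == mode
    out[i] <- nominal_stress(model, mode, pts$lambda[i])
  }
  out
}

rel_residuals <- function(model, pts) {
  r <- predict_points(model, pts) / pts$stress - 1
  r[!is.finite(r)] <- 1e6
  r
}

objective <- function(model, pts) sum(rel_residuals(model, pts)^2)

# ---- family-specific fitting ----

# linear families: stress is linear in the coefficients, so the relative-LS
# problem is an ordinary linear least squares on the scaled design matrix
fit_linear_family <- function(family, order, pts, D) {
  nm <- if (family == "reduced_polynomial") sprintf("C%d0", seq_len(order))
  else { ij <- poly_terms(order); sprintf("C%d%d", ij$i, ij$j) }
  X <- vapply(nm, function(n) {
    unit <- hyperelastic(family, C = stats::setNames(1, n))
    predict_points(unit, pts) / pts$stress
  }, numeric(nrow(pts)))
  X <- matrix(X, nrow = nrow(pts))
  sol <- stats::lm.fit(X, rep(1, nrow(pts)))
  coefs <- stats::setNames(as.numeric(sol$coefficients), nm)
  coefs[is.na(coefs)] <- 0
  list(model = hyperelastic(family, C = coefs, D = D),
       n_iterations = 1L, converged = TRUE)
}

poly_terms <- function(order) {
  i <- j <- integer(0)
  for (s in seq_len(order)) for (ii in s:0) {
    i <- c(i, ii); j <- c(j, s - ii)
  }
  list(i = i, j = j)
}

# Ogden: multistart over exponent combinations from a fixed grid with the
# shear coefficients mu solved linearly per exponent set (variable
# projection); Levenberg-Marquardt over the exponents for the best-scoring
# starts, then a joint polish over (mu, alpha).
fit_ogden <- function(order, pts, D, n_refine = 5L) {
  grid <- c(1, -1, 2, -2, 4, -4, 7, -7)
  combos <- utils::combn(length(grid), order)
  starts <- lapply(seq_len(ncol(combos)), function(k) grid[combos[, k]])
  design <- function(alpha) {
    X <- vapply(alpha, function(a) {
      unit <- hyperelastic("ogden", mu = 1, alpha = a)
      predict_points(unit, pts) / pts$stress
    }, numeric(nrow(pts)))
    matrix(X, nrow = nrow(pts))
  }
  mu_solve <- function(alpha) {
    sol <- stats::lm.fit(design(alpha), rep(1, nrow(pts)))
    mu <- as.numeric(sol$coefficients); mu[is.na(mu)] <- 0
    list(mu = mu, res = sol$residuals)
  }
  clip_alpha <- function(alpha) {
    small <- abs(alpha) < 1e-3
    alpha[small] <- 1e-3 * ifelse(alpha[small] < 0, -1, 1)
    alpha
  }
  vp_res <- function(alpha) mu_solve(clip_alpha(alpha))$res
  score <- vapply(starts, function(a) sum(vp_res(a)^2), numeric(1))
  ord <- order(score)
  best <- list(obj = Inf, alpha = starts[[ord[1]]], iters = 0L,
               converged = FALSE)
  ctl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15, ptol = 1e-13)
  for (k in ord[seq_len(min(n_refine, length(ord)))]) {
    fit <- try(minpack.lm::nls.lm(starts[[k]], fn = vp_res, control = ctl),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$deviance < best$obj)
      best <- list(obj = fit$deviance, alpha = clip_alpha(fit$par),
                   iters = fit$niter, converged = fit$info %in% 1:4)
  }
  # joint polish of all 2N parameters from the variable-projection optimum
  mu <- mu_solve(best$alpha)$mu
  joint_res <- function(p) {
    mu <- p[seq_len(order)]; al <- clip_alpha(p[order + seq_len(order)])
    rel_residuals(hyperelastic("ogden", mu = mu, alpha = al, D = D), pts)
  }
  pol <- try(minpack.lm::nls.lm(c(mu, best$alpha), fn = joint_res,
                                control = ctl), silent = TRUE)
  if (!inherits(pol, "try-error") && pol$deviance <= best$obj) {
    mu <- pol$par[seq_len(order)]
    best$alpha <- clip_alpha(pol$par[order + seq_len(order)])
    best$obj <- pol$deviance
    best$iters <- best$iters + pol$niter
    best$converged <- best$converged || pol$info %in% 1:4
  }
  list(model = hyperelastic("ogden", mu = mu, alpha = best$alpha, D = D),
       n_iterations = max(best$iters, 1L), converged = best$converged)
}

fit_vdw <- function(pts, D) {
  lam_max <- max(pts$lambda)
  starts <- expand.grid(lambda_m = pmax(c(2, 3, 5, 8), lam_max * 1.05),
                        beta = c(0, 0.5, 1), a = c(0.1, 0.5))
  mu0 <- 1
  best <- list(obj = Inf)
  for (k in seq_len(nrow(starts))) {
    p0 <- c(mu0, starts$lambda_m[k], starts$a[k], starts$beta[k])
    res_fun <- function(p) {
      m <- try(hyperelastic("van_der_waals", mu = p[1], lambda_m = p[2],
                            a = p[3], beta = p[4]), silent = TRUE)
      if (inherits(m, "try-error")) return(rep(1e6, nrow(pts)))
      rel_residuals(m, pts)
    }
    fit <- try(minpack.lm::nls.lm(p0, fn = res_fun,
                                  lower = c(-Inf, sqrt(3) + 1e-6, -Inf, 0),
                                  upper = c(Inf, Inf, Inf, 1),
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-15)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$deviance < best$obj) {
      p <- fit$par
      best <- list(obj = fit$deviance,
                   model = hyperelastic("van_der_waals", mu = p[1],
                                        lambda_m = p[2], a = p[3], beta = p[4],
                                        D = D),
                   iters = fit$niter, converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best$model)) rm_stop("van der Waals fit failed from every start",
                                   "respmech_fit")
  list(model = best$model, n_iterations = best$iters, converged = best$converged)
}

#' Fit a hyperelastic model to stress-strain test data
#'
#' Calibrates the deviatoric coefficients of one model family against one or
#' more nominal stress-strain curves by relative least squares
#' \eqn{\sum_k (T_{model}(\lambda_k)/T_k - 1)^2} (points with stress below
#' 1e-6 kPa are dropped).  Families whose stress is linear in the
#' coefficients (polynomial, reduced polynomial) are solved in one weighted
#' linear least-squares step; Ogden uses a fixed multistart grid of exponents
#' \eqn{\{\pm1,\pm2,\pm4,\pm7\}} with per-start linear solves for the shear
#' coefficients followed by Levenberg-Marquardt refinement; van der Waals is
#' a bounded multistart Levenberg-Marquardt fit.  Volumetric compliances
#' \code{D} are not fitted (no volumetric test data) and are passed through.
#'
#' @param data a \code{\link{test_dataset}} or list of them.
#' @param family model family (see \code{\link{hyperelastic}}).
#' @param order series order \eqn{N} (ignored for van der Waals).
#' @param D volumetric compliances forwarded to the fitted model (1/kPa).
#' @param stability_window nominal-strain screening window for the attached
#'   Drucker report.
#' @param seed integer seed controlling any stochastic refinement (the
#'   default pipeline is deterministic; the seed is recorded).
#' @return object of class \code{"hyperfit"}: fitted \code{model}, relative
#'   least-squares \code{residual}, \code{n_iterations}, \code{converged},
#'   a \code{stability} report, and the fitting data.
#' @seealso \code{\link{drucker_stability}}, \code{\link{rank_hyperelastic}}
#' @examples
#' d <- lung_test_dataset()
#' f <- hyperfit(d, "ogden", order = 2)
#' coef(f); f$residual
#' @export
hyperfit <- function(data, family = c("ogden", "polynomial",
                                      "reduced_polynomial", "van_der_waals"),
                     order = 1L, D = 0, stability_window = c(-0.9, 9),
                     seed = 20231003L) {
  family <- match.arg(family)
  datasets <- as_dataset_list(data)
  pts <- fit_points(datasets)
  n_par <- switch(family,
                  ogden = 2L * order,
                  polynomial = length(poly_terms(order)$i),
                  reduced_polynomial = order,
                  van_der_waals = 4L)
  if (nrow(pts) < max(n_par, 4))
    rm_stop(sprintf("need at least %d usable points to fit %d parameters",
                    max(n_par, 4), n_par), "respmech_input")
  if (all(pts$stress == 0))
    rm_stop("all stresses are zero: degenerate data", "respmech_input")
  set.seed(seed)
  fit <- switch(family,
                ogden = fit_ogden(order, pts, D),
                polynomial = fit_linear_family("polynomial", order, pts, D),
                reduced_polynomial = fit_linear_family("reduced_polynomial",
                                                       order, pts, D),
                van_der_waals = fit_vdw(pts, D))
  data_window <- range(unlist(lapply(datasets, `[[`, "strain")))
  out <- list(model = fit$model,
              residual = objective(fit$model, pts),
              n_iterations = fit$n_iterations,
              converged = fit$converged,
              stability = drucker_stability(fit$model,
                                            window = stability_window,
                                            data_window = data_window),
              data = datasets, points = pts, seed = seed)
  class(out) <- "hyperfit"
  out
}

#' @export
print.hyperfit <- function(x, ...) {
  cat(sprintf("Hyperelastic fit: %s  (relative LS residual %.4g%s)\n",
              x$model$label, x$residual,
              if (x$converged) "" else ", NOT converged"))
  print(x$model)
  cat(sprintf("Drucker stability on e in [%g, %g]: %s\n",
              x$stability$window[1], x$stability$window[2],
              if (x$stability$overall_stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' @export
summary.hyperfit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object, rel_residuals = r,
                 rms_percent = sqrt(mean(r^2)) * 100), class = "summary.hyperfit")
}

#' @export
print.summary.hyperfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("RMS relative misfit: %.3g%% over %d points\n",
              x$rms_percent, length(x$rel_residuals)))
  invisible(x)
}

#' @export
coef.hyperfit <- function(object, ...) {
  m <- object$model
  out <- switch(m$family,
                ogden = stats::setNames(c(m$mu, m$alpha),
                                        c(sprintf("mu%d", seq_len(m$order)),
                                          sprintf("alpha%d", seq_len(m$order)))),
                van_der_waals = c(mu = m$mu, lambda_m = m$lambda_m,
                                  a = m$a, beta = m$beta),
                stats::setNames(m$C, sprintf("C%d%d", m$i, m$j)))
  out
}

#' @export
predict.hyperfit <- function(object, stretch, mode = NULL, ...) {
  mode <- mode %||% attr(object$data[[1]], "mode")
  nominal_stress(object$model, mode, stretch)
}

#' @export
residuals.hyperfit <- function(object, ...) {
  rel_residuals(object$model, object$points)
}

#' @export
fitted.hyperfit <- function(object, ...) predict_points(object$model, object$points)

#' @export
simulate.hyperfit <- function(object, nsim = 1, seed = NULL, noise_sd = 0.05,
                              ...) {
  d <- object$data[[1]]
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
  else as.list(seed + seq_len(nsim) - 1L)
  out <- lapply(seeds, function(s)
    generate_test_data(object$model, attr(d, "mode"), d$strain,
                       noise_sd = noise_sd, seed = s))
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.hyperfit <- function(x, n = 200, ...) {
  d <- do.call(rbind, lapply(x$data, function(dd)
    cbind(dd, mode = attr(dd, "mode"))))
  lam <- seq(min(1 + d$strain), max(1 + d$strain), length.out = n)
  graphics::plot(d$strain, d$stress, pch = 1,
                 xlab = "nominal strain [-]", ylab = "nominal stress [kPa]",
                 main = sprintf("%s fit", x$model$label), ...)
  for (mode in unique(d$mode))
    graphics::lines(lam - 1, nominal_stress(x$model, mode, lam), col = 2)
  invisible(x)
}

# ---- Drucker stability ----

#' Drucker stability screening by homogeneous-path sweep
#'
#' Checks material stability (positive incremental stress work, d T d e > 0)
#' along the uniaxial, equibiaxial and planar homogeneous paths, tension and
#' compression, by requiring dT/d lambda > 0 at every grid point of the
#' sweep window.  Reports per-mode stable nominal-strain intervals and an
#' overall flag (stable on the entire window in every mode).  When a
#' \code{data_window} is given the restricted window is screened too.
#'
#' @param model a \code{hyperelastic_model} or \code{elastic_surrogate}.
#' @param window nominal-strain screening range containing 0 (default
#'   \code{c(-0.9, 9)}).
#' @param step sweep grid step (default 0.01).
#' @param data_window optional second, narrower window (e.g. the fitted-data
#'   strain range).
#' @return object of class \code{"drucker_report"}: per-mode interval lists,
#'   \code{overall_stable}, and (when requested) \code{data_window_stable}.
#' @export
drucker_stability <- function(model, window = c(-0.9, 9), step = 0.01,
                              data_window = NULL) {
  model <- as_hyperelastic(model)
  if (window[1] > 0 || window[2] < 0)
    rm_stop("stability window must contain 0", "respmech_config")
  if (step <= 0) rm_stop("step must be positive", "respmech_config")
  e <- seq(window[1], window[2], by = step)
  if (1 + min(e) <= 1e-8) {
    warning("stability grid clipped near lambda = 0")
    e <- e[1 + e > 1e-8]
  }
  modes <- c("uniaxial", "equibiaxial", "planar")
  sweep_mode <- function(mode) {
    lam <- 1 + e
    T <- suppressWarnings(nominal_stress(model, mode, lam))
    h <- step * 1e-2
    dT <- suppressWarnings(
      (nominal_stress(model, mode, lam + h) -
         nominal_stress(model, mode, lam - h)) / (2 * h))
    ok <- is.finite(dT) & dT > 0
    list(ok = ok, intervals = runs_to_intervals(e, ok))
  }
  sw <- lapply(modes, sweep_mode)
  names(sw) <- modes
  out <- list(window = window, step = step,
              intervals = lapply(sw, `[[`, "intervals"),
              overall_stable = all(vapply(sw, function(s) all(s$ok), logical(1))))
  if (!is.null(data_window)) {
    ind <- e >= data_window[1] & e <= data_window[2]
    out$data_window <- data_window
    out$data_window_stable <-
      all(vapply(sw, function(s) all(s$ok[ind]), logical(1)))
  }
  class(out) <- "drucker_report"
  out
}

runs_to_intervals <- function(e, ok) {
  if (!any(ok)) return(matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, c("from", "to"))))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cbind(from = e[starts[keep]], to = e[ends[keep]])
}

#' @export
print.drucker_report <- function(x, ...) {
  cat(sprintf("Drucker stability sweep, e in [%g, %g], step %g\n",
              x$window[1], x$window[2], x$step))
  for (mode in names(x$intervals)) {
    iv <- x$intervals[[mode]]
    cat(sprintf("  %-12s stable on %s\n", mode,
                if (!nrow(iv)) "nowhere"
                else paste(sprintf("[%.3g, %.3g]", iv[, 1], iv[, 2]),
                           collapse = ", ")))
  }
  cat(sprintf("  overall: %s\n",
              if (x$overall_stable) "stable on the whole window" else "UNSTABLE"))
  if (!is.null(x$data_window))
    cat(sprintf("  data window [%g, %g]: %s\n", x$data_window[1],
                x$data_window[2],
                if (x$data_window_stable) "stable" else "UNSTABLE"))
  invisible(x)
}

# ---- roster ranking ----

#' Default 15-model candidate roster
#'
#' Ogden orders 1-6, polynomial orders 1-2 (order 1 being Mooney-Rivlin),
#' reduced polynomial orders 1-6 (order 1 being neo-Hookean), and van der
#' Waals: 15 candidates.
#'
#' @return data.frame with columns \code{family}, \code{order}.
#' @export
default_roster <- function() {
  rbind(data.frame(family = "ogden", order = 1:6),
        data.frame(family = "polynomial", order = 1:2),
        data.frame(family = "reduced_polynomial", order = 1:6),
        data.frame(family = "van_der_waals", order = 1))
}

#' Fit and rank a roster of hyperelastic models
#'
#' Fits every candidate in \code{roster} to the same datasets with
#' \code{\link{hyperfit}}, screens Drucker stability, and returns the
#' candidates sorted by ascending relative least-squares residual.  Fit
#' failures are kept as rows with infinite residual rather than aborting.
#'
#' @inheritParams hyperfit
#' @param roster data.frame with columns \code{family}, \code{order}
#'   (default \code{\link{default_roster}()}).
#' @return object of class \code{"model_ranking"}: a data.frame with columns
#'   \code{label}, \code{family}, \code{order}, \code{residual},
#'   \code{overall_stable}, \code{data_window_stable}, \code{converged};
#'   attribute \code{fits} holds the hyperfit objects in ranked order.
#' @export
rank_hyperelastic <- function(data, roster = default_roster(),
                              stability_window = c(-0.9, 9),
                              seed = 20231003L) {
  if (!is.data.frame(roster) || !nrow(roster))
    rm_stop("roster must be a non-empty data.frame(family, order)",
            "respmech_config")
  datasets <- as_dataset_list(data)
  rows <- vector("list", nrow(roster))
  fits <- vector("list", nrow(roster))
  for (k in seq_len(nrow(roster))) {
    fam <- roster$family[k]; ord <- roster$order[k]
    f <- try(hyperfit(datasets, fam, order = ord,
                      stability_window = stability_window, seed = seed),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      rows[[k]] <- data.frame(label = paste0(fam, "_", ord), family = fam,
                              order = ord, residual = Inf,
                              overall_stable = NA, data_window_stable = NA,
                              converged = FALSE)
    } else {
      fits[[k]] <- f
      rows[[k]] <- data.frame(label = f$model$label, family = fam, order = ord,
                              residual = f$residual,
                              overall_stable = f$stability$overall_stable,
                              data_window_stable =
                                f$stability$data_window_stable %||% NA,
                              converged = f$converged)
    }
  }
  tab <- do.call(rbind, rows)
  o <- order(tab$residual)
  tab <- tab[o, ]
  rownames(tab) <- NULL
  structure(tab, fits = fits[o], class = c("model_ranking", "data.frame"))
}

#' @export
print.model_ranking <- function(x, ...) {
  cat(sprintf("Hyperelastic model ranking (%d candidates, ascending residual)\n",
              nrow(x)))
  df <- as.data.frame(x)
  df$residual <- signif(df$residual, 4)
  print(df, row.names = TRUE)
  invisible(x)
}

#' Read / write test datasets as CSV
#'
#' CSV layout: columns \code{mode}, \code{nominal_strain},
#' \code{nominal_stress_kPa}; one file may hold several modes.
#'
#' @param path CSV file path.
#' @param datasets list of \code{test_dataset} (for writing).
#' @return \code{read_test_data} returns a list of \code{test_dataset}.
#' @export
read_test_data <- function(path) {
  df <- utils::read.csv(path)
  need <- c("mode", "nominal_strain", "nominal_stress_kPa")
  if (!all(need %in% names(df)))
    rm_stop(sprintf("test-data CSV must have columns %s",
                    paste(need, collapse = ", ")), "respmech_input")
  lapply(split(df, df$mode), function(s) {
    s <- s[order(s$nominal_strain), ]
    test_dataset(s$mode[1], s$nominal_strain, s$nominal_stress_kPa,
                 provenance = path)
  })
}

#' @rdname read_test_data
#' @export
write_test_data <- function(datasets, path) {
  datasets <- as_dataset_list(datasets)
  df <- do.call(rbind, lapply(datasets, function(d)
    data.frame(mode = attr(d, "mode"), nominal_strain = d$strain,
               nominal_stress_kPa = d$stress)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
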