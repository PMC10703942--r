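# Respiratory validation metrics: landmark trajectories, truncated relative
# errors, slice cross-section areas, and volume reports.

# truncation toward zero at d decimals, with a tiny relative guard against
# binary floating-point sitting just under a decimal boundary
trunc_dec <- function(x, d) {
  trunc(x * 10^d * (1 + 1e-12) + 1e-12) / 10^d
}

#' Truncated relative error in percent
#'
#' \code{trunc(|sim - ref| / |ref| * 100, decimals)}: the error convention
#' of the landmark and volume comparison tables (truncation toward zero,
#' magnitudes of the compared values).
#'
#' @param sim simulated value(s).
#' @param ref reference value(s), nonzero.
#' @param decimals digits kept after the decimal point (1 for landmark
#'   tables, 2 for volume tables).
#' @return error(s) in percent.
#' @examples
#' relative_error_truncated(38.00, 38.70, 1)  # 1.8
#' relative_error_truncated(15.55, 15.10, 1)  # 2.9 (rounding would give 3.0)
#' @export
relative_error_truncated <- function(sim, ref, decimals = 1) {
  if (any(ref == 0)) rm_stop("reference value is zero: error undefined",
                             "respmech_domain")
  trunc_dec(abs(abs(sim) - abs(ref)) / abs(ref) * 100, decimals)
}

#' Landmark trajectories through a simulation
#'
#' Barycentric advection: position(t) = sum_i w_i (X_i + u_i(t)) over the
#' four host-element nodes; exact for nodal landmarks and linear in the
#' displacement field.
#'
#' @param result a \code{breath_sim}.
#' @param landmarks a \code{landmark_set} embedded in \code{result$mesh}.
#' @return array \code{[n_landmarks, 3, n_times + 1]}; slice 1 is the
#'   reference configuration.
#' @export
landmark_trajectories <- function(result, landmarks) {
  mesh <- result$mesh
  if (any(landmarks$element < 1 | landmarks$element > nrow(mesh$tets)))
    rm_stop("landmark host element missing from the mesh", "respmech_input")
  W <- as.matrix(landmarks[, c("w1", "w2", "w3", "w4")])
  nt <- length(result$times)
  out <- array(NA_real_, c(nrow(landmarks), 3, nt + 1))
  for (s in 0:nt) {
    x <- mesh$nodes + if (s == 0) 0 else result$U[[s]]
    for (k in seq_len(nrow(landmarks))) {
      X <- x[mesh$tets[landmarks$element[k], ], , drop = FALSE]
      out[k, , s + 1] <- as.numeric(t(X) %*% W[k, ])
    }
  }
  dimnames(out) <- list(landmarks$id, c("x", "y", "z"), NULL)
  out
}

#' Directional landmark displacements
#'
#' Displacement of each landmark between the reference state and a given
#' time, decomposed along the patient axes x = left/right, y =
#' anterior/posterior, z = superior/inferior, with per-case (mean) values.
#'
#' @param result a \code{breath_sim}.
#' @param landmarks a \code{landmark_set}.
#' @param time time at which to evaluate (default: peak of the schedule,
#'   i.e. end of exhalation).
#' @return data.frame (id, lr, ap, si) with attribute \code{means}
#'   (named length-3 vector).
#' @export
directional_displacements <- function(result, landmarks, time = NULL) {
  tr <- landmark_trajectories(result, landmarks)
  times <- result$times
  if (is.null(time)) time <- times[which.max(schedule_factor(result$schedule,
                                                             times))]
  s <- which.min(abs(times - time))
  d <- tr[, , s + 1, drop = FALSE][, , 1] - tr[, , 1]
  if (nrow(landmarks) == 1) d <- matrix(d, ncol = 3)  # drop-dim guard
  df <- data.frame(id = landmarks$id, lr = d[, 1], ap = d[, 2], si = d[, 3])
  means <- c(lr = mean(df$lr), ap = mean(df$ap), si = mean(df$si))
  attr(df, "means") <- means
  attr(df, "time") <- times[s]
  df
}

#' Landmark mean-displacement error table
#'
#' One row per case and direction comparing reference (CT-derived) and
#' simulated mean landmark displacements, with the truncated percent error
#' on component magnitudes.
#'
#' @param ct data.frame with columns \code{case}, \code{lr}, \code{ap},
#'   \code{si} (reference mean displacements, mm).
#' @param sim same layout, simulated.
#' @param decimals truncation digits (default 1).
#' @return data.frame of class \code{"error_table"}: case, direction, ref,
#'   sim, error_pct (flagged NA when the reference component is zero).
#' @export
landmark_error_table <- function(ct, sim, decimals = 1) {
  if (!all(c("case", "lr", "ap", "si") %in% names(ct)) ||
      !all(c("case", "lr", "ap", "si") %in% names(sim)))
    rm_stop("ct and sim need columns case, lr, ap, si", "respmech_input")
  if (!identical(ct$case, sim$case))
    rm_stop("mismatched case lists", "respmech_input")
  rows <- list()
  for (k in seq_len(nrow(ct))) {
    for (dir in c("lr", "ap", "si")) {
      r <- ct[[dir]][k]; s <- sim[[dir]][k]
      err <- if (r == 0) NA_real_ else relative_error_truncated(s, r, decimals)
      rows[[length(rows) + 1]] <- data.frame(case = ct$case[k],
                                             direction = toupper(dir),
                                             ref = r, sim = s,
                                             error_pct = err)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("error_table", "data.frame")
  out
}

#' Volume comparison report
#'
#' Per-case lung volumes at full inspiration and full expiration (reference
#' and simulated), percent volume error at 2-decimal truncation, and the
#' column summaries (arithmetic mean and population standard deviation,
#' both truncated to 2 decimals).
#'
#' @param cases data.frame with columns \code{case}, \code{inspiration_L},
#'   \code{ct_expiration_L}, \code{fem_expiration_L} (litres).
#' @return object of class \code{"volume_report"}: \code{rows} (with
#'   \code{error_pct}) and \code{summary} (mean/sd per column).
#' @export
volume_report <- function(cases) {
  need <- c("case", "inspiration_L", "ct_expiration_L", "fem_expiration_L")
  if (!is.data.frame(cases) || !nrow(cases) || !all(need %in% names(cases)))
    rm_stop(sprintf("cases must be a non-empty data.frame with columns %s",
                    paste(need, collapse = ", ")), "respmech_input")
  if (any(cases$inspiration_L <= 0 | cases$ct_expiration_L <= 0 |
            cases$fem_expiration_L <= 0))
    rm_stop("volumes must be positive", "respmech_input")
  rows <- cases[need]
  rows$error_pct <- relative_error_truncated(cases$fem_expiration_L,
                                             cases$ct_expiration_L,
                                             decimals = 2)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summ <- data.frame(
    column = c("inspiration_L", "ct_expiration_L", "fem_expiration_L",
               "error_pct"),
    mean = trunc_dec(c(mean(rows$inspiration_L), mean(rows$ct_expiration_L),
                       mean(rows$fem_expiration_L), mean(rows$error_pct)), 2),
    sd = trunc_dec(c(pop_sd(rows$inspiration_L), pop_sd(rows$ct_expiration_L),
                     pop_sd(rows$fem_expiration_L), pop_sd(rows$error_pct)), 2))
  structure(list(rows = rows, summary = summ), class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("Volumetric comparison (litres; error % truncated to 2 decimals)\n")
  print(x$rows, row.names = FALSE)
  cat("Mean (population SD):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Total landmark census
#' @param counts non-negative per-case landmark counts.
#' @return their sum.
#' @export
landmark_census <- function(counts) {
  if (length(counts) == 0) return(0L)
  if (any(counts < 0) || any(counts != round(counts)))
    rm_stop("counts must be non-negative integers", "respmech_input")
  as.integer(sum(counts))
}

#' Bundled nine-case clinical validation dataset
#'
#' Mean landmark displacements (CT-derived reference vs simulated, mm along
#' the L/R, A/P, S/I axes), lung volumes at full inspiration/expiration
#' (litres) and per-case landmark/element counts for nine adult cases from
#' a published respiratory-motion validation study; used as the worked
#' example for the error tables.
#'
#' @return list of data.frames: \code{landmarks}, \code{volumes},
#'   \code{counts}.
#' @export
clinical_cases <- function() {
  p <- function(f) system.file("extdata", f, package = "respmech",
                               mustWork = TRUE)
  list(landmarks = utils::read.csv(p("clinical_cases_landmarks.csv")),
       volumes = utils::read.csv(p("clinical_cases_volumes.csv")),
       counts = utils::read.csv(p("clinical_cases_counts.csv")))
}

# ---- slice cross-sections ----

#' Cross-sectional areas on parallel planes
#'
#' Slices a watertight surface with \code{n_planes} planes perpendicular to
#' the z (superior-inferior) axis, spaced \code{spacing} mm apart from the
#' anchor downward (superior to inferior, labels C1..Cn).  Per plane, the
#' mesh-plane intersection loops are chained and their polygon areas
#' (shoelace) summed per component; components are labelled left/right by
#' the sign of the loop centroid x.
#'
#' @param surface a \code{tri_surface} (or \code{tet_mesh}, whose boundary
#'   is used).
#' @param n_planes number of planes (default 5).
#' @param spacing plane spacing in mm (default 28.6).
#' @param anchor z of the first (most superior) plane; default one spacing
#'   below the apex (max z).
#' @return data.frame of class \code{"slice_profile"}: \code{slice},
#'   \code{z}, \code{area_left}, \code{area_right}, \code{area_total}
#'   (mm^2).
#' @export
slice_cross_sections <- function(surface, n_planes = 5, spacing = 28.6,
                                 anchor = NULL) {
  if (inherits(surface, "tet_mesh")) surface <- boundary_surface(surface)
  if (!inherits(surface, "tri_surface"))
    rm_stop("need a tri_surface or tet_mesh", "respmech_input")
  v <- surface$vertices
  if (is.null(anchor)) anchor <- max(v[, 3]) - spacing
  zs <- anchor - spacing * (seq_len(n_planes) - 1)
  rows <- lapply(seq_along(zs), function(k) {
    loops <- plane_section_loops(v, surface$faces, zs[k])
    if (!length(loops)) {
      warning(sprintf("plane z = %.3g misses the surface", zs[k]))
      return(data.frame(slice = paste0("C", k), z = zs[k], area_left = 0,
                        area_right = 0, area_total = 0))
    }
    aL <- aR <- 0
    for (lp in loops) {
      a <- abs(polygon_area_xy(lp))
      if (mean(lp[, 1]) > 0) aL <- aL + a else aR <- aR + a
    }
    data.frame(slice = paste0("C", k), z = zs[k], area_left = aL,
               area_right = aR, area_total = aL + aR)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("slice_profile", "data.frame")
  out
}

# closed intersection loops of a triangulated surface with plane z = z0;
# returns a list of m x 3 ordered loop-vertex matrices
plane_section_loops <- function(v, f, z0) {
  z <- v[, 3] - z0
  eps <- 1e-9 * max(1, max(abs(z)))
  z[abs(z) < eps] <- eps              # nudge vertices off the plane
  below <- z < 0
  nb <- below[f[, 1]] + below[f[, 2]] + below[f[, 3]]
  cut <- which(nb == 1 | nb == 2)
  if (!length(cut)) return(list())
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  # each cut triangle contributes one segment between its two cut edges
  segs <- matrix("", length(cut), 2)
  pts <- new.env()
  for (i in seq_along(cut)) {
    tri <- f[cut[i], ]
    ek <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tri[e[1]]; b <- tri[e[2]]
      if (xor(below[a], below[b])) {
        key <- ekey(a, b)
        if (!exists(key, envir = pts, inherits = FALSE)) {
          t_ <- z[a] / (z[a] - z[b])
          assign(key, v[a, ] + t_ * (v[b, ] - v[a, ]), envir = pts)
        }
        ek <- c(ek, key)
      }
    }
    segs[i, ] <- ek
  }
  # chain segments into loops (each edge key appears in exactly 2 segments)
  loops <- list()
  used <- rep(FALSE, nrow(segs))
  repeat {
    s0 <- which(!used)[1]
    if (is.na(s0)) break
    loop_keys <- segs[s0, 1]
    cur <- segs[s0, 2]; used[s0] <- TRUE
    while (cur != loop_keys[1]) {
      loop_keys <- c(loop_keys, cur)
      nxt <- which(!used & (segs[, 1] == cur | segs[, 2] == cur))[1]
      if (is.na(nxt)) break               # open chain: abandon (shouldn't occur)
      cur <- if (segs[nxt, 1] == cur) segs[nxt, 2] else segs[nxt, 1]
      used[nxt] <- TRUE
    }
    if (length(loop_keys) >= 3)
      loops[[length(loops) + 1]] <-
        do.call(rbind, lapply(loop_keys, function(k) get(k, envir = pts)))
  }
  loops
}

polygon_area_xy <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Relative slice-area errors between two surfaces
#'
#' @param ref,sim \code{slice_profile} objects on the same planes.
#' @param decimals truncation digits (default 2).
#' @return data.frame: slice, z, and truncated percent errors for left,
#'   right and total areas (NA where the reference area is zero).
#' @export
slice_area_errors <- function(ref, sim, decimals = 2) {
  if (nrow(ref) != nrow(sim) || any(abs(ref$z - sim$z) > 1e-9))
    rm_stop("profiles are on different planes", "respmech_input")
  err <- function(s, r) ifelse(r == 0, NA_real_,
                               relative_error_truncated(s, r, decimals))
  data.frame(slice = ref$slice, z = ref$z,
             error_left = err(sim$area_left, ref$area_left),
             error_right = err(sim$area_right, ref$area_right),
             error_total = err(sim$area_total, ref$area_total))
}
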