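# Tetrahedral meshes, the synthetic half-ellipsoid lung phantom, landmark
# embedding, volumes, and STL / VTU plumbing.

signed_tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  u <- nodes[tets[, 2], , drop = FALSE] - a
  v <- nodes[tets[, 3], , drop = FALSE] - a
  w <- nodes[tets[, 4], , drop = FALSE] - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) +
     u[, 2] * (v[, 3] * w[, 1] - v[, 1] * w[, 3]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

# outward faces of positively oriented tets (a,b,c,d):
# (a,c,b), (a,b,d), (b,c,d), (a,d,c)
tet_faces <- function(tets) {
  rbind(tets[, c(1, 3, 2), drop = FALSE],
        tets[, c(1, 2, 4), drop = FALSE],
        tets[, c(2, 3, 4), drop = FALSE],
        tets[, c(1, 4, 3), drop = FALSE])
}

#' Tetrahedral mesh with named node and facet sets
#'
#' Nodes are in mm.  Tetrahedra are re-oriented to positive volume on
#' construction; the boundary is extracted as the faces owned by exactly one
#' tetrahedron, stored with outward orientation, and checked watertight
#' (every boundary edge shared by exactly two boundary triangles).
#'
#' @param nodes numeric n x 3 matrix of coordinates (mm).
#' @param tets integer m x 4 matrix of node indices.
#' @param node_sets named list of node index vectors.
#' @param facet_sets named list of boundary-facet index vectors (rows of
#'   \code{$boundary}).
#' @param meta free-form list (provenance, seed, spec).
#' @return object of class \code{"tet_mesh"}: \code{nodes}, \code{tets},
#'   \code{boundary} (b x 3, outward), \code{node_sets}, \code{facet_sets},
#'   \code{meta}.
#' @export
tet_mesh <- function(nodes, tets, node_sets = list(), facet_sets = list(),
                     meta = list()) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3 || ncol(tets) != 4)
    rm_stop("nodes must be n x 3 and tets m x 4", "respmech_mesh")
  if (any(tets < 1L) || any(tets > nrow(nodes)))
    rm_stop("tet indices out of range", "respmech_mesh")
  vol <- signed_tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  vol <- abs(vol)
  if (any(vol <= 0))
    rm_stop(sprintf("%d degenerate tetrahedra (zero volume)", sum(vol <= 0)),
            "respmech_mesh")
  faces <- tet_faces(tets)
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  cnt <- table(key)
  if (any(cnt > 2)) rm_stop("non-manifold interior face", "respmech_mesh")
  boundary <- faces[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  check_watertight(boundary)
  bad <- vapply(node_sets, function(s) any(s < 1 | s > nrow(nodes)), logical(1))
  if (any(bad)) rm_stop("node set index out of range", "respmech_mesh")
  bad <- vapply(facet_sets, function(s) any(s < 1 | s > nrow(boundary)),
                logical(1))
  if (any(bad)) rm_stop("facet set index out of range", "respmech_mesh")
  structure(list(nodes = nodes, tets = tets, boundary = boundary,
                 node_sets = node_sets, facet_sets = facet_sets, meta = meta),
            class = "tet_mesh")
}

check_watertight <- function(tris) {
  if (!nrow(tris)) rm_stop("empty boundary", "respmech_mesh")
  edges <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  ukey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(ukey)
  if (any(cnt != 2)) {
    open <- names(cnt)[cnt != 2]
    rm_stop(sprintf("surface not watertight: %d open/overshared edges (e.g. %s)",
                    length(open), paste(utils::head(open, 3), collapse = "; ")),
            "respmech_mesh")
  }
  dkey <- paste(edges[, 1], edges[, 2])
  if (any(table(dkey) != 1))
    rm_stop("surface orientation inconsistent (repeated directed edge)",
            "respmech_mesh")
  invisible(TRUE)
}

#' @export
print.tet_mesh <- function(x, ...) {
  v <- sum(signed_tet_volumes(x$nodes, x$tets))
  cat(sprintf("tet_mesh: %d nodes, %d tets, %d boundary triangles, volume %.4g mm^3 (%.4g L)\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary), v, v / 1e6))
  if (length(x$node_sets))
    cat("  node sets: ", paste(sprintf("%s(%d)", names(x$node_sets),
                                       lengths(x$node_sets)), collapse = ", "), "\n")
  if (length(x$facet_sets))
    cat("  facet sets:", paste(sprintf("%s(%d)", names(x$facet_sets),
                                       lengths(x$facet_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Triangulated closed surface
#'
#' @param vertices n x 3 matrix (mm).
#' @param faces m x 3 integer matrix, consistently oriented (outward for a
#'   positive enclosed volume).
#' @param check validate watertightness (default TRUE).
#' @return object of class \code{"tri_surface"}.
#' @export
tri_surface <- function(vertices, faces, check = TRUE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (check) check_watertight(faces)
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

#' Extract the boundary of a tet mesh as a surface
#' @param mesh a \code{tet_mesh}.
#' @param facets optional boundary facet row indices (default all).
#' @param check validate watertightness of the extracted patch.
#' @return a \code{tri_surface}.
#' @export
boundary_surface <- function(mesh, facets = NULL, check = TRUE) {
  tris <- if (is.null(facets)) mesh$boundary
  else mesh$boundary[facets, , drop = FALSE]
  keep <- sort(unique(as.vector(tris)))
  remap <- match(tris, keep)
  tri_surface(mesh$nodes[keep, , drop = FALSE],
              matrix(remap, ncol = 3), check = check)
}

# ---- volume ----

#' Enclosed volume of a mesh or closed surface
#'
#' For a \code{tet_mesh} the volume is the sum of (positive) tetrahedron
#' volumes; for a \code{tri_surface} it is the divergence-theorem sum over
#' outward triangles.  The two routes agree to machine precision on the same
#' body and are cross-checked in the test-suite.
#'
#' @param x a \code{tet_mesh} or \code{tri_surface}.
#' @param units \code{"mm3"} (default) or \code{"L"}.
#' @return scalar volume.
#' @export
mesh_volume <- function(x, units = c("mm3", "L")) UseMethod("mesh_volume")

#' @export
mesh_volume.tet_mesh <- function(x, units = c("mm3", "L")) {
  units <- match.arg(units)
  v <- sum(signed_tet_volumes(x$nodes, x$tets))
  if (units == "L") v / 1e6 else v
}

#' @export
mesh_volume.tri_surface <- function(x, units = c("mm3", "L")) {
  units <- match.arg(units)
  v <- surface_volume(x$vertices, x$faces)
  if (units == "L") v / 1e6 else v
}

surface_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# ---- phantom ----

#' Specification of the synthetic lung phantom
#'
#' @param semi_axes ellipsoid semi-axes (a, b, c) in mm; the phantom is the
#'   half-ellipsoid z >= 0, flat base (diaphragm) at z = 0, apex (tracheal
#'   pole) at z = c.
#' @param edge target edge length (mm), smaller than the least semi-axis.
#' @param trachea_angle angular radius (rad) of the apex node patch standing
#'   in for the tracheal attachment.
#' @param seed integer recorded with the mesh (generation is deterministic).
#' @return object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(semi_axes = c(50, 50, 120), edge = 8,
                         trachea_angle = 0.35, seed = 1L) {
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    rm_stop("semi_axes must be 3 positive lengths", "respmech_config")
  if (edge <= 0 || edge >= min(semi_axes))
    rm_stop("edge length must be positive and below the least semi-axis",
            "respmech_config")
  structure(list(semi_axes = as.numeric(semi_axes), edge = edge,
                 trachea_angle = trachea_angle, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Kuhn (Freudenthal) 6-tet split of a structured hex cell; conforming
# across neighbouring cells.
kuhn_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Build the half-ellipsoid lung phantom mesh
#'
#' Generates a structured tetrahedral mesh of the solid half-ellipsoid
#' \eqn{(x/a)^2 + (y/b)^2 + (z/c)^2 \le 1,\; z \ge 0}: a Kuhn-subdivided
#' structured grid on the half-cube is mapped radially onto the half-ball
#' (sup-norm to Euclidean-norm map, which keeps boundary nodes exactly on
#' the ellipsoid) and scaled by the semi-axes.  Named sets:
#' \code{trachea_top} (apex node patch), \code{diaphragm_base} (flat-base
#' nodes and facets) and \code{outer_surface} (remaining boundary facets,
#' the pressure-loaded pleural surface).
#'
#' @param spec a \code{\link{phantom_spec}} (or arguments forwarded to it).
#' @param ... forwarded to \code{phantom_spec} when \code{spec} is missing.
#' @return a \code{\link{tet_mesh}}.
#' @examples
#' ph <- build_phantom(phantom_spec(semi_axes = c(30, 30, 60), edge = 10))
#' mesh_volume(ph) / (2 / 3 * pi * 30 * 30 * 60)
#' @export
build_phantom <- function(spec = phantom_spec(...), ...) {
  ax <- spec$semi_axes
  nx <- 2L * max(2L, as.integer(ceiling(ax[1] / spec$edge)))
  ny <- 2L * max(2L, as.integer(ceiling(ax[2] / spec$edge)))
  nz <- max(2L, as.integer(ceiling(ax[3] / spec$edge)))
  gx <- seq(-1, 1, length.out = nx + 1)
  gy <- seq(-1, 1, length.out = ny + 1)
  gz <- seq(0, 1, length.out = nz + 1)
  idx <- function(i, j, k) i + (nx + 1L) * (j - 1L + (ny + 1L) * (k - 1L))
  grid <- expand.grid(x = gx, y = gy, z = gz)
  p <- as.matrix(grid)
  # smooth cube-to-ball map: cube surface goes exactly onto the unit sphere
  # and the base plane z = 0 stays flat
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  nodes <- cbind(x * sqrt(pmax(0, 1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3)),
                 y * sqrt(pmax(0, 1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3)),
                 z * sqrt(pmax(0, 1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3)))
  nodes <- sweep(nodes, 2, ax, "*")

  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  ncell <- nrow(cells)
  tets <- matrix(0L, 6L * ncell, 4L)
  ei <- diag(3)
  row <- 0L
  corner <- function(off) idx(cells$i + off[1], cells$j + off[2],
                              cells$k + off[3])
  for (pm in seq_len(6)) {
    o0 <- c(0L, 0L, 0L)
    o1 <- o0 + ei[kuhn_perms[pm, 1], ]
    o2 <- o1 + ei[kuhn_perms[pm, 2], ]
    o3 <- c(1L, 1L, 1L)
    tets[row + seq_len(ncell), ] <- cbind(corner(o0), corner(o1),
                                          corner(o2), corner(o3))
    row <- row + ncell
  }
  # the radial map can collapse tets touching degenerate grid images; drop
  # exact duplicates of mapped nodes first
  key <- apply(round(nodes, 9), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  remap <- cumsum(uniq)[match(key, key[uniq])]
  nodes <- nodes[uniq, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4)
  degen <- abs(signed_tet_volumes(nodes, tets)) < 1e-9 * prod(ax) / 1e6
  tets <- tets[!degen, , drop = FALSE]
  if (!nrow(tets))
    rm_stop("phantom meshing failed: all cells degenerate (edge too coarse?)",
            "respmech_mesh")

  mesh <- tet_mesh(nodes, tets, meta = list(spec = spec))
  # named sets
  zmin <- min(mesh$nodes[, 3])
  base_nodes <- which(mesh$nodes[, 3] <= zmin + 1e-9 * ax[3])
  q <- sweep(mesh$nodes, 2, ax, "/")
  bidx <- sort(unique(as.vector(mesh$boundary)))
  on_dome <- abs(rowSums(q[bidx, , drop = FALSE]^2) - 1) < 1e-6
  ang <- acos(pmin(1, pmax(-1, q[bidx, 3])))
  trachea <- bidx[on_dome & ang <= spec$trachea_angle]
  if (!length(trachea))
    rm_stop("phantom meshing failed: empty tracheal patch (angle too small)",
            "respmech_mesh")
  fz <- matrix(mesh$nodes[mesh$boundary, 3], ncol = 3)
  base_facets <- which(apply(fz <= zmin + 1e-9 * ax[3], 1, all))
  outer <- setdiff(seq_len(nrow(mesh$boundary)), base_facets)
  mesh$node_sets <- list(trachea_top = trachea, diaphragm_base = base_nodes)
  mesh$facet_sets <- list(diaphragm_base = base_facets, outer_surface = outer)
  mesh
}

# ---- landmarks ----

barycentric <- function(p, X) {
  # X: 4 x 3 tet vertex matrix; returns weights of p (sum 1)
  A <- rbind(t(X), rep(1, 4))
  as.numeric(solve(A, c(p, 1)))
}

#' Embed landmarks in a tet mesh
#'
#' Seeds \code{n} material points (landmarks), each stored as a host element
#' plus barycentric weights so it can be advected exactly with the
#' displacement field.  The region is either an axis-aligned box
#' \code{c(xmin, xmax, ymin, ymax, zmin, zmax)} (points drawn uniformly over
#' the contained tetrahedra) or the name of a node set (landmarks placed at
#' distinct nodes of that set).
#'
#' @param mesh a \code{tet_mesh}.
#' @param region box (length-6 numeric) or node-set name.
#' @param n number of landmarks.
#' @param seed integer seed; fixed seed reproduces the draw.
#' @return data.frame of class \code{"landmark_set"}: \code{id}, \code{x},
#'   \code{y}, \code{z}, \code{element}, \code{w1..w4}.
#' @export
seed_landmarks <- function(mesh, region, n, seed = 1L) {
  set.seed(seed)
  if (is.character(region)) {
    cand <- mesh$node_sets[[region]]
    if (is.null(cand)) rm_stop(sprintf("no node set '%s'", region),
                               "respmech_input")
    if (n > length(cand))
      rm_stop(sprintf("n = %d exceeds the %d candidate nodes", n, length(cand)),
              "respmech_input")
    picks <- sample(cand, n)
    out <- lapply(seq_len(n), function(k) {
      nd <- picks[k]
      el <- which(apply(mesh$tets == nd, 1, any))[1]
      w <- as.numeric(mesh$tets[el, ] == nd)
      c(nd = nd, el = el, w)
    })
    tab <- do.call(rbind, out)
    pos <- mesh$nodes[tab[, 1], , drop = FALSE]
    df <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                     element = as.integer(tab[, 2]),
                     w1 = tab[, 3], w2 = tab[, 4], w3 = tab[, 5], w4 = tab[, 6])
    class(df) <- c("landmark_set", "data.frame")
    return(df)
  }
  if (length(region) != 6) rm_stop("box region must be length 6", "respmech_input")
  box <- matrix(region, 2)
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
            mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  inside <- cen[, 1] >= box[1, 1] & cen[, 1] <= box[2, 1] &
    cen[, 2] >= box[1, 2] & cen[, 2] <= box[2, 2] &
    cen[, 3] >= box[1, 3] & cen[, 3] <= box[2, 3]
  els <- which(inside)
  if (!length(els)) rm_stop("region does not intersect the mesh",
                            "respmech_input")
  vol <- signed_tet_volumes(mesh$nodes, mesh$tets[els, , drop = FALSE])
  host <- sample(els, n, replace = TRUE, prob = vol)
  # uniform barycentric sampling (Dirichlet(1,1,1,1) via sorted uniforms)
  w <- t(vapply(seq_len(n), function(k) {
    u <- sort(stats::runif(3))
    c(u[1], u[2] - u[1], u[3] - u[2], 1 - u[3])
  }, numeric(4)))
  pos <- t(vapply(seq_len(n), function(k) {
    as.numeric(t(mesh$nodes[mesh$tets[host[k], ], ]) %*% w[k, ])
  }, numeric(3)))
  df <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   element = host, w1 = w[, 1], w2 = w[, 2], w3 = w[, 3],
                   w4 = w[, 4])
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' Reconstruct landmark reference positions from their embedding
#' @param mesh the host \code{tet_mesh}.
#' @param landmarks a \code{landmark_set}.
#' @return n x 3 matrix of positions (mm).
#' @export
landmark_positions <- function(mesh, landmarks) {
  W <- as.matrix(landmarks[, c("w1", "w2", "w3", "w4")])
  t(vapply(seq_len(nrow(landmarks)), function(k) {
    X <- mesh$nodes[mesh$tets[landmarks$element[k], ], , drop = FALSE]
    as.numeric(t(X) %*% W[k, ])
  }, numeric(3)))
}

#' @rdname seed_landmarks
#' @param landmarks a \code{landmark_set}.
#' @param path CSV path (columns id, x, y, z).
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks[, c("id", "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

# brute-force point location (test oracle and STL-landmark import)
locate_point <- function(mesh, p, tol = 1e-9) {
  for (el in seq_len(nrow(mesh$tets))) {
    w <- try(barycentric(p, mesh$nodes[mesh$tets[el, ], , drop = FALSE]),
             silent = TRUE)
    if (inherits(w, "try-error")) next
    if (all(w >= -tol)) return(list(element = el, w = pmax(w, 0) / sum(pmax(w, 0))))
  }
  NULL
}

# ---- STL ----

#' Read and write STL surface files
#'
#' Binary STL is the default write dialect (exact single-precision
#' round-trip); ASCII is auto-detected on read.  Import performs validation
#' only (watertightness and consistent orientation when \code{check} is
#' TRUE); repair is out of scope.
#'
#' @param path STL file path.
#' @param surface a \code{tri_surface}.
#' @param check validate watertightness on read.
#' @param ascii write the ASCII dialect instead of binary.
#' @return \code{read_stl} returns a \code{tri_surface}.
#' @export
read_stl <- function(path, check = TRUE) {
  head <- readBin(path, "raw", 80)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.size(path)
  if (!is.na(ntri) && fsize == 84 + 50 * ntri && ntri > 0) {
    raw <- readBin(con, "raw", 50 * ntri)
    m <- matrix(raw, nrow = 50)
    vert <- matrix(0, 3 * ntri, 3)
    for (t in seq_len(ntri)) {
      vals <- readBin(m[1:48, t], "numeric", 12, size = 4, endian = "little")
      vert[3 * t - 2:0, ] <- matrix(vals[4:12], 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl)) rm_stop("not a recognisable STL file", "respmech_input")
    vert <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  }
  key <- apply(vert, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- vert[uniq, , drop = FALSE]
  faces <- matrix(match(key, key[uniq]), ncol = 3, byrow = TRUE)
  tri_surface(verts, faces, check = check)
}

#' @rdname read_stl
#' @export
write_stl <- function(surface, path, ascii = FALSE) {
  v <- surface$vertices; f <- surface$faces
  n1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
               n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
               n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid respmech", con)
    for (t in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[t, 1], nrm[t, 2], nrm[t, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[t, k], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid respmech", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[t, ], t(v[f[t, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

# ---- VTU ----

#' Export a mesh (and optional nodal fields) as VTK unstructured grid
#'
#' Writes an ASCII .vtu file readable by ParaView; nodal vector fields
#' (e.g. displacements) are attached as PointData.
#'
#' @param mesh a \code{tet_mesh}.
#' @param path output path (.vtu).
#' @param point_data named list of per-node scalars (length n) or vectors
#'   (n x 3 matrices).
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(apply(mesh$nodes, 1, paste, collapse = " "),
                   collapse = "\n"), con)
  w('        </DataArray>')
  w('      </Points>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      nc <- if (is.matrix(d)) ncol(d) else 1L
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, nc)
      dd <- if (is.matrix(d)) apply(d, 1, paste, collapse = " ") else as.character(d)
      writeLines(paste(dd, collapse = "\n"), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(apply(mesh$tets - 1L, 1, paste, collapse = " "),
                   collapse = "\n"), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 4L, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(10L, m), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
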