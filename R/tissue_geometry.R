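#' @section Tissue representation:
#' A `vm_tissue` is a list with the merged polyhedral complex (vertex matrix,
#' face cycles with periodic image shifts, face-to-cell incidence) plus a
#' `cells` data frame carrying the persistent cell identities, types and
#' mechanical targets.  Lengths are nondimensionalized so that the default
#' target cell volume is 1.
#' @name vm_tissue
NULL

# assemble the list handed to the C++ core
.tess_arg <- function(tissue) {
  list(face_vertices = tissue$face_vertices,
       face_shifts = tissue$face_shifts,
       face_cells = tissue$face_cells,
       cell_faces = tissue$cell_faces,
       cell_ref = tissue$cell_ref,
       cell_type = .type_code(tissue$cells$type),
       box = tissue$box)
}

.wrap_xy <- function(p, box) {
  p[, 1] <- p[, 1] - box[1] * floor(p[, 1] / box[1])
  p[, 2] <- p[, 2] - box[2] * floor(p[, 2] / box[2])
  if (box[5] != 0) {
    Lz <- box[4] - box[3]
    p[, 3] <- box[3] + (p[, 3] - box[3]) - Lz * floor((p[, 3] - box[3]) / Lz)
  }
  p
}

# rebuild a vm_tissue from seeds + an existing cells data frame.
# Coincident seeds (e.g. a ghost cell squeezed onto a neighbour) are
# perturbed deterministically and retried.
.tessellate <- function(seeds, box, cells) {
  seeds <- .wrap_xy(seeds, box)
  if (box[5] == 0) {
    eps <- 1e-3
    seeds[, 3] <- pmin(pmax(seeds[, 3], box[3] + eps), box[4] - eps)
  }
  vor <- NULL
  for (try in 0:3) {
    vor <- tryCatch(
      .vm_voronoi(seeds, box[1], box[2], box[3], box[4], box[5] != 0, -1),
      error = function(e) e)
    if (!inherits(vor, "error")) break
    if (!grepl("duplicate seeds", conditionMessage(vor)) || try == 3)
      stop(vor)
    n <- nrow(seeds)
    seeds <- seeds + 1e-5 * (try + 1) *
      cbind(sin(seq_len(n) * 1.7), cos(seq_len(n) * 2.3),
            sin(seq_len(n) * 3.1))
    seeds <- .wrap_xy(seeds, box)
  }
  tissue <- list(
    vertices = vor$vertices,
    face_vertices = vor$face_vertices,
    face_shifts = vor$face_shifts,
    face_cells = vor$face_cells,
    cell_faces = vor$cell_faces,
    cell_ref = seeds,
    box = box,
    cells = cells,
    time = 0)
  tissue$pinned <- .pin_mask(tissue)
  class(tissue) <- "vm_tissue"
  tissue
}

.pin_mask <- function(tissue) {
  if (tissue$box[5] != 0) return(rep(FALSE, nrow(tissue$vertices)))
  z <- tissue$vertices[, 3]
  tol <- 1e-7 * max(tissue$box[1], tissue$box[2])
  (abs(z - tissue$box[3]) < tol) | (abs(z - tissue$box[4]) < tol)
}

.lattice_dims <- function(n, aspect) {
  divs <- seq_len(n)[n %% seq_len(n) == 0]
  best <- NULL
  best_err <- Inf
  for (nx in divs) {
    ny <- n / nx
    err <- abs(log((nx / ny) / aspect))
    if (err < best_err) {
      best_err <- err
      best <- c(nx, ny)
    }
  }
  if (max(best) / min(best) > 4 * max(aspect, 1 / aspect))
    stop("n_basal = ", n, " has no reasonable lattice factorization")
  best
}

#' Build a layered periodic tissue
#'
#' Constructs the initial stratified tissue: one basement layer (bottom
#' vertices pinned), one basal monolayer of `n_basal` cells, `n_suprabasal_layers`
#' suprabasal layers, and one layer of ghost cells capping the slab.  Cell
#' seeds sit on a jittered square lattice with unit spacing; the tissue is
#' periodic in x and y and bounded in z.
#'
#' @param n_basal number of basal cells (>= 4, must factor into a lattice).
#' @param n_suprabasal_layers number of suprabasal layers (>= 1).
#' @param box_aspect target Lx/Ly aspect ratio of the periodic box.
#' @param jitter lateral seed jitter amplitude (lattice units).
#' @param seed optional RNG seed.
#' @param ghost_height height of the ghost-cell head space.
#' @return a `vm_tissue`.
#' @export
build_initial_tissue <- function(n_basal, n_suprabasal_layers = 2,
                                 box_aspect = 1, jitter = 0.25, seed = NULL,
                                 ghost_height = 1.5) {
  if (n_basal < 4) stop("n_basal must be at least 4")
  if (n_suprabasal_layers < 1) stop("need at least one suprabasal layer")
  if (!is.null(seed)) set.seed(seed)
  dims <- .lattice_dims(n_basal, box_aspect)
  nx <- dims[1]; ny <- dims[2]
  Lx <- nx; Ly <- ny
  zmax <- 2 + n_suprabasal_layers + ghost_height
  box <- c(Lx, Ly, 0, zmax, 0)

  layer_z <- c(basement = 0.5, basal = 1.5,
               setNames(2.5 + seq_len(n_suprabasal_layers) - 1,
                        rep("suprabasal", n_suprabasal_layers)),
               ghost = 2 + n_suprabasal_layers + ghost_height / 2)
  grid <- expand.grid(x = seq_len(nx) - 0.5, y = seq_len(ny) - 0.5)

  seeds <- NULL
  types <- character(0)
  for (k in seq_along(layer_z)) {
    n <- nrow(grid)
    jx <- if (jitter > 0) runif(n, -jitter, jitter) else 0
    jy <- if (jitter > 0) runif(n, -jitter, jitter) else 0
    jz <- if (jitter > 0) runif(n, -0.05, 0.05) else 0
    seeds <- rbind(seeds, cbind(grid$x + jx, grid$y + jy, layer_z[k] + jz))
    types <- c(types, rep(names(layer_z)[k], n))
  }
  cells <- data.frame(id = seq_along(types), type = types,
                      s0 = NA_real_, V0 = 1, S0 = NA_real_, alpha = 0,
                      stringsAsFactors = FALSE)
  tries <- 0
  repeat {
    tissue <- tryCatch(.tessellate(seeds, box, cells), error = function(e) e)
    if (!inherits(tissue, "error")) break
    tries <- tries + 1
    if (tries > 5) stop("degenerate tessellation after retries: ",
                        conditionMessage(tissue))
    idx <- seq_len(nrow(seeds))
    seeds[, 1:2] <- seeds[, 1:2] + matrix(runif(2 * length(idx), -1e-3, 1e-3),
                                          ncol = 2)
  }
  tissue
}

#' Build a fully periodic bulk tissue (droplet rheometer geometry)
#'
#' @param nx,ny,nz lattice dimensions (cells per direction).
#' @param jitter seed jitter amplitude.
#' @param seed optional RNG seed.
#' @return a `vm_tissue` of uniform `suprabasal`-typed cells, periodic in all
#'   three directions, with no pinned vertices.
#' @export
build_bulk_tissue <- function(nx, ny, nz, jitter = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  box <- c(nx, ny, 0, nz, 1)
  grid <- expand.grid(x = seq_len(nx) - 0.5, y = seq_len(ny) - 0.5,
                      z = seq_len(nz) - 0.5)
  n <- nrow(grid)
  j <- function() if (jitter > 0) runif(n, -jitter, jitter) else 0
  seeds <- cbind(grid$x + j(), grid$y + j(), grid$z + j())
  cells <- data.frame(id = seq_len(n), type = "suprabasal",
                      s0 = NA_real_, V0 = 1, S0 = NA_real_, alpha = 0,
                      stringsAsFactors = FALSE)
  .tessellate(seeds, box, cells)
}

#' Recompute the tissue topology from the periodic Voronoi diagram
#'
#' Seeds are refreshed to the current cell centroids (unless
#' `refresh_seeds = FALSE`), the full periodic Voronoi diagram is recomputed
#' and the tissue topology rebuilt.  Cell identities, types and mechanical
#' targets are preserved.
#'
#' @param tissue a `vm_tissue`.
#' @param refresh_seeds refresh seeds to current centroids first.
#' @return a `vm_tissue` with fresh topology.
#' @export
retessellate <- function(tissue, refresh_seeds = TRUE) {
  seeds <- tissue$cell_ref
  if (refresh_seeds) {
    geo <- tissue_metrics(tissue)
    seeds <- geo$centroid
  }
  out <- .tessellate(seeds, tissue$box, tissue$cells)
  out$time <- tissue$time
  out
}

#' Per-cell geometry of the whole tissue
#'
#' @param tissue a `vm_tissue`.
#' @return list with per-cell `volume`, `area` and `centroid` (n x 3).
#' @export
tissue_metrics <- function(tissue) {
  n <- nrow(tissue$cells)
  out <- .vm_eval(tissue$vertices, .tess_arg(tissue), rep(0, n), rep(0, n),
                  0, 0, matrix(0, 5, 5), FALSE)
  list(volume = out$volume, area = out$area, centroid = out$centroid)
}

#' Geometry of a single cell
#'
#' Volume from signed tetrahedra fanned from each face centroid, surface area
#' as the sum of triangulated face areas.
#'
#' @param tissue a `vm_tissue`.
#' @param cell_id persistent cell id.
#' @return list with `volume`, `surface_area`, `centroid`.
#' @export
cell_geometry <- function(tissue, cell_id) {
  row <- match(cell_id, tissue$cells$id)
  if (is.na(row)) stop("no cell with id ", cell_id)
  if (tissue$cells$type[row] == "ghost")
    stop("cell_geometry is undefined for ghost cells")
  geo <- tissue_metrics(tissue)
  list(volume = geo$volume[row], surface_area = geo$area[row],
       centroid = geo$centroid[row, ])
}

#' Slab volume of the simulation box
#' @param tissue a `vm_tissue`.
#' @return box volume Lx * Ly * (z_max - z_min).
#' @export
slab_volume <- function(tissue) {
  b <- tissue$box
  b[1] * b[2] * (b[4] - b[3])
}

#' Ellipsoidal fit of a cell via the vertex gyration tensor
#'
#' Eigen-decomposition of the (unweighted) gyration tensor of the cell's
#' vertices about their mean.  `theta_long` is the angle between the longest
#' principal axis and the basal (x-y) plane, folded into \[0, pi/2\].
#'
#' @param tissue a `vm_tissue`.
#' @param cell_id persistent cell id.
#' @param degeneracy_tol relative gap below which the two leading axes are
#'   considered degenerate and `theta_long` ill-defined.
#' @return list with `semi_axes` (descending), `principal_axes` (columns),
#'   `theta_long`, `phi_long` (azimuth of the long axis) and `degenerate`.
#' @export
fit_ellipsoid <- function(tissue, cell_id, degeneracy_tol = 1e-6) {
  row <- match(cell_id, tissue$cells$id)
  if (is.na(row)) stop("no cell with id ", cell_id)
  pts <- .vm_cell_vertices(tissue$vertices, .tess_arg(tissue), row)
  if (nrow(pts) < 4) stop("cell has fewer than 4 vertices")
  .gyration_axes(pts, degeneracy_tol)
}

# eigen-decomposition of the gyration tensor of a point cloud
.gyration_axes <- function(pts, degeneracy_tol = 1e-6) {
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  G <- crossprod(d) / nrow(d)
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  degenerate <- (ev[1] - ev[2]) <= degeneracy_tol * max(ev[1], .Machine$double.eps)
  n1 <- eg$vectors[, 1]
  if (n1[3] < 0) n1 <- -n1  # fold the sign-ambiguous axis to the upper hemisphere
  theta <- asin(min(1, abs(n1[3])))
  phi <- atan2(n1[2], n1[1]) %% (2 * pi)
  list(semi_axes = sqrt(5 * ev), principal_axes = eg$vectors,
       theta_long = if (degenerate) NA_real_ else theta,
       phi_long = if (degenerate) NA_real_ else phi,
       degenerate = degenerate)
}

#' Dimensionless shape indices of a cell
#'
#' `s3d = S * V^(-2/3)` of the polyhedron; `s2d = P * A^(-1/2)` of the cell's
#' cross-section polygon in the plane parallel to the basement membrane
#' through the cell centroid (defined for basal cells; `NA` when the section
#' is empty).
#'
#' @param tissue a `vm_tissue`.
#' @param cell_id persistent cell id.
#' @return named numeric vector `c(s3d = , s2d = )`.
#' @export
shape_indices <- function(tissue, cell_id) {
  row <- match(cell_id, tissue$cells$id)
  if (is.na(row)) stop("no cell with id ", cell_id)
  if (tissue$cells$type[row] == "ghost")
    stop("shape indices are undefined for ghost cells")
  geo <- tissue_metrics(tissue)
  s3d <- geo$area[row] * geo$volume[row]^(-2 / 3)
  cs <- .vm_cross_section(tissue$vertices, .tess_arg(tissue), row,
                          geo$centroid[row, 3])
  s2d <- if (is.na(cs[1]) || cs[1] <= 0) NA_real_ else cs[2] / sqrt(cs[1])
  c(s3d = s3d, s2d = s2d)
}

#' Face centroids (in the owning cell's frame)
#' @param tissue a `vm_tissue`.
#' @param face_ids face indices (default all).
#' @return matrix of face centroid coordinates.
#' @export
face_centroids <- function(tissue, face_ids = seq_along(tissue$face_vertices)) {
  V <- tissue$vertices
  b <- tissue$box
  L <- c(b[1], b[2], b[4] - b[3])
  t(vapply(face_ids, function(f) {
    ids <- tissue$face_vertices[[f]]
    sh <- tissue$face_shifts[[f]]
    colMeans(V[ids, , drop = FALSE] + sh %*% diag(L))
  }, numeric(3)))
}

#' Cell adjacency from shared faces
#' @param tissue a `vm_tissue`.
#' @return two-column matrix of adjacent cell row pairs (internal faces only).
#' @export
cell_adjacency <- function(tissue) {
  fc <- tissue$face_cells
  fc[fc[, 1] > 0 & fc[, 2] > 0, , drop = FALSE]
}

#' @export
print.vm_tissue <- function(x, ...) {
  tab <- table(x$cells$type)
  cat("<vm_tissue> ", nrow(x$cells), " cells, ", nrow(x$vertices),
      " vertices, ", length(x$face_vertices), " faces\n", sep = "")
  cat("  box: ", sprintf("%.3g x %.3g, z in [%.3g, %.3g]%s", x$box[1], x$box[2],
                         x$box[3], x$box[4],
                         if (x$box[5] != 0) " (periodic)" else ""), "\n", sep = "")
  cat("  cells:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  time:", x$time, "tau\n")
  invisible(x)
}
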