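# Small fixtures shared across test files, built once per session.
.fx <- new.env()

# jitter-free 3x3 basal lattice: every cell is an exact rectangular prism
fx_prism <- function() {
  if (is.null(.fx$prism)) .fx$prism <- build_initial_tissue(9, 1, jitter = 0)
  .fx$prism
}

# jittered layered tissue with E14 targets applied
fx_layered <- function() {
  if (is.null(.fx$layered)) {
    p <- default_params(stage = "E14")
    tis <- build_initial_tissue(16, 2, jitter = 0.25, seed = 3)
    tis <- set_cell_targets(tis, p)
    .fx$layered <- list(tissue = tis, params = p)
  }
  .fx$layered
}

# relaxed version of the layered fixture
fx_layered_relaxed <- function() {
  if (is.null(.fx$layered_rel)) {
    fx <- fx_layered()
    tis <- suppressWarnings(minimize_tissue(fx$tissue, fx$params, maxit = 400))
    .fx$layered_rel <- list(tissue = tis, params = fx$params)
  }
  .fx$layered_rel
}

# fully periodic jitter-free bulk: unit cubes
fx_bulk_cubes <- function() {
  if (is.null(.fx$cubes)) .fx$cubes <- build_bulk_tissue(3, 3, 3, jitter = 0)
  .fx$cubes
}

# jittered bulk tissue, single type
fx_bulk <- function() {
  if (is.null(.fx$bulk)) .fx$bulk <- build_bulk_tissue(3, 3, 2, jitter = 0.3,
                                                       seed = 4)
  .fx$bulk
}

# audit helpers -------------------------------------------------------------

# every internal face is used by exactly its two incident cells
expect_face_pairing <- function(tissue) {
  cnt <- integer(length(tissue$face_vertices))
  for (r in seq_len(nrow(tissue$cells)))
    for (f in tissue$cell_faces[[r]]) cnt[f] <- cnt[f] + 1L
  internal <- tissue$face_cells[, 1] > 0 & tissue$face_cells[, 2] > 0
  expect_true(all(cnt[internal] == 2L))
  expect_true(all(cnt[!internal] == 1L))
}

# per-cell closure: V - E + F = 2 for every cell's boundary complex
expect_cells_closed <- function(tissue) {
  chi <- vapply(seq_len(nrow(tissue$cells)), function(r) {
    fids <- tissue$cell_faces[[r]]
    nv <- length(unique(unlist(tissue$face_vertices[fids])))
    ne <- sum(lengths(tissue$face_vertices[fids])) / 2
    nv - ne + length(fids)
  }, numeric(1))
  expect_true(all(chi == 2))
}

expect_confluent <- function(tissue, tol = 1e-6) {
  vol <- sum(tissue_metrics(tissue)$volume)
  expect_lt(abs(vol - slab_volume(tissue)) / slab_volume(tissue), tol)
}

# deterministic point cloud on an ellipsoid with given semi-axes, optionally
# rotated by `rot` (3x3)
ellipsoid_cloud <- function(axes, n = 800, rot = diag(3)) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)        # Fibonacci sphere
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  pts <- sweep(pts, 2, axes, `*`)
  pts %*% t(rot)
}

rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                              -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
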