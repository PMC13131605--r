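test_that("droplet embedding re-types a contiguous central blob", {
  tis <- build_bulk_tissue(6, 6, 5, jitter = 0.3, seed = 2)
  emb <- embed_droplet(tis, droplet_config(n_droplet_cells = 17), default_params())
  drop <- which(emb$tissue$cells$type == "droplet")
  expect_length(drop, 17)
  # contiguity: breadth-first search over shared faces spans the blob
  adj <- cell_adjacency(emb$tissue)
  adj <- adj[adj[, 1] %in% drop & adj[, 2] %in% drop, , drop = FALSE]
  reach <- drop[1]
  repeat {
    nxt <- unique(c(adj[adj[, 1] %in% reach, 2], adj[adj[, 2] %in% reach, 1]))
    nxt <- union(reach, nxt)
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(reach, drop)
  # droplet-tissue tension is applied symmetrically
  expect_equal(emb$params$sigma["droplet", "suprabasal"], 0.8,
               ignore_attr = TRUE)
  expect_error(embed_droplet(build_bulk_tissue(3, 3, 2, jitter = 0.2),
                             droplet_config(17), default_params()),
               "too small")
})

test_that("the dipole is a zero-net-force stretching pair", {
  tis <- build_bulk_tissue(6, 6, 5, jitter = 0.3, seed = 2)
  emb <- embed_droplet(tis, droplet_config(n_droplet_cells = 17, f = 0.5),
                       default_params())
  F <- apply_dipole(emb$tissue, emb$config <- droplet_config(17, f = 0.5))
  expect_equal(sum(F[, 1]), 0, tolerance = 1e-10)
  expect_true(all(F[, 2:3] == 0))
  mask <- epivertex:::.droplet_vertex_mask(emb$tissue)
  x <- emb$tissue$vertices[mask, 1]
  expect_equal(F[mask, 1], 0.5 * (x - mean(x)))
  expect_true(all(F[!mask, ] == 0))
  F0 <- apply_dipole(emb$tissue, droplet_config(17, f = 0))
  expect_true(all(F0 == 0))
})

test_that("strain measures elongation along the force axis", {
  sphere <- ellipsoid_cloud(c(1, 1, 1))
  expect_equal(epivertex:::.strain_of_points(sphere), 0, tolerance = 1e-4)
  stretched <- ellipsoid_cloud(c(1.2, 1, 1))
  expect_equal(epivertex:::.strain_of_points(stretched), 0.2, tolerance = 1e-4)
  squashed <- ellipsoid_cloud(c(0.8, 1, 1))
  expect_lt(epivertex:::.strain_of_points(squashed), 0)
})

test_that("two-timescale relaxation fits recover synthetic parameters", {
  tr <- generate_fixture("synthetic_strain_trace",
                         params = list(A1 = 0.05, tau1 = 10, A2 = 0.05,
                                       tau2 = 68, noise = 0.01, t_max = 400),
                         seed = 6)
  fit <- fit_relaxation(tr)
  expect_true(fit$converged)
  expect_equal(fit$tau1, 10, tolerance = 0.05)
  expect_equal(fit$tau2, 68, tolerance = 0.05)
  expect_equal(fit$A1 + fit$A2, tr$strain[1], tolerance = 0.03)

  # single-exponential input: both timescales collapse or one amplitude dies
  t <- seq(0, 200, by = 0.5)
  single <- data.frame(time = t, strain = 0.1 * exp(-t / 20), phase = "off")
  fs <- fit_relaxation(single)
  expect_true(abs(fs$tau1 - fs$tau2) / fs$tau2 < 0.2 ||
              min(abs(c(fs$A1, fs$A2))) < 0.005)
  # noiseless two-exponential: strain at t = 0 equals A1 + A2
  noiseless <- generate_fixture("synthetic_strain_trace",
                                params = list(noise = 0), seed = 1)
  fn <- fit_relaxation(noiseless)
  expect_equal(fn$A1 + fn$A2, noiseless$strain[1], tolerance = 1e-6)
})

test_that("a short actuation stretches the droplet along x", {
  set.seed(13)
  p <- default_params(D_t = 0)
  p$s0["suprabasal"] <- 5.8
  cfg <- droplet_config(n_droplet_cells = 9, f = 0.02, sigma_drop = 0.8,
                        t_on = 8, t_off = 2, n_cycles = 1)
  tr <- suppressWarnings(run_droplet_experiment(
    cfg, p, tissue = build_bulk_tissue(5, 5, 4, jitter = 0.3, seed = 13),
    seed = 13, relax_maxit = 600, retess_maxit = 80))
  expect_lt(abs(tr$strain[1]), 0.1)           # near-spherical after relaxation
  expect_gt(max(tr$strain[tr$phase == "on"]), 0.05)
})
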