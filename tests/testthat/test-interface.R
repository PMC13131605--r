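test_that("identical configuration and seed replay bit-identically", {
  run_once <- function() {
    set.seed(17)
    p <- default_params(stage = "E14", D_t = 0)
    tis <- build_initial_tissue(9, 1, jitter = 0.25, seed = 17)
    tis <- set_cell_targets(tis, p)
    tis <- suppressWarnings(minimize_tissue(tis, p, maxit = 200))
    suppressWarnings(simulate_epidermis(
      tis, p, t_end = 15, spec = division_spec(pi / 4, t_div = 5),
      protocol = "homeostatic", alpha = 0.1))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(division_table(a$log), division_table(b$log))
  expect_identical(event_table(a$log), event_table(b$log))
  expect_identical(a$tissue$vertices, b$tissue$vertices)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("volume-threshold division mode divides at the target volume", {
  set.seed(23)
  p <- default_params(stage = "E14", D_t = 0)
  tis <- build_initial_tissue(9, 1, jitter = 0.25, seed = 23)
  tis <- set_cell_targets(tis, p)
  tis <- suppressWarnings(minimize_tissue(tis, p, maxit = 200))
  res <- suppressWarnings(simulate_epidermis(
    tis, p, t_end = 14, spec = division_spec(0, t_div = 100),
    protocol = "homeostatic", alpha = 0.25,
    division_mode = "volume", division_volume_threshold = 2))
  # alpha = 0.25: the growing cell reaches V0 = 2 after ~4 tau, well before
  # the 100-tau timer would fire
  expect_gte(res$log$N_div, 2L)
  dv <- division_table(res$log)
  rows <- match(c(dv$d1[1], dv$d2[1]), res$trajectories$cell)
  expect_true(all(is.finite(rows)))
  ev <- event_table(res$log)
  if (nrow(ev) > 0)
    expect_true(all(ev$context[ev$kind == "homotypic"] %in%
                      c("daughter", "neighbor")))
})

test_that("a zero-length run returns only the initial snapshot", {
  fx <- fx_layered_relaxed()
  res <- simulate_epidermis(fx$tissue, fx$params, t_end = 0)
  expect_equal(unique(res$trajectories$time), fx$tissue$time)
  expect_equal(res$log$N_div, 0L)
  expect_equal(nrow(res$trajectories), nrow(fx$tissue$cells))
})

test_that("fixtures are deterministic given a seed", {
  a <- generate_fixture("synthetic_strain_trace", seed = 3)
  b <- generate_fixture("synthetic_strain_trace", seed = 3)
  expect_identical(a, b)
  c1 <- generate_fixture("synthetic_separation_trace",
                         params = list(n_pairs = 5, t_max = 10), seed = 4)
  c2 <- generate_fixture("synthetic_separation_trace",
                         params = list(n_pairs = 5, t_max = 10), seed = 4)
  expect_identical(c1, c2)
  tiny <- generate_fixture("tiny_tissue", seed = 5)
  expect_confluent(tiny, 1e-6)
  expect_face_pairing(tiny)
  expect_error(generate_fixture("nope"), "arg")
})

test_that("snapshots round-trip cell volumes through the mesh format", {
  fx <- fx_layered()
  tis <- fx$tissue
  path <- file.path(withr::local_tempdir(), "snap")
  snapshot_writer(tis, path)
  snap <- read_snapshot(path)
  expect_equal(snap$cells$ghost, tis$cells$type == "ghost")
  vols <- mesh_cell_volumes(snap)
  expect_equal(vols, tissue_metrics(tis)$volume, tolerance = 1e-6)
})

test_that("run_experiment drives a growth-orientation run end to end", {
  out_dir <- withr::local_tempdir()
  res <- suppressWarnings(run_experiment(list(
    experiment = "growth_orientation", stage = "E14", seed = 2,
    n_basal = 9, n_suprabasal_layers = 1, t_end = 40, t_div = 10,
    alpha = 0.12, out_dir = out_dir)))
  expect_gte(nrow(res$long_axis), 2)
  expect_s3_class(res$distribution, "angle_distribution")
  expect_true(file.exists(file.path(out_dir, "trajectories.csv")))
  expect_true(file.exists(file.path(out_dir, "long_axis.csv")))
  expect_true(file.exists(file.path(out_dir, "config.csv")))
})
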