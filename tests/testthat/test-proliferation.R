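test_that("division-rate conversions reproduce the printed values", {
  rc <- rate_conversions(150, 50)
  expect_equal(rc$lambda_sim, 1 / (150 * 50))
  expect_equal(rc$lambda_per_day, 1.92)
  expect_equal(rc$tau_per_day, 14400)
  expect_equal(rate_conversions(144, 100)$lambda_per_day, 1.0)
  expect_error(rate_conversions(0, 50), "positive")
  expect_equal(tdiv_for_rate(150, 1.92), 50)
})

test_that("speed conversions link the physical and simulation units", {
  sc <- speed_conversions(0.55, cell_size_um = 10, tau_minutes = 0.1)
  expect_equal(sc$l_per_min, 0.055)
  expect_equal(sc$l_per_tau, 0.0055)
})

test_that("the division schedule fires once per interval", {
  expect_equal(division_times(500, 50), seq(50, 500, by = 50))
  expect_length(division_times(10 * 37, 37), 10)
  expect_true(all(diff(division_times(1000, 25)) == 25))
})

test_that("division conserves the target volume and splits along the axis", {
  fx <- fx_layered_relaxed()
  tis <- fx$tissue
  p <- fx$params
  basal_id <- tis$cells$id[which(tis$cells$type == "basal")[3]]
  V0p <- tis$cells$V0[match(basal_id, tis$cells$id)]

  dv <- divide_cell(tis, basal_id, division_spec(pi / 2, t_div = 10), p,
                    relax_maxit = 50)
  out <- dv$tissue
  ev <- dv$event
  expect_equal(nrow(out$cells), nrow(tis$cells) + 1)
  rows <- match(c(ev$d1, ev$d2), out$cells$id)
  expect_equal(sum(out$cells$V0[rows]), V0p)            # exact conservation
  expect_equal(out$cells$V0[rows[1]], out$cells$V0[rows[2]])
  expect_true(all(out$cells$type[rows] == "basal"))     # inherit basal identity
  # perpendicular division: seed displacement purely vertical
  expect_equal(ev$pos1[1:2], ev$pos2[1:2], tolerance = 1e-12)
  expect_gt(abs(ev$pos2[3] - ev$pos1[3]), 0)
  expect_confluent(out, 1e-6)
  expect_face_pairing(out)
})

test_that("an in-plane division on the symmetric lattice separates along x", {
  tis <- fx_prism()
  p <- default_params(stage = "E14")
  tis <- set_cell_targets(tis, p)
  basal_id <- tis$cells$id[which(tis$cells$type == "basal")[5]]
  dv <- divide_cell(tis, basal_id, division_spec(0, phi = 0, t_div = 10), p,
                    relax_maxit = 0)
  geo <- tissue_metrics(dv$tissue)
  rows <- match(c(dv$event$d1, dv$event$d2), dv$tissue$cells$id)
  sep <- geo$centroid[rows[2], ] - geo$centroid[rows[1], ]
  # mirror symmetry of the lattice: daughters differ only in x
  expect_gt(abs(sep[1]), 0.1)
  expect_lt(abs(sep[2]), 1e-6)
  expect_lt(abs(sep[3]), 1e-6)
})

test_that("exactly one growing basal cell is maintained, chosen uniformly", {
  fx <- fx_layered()
  tis <- ensure_growing_cell(fx$tissue, alpha = 0.01)
  expect_equal(sum(tis$cells$alpha > 0), 1)
  gid <- attr(tis, "growing_cell")
  # persists while still basal
  tis2 <- ensure_growing_cell(tis, alpha = 0.01)
  expect_equal(attr(tis2, "growing_cell"), gid)

  # forced reassignment is uniform over basal cells
  basal_ids <- tis$cells$id[tis$cells$type == "basal"]
  set.seed(42)
  picks <- replicate(3000, {
    t0 <- tis
    t0$cells$alpha <- 0
    attr(ensure_growing_cell(t0, 0.01), "growing_cell")
  })
  tab <- table(factor(picks, levels = basal_ids))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("growth advances the target volume linearly", {
  fx <- fx_layered()
  tis <- ensure_growing_cell(fx$tissue, alpha = 1)
  g <- which(tis$cells$alpha > 0)
  V0 <- tis$cells$V0[g]
  tis <- grow_step(tis, 0.01)
  expect_equal(tis$cells$V0[g] - V0, 0.01)
  expect_equal(tis$cells$S0[g], tis$cells$s0[g] * tis$cells$V0[g]^(2 / 3))
  for (k in 1:10) tis <- grow_step(tis, 0.05)
  expect_equal(tis$cells$V0[g] - V0, 0.01 + 10 * 0.05, tolerance = 1e-12)
  # alpha = 0 cells are untouched
  expect_true(all(tis$cells$V0[-g] == fx$tissue$cells$V0[-g]))
})
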