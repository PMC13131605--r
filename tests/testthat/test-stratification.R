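test_that("the basal-suprabasal interface sits between the two layers", {
  tis <- fx_prism()
  # jitter-free lattice: all shared faces lie exactly at z = 2
  expect_equal(compute_bs_interface(tis), 2, tolerance = 1e-9)

  fx <- fx_layered()
  iface <- compute_bs_interface(fx$tissue)
  geo <- tissue_metrics(fx$tissue)
  zb <- mean(geo$centroid[fx$tissue$cells$type == "basal", 3])
  zs <- mean(geo$centroid[fx$tissue$cells$type == "suprabasal", 3])
  expect_gt(iface, zb)
  expect_lt(iface, zs)
})

test_that("homotypic detection needs both detachment and height", {
  fx <- fx_layered()
  tis <- fx$tissue
  # pristine layered tissue: nobody stratifies
  expect_length(detect_homotypic(tis), 0)
  # basal cells sit above an artificially low interface but still touch the
  # basement: not stratified
  expect_length(detect_homotypic(tis, interface = 1.0), 0)
  # a suprabasal cell relabelled basal is detached and above: detected
  sup <- which(tis$cells$type == "suprabasal")
  geo <- tissue_metrics(tis)
  hi <- sup[which.max(geo$centroid[sup, 3])]
  tis$cells$type[hi] <- "basal"
  expect_true(tis$cells$id[hi] %in% detect_homotypic(tis))
})

test_that("identity switches update the mechanical targets one way", {
  fx <- fx_layered()
  tis <- fx$tissue
  p <- fx$params
  id <- tis$cells$id[which(tis$cells$type == "basal")[1]]
  out <- switch_to_suprabasal(tis, id, p)
  row <- match(id, out$cells$id)
  expect_equal(out$cells$type[row], "suprabasal")
  expect_equal(out$cells$s0[row], unname(p$s0["suprabasal"]))
  expect_equal(out$cells$S0[row],
               unname(p$s0["suprabasal"]) * out$cells$V0[row]^(2 / 3))
  expect_error(switch_to_suprabasal(out, id, p), "only basal")
})

test_that("ghost conversion removes the top-most suprabasal cell", {
  fx <- fx_layered()
  tis <- fx$tissue
  geo <- tissue_metrics(tis)
  sup <- which(tis$cells$type == "suprabasal")
  top <- sup[which.max(geo$centroid[sup, 3])]
  n_ghost <- sum(tis$cells$type == "ghost")
  out <- ghost_convert_top(tis)
  expect_equal(out$cells$type[top], "ghost")
  expect_equal(sum(out$cells$type == "ghost"), n_ghost + 1)
  expect_equal(sum(out$cells$type == "suprabasal"), length(sup) - 1)

  none <- tis
  none$cells$type[none$cells$type == "suprabasal"] <- "ghost"
  expect_error(ghost_convert_top(none), "no suprabasal")
})

test_that("the homeostatic check fires only above the +2 threshold", {
  fx <- fx_layered()
  tis <- fx$tissue
  p <- fx$params
  n_basal <- sum(tis$cells$type == "basal")

  log2 <- new_event_log("homeostatic", t_pop = 10, n_basal0 = n_basal - 2)
  out <- homeostatic_check(tis, log2, p)       # expansion == +2: no conversion
  expect_null(out$converted)
  expect_equal(log2$N_fate, 0L)

  log3 <- new_event_log("homeostatic", t_pop = 10, n_basal0 = n_basal - 3)
  set.seed(1)
  out <- homeostatic_check(tis, log3, p)       # +3: exactly one conversion
  expect_false(is.null(out$converted))
  expect_equal(log3$N_fate, 1L)
  expect_equal(sum(out$tissue$cells$type == "basal"), n_basal - 1)

  logd <- new_event_log("densifying", t_pop = 10, n_basal0 = n_basal - 5)
  out <- homeostatic_check(tis, logd, p)       # densifying: never fires
  expect_null(out$converted)
  expect_equal(logd$N_fate, 0L)
})

test_that("stratification yields normalise the event counts", {
  log <- new_event_log("homeostatic", t_pop = 10, n_basal0 = 10)
  log$N_homo <- 7L; log$N_fate <- 3L; log$N_div <- 10L
  expect_equal(stratification_yield(log), c(homo = 0.7, fate = 0.3))
  log$N_div <- 0L
  expect_true(all(is.na(stratification_yield(log))))
})

test_that("a division run only ever moves identities forward", {
  set.seed(21)
  p <- default_params(stage = "E14")
  tis <- build_initial_tissue(9, 2, jitter = 0.25, seed = 21)
  tis <- set_cell_targets(tis, p)
  tis <- suppressWarnings(minimize_tissue(tis, p, maxit = 300))
  res <- suppressWarnings(simulate_epidermis(
    tis, p, t_end = 25, spec = division_spec(pi / 2, t_div = 5),
    protocol = "homeostatic", alpha = 0.15))
  expect_equal(res$log$N_div, 5L)
  expect_equal(length(res$log$divisions), res$log$N_div)

  rank <- c(basement = 0, basal = 1, suprabasal = 2, ghost = 3)
  tr <- res$trajectories
  for (id in unique(tr$cell)) {
    seq_types <- rank[tr$type[tr$cell == id]]
    expect_true(all(diff(seq_types) >= 0))
    if (seq_types[1] == 0) expect_true(all(seq_types == 0))
  }
  # every stratification event paired with one ghost conversion
  n_ghost0 <- 9
  expect_equal(sum(res$tissue$cells$type == "ghost") - n_ghost0,
               res$log$N_homo + res$log$N_fate)
})
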