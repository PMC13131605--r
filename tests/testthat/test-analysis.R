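test_that("division-angle weights pass printed fractions through unchanged", {
  w14 <- division_angle_weights(stage_division_fractions("E14"))
  expect_equal(unclass(w14),
               c(planar = 0.20, oblique = 0.25, perpendicular = 0.55))
  w16 <- division_angle_weights(stage_division_fractions("E16"))
  expect_equal(unclass(w16),
               c(planar = 0.60, oblique = 0.25, perpendicular = 0.15))
  expect_equal(sum(w14), 1)
  expect_equal(sum(w16), 1)
  expect_equal(unclass(division_angle_weights(c(2, 3, 5))), c(0.2, 0.3, 0.5))
  expect_error(division_angle_weights(c(0, 0, 0)), "zero")
  expect_error(division_angle_weights(c(-1, 2, 1)), "nonnegative")
})

test_that("angle bins are half-open exactly as printed", {
  expect_equal(classify_division_angle(0), "planar")
  expect_equal(classify_division_angle(pi / 6), "planar")
  expect_equal(classify_division_angle(pi / 6 + 1e-9), "oblique")
  expect_equal(classify_division_angle(pi / 4), "oblique")
  expect_equal(classify_division_angle(pi / 3), "oblique")
  expect_equal(classify_division_angle(pi / 3 + 1e-9), "perpendicular")
  expect_equal(classify_division_angle(pi / 2), "perpendicular")
  expect_error(classify_division_angle(2), "out of")
})

test_that("isotropic orientations give a flat normalized distribution", {
  set.seed(8)
  theta <- acos(runif(1e5))          # 3D-isotropic, folded to [0, pi/2]
  dist <- long_axis_distribution(theta, n_bins = 9)
  expect_equal(sum(dist$P * diff(dist$edges)), 1, tolerance = 1e-12)
  expect_true(all(abs(dist$ratio - 1) < 0.05))
  expect_lt(dist$metrics["anisotropy_ratio"], 1.1)

  conc <- long_axis_distribution(rep(pi / 2, 500) - abs(rnorm(500, 0, 0.02)),
                                 n_bins = 9)
  expect_equal(dist$mids[which.max(conc$ratio)], pi / 2, tolerance = 0.1)
  expect_lt(conc$metrics["fwhm"], 2.5 * (pi / 18))
  expect_error(long_axis_distribution(numeric(0)), "no orientation")
})

test_that("daughter separation is zero at division and under rigid motion", {
  tr <- data.frame(
    time = rep(0:5, 2),
    cell = rep(c(1L, 2L), each = 6),
    type = "basal",
    x = c(0:5, 1 + 0:5), y = c(0:5 * 2, 0:5 * 2), z = 0)
  ev <- data.frame(time = 0, d1 = 1L, d2 = 2L)
  box <- c(100, 100, 0, 100, 0)
  out <- daughter_separation(ev, tr, box)
  expect_equal(out$dd2[out$t == 0], 0)
  expect_equal(out$dd2, rep(0, 6))   # common translation is filtered out

  # censoring once a daughter leaves the basal layer
  tr2 <- tr
  tr2$type[tr2$cell == 2 & tr2$time >= 3] <- "suprabasal"
  out2 <- daughter_separation(ev, tr2, box)
  expect_equal(max(out2$t), 2)
})

test_that("independent Brownian daughters recover dd2 = 12 D0 t", {
  fx <- generate_fixture("synthetic_separation_trace",
                         params = list(n_pairs = 1000, D0 = 0.01,
                                       t_max = 20, dt = 1), seed = 2)
  tr <- daughter_separation(fx$events, fx$trajectories, fx$box)
  binned <- aggregate(dd2 ~ t, data = tr, FUN = mean)
  fit <- lm(dd2 ~ 0 + t, data = binned)
  expect_equal(unname(coef(fit)[1]), 12 * fx$D0, tolerance = 0.05)
})

test_that("binning with subgroup errors matches the stated partition", {
  set.seed(3)
  tr <- data.frame(event = rep(1:40, each = 10),
                   t = rep(seq(0.5, 9.5, by = 1), 40))
  tr$dd2 <- 0.1 * tr$t + rnorm(nrow(tr), sd = 0.05)
  b <- bin_with_bootstrap(tr, bin_width = 2, n_subgroups = 5)
  expect_equal(nrow(b), 5)
  expect_true(all(is.finite(b$error)))
  expect_error(bin_with_bootstrap(tr[tr$event <= 39, ], 2, 5), "divisible")

  # identical subgroups give zero error
  tr0 <- tr
  tr0$dd2 <- 0.1 * tr0$t
  b0 <- bin_with_bootstrap(tr0, bin_width = 2, n_subgroups = 5)
  expect_true(all(b0$error < 1e-12))

  # the subgroup error tracks the true standard error within a factor 2
  reps <- replicate(40, {
    x <- data.frame(event = rep(1:40, each = 2), t = rep(c(0.5, 1.5), 40),
                    dd2 = rnorm(80))
    bb <- bin_with_bootstrap(x, 1, 5)
    bb$error[1]
  })
  se_true <- 1 / sqrt(40)
  expect_gt(mean(reps), se_true / 2)
  expect_lt(mean(reps), se_true * 2)
})

test_that("diffusion fits recover the slope convention dd2 ~ D t", {
  b <- data.frame(t = seq(2.5, 50, by = 5), mean = 0.02 * seq(2.5, 50, by = 5))
  expect_equal(fit_diffusion(b, window = c(0, 50))$D, 0.02, tolerance = 1e-12)
  b0 <- data.frame(t = seq(2.5, 50, by = 5), mean = 1)
  expect_equal(fit_diffusion(b0, window = c(0, 50))$D, 0, tolerance = 1e-12)

  set.seed(4)
  hits <- replicate(100, {
    bn <- data.frame(t = seq(2.5, 50, by = 5))
    bn$mean <- 0.02 * bn$t * (1 + rnorm(nrow(bn), sd = 0.05))
    abs(fit_diffusion(bn, window = c(0, 50))$D - 0.02) < 0.004
  })
  expect_gt(mean(hits), 0.9)
  expect_error(fit_diffusion(b[1:2, ], window = c(0, 50)), "fewer than 3")
})

test_that("orientation-weighted averages follow the stage weights", {
  w <- division_angle_weights(stage_division_fractions("E14"))
  x <- c(planar = 1, oblique = 2, perpendicular = 3)
  out <- orientation_weighted_average(x, w)
  expect_equal(out$mean, 2.35)
  expect_equal(orientation_weighted_average(c(planar = 7, oblique = 7,
                                              perpendicular = 7), w)$mean, 7)
  wd <- division_angle_weights(c(planar = 1, oblique = 0, perpendicular = 0))
  expect_equal(orientation_weighted_average(x, wd)$mean, 1)
  expect_error(orientation_weighted_average(c(planar = 1, oblique = NA,
                                              perpendicular = 2), w), "every")
})

test_that("the scaling exponent separates diffusive from caged traces", {
  t <- seq(1, 100, by = 1)
  lin <- data.frame(t = t, mean = 0.05 * t)
  expect_equal(msd_exponent(lin, window = c(5, 100))$exponent, 1,
               tolerance = 1e-9)
  expect_equal(msd_exponent(lin, window = c(5, 100))$regime, "diffusive")
  sub <- data.frame(t = t, mean = 0.05 * sqrt(t))
  expect_equal(msd_exponent(sub, window = c(5, 100))$exponent, 0.5,
               tolerance = 1e-9)
  caged <- data.frame(t = t, mean = 0.2 * (1 - exp(-t / 3)))
  late <- msd_exponent(caged, window = c(40, 100))
  expect_lt(late$exponent, 0.3)
  expect_equal(late$regime, "subdiffusive")
})
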