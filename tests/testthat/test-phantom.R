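test_that("label map respects the requested lesion fraction", {
  lm0 <- build_labelmap(tiny_spec(lesion_fraction = 0))
  expect_false(any(lm0$labels == 3L))

  lm1 <- build_labelmap(tiny_spec(lesion_fraction = 1))
  expect_false(any(lm1$labels %in% c(1L, 2L)))
  expect_gt(sum(lm1$labels == 3L), 0)

  for (f in c(0.1, 0.25, 0.5)) {
    sp <- tiny_spec(lesion_fraction = f)
    lm <- build_labelmap(sp)
    n_muscle <- sum(lm$labels %in% c(1L, 2L, 3L))
    expect_equal(sum(lm$labels == 3L), round(f * n_muscle))
  }
})

test_that("label map generation is deterministic under a fixed seed", {
  sp <- tiny_spec(lesion_fraction = 0.3, seed = 42L)
  expect_identical(build_labelmap(sp)$labels, build_labelmap(sp)$labels)
  ph1 <- tiny_phantom(lesion_fraction = 0.2, snr = 33, seed = 7L)
  ph2 <- tiny_phantom(lesion_fraction = 0.2, snr = 33, seed = 7L)
  expect_identical(ph1$volume$si_te1, ph2$volume$si_te1)
  expect_identical(ph1$volume$si_te2, ph2$volume$si_te2)
})

test_that("overlapping or out-of-grid compartments raise geometry errors", {
  sp <- tiny_spec()
  sp$compartments[[2]]$center <- sp$compartments[[1]]$center
  expect_error(build_labelmap(sp), "geometry error")
  sp2 <- tiny_spec()
  sp2$compartments[[1]]$center <- c(0.5, 7.5)  # ellipse pokes out of FOV
  expect_error(build_labelmap(sp2), "geometry error")
})

test_that("noise-free dual-echo signal follows proton density and T2", {
  ph <- tiny_phantom(muscle_t2 = 24.83, snr = Inf)
  muscle <- ph$labelmap$labels %in% c(1L, 2L)
  ratio <- ph$volume$si_te1[muscle] / ph$volume$si_te2[muscle]
  expect_equal(ratio, rep(exp(26 / 24.83), sum(muscle)), tolerance = 1e-12)
  # background carries no signal when noise-free
  expect_true(all(ph$volume$si_te1[ph$labelmap$labels == 0L] == 0))
})

test_that("a label without a tissue spec is a mapping error", {
  lm <- build_labelmap(tiny_spec())
  expect_error(simulate_dual_echo(lm, default_tissues()[1:2]),
               "mapping error")
})

test_that("Rician noise hits the requested muscle SNR and floors background", {
  ph <- tiny_phantom(grid = c(64, 64, 10), snr = 33, seed = 5L)
  labs <- ph$labelmap$labels
  bg <- labs == 0L
  expect_gt(mean(ph$volume$si_te1[bg]), 0)  # Rician floor
  # estimate sigma from the Rayleigh background mean: E|n| = sigma*sqrt(pi/2)
  sigma_hat <- mean(ph$volume$si_te1[bg]) / sqrt(pi / 2)
  snr_hat <- mean(ph$volume$si_te1[labs %in% c(1L, 2L)]) / sigma_hat
  expect_equal(snr_hat, 33, tolerance = 0.05)
})

test_that("zero proton density voxels are Rayleigh-distributed under noise", {
  # Rayleigh: mean sigma*sqrt(pi/2), sd sigma*sqrt(2 - pi/2)
  ph <- tiny_phantom(grid = c(64, 64, 10), snr = 33, seed = 9L)
  bg <- ph$volume$si_te1[ph$labelmap$labels == 0L]
  expect_equal(sd(bg) / mean(bg),
               sqrt(2 - pi / 2) / sqrt(pi / 2), tolerance = 0.05)
})

test_that("STEAM decay matches the multi-exponential model", {
  # single component: definition of T2
  d1 <- simulate_steam_decay(rbind(c(1, 31)),
                             acq = acquisition_spec(te = c(31, 62), tr = 9000))
  expect_equal(d1$magnitude[1], exp(-1), tolerance = 1e-12)
  # two components at TE 5 ms: direct evaluation
  d2 <- simulate_steam_decay(rbind(c(0.7, 20), c(0.3, 80)))
  expect_equal(d2$magnitude[1],
               0.7 * exp(-5 / 20) + 0.3 * exp(-5 / 80), tolerance = 1e-12)
  expect_equal(d2$magnitude[1], 0.8270, tolerance = 1e-4)
  # zero phase, no noise: imaginary part identically zero
  expect_true(all(Im(d2$signal) == 0))
  expect_length(d2$te, 29)
  expect_error(simulate_steam_decay(matrix(numeric(0), ncol = 2)),
               "empty")
})

test_that("cohort generator recovers group means and honours sd = 0", {
  spec <- cohort_spec("WT", 400, 18.05, 2.91, 24.83, 0.66,
                      mac1_mean = 3.915, mac1_sd = 1.2)
  tab <- simulate_cohort(spec, seed = 21L)$table
  w <- tab$value[tab$measurement == "weight"]
  se <- 2.91 / sqrt(length(w))
  expect_lt(abs(mean(w) - 18.05), 3 * se)

  frozen <- cohort_spec("X", 5, 10, 0, 20, 0, mac1_mean = 4, mac1_sd = 0)
  ft <- simulate_cohort(frozen, seed = 1L)$table
  expect_true(all(ft$value[ft$measurement == "weight"] == 10))
  expect_true(all(ft$value[ft$measurement == "muscle_t2"] == 20))
  expect_true(all(ft$value[ft$measurement == "mac1"] == 4))
})

test_that("cohort phantoms carry each animal's drawn ground truth", {
  tmpl <- tiny_spec(grid = c(24, 24, 6))
  co <- simulate_cohort(study_cohorts()["DyW"], phantom_template = tmpl,
                        seed = 2L)
  a <- co$animals[[1]]
  m <- make_t2_map(a$volume, a$labelmap, labels = c(1, 2))
  # noise-free muscle pixels sit exactly at the animal's drawn T2
  expect_equal(unique(round(m$t2[m$valid], 9)),
               round(a$truth$muscle_t2, 9))
})
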