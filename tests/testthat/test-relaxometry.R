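# brute-force NNLS oracle for small grids: enumerate active sets, solve
# ordinary least squares on each, keep feasible (x >= 0) candidates, and
# return the amplitude vector with minimal residual.
nnls_bruteforce <- function(te, s, grid) {
  A <- exp(-outer(te, grid, "/"))
  k <- length(grid)
  best <- list(x = rep(0, k), rss = sum(s^2))
  for (bits in 1:(2^k - 1)) {
    act <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    Asub <- A[, act, drop = FALSE]
    x_act <- tryCatch(qr.solve(crossprod(Asub), crossprod(Asub, s)),
                      error = function(e) NULL)
    if (is.null(x_act) || any(x_act < -1e-10)) next
    x <- rep(0, k); x[act] <- pmax(as.numeric(x_act), 0)
    rss <- sum((A %*% x - s)^2)
    if (rss < best$rss - 1e-14) best <- list(x = x, rss = rss)
  }
  best
}

test_that("NNLS matches a brute-force active-set oracle on small grids", {
  te <- steam_te_list()
  grid <- c(10, 31, 100, 300)
  set.seed(5)
  for (i in 1:10) {
    truth <- pmax(rnorm(4, c(0, 1, 0.3, 0), 0.2), 0)
    s <- as.numeric(exp(-outer(te, grid, "/")) %*% truth)
    fit <- fit_nnls(decay_curve(te, s), grid = grid)
    oracle <- nnls_bruteforce(te, s, grid)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
    expect_equal(fit$amplitude, oracle$x, tolerance = 1e-6)
  }
})

test_that("a single on-grid component collapses to its node", {
  te <- steam_te_list()
  grid <- nnls_grid()
  node <- grid[17]
  s <- exp(-te / node)
  fit <- fit_nnls(decay_curve(te, s), grid = grid)
  expect_lt(fit$rss, 1e-12)
  expect_equal(which.max(fit$amplitude), 17L)
  expect_equal(sum(fit$amplitude) - fit$amplitude[17], 0, tolerance = 1e-6)
})

test_that("zero signal yields a zero spectrum", {
  fit <- fit_nnls(decay_curve(steam_te_list(), rep(0, 29)))
  expect_true(all(fit$amplitude == 0))
  expect_equal(fit$rss, 0)
})

test_that("two well-separated components are resolved with their fractions", {
  d <- simulate_steam_decay(rbind(c(0.7, 20), c(0.3, 80)))
  sm <- spectrum_summary(fit_nnls(d, grid = nnls_grid(5, 500, 40)))
  expect_equal(sm$n_components, 2)
  expect_equal(sm$component_t2[1], 20, tolerance = 0.05)
  expect_equal(sm$component_t2[2], 80, tolerance = 0.05)
  expect_equal(sm$fractions, c(0.7, 0.3), tolerance = 0.05)
  expect_equal(sum(sm$fractions), 1, tolerance = 1e-12)
})

test_that("spectrum summary reports geometric-mean T2 per component", {
  one <- structure(list(grid = c(25), amplitude = c(2), rss = 0),
                   class = "t2_spectrum")
  expect_error(spectrum_summary(
    structure(list(grid = c(10, 20), amplitude = c(0, 0), rss = 0),
              class = "t2_spectrum")), "all-zero")
  two <- structure(list(grid = c(10, 1000), amplitude = c(1, 1), rss = 0),
                   class = "t2_spectrum")
  sm <- spectrum_summary(two)
  expect_equal(sm$gm_t2, 100)  # sqrt(10 * 1000)
  single <- structure(list(grid = c(5, 25, 100),
                           amplitude = c(0, 3, 0), rss = 0),
                      class = "t2_spectrum")
  ss <- spectrum_summary(single)
  expect_equal(ss$gm_t2, 25)
  expect_equal(ss$n_components, 1)
  expect_equal(ss$fractions, 1)
})

test_that("mono-exponential fits recover exact-model decays", {
  d <- simulate_steam_decay(rbind(c(1, 31)))
  fit <- fit_monoexp(d)
  expect_true(fit$converged)
  expect_equal(fit$t2, 31, tolerance = 1e-6)
  expect_equal(fit$s0, 1, tolerance = 1e-6)

  # two points are exactly determined: same closed form as two_echo_t2
  d2 <- decay_curve(c(14, 40), c(200, 100))
  fit2 <- fit_monoexp(d2)
  expect_equal(fit2$t2, 26 / log(2), tolerance = 1e-4)
  expect_lt(fit2$rss, 1e-8)
})

test_that("non-decaying input is flagged instead of erroring", {
  flat <- decay_curve(steam_te_list(), rep(1, 29))
  fit <- fit_monoexp(flat)
  expect_false(fit$converged)
  expect_gte(fit$t2, 1999)  # pinned at the upper bound
})

test_that("mono-exponential fit is scale-equivariant", {
  d <- simulate_steam_decay(rbind(c(1, 45)), noise_sd = 0.01, seed = 3L)
  base_fit <- fit_monoexp(d)
  for (c_scale in c(0.1, 7, 1000)) {
    ds <- decay_curve(d$te, d$magnitude * c_scale)
    fit <- fit_monoexp(ds)
    expect_equal(fit$t2, base_fit$t2, tolerance = 1e-5)
    expect_equal(fit$s0, base_fit$s0 * c_scale, tolerance = 1e-4)
  }
})

test_that("noisy single-component recovery: median error under 2%", {
  set.seed(19)
  errs <- replicate(200, {
    t2_true <- runif(1, 15, 60)
    d <- simulate_steam_decay(rbind(c(1, t2_true)), noise_sd = 0.01)
    abs(fit_monoexp(d)$t2 - t2_true) / t2_true
  })
  expect_lt(median(errs), 0.02)
})

test_that("NNLS never fits worse than the nested mono-exponential", {
  # nesting holds whenever the mono-exponential optimum is representable
  # on the grid, so the comparison grid includes the fitted T2
  set.seed(23)
  for (i in 1:20) {
    comp <- rbind(c(runif(1, 0.3, 1), runif(1, 10, 50)),
                  c(runif(1, 0, 0.5), runif(1, 60, 200)))
    d <- simulate_steam_decay(comp, noise_sd = runif(1, 0, 0.02))
    mono <- fit_monoexp(d)
    grid <- sort(unique(c(nnls_grid(), mono$t2)))
    expect_lte(fit_nnls(d, grid = grid)$rss, mono$rss + 1e-10)
  }
})

test_that("complex PCA recovers rank-1 decays up to scale and phase", {
  te <- steam_te_list()
  decay <- exp(-te / 31)
  profile <- complex(real = rnorm(8), imaginary = rnorm(8))
  m <- outer(profile, decay)
  out <- cpca_extract(m, te)
  expect_equal(out$magnitude / out$magnitude[1], decay / decay[1],
               tolerance = 1e-9)
  expect_gte(attr(out, "energy_fraction"), 1 - 1e-12)

  # global phase invariance
  out_rot <- cpca_extract(m * exp(1i * 1.234), te)
  expect_equal(out$magnitude, out_rot$magnitude, tolerance = 1e-9)

  expect_error(cpca_extract(matrix(0i, 4, 29)), "degenerate")
  expect_error(cpca_extract(m[1, , drop = FALSE], te), "2 samples")
})

test_that("cpca + monoexp equals monoexp on the true decay", {
  te <- steam_te_list()
  decay <- 2.5 * exp(-te / 27)
  profile <- complex(real = rnorm(6, 1), imaginary = rnorm(6))
  out <- cpca_extract(outer(profile, decay), te)
  fit_extracted <- fit_monoexp(out)
  fit_true <- fit_monoexp(decay_curve(te, decay))
  expect_equal(fit_extracted$t2, fit_true$t2, tolerance = 1e-6)
})

test_that("noisy rank-1 data keeps first-component energy above 0.99", {
  set.seed(31)
  te <- steam_te_list()
  decay <- exp(-te / 31)
  profile <- complex(real = rnorm(16, 2), imaginary = rnorm(16))
  noise <- matrix(complex(real = rnorm(16 * 29, 0, 0.01),
                          imaginary = rnorm(16 * 29, 0, 0.01)), 16, 29)
  out <- cpca_extract(outer(profile, decay) + noise, te)
  expect_gt(attr(out, "energy_fraction"), 0.99)
})
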