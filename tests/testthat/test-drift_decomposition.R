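two_gauss <- function(t, a1, a2, c1 = 7.4, c2 = 10.2, w = 0.4) {
  a1 * exp(-(t - c1)^2 / (2 * w^2)) + a2 * exp(-(t - c2)^2 / (2 * w^2))
}
grid_t <- seq(5, 13, by = 0.05)
profile <- function(y, cond = "x") {
  structure(data.frame(time = grid_t, intensity = pmax(y, 0)),
            condition = cond, class = c("drift_profile", "data.frame"))
}

test_that("identical noiseless profiles give equal amplitudes and exact parameters", {
  y <- two_gauss(grid_t, 1, 0.6)
  fit <- fit_shared_mixture(profile(y), profile(y), n_components = 2)
  expect_equal(fit$centers, c(7.4, 10.2), tolerance = 1e-4)
  expect_equal(unname(fit$widths), c(0.4, 0.4), tolerance = 1e-4)
  expect_equal(unname(fit$amplitudes["before", ]),
               unname(fit$amplitudes["after", ]), tolerance = 1e-4)
  expect_equal(unname(fit$amplitudes["before", ]), c(1, 0.6),
               tolerance = 1e-3)
})

test_that("amplitude shifts are recovered within 5% at signal-to-noise 50", {
  # condition B halves the compact component's share change: amplitudes
  # (1, 1) -> (0.5, 2) across the two components
  set.seed(31)
  sd_n <- max(two_gauss(grid_t, 1, 1)) / 50
  b <- profile(two_gauss(grid_t, 1, 1) + rnorm(length(grid_t), sd = sd_n))
  a <- profile(two_gauss(grid_t, 0.5, 2) + rnorm(length(grid_t), sd = sd_n))
  fit <- fit_shared_mixture(b, a, n_components = 2)
  ratio_before <- unname(fit$amplitudes["before", 1] /
    fit$amplitudes["before", 2])
  ratio_after <- unname(fit$amplitudes["after", 1] /
    fit$amplitudes["after", 2])
  expect_equal(ratio_before, 1, tolerance = 0.05)
  expect_equal(ratio_after, 0.25, tolerance = 0.05)
})

test_that("a single-component fit reduces to moment matching", {
  y <- 2 * exp(-(grid_t - 8.3)^2 / (2 * 0.55^2))
  fit <- fit_shared_mixture(profile(y), profile(y), n_components = 1)
  mu <- weighted.mean(grid_t, y)
  sdv <- sqrt(weighted.mean((grid_t - mu)^2, y))
  expect_equal(fit$centers, mu, tolerance = 1e-4)
  expect_equal(unname(fit$widths), sdv, tolerance = 1e-3)
})

test_that("population shift report labels gaining and losing components", {
  b <- profile(two_gauss(grid_t, 1, 1))
  a <- profile(two_gauss(grid_t, 2, 0.5))
  rep <- population_shift_report(
    fit_shared_mixture(b, a, n_components = 2))
  expect_equal(rep$direction, c("gains", "loses"))
  expect_identical(attr(rep, "overall"), "toward compact")
  expect_equal(sum(rep$fraction_before), 1, tolerance = 1e-9)
  expect_equal(sum(rep$fraction_after), 1, tolerance = 1e-9)

  same <- population_shift_report(
    fit_shared_mixture(b, b, n_components = 2))
  expect_true(all(abs(same$delta_fraction) < 1e-6))
})

test_that("a component absent after reaction gets an after-fraction of zero", {
  three <- function(a3) two_gauss(grid_t, 1, 0.8) +
    a3 * exp(-(grid_t - 11.9)^2 / (2 * 0.35^2))
  fit <- fit_shared_mixture(profile(three(0.7)), profile(three(0)),
                            n_components = 3)
  rep <- population_shift_report(fit)
  third <- which.max(rep$center_ms)
  expect_equal(rep$center_ms[third], 11.9, tolerance = 0.05)
  expect_lt(rep$fraction_after[third], 1e-3)
})

test_that("fractions are invariant to joint intensity rescaling", {
  set.seed(5)
  noise <- rnorm(length(grid_t), sd = 0.01)
  b <- two_gauss(grid_t, 1, 0.7) + noise
  a <- two_gauss(grid_t, 1.5, 0.3) + noise
  f1 <- fit_shared_mixture(profile(b), profile(a), n_components = 2)
  f2 <- fit_shared_mixture(profile(1000 * b), profile(1000 * a),
                           n_components = 2)
  expect_equal(f1$fractions, f2$fractions, tolerance = 1e-6)
  expect_equal(f1$centers, f2$centers, tolerance = 1e-6)
})

test_that("the shared-parameter fit cannot beat the unconstrained fit", {
  set.seed(9)
  sd_n <- 0.02
  # generating centers coincide across conditions, so the constrained
  # residual should approach the unconstrained one
  b <- profile(two_gauss(grid_t, 1, 1) + rnorm(length(grid_t), sd = sd_n))
  a <- profile(two_gauss(grid_t, 0.6, 1.4) +
                 rnorm(length(grid_t), sd = sd_n))
  shared <- fit_shared_mixture(b, a, n_components = 2)
  free <- fit_shared_mixture(b, a, n_components = 2, shared = FALSE)
  expect_gte(shared$objective, free$objective - 1e-9)
  expect_lt(shared$objective, 1.5 * free$objective)
})

test_that("amplitudes are never negative and zero components are inert", {
  set.seed(13)
  b <- profile(two_gauss(grid_t, 1, 0) +
                 rnorm(length(grid_t), sd = 0.005))
  a <- profile(two_gauss(grid_t, 0.8, 0) +
                 rnorm(length(grid_t), sd = 0.005))
  fit <- fit_shared_mixture(b, a, n_components = 2)
  expect_true(all(fit$amplitudes >= 0))
})

test_that("component-count selection balances fit against parsimony", {
  one <- profile(two_gauss(grid_t, 1, 0))
  expect_equal(as.integer(select_n_components(one, one, n_max = 3)), 1L)

  two_b <- profile(two_gauss(grid_t, 1, 1))
  two_a <- profile(two_gauss(grid_t, 0.5, 1.5))
  expect_equal(as.integer(select_n_components(two_b, two_a, n_max = 3)),
               2L)

  set.seed(77)
  noise_p <- function() profile(abs(rnorm(length(grid_t), sd = 0.1)))
  sel <- select_n_components(noise_p(), noise_p(), n_max = 2)
  expect_equal(as.integer(sel), 1L)
  expect_true(attr(sel, "ill_conditioned"))
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(21)
  b <- profile(two_gauss(grid_t, 1, 1) + rnorm(length(grid_t), sd = 0.02))
  a <- profile(two_gauss(grid_t, 2, 0.5) +
                 rnorm(length(grid_t), sd = 0.02))
  f1 <- fit_shared_mixture(b, a, n_components = 2, seed = 4)
  f2 <- fit_shared_mixture(b, a, n_components = 2, seed = 4)
  expect_identical(f1$amplitudes, f2$amplitudes)
  expect_identical(f1$objective, f2$objective)
})
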