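test_that("degenerate walks behave as closed forms dictate", {
  w0 <- run_walk(diff = 0, p_off = 10, n_walkers = 100, n_steps = 50, seed = 1)
  expect_true(all(w0$end_distances == 0))

  # free 2D diffusion: mean square end distance = 4 D T
  w <- run_walk(diff = 0.1, p_off = 0, n_walkers = 1000, n_steps = 200,
                dt = 0.01, seed = 2)
  msd <- mean(w$end_distances^2)
  expected <- 4 * 0.1 * 1e6 * 2 # nm^2
  se <- sd(w$end_distances^2) / sqrt(1000)
  expect_lt(abs(msd - expected), 3 * se)

  expect_error(run_walk(diff = 0.1, p_off = 200, dt = 0.01),
               class = "kinseg_invalid_config")
})

test_that("end distances match the geometric-lifetime mixture oracle", {
  diff <- 0.1; p_off <- 10; dt <- 0.01; n_steps <- 1000
  w <- run_walk(diff, p_off, n_walkers = 3000, n_steps = n_steps, dt = dt,
                seed = 3)
  # oracle: lifetime K = min(1 + Geom(p), n_steps) steps (the walker moves,
  # then may deactivate); position is then Gaussian with per-axis variance
  # K * 2 D dt, so distance is Rayleigh
  set.seed(99)
  K <- pmin(1 + rgeom(3000, p_off * dt), n_steps)
  sigma2 <- K * 2 * diff * 1e6 * dt
  r_oracle <- sqrt(rnorm(3000, 0, sqrt(sigma2))^2 +
                     rnorm(3000, 0, sqrt(sigma2))^2)
  p <- suppressWarnings(ks.test(w$end_distances, r_oracle))$p.value
  expect_gt(p, 0.01)
})

test_that("decay-length fit is exact on its own model and scale-invariant", {
  r <- seq(10, 590, by = 20)
  h <- data.frame(r = r, count = 1e4 * exp(-r / 50))
  expect_equal(fit_decay_length(h)$decay_length, 50, tolerance = 1e-8)
  h2 <- h; h2$count <- 2 * h2$count
  expect_equal(fit_decay_length(h2)$decay_length,
               fit_decay_length(h)$decay_length, tolerance = 1e-12)
  expect_error(fit_decay_length(data.frame(r = 1:2, count = c(5, 5))),
               class = "kinseg_insufficient_data")
})

test_that("histogram fit agrees with the maximum-likelihood rate", {
  w <- run_walk(diff = 0.1, p_off = 10, n_walkers = 1e5, seed = 4)
  ll <- fit_decay_length(w, method = "loglinear")$decay_length
  ml <- fit_decay_length(w, method = "mle")$decay_length
  expect_lt(abs(ll - ml) / ml, 0.10)
})

test_that("decay length is monotone in diffusion and deactivation", {
  dl <- function(diff, p_off)
    fit_decay_length(run_walk(diff, p_off, n_walkers = 2000,
                              seed = 5))$decay_length
  expect_gt(dl(0.3, 10), dl(0.03, 10))
  expect_gt(dl(0.1, 1), dl(0.1, 30))
})
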