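test_that("topography-driven sampling follows the height weighting", {
  # two-level topography: nearly all points land on the low half
  z <- cbind(matrix(0, 40, 20), matrix(100, 40, 20))
  topo <- list(z = z, spacing = 25)
  pts <- estimate_tcr_from_topography(topo, 2000, z_scale = 10, seed = 1)
  low <- mean(pts$y <= 20 * 25)
  expect_gt(low, 0.9999 - 1e-4)

  # constant topography: uniform sampling (x-marginal KS test)
  flat <- list(z = matrix(5, 40, 40), spacing = 25)
  u <- estimate_tcr_from_topography(flat, 1000, z_scale = 10, seed = 2)
  p <- suppressWarnings(ks.test(u$x, "punif", 0, 1000))$p.value
  expect_gt(p, 0.01)

  # a depression concentrates points near its center
  pars <- scene_params(noise_sd = 0)
  sc <- generate_scene(pars, seed = 3)
  r <- sqrt((sc$tcr$x - 1000)^2 + (sc$tcr$y - 1000)^2)
  expect_lt(median(r), pars$contact_radius)
  expect_error(estimate_tcr_from_topography(flat, 0),
               class = "kinseg_invalid_config")
})

test_that("scene estimates reduce to counting and ratio identities", {
  sc <- generate_scene(seed = 4)
  sc$tcr <- sc$tcr[1:100, ]
  sc$ptcr_idx <- 1:22
  est <- estimate_obs(sc)
  expect_equal(est$phos_obs, 0.22)
  sc$ptcr_idx <- seq_len(nrow(sc$tcr))
  expect_equal(estimate_obs(sc)$rg_obs, 1, tolerance = 1e-12)
  sc$ptcr_idx <- integer(0)
  expect_error(estimate_obs(sc), class = "kinseg_undefined_estimate")
})

test_that("the default scene reproduces the observation anchors", {
  est <- t(vapply(1:12, function(s) {
    e <- estimate_obs(generate_scene(seed = s))
    c(e$phos_obs, e$rg_obs)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 0.22), 0.05)
  expect_lt(abs(mean(est[, 2]) - 1.31), 0.15)
})

test_that("removing the peripheral bias removes the enrichment", {
  rg <- vapply(1:40, function(s) {
    estimate_obs(generate_scene(scene_params(ring_bias = 0),
                                seed = s))$rg_obs
  }, numeric(1))
  expect_lt(abs(mean(rg) - 1), 0.05)
})

test_that("scene generation is seed-deterministic and well-formed", {
  s1 <- generate_scene(seed = 6)
  s2 <- generate_scene(seed = 6)
  expect_identical(s1$topography$z, s2$topography$z)
  expect_identical(s1$tcr, s2$tcr)
  expect_identical(s1$ptcr_idx, s2$ptcr_idx)
  expect_true(all(s1$topography$z >= 0))
  expect_true(all(s1$ptcr_idx %in% seq_len(nrow(s1$tcr))))
  expect_true(all(s1$cd45$x >= 0 & s1$cd45$x <= 2000))
  expect_error(scene_params(contact_radius = -5),
               class = "kinseg_invalid_config")
})
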