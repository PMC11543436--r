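test_that("noiseless synthetic truth is recovered by the conjugate fit", {
  # LckA-style grid whose log decay length is exactly linear in the scaling
  # coordinate u = (log diff - log p_off) / 2
  axes <- list(diff = 10^seq(-2, 0, length.out = 4),
               p_off = 10^seq(-1, 2, length.out = 4))
  cells <- expand.grid(diff = axes$diff, p_off = axes$p_off, replicate = 1)
  u <- (log(cells$diff) - log(cells$p_off)) / 2
  a <- 4.6; b <- 1.0
  cells$decay_length <- exp(a + b * u)
  cells$flagged <- FALSE
  grid <- structure(list(cells = cells, model_tag = "LckA", axes = axes,
                         responses = "decay_length", n_replicates = 1,
                         seed = 1),
                    class = "training_grid")
  fit <- fit_surrogate(grid, degree = 1)
  co <- coef(fit, "decay_length")
  post_sd <- sqrt(diag(fit$fits$decay_length$Vn) * fit$fits$decay_length$s2)
  expect_lt(abs(co[1] - a), 2 * post_sd[1] + 1e-6)
  expect_lt(abs(co[2] - b), 2 * post_sd[2] + 1e-6)
  # evaluation consistency at a training cell
  pr <- predict(fit, cells[3, c("diff", "p_off")])
  expect_equal(log(pr$mean), a + b * u[3], tolerance = 1e-3)
})

test_that("predictive uncertainty grows away from the training hull", {
  s <- test_surrogates()
  inside <- predict(s$ks, data.frame(t = 50, rigidity = 50), "width")
  outside <- predict(s$ks, data.frame(t = 200, rigidity = 200), "width")
  expect_gt(outside$sd, inside$sd)
  expect_false(inside$extrapolated)
  expect_true(outside$extrapolated)
  expect_error(predict(s$ks, data.frame(t = 1, rigidity = 1), "nope"),
               class = "kinseg_interface_error")
})

test_that("training grids are seeded and reproducible", {
  g1 <- build_training_grid("LckA",
                            axes = list(diff = c(0.01, 0.1),
                                        p_off = c(1, 10)),
                            n_replicates = 1, seed = 5,
                            walk = list(n_walkers = 200))
  g2 <- build_training_grid("LckA",
                            axes = list(diff = c(0.01, 0.1),
                                        p_off = c(1, 10)),
                            n_replicates = 1, seed = 5,
                            walk = list(n_walkers = 200))
  expect_identical(g1$cells, g2$cells)
})

test_that("rigidity-zero rows of the KS grid show no depletion", {
  g <- test_surrogates()$grids$ks
  zero <- g$cells[g$cells$rigidity == 0 & !g$cells$flagged, "width"]
  expect_lt(mean(zero), 20)
  # and the surrogate inherits the negative control
  pr <- predict(test_surrogates()$ks, data.frame(t = 100, rigidity = 0),
                "width")
  expect_lt(pr$mean, 40)
})

test_that("LckA training grid reproduces the scaling-law slope", {
  g <- test_surrogates()$grids$lcka
  cells <- g$cells[!g$cells$flagged, ]
  u <- (log(cells$diff) - log(cells$p_off)) / 2
  slope <- coef(lm(log(cells$decay_length) ~ u))[["u"]]
  expect_lt(abs(slope - 1), 0.15)
})

test_that("pTCR surrogate is calibrated against its own simulator", {
  s <- test_surrogates()
  gs <- grid_summary(s$grids$ptcr)
  pr <- predict(s$ptcr, gs[, c("decay_length", "depletion")], "phos")
  cover <- mean(abs(gs$phos_mean - pr$mean) <= 2 * pmax(pr$sd, 0.02))
  expect_gte(cover, 0.9)
})

test_that("every root variable carries a prior covering the training axes", {
  s <- test_surrogates()
  pk <- s$ks$priors
  expect_true(pk$t$min <= min(s$grids$ks$axes$t) &&
                pk$t$max >= max(s$grids$ks$axes$t))
  pl <- s$lcka$priors
  # normal priors: every axis value within 4 prior SDs
  expect_true(all(abs(log10(s$grids$lcka$axes$diff) - pl$log10_diff$mean) <=
                    4 * pl$log10_diff$sd))
  expect_true(all(abs(log10(s$grids$lcka$axes$p_off) - pl$log10_p_off$mean) <=
                    4 * pl$log10_p_off$sd))
  pp <- s$ptcr$priors
  expect_true(all(dlnorm(s$grids$ptcr$axes$decay_length,
                         pp$decay_length$meanlog, pp$decay_length$sdlog) > 0))
})

test_that("surrogates serialize to plain lists", {
  s <- test_surrogates()
  l <- surrogate_to_list(s$lcka)
  expect_type(l, "list")
  expect_identical(l$model_tag, "LckA")
  expect_true(all(vapply(l$fits, function(f) is.numeric(f$coef), logical(1))))
})
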