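test_that("the summed exponential kernel obeys its identities", {
  # e-fold drop over one decay length
  rho <- lck_density(cbind(0, 0), decay_length = 70,
                     query = cbind(c(0, 70), c(0, 0)))
  expect_equal(rho[2] / rho[1], exp(-1), tolerance = 1e-12)
  # additivity: coincident sources double the field everywhere
  q <- cbind(runif(20, -500, 500), runif(20, -500, 500))
  one <- lck_density(cbind(10, -5), 70, q)
  two <- lck_density(rbind(c(10, -5), c(10, -5)), 70, q)
  expect_equal(two, 2 * one, tolerance = 1e-12)
  # infinite decay length flattens the field
  set.seed(1)
  cd <- cbind(runif(50, 0, 2000), runif(50, 0, 2000))
  qq <- cbind(runif(100, 0, 2000), runif(100, 0, 2000))
  rho <- lck_density(cd, 1e7, qq)
  expect_lt(max(rho) / min(rho), 1.001)
  expect_warning(out <- lck_density(cd[0, , drop = FALSE], 70, qq),
                 "empty CD45")
  expect_true(all(out == 0))
})

test_that("Rg ratio matches hand-computable cases", {
  tcr <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  expect_equal(rg_ratio(tcr, tcr), 1, tolerance = 1e-12)
  tcr2 <- rbind(c(0, 0), c(0, 0), c(0, 0), c(2, 0))
  expect_equal(rg_ratio(tcr2, rbind(c(2, 0))), sqrt(3), tolerance = 1e-12)
  expect_error(rg_ratio(tcr, tcr[0, , drop = FALSE]),
               class = "kinseg_undefined_ratio")
  expect_error(rg_ratio(tcr[1, , drop = FALSE], tcr),
               class = "kinseg_insufficient_pattern")
})

test_that("unbiased subsampling keeps the Rg ratio at one", {
  set.seed(3)
  disk <- kinseg:::runif_disk(10000, 500)
  ratios <- vapply(1:100, function(i) {
    idx <- sample.int(10000, 5000)
    rg_ratio(disk, disk[idx, ])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.02)
})

test_that("phosphorylation assignment respects its probability rules", {
  set.seed(4)
  pp <- segregated_pattern(depletion = 100)
  # no kinase source: nothing phosphorylates, ratio undefined but flagged
  no_cd <- suppressWarnings(
    assign_phosphorylation(pp[pp$species == "TCR", ],
                           pp[0, ], phos_config(seed = 1)))
  expect_equal(no_cd$phos, 0)
  expect_false(no_cd$rg_defined)
  # saturated probabilities phosphorylate every TCR: ratio exactly one
  sat <- assign_phosphorylation(pp, pp, phos_config(beta = 1e9, seed = 1))
  expect_equal(sat$phos, 1)
  expect_equal(sat$rg_ratio, 1, tolerance = 1e-12)
  # only_bound gates unbound TCRs to probability zero
  bound <- rep(c(TRUE, FALSE), length.out = sum(pp$species == "TCR"))
  ob <- assign_phosphorylation(pp, pp,
                               phos_config(beta = 1e9, only_bound = TRUE,
                                           seed = 1), bound = bound)
  expect_true(all(!ob$flags[!bound]))
  expect_true(all(ob$flags[bound]))
})

test_that("segregated geometry yields peripheral phosphorylation", {
  rg <- vapply(1:30, function(s) {
    set.seed(s)
    pp <- segregated_pattern(n_tcr = 150, n_cd45 = 1200, depletion = 80)
    r <- assign_phosphorylation(pp, pp, phos_config(decay_length = 50,
                                                    seed = s))
    if (r$rg_defined) r$rg_ratio else NA_real_
  }, numeric(1))
  expect_gt(mean(rg, na.rm = TRUE), 1.05)
})

test_that("expected phosphorylation grows with the decay length", {
  mean_phos <- function(dl) {
    mean(vapply(1:25, function(s) {
      set.seed(s)
      pp <- segregated_pattern(depletion = 100)
      assign_phosphorylation(pp, pp,
                             phos_config(decay_length = dl, seed = s))$phos
    }, numeric(1)))
  }
  expect_gt(mean_phos(100), mean_phos(40))
  expect_gt(mean_phos(40), mean_phos(15))
})

test_that("Csk feedback only ever attenuates the field", {
  set.seed(6)
  pp <- segregated_pattern(depletion = 60)
  ph <- assign_phosphorylation(pp, pp, phos_config(decay_length = 70,
                                                   seed = 2))
  same <- apply_csk_inhibition(ph, csk_strength = 0)
  expect_equal(as.numeric(same$densities), as.numeric(ph$densities),
               tolerance = 1e-12)
  a1 <- apply_csk_inhibition(ph, csk_strength = 0.5)$densities
  a2 <- apply_csk_inhibition(ph, csk_strength = 1)$densities
  expect_true(all(a1 <= ph$densities + 1e-12))
  expect_true(all(a2 <= a1 + 1e-12))
  expect_error(apply_csk_inhibition(ph, csk_strength = -1),
               class = "kinseg_invalid_config")
})
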