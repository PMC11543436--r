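test_that("sustained-duration extraction follows run-length logic", {
  expect_equal(unname(max_sustained_duration(rep(6, 91), n_min = 5, dt = 1)),
               90)
  expect_equal(unname(max_sustained_duration(rep(5, 50), n_min = 5, dt = 1)),
               0)
  # intervals of 8 s and 12 s (9 and 13 samples at 1 s cadence)
  v <- c(rep(0, 3), rep(7, 9), 0, rep(7, 13), 0)
  expect_equal(unname(max_sustained_duration(v, n_min = 5, dt = 1)), 12)
})

test_that("the activation rule is a threshold on sustained duration", {
  s90 <- fake_series(cbind(rep(6, 91)))
  expect_true(activation_outcome(s90, activation_rule(5, 10)))
  s8 <- fake_series(cbind(c(rep(6, 8), rep(0, 83))))
  expect_false(activation_outcome(s8, activation_rule(5, 10)))
  s15 <- fake_series(cbind(c(rep(6, 15), rep(0, 76))))
  expect_true(activation_outcome(s15, activation_rule(5, 10)))
  expect_false(activation_outcome(s15, activation_rule(5, 20)))
  expect_error(activation_rule(0, 10), class = "kinseg_invalid_config")
})

test_that("sensitivity and specificity handle the degenerate corners", {
  proto <- contact_protocol(dl_grid = c(40, 80), n_replicates = 1)
  mk_scan <- function(counts_by_u) {
    series <- lapply(names(counts_by_u), function(u) {
      s <- fake_series(counts_by_u[[u]], u_assoc = as.numeric(u))
      s$dl_grid <- c(40, 80)
      s
    })
    structure(list(series = series, protocol = proto,
                   runs = data.frame()), class = "affinity_scan")
  }
  on <- cbind(rep(9, 60), rep(9, 60))   # activates at every decay length
  off <- cbind(rep(0, 60), rep(0, 60))
  perfect <- mk_scan(list(`10` = off, `20` = off, `30` = on, `40` = on))
  ss <- sensitivity_specificity(perfect, activation_rule(5, 10))
  expect_equal(ss$sensitivity, c(1, 1))
  expect_equal(ss$specificity, c(1, 1))
  dead <- mk_scan(list(`10` = off, `20` = off, `30` = off, `40` = off))
  ss2 <- sensitivity_specificity(dead, activation_rule(5, 10))
  expect_equal(ss2$sensitivity, c(0, 0))
  expect_equal(ss2$specificity, c(1, 1))
  single <- mk_scan(list(`30` = on, `40` = on))
  expect_error(sensitivity_specificity(single),
               class = "kinseg_undefined_metric")
})

test_that("contact runs respect the count ordering invariants", {
  proto <- contact_protocol(clamp_duration = 5, free_duration = 15,
                            dl_grid = c(30, 70), n_replicates = 1)
  cfg <- ks_config(n_tcr = 60, n_cd45 = 800, n_pmhc = 90, u_assoc = 50,
                   log_every = 0, seed = 21)
  s <- run_contact(cfg, proto)
  expect_true(all(s$n_ptcr <= s$n_bound))
  expect_true(all(s$n_bound <= cfg$n_tcr))
  expect_true(all(s$n_ptcr[, 2] >= s$n_ptcr[, 1] - 8)) # longer reach, more pTCR
  expect_gt(max(s$n_bound), 0.5 * cfg$n_tcr)

  # weak association: the contact dissolves shortly after release
  cfg5 <- ks_config(n_tcr = 60, n_cd45 = 800, n_pmhc = 90, u_assoc = 5,
                    log_every = 0, seed = 22)
  s5 <- run_contact(cfg5, proto)
  expect_false(is.na(s5$detach_time))
  expect_equal(tail(s5$n_bound, 1), 0)
})

test_that("sticky bookkeeping can only increase phosphorylated counts", {
  proto0 <- contact_protocol(clamp_duration = 5, free_duration = 10,
                             dl_grid = c(40), n_replicates = 1)
  proto1 <- contact_protocol(clamp_duration = 5, free_duration = 10,
                             dl_grid = c(40), n_replicates = 1, sticky = TRUE)
  cfg <- ks_config(n_tcr = 60, n_cd45 = 800, n_pmhc = 90, u_assoc = 50,
                   log_every = 0, seed = 23)
  snap <- run_contact(cfg, proto0)
  stick <- run_contact(cfg, proto1)
  expect_true(all(stick$n_ptcr >= snap$n_ptcr))
})
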