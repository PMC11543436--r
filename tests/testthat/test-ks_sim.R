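test_that("configuration invariants are enforced", {
  expect_s3_class(ks_config(), "ks_config")
  expect_error(ks_config(grid_spacing = 30), class = "kinseg_invalid_config")
  expect_error(ks_config(h_cd45 = 10), class = "kinseg_invalid_config")
  expect_error(ks_config(n_tcr = -1), class = "kinseg_invalid_config")
  expect_error(ks_config(u_assoc = -5), class = "kinseg_invalid_config")
  expect_error(ks_config(n_tcr = 5000, tcr_cluster_radius = 100),
               class = "kinseg_invalid_config")
})

test_that("initial state places one central cluster and no bonds", {
  cfg <- tiny_ks_config(seed = 7)
  st <- init_state(cfg)
  mol <- st$molecules
  expect_equal(nrow(mol), cfg$n_tcr + cfg$n_cd45 + cfg$n_pmhc)
  expect_true(all(mol$x >= 0 & mol$x <= cfg$patch_size))
  expect_true(all(mol$y >= 0 & mol$y <= cfg$patch_size))
  ctr <- cfg$patch_size / 2
  r_tcr <- with(mol[mol$species == "TCR", ],
                sqrt((x - ctr)^2 + (y - ctr)^2))
  expect_true(all(r_tcr <= cfg$tcr_cluster_radius))
  r_cd <- with(mol[mol$species == "CD45", ],
               sqrt((x - ctr)^2 + (y - ctr)^2))
  expect_true(all(r_cd > cfg$tcr_cluster_radius))
  expect_false(any(mol$bound, na.rm = TRUE))
  # established-contact profile: complex height at the center, resting
  # separation at the edge
  n <- nrow(st$z)
  expect_lt(abs(st$z[n / 2, n / 2] - cfg$h_tcr_bond), 1)
  expect_lt(abs(st$z[1, 1] - cfg$boundary_height), 1)
  flat <- init_state(tiny_ks_config(init_contact = FALSE, seed = 2))
  expect_true(all(flat$z == flat$config$init_height))

  # empty species and seeded determinism
  st0 <- init_state(tiny_ks_config(n_tcr = 0, seed = 1))
  expect_equal(sum(st0$molecules$species == "TCR"), 0)
  expect_identical(init_state(cfg), init_state(cfg))
})

test_that("trajectories are bit-reproducible under the same seed", {
  cfg <- tiny_ks_config(seed = 42, t_end = 2, sample_times = c(0, 2))
  t1 <- run_ks(cfg)
  t2 <- run_ks(cfg)
  expect_identical(t1$states[[2]]$z, t2$states[[2]]$z)
  expect_identical(t1$states[[2]]$molecules, t2$states[[2]]$molecules)
})

test_that("bonds form under strong association and are conserved", {
  cfg <- tiny_ks_config(seed = 5, u_assoc = 50, t_end = 20,
                        sample_times = c(0, 5, 10, 20), log_every = 100)
  traj <- run_ks(cfg)
  nb <- vapply(traj$states, function(s) sum(s$molecules$bound, na.rm = TRUE),
               numeric(1))
  expect_gt(nb[2], 0.5 * cfg$n_tcr)
  # at 50 kT the bound population never collapses once formed
  expect_gte(nb[4], 0.9 * max(nb))
})

test_that("with all couplings off the dynamics preserve the uniform law", {
  cfg <- ks_config(grid_spacing = 50, n_tcr = 100, n_cd45 = 500, n_pmhc = 0,
                   rigidity = 0, u_rep = 0, u_adh = 0, tether_k = 0,
                   tcr_cluster_radius = Inf, corral_radius = Inf,
                   t_end = 10, sample_times = c(0, 10), log_every = 0,
                   seed = 11)
  traj <- run_ks(cfg)
  ctr <- cfg$patch_size / 2
  radial <- function(st) {
    m <- st$molecules
    sqrt((m$x - ctr)^2 + (m$y - ctr)^2)
  }
  p <- suppressWarnings(
    ks.test(radial(traj$states[[1]]), radial(traj$states[[2]])))$p.value
  expect_gt(p, 0.01)
})

test_that("depletion width recovers constructed gaps and degenerate cases", {
  set.seed(1)
  pp <- segregated_pattern(n_tcr = 2000, n_cd45 = 6000, tcr_radius = 200,
                           tcr_taper = Inf, depletion = 100,
                           cd45_width = 700)
  d <- depletion_width(pp)
  expect_lt(abs(d$width - 100), 25)
  # interleaved species: no depletion zone
  set.seed(2)
  mixed <- point_pattern(rep(c("TCR", "CD45"), each = 800),
                         x = runif(1600, 400, 1600),
                         y = runif(1600, 400, 1600))
  expect_lt(depletion_width(mixed)$width, 25)
  expect_error(depletion_width(pp[pp$species == "TCR", ]),
               class = "kinseg_insufficient_pattern")
})

test_that("depletion width grows with CD45 ectodomain height", {
  widths <- vapply(c(40, 70), function(hc) {
    mean(vapply(1:2, function(s) {
      cfg <- ks_config(n_tcr = 60, n_cd45 = 800, n_pmhc = 90, h_cd45 = hc,
                       boundary_height = hc, t_end = 30,
                       sample_times = c(0, 30), log_every = 0, seed = 20 + s)
      depletion_width(run_ks(cfg)$states[[2]])$width
    }, numeric(1)))
  }, numeric(1))
  expect_gt(widths[2], widths[1])
})

test_that("trajectory export flattens every sampled state", {
  cfg <- tiny_ks_config(seed = 3, t_end = 2, sample_times = c(0, 2))
  tab <- trajectory_table(run_ks(cfg))
  expect_s3_class(tab, "data.frame")
  expect_setequal(unique(tab$t_s), c(0, 2))
  expect_equal(nrow(tab), 2 * (cfg$n_tcr + cfg$n_cd45 + cfg$n_pmhc))
})
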