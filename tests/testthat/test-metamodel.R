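test_that("coupling validates structure and produces an acyclic graph", {
  s <- test_surrogates()
  expect_error(couple_metamodel(s$lcka, s$ks, s$ptcr),
               class = "kinseg_coupling_error")
  mm <- test_metamodel()
  expect_true(all(mm$sigma_c > 0))
  # Kahn-style peeling: the edge list must admit a topological order
  edges <- as.data.frame(mm$edges)
  nodes <- unique(c(edges$parent, edges$child))
  expect_equal(anyDuplicated(nodes), 0)
  remaining <- edges
  for (k in seq_along(nodes)) {
    roots <- setdiff(unique(c(remaining$parent, remaining$child)),
                     remaining$child)
    if (nrow(remaining) == 0) break
    expect_gt(length(roots), 0) # a cycle would leave no root
    remaining <- remaining[!(remaining$parent %in% roots), , drop = FALSE]
  }
  expect_equal(nrow(remaining), 0)
})

test_that("a vanishing coupling scale locks the coupled variables together", {
  s <- test_surrogates()
  mm <- couple_metamodel(s$ks, s$lcka, s$ptcr,
                         sigma_c = c(dep = 1e-6, dl = 1e-8))
  pr <- sample_metamodel_prior(mm, n = 2000, seed = 2)
  # compare where the parent lies inside the coupled model's support
  ok_dep <- pr$Dep_KS <= mm$support$dep[2]
  ok_dl <- pr$DL_LckA >= mm$support$dl[1] & pr$DL_LckA <= mm$support$dl[2]
  scale_dep <- diff(range(pr$Dep_KS))
  expect_lt(max(abs(pr$Dep_KS - pr$Dep_pTCR)[ok_dep]),
            1e-3 * max(scale_dep, 1))
  expect_lt(max(abs(log(pr$DL_LckA) - log(pr$DL_pTCR))[ok_dl]), 1e-3)
})

test_that("conditioning on nothing reproduces the prior predictive", {
  mm <- test_metamodel()
  post <- condition_metamodel(mm, obs = NULL, n_iter = 6000, burn = 2000,
                              n_chains = 2, seed = 8)
  prior <- sample_metamodel_prior(mm, n = 3000, seed = 9)
  thin <- post$draws[seq(1, nrow(post$draws), by = 48), ]
  for (v in c("t", "log10_diff", "Dep_KS")) {
    p <- suppressWarnings(ks.test(thin[[v]], prior[[v]]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("infinite observation noise washes out the data", {
  mm <- test_metamodel()
  post <- condition_metamodel(mm, c(phos = 0.22, rg = 1.31),
                              obs_noise = c(phos = 1e6, rg = 1e6),
                              n_iter = 6000, burn = 2000, n_chains = 2,
                              seed = 10)
  prior <- sample_metamodel_prior(mm, n = 3000, seed = 11)
  thin <- post$draws[seq(1, nrow(post$draws), by = 48), ]
  for (v in c("rigidity", "log10_p_off")) {
    p <- suppressWarnings(ks.test(thin[[v]], prior[[v]]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("conditioning shifts the upstream parameter marginals", {
  mm <- test_metamodel()
  post <- condition_metamodel(mm, c(phos = 0.22, rg = 1.31),
                              n_iter = 6000, burn = 2000, n_chains = 2,
                              seed = 12)
  prior <- sample_metamodel_prior(mm, n = 4000, seed = 13)
  # backpropagation: the Lck diffusion/off-rate marginals must move
  d_diff <- abs(mean(post$draws$log10_diff) - mean(prior$log10_diff))
  d_poff <- abs(mean(post$draws$log10_p_off) - mean(prior$log10_p_off))
  expect_gt(max(d_diff, d_poff), 0.3)
  ks_dl <- suppressWarnings(
    ks.test(post$draws$DL_LckA[seq(1, nrow(post$draws), 24)],
            prior$DL_LckA))
  expect_lt(ks_dl$p.value, 0.01)
})

test_that("the likelihood surface is a proportionality ridge in (diff, p_off)", {
  mm <- test_metamodel()
  # diagonal cells share log10(diff) - log10(p_off), i.e. one decay length;
  # the offset is chosen so the diagonal sits at DL ~ 45 nm
  grid <- list(log10_diff = seq(-3.2, -0.2, length.out = 7),
               log10_p_off = seq(-0.5, 2.5, length.out = 7))
  lmap <- likelihood_map(mm, c(phos = 0.22, rg = 1.31),
                         grid = grid, n_mc = 400, seed = 3)
  expect_true(all(is.finite(lmap$surface)))
  expect_true(all(lmap$surface >= 0))
  ridge <- mean(diag(lmap$surface))
  corners <- mean(c(lmap$surface[1, 7], lmap$surface[7, 1]))
  expect_gt(ridge, corners)
  expect_error(likelihood_map(mm, c(phos = 0.2, rg = 1.2),
                              var_pair = c("foo", "bar")),
               class = "kinseg_interface_error")
})

test_that("posterior summaries expose modes and intervals", {
  mm <- test_metamodel()
  post <- condition_metamodel(mm, c(phos = 0.22, rg = 1.31),
                              n_iter = 4000, burn = 1500, n_chains = 2,
                              seed = 14)
  s <- summary(post)
  expect_true(all(c("variable", "mean", "mode", "q5", "q95") %in% names(s)))
  expect_true(all(s$q5 <= s$q95))
  expect_equal(posterior_mode(c(rep(1, 5), 1.01, 5)), 1, tolerance = 0.2)
})
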