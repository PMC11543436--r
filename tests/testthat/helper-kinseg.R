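# Shared fixtures: everything is generated in code, scaled for test runtime.

# reduced membrane configuration for fast simulator tests
tiny_ks_config <- function(...) {
  args <- modifyList(list(grid_spacing = 50, n_tcr = 40, n_cd45 = 300,
                          n_pmhc = 60, t_end = 10, sample_times = c(0, 10),
                          log_every = 0), list(...))
  do.call(ks_config, args)
}

# minimal binding_series stand-in for the rule/metric operations
fake_series <- function(n_ptcr, dt = 1, u_assoc = 30, detach_time = NA) {
  m <- as.matrix(n_ptcr)
  structure(list(t = seq(0, by = dt, length.out = nrow(m)),
                 n_bound = apply(m, 1, max), n_ptcr = m,
                 detach_time = detach_time, u_assoc = u_assoc,
                 dl_grid = seq_len(ncol(m))),
            class = "binding_series")
}

# surrogate set at the resolution used throughout the metamodel tests;
# built once per test run (the kinetic-segregation grid dominates the cost)
.surr_cache <- new.env(parent = emptyenv())
test_surrogates <- function() {
  if (is.null(.surr_cache$set)) {
    gk <- build_training_grid("KS", n_replicates = 3, seed = 3)
    gl <- build_training_grid("LckA", n_replicates = 3, seed = 3)
    gp <- build_training_grid("pTCR", n_replicates = 3, seed = 3)
    .surr_cache$set <- list(
      grids = list(ks = gk, lcka = gl, ptcr = gp),
      ks = fit_surrogate(gk), lcka = fit_surrogate(gl),
      ptcr = fit_surrogate(gp))
  }
  .surr_cache$set
}

test_metamodel <- function() {
  s <- test_surrogates()
  couple_metamodel(s$ks, s$lcka, s$ptcr)
}

# Deterministic evaluation of the conditioned joint density, with the
# normal/lognormal chains collapsed analytically and the Dep_KS >= 0
# truncation carried as the half-line mass of the normal-normal product.
# Marginals are integrated on an oversampled internal grid and aggregated
# onto the coarse comparison bins, so the oracle carries integration bias
# well below the stated total-variation tolerance. Serves both as the exact
# posterior (mode assertions) and as the brute-force oracle the sampler is
# compared against.
enumerate_metamodel <- function(mm, obs, n_bins = 11, n_dl = 36, n_dep = 36,
                                over = 4) {
  mids <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
  t_edges <- seq(0, 100, length.out = n_bins + 1)
  ld_edges <- seq(-3.5, 1.5, length.out = n_bins + 1)
  t_g <- mids(seq(0, 100, length.out = n_bins * over + 1))
  r_g <- mids(seq(0, 100, length.out = 25))
  ld_g <- mids(seq(-3.5, 1.5, length.out = n_bins * over + 1))
  lp_g <- mids(seq(-2, 4, length.out = 25))
  fks <- kinseg:::.mm_fast_moment(mm$surrogates$ks, "width")
  flc <- kinseg:::.mm_fast_moment(mm$surrogates$lcka, "decay_length")
  fph <- kinseg:::.mm_fast_moment(mm$surrogates$ptcr, "phos")
  frg <- kinseg:::.mm_fast_moment(mm$surrogates$ptcr, "rg")
  on <- mm$obs_noise; sc <- mm$sigma_c
  dl_edges <- exp(seq(log(mm$support$dl[1]), log(mm$support$dl[2]),
                      length.out = n_dl + 1))
  dep_edges <- seq(0, mm$support$dep[2], length.out = n_dep + 1)
  dl_g <- exp(mids(seq(log(mm$support$dl[1]), log(mm$support$dl[2]),
                       length.out = n_dl * over + 1)))
  dep_g <- mids(seq(0, mm$support$dep[2], length.out = n_dep * over + 1))
  w_dl <- diff(exp(seq(log(mm$support$dl[1]), log(mm$support$dl[2]),
                       length.out = n_dl * over + 1)))

  gg <- expand.grid(dl = dl_g, dep = dep_g)
  ph <- fph(gg$dl, gg$dep); rg <- frg(gg$dl, gg$dep)
  gfac <- matrix(
    dnorm(obs[["phos"]], pmin(pmax(ph$mu, 0), 1),
          sqrt(ph$sd^2 + sc[["phos"]]^2 + on[["phos"]]^2)) *
      dnorm(obs[["rg"]], pmax(rg$mu, 0),
            sqrt(rg$sd^2 + sc[["rg"]]^2 + on[["rg"]]^2)),
    length(dl_g), length(dep_g))

  tr <- expand.grid(t = t_g, r = r_g)
  ksm <- fks(tr$t, tr$r)
  s2 <- ksm$sd^2; c2 <- 2 * sc[["dep"]]^2
  dep_lik <- vapply(seq_along(dep_g), function(j) {
    mu_post <- (ksm$mu / s2 + dep_g[j] / c2) / (1 / s2 + 1 / c2)
    sd_post <- sqrt(1 / (1 / s2 + 1 / c2))
    dnorm(dep_g[j], ksm$mu, sqrt(s2 + c2)) * pnorm(mu_post / sd_post)
  }, numeric(nrow(tr)))
  lg <- expand.grid(ld = ld_g, lp = lp_g)
  lcm <- flc(10^lg$ld, 10^lg$lp)
  dl_lik <- vapply(seq_along(dl_g), function(j)
    dlnorm(dl_g[j], lcm$mu, sqrt(lcm$sd^2 + 2 * sc[["dl"]]^2)),
    numeric(nrow(lg)))
  w_root_l <- dnorm(lg$ld, -1, 1) * dnorm(lg$lp, 1, 1)

  A <- colSums(dep_lik)           # prior-mixed Dep factor
  B <- colSums(dl_lik * w_root_l) # prior-mixed DL factor
  dens <- gfac * B %o% A          # joint density over (DL, Dep)
  W <- dens * w_dl                # cell masses (Dep cells are uniform)
  C_dep <- colSums(gfac * (B * w_dl))
  D_dl <- colSums(t(gfac) * A)
  w_t <- rowSums(matrix(dep_lik %*% C_dep, length(t_g), length(r_g)))
  w_ld <- rowSums(matrix((dl_lik * w_dl[col(dl_lik)]) %*% D_dl * w_root_l,
                         length(ld_g), length(lp_g)))
  jm <- which(dens == max(dens), arr.ind = TRUE)[1, ]
  agg <- function(v, k) colSums(matrix(v, nrow = k))
  list(dl_edges = dl_edges, dep_edges = dep_edges,
       t_edges = t_edges, ld_edges = ld_edges,
       dl_marg = agg(rowSums(W), over), dep_marg = agg(colSums(W), over),
       t_marg = agg(w_t, over), ld_marg = agg(w_ld, over),
       joint_mode = c(dl = dl_g[jm[1]], dep = dep_g[jm[2]]))
}
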