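#' Couple the three surrogates into a Bayesian metamodel
#'
#' Builds one joint probabilistic model over the variables of the three
#' partial-model surrogates by introducing coupling variables for the
#' quantities shared between models: the depletion width produced by the
#' kinetic-segregation model feeds the depletion input of the
#' phosphorylation model (`Dep_KS -> Dep_C -> Dep_pTCR`), the decay length
#' produced by the Lck-activation model feeds its decay-length input
#' (`DL_LckA -> DL_C -> DL_pTCR`), and the phosphorylation outputs map to
#' observable coupling variables (`Phos_pTCR -> Phos_C`, `Rg_pTCR -> Rg_C`).
#' Each coupling conditional is normal with scale `sigma_c`, which defaults
#' to 2% of the corresponding training-range span.
#'
#' @param ks,lcka,ptcr Fitted [fit_surrogate()] models with tags `"KS"`,
#'   `"LckA"`, `"pTCR"`.
#' @param sigma_c Optional named numeric overrides for the coupling scales
#'   (`dep`, `dl`, `phos`, `rg`).
#' @param obs_noise Observation noise SDs for the two observable coupling
#'   variables (`phos`, `rg`).
#' @return A `metamodel` object (surrogates, coupling scales, graph edges).
#' @export
couple_metamodel <- function(ks, lcka, ptcr, sigma_c = NULL,
                             obs_noise = c(phos = 0.03, rg = 0.1)) {
  tags <- c(ks$model_tag, lcka$model_tag, ptcr$model_tag)
  if (!identical(tags, c("KS", "LckA", "pTCR")))
    stop_kinseg("kinseg_coupling_error",
                "expected surrogates tagged KS, LckA, pTCR; got %s",
                paste(tags, collapse = ", "))
  span <- function(r) diff(range(r))
  sc <- c(dep = 0.02 * span(ks$response_ranges$width),
          dl = 0.02 * span(log(pmax(lcka$response_ranges$decay_length, 1))),
          phos = 0.02 * max(span(ptcr$response_ranges$phos), 0.5),
          rg = 0.02 * max(span(ptcr$response_ranges$rg), 0.5))
  if (!is.null(sigma_c)) sc[names(sigma_c)] <- sigma_c
  if (any(sc <= 0))
    stop_kinseg("kinseg_coupling_error", "coupling scales must be positive")
  edges <- rbind(
    c("t", "Dep_KS"), c("rigidity", "Dep_KS"),
    c("log10_diff", "DL_LckA"), c("log10_p_off", "DL_LckA"),
    c("Dep_KS", "Dep_C"), c("Dep_C", "Dep_pTCR"),
    c("DL_LckA", "DL_C"), c("DL_C", "DL_pTCR"),
    c("Dep_pTCR", "Phos_pTCR"), c("DL_pTCR", "Phos_pTCR"),
    c("Dep_pTCR", "Rg_pTCR"), c("DL_pTCR", "Rg_pTCR"),
    c("Phos_pTCR", "Phos_C"), c("Rg_pTCR", "Rg_C"))
  colnames(edges) <- c("parent", "child")
  # the pTCR conditionals are regressions: the joint model is defined on
  # (a modest buffer around) their training domain, never on extrapolations
  support <- list(
    dl = c(0.5 * min(ptcr$ranges$decay_length),
           2 * max(ptcr$ranges$decay_length)),
    dep = c(0, ptcr$priors$depletion$max))
  structure(list(surrogates = list(ks = ks, lcka = lcka, ptcr = ptcr),
                 sigma_c = sc, obs_noise = obs_noise, edges = edges,
                 support = support),
            class = "metamodel")
}

#' @export
print.metamodel <- function(x, ...) {
  cat("Bayesian metamodel over 3 coupled surrogates\n")
  cat(sprintf("  coupling scales: Dep %.3g nm, DL %.3g nm, Phos %.3g, Rg %.3g\n",
              x$sigma_c["dep"], x$sigma_c["dl"], x$sigma_c["phos"],
              x$sigma_c["rg"]))
  cat(sprintf("  %d edges, variables: %s\n", nrow(x$edges),
              paste(unique(c(x$edges)), collapse = ", ")))
  invisible(x)
}

# sampled coordinates of the joint model
.mm_vars <- c("t", "rigidity", "log10_diff", "log10_p_off",
              "Dep_KS", "DL_LckA", "Dep_pTCR", "DL_pTCR")

# surrogate conditional moments, vectorized over data frames
.mm_ks_pred <- function(mm, t, R) {
  predict(mm$surrogates$ks, data.frame(t = t, rigidity = R), "width")
}
.mm_lcka_pred <- function(mm, ld, lp) {
  predict(mm$surrogates$lcka, data.frame(diff = 10^ld, p_off = 10^lp),
          "decay_length")
}
.mm_ptcr_pred <- function(mm, dl, dep, response) {
  predict(mm$surrogates$ptcr,
          data.frame(decay_length = dl, depletion = dep), response)
}

# lightweight moment evaluators (no data-frame plumbing) for the sampler
.mm_fast_moment <- function(surr, response) {
  fit <- surr$fits[[response]]
  tag <- surr$model_tag
  scal <- surr$scalers
  function(x1, x2) {
    X <- cbind(x1, x2)
    B <- .surrogate_basis(tag, .surrogate_coords(tag, X, scal), surr$degree)
    mu <- drop(B %*% fit$coef)
    pv <- fit$s2 * (1 + rowSums((B %*% fit$Vn) * B))
    if (fit$transform == "logit") {
      m <- stats::plogis(mu)
      list(mu = m, sd = sqrt(pv) * m * (1 - m))
    } else list(mu = mu, sd = sqrt(pv)) # "log" fits return log-scale moments
  }
}

# log joint density of theta (unnamed numeric in .mm_vars order) and
# observations; f* are the fast moment closures built once per run
.mm_logpost <- function(mm, th, obs, obs_noise, fks, flc, fph, frg) {
  pks <- mm$surrogates$ks$priors
  if (th[1] < pks$t$min || th[1] > pks$t$max) return(-Inf)
  if (th[2] < pks$rigidity$min || th[2] > pks$rigidity$max) return(-Inf)
  if (th[5] < 0 || th[6] <= 0 || th[7] < 0 || th[8] <= 0) return(-Inf)
  if (th[7] > mm$support$dep[2] || th[8] < mm$support$dl[1] ||
      th[8] > mm$support$dl[2]) return(-Inf)
  pl <- mm$surrogates$lcka$priors
  lp <- dnorm(th[3], pl$log10_diff$mean, pl$log10_diff$sd, log = TRUE) +
        dnorm(th[4], pl$log10_p_off$mean, pl$log10_p_off$sd, log = TRUE)
  ks <- fks(th[1], th[2])
  lp <- lp + dnorm(th[5], ks$mu, ks$sd, log = TRUE)
  lc <- flc(10^th[3], 10^th[4]) # moments of log decay length
  lp <- lp + dnorm(log(th[6]), lc$mu, lc$sd, log = TRUE) - log(th[6])
  # two coupling steps collapse to one normal with variance 2 sigma_c^2;
  # the decay length couples on the log scale
  lp <- lp + dnorm(th[7], th[5], sqrt(2) * mm$sigma_c[["dep"]], log = TRUE)
  lp <- lp + dnorm(log(th[8]), log(th[6]), sqrt(2) * mm$sigma_c[["dl"]],
                   log = TRUE) - log(th[8])
  if (!is.null(obs)) {
    ph <- fph(th[8], th[7])
    rg <- frg(th[8], th[7])
    lp <- lp + dnorm(obs[["phos"]], min(max(ph$mu, 0), 1),
                     sqrt(ph$sd^2 + mm$sigma_c[["phos"]]^2 +
                            obs_noise[["phos"]]^2), log = TRUE)
    lp <- lp + dnorm(obs[["rg"]], max(rg$mu, 0),
                     sqrt(rg$sd^2 + mm$sigma_c[["rg"]]^2 +
                            obs_noise[["rg"]]^2), log = TRUE)
  }
  unname(lp)
}

#' Condition the metamodel on observed coupling variables
#'
#' Draws posterior samples over all metamodel variables given observed values
#' of the phosphorylated fraction and Rg ratio (the observable coupling
#' variables), by adaptive random-walk Metropolis over
#' (t, rigidity, log10 diff, log10 p_off, Dep_KS, DL_LckA, Dep_pTCR,
#' DL_pTCR). The posterior is proportional to the data likelihood times the
#' root-variable priors; information flows against the edge direction into
#' the upstream simulator parameters (backpropagation).
#'
#' @param metamodel A [couple_metamodel()] object.
#' @param obs Named numeric: `phos` (fraction in `[0, 1]`) and `rg` (> 0).
#'   `NULL` samples the joint prior (no conditioning).
#' @param obs_noise Optional override of the observation-noise SDs.
#' @param n_iter Iterations per chain (after burn-in, thinned draws are
#'   returned).
#' @param n_chains Independent chains (used for the split-chain scale
#'   reduction diagnostic).
#' @param burn Burn-in iterations per chain (also the adaptation window).
#' @param seed Integer seed.
#' @return A `metamodel_posterior`: `draws` (data frame over the sampled
#'   variables plus derived coupling variables), `diagnostics` (R-hat per
#'   variable, acceptance rate), and provenance (priors, scales, seed).
#' @export
condition_metamodel <- function(metamodel, obs = c(phos = 0.22, rg = 1.31),
                                obs_noise = NULL, n_iter = 8000,
                                n_chains = 3, burn = 3000, seed = 1L) {
  if (!is.null(obs)) {
    if (obs["phos"] < 0 || obs["phos"] > 1 || obs["rg"] <= 0)
      stop_kinseg("kinseg_invalid_config",
                  "obs must satisfy 0 <= phos <= 1 and rg > 0")
  }
  on <- metamodel$obs_noise
  if (!is.null(obs_noise)) on[names(obs_noise)] <- obs_noise
  set.seed(seed)
  chains <- vector("list", n_chains)
  acc_all <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    res <- .mm_mcmc(metamodel, obs, on, n_iter = n_iter, burn = burn)
    chains[[ch]] <- res$draws
    acc_all[ch] <- res$acc
  }
  draws <- do.call(rbind, chains)
  rhat <- vapply(seq_along(.mm_vars), function(j) {
    .split_rhat(lapply(chains, function(d) d[, j]))
  }, numeric(1))
  names(rhat) <- .mm_vars
  draws <- as.data.frame(draws)
  names(draws) <- .mm_vars
  # derived coupling variables (midpoints of the two-step normal chain)
  draws$Dep_C <- (draws$Dep_KS + draws$Dep_pTCR) / 2
  draws$DL_C <- exp((log(draws$DL_LckA) + log(draws$DL_pTCR)) / 2)
  out <- list(draws = draws, diagnostics = list(rhat = rhat,
                                                acceptance = mean(acc_all)),
              obs = obs, obs_noise = on, sigma_c = metamodel$sigma_c,
              n_chains = n_chains, seed = seed)
  class(out) <- "metamodel_posterior"
  if (any(is.finite(rhat) & rhat > 1.05))
    warning(sprintf("sampler convergence diagnostic exceeded 1.05 for: %s",
                    paste(names(rhat)[rhat > 1.05], collapse = ", ")))
  out
}

.mm_init <- function(mm) {
  th <- c(t = 50, rigidity = 50, log10_diff = -1, log10_p_off = 1,
          Dep_KS = NA, DL_LckA = NA, Dep_pTCR = NA, DL_pTCR = NA)
  dep <- min(max(.mm_ks_pred(mm, th["t"], th["rigidity"])$mean, 1),
             0.9 * mm$support$dep[2])
  # the log-scale median stays inside the support where the mean may not
  dl <- exp(.mm_lcka_pred(mm, th["log10_diff"], th["log10_p_off"])$log_mean)
  dl <- min(max(dl, 1.2 * mm$support$dl[1]), mm$support$dl[2] / 1.2)
  th["Dep_KS"] <- dep
  th["DL_LckA"] <- dl
  th["Dep_pTCR"] <- dep
  th["DL_pTCR"] <- dl
  th
}

.mm_mcmc <- function(mm, obs, obs_noise, n_iter, burn) {
  fks <- .mm_fast_moment(mm$surrogates$ks, "width")
  flc <- .mm_fast_moment(mm$surrogates$lcka, "decay_length")
  fph <- .mm_fast_moment(mm$surrogates$ptcr, "phos")
  frg <- .mm_fast_moment(mm$surrogates$ptcr, "rg")
  lpost <- function(th) .mm_logpost(mm, th, obs, obs_noise, fks, flc, fph, frg)
  th <- unname(.mm_init(mm))
  d <- length(th)
  # 8 componentwise scales plus two pair moves that shift the tightly
  # coupled (Dep_KS, Dep_pTCR) and (DL_LckA, DL_pTCR) chains together --
  # without them the coupled pairs random-walk at the coupling scale
  scales <- c(10, 10, 0.3, 0.3, max(th[5] * 0.2, 5), max(th[6] * 0.2, 5),
              max(th[7] * 0.2, 5), max(th[8] * 0.2, 5), 25, 0.4)
  n_moves <- length(scales)
  lp <- lpost(th)
  if (!is.finite(lp)) { # nudge the start until the density is finite
    for (k in 1:100) {
      th2 <- th * exp(rnorm(d, 0, 0.2))
      th2[1] <- runif(1, 0, 100); th2[2] <- runif(1, 0, 100)
      lp2 <- lpost(th2)
      if (is.finite(lp2)) { th <- th2; lp <- lp2; break }
    }
    if (!is.finite(lp))
      stop_kinseg("kinseg_fit_error",
                  "could not find a starting point with finite density")
  }
  keep <- matrix(NA_real_, n_iter, d)
  acc <- 0
  win_acc <- numeric(n_moves); win_n <- 0
  for (it in seq_len(burn + n_iter)) {
    for (j in seq_len(n_moves)) {
      prop <- th
      jac <- 0
      if (j <= d) { # componentwise random walk
        prop[j] <- th[j] + rnorm(1) * scales[j]
      } else if (j == d + 1) { # joint depletion shift
        dd <- rnorm(1) * scales[j]
        prop[5] <- th[5] + dd; prop[7] <- th[7] + dd
      } else { # joint multiplicative decay-length shift
        f <- rnorm(1) * scales[j]
        prop[6] <- th[6] * exp(f); prop[8] <- th[8] * exp(f)
        jac <- 2 * f # log-Jacobian of the multiplicative proposal
      }
      lp2 <- lpost(prop)
      if (is.finite(lp2) && log(runif(1)) < lp2 - lp + jac) {
        th <- prop; lp <- lp2
        win_acc[j] <- win_acc[j] + 1
        if (it > burn) acc <- acc + 1
      }
    }
    win_n <- win_n + 1
    if (it <= burn && win_n == 50) { # adapt toward ~40% per-move
      scales <- scales * exp(0.8 * (win_acc / win_n - 0.4))
      win_acc[] <- 0; win_n <- 0
    }
    if (it > burn) keep[it - burn, ] <- th
  }
  list(draws = keep, acc = acc / (n_iter * n_moves))
}

# split-chain potential scale reduction
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    m <- length(v) %/% 2
    list(v[seq_len(m)], v[m + seq_len(m)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.metamodel_posterior <- function(x, ...) {
  cat(sprintf("metamodel_posterior: %d draws (%d chains), acceptance %.2f\n",
              nrow(x$draws), x$n_chains, x$diagnostics$acceptance))
  if (!is.null(x$obs))
    cat(sprintf("  conditioned on Phos = %g, Rg = %g\n", x$obs["phos"],
                x$obs["rg"]))
  cat(sprintf("  max R-hat = %.3f\n", max(x$diagnostics$rhat, na.rm = TRUE)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.metamodel_posterior <- function(object, ...) {
  vars <- names(object$draws)
  data.frame(
    variable = vars,
    mean = vapply(object$draws, mean, numeric(1)),
    mode = vapply(object$draws, posterior_mode, numeric(1)),
    q5 = vapply(object$draws, quantile, numeric(1), probs = 0.05),
    q95 = vapply(object$draws, quantile, numeric(1), probs = 0.95),
    row.names = NULL)
}

#' @export
plot.metamodel_posterior <- function(x, vars = c("DL_pTCR", "Dep_pTCR"), ...) {
  old <- par(mfrow = c(1, length(vars)))
  on.exit(par(old))
  for (v in vars) {
    d <- density(x$draws[[v]])
    plot(d, main = v, xlab = v, ...)
    abline(v = posterior_mode(x$draws[[v]]), col = "red3", lty = 2)
  }
  invisible(x)
}

#' Kernel-density mode of a sample
#'
#' @param x Numeric vector of draws.
#' @param ... Passed to [stats::density()].
#' @return The location of the maximum of the kernel density estimate.
#' @export
posterior_mode <- function(x, ...) {
  d <- density(x, ...)
  d$x[which.max(d$y)]
}

#' Likelihood surface over a pair of model inputs
#'
#' Evaluates `p(obs | pair)` on a grid, marginalizing all other variables by
#' forward Monte-Carlo from the priors and conditionals.
#'
#' @param metamodel A [couple_metamodel()] object.
#' @param obs Named observation vector (`phos`, `rg`).
#' @param var_pair Two root-variable names among `t`, `rigidity`,
#'   `log10_diff`, `log10_p_off`.
#' @param grid Named list with the two axis vectors.
#' @param n_mc Monte-Carlo draws per cell.
#' @param seed Integer seed.
#' @return A list with the axes and the likelihood `surface` matrix
#'   (rows: first axis).
#' @export
likelihood_map <- function(metamodel, obs, var_pair = c("log10_diff",
                                                        "log10_p_off"),
                           grid = NULL, n_mc = 400, seed = 1L) {
  roots <- c("t", "rigidity", "log10_diff", "log10_p_off")
  if (!all(var_pair %in% roots))
    stop_kinseg("kinseg_interface_error",
                "var_pair must be two of: %s", paste(roots, collapse = ", "))
  if (is.null(grid))
    grid <- setNames(list(seq(-2, 0, length.out = 11),
                          seq(-1, 2, length.out = 11)), var_pair)
  set.seed(seed)
  surface <- matrix(NA_real_, length(grid[[1]]), length(grid[[2]]))
  for (i in seq_along(grid[[1]])) {
    for (j in seq_along(grid[[2]])) {
      fixed <- setNames(c(grid[[1]][i], grid[[2]][j]), var_pair)
      surface[i, j] <- .mm_forward_lik(metamodel, obs, fixed, n_mc)
    }
  }
  list(axes = grid, surface = surface, obs = obs, var_pair = var_pair)
}

# one forward pass through the joint model; roots in `fixed` are pinned
.mm_forward_draw <- function(mm, n, fixed = NULL) {
  pks <- mm$surrogates$ks$priors
  pl <- mm$surrogates$lcka$priors
  pin <- function(name, draw) {
    if (!is.null(fixed) && name %in% names(fixed)) rep(fixed[[name]], n)
    else draw
  }
  t <- pin("t", runif(n, pks$t$min, pks$t$max))
  R <- pin("rigidity", runif(n, pks$rigidity$min, pks$rigidity$max))
  ld <- pin("log10_diff", rnorm(n, pl$log10_diff$mean, pl$log10_diff$sd))
  lp <- pin("log10_p_off", rnorm(n, pl$log10_p_off$mean, pl$log10_p_off$sd))
  ks <- .mm_ks_pred(mm, t, R)
  dep_ks <- rnorm(n, ks$mean, ks$sd)
  lc <- .mm_lcka_pred(mm, ld, lp)
  dl_lcka <- exp(rnorm(n, lc$log_mean, lc$log_sd))
  dep_p <- rnorm(n, dep_ks, sqrt(2) * mm$sigma_c[["dep"]])
  dl_p <- exp(rnorm(n, log(dl_lcka), sqrt(2) * mm$sigma_c[["dl"]]))
  data.frame(t = t, rigidity = R, log10_diff = ld, log10_p_off = lp,
             Dep_KS = dep_ks, DL_LckA = dl_lcka, Dep_pTCR = dep_p,
             DL_pTCR = dl_p)
}

# joint-rejection forward sampler: rows outside the model support are
# redrawn wholesale, the same truncation the conditioned density applies
.mm_forward_sample <- function(mm, n, fixed = NULL, max_rounds = 200) {
  d <- .mm_forward_draw(mm, n, fixed)
  for (k in seq_len(max_rounds)) {
    bad <- which(d$Dep_KS < 0 | d$Dep_pTCR < 0 |
                   d$Dep_pTCR > mm$support$dep[2] |
                   d$DL_pTCR < mm$support$dl[1] |
                   d$DL_pTCR > mm$support$dl[2])
    if (length(bad) == 0) break
    d[bad, ] <- .mm_forward_draw(mm, length(bad), fixed)
  }
  d
}

# Monte-Carlo estimate of p(obs | fixed root values)
.mm_forward_lik <- function(mm, obs, fixed, n_mc) {
  d <- .mm_forward_sample(mm, n_mc, fixed)
  ph <- .mm_ptcr_pred(mm, d$DL_pTCR, d$Dep_pTCR, "phos")
  rg <- .mm_ptcr_pred(mm, d$DL_pTCR, d$Dep_pTCR, "rg")
  lik <- dnorm(obs["phos"], pmin(pmax(ph$mean, 0), 1),
               sqrt(ph$sd^2 + mm$sigma_c["phos"]^2 +
                      mm$obs_noise["phos"]^2)) *
         dnorm(obs["rg"], pmax(rg$mean, 0),
               sqrt(rg$sd^2 + mm$sigma_c["rg"]^2 + mm$obs_noise["rg"]^2))
  mean(lik)
}

#' Prior-predictive (unconditioned) samples of the metamodel
#'
#' Forward-samples the joint model with no observations attached; useful as
#' the reference against which conditioning is compared.
#'
#' @param metamodel A [couple_metamodel()] object.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Data frame of draws over the metamodel variables.
#' @export
sample_metamodel_prior <- function(metamodel, n = 4000, seed = 1L) {
  set.seed(seed)
  .mm_forward_sample(metamodel, n)
}
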