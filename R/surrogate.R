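#' Training grid for a partial-model surrogate
#'
#' Runs one of the three partial models over a factorial grid of its inputs,
#' with seeded replicates per cell, and records the model outputs:
#' * `"KS"`: depletion width (nm) over time `t` (s) x membrane rigidity `R`
#'   (kT nm^2). One simulation per (rigidity, replicate) yields the whole
#'   time row.
#' * `"LckA"`: fitted Lck* decay length (nm) over diffusion coefficient
#'   (um^2/s) x deactivation rate (1/s), both usually log-spaced.
#' * `"pTCR"`: Phos fraction and Rg ratio over Lck* decay length (nm) x
#'   depletion width (nm), evaluated on the idealized segregated geometry
#'   ([segregated_pattern()]).
#'
#' @param model_tag `"KS"`, `"LckA"` or `"pTCR"`.
#' @param axes Named list of two strictly increasing axis vectors:
#'   `list(t=, rigidity=)`, `list(diff=, p_off=)`, or
#'   `list(decay_length=, depletion=)`. Defaults cover the documented sweep
#'   ranges.
#' @param n_replicates Replicates per cell.
#' @param seed Integer seed; every cell derives its own stream.
#' @param config Base [ks_config()] for the KS model.
#' @param walk Named list of [run_walk()] settings for the LckA model
#'   (`n_walkers`, `n_steps`, `dt`).
#' @param geometry Named list for the pTCR model geometry (`n_tcr`, `n_cd45`,
#'   `tcr_radius`, `cd45_width`, `patch_size`).
#' @return A `training_grid`: data frame `cells` (axis values, replicate,
#'   outputs, `flagged`), plus metadata.
#' @export
#' @examples
#' g <- build_training_grid("pTCR",
#'   axes = list(decay_length = c(20, 70, 250), depletion = c(20, 100)),
#'   n_replicates = 2, seed = 1)
#' g
build_training_grid <- function(model_tag = c("KS", "LckA", "pTCR"),
                                axes = NULL, n_replicates = 5, seed = 1L,
                                config = NULL, walk = list(), geometry = list()) {
  model_tag <- match.arg(model_tag)
  axes <- .default_axes(model_tag, axes)
  if (any(vapply(axes, function(a) any(diff(a) <= 0), logical(1))))
    stop_kinseg("kinseg_invalid_config", "axes must be strictly increasing")
  an <- names(axes)
  cells <- expand.grid(a1 = axes[[1]], a2 = axes[[2]],
                       replicate = seq_len(n_replicates))
  names(cells)[1:2] <- an
  out <- switch(model_tag,
    KS = .grid_ks(axes, n_replicates, seed, config),
    LckA = .grid_lcka(cells, seed, walk),
    pTCR = .grid_ptcr(cells, seed, geometry))
  structure(list(cells = out$cells, model_tag = model_tag, axes = axes,
                 responses = out$responses, n_replicates = n_replicates,
                 seed = seed),
            class = "training_grid")
}

.default_axes <- function(model_tag, axes) {
  if (!is.null(axes)) return(axes)
  switch(model_tag,
    KS = list(t = c(0, 5, 10, 20, 50, 100), rigidity = seq(0, 100, by = 20)),
    LckA = list(diff = 10^seq(-2, 0, length.out = 5),
                p_off = 10^seq(-1, 2, length.out = 5)),
    pTCR = list(decay_length = round(exp(seq(log(20), log(1500),
                                             length.out = 10))),
                depletion = c(20, 60, 100, 140, 180, 220)))
}

.grid_ks <- function(axes, n_replicates, seed, config) {
  if (is.null(config)) config <- ks_config()
  rows <- list()
  for (R in axes[[2]]) {
    for (rep in seq_len(n_replicates)) {
      cfg <- config
      cfg$rigidity <- R
      cfg$sample_times <- axes[[1]]
      cfg$t_end <- max(axes[[1]])
      cfg$seed <- as.integer((seed * 211L + R * 17L + rep * 7919L) %%
                               .Machine$integer.max)
      row <- tryCatch({
        traj <- run_ks(cfg)
        w <- vapply(traj$states, function(s) depletion_width(s)$width,
                    numeric(1))
        data.frame(t = axes[[1]], rigidity = R, replicate = rep, width = w,
                   flagged = FALSE)
      }, error = function(e) {
        data.frame(t = axes[[1]], rigidity = R, replicate = rep,
                   width = NA_real_, flagged = TRUE)
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  names(rows) <- NULL
  cells <- do.call(rbind, rows)
  list(cells = cells, responses = "width")
}

.grid_lcka <- function(cells, seed, walk) {
  wk <- modifyList(list(n_walkers = 1000, n_steps = 1000, dt = 0.01), walk)
  cells$decay_length <- NA_real_
  cells$flagged <- FALSE
  for (i in seq_len(nrow(cells))) {
    res <- tryCatch({
      w <- run_walk(cells$diff[i], cells$p_off[i], n_walkers = wk$n_walkers,
                    n_steps = wk$n_steps, dt = wk$dt,
                    seed = (seed * 131L + i * 9973L) %% .Machine$integer.max)
      fit_decay_length(w)$decay_length
    }, error = function(e) NA_real_)
    # a non-decaying histogram yields an absurd fitted length: flag the cell
    # as a failed fit rather than letting it poison the log-scale regression
    if (is.finite(res) && res > 1e6) res <- NA_real_
    cells$decay_length[i] <- res
    cells$flagged[i] <- is.na(res)
  }
  list(cells = cells, responses = "decay_length")
}

.grid_ptcr <- function(cells, seed, geometry) {
  geo <- modifyList(list(n_tcr = 100, n_cd45 = 1200, tcr_radius = 250,
                         cd45_width = 750, patch_size = 2000), geometry)
  cells$phos <- NA_real_
  cells$rg <- NA_real_
  cells$flagged <- FALSE
  for (i in seq_len(nrow(cells))) {
    res <- tryCatch({
      set.seed((seed * 389L + i * 104729L) %% .Machine$integer.max)
      pp <- segregated_pattern(n_tcr = geo$n_tcr, n_cd45 = geo$n_cd45,
                               tcr_radius = geo$tcr_radius,
                               depletion = cells$depletion[i],
                               cd45_width = max(100, geo$cd45_width -
                                                  cells$depletion[i]),
                               patch_size = geo$patch_size)
      ph <- assign_phosphorylation(pp, pp,
        phos_config(decay_length = cells$decay_length[i],
                    seed = (seed * 389L + i * 104729L + 1L) %%
                      .Machine$integer.max))
      c(ph$phos, if (ph$rg_defined) ph$rg_ratio else NA_real_)
    }, error = function(e) c(NA_real_, NA_real_))
    cells$phos[i] <- res[1]
    cells$rg[i] <- res[2]
    cells$flagged[i] <- is.na(res[1])
  }
  list(cells = cells, responses = c("phos", "rg"))
}

#' @export
print.training_grid <- function(x, ...) {
  cat(sprintf("training_grid (%s): %d x %d cells, %d replicates, responses: %s\n",
              x$model_tag, length(x$axes[[1]]), length(x$axes[[2]]),
              x$n_replicates, paste(x$responses, collapse = ", ")))
  cat(sprintf("  flagged cells: %d / %d\n", sum(x$cells$flagged),
              nrow(x$cells)))
  invisible(x)
}

#' Aggregate a training grid to per-cell mean and SD
#'
#' @param grid A `training_grid`.
#' @return Data frame with the two axes and, per response, `<resp>_mean` and
#'   `<resp>_sd`.
#' @export
grid_summary <- function(grid) {
  an <- names(grid$axes)
  ok <- !grid$cells$flagged
  f <- stats::as.formula(paste("cbind(", paste(grid$responses, collapse = ","),
                               ") ~", paste(an, collapse = "+")))
  m <- aggregate(f, data = grid$cells[ok, ],
                 FUN = function(v) mean(v, na.rm = TRUE),
                 na.action = stats::na.pass)
  s <- aggregate(f, data = grid$cells[ok, ],
                 FUN = function(v) sd(v[is.finite(v)]),
                 na.action = stats::na.pass)
  for (r in grid$responses) {
    names(m)[names(m) == r] <- paste0(r, "_mean")
    names(s)[names(s) == r] <- paste0(r, "_sd")
  }
  merge(m, s, by = an)
}

# basis evaluation per model family; KS inputs arrive standardized
.surrogate_basis <- function(model_tag, X, degree) {
  if (model_tag == "LckA") {
    # scaling-law basis: u = (log diff - log p_off) / 2
    u <- (log(X[, 1]) - log(X[, 2])) / 2
    B <- outer(u, 0:degree, `^`)
    colnames(B) <- paste0("u^", 0:degree)
    return(B)
  }
  if (model_tag == "pTCR") {
    # kernel-informed features: the log summed exponential kernel at a TCR a
    # distance ~Dep from the CD45 front behaves like
    # const + 2 log DL - Dep/DL - c/DL
    dl <- X[, 1]; dep <- X[, 2]
    B <- cbind(1, log(dl), dep / 100, dep / dl, 100 / dl,
               (dep / dl)^2, (100 / dl)^2)
    colnames(B) <- c("1", "logDL", "Dep", "Dep/DL", "1/DL", "(Dep/DL)^2",
                     "(1/DL)^2")
    return(B)
  }
  x <- X[, 1]; y <- X[, 2]
  terms <- list(`1` = rep(1, length(x)))
  for (i in 0:degree) for (j in 0:degree)
    if (i + j > 0 && i + j <= degree)
      terms[[paste0("x", i, "y", j)]] <- x^i * y^j
  B <- do.call(cbind, terms)
  B
}

# map raw inputs to the coordinates used by the basis (KS standardizes;
# LckA and pTCR bases work on raw inputs)
.surrogate_coords <- function(model_tag, inputs, scal) {
  X <- as.matrix(inputs)
  if (model_tag != "KS") return(X)
  x <- log1p(X[, 1] / 5) # time saturates; log placement
  y <- X[, 2]
  cbind((x - scal$mx) / scal$sx, (y - scal$my) / scal$sy)
}

#' Fit a probabilistic surrogate to a training grid
#'
#' For each output of the partial model, fits a Bayesian linear regression of
#' the response on a low-order polynomial basis of the inputs (conjugate
#' normal-inverse-gamma posterior, fitted exactly): the KS surrogate uses a
#' polynomial in (log-placed time, rigidity); the LckA surrogate regresses
#' log decay length on powers of `(log diff - log p_off)/2`, the basis implied
#' by the diffusion-limited scaling law; the pTCR surrogate uses a polynomial
#' in (log decay length, depletion). Each root input variable carries an
#' explicit prior wide enough to cover the training axes; together with the
#' fitted conditionals this forms a directed probabilistic model (inputs ->
#' outputs).
#'
#' @param grid A [build_training_grid()] result (at least 80% of cells
#'   unflagged).
#' @param degree Polynomial degree of the mean function for the KS and LckA
#'   surrogates (default 2). The pTCR surrogate instead uses a fixed
#'   kernel-informed feature basis (log decay length, depletion, their
#'   kernel-implied ratios) on which its logit-scale Phos response is
#'   near-linear; `degree` is ignored there.
#' @param priors Optional named list overriding the root-variable prior
#'   specifications.
#' @return A `surrogate_model` with fitted coefficient posteriors, noise
#'   scales, root priors, training ranges and fit diagnostics (training R^2
#'   and leave-one-out 95% coverage per response).
#' @export
fit_surrogate <- function(grid, degree = 2, priors = NULL) {
  ok <- !grid$cells$flagged
  if (mean(ok) < 0.8)
    stop_kinseg("kinseg_fit_error",
                "more than 20%% of training cells are flagged")
  an <- names(grid$axes)
  X <- as.matrix(grid$cells[ok, an])
  scal <- NULL
  if (grid$model_tag == "KS") {
    x <- log1p(X[, 1] / 5)
    y <- X[, 2]
    scal <- list(mx = mean(x), sx = max(sd(x), 1e-9),
                 my = mean(y), sy = max(sd(y), 1e-9))
  }
  B <- .surrogate_basis(grid$model_tag,
                        .surrogate_coords(grid$model_tag, X, scal), degree)
  fits <- list()
  for (resp in grid$responses) {
    yv <- grid$cells[ok, resp]
    transform <- "identity"
    if (grid$model_tag == "LckA") {
      yv <- log(yv)
      transform <- "log"
    } else if (resp == "phos") {
      # the saturating fraction is near-linear on the logit scale
      yv <- stats::qlogis(pmin(pmax(yv, 0.002), 0.998))
      transform <- "logit"
    }
    keep <- is.finite(yv)
    fits[[resp]] <- c(.blr_fit(B[keep, , drop = FALSE], yv[keep]),
                      list(transform = transform))
  }
  pri <- .default_priors(grid$model_tag, grid)
  if (!is.null(priors)) pri <- modifyList(pri, priors)
  structure(list(model_tag = grid$model_tag, input_names = an,
                 responses = grid$responses, fits = fits, degree = degree,
                 scalers = scal, priors = pri,
                 ranges = lapply(grid$axes, range),
                 response_ranges = lapply(
                   grid$responses,
                   function(r) range(grid$cells[ok, r], na.rm = TRUE)) |>
                   setNames(grid$responses),
                 grid_seed = grid$seed),
            class = "surrogate_model")
}

# conjugate normal-inverse-gamma Bayesian linear regression
.blr_fit <- function(B, y, g = 100, a0 = 0.01, b0 = 0.01) {
  p <- ncol(B)
  V0i <- diag(1 / g, p)
  Vni <- V0i + crossprod(B)
  Vn <- solve(Vni)
  bn <- Vn %*% crossprod(B, y)
  an <- a0 + length(y) / 2
  bnig <- b0 + 0.5 * (sum(y^2) - t(bn) %*% Vni %*% bn)[1, 1]
  s2 <- bnig / (an - 1) # posterior-mean noise variance
  fitted <- drop(B %*% bn)
  # analytic leave-one-out via the hat matrix (coverage diagnostic)
  h <- pmin(rowSums((B %*% Vn) * B), 0.99)
  loo_res <- (y - fitted) / (1 - h)
  loo_sd <- sqrt(s2 / (1 - h))
  cover <- mean(abs(loo_res) <= qt(0.975, df = 2 * an) * loo_sd)
  list(coef = drop(bn), Vn = Vn, a = an, b = bnig, s2 = s2,
       r2 = 1 - var(y - fitted) / var(y), loo_coverage = cover)
}

.default_priors <- function(model_tag, grid) {
  switch(model_tag,
    KS = list(t = list(dist = "uniform", min = 0, max = 100, unit = "s"),
              rigidity = list(dist = "uniform", min = 0, max = 100,
                              unit = "kT nm^2")),
    LckA = list(log10_diff = list(dist = "normal", mean = -1, sd = 1,
                                  unit = "log10 um^2/s"),
                log10_p_off = list(dist = "normal", mean = 1, sd = 1,
                                   unit = "log10 1/s")),
    pTCR = list(decay_length = list(dist = "lognormal",
                                    meanlog = log(sqrt(20 * 5000)),
                                    sdlog = (log(5000) - log(20)) / 4,
                                    unit = "nm"),
                depletion = list(dist = "uniform", min = 0,
                                 max = 1.2 * max(grid$axes[[2]]),
                                 unit = "nm")))
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("surrogate_model (%s): %s -> %s\n", x$model_tag,
              paste(x$input_names, collapse = " x "),
              paste(x$responses, collapse = ", ")))
  for (r in x$responses)
    cat(sprintf("  %s: R^2 = %.3f, noise sd = %.3g, LOO 95%% coverage = %.2f\n",
                r, x$fits[[r]]$r2, sqrt(x$fits[[r]]$s2),
                x$fits[[r]]$loo_coverage))
  invisible(x)
}

#' @export
coef.surrogate_model <- function(object, response = object$responses[1], ...) {
  object$fits[[response]]$coef
}

#' Predictive mean and SD of a surrogate
#'
#' @param object A `surrogate_model`.
#' @param newdata Data frame (or matrix) with the surrogate's input columns.
#' @param response Which output to predict (default: first).
#' @param ... Unused.
#' @return Data frame with `mean`, `sd` (predictive, on the response scale)
#'   and `extrapolated` (input outside the training box).
#' @export
predict.surrogate_model <- function(object, newdata,
                                    response = object$responses[1], ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$input_names, drop = FALSE])
  fit <- object$fits[[response]]
  if (is.null(fit))
    stop_kinseg("kinseg_interface_error", "unknown response '%s'", response)
  B <- .surrogate_basis(object$model_tag,
                        .surrogate_coords(object$model_tag, X, object$scalers),
                        object$degree)
  mu <- drop(B %*% fit$coef)
  pv <- fit$s2 * (1 + rowSums((B %*% fit$Vn) * B))
  extra <- rep(FALSE, nrow(X))
  for (k in seq_along(object$input_names)) {
    rng <- object$ranges[[object$input_names[k]]]
    extra <- extra | X[, k] < rng[1] | X[, k] > rng[2]
  }
  if (fit$transform == "log")
    data.frame(mean = exp(mu + pv / 2),
               sd = sqrt((exp(pv) - 1) * exp(2 * mu + pv)),
               log_mean = mu, log_sd = sqrt(pv), extrapolated = extra)
  else if (fit$transform == "logit") {
    m <- stats::plogis(mu)
    data.frame(mean = m, sd = sqrt(pv) * m * (1 - m), # delta method
               link_mean = mu, link_sd = sqrt(pv), extrapolated = extra)
  } else
    data.frame(mean = mu, sd = sqrt(pv), extrapolated = extra)
}

#' @rdname predict.surrogate_model
#' @param model A `surrogate_model`.
#' @param inputs Data frame of input values.
#' @export
surrogate_predict <- function(model, inputs, response = model$responses[1]) {
  predict(model, newdata = inputs, response = response)
}

#' Serialize a surrogate to a plain list (JSON-ready)
#'
#' @param model A `surrogate_model`.
#' @return A nested list of plain vectors mirroring the object.
#' @export
surrogate_to_list <- function(model) {
  list(model_tag = model$model_tag, input_names = model$input_names,
       responses = model$responses, degree = model$degree,
       scalers = model$scalers, priors = model$priors,
       ranges = model$ranges,
       fits = lapply(model$fits, function(f)
         list(coef = unname(f$coef), Vn = unname(f$Vn), a = f$a, b = f$b,
              s2 = f$s2, r2 = f$r2, transform = f$transform)))
}
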