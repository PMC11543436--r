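#' Random-walk model of activated Lck spreading from CD45
#'
#' Each walker represents an Lck molecule activated at a CD45 located at the
#' origin. Per step it takes an isotropic Gaussian displacement with per-axis
#' standard deviation `sqrt(2 * diff * dt)` and is then deactivated with
#' probability `p_off * dt`; a deactivated walker keeps its position. End
#' distances from the origin after `n_steps` (or at deactivation) summarize
#' the lateral reach of active Lck.
#'
#' @param diff Diffusion coefficient, um^2/s.
#' @param p_off Deactivation probability per second, 1/s.
#' @param n_walkers Number of walkers.
#' @param n_steps Steps per walker.
#' @param dt Seconds per step; `p_off * dt` must lie in `[0, 1]`.
#' @param grid_size Nominal grid side, nm (only used for histogram binning;
#'   walkers are unbounded).
#' @param seed Integer seed.
#' @return A `walk_result` with `end_distances` (nm), `deactivated`, `steps`,
#'   `radial_histogram` (20 nm bins up to `grid_size / 2`) and the parameters.
#' @seealso [fit_decay_length()]
#' @export
#' @examples
#' w <- run_walk(diff = 0.1, p_off = 10, n_walkers = 500, seed = 1)
#' fit_decay_length(w)
run_walk <- function(diff, p_off, n_walkers = 1000, n_steps = 1000, dt = 0.01,
                     grid_size = 2000, seed = 1L) {
  if (diff < 0 || p_off < 0 || n_walkers < 1 || n_steps < 1 || dt <= 0)
    stop_kinseg("kinseg_invalid_config",
                "diff, p_off >= 0 and n_walkers, n_steps, dt > 0 required")
  p_step <- p_off * dt
  if (p_step > 1)
    stop_kinseg("kinseg_invalid_config",
                "p_off * dt = %.3g exceeds 1; decrease dt", p_step)
  set.seed(seed)
  step_sd <- sqrt(2 * diff * 1e6 * dt) # nm
  res <- .lck_walk_cpp(as.integer(n_walkers), as.integer(n_steps), step_sd,
                       p_step)
  out <- list(end_distances = res$end_distance, deactivated = res$deactivated,
              steps = res$steps,
              radial_histogram = radial_histogram(res$end_distance, grid_size),
              diff = diff, p_off = p_off, n_walkers = n_walkers,
              n_steps = n_steps, dt = dt, grid_size = grid_size, seed = seed)
  class(out) <- "walk_result"
  out
}

# 20 nm bins from the origin out to the farthest walker (at least the
# nominal half-grid, so sparse distributions keep a stable binning)
radial_histogram <- function(distances, grid_size, bin_width = 20) {
  top <- max(grid_size / 2, max(distances))
  breaks <- seq(0, top + bin_width, by = bin_width)
  h <- hist(distances, breaks = breaks, plot = FALSE)
  data.frame(r = h$mids, count = h$counts)
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("walk_result: %d walkers (%d steps of %g s), diff %g um^2/s, p_off %g /s\n",
              x$n_walkers, x$n_steps, x$dt, x$diff, x$p_off))
  cat(sprintf("  %.1f%% deactivated; median end distance %.0f nm\n",
              100 * mean(x$deactivated), median(x$end_distances)))
  invisible(x)
}

#' @export
plot.walk_result <- function(x, fit = NULL, ...) {
  h <- x$radial_histogram[x$radial_histogram$count > 0, ]
  plot(h$r, h$count, log = "y", pch = 16, xlab = "distance from origin (nm)",
       ylab = "count", ...)
  if (!is.null(fit))
    lines(h$r, exp(fit$log_intercept - h$r / fit$decay_length), col = "red3")
  invisible(x)
}

#' Exponential decay length of the Lck* radial distribution
#'
#' The radial histogram of walker end distances is summarized by a single
#' decay length: the default fits `count(r) ~ exp(-r / lambda)` by least
#' squares on log counts of nonempty bins; `method = "mle"` instead uses the
#' maximum-likelihood exponential rate on the raw distances
#' (`lambda = mean(r)`).
#'
#' @param result A `walk_result`, or a data frame with columns `r`, `count`.
#' @param method `"loglinear"` (default) or `"mle"`.
#' @return A `decay_fit` with `decay_length` (nm), `fit_residual` (root mean
#'   squared residual on log counts; `NA` for `"mle"`), `log_intercept` and
#'   `method`. A non-decaying histogram yields a finite (possibly very large)
#'   decay length with a large `fit_residual` rather than an error.
#' @export
#' @examples
#' h <- data.frame(r = seq(10, 390, 20), count = round(1e4 * exp(-seq(10, 390, 20) / 50)))
#' fit_decay_length(h)$decay_length
fit_decay_length <- function(result, method = c("loglinear", "mle")) {
  method <- match.arg(method)
  h <- if (inherits(result, "walk_result")) result$radial_histogram else result
  if (method == "mle") {
    if (!inherits(result, "walk_result"))
      stop_kinseg("kinseg_invalid_config",
                  "method 'mle' needs a walk_result with raw distances")
    lambda <- mean(result$end_distances)
    out <- list(decay_length = lambda, fit_residual = NA_real_,
                log_intercept = NA_real_, method = "mle")
    class(out) <- "decay_fit"
    return(out)
  }
  keep <- h$count > 0
  if (sum(keep) < 3)
    stop_kinseg("kinseg_insufficient_data",
                "decay fit needs at least 3 nonempty histogram bins")
  # count-weighted least squares on log counts: sparse far bins carry
  # Poisson-level information and must not flatten the slope
  fit <- lm(log(count) ~ r, data = h[keep, ], weights = h$count[keep])
  slope <- coef(fit)[["r"]]
  # non-decaying histograms map to a huge positive decay length, flagged by
  # the residual; callers can also inspect the sign via log_intercept/slope
  lambda <- if (slope < 0) -1 / slope else Inf
  if (!is.finite(lambda)) lambda <- .Machine$double.xmax^0.25
  out <- list(decay_length = lambda,
              fit_residual = sqrt(mean(fit$residuals^2)),
              log_intercept = coef(fit)[["(Intercept)"]],
              method = "loglinear")
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit (%s): decay length %.4g nm (log-residual %.3g)\n",
              x$method, x$decay_length, x$fit_residual))
  invisible(x)
}

#' Decay length over a (diff, p_off) grid and the scaling exponent
#'
#' Runs the Lck random walk over a log-spaced grid of diffusion coefficients
#' and deactivation rates, fits the decay length per cell, and estimates the
#' exponent `alpha` of the iso-decay-length relation `diff ~ C * p_off^alpha`
#' by regressing `log(decay_length)` on `(log(diff) - log(p_off)) / 2`. For
#' the diffusion-limited scaling `DL ~ sqrt(diff / p_off)` the fitted slope
#' is 1.
#'
#' @param diff_grid,p_off_grid Axis values (um^2/s and 1/s).
#' @param n_walkers,n_steps,dt Passed to [run_walk()].
#' @param seed Integer seed (one stream per cell, derived deterministically).
#' @return A list with the `grid` data frame (`diff`, `p_off`, `decay_length`,
#'   `fit_residual`), the scaling exponent `alpha`, its standard error, and
#'   the decay-length `range` spanned.
#' @export
lck_scaling <- function(diff_grid = 10^seq(-2, 0, length.out = 5),
                        p_off_grid = 10^seq(-1, 2, length.out = 5),
                        n_walkers = 1000, n_steps = 1000, dt = 0.01,
                        seed = 1L) {
  cells <- expand.grid(diff = diff_grid, p_off = p_off_grid)
  cells$decay_length <- NA_real_
  cells$fit_residual <- NA_real_
  for (i in seq_len(nrow(cells))) {
    w <- run_walk(cells$diff[i], cells$p_off[i], n_walkers = n_walkers,
                  n_steps = n_steps, dt = dt, seed = seed + i)
    f <- fit_decay_length(w)
    cells$decay_length[i] <- f$decay_length
    cells$fit_residual[i] <- f$fit_residual
  }
  u <- (log(cells$diff) - log(cells$p_off)) / 2
  fit <- lm(log(decay_length) ~ u, data = cells)
  list(grid = cells, alpha = unname(coef(fit)["u"]),
       alpha_se = summary(fit)$coefficients["u", "Std. Error"],
       range = range(cells$decay_length))
}
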