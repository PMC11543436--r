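#' Initial-contact protocol for the affinity scan
#'
#' Describes the simplified early-contact scenario: the T-cell membrane is
#' constrained next to the APC over a central disk for `clamp_duration`
#' seconds (close enough for TCRs to bind and detach from pMHC), then the
#' constraint is released and the contact evolves freely for `free_duration`
#' seconds.
#'
#' @param clamp_duration Seconds of membrane constraint (default 10).
#' @param free_duration Seconds of free evolution after release (default 90).
#' @param clamp_height Constrained membrane height, nm; defaults to the
#'   TCR-pMHC complex height so bonds can form.
#' @param clamp_radius Radius of the constrained disk, nm.
#' @param u_assoc_grid TCR-pMHC association energies to scan, kT.
#' @param dl_grid Lck* decay lengths at which phosphorylation is evaluated,
#'   nm.
#' @param n_replicates Independent replicates per association strength.
#' @param sample_dt Sampling cadence for the time series, s.
#' @param sticky Phosphorylation bookkeeping: `FALSE` (default) re-draws
#'   phosphorylation as a memoryless snapshot at every sample time; `TRUE`
#'   keeps a TCR phosphorylated while it remains bound once drawn.
#' @param seed Integer seed for the scan.
#' @return A `contact_protocol` list.
#' @export
contact_protocol <- function(clamp_duration = 10, free_duration = 90,
                             clamp_height = NULL, clamp_radius = 300,
                             u_assoc_grid = seq(5, 50, by = 5),
                             dl_grid = seq(10, 100, by = 10),
                             n_replicates = 5, sample_dt = 1, sticky = FALSE,
                             seed = 1L) {
  if (clamp_duration <= 0 || free_duration <= 0 || sample_dt <= 0)
    stop_kinseg("kinseg_invalid_config", "durations must be positive")
  if (any(u_assoc_grid <= 0))
    stop_kinseg("kinseg_invalid_config", "u_assoc values must be positive")
  structure(list(clamp_duration = clamp_duration,
                 free_duration = free_duration, clamp_height = clamp_height,
                 clamp_radius = clamp_radius, u_assoc_grid = u_assoc_grid,
                 dl_grid = dl_grid, n_replicates = as.integer(n_replicates),
                 sample_dt = sample_dt, sticky = isTRUE(sticky),
                 seed = as.integer(seed)),
            class = "contact_protocol")
}

#' Run one initial-contact simulation
#'
#' Runs the kinetic-segregation simulation under the contact protocol (local
#' membrane clamp, then release) and tracks, at each sample time, the number
#' of pMHC-bound TCRs and -- for every decay length in `dl_grid` -- the number
#' of phosphorylated TCRs. Phosphorylation is restricted to bound TCRs and
#' assigned from the instantaneous CD45 pattern through the absolute
#' linear-capped probability rule (see [assign_phosphorylation()]).
#'
#' @param config A [ks_config()]; its `u_assoc` and `seed` define the run.
#' @param protocol A [contact_protocol()].
#' @return A `binding_series`: data frame `t` (s), `n_bound`, `central_z`
#'   (mean membrane height over the clamped disk, nm), matrix `n_ptcr`
#'   (time x decay length), `detach_time` (first time after release with no
#'   bonds and a lifted membrane; `NA` if the contact persists), `u_assoc`,
#'   and `seed`.
#' @export
run_contact <- function(config, protocol = contact_protocol()) {
  clamp_h <- if (is.null(protocol$clamp_height)) config$h_tcr_bond
             else protocol$clamp_height
  t_end <- protocol$clamp_duration + protocol$free_duration
  times <- seq(0, t_end, by = protocol$sample_dt)
  traj <- .run_engine(config, sample_times = times,
                      clamp_until = protocol$clamp_duration,
                      clamp_height = clamp_h,
                      clamp_radius = protocol$clamp_radius, t_end = t_end)
  dl <- protocol$dl_grid
  n_bound <- integer(length(traj$states))
  central_z <- numeric(length(traj$states))
  n_ptcr <- matrix(0L, length(traj$states), length(dl),
                   dimnames = list(NULL, paste0("DL", dl)))
  n <- config$patch_size / config$grid_spacing
  ctr_cells <- which(outer((seq_len(n) - 0.5) * config$grid_spacing -
                             config$patch_size / 2,
                           (seq_len(n) - 0.5) * config$grid_spacing -
                             config$patch_size / 2,
                           function(a, b) a^2 + b^2) <=
                       protocol$clamp_radius^2)
  prev_flags <- NULL
  for (k in seq_along(traj$states)) {
    st <- traj$states[[k]]
    mol <- st$molecules
    is_tcr <- mol$species == "TCR"
    bound <- !is.na(mol$bound) & mol$bound
    n_bound[k] <- sum(bound)
    central_z[k] <- mean(st$z[ctr_cells])
    if (n_bound[k] > 0) {
      flags <- .snapshot_phosphorylation(
        tcr = cbind(mol$x[is_tcr & bound], mol$y[is_tcr & bound]),
        cd45 = cbind(mol$x[mol$species == "CD45"],
                     mol$y[mol$species == "CD45"]),
        dl = dl, seed = config$seed * 1000L + k)
      rownames(flags) <- as.character(which(is_tcr & bound))
      if (protocol$sticky && !is.null(prev_flags)) {
        # a TCR stays phosphorylated while it remains bound
        common <- intersect(rownames(flags), rownames(prev_flags))
        flags[common, ] <- flags[common, , drop = FALSE] |
          prev_flags[common, , drop = FALSE]
      }
      n_ptcr[k, ] <- colSums(flags)
      prev_flags <- flags
    } else prev_flags <- NULL
  }
  release <- times > protocol$clamp_duration
  lifted <- n_bound == 0 &
    central_z > (config$h_tcr_bond + config$h_cd45) / 2
  detach_idx <- which(release & lifted)
  out <- list(t = times, n_bound = n_bound, n_ptcr = n_ptcr,
              central_z = central_z,
              detach_time = if (length(detach_idx)) times[min(detach_idx)]
                            else NA_real_,
              u_assoc = config$u_assoc, dl_grid = dl, seed = config$seed,
              protocol = protocol)
  class(out) <- "binding_series"
  out
}

# Bernoulli phosphorylation flags for bound TCRs at each decay length,
# using the absolute linear-capped rule (beta = 1): the summed kernel is the
# expected number of active Lck within reach.
.snapshot_phosphorylation <- function(tcr, cd45, dl, seed, beta = 1) {
  rho_tcr <- .density_sum_cpp(tcr[, 1], tcr[, 2], cd45[, 1], cd45[, 2], dl)
  p <- beta * rho_tcr
  p[p > 1] <- 1
  set.seed(seed %% .Machine$integer.max)
  flags <- matrix(runif(length(p)) < p, nrow(p), ncol(p))
  rownames(flags) <- seq_len(nrow(p))
  flags
}

#' @export
print.binding_series <- function(x, ...) {
  cat(sprintf("binding_series: U_assoc = %g kT, %d samples over %g s\n",
              x$u_assoc, length(x$t), max(x$t)))
  cat(sprintf("  bound TCRs: start %d, end %d; detach time %s\n",
              x$n_bound[1], tail(x$n_bound, 1),
              if (is.na(x$detach_time)) "none (persistent)"
              else sprintf("%g s", x$detach_time)))
  invisible(x)
}

#' @export
plot.binding_series <- function(x, ...) {
  plot(x$t, x$n_bound, type = "l", lwd = 2, xlab = "time (s)",
       ylab = "count", main = sprintf("U_assoc = %g kT", x$u_assoc), ...)
  cols <- grDevices::hcl.colors(ncol(x$n_ptcr), "viridis")
  for (k in seq_len(ncol(x$n_ptcr)))
    lines(x$t, x$n_ptcr[, k], col = cols[k])
  legend("topright", c("bound", colnames(x$n_ptcr)),
         col = c("black", cols), lwd = c(2, rep(1, ncol(x$n_ptcr))),
         cex = 0.6)
  invisible(x)
}

#' Longest sustained supra-threshold phosphorylation
#'
#' Length of the longest contiguous time interval during which the
#' phosphorylated-TCR count exceeds `n_min`, per decay length.
#'
#' @param series A `binding_series` (or a numeric vector of counts with
#'   attribute-free sampling, in which case `dt` must be given).
#' @param n_min Threshold count (strict: intervals require `n_ptcr > n_min`).
#' @param dt Sample spacing, s (taken from the series when omitted).
#' @return Named numeric vector of durations (s), one per decay length.
#' @export
#' @examples
#' max_sustained_duration(c(0, 6, 6, 6, 0, 6, 6, 0), n_min = 5, dt = 1)
max_sustained_duration <- function(series, n_min = 5, dt = NULL) {
  if (inherits(series, "binding_series")) {
    counts <- series$n_ptcr
    dt <- series$t[2] - series$t[1]
  } else {
    counts <- matrix(series, ncol = 1)
    if (is.null(dt))
      stop_kinseg("kinseg_invalid_config", "dt required for raw counts")
  }
  apply(counts, 2, function(v) {
    above <- v > n_min
    if (!any(above)) return(0)
    runs <- rle(above)
    # n contiguous samples at spacing dt span (n - 1) * dt seconds
    (max(runs$lengths[runs$values]) - 1) * dt
  })
}

#' Activation rule for early TCR triggering
#'
#' @param n_min Minimal number of phosphorylated TCRs (default 5).
#' @param tau Minimal duration over which they must persist, s (default 10).
#' @return An `activation_rule` list.
#' @export
activation_rule <- function(n_min = 5, tau = 10) {
  if (n_min < 1 || tau <= 0)
    stop_kinseg("kinseg_invalid_config", "n_min >= 1 and tau > 0 required")
  structure(list(n_min = n_min, tau = tau), class = "activation_rule")
}

#' Activation outcome of a contact
#'
#' A contact activates the T cell if more than `rule$n_min` phosphorylated
#' TCRs persist for at least `rule$tau` seconds.
#'
#' @param series A `binding_series`.
#' @param rule An [activation_rule()].
#' @return Named logical vector, one outcome per decay length.
#' @export
activation_outcome <- function(series, rule = activation_rule()) {
  max_sustained_duration(series, rule$n_min) >= rule$tau
}

#' Scan pMHC:TCR association strengths
#'
#' Runs [run_contact()] for every association energy in the protocol grid and
#' every replicate, classifying each run as persistent (bound TCRs remain at
#' 90 s) or detached.
#'
#' @param config Base [ks_config()]; `u_assoc` and `seed` are overridden per
#'   run.
#' @param protocol A [contact_protocol()].
#' @param verbose Print one line per run.
#' @return An `affinity_scan`: list of `binding_series` plus a `runs` data
#'   frame (`u_assoc`, `replicate`, `detached`, `detach_time`,
#'   `final_bound`).
#' @export
affinity_scan <- function(config = ks_config(), protocol = contact_protocol(),
                          verbose = FALSE) {
  grid <- expand.grid(replicate = seq_len(protocol$n_replicates),
                      u_assoc = protocol$u_assoc_grid)
  series <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$u_assoc <- grid$u_assoc[i]
    cfg$seed <- as.integer((protocol$seed * 563L + i * 7919L) %% .Machine$integer.max)
    series[[i]] <- run_contact(cfg, protocol)
    if (verbose)
      cat(sprintf("U=%2g kT rep %d: final bound %d, detach %s\n",
                  grid$u_assoc[i], grid$replicate[i],
                  tail(series[[i]]$n_bound, 1),
                  format(series[[i]]$detach_time)))
  }
  grid$detached <- vapply(series, function(s) !is.na(s$detach_time), logical(1))
  grid$detach_time <- vapply(series, `[[`, numeric(1), "detach_time")
  grid$final_bound <- vapply(series, function(s) tail(s$n_bound, 1), numeric(1))
  structure(list(series = series, runs = grid, protocol = protocol,
                 config = config),
            class = "affinity_scan")
}

#' @export
print.affinity_scan <- function(x, ...) {
  agg <- aggregate(cbind(detached, final_bound) ~ u_assoc, data = x$runs, mean)
  cat("affinity_scan:\n")
  print(agg, row.names = FALSE)
  cat(sprintf("  transition U = %g kT\n", transition_u(x)))
  invisible(x)
}

#' Detachment-transition association strength
#'
#' Midpoint between the largest association energy at which the majority of
#' replicates detach and the smallest at which the majority persist.
#'
#' @param scan An `affinity_scan`.
#' @return Transition energy, kT.
#' @export
transition_u <- function(scan) {
  agg <- aggregate(detached ~ u_assoc, data = scan$runs, mean)
  det <- agg$u_assoc[agg$detached > 0.5]
  per <- agg$u_assoc[agg$detached <= 0.5]
  if (length(det) == 0 || length(per) == 0)
    stop_kinseg("kinseg_undefined_metric",
                "scan contains a single detachment class")
  (max(det) + min(per)) / 2
}

#' Sensitivity and specificity of the activation rule across decay lengths
#'
#' Association strengths above `truth_threshold` define ground-truth
#' positives (agonist-like ligands), the rest negatives. For each decay
#' length, sensitivity is the fraction of positive runs that activate under
#' the rule and specificity the fraction of negative runs that do not.
#'
#' @param scan An `affinity_scan`.
#' @param rule An [activation_rule()].
#' @param truth_threshold Class boundary, kT (default 25).
#' @return Data frame with `decay_length`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @export
sensitivity_specificity <- function(scan, rule = activation_rule(),
                                    truth_threshold = 25) {
  u <- vapply(scan$series, `[[`, numeric(1), "u_assoc")
  pos <- u > truth_threshold
  if (all(pos) || !any(pos))
    stop_kinseg("kinseg_undefined_metric",
                "both truth classes are required for sensitivity/specificity")
  act <- t(vapply(scan$series, activation_outcome, rule = rule,
                  logical(length(scan$protocol$dl_grid))))
  data.frame(decay_length = scan$protocol$dl_grid,
             sensitivity = colMeans(act[pos, , drop = FALSE]),
             specificity = colMeans(!act[!pos, , drop = FALSE]),
             balanced_accuracy = (colMeans(act[pos, , drop = FALSE]) +
                                    colMeans(!act[!pos, , drop = FALSE])) / 2,
             row.names = NULL)
}
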