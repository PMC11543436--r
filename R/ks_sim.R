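#' Initial state of the membrane simulation
#'
#' Places one central TCR cluster, CD45 scattered uniformly over the rest of
#' the patch, a matching pMHC cluster on the APC opposite the TCR cluster, and
#' the initial membrane: an established tight contact (a depression at the
#' complex height over the cluster, ramping to the resting separation) by
#' default, or a flat membrane at `init_height` with `init_contact = FALSE`.
#' No TCR-pMHC bonds exist yet.
#'
#' @param config A [ks_config()] object.
#' @return A `membrane_state`: list with height matrix `z` (nm), `molecules`
#'   (a [point_pattern()] with a `partner` bond index column), time `t`, and
#'   the configuration.
#' @export
#' @examples
#' st <- init_state(ks_config(n_tcr = 10, n_cd45 = 30, n_pmhc = 10))
#' range(st$molecules$x)
init_state <- function(config) {
  validate_ks_config(config)
  set.seed(config$seed)
  .init_state_impl(config)
}

# state construction without touching the RNG seed (used inside run loops)
.init_state_impl <- function(config) {
  L <- config$patch_size
  ctr <- c(L / 2, L / 2)
  rc <- config$tcr_cluster_radius
  tcr <- if (is.finite(rc)) runif_disk(config$n_tcr, rc, ctr)
         else runif_patch(config$n_tcr, L)
  cd45 <- runif_patch(config$n_cd45, L,
                      exclude_radius = if (is.finite(rc)) rc else 0)
  pmhc <- if (is.finite(rc)) runif_disk(config$n_pmhc, rc, ctr)
          else runif_patch(config$n_pmhc, L)
  mol <- point_pattern(
    species = rep(c("TCR", "CD45", "pMHC"),
                  c(config$n_tcr, config$n_cd45, config$n_pmhc)),
    x = c(tcr[, 1], cd45[, 1], pmhc[, 1]),
    y = c(tcr[, 2], cd45[, 2], pmhc[, 2]),
    bound = c(rep(FALSE, config$n_tcr),
              rep(NA, config$n_cd45 + config$n_pmhc)))
  mol$partner <- NA_integer_
  st <- list(z = .init_height_field(config), molecules = mol, t = 0,
             config = config)
  class(st) <- "membrane_state"
  st
}

# initial height field: established-contact depression or flat separation
.init_height_field <- function(config) {
  n <- config$patch_size / config$grid_spacing
  if (!config$init_contact || !is.finite(config$tcr_cluster_radius))
    return(matrix(config$init_height, n, n))
  xc <- (seq_len(n) - 0.5) * config$grid_spacing - config$patch_size / 2
  r <- sqrt(outer(xc^2, xc^2, `+`))
  r0 <- config$tcr_cluster_radius + 100 # ramp center just outside the cluster
  config$h_tcr_bond + (config$boundary_height - config$h_tcr_bond) /
    (1 + exp(-(r - r0) / 40))
}

# convert one C++ snapshot into a membrane_state
.state_from_cpp <- function(s, config) {
  mol <- point_pattern(
    species = c("TCR", "CD45", "pMHC")[s$species],
    x = s$x, y = s$y,
    bound = ifelse(s$species == 1L, !is.na(s$partner), NA))
  mol$partner <- s$partner
  st <- list(z = s$z, molecules = mol, t = s$t, config = config)
  class(st) <- "membrane_state"
  st
}

#' @export
print.membrane_state <- function(x, ...) {
  nb <- sum(x$molecules$bound, na.rm = TRUE)
  cat(sprintf("membrane_state at t = %g s: %d molecules, %d bonds, mean height %.1f nm\n",
              x$t, nrow(x$molecules), nb, mean(x$z)))
  invisible(x)
}

# shared engine behind run_ks() and run_contact()
.run_engine <- function(config, sample_times, clamp_until = 0, clamp_height = 0,
                        clamp_radius = 0, t_end = config$t_end) {
  validate_ks_config(config)
  set.seed(config$seed)
  init <- .init_state_impl(config)
  mol <- init$molecules
  sp <- as.character(mol$species)
  n <- as.integer(config$patch_size / config$grid_spacing)
  step_sd <- sqrt(2 * config$mol_diff * 1e6 * config$sweep_dt) # nm per axis
  res <- .ks_run_cpp(
    n = n,
    a = config$grid_spacing,
    boundary_h = config$boundary_height,
    z_init = if (clamp_until > 0) matrix(config$init_height, n, n)
             else .init_height_field(config),
    tcr_x = mol$x[sp == "TCR"], tcr_y = mol$y[sp == "TCR"],
    cd45_x = mol$x[sp == "CD45"], cd45_y = mol$y[sp == "CD45"],
    pmhc_x = mol$x[sp == "pMHC"], pmhc_y = mol$y[sp == "pMHC"],
    R = config$rigidity, hb = config$h_tcr_bond, hc = config$h_cd45,
    U = config$u_assoc, Sent = config$bond_entropy,
    urep = config$u_rep, uadh = config$u_adh,
    wadh = config$adh_width, kb = config$bond_k,
    tether_k = config$tether_k,
    corral = if (is.finite(config$corral_radius)) config$corral_radius else -1,
    capture = config$capture_radius, bind_tol = config$bind_tol,
    step_sd = step_sd,
    pmhc_step_sd = sqrt(2 * config$pmhc_diff * 1e6 * config$sweep_dt),
    hstep = config$height_step,
    sweep_dt = config$sweep_dt, t_end = t_end,
    sample_times = sample_times,
    clamp_until = clamp_until, clamp_h = clamp_height,
    clamp_radius = clamp_radius,
    log_every = config$log_every)
  states <- lapply(res$states, .state_from_cpp, config = config)
  structure(list(states = states, config = config, log = res$log),
            class = "ks_trajectory")
}

#' Run the kinetic-segregation simulation
#'
#' Metropolis dynamics over single-node membrane-height perturbations (scored
#' by the bending energy, bound-TCR springs and the CD45 steric/adhesion
#' potential), lateral molecule hops calibrated to the configured diffusion
#' coefficient, and TCR-pMHC bond toggling with acceptance driven by the
#' association energy `u_assoc` (binding is only attempted where the local
#' membrane height is within `bind_tol` of the complex height). States are
#' recorded at `config$sample_times`.
#'
#' @param config A [ks_config()] object.
#' @return A `ks_trajectory`: list of `membrane_state`s (at the sample times),
#'   the configuration, and an energy/acceptance log.
#' @seealso [depletion_width()], [run_contact()]
#' @export
#' @examples
#' cfg <- ks_config(n_tcr = 20, n_cd45 = 60, n_pmhc = 30, t_end = 2,
#'                  sample_times = c(0, 2), grid_spacing = 50)
#' traj <- run_ks(cfg)
#' traj
run_ks <- function(config) {
  .run_engine(config, sample_times = config$sample_times)
}

#' @export
print.ks_trajectory <- function(x, ...) {
  ts <- vapply(x$states, `[[`, numeric(1), "t")
  cat(sprintf("ks_trajectory: %d states at t = %s s\n", length(ts),
              paste(signif(ts, 3), collapse = ", ")))
  nb <- vapply(x$states, function(s) sum(s$molecules$bound, na.rm = TRUE),
               numeric(1))
  cat(sprintf("  bound TCRs: %s\n", paste(nb, collapse = ", ")))
  invisible(x)
}

#' @export
plot.ks_trajectory <- function(x, which = length(x$states), ...) {
  st <- x$states[[which]]
  mol <- st$molecules
  cols <- c(TCR = "forestgreen", CD45 = "red3", pMHC = "grey70")
  plot(mol$x, mol$y, col = cols[as.character(mol$species)],
       pch = ifelse(!is.na(mol$bound) & mol$bound, 19, 1), cex = 0.6,
       asp = 1, xlab = "x (nm)", ylab = "y (nm)",
       main = sprintf("t = %g s", st$t), ...)
  legend("topright", legend = names(cols), col = cols, pch = 1, cex = 0.8)
  invisible(x)
}

#' Molecule table of a trajectory
#'
#' Flattens a `ks_trajectory` into one data frame (columns `t_s`, `species`,
#' `x_nm`, `y_nm`, `bound`), the plain-text export format of the simulator.
#'
#' @param traj A `ks_trajectory`.
#' @return A `data.frame`.
#' @export
trajectory_table <- function(traj) {
  do.call(rbind, lapply(traj$states, function(s) {
    data.frame(t_s = s$t, species = as.character(s$molecules$species),
               x_nm = s$molecules$x, y_nm = s$molecules$y,
               bound = s$molecules$bound)
  }))
}

#' TCR:CD45 depletion width of a membrane state
#'
#' The depletion zone is the annulus between the TCR cluster and the
#' surrounding CD45 from which both species are absent. Both edges are
#' estimated from binned radial density profiles about the TCR center of
#' mass. The default `"threshold"` method locates the TCR outer edge where
#' the TCR density falls below half its core value, and the CD45 inner edge
#' where the CD45 density first rises to half its far-field plateau
#' (sustained over two bins, with linear interpolation of the crossing). The
#' `"quantile"` method instead uses the radius containing `quantiles["tcr"]`
#' of the TCR points and the `quantiles["cd45"]` quantile of CD45 radial
#' distances; note that a global quantile carries a positive area bias of
#' order the cluster radius, so the threshold method is the default. The
#' width is the edge difference, clamped at zero.
#'
#' @param state A `membrane_state`, or any [point_pattern()] with TCR and CD45
#'   species.
#' @param method `"threshold"` (default) or `"quantile"`.
#' @param quantiles Length-2 named vector (`tcr`, `cd45`) for the quantile
#'   method; defaults to the state's configuration (95% / 5%).
#' @param bin_width Radial bin width for the density profiles, nm.
#' @return A `depletion_result` with fields `width` (nm), `tcr_outer_radius`,
#'   `cd45_inner_radius`, and `radial_profiles`.
#' @export
#' @examples
#' set.seed(1)
#' pp <- segregated_pattern(depletion = 100, n_tcr = 400, n_cd45 = 1200)
#' depletion_width(pp)
depletion_width <- function(state, method = c("threshold", "quantile"),
                            quantiles = NULL, bin_width = 20) {
  method <- match.arg(method)
  mol <- if (inherits(state, "membrane_state")) state$molecules else state
  if (is.null(quantiles))
    quantiles <- if (inherits(state, "membrane_state"))
      state$config$dep_quantiles else c(tcr = 0.95, cd45 = 0.05)
  tcr <- mol[mol$species == "TCR", , drop = FALSE]
  cd45 <- mol[mol$species == "CD45", , drop = FALSE]
  if (nrow(tcr) < 1 || nrow(cd45) < 1)
    stop_kinseg("kinseg_insufficient_pattern",
                "depletion width needs at least one TCR and one CD45 point")
  ctr <- c(mean(tcr$x), mean(tcr$y))
  r_tcr <- sqrt((tcr$x - ctr[1])^2 + (tcr$y - ctr[2])^2)
  r_cd <- sqrt((cd45$x - ctr[1])^2 + (cd45$y - ctr[2])^2)
  rmax <- max(r_tcr, r_cd)
  breaks <- seq(0, rmax + bin_width, by = bin_width)
  prof <- function(r) {
    h <- hist(r, breaks = breaks, plot = FALSE)
    data.frame(r = h$mids,
               density = h$counts / (pi * (breaks[-1]^2 - head(breaks, -1)^2)))
  }
  profiles <- list(TCR = prof(r_tcr), CD45 = prof(r_cd))
  if (method == "quantile") {
    outer <- unname(quantile(r_tcr, quantiles[["tcr"]], type = 7))
    inner <- unname(quantile(r_cd, quantiles[["cd45"]], type = 7))
  } else {
    outer <- .edge_falling(profiles$TCR, r_tcr)
    inner <- .edge_rising(profiles$CD45, r_cd,
                          rmax_plateau = if (inherits(state, "membrane_state"))
                            state$config$patch_size / 2 else NA)
  }
  out <- list(width = max(0, inner - outer), tcr_outer_radius = outer,
              cd45_inner_radius = inner, center = ctr, method = method,
              radial_profiles = profiles)
  class(out) <- "depletion_result"
  out
}

# outward half-density crossing of a falling (cluster) profile
.edge_falling <- function(prof, r) {
  core <- median(r) # radius containing half the points
  ref <- mean(prof$density[prof$r <= core])
  if (!is.finite(ref) || ref <= 0) return(unname(quantile(r, 0.95)))
  idx <- which(prof$r > core & prof$density < ref / 2)
  if (length(idx) == 0) return(max(r))
  i <- idx[1]
  if (i == 1) return(prof$r[1])
  # linear interpolation between the last bin above and first below half
  r0 <- prof$r[i - 1]; d0 <- prof$density[i - 1]
  r1 <- prof$r[i]; d1 <- prof$density[i]
  r0 + (d0 - ref / 2) / max(d0 - d1, 1e-12) * (r1 - r0)
}

# inward edge where a rising profile reaches half its far-field plateau,
# sustained over two consecutive bins
.edge_rising <- function(prof, r, rmax_plateau = NA) {
  lim <- if (is.finite(rmax_plateau)) rmax_plateau else 0.7 * max(r)
  span <- prof$r >= (min(r) + lim) / 2 & prof$r <= lim
  plateau <- median(prof$density[span])
  if (!is.finite(plateau) || plateau <= 0) return(unname(quantile(r, 0.05)))
  d <- prof$density
  bw <- if (nrow(prof) > 1) prof$r[2] - prof$r[1] else 20
  counts <- d * pi * ((prof$r + bw / 2)^2 - (prof$r - bw / 2)^2)
  # a single molecule in a small inner annulus must not trigger the edge:
  # require half-plateau density AND >= 2 points, sustained over two bins
  solid <- d >= plateau / 2 & counts >= 2
  ok <- solid & c(solid[-1], FALSE)
  idx <- which(ok)
  if (length(idx) == 0) return(unname(quantile(r, 0.05)))
  i <- idx[1]
  if (i == 1) return(prof$r[1])
  r0 <- prof$r[i - 1]; d0 <- prof$density[i - 1]
  r1 <- prof$r[i]; d1 <- prof$density[i]
  r1 - (d1 - plateau / 2) / max(d1 - d0, 1e-12) * (r1 - r0)
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("depletion width %.1f nm (TCR outer %.1f nm, CD45 inner %.1f nm)\n",
              x$width, x$tcr_outer_radius, x$cd45_inner_radius))
  invisible(x)
}
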