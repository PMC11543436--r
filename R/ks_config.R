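#' Configuration for the kinetic-segregation membrane simulator
#'
#' Assembles and validates the full parameter set of the Metropolis Monte-Carlo
#' simulation of a square T-cell membrane patch in contact with an
#' antigen-presenting cell (APC). The membrane height field `z` (nm above the
#' APC surface) evolves under a discretized bending energy; TCR molecules bind
#' pMHC on the APC when the local membrane height is near the TCR-pMHC complex
#' height, and bound TCRs pull the membrane toward that height through a
#' harmonic spring; CD45, with its tall ectodomain, pays a steric penalty where
#' the membrane is lower than its height and enjoys a shallow adhesion minimum
#' at it. The ~37 nm default height mismatch between the CD45 ectodomain and
#' the TCR-pMHC complex is what drives kinetic segregation.
#'
#' @param patch_size Side of the square membrane patch, nm.
#' @param grid_spacing Height-field grid spacing, nm; must divide `patch_size`.
#' @param n_tcr,n_cd45,n_pmhc Molecule counts (TCR and CD45 on the T cell,
#'   pMHC on the APC).
#' @param rigidity Membrane bending-energy coefficient, kT nm^2 (0-100 is the
#'   range explored by the surrogate training grids).
#' @param h_tcr_bond Height of the bound TCR-pMHC complex, nm.
#' @param h_cd45 Height of the CD45 ectodomain, nm; must exceed `h_tcr_bond`.
#' @param u_assoc TCR-pMHC association energy, kT (the baseline default 60 kT,
#'   net 38 kT after the binding entropy, keeps the contact bound throughout
#'   a 100 s run, the persistent wild-type scenario). Controls bond persistence;
#'   the affinity scan sweeps it over 5-50 kT.
#' @param bond_entropy Entropy cost of TCR-pMHC binding, kT. The net binding
#'   free energy is `u_assoc - bond_entropy`; it sets the Metropolis
#'   acceptance of bond formation and release, so dissociation kinetics scale
#'   as `exp(-(u_assoc - bond_entropy) + strain)`.
#' @param u_rep CD45 steric-wall coefficient, kT/nm^2 (one-sided harmonic for
#'   membrane heights below `h_cd45`).
#' @param u_adh Depth of the shallow CD45 adhesion well at `h_cd45`, kT.
#' @param adh_width Width of the adhesion well, nm.
#' @param bond_k TCR-pMHC bond spring constant, kT/nm^2 (penalizes local
#'   membrane height away from `h_tcr_bond`; the released strain assists
#'   unbinding).
#' @param tether_k Weak per-node restoring coefficient toward
#'   `boundary_height`, kT/nm^2. Represents the elastic connection of the
#'   patch to the surrounding cell surface; keeps the free membrane near its
#'   resting separation.
#' @param corral_radius Maximal TCR distance from the patch center, nm
#'   (`Inf` disables). Implements the pre-formed TCR cluster assumption:
#'   receptors stay within a corral instead of dispersing over the patch.
#' @param mol_diff Lateral diffusion coefficient of the T-cell molecules,
#'   um^2/s.
#' @param pmhc_diff Lateral diffusion coefficient of pMHC on the APC, um^2/s.
#'   The default 0 treats pMHC as immobile ligands; a bound TCR is then
#'   tethered within `capture_radius` of its pMHC.
#' @param sweep_dt Physical seconds per Monte-Carlo sweep. The lateral hop
#'   scale is calibrated so a free molecule's mean-square displacement per
#'   sweep equals `4 * mol_diff * sweep_dt`.
#' @param t_end Simulated time, s.
#' @param sample_times Times (s) at which full states are recorded.
#' @param tcr_cluster_radius Radius of the central TCR (and pMHC) cluster, nm;
#'   `Inf` scatters TCR uniformly over the patch.
#' @param init_height Initial membrane separation away from the contact, nm
#'   (also the flat initial separation when `init_contact = FALSE`).
#' @param init_contact If `TRUE` (default), the run starts from an
#'   established tight contact: the height field begins at `h_tcr_bond` over
#'   the cluster disk and ramps smoothly to `boundary_height` outside.
#'   Without it, whether a contact nucleates before the free membrane
#'   relaxes to its resting separation is a seed-dependent race.
#' @param boundary_height Clamped height outside the patch edge, nm; defaults
#'   to `h_cd45` (resting separation of the free membrane).
#' @param capture_radius Maximal lateral TCR-pMHC distance for bond formation,
#'   nm.
#' @param bind_tol Tolerance around `h_tcr_bond` within which binding is
#'   permitted, nm.
#' @param height_step Maximal single-node height perturbation per move, nm.
#' @param dep_quantiles Length-2 vector: TCR outer quantile and CD45 inner
#'   quantile used by [depletion_width()].
#' @param log_every Log energy/acceptance every this many sweeps (0 disables).
#' @param seed Integer seed; every simulation entry point is deterministic
#'   given the seed and configuration.
#'
#' @return An object of class `ks_config` (a validated named list).
#' @seealso [init_state()], [run_ks()], [depletion_width()]
#' @export
#' @examples
#' cfg <- ks_config(n_tcr = 20, n_cd45 = 50, n_pmhc = 20, t_end = 1)
#' cfg
ks_config <- function(patch_size = 2000,
                      grid_spacing = 25,
                      n_tcr = 100,
                      n_cd45 = 1200,
                      n_pmhc = 150,
                      rigidity = 50,
                      h_tcr_bond = 13,
                      h_cd45 = 50,
                      u_assoc = 60,
                      bond_entropy = 22,
                      u_rep = 0.25,
                      u_adh = 2,
                      adh_width = 4,
                      bond_k = 0.25,
                      tether_k = 0.002,
                      corral_radius = 1.25 * tcr_cluster_radius,
                      mol_diff = 0.05,
                      pmhc_diff = 0,
                      sweep_dt = 0.05,
                      t_end = 100,
                      sample_times = c(0, 5, 10, 20, 50, 100),
                      tcr_cluster_radius = 200,
                      init_height = 15,
                      init_contact = TRUE,
                      boundary_height = h_cd45,
                      capture_radius = 10,
                      bind_tol = 5,
                      height_step = 3,
                      dep_quantiles = c(tcr = 0.95, cd45 = 0.05),
                      log_every = 100,
                      seed = 1L) {
  cfg <- list(patch_size = patch_size, grid_spacing = grid_spacing,
              n_tcr = as.integer(n_tcr), n_cd45 = as.integer(n_cd45),
              n_pmhc = as.integer(n_pmhc), rigidity = rigidity,
              h_tcr_bond = h_tcr_bond, h_cd45 = h_cd45, u_assoc = u_assoc,
              bond_entropy = bond_entropy,
              u_rep = u_rep, u_adh = u_adh, adh_width = adh_width,
              bond_k = bond_k, tether_k = tether_k,
              corral_radius = corral_radius,
              mol_diff = mol_diff, pmhc_diff = pmhc_diff,
              sweep_dt = sweep_dt,
              t_end = t_end, sample_times = sort(unique(sample_times)),
              tcr_cluster_radius = tcr_cluster_radius,
              init_height = init_height, init_contact = isTRUE(init_contact),
              boundary_height = boundary_height,
              capture_radius = capture_radius, bind_tol = bind_tol,
              height_step = height_step, dep_quantiles = dep_quantiles,
              log_every = as.integer(log_every), seed = as.integer(seed))
  validate_ks_config(cfg)
  class(cfg) <- "ks_config"
  cfg
}

validate_ks_config <- function(cfg) {
  with(cfg, {
    if (patch_size <= 0)
      stop_kinseg("kinseg_invalid_config", "patch_size must be positive")
    if (grid_spacing <= 0 || abs(patch_size / grid_spacing -
                                 round(patch_size / grid_spacing)) > 1e-9)
      stop_kinseg("kinseg_invalid_config",
                  "grid_spacing must be positive and divide patch_size")
    if (n_tcr < 0 || n_cd45 < 0 || n_pmhc < 0)
      stop_kinseg("kinseg_invalid_config", "molecule counts must be >= 0")
    if (rigidity < 0)
      stop_kinseg("kinseg_invalid_config", "rigidity must be >= 0")
    if (h_cd45 <= h_tcr_bond)
      stop_kinseg("kinseg_invalid_config", "h_cd45 must exceed h_tcr_bond")
    if (u_assoc < 0)
      stop_kinseg("kinseg_invalid_config", "u_assoc must be >= 0")
    if (sweep_dt <= 0 || t_end < 0)
      stop_kinseg("kinseg_invalid_config", "sweep_dt and t_end must be positive")
    if (init_height < 0)
      stop_kinseg("kinseg_invalid_config", "init_height must be >= 0")
    n_cells <- (patch_size / grid_spacing)^2
    if (n_tcr + n_cd45 + n_pmhc > 20 * n_cells)
      stop_kinseg("kinseg_invalid_config",
                  "molecule counts exceed the grid capacity (%d cells)", n_cells)
    if (is.finite(tcr_cluster_radius)) {
      cap <- floor(pi * tcr_cluster_radius^2 / 100) # ~1 molecule per (10 nm)^2
      if (n_tcr > cap)
        stop_kinseg("kinseg_invalid_config",
                    "n_tcr = %d exceeds the cluster-disk capacity (%d)", n_tcr, cap)
    }
  })
  invisible(cfg)
}

#' @export
print.ks_config <- function(x, ...) {
  cat("Kinetic-segregation simulator configuration\n")
  cat(sprintf("  patch %g nm, grid %g nm (%d x %d nodes)\n", x$patch_size,
              x$grid_spacing, x$patch_size / x$grid_spacing,
              x$patch_size / x$grid_spacing))
  cat(sprintf("  molecules: %d TCR, %d CD45, %d pMHC (cluster radius %g nm)\n",
              x$n_tcr, x$n_cd45, x$n_pmhc, x$tcr_cluster_radius))
  cat(sprintf("  rigidity %g kT nm^2, U_assoc %g kT, heights %g / %g nm\n",
              x$rigidity, x$u_assoc, x$h_tcr_bond, x$h_cd45))
  cat(sprintf("  %g s in sweeps of %g s, diffusion %g um^2/s, seed %d\n",
              x$t_end, x$sweep_dt, x$mol_diff, x$seed))
  invisible(x)
}
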