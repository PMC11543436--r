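#' Summed Lck* density field around CD45 molecules
#'
#' Active Lck spreads from each CD45 with an exponentially decaying radial
#' profile; the field is the plain sum of kernels
#' `rho(x) = sum_j exp(-|x - c_j| / decay_length)` over CD45 positions `c_j`.
#' It is additive and nonnegative; no dephosphorylation term is applied at any
#' distance (segregated CD45 requires direct contact to dephosphorylate, which
#' the model excludes by construction).
#'
#' @param cd45 A [point_pattern()] (its CD45 rows are used) or a two-column
#'   matrix/data frame of coordinates, nm.
#' @param decay_length Exponential decay length, nm (> 0).
#' @param query Two-column matrix/data frame of query coordinates, nm.
#' @return Numeric vector of densities at the query points. With an empty CD45
#'   set, an all-zero vector with attribute `empty_cd45 = TRUE`.
#' @export
#' @examples
#' lck_density(cbind(0, 0), decay_length = 70, query = cbind(c(0, 70), 0))
lck_density <- function(cd45, decay_length, query) {
  if (!is.numeric(decay_length) || decay_length <= 0)
    stop_kinseg("kinseg_invalid_config", "decay_length must be > 0")
  cd45 <- .coords(cd45, species = "CD45")
  query <- .coords(query)
  if (nrow(cd45) == 0) {
    warning("empty CD45 set: returning an all-zero density field")
    return(structure(rep(0, nrow(query)), empty_cd45 = TRUE))
  }
  drop(.density_sum_cpp(query[, 1], query[, 2], cd45[, 1], cd45[, 2],
                        decay_length))
}

# coordinate extraction: point_pattern rows of one species, or raw coordinates
.coords <- function(obj, species = NULL) {
  if (inherits(obj, "membrane_state")) obj <- obj$molecules
  if (is.data.frame(obj) && "species" %in% names(obj) && !is.null(species))
    obj <- obj[obj$species == species, , drop = FALSE]
  if (is.data.frame(obj)) obj <- cbind(obj$x, obj$y)
  m <- as.matrix(obj)
  if (length(m) == 0) m <- matrix(numeric(0), ncol = 2)
  storage.mode(m) <- "double"
  m
}

#' Phosphorylation-model configuration
#'
#' @param decay_length Lck* decay length, nm.
#' @param prob_rule Mapping from density to per-TCR phosphorylation
#'   probability: `"linear-capped"` (`p = min(1, beta * rho)`),
#'   `"normalize-by-max"` (`p = beta * rho / max(rho)`, capped at 1), or
#'   `"exp-saturating"` (`p = 1 - exp(-beta * rho)`).
#' @param beta Scale of the rule. The default 1 reads the summed kernel as
#'   the expected number of active Lck molecules within reach of the TCR, so
#'   one expected Lck* saturates the probability; this gives the
#'   all-bound-TCRs-phosphorylated regime at large decay lengths. `NULL`
#'   instead calibrates `beta` so the patch-maximum density maps to
#'   probability `beta_target` (a purely relative convention).
#' @param beta_target Calibration target when `beta = NULL` (default 0.95).
#' @param only_bound If `TRUE`, only pMHC-bound TCRs can be phosphorylated
#'   (unbound TCRs get probability 0).
#' @param seed Integer seed for the Bernoulli draws.
#' @return A `phos_config` list.
#' @export
phos_config <- function(decay_length = 70,
                        prob_rule = c("linear-capped", "normalize-by-max",
                                      "exp-saturating"),
                        beta = 1, beta_target = 0.95, only_bound = FALSE,
                        seed = 1L) {
  if (decay_length <= 0)
    stop_kinseg("kinseg_invalid_config", "decay_length must be > 0")
  structure(list(decay_length = decay_length, prob_rule = match.arg(prob_rule),
                 beta = beta, beta_target = beta_target,
                 only_bound = isTRUE(only_bound), seed = as.integer(seed)),
            class = "phos_config")
}

#' Calibrate the density-to-probability scale
#'
#' Returns `beta` such that the maximum of the Lck* density field over the
#' patch (approximated at the CD45 positions, where the summed kernel peaks)
#' maps to probability `target` under the linear rule.
#'
#' @inheritParams lck_density
#' @param target Probability assigned to the patch-maximum density.
#' @return Scalar `beta`.
#' @export
calibrate_beta <- function(cd45, decay_length, target = 0.95) {
  cd45 <- .coords(cd45, species = "CD45")
  if (nrow(cd45) == 0) return(NA_real_)
  rho <- .density_sum_cpp(cd45[, 1], cd45[, 2], cd45[, 1], cd45[, 2],
                          decay_length)
  target / max(rho)
}

#' Assign TCR phosphorylation from the Lck* density field
#'
#' Each TCR is phosphorylated by an independent Bernoulli draw whose
#' probability maps from the summed Lck* density at its position (see
#' [phos_config()] for the rules). ITAM phosphorylation is all-or-none per
#' TCR. The pattern is summarized by `phos` (fraction of TCRs phosphorylated)
#' and the `rg_ratio` (see [rg_ratio()]).
#'
#' @param tcr A [point_pattern()] (its TCR rows are used) or coordinates; a
#'   `bound` column (or the `bound` argument) marks pMHC-bound TCRs.
#' @param cd45 CD45 positions (pattern or coordinates).
#' @param config A [phos_config()].
#' @param bound Optional logical vector overriding the `bound` mark.
#' @return A `phos_pattern`: `flags` (per-TCR logical), `phos`, `rg_ratio`
#'   (`NA` with `rg_defined = FALSE` when no TCR is phosphorylated),
#'   `densities`, `prob`, `beta`, and the inputs.
#' @export
#' @examples
#' set.seed(1)
#' pp <- segregated_pattern(depletion = 100)
#' ph <- assign_phosphorylation(pp, pp, phos_config(decay_length = 70, seed = 2))
#' ph
assign_phosphorylation <- function(tcr, cd45, config = phos_config(),
                                   bound = NULL) {
  xy <- .coords(tcr, species = "TCR")
  if (nrow(xy) < 1)
    stop_kinseg("kinseg_insufficient_pattern", "need at least one TCR")
  if (is.null(bound)) {
    bound <- if (is.data.frame(tcr) && "bound" %in% names(tcr))
      tcr$bound[tcr$species == "TCR"] else rep(TRUE, nrow(xy))
  }
  bound[is.na(bound)] <- FALSE
  rho <- suppressWarnings(lck_density(cd45, config$decay_length, xy))
  beta <- config$beta
  if (is.null(beta))
    beta <- calibrate_beta(cd45, config$decay_length, config$beta_target)
  p <- switch(config$prob_rule,
    "linear-capped" = pmin(1, beta * rho),
    "normalize-by-max" = if (max(rho) > 0) pmin(1, beta * rho / max(rho))
                         else rho,
    "exp-saturating" = 1 - exp(-beta * rho))
  p[is.na(p)] <- 0
  if (config$only_bound) p[!bound] <- 0
  set.seed(config$seed)
  flags <- runif(length(p)) < p
  phos <- mean(flags)
  rg <- if (any(flags)) rg_ratio(xy, xy[flags, , drop = FALSE]) else NA_real_
  structure(list(flags = flags, phos = phos, rg_ratio = rg,
                 rg_defined = any(flags), densities = rho, prob = p,
                 beta = beta, coords = xy, bound = bound, config = config),
            class = "phos_pattern")
}

#' @export
print.phos_pattern <- function(x, ...) {
  cat(sprintf("phos_pattern: %d/%d TCRs phosphorylated (Phos = %.3f), Rg ratio %s\n",
              sum(x$flags), length(x$flags), x$phos,
              if (x$rg_defined) sprintf("%.3f", x$rg_ratio) else "undefined"))
  invisible(x)
}

#' Rg ratio: peripheral enrichment of phosphorylated TCRs
#'
#' Ratio between the root-mean-square deviation of the phosphorylated TCRs
#' from the center of mass of all TCRs, and the radius of gyration of all
#' TCRs about that same center. Values above 1 indicate peripheral enrichment
#' of pTCRs, 1 a pTCR dispersion like all TCRs, below 1 central concentration.
#' The center and radius of gyration use all TCRs regardless of
#' phosphorylation state.
#'
#' @param all_tcr Coordinates of all TCRs (n >= 2).
#' @param ptcr Coordinates of the phosphorylated subset (n >= 1).
#' @return Dimensionless scalar >= 0.
#' @export
#' @examples
#' tcr <- rbind(c(0, 0), c(0, 0), c(0, 0), c(2, 0))
#' rg_ratio(tcr, rbind(c(2, 0))) # sqrt(3)
rg_ratio <- function(all_tcr, ptcr) {
  all_tcr <- .coords(all_tcr, species = "TCR")
  ptcr <- .coords(ptcr)
  if (nrow(ptcr) < 1)
    stop_kinseg("kinseg_undefined_ratio",
                "Rg ratio undefined: no phosphorylated TCRs")
  if (nrow(all_tcr) < 2)
    stop_kinseg("kinseg_insufficient_pattern", "need at least 2 TCRs")
  ctr <- colMeans(all_tcr)
  rmsd <- gyration_radius(ptcr[, 1], ptcr[, 2], ctr)
  rg <- gyration_radius(all_tcr[, 1], all_tcr[, 2], ctr)
  if (rg == 0)
    stop_kinseg("kinseg_undefined_ratio", "all TCRs coincide: Rg = 0")
  rmsd / rg
}

#' Csk-mediated attenuation of the Lck* field
#'
#' Csk accumulating at the current pTCR positions locally suppresses Lck
#' activity. The Lck* density at each TCR is multiplied by
#' `exp(-csk_strength * sigma(x))`, where `sigma` is a summed
#' exponential-kernel Csk density (short decay, default 20 nm) about the
#' phosphorylated-TCR positions. Intended for iterated re-assignment; a
#' single pass is applied here.
#'
#' @param ptcr_pattern A `phos_pattern` from [assign_phosphorylation()].
#' @param csk_strength Nonnegative attenuation scale (0 leaves the field
#'   unchanged).
#' @param csk_decay Decay length of the Csk kernel, nm.
#' @return The `phos_pattern` with attenuated `densities` (attribute
#'   `attenuation` holds the per-TCR factors); flags and summaries are not
#'   re-drawn.
#' @export
apply_csk_inhibition <- function(ptcr_pattern, csk_strength, csk_decay = 20) {
  if (csk_strength < 0)
    stop_kinseg("kinseg_invalid_config", "csk_strength must be >= 0")
  xy <- ptcr_pattern$coords
  pt <- xy[ptcr_pattern$flags, , drop = FALSE]
  sigma <- if (nrow(pt) == 0) rep(0, nrow(xy))
           else drop(.density_sum_cpp(xy[, 1], xy[, 2], pt[, 1], pt[, 2],
                                      csk_decay))
  att <- exp(-csk_strength * sigma)
  out <- ptcr_pattern
  out$densities <- ptcr_pattern$densities * att
  attr(out$densities, "attenuation") <- att
  out
}
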