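#' Labeled 2D point patterns
#'
#' A point pattern is a plain `data.frame` with columns `species` (factor),
#' `x`, `y` (nm) and optional logical marks (`bound`, `phosphorylated`). This
#' constructor validates and normalizes the columns.
#'
#' @param species Character or factor vector of species labels.
#' @param x,y Coordinates in nm.
#' @param bound Optional logical mark (TCR bound to pMHC).
#' @param phosphorylated Optional logical mark.
#' @return A `data.frame` of class `point_pattern`.
#' @export
#' @examples
#' point_pattern(c("TCR", "CD45"), x = c(0, 100), y = c(0, 0))
point_pattern <- function(species, x, y, bound = NULL, phosphorylated = NULL) {
  if (length(x) != length(y) || length(x) != length(species))
    stop_kinseg("kinseg_invalid_config", "species, x, y must have equal length")
  df <- data.frame(species = factor(species), x = as.numeric(x),
                   y = as.numeric(y))
  if (!is.null(bound)) df$bound <- as.logical(bound)
  if (!is.null(phosphorylated)) df$phosphorylated <- as.logical(phosphorylated)
  class(df) <- c("point_pattern", "data.frame")
  df
}

# uniform points in a disk (exact, via inverse-CDF radius)
runif_disk <- function(n, radius, center = c(0, 0)) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# uniform points in the square [0, L]^2, optionally excluding a central disk
runif_patch <- function(n, L, exclude_radius = 0, center = c(L / 2, L / 2)) {
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    p <- cbind(runif(m, 0, L), runif(m, 0, L))
    if (exclude_radius > 0) {
      keep <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 > exclude_radius^2
      p <- p[keep, , drop = FALSE]
    }
    out <- rbind(out, p)
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Generate a segregated TCR/CD45 pattern
#'
#' Idealized geometry used to train the TCR-phosphorylation surrogate: a
#' central disk of TCRs and a surrounding CD45 annulus separated from the
#' cluster edge by a depletion gap. This reproduces, as a parametric family,
#' the arrangement that the kinetic-segregation simulator produces dynamically.
#'
#' @param n_tcr,n_cd45 Point counts.
#' @param tcr_radius TCR cluster (disk) radius, nm.
#' @param tcr_taper Radial scale (nm) of the exponential center-weighting of
#'   the TCR density, `f(r) ~ r exp(-r / tcr_taper)` truncated at
#'   `tcr_radius`; matches the center-heavy clusters the membrane simulator
#'   produces (rebinding pulls receptors toward the ligand-rich center).
#'   `Inf` gives a uniform disk.
#' @param depletion Gap between the TCR disk edge and the CD45 inner edge, nm.
#' @param cd45_width Radial width of the CD45 annulus, nm.
#' @param patch_size Patch side, nm (points are centered in the patch).
#' @param bound Fraction (or logical vector) of TCRs marked bound.
#' @return A `point_pattern` with TCR and CD45 points.
#' @export
#' @examples
#' set.seed(1)
#' pp <- segregated_pattern(depletion = 100)
#' table(pp$species)
segregated_pattern <- function(n_tcr = 100, n_cd45 = 300, tcr_radius = 200,
                               tcr_taper = 0.45 * tcr_radius,
                               depletion = 100, cd45_width = 400,
                               patch_size = 2000, bound = TRUE) {
  if (depletion < 0 || tcr_radius <= 0)
    stop_kinseg("kinseg_invalid_config", "radii must be positive")
  ctr <- c(patch_size / 2, patch_size / 2)
  tcr <- if (is.finite(tcr_taper)) {
    # rejection from the uniform disk against the exponential taper
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < n_tcr) {
      cand <- runif_disk(2 * (n_tcr - nrow(out)) + 8, tcr_radius, ctr)
      rr <- sqrt((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2)
      out <- rbind(out, cand[runif(nrow(cand)) < exp(-rr / tcr_taper), ,
                             drop = FALSE])
    }
    out[seq_len(n_tcr), , drop = FALSE]
  } else runif_disk(n_tcr, tcr_radius, ctr)
  r0 <- tcr_radius + depletion
  r1 <- r0 + cd45_width
  r <- sqrt(runif(n_cd45, r0^2, r1^2)) # uniform density in the annulus
  th <- runif(n_cd45, 0, 2 * pi)
  cd45 <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
  b <- rep_len(if (is.logical(bound)) bound else runif(n_tcr) < bound, n_tcr)
  point_pattern(species = rep(c("TCR", "CD45"), c(n_tcr, n_cd45)),
                x = c(tcr[, 1], cd45[, 1]), y = c(tcr[, 2], cd45[, 2]),
                bound = c(b, rep(NA, n_cd45)))
}

# radius of gyration about a fixed center
gyration_radius <- function(x, y, center) {
  sqrt(mean((x - center[1])^2 + (y - center[2])^2))
}
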