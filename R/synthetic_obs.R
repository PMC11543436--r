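#' Parameters of the synthetic observation scene
#'
#' The scene is a synthetic stand-in for the imaging inputs the empirical
#' estimates are derived from: an interference-contrast-style membrane
#' topography over a patch with one tight-contact depression, a TCR point
#' pattern concentrated at low membrane height, a CD45 pattern concentrated
#' at 30-40 nm height, and a pTCR subset enriched at the contact periphery
#' (the ZAP-70 proxy). Defaults are calibrated so that [estimate_obs()] on
#' the default scene reproduces the anchor values Phos ~ 0.22 and
#' Rg ratio ~ 1.31.
#'
#' @param patch_size Patch side, nm.
#' @param grid_spacing Topography grid spacing, nm.
#' @param contact_radius Radius of the tight-contact depression, nm.
#' @param shoulder_width Width of the rim where the height rises, nm.
#' @param far_height Far-field membrane height, nm.
#' @param noise_sd,noise_corr SD (nm) and correlation length (nm) of the
#'   correlated Gaussian surface noise.
#' @param n_tcr,n_cd45 Point counts.
#' @param z_scale TCR height-weighting scale, nm (density ~
#'   `exp(-(z - min z)/z_scale)`).
#' @param cd45_band_center,cd45_band_width CD45 height preference, nm.
#' @param phos_frac Expected fraction of TCRs marked phosphorylated.
#' @param ring_radius,ring_width,ring_bias Peripheral-annulus bias of the
#'   pTCR subset: selection weight `1 + ring_bias * exp(-(r - ring_radius)^2
#'   / (2 ring_width^2))`; `ring_bias = 0` gives unbiased subsampling.
#' @return A `scene_params` list.
#' @export
scene_params <- function(patch_size = 2000, grid_spacing = 25,
                         contact_radius = 300, shoulder_width = 60,
                         far_height = 100, noise_sd = 3, noise_corr = 100,
                         n_tcr = 200, n_cd45 = 600, z_scale = 10,
                         cd45_band_center = 35, cd45_band_width = 6,
                         phos_frac = 0.22, ring_radius = 210,
                         ring_width = 25, ring_bias = 100) {
  if (contact_radius <= 0 || ring_radius <= 0)
    stop_kinseg("kinseg_invalid_config", "radii must be positive")
  structure(as.list(environment()), class = "scene_params")
}

#' Generate a synthetic observation scene
#'
#' @param params A [scene_params()] list.
#' @param seed Integer seed.
#' @return A `synthetic_scene`: `topography` (list with height matrix `z` in
#'   nm and `spacing`), `tcr`, `cd45` point patterns, `ptcr_idx` (indices
#'   into the TCR pattern), the parameters and seed.
#' @seealso [estimate_obs()], [estimate_tcr_from_topography()]
#' @export
#' @examples
#' sc <- generate_scene(scene_params(n_tcr = 100, n_cd45 = 200), seed = 1)
#' sc
generate_scene <- function(params = scene_params(), seed = 1L) {
  set.seed(seed)
  L <- params$patch_size; a <- params$grid_spacing
  n <- round(L / a)
  xc <- (seq_len(n) - 0.5) * a - L / 2
  r <- sqrt(outer(xc^2, xc^2, `+`))
  z <- params$far_height / (1 + exp(-(r - params$contact_radius) /
                                      params$shoulder_width))
  if (params$noise_sd > 0) {
    w <- matrix(rnorm(n * n), n, n)
    k <- params$noise_corr / a
    sm <- .gauss_smooth(w, k)
    z <- z + params$noise_sd * sm / sd(sm)
  }
  z[z < 0] <- 0
  topo <- list(z = z, spacing = a)
  tcr <- estimate_tcr_from_topography(topo, params$n_tcr, params$z_scale,
                                      seed = seed + 1L)
  cd45 <- .sample_from_weights(
    topo, exp(-(z - params$cd45_band_center)^2 /
                (2 * params$cd45_band_width^2)) + 0.02,
    params$n_cd45, species = "CD45")
  # peripheral-annulus bias for the pTCR subset
  rr <- sqrt((tcr$x - L / 2)^2 + (tcr$y - L / 2)^2)
  w <- 1 + params$ring_bias *
    exp(-(rr - params$ring_radius)^2 / (2 * params$ring_width^2))
  p <- params$phos_frac * w / mean(w)
  p[p > 1] <- 1
  ptcr_idx <- which(runif(length(p)) < p)
  structure(list(topography = topo, tcr = tcr, cd45 = cd45,
                 ptcr_idx = ptcr_idx, params = params, seed = seed),
            class = "synthetic_scene")
}

# separable Gaussian smoothing with reflection padding
.gauss_smooth <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_cells))
  kern <- dnorm(seq(-half, half), sd = sigma_cells)
  kern <- kern / sum(kern)
  pad <- function(v) c(rev(v[seq_len(half)]), v,
                       rev(v[length(v) - seq_len(half) + 1]))
  smooth1 <- function(v) {
    f <- stats::filter(pad(v), kern, sides = 2)
    f[half + seq_along(v)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(t(m), 2, smooth1))
}

.sample_from_weights <- function(topo, w, n_points, species) {
  idx <- sample.int(length(w), n_points, replace = TRUE, prob = as.vector(w))
  a <- topo$spacing
  nn <- nrow(topo$z)
  i <- (idx - 1) %% nn
  j <- (idx - 1) %/% nn
  point_pattern(species = rep(species, n_points),
                x = (i + runif(n_points)) * a,
                y = (j + runif(n_points)) * a)
}

#' Sample TCR positions from a membrane topography
#'
#' TCR molecules concentrate where the membrane is closest to the activating
#' surface; positions are drawn with density proportional to
#' `exp(-(z - min(z)) / z_scale)` (default scale 10 nm, the height band in
#' which TCRs are found).
#'
#' @param topography List with height matrix `z` (nm) and `spacing` (nm).
#' @param n_points Number of points to draw (> 0).
#' @param z_scale Height scale, nm (> 0).
#' @param seed Integer seed.
#' @return A TCR [point_pattern()].
#' @export
estimate_tcr_from_topography <- function(topography, n_points, z_scale = 10,
                                         seed = 1L) {
  if (n_points <= 0)
    stop_kinseg("kinseg_invalid_config", "n_points must be positive")
  if (z_scale <= 0)
    stop_kinseg("kinseg_invalid_config", "z_scale must be positive")
  if (!all(is.finite(topography$z)))
    stop_kinseg("kinseg_invalid_config", "topography must be finite")
  set.seed(seed)
  w <- exp(-(topography$z - min(topography$z)) / z_scale)
  .sample_from_weights(topography, w, n_points, species = "TCR")
}

#' Empirical-style estimates from a scene
#'
#' Computes the observables that feed the metamodel: the phosphorylated
#' fraction (pTCR count over TCR count) and the Rg ratio of the pTCR subset
#' relative to all TCRs ([rg_ratio()]).
#'
#' @param scene A [generate_scene()] result.
#' @return List with `phos_obs`, `rg_obs`, `n_tcr_used`, `n_ptcr_used`.
#' @export
estimate_obs <- function(scene) {
  n_tcr <- nrow(scene$tcr)
  if (n_tcr < 2)
    stop_kinseg("kinseg_insufficient_pattern", "scene needs at least 2 TCRs")
  if (length(scene$ptcr_idx) < 1)
    stop_kinseg("kinseg_undefined_estimate", "scene contains no pTCRs")
  pt <- scene$tcr[scene$ptcr_idx, , drop = FALSE]
  list(phos_obs = length(scene$ptcr_idx) / n_tcr,
       rg_obs = rg_ratio(scene$tcr, pt),
       n_tcr_used = n_tcr, n_ptcr_used = length(scene$ptcr_idx))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  est <- tryCatch(estimate_obs(x), error = function(e) NULL)
  cat(sprintf("synthetic_scene: %d TCR (%d pTCR), %d CD45, %dx%d topography\n",
              nrow(x$tcr), length(x$ptcr_idx), nrow(x$cd45),
              nrow(x$topography$z), ncol(x$topography$z)))
  if (!is.null(est))
    cat(sprintf("  estimates: Phos = %.3f, Rg ratio = %.3f\n", est$phos_obs,
                est$rg_obs))
  invisible(x)
}

#' @export
plot.synthetic_scene <- function(x, ...) {
  a <- x$topography$spacing
  n <- nrow(x$topography$z)
  ax <- (seq_len(n) - 0.5) * a
  image(ax, ax, x$topography$z, col = grey.colors(64, rev = TRUE),
        xlab = "x (nm)", ylab = "y (nm)", asp = 1, ...)
  contour(ax, ax, x$topography$z, add = TRUE, col = "grey40", nlevels = 5)
  points(x$cd45$x, x$cd45$y, col = "red3", pch = 16, cex = 0.4)
  points(x$tcr$x, x$tcr$y, col = "forestgreen", pch = 16, cex = 0.4)
  points(x$tcr$x[x$ptcr_idx], x$tcr$y[x$ptcr_idx], col = "orange", pch = 16,
         cex = 0.6)
  invisible(x)
}
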