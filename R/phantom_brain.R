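# Folded-cortex phantom: a labelled brain-like solid with analytically
# known surface areas, used as ground truth for the gyrification pipeline.
#
# The pial surface is the radial graph
#     r(theta, phi) = R + a(phi) * sin(k * theta) * sin(k * phi)
# with a(phi) = fold_amplitude_mm * lobe_amplitude[sector(phi)] constant on
# each azimuthal quadrant. With even k the fold term vanishes at the
# quadrant boundaries, so the stepwise per-lobe amplitudes leave the
# surface continuous and the sector-wise quadrature exact. The solid is all
# points with radius below r(theta, phi); the outer cortical ribbon of the
# stated thickness is labelled cGM and the interior WM, each split into the
# four azimuthal "lobes".

PHANTOM_LOBES <- c("frontal", "parietal", "temporal", "occipital")

#' Specify a folded-cortex phantom
#'
#' @param base_radius_mm radius R of the unfolded sphere (mm).
#' @param fold_amplitude_mm fold amplitude a (mm); 0 gives a plain ball.
#'   Must be below `base_radius_mm / 2`.
#' @param fold_frequency integer angular frequency k (folds per hemicircle);
#'   must be even when per-lobe amplitudes differ so the surface stays
#'   continuous across quadrant boundaries.
#' @param cortical_thickness_mm thickness of the outer cGM ribbon (mm).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param grid_shape integer length-3 output grid; must contain the sphere
#'   of radius `base_radius_mm + max fold amplitude` plus a 4-voxel margin.
#' @param lobe_amplitude 4 non-negative multipliers of the fold amplitude,
#'   one per azimuthal quadrant (frontal, parietal, temporal, occipital).
#'   The default is uniform folding; distinct values give the four lobes
#'   genuinely different gyrification for regional analyses.
#' @param seed integer; kept for provenance. The phantom is a deterministic
#'   function of its parameters (no random component).
#' @return A list of class \code{folded_brain_spec}.
#' @export
folded_brain_spec <- function(base_radius_mm = 60,
                              fold_amplitude_mm = 2,
                              fold_frequency = 22,
                              cortical_thickness_mm = 2,
                              voxel_size_mm = 1,
                              grid_shape = c(144, 144, 144),
                              lobe_amplitude = c(1, 1, 1, 1),
                              seed = 1L) {
  if (base_radius_mm <= 0) stop("base_radius_mm must be positive")
  if (fold_amplitude_mm < 0) stop("fold_amplitude_mm must be non-negative")
  if (fold_amplitude_mm >= base_radius_mm / 2) {
    stop("fold_amplitude_mm must be below base_radius_mm / 2")
  }
  if (fold_frequency < 1 || fold_frequency != round(fold_frequency)) {
    stop("fold_frequency must be a positive integer")
  }
  if (length(lobe_amplitude) != 4 || any(lobe_amplitude < 0)) {
    stop("lobe_amplitude must be 4 non-negative multipliers")
  }
  if (length(unique(lobe_amplitude)) > 1 && fold_frequency %% 2 != 0) {
    stop("fold_frequency must be even when lobe amplitudes differ ",
         "(the fold must vanish at quadrant boundaries)")
  }
  if (cortical_thickness_mm <= 0) stop("cortical_thickness_mm must be positive")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (length(grid_shape) != 3 || any(grid_shape < 2)) {
    stop("grid_shape must be 3 positive integers")
  }
  spec <- list(base_radius_mm = base_radius_mm,
               fold_amplitude_mm = fold_amplitude_mm,
               fold_frequency = as.integer(fold_frequency),
               cortical_thickness_mm = cortical_thickness_mm,
               voxel_size_mm = voxel_size_mm,
               grid_shape = as.integer(grid_shape),
               lobe_amplitude = as.numeric(lobe_amplitude),
               seed = as.integer(seed))
  class(spec) <- "folded_brain_spec"
  max_r <- max_phantom_radius(spec)
  need <- ceiling(2 * max_r / voxel_size_mm) + 8L  # 4-voxel margin per side
  if (any(grid_shape < need)) {
    stop("grid too small: the phantom of outer radius ", signif(max_r, 5),
         " mm needs at least ", need, " voxels per axis at ",
         voxel_size_mm, " mm, got ", paste(grid_shape, collapse = "x"))
  }
  spec
}

max_phantom_radius <- function(spec) {
  spec$base_radius_mm + spec$fold_amplitude_mm * max(spec$lobe_amplitude)
}

# quadrant index 1..4 from azimuth in [0, 2*pi)
phantom_sector <- function(phi) {
  pmin(floor(phi / (pi / 2)) + 1, 4)
}

phantom_radius_fun <- function(spec) {
  R <- spec$base_radius_mm
  a <- spec$fold_amplitude_mm
  k <- spec$fold_frequency
  m <- spec$lobe_amplitude
  function(theta, phi) {
    R + a * m[phantom_sector(phi)] * sin(k * theta) * sin(k * phi)
  }
}

#' Voxelise the folded-cortex phantom into a labelled volume
#'
#' Labels 1..4 are the cortical grey matter ribbon (outer
#' `cortical_thickness_mm`) in the frontal, parietal, temporal and occipital
#' azimuthal quadrants; labels 5..8 the corresponding white matter interior;
#' 0 is background. The companion mapping is
#' \code{\link{phantom_region_scheme}}. The output is a deterministic
#' function of the spec.
#'
#' @param spec a \code{\link{folded_brain_spec}}.
#' @return A \code{\link{label_volume}}.
#' @export
make_folded_brain <- function(spec) {
  stopifnot(inherits(spec, "folded_brain_spec"))
  d <- spec$grid_shape
  vox <- spec$voxel_size_mm
  centre <- (d - 1) / 2
  x <- (seq_len(d[1]) - 1 - centre[1]) * vox
  y <- (seq_len(d[2]) - 1 - centre[2]) * vox
  z <- (seq_len(d[3]) - 1 - centre[3]) * vox

  rfun <- phantom_radius_fun(spec)
  labels <- array(0L, dim = d)
  thick <- spec$cortical_thickness_mm
  # process by z-slab to keep memory flat
  xg <- matrix(x, nrow = d[1], ncol = d[2])
  yg <- matrix(y, nrow = d[1], ncol = d[2], byrow = TRUE)
  rho2 <- xg^2 + yg^2
  phi <- atan2(yg, xg) %% (2 * pi)
  sector <- phantom_sector(phi)
  for (kz in seq_len(d[3])) {
    rr <- sqrt(rho2 + z[kz]^2)
    theta <- acos(pmin(pmax(ifelse(rr > 0, z[kz] / rr, 1), -1), 1))
    rp <- rfun(theta, phi)
    inside <- rr <= rp
    cgm <- inside & rr > (rp - thick)
    slab <- matrix(0L, d[1], d[2])
    slab[cgm] <- sector[cgm]
    slab[inside & !cgm] <- sector[inside & !cgm] + 4L
    labels[, , kz] <- slab
  }
  label_volume(labels, rep(vox, 3))
}

#' Region scheme for the folded-cortex phantom
#'
#' @return A \code{\link{region_scheme}} mapping labels 1..8 of
#'   \code{\link{make_folded_brain}} to (tissue, lobe) pairs.
#' @export
phantom_region_scheme <- function() {
  region_scheme(label = 1:8,
                tissue = rep(c("cGM", "WM"), each = 4),
                lobe = rep(PHANTOM_LOBES, 2))
}

#' Analytic surface areas of the folded-cortex phantom
#'
#' The pial area is computed by dense midpoint quadrature of the
#' first-fundamental-form area element of the radial surface; the hull
#' (superficial surface) area is the analytic envelope: the sum over the
#' four azimuthal quadrants of a quarter sphere of radius
#' `R + a * lobe_amplitude`. The envelope is only a valid model of the
#' morphologically closed mask when the gyral spacing `pi * (R + a) / k` is
#' at most three times the closing radius (`n_dilations` voxels); specs
#' outside this regime are rejected rather than silently mis-oracled.
#'
#' @param spec a \code{\link{folded_brain_spec}}.
#' @param n_theta quadrature resolution in the polar direction (the
#'   azimuthal direction uses `2 * n_theta` points).
#' @param closing_radius_mm closing radius assumed by the envelope-validity
#'   guard; defaults to 3 dilation steps at the spec's voxel size.
#' @return A list with `pial_area_mm2`, `hull_area_mm2`, `gi`,
#'   `volume_mm3`, and per-lobe pial areas.
#' @export
analytic_phantom_areas <- function(spec, n_theta = 2000,
                                   closing_radius_mm = 3 * spec$voxel_size_mm) {
  stopifnot(inherits(spec, "folded_brain_spec"))
  R <- spec$base_radius_mm
  a <- spec$fold_amplitude_mm
  k <- spec$fold_frequency
  max_r <- max_phantom_radius(spec)
  spacing <- pi * max_r / k
  if (a > 0 && spacing > 3 * closing_radius_mm) {
    stop("spec outside the envelope-validity regime: gyral spacing ",
         signif(spacing, 4), " mm exceeds 3 x closing radius (",
         signif(3 * closing_radius_mm, 4), " mm); the morphological hull ",
         "would sag below the analytic envelope. Increase fold_frequency ",
         "or the closing radius.")
  }

  nt <- n_theta
  np <- 2 * n_theta
  theta <- (seq_len(nt) - 0.5) * pi / nt
  phi <- (seq_len(np) - 0.5) * 2 * pi / np
  dtheta <- pi / nt
  dphi <- 2 * pi / np

  st <- sin(theta); skt <- sin(k * theta); ckt <- cos(k * theta)
  skp <- sin(k * phi); ckp <- cos(k * phi)
  amp <- a * spec$lobe_amplitude[phantom_sector(phi)]

  pial_by_lobe <- numeric(4)
  volume <- 0
  # vectorise over theta, loop over phi (keeps peak memory small)
  for (j in seq_len(np)) {
    aj <- amp[j]
    r <- R + aj * skt * skp[j]
    rt <- aj * k * ckt * skp[j]
    rp <- aj * k * skt * ckp[j]
    dA <- r * sqrt(r^2 * st^2 + rt^2 * st^2 + rp^2)
    s <- phantom_sector(phi[j])
    pial_by_lobe[s] <- pial_by_lobe[s] + sum(dA) * dtheta * dphi
    volume <- volume + sum(r^3 / 3 * st) * dtheta * dphi
  }
  hull_by_lobe <- pi * (R + a * spec$lobe_amplitude)^2
  list(pial_area_mm2 = sum(pial_by_lobe),
       hull_area_mm2 = sum(hull_by_lobe),
       gi = sum(pial_by_lobe) / sum(hull_by_lobe),
       volume_mm3 = volume,
       pial_by_lobe_mm2 = stats::setNames(pial_by_lobe, PHANTOM_LOBES),
       hull_by_lobe_mm2 = stats::setNames(hull_by_lobe, PHANTOM_LOBES))
}
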