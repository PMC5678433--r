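# Phase-contrast flow phantom: pulsatile parabolic (Poiseuille) vessel
# profiles with closed-form time-averaged flow.

VESSEL_NAMES <- c("left_ica", "right_ica", "basilar")

#' Specify a phase-contrast flow phantom
#'
#' Three vessels (left and right internal carotid, basilar) carry parabolic
#' through-plane velocity profiles \code{v(r, p) = v_peak * m_p * (1 -
#' (r/R)^2)} modulated over the cardiac cycle by a waveform with mean 1.
#' The analytic time-averaged flow of each vessel is
#' \code{(v_peak / 2) * pi * R^2 * mean(m) * 60} ml/min.
#'
#' @param vessel_radii_mm radii of the three vessels (mm); the defaults
#'   approximate neonatal internal carotid and basilar calibres, giving a
#'   total flow around 100 ml/min.
#' @param peak_velocities_cm_s peak centreline velocities (cm/s); the
#'   instantaneous peak \code{v_peak * max(m)} must stay below the encoding
#'   ceiling.
#' @param n_phases number of cardiac phases.
#' @param waveform_modulation non-negative per-phase multipliers with
#'   mean 1; default a raised sinusoid over the cycle.
#' @param pixel_size_mm in-plane pixel size (mm).
#' @param grid_shape 2 positive integers, the velocity-map grid.
#' @param venc_cm_s maximal encoding velocity; velocities above it would
#'   alias in a real acquisition (default 140 cm/s).
#' @return A list of class \code{flow_phantom_spec}.
#' @export
flow_phantom_spec <- function(vessel_radii_mm = c(1, 1, 0.9),
                              peak_velocities_cm_s = c(40, 40, 30),
                              n_phases = 20,
                              waveform_modulation = NULL,
                              pixel_size_mm = 0.2,
                              grid_shape = c(128, 128),
                              venc_cm_s = 140) {
  if (length(vessel_radii_mm) != 3 || any(vessel_radii_mm <= 0)) {
    stop("vessel_radii_mm must be 3 positive radii")
  }
  if (length(peak_velocities_cm_s) != 3 || any(peak_velocities_cm_s < 0)) {
    stop("peak_velocities_cm_s must be 3 non-negative velocities")
  }
  if (n_phases < 1) stop("n_phases must be positive")
  if (is.null(waveform_modulation)) {
    p <- seq_len(n_phases) - 1
    waveform_modulation <- 1 + 0.6 * sin(2 * pi * p / n_phases)
    waveform_modulation <- waveform_modulation / mean(waveform_modulation)
  }
  if (length(waveform_modulation) != n_phases) {
    stop("waveform_modulation must have n_phases values")
  }
  if (any(waveform_modulation < 0)) {
    stop("waveform_modulation must be non-negative")
  }
  if (abs(mean(waveform_modulation) - 1) > 1e-8) {
    stop("waveform_modulation must have mean 1")
  }
  vmax <- max(peak_velocities_cm_s) * max(waveform_modulation)
  if (vmax > venc_cm_s) {
    stop("instantaneous peak velocity ", signif(vmax, 4),
         " cm/s exceeds the encoding ceiling (vENC ", venc_cm_s, " cm/s)")
  }
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  if (length(grid_shape) != 2 || any(grid_shape < 4)) {
    stop("grid_shape must be 2 positive integers")
  }
  structure(list(vessel_radii_mm = vessel_radii_mm,
                 peak_velocities_cm_s = peak_velocities_cm_s,
                 n_phases = as.integer(n_phases),
                 waveform_modulation = waveform_modulation,
                 pixel_size_mm = pixel_size_mm,
                 grid_shape = as.integer(grid_shape),
                 venc_cm_s = venc_cm_s),
            class = "flow_phantom_spec")
}

#' Generate the phase-contrast phantom
#'
#' Vessels are placed along the horizontal midline at 1/4, 1/2 and 3/4 of
#' the field of view; overlapping vessels are a geometry error. ROIs are
#' the exact vessel masks (pixel centre inside the vessel radius).
#'
#' @param spec a \code{\link{flow_phantom_spec}}.
#' @return A list with `series` (a \code{\link{phase_contrast_series}}),
#'   `rois` (named list of logical masks) and `analytic_flows_ml_min`
#'   (named per-vessel closed-form flows, plus `total`).
#' @export
make_phase_contrast_phantom <- function(spec) {
  stopifnot(inherits(spec, "flow_phantom_spec"))
  d <- spec$grid_shape
  px <- spec$pixel_size_mm
  fov <- d * px
  centres <- rbind(c(fov[1] * 0.25, fov[2] * 0.5),
                   c(fov[1] * 0.50, fov[2] * 0.5),
                   c(fov[1] * 0.75, fov[2] * 0.5))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      gap <- sqrt(sum((centres[i, ] - centres[j, ])^2))
      if (gap <= spec$vessel_radii_mm[i] + spec$vessel_radii_mm[j]) {
        stop("vessels ", VESSEL_NAMES[i], " and ", VESSEL_NAMES[j],
             " overlap on this grid; enlarge grid_shape or shrink radii")
      }
    }
  }
  xg <- matrix((seq_len(d[1]) - 0.5) * px, d[1], d[2])
  yg <- matrix((seq_len(d[2]) - 0.5) * px, d[1], d[2], byrow = TRUE)

  rois <- list()
  profile <- matrix(0, d[1], d[2])
  for (i in 1:3) {
    r2 <- (xg - centres[i, 1])^2 + (yg - centres[i, 2])^2
    R <- spec$vessel_radii_mm[i]
    inside <- r2 <= R^2
    rois[[VESSEL_NAMES[i]]] <- inside
    profile[inside] <- spec$peak_velocities_cm_s[i] * (1 - r2[inside] / R^2)
  }
  maps <- array(0, dim = c(d[1], d[2], spec$n_phases))
  for (p in seq_len(spec$n_phases)) {
    maps[, , p] <- profile * spec$waveform_modulation[p]
  }
  series <- phase_contrast_series(maps, rep(px, 2))

  r_cm <- spec$vessel_radii_mm / 10
  flows <- (spec$peak_velocities_cm_s / 2) * pi * r_cm^2 *
    mean(spec$waveform_modulation) * 60
  names(flows) <- VESSEL_NAMES
  list(series = series, rois = rois,
       analytic_flows_ml_min = c(flows, total = sum(flows)))
}

#' Write a flow phantom to disk
#'
#' The velocity series goes to a single multi-volume NIfTI
#' (`<prefix>_phases.nii.gz`, third dimension = cardiac phase, which keeps
#' the pixel spacing in the header), each vessel ROI to
#' `<prefix>_roi_<name>.nii.gz`, and the analytic flows to a JSON sidecar.
#'
#' @param phantom result of \code{\link{make_phase_contrast_phantom}}.
#' @param prefix output path prefix.
#' @return The sidecar path, invisibly.
#' @export
write_flow_phantom <- function(phantom, prefix) {
  s <- phantom$series
  img <- RNifti::asNifti(s$velocity_maps)
  RNifti::pixdim(img) <- c(s$pixel_spacing_mm, 1)
  RNifti::writeNifti(img, sprintf("%s_phases.nii.gz", prefix))
  for (nm in names(phantom$rois)) {
    img <- RNifti::asNifti(array(as.integer(phantom$rois[[nm]]),
                                 dim = c(dim(phantom$rois[[nm]]), 1)))
    RNifti::pixdim(img) <- c(s$pixel_spacing_mm, 1)
    RNifti::writeNifti(img, sprintf("%s_roi_%s.nii.gz", prefix, nm))
  }
  side <- paste0(prefix, "_truth.json")
  jsonlite::write_json(as.list(phantom$analytic_flows_ml_min), side,
                       auto_unbox = TRUE, digits = NA)
  invisible(side)
}
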