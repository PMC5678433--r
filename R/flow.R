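# Vessel flow quantification from phase-contrast velocity series, total
# cerebral blood flow, and cerebral oxygen delivery.

#' Construct a phase-contrast velocity series
#'
#' @param velocity_maps numeric array `nx x ny x n_phases` of signed
#'   through-plane velocities in cm/s.
#' @param pixel_spacing_mm in-plane pixel spacing, 2 positive values (mm).
#' @return An object of class \code{phase_contrast_series}.
#' @export
phase_contrast_series <- function(velocity_maps, pixel_spacing_mm) {
  d <- dim(velocity_maps)
  if (is.null(d) || !(length(d) %in% 2:3)) {
    stop("velocity_maps must be an nx x ny x n_phases array")
  }
  if (length(d) == 2) {
    velocity_maps <- array(velocity_maps, dim = c(d, 1))
    d <- dim(velocity_maps)
  }
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (length(pixel_spacing_mm) != 2 || any(pixel_spacing_mm <= 0)) {
    stop("pixel_spacing_mm must be 2 positive values")
  }
  structure(list(velocity_maps = velocity_maps,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 n_phases = d[3]),
            class = "phase_contrast_series")
}

#' Read a phase-contrast series from NIfTI
#'
#' Accepts either a single multi-volume NIfTI whose third dimension is the
#' cardiac phase, or a vector of per-phase 2D NIfTI files in cardiac order
#' (stored values in cm/s). NIfTI does not reliably carry pixel spacing for
#' plain 2D images, so `pixel_spacing_mm` can override the header.
#'
#' @param paths one multi-volume file or several per-phase files.
#' @param pixel_spacing_mm optional in-plane spacing override (mm).
#' @return A \code{\link{phase_contrast_series}}.
#' @export
read_phase_contrast_series <- function(paths, pixel_spacing_mm = NULL) {
  if (length(paths) == 0) stop("no phase files given")
  for (p in paths) if (!file.exists(p)) stop("no such file: ", p)
  if (length(paths) == 1) {
    img <- RNifti::readNifti(paths)
    a <- as.array(img)
    if (length(dim(a)) == 2) a <- array(a, dim = c(dim(a), 1))
    if (length(dim(a)) != 3) {
      stop("expected a 2D image or an x-y-phase stack, got ",
           length(dim(a)), "D data")
    }
    spacing <- pixel_spacing_mm %||% RNifti::pixdim(img)[1:2]
    return(phase_contrast_series(a, spacing))
  }
  imgs <- lapply(paths, function(p) {
    a <- as.array(RNifti::readNifti(p))
    if (length(dim(a)) > 2) a <- a[, , 1, drop = TRUE]
    a
  })
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(a) identical(dim(a), d), logical(1)))) {
    stop("phase images do not share a common grid")
  }
  spacing <- pixel_spacing_mm %||% RNifti::pixdim(RNifti::readNifti(paths[1]))[1:2]
  phase_contrast_series(array(unlist(imgs), dim = c(d, length(imgs))), spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Net flow through one vessel ROI
#'
#' Per-phase flow is the sum over ROI pixels of signed velocity times pixel
#' area (cm/s x cm^2 = cm^3/s); the vessel flow is the mean over cardiac
#' phases, converted to ml/min. Signed velocities are integrated as-is, so
#' the result is the net through-plane flow; negating the maps negates the
#' flow.
#'
#' @param series a \code{\link{phase_contrast_series}}.
#' @param roi logical matrix on the velocity-map grid.
#' @return Flow in ml/min.
#' @export
vessel_flow <- function(series, roi) {
  d <- dim(series$velocity_maps)
  if (!identical(dim(roi), d[1:2])) {
    stop("ROI grid ", paste(dim(roi), collapse = "x"),
         " does not match velocity maps ", paste(d[1:2], collapse = "x"))
  }
  if (!any(roi)) stop("ROI is empty")
  pix_area_cm2 <- prod(series$pixel_spacing_mm / 10)
  per_phase <- vapply(seq_len(d[3]), function(p) {
    vmap <- series$velocity_maps[, , p]
    if (anyNA(vmap[roi])) stop("velocity maps contain NA inside the ROI")
    sum(vmap[roi]) * pix_area_cm2
  }, numeric(1))
  mean(per_phase) * 60
}

#' Total cerebral blood flow
#'
#' The sum of the net flows through the left and right internal carotid
#' arteries and the basilar artery. The vertebral contribution to the
#' posterior circulation below the basilar confluence is not modelled (in
#' healthy adults it is under 3 percent of total brain flow).
#'
#' @param series a \code{\link{phase_contrast_series}}.
#' @param rois named list with non-empty logical masks `left_ica`,
#'   `right_ica`, `basilar` (pairwise disjoint).
#' @return CBF in ml/min.
#' @export
total_cbf <- function(series, rois) {
  missing <- setdiff(VESSEL_NAMES, names(rois))
  if (length(missing)) {
    stop("missing ROI(s): ", paste(missing, collapse = ", "))
  }
  for (i in 1:2) {
    for (j in (i + 1):3) {
      if (any(rois[[VESSEL_NAMES[i]]] & rois[[VESSEL_NAMES[j]]])) {
        stop("ROIs ", VESSEL_NAMES[i], " and ", VESSEL_NAMES[j],
             " overlap; vessel masks must be disjoint")
      }
    }
  }
  sum(vapply(VESSEL_NAMES, function(nm) vessel_flow(series, rois[[nm]]),
             numeric(1)))
}

#' Cerebral oxygen delivery
#'
#' Computes \code{CDO2 = SaO2 x Hb(g/dL) x 1.36 x CBF(ml/min)} where 1.36
#' ml O2 per g Hb is Huefner's constant. The default `as_printed` mode
#' evaluates the formula literally with haemoglobin in g/dL, matching the
#' scale on which neonatal CDO2 values around 1600 are reported; this
#' embeds a factor-of-100 unit convention (per dL of blood rather than per
#' ml). The `si` mode divides by 10, expressing Hb per ml of blood, which
#' is the dimensionally conventional ml O2/min.
#'
#' @param sao2 arterial oxygen saturation as a fraction in (0, 1]. Percent
#'   inputs must be divided by 100 by the caller.
#' @param hb haemoglobin concentration.
#' @param cbf cerebral blood flow in ml/min.
#' @param mode `"as_printed"` (default) or `"si"`.
#' @param hb_unit `"g_dl"` (default) or `"g_l"`; g/L inputs are divided by
#'   10 before entering the formula.
#' @param brain_volume_ml optional brain tissue volume, enabling
#'   \code{\link{indexed_cdo2}}.
#' @return A list of class \code{haemodynamic_record} with fields `sao2`,
#'   `hb_g_dl`, `cbf_ml_min`, `cdo2`, `mode`, `brain_volume_ml`.
#' @export
cdo2 <- function(sao2, hb, cbf, mode = c("as_printed", "si"),
                 hb_unit = c("g_dl", "g_l"), brain_volume_ml = NULL) {
  mode <- match.arg(mode)
  hb_unit <- match.arg(hb_unit)
  if (is.na(sao2) || sao2 <= 0 || sao2 > 1) {
    stop("sao2 must be a fraction in (0, 1]; percent values must be ",
         "divided by 100 before calling")
  }
  if (is.na(hb) || hb <= 0) stop("hb must be positive")
  if (is.na(cbf) || cbf <= 0) stop("cbf must be positive")
  hb_g_dl <- if (hb_unit == "g_l") hb / 10 else hb
  value <- sao2 * hb_g_dl * 1.36 * cbf
  if (mode == "si") value <- value / 10
  structure(list(sao2 = sao2, hb_g_dl = hb_g_dl, cbf_ml_min = cbf,
                 cdo2 = value, mode = mode,
                 brain_volume_ml = brain_volume_ml),
            class = "haemodynamic_record")
}

#' Oxygen delivery indexed per 100 ml of brain tissue
#'
#' @param record a \code{\link{cdo2}} result carrying `brain_volume_ml`.
#' @return CDO2 per 100 ml brain volume.
#' @export
indexed_cdo2 <- function(record) {
  stopifnot(inherits(record, "haemodynamic_record"))
  bv <- record$brain_volume_ml
  if (is.null(bv) || is.na(bv) || bv <= 0) {
    stop("brain_volume_ml is required to index CDO2")
  }
  record$cdo2 / (bv / 100)
}
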