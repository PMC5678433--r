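# Labelled segmentation volumes, tissue/lobe schemes and volumetrics.

TISSUE_CLASSES <- c("cGM", "WM", "deepGM", "cerebellum", "ventricle",
                    "extra_axial_CSF", "background")
LOBES <- c("frontal", "parietal", "temporal", "occipital", "none")

#' Construct a labelled volume
#'
#' A \code{label_volume} holds a 3D array of non-negative integer labels
#' together with its physical voxel spacing and a 4x4 affine. Voxel indices
#' are 0-based in physical terms: voxel \code{[i, j, k]} (1-based in R) sits
#' at physical position \code{(i-1, j-1, k-1) * spacing} under the default
#' diagonal affine. All volumes and areas downstream are reported in
#' physical units (ml, mm^2).
#'
#' @param voxels 3D array of non-negative integers (tissue/region labels).
#' @param spacing_mm numeric length-3, strictly positive voxel spacing in mm.
#' @param affine optional 4x4 matrix; defaults to \code{diag(c(spacing_mm, 1))}.
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(voxels, spacing_mm, affine = NULL) {
  if (length(dim(voxels)) != 3) {
    stop("`voxels` must be a 3D array; got ", length(dim(voxels)), " dimensions")
  }
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 strictly positive values")
  }
  storage.mode(voxels) <- "integer"
  if (any(voxels < 0, na.rm = TRUE) || anyNA(voxels)) {
    stop("labels must be non-negative integers without missing values")
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
  }
  structure(
    list(voxels = voxels, spacing_mm = as.numeric(spacing_mm), affine = affine),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels @", paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  tab <- table(x$voxels)
  cat("  labels:", paste(names(tab), collapse = ", "), "\n")
  invisible(x)
}

voxel_volume_ml <- function(lv) prod(lv$spacing_mm) / 1000

#' Read a labelled volume from a NIfTI file
#'
#' Accepts 3D NIfTI-1/2 images whose data are integer-valued (float storage
#' is tolerated when every value is integral, and cast). 4D images and
#' non-integral data are rejected.
#'
#' @param path path to a NIfTI file.
#' @return A \code{\link{label_volume}}.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4 && d[4] == 1) {
    arr <- arr[, , , 1, drop = TRUE]
    d <- dim(arr)
  }
  if (length(d) != 3) {
    stop("expected a 3D label volume, got ", length(d),
         "D data; 4D time series are not label maps")
  }
  if (any(abs(arr - round(arr)) > 1e-6)) {
    stop("volume contains non-integer values and cannot be a label map")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  label_volume(array(as.integer(round(arr)), dim = d), spacing,
               affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a labelled volume to NIfTI-1
#'
#' @param lv a \code{\link{label_volume}}.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path) {
  img <- RNifti::asNifti(lv$voxels)
  RNifti::pixdim(img) <- lv$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Define a label-to-(tissue, lobe) mapping
#'
#' Each integer label used in a volume maps to exactly one tissue class
#' (`cGM`, `WM`, `deepGM`, `cerebellum`, `ventricle`, `extra_axial_CSF`,
#' `background`) and one lobe (`frontal`, `parietal`, `temporal`,
#' `occipital`, or `none`).
#'
#' @param label integer vector of labels.
#' @param tissue character vector of tissue classes, one per label.
#' @param lobe character vector of lobes, one per label.
#' @return A data frame of class \code{region_scheme}.
#' @export
region_scheme <- function(label, tissue, lobe) {
  if (length(label) != length(tissue) || length(label) != length(lobe)) {
    stop("label, tissue and lobe must have equal length")
  }
  if (anyDuplicated(label)) {
    stop("duplicate labels in scheme: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  bad_t <- setdiff(unique(tissue), TISSUE_CLASSES)
  if (length(bad_t)) stop("unknown tissue class(es): ", paste(bad_t, collapse = ", "))
  bad_l <- setdiff(unique(lobe), LOBES)
  if (length(bad_l)) stop("unknown lobe(s): ", paste(bad_l, collapse = ", "))
  structure(
    data.frame(label = as.integer(label), tissue = as.character(tissue),
               lobe = as.character(lobe), stringsAsFactors = FALSE),
    class = c("region_scheme", "data.frame")
  )
}

#' Read a region scheme from CSV or JSON
#'
#' The CSV dialect has columns \code{label,tissue,lobe}; the JSON form is an
#' array of objects with the same fields.
#'
#' @param path path to a `.csv` or `.json` scheme file.
#' @return A \code{\link{region_scheme}}.
#' @export
read_region_scheme <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("label", "tissue", "lobe")
  if (!all(need %in% names(df))) {
    stop("scheme must have columns ", paste(need, collapse = ", "))
  }
  region_scheme(df$label, df$tissue, df$lobe)
}

#' @rdname read_region_scheme
#' @param scheme a \code{\link{region_scheme}} to write.
#' @export
write_region_scheme <- function(scheme, path) {
  utils::write.csv(as.data.frame(scheme), path, row.names = FALSE)
  invisible(path)
}

check_scheme_covers <- function(lv, scheme) {
  present <- sort(unique(as.vector(lv$voxels)))
  known <- c(0L, scheme$label)  # label 0 is implicit background if unmapped
  missing <- setdiff(present, known)
  if (length(missing)) {
    stop("labels present in volume but absent from scheme: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

scheme_lookup <- function(lv, scheme) {
  # label value -> row index of scheme (0 for implicit background)
  maxlab <- max(max(lv$voxels), max(scheme$label))
  tis <- rep("background", maxlab + 1L)
  lob <- rep("none", maxlab + 1L)
  tis[scheme$label + 1L] <- scheme$tissue
  lob[scheme$label + 1L] <- scheme$lobe
  list(tissue = tis, lobe = lob)
}

#' Regional tissue volumes in ml
#'
#' Computes the volumetric outcomes reported for a segmented brain: per
#' tissue class, lobar cortical grey matter, and whole brain. Whole brain is
#' defined as cGM + WM + deepGM + cerebellum, excluding ventricles and
#' extra-axial CSF (which are reported separately).
#'
#' @param lv a \code{\link{label_volume}}.
#' @param scheme a \code{\link{region_scheme}} covering every label in `lv`.
#' @return A data frame with columns `region` and `volume_ml`.
#' @export
tissue_volumes <- function(lv, scheme) {
  check_scheme_covers(lv, scheme)
  lk <- scheme_lookup(lv, scheme)
  vv <- voxel_volume_ml(lv)
  counts <- tabulate(lv$voxels + 1L, nbins = length(lk$tissue))

  vol_of <- function(tissues, lobes = LOBES) {
    sum(counts[lk$tissue %in% tissues & lk$lobe %in% lobes]) * vv
  }
  rows <- rbind(
    data.frame(region = "whole_brain",
               volume_ml = vol_of(c("cGM", "WM", "deepGM", "cerebellum"))),
    data.frame(region = "cortical_grey_matter", volume_ml = vol_of("cGM")),
    data.frame(region = paste0(c("frontal", "parietal", "temporal", "occipital"),
                               "_grey_matter"),
               volume_ml = vapply(c("frontal", "parietal", "temporal", "occipital"),
                                  function(lb) vol_of("cGM", lb), numeric(1))),
    data.frame(region = "white_matter", volume_ml = vol_of("WM")),
    data.frame(region = "deep_grey_matter", volume_ml = vol_of("deepGM")),
    data.frame(region = "cerebellum", volume_ml = vol_of("cerebellum")),
    data.frame(region = "ventricles", volume_ml = vol_of("ventricle")),
    data.frame(region = "extra_axial_CSF", volume_ml = vol_of("extra_axial_CSF"))
  )
  rownames(rows) <- NULL
  rows
}

#' Select a binary mask by tissue class and lobe
#'
#' @param lv a \code{\link{label_volume}}.
#' @param scheme a \code{\link{region_scheme}}.
#' @param tissues character vector of tissue classes to include.
#' @param lobes character vector of lobes to include (default: all).
#' @return A logical 3D array, TRUE where the voxel's (tissue, lobe) pair
#'   matches the request.
#' @export
combine_regions <- function(lv, scheme, tissues, lobes = LOBES) {
  if (length(tissues) == 0 || length(lobes) == 0) {
    stop("empty selection: at least one tissue and one lobe must be requested")
  }
  bad_t <- setdiff(tissues, TISSUE_CLASSES)
  if (length(bad_t)) stop("unknown tissue class(es): ", paste(bad_t, collapse = ", "))
  bad_l <- setdiff(lobes, LOBES)
  if (length(bad_l)) stop("unknown lobe(s): ", paste(bad_l, collapse = ", "))
  check_scheme_covers(lv, scheme)
  lk <- scheme_lookup(lv, scheme)
  sel <- lk$tissue %in% tissues & lk$lobe %in% lobes
  array(sel[lv$voxels + 1L], dim = dim(lv$voxels))
}
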