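# End-to-end orchestration: per-subject metrics, cohort statistics and
# report tables, driven by a serialisable run configuration.

#' Create a run configuration
#'
#' @param cohort_csv path to the cohort table (columns `subject_id`,
#'   `group`, `ga_wk`, `pma_wk`, optionally `sao2`, `hb_g_dl`, `rsco2`,
#'   `rsco2_repeat`, `physiology`, and pre-computed metrics such as `gi`
#'   or `gmv_ml`).
#' @param out_dir output directory (created if needed).
#' @param volumes_dir directory of per-subject label volumes
#'   (`<subject_id>.nii.gz`); optional.
#' @param flow_dir directory of per-subject phase-contrast data written in
#'   the layout of \code{\link{write_flow_phantom}}; optional.
#' @param scheme_csv region scheme for the volumes; required with
#'   `volumes_dir`.
#' @param gi a \code{\link{gi_params}} list.
#' @param cdo2_mode `"as_printed"` or `"si"` (see \code{\link{cdo2}}).
#' @param covariates ANCOVA covariates (default postmenstrual age).
#' @param alpha significance level; lobar families are Bonferroni-corrected
#'   to `alpha / regional_family`.
#' @param regional_family size of the lobar comparison family (default 4).
#' @param seed integer seed recorded in the manifest and used for any
#'   randomised step.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(cohort_csv, out_dir,
                       volumes_dir = NULL, flow_dir = NULL,
                       scheme_csv = NULL,
                       gi = gi_params(),
                       cdo2_mode = "as_printed",
                       covariates = "pma_wk",
                       alpha = 0.05, regional_family = 4,
                       seed = 1L) {
  if (!file.exists(cohort_csv)) stop("cohort_csv not found: ", cohort_csv)
  for (p in c(volumes_dir, flow_dir, scheme_csv)) {
    if (!is.null(p) && !file.exists(p)) stop("path not found: ", p)
  }
  if (!is.null(volumes_dir) && is.null(scheme_csv)) {
    stop("scheme_csv is required when volumes_dir is given")
  }
  structure(list(cohort_csv = cohort_csv, out_dir = out_dir,
                 volumes_dir = volumes_dir, flow_dir = flow_dir,
                 scheme_csv = scheme_csv, gi = unclass(gi),
                 cdo2_mode = cdo2_mode, covariates = covariates,
                 alpha = alpha, regional_family = regional_family,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file to write/read.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(run_config, c(
    x[setdiff(names(x), "gi")],
    list(gi = do.call(gi_params, as.list(x$gi)))
  ))
}

subject_volume_path <- function(config, subject_id) {
  for (ext in c(".nii.gz", ".nii")) {
    p <- file.path(config$volumes_dir, paste0(subject_id, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

read_subject_flow <- function(config, subject_id) {
  prefix <- file.path(config$flow_dir, subject_id)
  stack <- Sys.glob(sprintf("%s_phases.nii*", prefix))
  phases <- setdiff(Sys.glob(sprintf("%s_phase*.nii*", prefix)), stack)
  if (length(stack) == 0 && length(phases) == 0) return(NULL)
  series <- if (length(stack)) {
    read_phase_contrast_series(stack[1])
  } else {
    read_phase_contrast_series(sort(phases))
  }
  rois <- lapply(VESSEL_NAMES, function(nm) {
    p <- Sys.glob(sprintf("%s_roi_%s.nii*", prefix, nm))
    if (length(p) == 0) stop("missing ROI mask '", nm, "' for ", subject_id)
    as.array(RNifti::readNifti(p[1])) != 0
  })
  names(rois) <- VESSEL_NAMES
  list(series = series, rois = rois)
}

#' Compute all metrics for one subject
#'
#' Volumetrics (whole brain, tissue classes, lobar grey matter),
#' gyrification (whole brain plus four lobes) and, when flow data and the
#' needed covariates are present, CBF and (indexed) oxygen delivery.
#' Subjects without flow data get populated GI/volume fields and NA
#' haemodynamics.
#'
#' @param config a \code{\link{run_config}}.
#' @param subject_id subject identifier.
#' @param cohort_row optional one-row data frame with this subject's
#'   covariates (`sao2`, `hb_g_dl`) for the CDO2 computation.
#' @return A one-row data frame of metrics.
#' @export
run_subject <- function(config, subject_id, cohort_row = NULL) {
  out <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  scheme <- if (!is.null(config$scheme_csv)) {
    read_region_scheme(config$scheme_csv)
  }

  vol_path <- if (!is.null(config$volumes_dir)) {
    subject_volume_path(config, subject_id)
  }
  if (!is.null(vol_path)) {
    lv <- read_label_volume(vol_path)
    vols <- tissue_volumes(lv, scheme)
    vcols <- stats::setNames(vols$volume_ml, paste0("vol_", vols$region))
    out <- cbind(out, as.data.frame(as.list(vcols)))
    params <- do.call(gi_params, config$gi)
    git <- gyrification_table(lv, scheme, params = params)
    gcols <- stats::setNames(git$gi, paste0("gi_", git$region))
    out <- cbind(out, as.data.frame(as.list(gcols)))
  }

  out$cbf_ml_min <- NA_real_
  out$cdo2 <- NA_real_
  out$cdo2_indexed <- NA_real_
  if (!is.null(config$flow_dir)) {
    flow <- read_subject_flow(config, subject_id)
    if (!is.null(flow)) {
      cbf <- total_cbf(flow$series, flow$rois)
      out$cbf_ml_min <- cbf
      if (!is.null(cohort_row) &&
          all(c("sao2", "hb_g_dl") %in% names(cohort_row)) &&
          !is.na(cohort_row$sao2) && !is.na(cohort_row$hb_g_dl) && cbf > 0) {
        bv <- if ("vol_whole_brain" %in% names(out)) out$vol_whole_brain else NULL
        rec <- cdo2(cohort_row$sao2, cohort_row$hb_g_dl, cbf,
                    mode = config$cdo2_mode, brain_volume_ml = bv)
        out$cdo2 <- rec$cdo2
        if (!is.null(bv)) out$cdo2_indexed <- indexed_cdo2(rec)
      }
    }
  }
  out
}

gi_lobe_outcomes <- function(nms) {
  intersect(paste0("gi_", c("frontal", "parietal", "temporal", "occipital")),
            nms)
}

#' Run the full cohort pipeline
#'
#' Computes per-subject metrics, matches controls to cases on (GA, PMA),
#' fits the group ANCOVAs (with Bonferroni flag for the lobar GI family),
#' regresses oxygen delivery and NIRS saturation against the cortical
#' metrics, and writes the report bundle to `config$out_dir`:
#' `cohort_metrics.csv`, `group_comparisons.csv`, `regressions.csv`,
#' `matching.csv`, `failures.csv` (when any subject failed) and
#' `manifest.json`. Identical config and inputs give byte-identical
#' outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return The report bundle as a named list, invisibly.
#' @export
run_cohort <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group", "ga_wk", "pma_wk") %in% names(cohort))) {
    stop("cohort CSV must have subject_id, group, ga_wk, pma_wk")
  }

  failures <- list()
  metrics <- list()
  if (!is.null(config$volumes_dir) || !is.null(config$flow_dir)) {
    for (i in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[i]
      row <- tryCatch(run_subject(config, sid, cohort[i, ]),
                      error = function(e) e)
      if (inherits(row, "error")) {
        failures[[sid]] <- conditionMessage(row)
      } else {
        metrics[[sid]] <- row
      }
    }
  }
  computed <- if (length(metrics)) {
    Reduce(function(a, b) merge(a, b, all = TRUE), metrics)
  }
  full <- if (is.null(computed)) cohort else {
    merge(cohort, computed, by = "subject_id", all.x = TRUE, sort = TRUE)
  }
  full <- full[order(full$subject_id), ]

  # outcomes for the group comparison: computed volumes and GI, plus any
  # pre-computed metric columns provided in the cohort CSV
  candidate <- c(grep("^(vol_|gi_)", names(full), value = TRUE),
                 intersect(c("gi", "gmv_ml"), names(full)))
  usable <- function(oc) {
    ok <- stats::complete.cases(full[c(oc, "group", config$covariates)])
    length(unique(full$group[ok])) == 2 &&
      all(table(full$group[ok]) >= 3) &&
      stats::var(full[[oc]][ok]) > 0
  }
  outcomes <- Filter(usable, candidate)

  lobe_family <- gi_lobe_outcomes(outcomes)
  thr_lobe <- bonferroni_threshold(config$alpha,
                                   max(config$regional_family, 1))
  comparisons <- do.call(rbind, lapply(outcomes, function(oc) {
    a <- ancova_group_effect(full, oc, covariates = config$covariates)
    in_family <- oc %in% lobe_family
    thr <- if (in_family) thr_lobe else config$alpha
    data.frame(outcome = oc, group_effect = a$group_effect,
               p = a$group_p,
               n_control = a$n_per_group["control"],
               n_chd = a$n_per_group["CHD"],
               bonferroni_family = ifelse(in_family, "lobar_gi", "none"),
               threshold = thr, significant = a$group_p < thr,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  # physiology subgroups (abnormal mixing / left-sided / right-sided), each
  # versus its matched controls
  if ("physiology" %in% names(full)) {
    controls <- full[full$group == "control", ]
    subs <- setdiff(unique(stats::na.omit(full$physiology)), "")
    for (sg in sort(subs)) {
      cases <- full[full$group == "CHD" & !is.na(full$physiology) &
                      full$physiology == sg, ]
      if (nrow(cases) < 3 || nrow(controls) < nrow(cases)) next
      mt <- match_controls(cases, controls)
      sub_tab <- rbind(cases, controls[controls$subject_id %in% mt$control_id, ])
      for (oc in intersect(outcomes, c("gi", "gi_whole"))) {
        ok <- stats::complete.cases(sub_tab[c(oc, "group", config$covariates)])
        if (length(unique(sub_tab$group[ok])) < 2 ||
            any(table(sub_tab$group[ok]) < 3)) next
        a <- ancova_group_effect(sub_tab, oc, covariates = config$covariates)
        comparisons <- rbind(comparisons, data.frame(
          outcome = paste0(oc, "[", sg, "]"),
          group_effect = a$group_effect, p = a$group_p,
          n_control = a$n_per_group["control"],
          n_chd = a$n_per_group["CHD"],
          bonferroni_family = "none", threshold = config$alpha,
          significant = a$group_p < config$alpha,
          stringsAsFactors = FALSE, row.names = NULL))
      }
    }
  }

  # regressions of CDO2 / indexed CDO2 / rScO2 against cortical metrics
  xs <- intersect(c("cdo2", "cdo2_indexed", "rsco2"), names(full))
  ys <- intersect(c("gi", "gi_whole", "gmv_ml", "vol_cortical_grey_matter",
                    "vol_whole_brain"), names(full))
  regressions <- NULL
  for (x in xs) {
    for (y in ys) {
      ok <- stats::complete.cases(full[c(x, y)])
      if (sum(ok) < 3 || stats::var(full[[x]][ok]) == 0) next
      r <- linreg(full, x, y)
      regressions <- rbind(regressions, data.frame(
        x = x, y = y, slope = r$slope, intercept = r$intercept,
        r_squared = r$r_squared, p = r$p, n = r$n,
        stringsAsFactors = FALSE))
    }
  }
  if ("rsco2_repeat" %in% names(full)) {
    ok <- stats::complete.cases(full[c("rsco2", "rsco2_repeat")])
    if (sum(ok) >= 3) {
      r <- repeatability(full$rsco2[ok], full$rsco2_repeat[ok])
      regressions <- rbind(regressions, data.frame(
        x = "rsco2", y = "rsco2_repeat", slope = r$slope,
        intercept = r$intercept, r_squared = r$r_squared, p = r$p, n = r$n,
        stringsAsFactors = FALSE))
    }
  }

  matching <- match_controls(full[full$group == "CHD", ],
                             full[full$group == "control", ])

  write_out <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }
  write_out(full, "cohort_metrics.csv")
  write_out(comparisons, "group_comparisons.csv")
  if (!is.null(regressions)) write_out(regressions, "regressions.csv")
  write_out(matching, "matching.csv")
  if (length(failures)) {
    write_out(data.frame(subject_id = names(failures),
                         error = unlist(failures)), "failures.csv")
  }

  cfg_file <- tempfile(fileext = ".json")
  write_run_config(config, cfg_file)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   seed = config$seed,
                   n_subjects = nrow(full),
                   n_failed = length(failures),
                   package_version = as.character(utils::packageVersion("gyriflow")))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(cohort_metrics = full, group_comparisons = comparisons,
                 regressions = regressions, matching = matching,
                 failures = failures, manifest = manifest))
}

#' Generate a self-contained demonstration cohort on disk
#'
#' Writes a small two-group phantom cohort: per-subject folded-cortex label
#' volumes whose fold amplitude differs between groups (controls fold more,
#' emulating the reduced gyrification of the disease group), per-subject
#' phase-contrast phantoms for the CHD group, the region scheme, the cohort
#' CSV and a ready-to-run config JSON.
#'
#' @param dir output directory.
#' @param n_per_group subjects per group (default 4).
#' @param seed integer seed.
#' @param control_amplitude,chd_amplitude group mean fold amplitudes (mm).
#' @param voxel_size_mm phantom resolution (default 1.5 mm, keeping the
#'   demonstration light).
#' @return The \code{\link{run_config}} for the generated data, invisibly.
#' @export
demo_phantom_cohort <- function(dir, n_per_group = 4, seed = 1L,
                                control_amplitude = 2.5,
                                chd_amplitude = 1.5,
                                voxel_size_mm = 1.25) {
  vol_dir <- file.path(dir, "volumes")
  flow_dir <- file.path(dir, "flow")
  dir.create(vol_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(flow_dir, recursive = TRUE, showWarnings = FALSE)

  scheme <- phantom_region_scheme()
  scheme_path <- file.path(dir, "scheme.csv")
  write_region_scheme(scheme, scheme_path)

  with_seed(seed, {
    n <- 2 * n_per_group
    group <- rep(c("control", "CHD"), each = n_per_group)
    ids <- sprintf("%s%02d", ifelse(group == "CHD", "chd", "con"),
                   c(seq_len(n_per_group), seq_len(n_per_group)))
    ga <- stats::rnorm(n, 38.6, 0.8)
    pma <- pmax(stats::rnorm(n, 39.2, 0.6), ga)
    amp <- ifelse(group == "CHD", chd_amplitude, control_amplitude) +
      stats::rnorm(n, 0, 0.05)
    sao2 <- pmin(pmax(stats::rnorm(n, 0.93, 0.04), 0.6), 1)
    hb <- pmax(stats::rnorm(n, 16.1, 2.1), 8)
    vflow <- stats::runif(n, 0.7, 1.2)

    grid <- ceiling((2 * 33 / voxel_size_mm + 10) / 8) * 8
    for (i in seq_len(n)) {
      spec <- folded_brain_spec(
        base_radius_mm = 30, fold_amplitude_mm = amp[i], fold_frequency = 10,
        cortical_thickness_mm = 2, voxel_size_mm = voxel_size_mm,
        grid_shape = rep(grid, 3), lobe_amplitude = c(1, 1, 1, 1),
        seed = seed + i)
      lv <- make_folded_brain(spec)
      write_label_volume(lv, file.path(vol_dir, paste0(ids[i], ".nii.gz")))
      if (group[i] == "CHD") {
        fspec <- flow_phantom_spec(
          peak_velocities_cm_s = c(40, 40, 30) * vflow[i])
        ph <- make_phase_contrast_phantom(fspec)
        write_flow_phantom(ph, file.path(flow_dir, ids[i]))
      }
    }
    physiology <- rep(NA_character_, n)
    physiology[group == "CHD"] <-
      rep_len(c("mixing", "left_sided", "right_sided"), n_per_group)
    cohort <- data.frame(subject_id = ids, group = group,
                         ga_wk = ga, pma_wk = pma,
                         sao2 = ifelse(group == "CHD", sao2, NA),
                         hb_g_dl = ifelse(group == "CHD", hb, NA),
                         physiology = physiology,
                         stringsAsFactors = FALSE)
    cohort_path <- file.path(dir, "cohort.csv")
    utils::write.csv(cohort, cohort_path, row.names = FALSE)

    config <- run_config(cohort_csv = cohort_path,
                         out_dir = file.path(dir, "out"),
                         volumes_dir = vol_dir, flow_dir = flow_dir,
                         scheme_csv = scheme_path, seed = seed)
    write_run_config(config, file.path(dir, "config.json"))
    invisible(config)
  })
}
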