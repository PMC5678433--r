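# Synthetic cohort generator: two groups with a stated linear dependence of
# cortical metrics on cerebral oxygen delivery, plus group offsets and
# Gaussian noise. Ground truth for the statistical layer.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specify a synthetic cohort
#'
#' Controls and a disease ("CHD") group share gestational and postmenstrual
#' age distributions. Oxygen delivery (CDO2) is drawn for the CHD group
#' only (flow data are typically unavailable for healthy controls).
#' Gyrification index and cortical grey matter volume follow
#' \code{y = intercept + slope * CDO2 + group_offset + noise}, with
#' controls evaluated at the CDO2 population mean so that group offsets
#' read directly as CHD-minus-control differences.
#'
#' The population R-squared of a metric on CDO2 within the CHD group is
#' \code{(slope * cdo2_sd)^2 / ((slope * cdo2_sd)^2 + noise_sd^2)}. The
#' defaults put it near 0.48 for grey matter volume and 0.28 for
#' gyrification, with group means around 2.46 / 2.37 (GI) and 132 / 122 ml
#' (cortical grey matter), typical of term newborns scanned around 39
#' weeks postmenstrual age.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param ga_mean_wk,ga_sd_wk gestational age at birth, weeks.
#' @param pma_mean_wk,pma_sd_wk postmenstrual age at scan, weeks.
#' @param cdo2_mean,cdo2_sd oxygen delivery distribution (CHD group).
#' @param gi_intercept,gi_slope_per_cdo2,gi_noise_sd gyrification model.
#' @param gmv_intercept_ml,gmv_slope_per_cdo2,gmv_noise_sd_ml grey matter
#'   volume model (ml).
#' @param group_gi_offset,group_gmv_offset_ml additive CHD-minus-control
#'   offsets.
#' @param rsco2_mean,rsco2_sd,rsco2_repeat_r2 regional cerebral oxygen
#'   saturation (NIRS) level, spread, and the population R-squared between
#'   consecutive readings.
#' @param hb_mean_g_dl,hb_sd_g_dl,sao2_mean,sao2_sd haemoglobin and
#'   arterial saturation (CHD group; saturation truncated to (0, 1]).
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return A list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 30,
                        ga_mean_wk = 38.6, ga_sd_wk = 1.0,
                        pma_mean_wk = 39.2, pma_sd_wk = 0.8,
                        cdo2_mean = 1700, cdo2_sd = 450,
                        gi_intercept = 2.211,
                        gi_slope_per_cdo2 = 1.49e-4,
                        gi_noise_sd = 0.108,
                        gmv_intercept_ml = 94.3,
                        gmv_slope_per_cdo2 = 0.0222,
                        gmv_noise_sd_ml = 10.4,
                        group_gi_offset = -0.091,
                        group_gmv_offset_ml = -10,
                        rsco2_mean = 70, rsco2_sd = 7,
                        rsco2_repeat_r2 = 0.86,
                        hb_mean_g_dl = 16.1, hb_sd_g_dl = 2.1,
                        sao2_mean = 0.93, sao2_sd = 0.05,
                        seed = 1L) {
  if (n_per_group < 3) stop("n_per_group must be at least 3")
  sds <- c(ga_sd_wk, pma_sd_wk, cdo2_sd, rsco2_sd, hb_sd_g_dl, sao2_sd)
  if (any(sds <= 0)) stop("all sd fields must be strictly positive")
  if (gi_noise_sd < 0 || gmv_noise_sd_ml < 0) {
    stop("noise sds must be non-negative")
  }
  if (rsco2_repeat_r2 <= 0 || rsco2_repeat_r2 > 1) {
    stop("rsco2_repeat_r2 must be in (0, 1]")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A data frame with columns `subject_id`, `group`, `ga_wk`,
#'   `pma_wk`, `cdo2`, `gi`, `gmv_ml`, `rsco2`, `rsco2_repeat`, `hb_g_dl`,
#'   `sao2` (flow-derived fields are NA for controls). Identical spec and
#'   seed give an identical table.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  with_seed(spec$seed, {
    group <- rep(c("control", "CHD"), each = n)
    ga <- stats::rnorm(2 * n, spec$ga_mean_wk, spec$ga_sd_wk)
    pma <- pmax(stats::rnorm(2 * n, spec$pma_mean_wk, spec$pma_sd_wk), ga)
    cdo2 <- rep(NA_real_, 2 * n)
    chd <- group == "CHD"
    cdo2[chd] <- pmax(stats::rnorm(n, spec$cdo2_mean, spec$cdo2_sd),
                      spec$cdo2_mean / 10)
    # controls are evaluated at the population-mean CDO2 so the injected
    # group offsets are exactly the expected group differences
    cdo2_eff <- ifelse(chd, cdo2, spec$cdo2_mean)
    off <- as.numeric(chd)
    gi <- spec$gi_intercept + spec$gi_slope_per_cdo2 * cdo2_eff +
      off * spec$group_gi_offset + stats::rnorm(2 * n, 0, spec$gi_noise_sd)
    gmv <- spec$gmv_intercept_ml + spec$gmv_slope_per_cdo2 * cdo2_eff +
      off * spec$group_gmv_offset_ml +
      stats::rnorm(2 * n, 0, spec$gmv_noise_sd_ml)
    rsco2 <- stats::rnorm(2 * n, spec$rsco2_mean, spec$rsco2_sd)
    noise_sd <- spec$rsco2_sd * sqrt(1 / spec$rsco2_repeat_r2 - 1)
    rsco2_rep <- rsco2 + stats::rnorm(2 * n, 0, noise_sd)
    hb <- rep(NA_real_, 2 * n)
    sao2 <- rep(NA_real_, 2 * n)
    hb[chd] <- pmax(stats::rnorm(n, spec$hb_mean_g_dl, spec$hb_sd_g_dl), 5)
    sao2[chd] <- pmin(pmax(stats::rnorm(n, spec$sao2_mean, spec$sao2_sd),
                           0.5), 1)
    data.frame(
      subject_id = sprintf("%s%02d", ifelse(chd, "chd", "con"),
                           c(seq_len(n), seq_len(n))),
      group = group,
      ga_wk = ga,
      pma_wk = pma,
      cdo2 = cdo2,
      gi = gi,
      gmv_ml = gmv,
      rsco2 = rsco2,
      rsco2_repeat = rsco2_rep,
      hb_g_dl = hb,
      sao2 = sao2,
      stringsAsFactors = FALSE
    )
  })
}
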