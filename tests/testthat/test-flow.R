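# Phase-contrast flow quantification and oxygen delivery.

test_that("uniform velocity over a known ROI gives the closed-form flow", {
  # 10 cm/s over 1 cm^2 (100 pixels of 1 mm^2) -> 10 cm3/s -> 600 ml/min
  maps <- array(0, c(20, 20, 4))
  maps[1:10, 1:10, ] <- 10
  s <- phase_contrast_series(maps, c(1, 1))
  roi <- matrix(FALSE, 20, 20)
  roi[1:10, 1:10] <- TRUE
  expect_equal(vessel_flow(s, roi), 600)
  # linearity in ROI area: half the ROI, half the flow
  roi2 <- roi
  roi2[1:5, ] <- FALSE
  expect_equal(vessel_flow(s, roi2), 300)
})

test_that("Poiseuille phantom recovers the analytic flow within 5%", {
  ph <- make_phase_contrast_phantom(flow_phantom_spec())
  for (nm in names(ph$rois)) {
    measured <- vessel_flow(ph$series, ph$rois[[nm]])
    expect_equal(measured, ph$analytic_flows_ml_min[[nm]], tolerance = 0.05)
  }
})

test_that("flow is signed and linear in velocity", {
  ph <- make_phase_contrast_phantom(flow_phantom_spec())
  f <- vessel_flow(ph$series, ph$rois$left_ica)
  neg <- ph$series
  neg$velocity_maps <- -neg$velocity_maps
  expect_equal(vessel_flow(neg, ph$rois$left_ica), -f)
  dbl <- ph$series
  dbl$velocity_maps <- 2 * dbl$velocity_maps
  expect_equal(vessel_flow(dbl, ph$rois$left_ica), 2 * f)
  # analytic flow is linear in v_peak too
  ph2 <- make_phase_contrast_phantom(
    flow_phantom_spec(peak_velocities_cm_s = 2 * c(40, 40, 30)))
  expect_equal(ph2$analytic_flows_ml_min[["total"]],
               2 * ph$analytic_flows_ml_min[["total"]])
  # zero peak velocity -> zero analytic flow
  ph0 <- make_phase_contrast_phantom(
    flow_phantom_spec(peak_velocities_cm_s = c(0, 0, 0)))
  expect_equal(unname(ph0$analytic_flows_ml_min[["total"]]), 0)
})

test_that("discretisation error shrinks with pixel size", {
  err_at <- function(px, grid) {
    ph <- make_phase_contrast_phantom(
      flow_phantom_spec(pixel_size_mm = px, grid_shape = c(grid, grid)))
    abs(vessel_flow(ph$series, ph$rois$left_ica) -
          ph$analytic_flows_ml_min[["left_ica"]]) /
      ph$analytic_flows_ml_min[["left_ica"]]
  }
  expect_lt(err_at(0.1, 256), err_at(0.4, 64))
})

test_that("total CBF is the sum of the three vessels and name-symmetric", {
  ph <- make_phase_contrast_phantom(flow_phantom_spec())
  flows <- vapply(names(ph$rois), function(nm) {
    vessel_flow(ph$series, ph$rois[[nm]])
  }, numeric(1))
  cbf <- total_cbf(ph$series, ph$rois)
  expect_equal(cbf, sum(flows))
  expect_equal(total_cbf(ph$series, ph$rois[c(3, 1, 2)]), cbf)
  # zeroing one vessel drops CBF by exactly that vessel's flow
  z <- ph$series
  z$velocity_maps[rep(ph$rois$basilar, z$n_phases)] <- 0
  expect_equal(total_cbf(z, ph$rois), cbf - flows[["basilar"]])
  expect_error(total_cbf(ph$series, ph$rois[1:2]), "basilar")
})

test_that("flow input validation", {
  ph <- make_phase_contrast_phantom(flow_phantom_spec())
  expect_error(vessel_flow(ph$series, matrix(FALSE, 8, 8)), "grid")
  empty <- matrix(FALSE, 128, 128)
  expect_error(vessel_flow(ph$series, empty), "empty")
  bad <- ph$series
  bad$velocity_maps[ph$rois$left_ica][1] <- NA
  expect_error(vessel_flow(bad, ph$rois$left_ica), "NA")
  expect_error(flow_phantom_spec(peak_velocities_cm_s = c(200, 40, 30)),
               "vENC")
  expect_error(flow_phantom_spec(waveform_modulation = rep(2, 20)), "mean 1")
  expect_error(
    make_phase_contrast_phantom(flow_phantom_spec(
      vessel_radii_mm = c(4, 4, 1), grid_shape = c(48, 48))),
    "overlap")
})

test_that("flow phantom round-trips through NIfTI with spacing intact", {
  ph <- make_phase_contrast_phantom(flow_phantom_spec())
  pre <- file.path(tempdir(), "flowrt")
  write_flow_phantom(ph, pre)
  s2 <- read_phase_contrast_series(paste0(pre, "_phases.nii.gz"))
  expect_equal(s2$pixel_spacing_mm, ph$series$pixel_spacing_mm)
  expect_equal(s2$n_phases, ph$series$n_phases)
  roi <- as.array(RNifti::readNifti(paste0(pre, "_roi_basilar.nii.gz"))) != 0
  # velocities are stored as float32, so agreement is to single precision
  expect_equal(vessel_flow(s2, roi),
               vessel_flow(ph$series, ph$rois$basilar), tolerance = 1e-6)
  truth <- jsonlite::fromJSON(paste0(pre, "_truth.json"))
  expect_equal(truth$total, ph$analytic_flows_ml_min[["total"]])
})

test_that("CDO2 formula: unit values, printed magnitude, SI mode", {
  expect_equal(cdo2(1.0, 10, 100)$cdo2, 1360.0)
  expect_equal(cdo2(1.0, 10, 100, mode = "si")$cdo2, 136.0)
  # independently computed product: 0.98 * 16.1 * 1.36 * 76.4
  expect_equal(cdo2(0.98, 16.1, 76.4)$cdo2, 1639.397312)
  # g/L inputs are converted to g/dL
  expect_equal(cdo2(0.98, 161, 76.4, hb_unit = "g_l")$cdo2,
               cdo2(0.98, 16.1, 76.4)$cdo2)
  expect_error(cdo2(98, 16.1, 76.4), "percent")
  expect_error(cdo2(0.5, -1, 76.4), "hb")
})

test_that("CDO2 is strictly monotone in each input", {
  base <- cdo2(0.9, 15, 80)$cdo2
  expect_gt(cdo2(0.95, 15, 80)$cdo2, base)
  expect_gt(cdo2(0.9, 16, 80)$cdo2, base)
  expect_gt(cdo2(0.9, 15, 90)$cdo2, base)
})

test_that("indexed CDO2 normalises per 100 ml of brain", {
  rec <- cdo2(1.0, 10, 110.3, brain_volume_ml = 300)
  expect_equal(indexed_cdo2(rec), rec$cdo2 / 3)
  rec2 <- cdo2(1.0, 10, 110.3, brain_volume_ml = 100)
  expect_equal(indexed_cdo2(rec2), rec2$cdo2)
  rec3 <- cdo2(1.0, 10, 110.3, brain_volume_ml = 600)
  expect_equal(indexed_cdo2(rec3), indexed_cdo2(rec) / 2)
  expect_error(indexed_cdo2(cdo2(1.0, 10, 110.3)), "brain_volume")
})
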