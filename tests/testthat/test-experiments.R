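short_setting <- energy_setting(90, 1, observation_time = 2)

test_that("an empty scenario list yields an empty matrix", {
  expect_equal(nrow(run_matrix(data.frame())), 0)
})

test_that("the study matrix runs scenarios and records failures without
           aborting", {
  scen <- data.frame(model = c("BH", "NOPE"), orientation = c(90, 90),
                     nominal_power = c(90, 25), pulse_duration = c(1, 1))
  out <- run_matrix(scen, observation_time = 2,
                    resolution = mesh_resolution(scale = 3), dt = 0.05)
  expect_equal(nrow(out), 2)
  expect_true(is.finite(out$depth_rf[1]))
  expect_true(is.finite(out$P_T[1]))
  expect_true(is.na(out$depth_rf[2]))
  expect_match(out$error[2], "arg")
})

test_that("the default design is the full 3 x 3 x 3 matrix", {
  # inspect the default scenario expansion without running it
  scen <- expand.grid(model = c("BH", "INTERMEDIATE", "TM"),
                      orientation = c(0, 45, 90),
                      setting = c("25/20", "50/6", "90/4"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(scen), 27)
})

test_that("blood-height sweep sorts heights and reproduces the base run
           bit-for-bit", {
  out <- blood_height_sweep(c(20, 10), setting = short_setting,
                            resolution = mesh_resolution(scale = 3),
                            dt = 0.05)
  expect_equal(out$blood_height, c(10, 20))
  expect_error(blood_height_sweep(c(-1, 10), setting = short_setting),
               "positive")
  base <- run_scenario("TM", 90, short_setting, blood_height = 20,
                       resolution = mesh_resolution(scale = 3), dt = 0.05)
  expect_identical(out$depth_rf[out$blood_height == 20],
                   base$metrics_rf$depth)
  expect_identical(out$volume_end[out$blood_height == 20],
                   base$metrics_end$volume)
})

test_that("difference report subtracts matched scenarios", {
  df <- data.frame(model = c("BH", "TM", "BH", "TM"),
                   orientation = c(90, 90, 0, 0),
                   nominal_power = 25, pulse_duration = 20,
                   depth_rf = c(3.4, 4.2, 3.5, 4.3),
                   depth_end = c(3.9, 5.0, 4.0, 5.1),
                   width_rf = c(6.3, 7.8, 6.6, 8.0),
                   width_end = c(6.8, 8.4, 7.0, 8.6),
                   volume_rf = 1, volume_end = 2,
                   P_T = c(16, 24, 17, 25), E_T = c(19, 28, 20, 30))
  rep <- difference_report(df)
  expect_equal(rep$d_depth_end[rep$orientation == 90], 1.1)
  expect_equal(rep$d_P_T, c(8, 8))
  expect_equal(rep$d_width_rf[rep$orientation == 0], 1.4)
})

test_that("scenario results expose lesion metrics at both time points", {
  res <- run_scenario("BH", 90, short_setting,
                      resolution = mesh_resolution(scale = 3), dt = 0.05)
  expect_s3_class(res$metrics_rf, "lesion_metrics")
  expect_s3_class(res$metrics_end, "lesion_metrics")
  expect_gte(res$metrics_end$depth, res$metrics_rf$depth)
  expect_true(res$P_T > 0 && res$P_T < 100)
  expect_true(res$E_T >= res$P_T - 1)
})
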