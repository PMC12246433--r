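dilution_sheet <- function(inputs) {
  sample_sheet(data.frame(
    sample_id = sprintf("M%d", seq_along(inputs)), compartment = "cell",
    donor = "pool", input_ng = inputs, dilution_member = TRUE))
}

test_that("dose-response QC passes linear probes and fails flat ones", {
  inputs <- c(12.5, 25, 50, 100)
  m <- make_matrix(rbind(prop = 2 * inputs, flat = rep(3, 4),
                         noisy = c(1, 3, 2, 4)),
                   probes = c("prop", "flat", "noisy"),
                   samples = sprintf("M%d", 1:4))
  qc <- probe_dose_response(m, dilution_sheet(inputs), alpha = 0.05)
  st <- qc$probe_stats
  expect_equal(st$pearson_r[st$probe_id == "prop"], 1, tolerance = 1e-12)
  expect_true(st$pass[st$probe_id == "prop"])
  expect_true(is.na(st$pearson_r[st$probe_id == "flat"]))
  expect_false(st$pass[st$probe_id == "flat"])
  expect_equal(qc$filtered_fraction, 2 / 3)

  expect_error(probe_dose_response(m[, 1:2], dilution_sheet(inputs[1:2])),
               "3 dilution")
})

test_that("per-probe Pearson agrees with the sum-of-products oracle", {
  inputs <- 1:6
  y <- c(1, 3, 2, 4, 6, 5)
  m <- make_matrix(rbind(y), probes = "p1", samples = sprintf("M%d", 1:6))
  qc <- probe_dose_response(m, dilution_sheet(inputs))
  expect_equal(qc$probe_stats$pearson_r, pearson_brute(inputs, y),
               tolerance = 1e-12)
  expect_equal(qc$probe_stats$pearson_r, 31 / 35, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    yy <- stats::runif(6)
    mm <- make_matrix(rbind(yy), probes = "p", samples = sprintf("M%d", 1:6))
    qq <- probe_dose_response(mm, dilution_sheet(inputs))
    expect_equal(qq$probe_stats$pearson_r, pearson_brute(inputs, yy),
                 tolerance = 1e-12)
  }
})

test_that("threshold is the pooled mean of first-detection intensities", {
  # step 1->2 newly detects intensities {1.0, 2.0}; step 2->3 detects {1.5}
  vals <- rbind(a = c(0, 1.0, 3.0),
                b = c(0, 2.0, 4.0),
                c = c(0, 0, 1.5),
                d = c(5, 6, 7))
  m <- make_matrix(vals, probes = rownames(vals), samples = sprintf("M%d", 1:3))
  thr <- derive_detection_threshold(m, dilution_sheet(c(25, 50, 100)))
  expect_equal(thr$value, mean(c(1.0, 2.0, 1.5)))
  expect_equal(thr$value, 1.5)
  expect_identical(thr$n_contributing_probes, 3L)
  expect_setequal(thr$per_step_new_probe_ids[["25->50"]], c("a", "b"))
  expect_identical(thr$per_step_new_probe_ids[["50->100"]], "c")
  expect_equal(unname(thr$per_step_means), c(1.5, 1.5))

  all_present <- make_matrix(matrix(1:6 + 0.0, 2), probes = c("a", "b"),
                             samples = sprintf("M%d", 1:3))
  expect_error(derive_detection_threshold(all_present, dilution_sheet(c(25, 50, 100))),
               "no newly detected")
})

test_that("threshold derivation is invariant to probe order and matches brute force on synthetic series", {
  cfg <- small_config(seed = 8)
  w <- generate_world(cfg)
  sheet <- preset_designs("dilution_series", cfg)
  m <- simulate_arrays(w, sheet, seed = 8)
  thr <- derive_detection_threshold(m, sheet)
  expect_equal(thr$value, threshold_brute(unclass(m), sheet$input_ng),
               tolerance = 1e-12)

  perm <- probe_matrix(unclass(m)[sample(nrow(m)), , drop = FALSE])
  thr_perm <- derive_detection_threshold(perm, sheet)
  expect_equal(thr_perm$value, thr$value, tolerance = 1e-12)
  expect_identical(thr_perm$n_contributing_probes, thr$n_contributing_probes)
})

test_that("at zero noise the filtered fraction equals the saturated-probe fraction exactly", {
  cfg <- zero_noise(small_config, nonlinear_probe_fraction = 0.1)
  w <- generate_world(cfg)
  sheet <- preset_designs("dilution_series", cfg)
  m <- simulate_arrays(w, sheet)
  qc <- probe_dose_response(m, sheet)
  expect_setequal(setdiff(rownames(m), qc$pass), names(w$nonlinear)[w$nonlinear])
  expect_equal(qc$filtered_fraction, sum(w$nonlinear) / length(w$nonlinear))
})

test_that("normalised dilution patterns correlate perfectly at zero noise and with themselves", {
  cfg <- zero_noise(small_config, nonlinear_probe_fraction = 0)
  w <- generate_world(cfg)
  sheet <- preset_designs("dilution_series", cfg)
  m <- simulate_arrays(w, sheet)
  rob <- pattern_robustness(m, sheet, reference_input = 100)
  expect_equal(rob$spearman_rho, rep(1, 6), tolerance = 1e-12)

  expect_error(pattern_robustness(m, sheet, reference_input = 60), "not in")

  cfg2 <- small_config(seed = 4)
  w2 <- generate_world(cfg2)
  m2 <- simulate_arrays(w2, sheet <- preset_designs("dilution_series", cfg2), seed = 4)
  rob2 <- pattern_robustness(m2, sheet, reference_input = 100)
  expect_equal(rob2$spearman_rho[rob2$input_ng == 100], 1, tolerance = 1e-12)
})
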