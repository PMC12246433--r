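test_that("world construction honours the overlap design and is deterministic", {
  w <- generate_world(small_config())
  expect_length(intersect(w$int_support, w$sec_support), 20L)
  expect_length(w$int_only, 10L)
  expect_length(w$sec_only, 10L)
  expect_equal(sum(w$profiles$int), 1, tolerance = 1e-9)
  expect_equal(sum(w$profiles$sec), 1, tolerance = 1e-9)
  expect_setequal(names(w$profiles$int)[w$profiles$int > 0], w$int_support)

  w2 <- generate_world(small_config())
  expect_identical(w$profiles, w2$profiles)
  expect_identical(w$slopes, w2$slopes)
  expect_identical(w$sec_trends, w2$sec_trends)

  w3 <- generate_world(generator_config(n_mirnas = 1000,
                                        nonlinear_probe_fraction = 0.027))
  expect_identical(sum(w3$nonlinear), 27L)

  expect_error(generator_config(n_mirnas = 30,
                                overlap_design = c(int_only = 20, sec_only = 20, shared = 20)),
               "exceed")
})

test_that("zero-noise arrays follow the deterministic signal model exactly", {
  cfg <- zero_noise(background_level = 0.7)
  w <- generate_world(cfg)
  sheet <- sample_sheet(data.frame(
    sample_id = c("blank", "d50", "d100"),
    compartment = c("blank_medium", "cell", "cell"),
    culture_medium = c("MCDB", "none", "none"),
    donor = c(NA, "pool", "pool"),
    input_ng = c(NA, 50, 100),
    dilution_member = c(FALSE, TRUE, TRUE)))
  m <- simulate_arrays(w, sheet)
  expect_equal(unname(m[, "blank"]),
               unname(w$intercepts + 0.7), tolerance = 1e-12)
  lin <- !w$nonlinear
  expect_equal(unname(m[lin, "d100"] - w$intercepts[lin]),
               unname(2 * (m[lin, "d50"] - w$intercepts[lin])), tolerance = 1e-9)
  # saturated probes do not respond beyond the saturation input
  expect_equal(m[w$nonlinear, "d100"], m[w$nonlinear, "d50"], tolerance = 1e-12)
})

test_that("identical world, sheet and seed give bit-identical arrays", {
  cfg <- small_config(seed = 11)
  w <- generate_world(cfg)
  sheet <- preset_designs("huvec_grid", cfg)
  expect_identical(simulate_arrays(w, sheet, seed = 5),
                   simulate_arrays(w, sheet, seed = 5))
  expect_false(identical(simulate_arrays(w, sheet, seed = 5),
                         simulate_arrays(w, sheet, seed = 6)))
  bad <- sheet
  bad$donor[1] <- "nobody"
  expect_error(simulate_arrays(w, bad, seed = 5), "nobody")
})

test_that("preset designs match the study layout", {
  cfg <- small_config()
  hg <- preset_designs("huvec_grid", cfg)
  expect_identical(nrow(hg), 36L)   # 4 donors x 4 media x 2 compartments + 4 blanks
  expect_identical(sum(hg$compartment == "blank_medium"), 4L)

  dil <- preset_designs("dilution_series", cfg)
  expect_identical(nrow(dil), 6L)
  expect_true(all(diff(dil$input_ng) > 0))
  expect_true(all(dil$dilution_member))
  expect_equal(range(dil$input_ng), c(12.5, 150))

  tc <- preset_designs("timecourse", cfg)
  expect_identical(sum(tc$compartment == "cell"), 15L)           # 5 times x 3 reps
  expect_identical(sum(tc$compartment == "conditioned_medium"), 15L)

  bp <- preset_designs("blood_panel", cfg)
  expect_identical(sum(bp$compartment == "serum"), 4L)
  expect_identical(sum(bp$compartment == "plasma"), 4L)

  expect_error(preset_designs("exosome_panel"), "unknown preset")
})

test_that("pure-pool fractions recover the compartment profile under the conservation conditions", {
  # equal slopes, no effects, no intercept/background/noise
  cfg <- zero_noise(slope_sdlog = 0, donor_effect_sd = 0, medium_effect_sd = 0,
                    nonlinear_probe_fraction = 0, background_level = 0)
  w <- generate_world(cfg)
  sheet <- sample_sheet(data.frame(sample_id = "cellA", compartment = "cell",
                                   donor = "1302", culture_medium = "MCDB"))
  m <- simulate_arrays(w, sheet)
  fr <- normalize_total(m)
  expect_equal(unname(fr[, 1]), unname(w$profiles$int), tolerance = 1e-12)
})

test_that("a pure endothelial-secretory serum sample matches the inverted signal model", {
  cfg <- zero_noise(donor_effect_sd = 0, medium_effect_sd = 0,
                    nonlinear_probe_fraction = 0,
                    serum_weights = c(endo_sec = 1, wbc_sec = 0, wbc_int = 0, other = 0))
  w <- generate_world(cfg)
  sheet <- sample_sheet(data.frame(sample_id = "S1", compartment = "serum",
                                   donor = "BD1"))
  m <- simulate_arrays(w, sheet)
  det <- call_detection(m, 0)
  fr <- normalize_total(m, mask = det)
  detected <- rownames(det)[det[, 1]]
  # oracle: divide the observed signal by the probe slopes to invert the model
  inverted <- fr[detected, 1] / w$slopes[detected]
  truth <- w$profiles$sec[detected]
  expect_equal(spearman_cor(inverted / sum(inverted), truth / sum(truth))$rho, 1)
})

test_that("trend deltas conserve mass and slope-weighted mass", {
  for (s in 1:5) {
    cfg <- small_config(seed = s)
    w <- generate_world(cfg)
    for (pool in c("sec", "int")) {
      tr <- w[[paste0(pool, "_trends")]]
      support <- w[[paste0(pool, "_support")]]
      eff <- w$slopes[tr$mirna] *
        w$donor_effects[tr$mirna, cfg$timecourse_donor] *
        w$medium_effects[tr$mirna, cfg$timecourse_medium] *
        ifelse(w$nonlinear[tr$mirna],
               min(cfg$default_input_ng, cfg$saturation_ng) / cfg$default_input_ng, 1)
      expect_equal(sum(tr$delta), 0, tolerance = 1e-12)
      expect_equal(sum(tr$delta * eff), 0, tolerance = 1e-12)
      f <- w$profiles[[pool]][tr$mirna]
      expect_true(all(f + tr$delta > 0))   # end-of-course profile stays positive
      expect_true(all((tr$delta > 0) == (tr$category == "up")))
      expect_true(all((tr$delta < 0) == (tr$category == "down")))
    }
  }
})

test_that("ground truth serialises and reads back", {
  w <- generate_world(small_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_world_truth(w, path)
  truth <- read_world_truth(path)
  expect_setequal(truth$int_only, w$int_only)
  expect_identical(truth$overlap_design$shared, 20L)
  expect_equal(truth$sec_trends$delta, w$sec_trends$delta)
})
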