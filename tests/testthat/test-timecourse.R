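tc_sheet <- function(times, reps = 1L, compartment = "conditioned_medium") {
  grid <- expand.grid(time_min = times, replicate = seq_len(reps))
  sample_sheet(data.frame(
    sample_id = sprintf("D_t%03d_r%d", grid$time_min, grid$replicate),
    compartment = compartment, donor = "1332", culture_medium = "MCDB",
    time_min = grid$time_min, replicate = grid$replicate))
}

test_that("trend categories follow the correlation-with-time rule", {
  times <- c(15, 30, 60, 120, 240)
  sheet <- tc_sheet(times)
  vals <- rbind(up = times / 100, flat = rep(0.2, 5),
                down = c(10, 8, 9, 4, 2))
  m <- make_matrix(vals, probes = rownames(vals), samples = sheet$sample_id)
  tt <- trend_classify(m, sheet, fraction = "sec", mode = "intensity")
  rec <- tt$records

  expect_equal(rec$pearson_r[rec$mirna == "up"], 1, tolerance = 1e-12)
  expect_identical(rec$category[rec$mirna == "up"], "increasing")
  expect_identical(rec$category[rec$mirna == "flat"], "unchanged")
  expect_true(is.na(rec$pearson_r[rec$mirna == "flat"]))

  r_oracle <- pearson_brute(times, c(10, 8, 9, 4, 2))
  expect_equal(rec$pearson_r[rec$mirna == "down"], r_oracle, tolerance = 1e-12)
  expect_lt(rec$p_value[rec$mirna == "down"], 0.05)
  expect_identical(rec$category[rec$mirna == "down"], "decreasing")

  expect_identical(unname(sum(tt$counts)), tt$total_detected)
  expect_error(trend_classify(m[, 1:2], tc_sheet(times[1:2])), "3 distinct")
})

test_that("replicates average per time point and sample order does not matter", {
  times <- c(15, 60, 240)
  sheet <- tc_sheet(times, reps = 2L)
  set.seed(3)
  vals <- matrix(stats::runif(2 * nrow(sheet), 0.1, 1), nrow = 2,
                 dimnames = list(c("a", "b"), sheet$sample_id))
  m <- probe_matrix(vals)
  base <- trend_classify(m, sheet, "sec", "intensity")

  shuf <- sheet[sample(nrow(sheet)), ]
  again <- trend_classify(m, shuf, "sec", "intensity")
  expect_equal(base$records[order(base$records$mirna), ],
               again$records[order(again$records$mirna), ], ignore_attr = TRUE)

  # manual replicate means as the oracle for one miRNA
  means <- vapply(times, function(t) {
    mean(vals["a", sheet$sample_id[sheet$time_min == t]])
  }, numeric(1))
  expect_equal(base$records$pearson_r[base$records$mirna == "a"],
               pearson_brute(times, means), tolerance = 1e-12)

  all_points <- trend_classify(m, sheet, "sec", "intensity",
                               average_replicates = FALSE)
  expect_equal(all_points$records$pearson_r[all_points$records$mirna == "a"],
               pearson_brute(sheet$time_min, vals["a", sheet$sample_id]),
               tolerance = 1e-12)
})

test_that("cross-referencing joins categories and builds the contingency", {
  sec <- structure(list(records = data.frame(
    mirna = c("a", "b"), category = c("decreasing", "unchanged"))),
    class = "trend_table")
  int <- structure(list(records = data.frame(
    mirna = c("a", "b"), category = c("increasing", "unchanged"))),
    class = "trend_table")
  xr <- cross_reference(sec, int)
  expect_identical(xr$table$int_category[xr$table$mirna == "a"], "increasing")
  expect_identical(unname(xr$contingency["decreasing", "increasing"]), 1L)

  ident <- cross_reference(sec, sec)
  expect_equal(sum(diag(xr$contingency)) + 0, 1)  # only b on the diagonal here
  expect_true(all(ident$table$sec_category == ident$table$int_category))

  disjoint <- structure(list(records = data.frame(
    mirna = "z", category = "unchanged")), class = "trend_table")
  expect_warning(empty <- cross_reference(sec, disjoint), "no miRNAs")
  expect_identical(nrow(empty$table), 0L)
})

test_that("zero-noise trend recovery matches the serialised truth, including the cross-reference", {
  cfg <- zero_noise(small_config, nonlinear_probe_fraction = 0, seed = 5)
  w <- generate_world(cfg)
  sheet <- preset_designs("timecourse", cfg)
  m <- simulate_arrays(w, sheet)
  res <- run_pipeline(m, sheet, analysis_config(detection_threshold = 1e-12))
  for (pool in c("sec", "int")) {
    truth <- w[[paste0(pool, "_trends")]]
    rec <- res[[paste0(pool, "_trends")]]$records
    j <- merge(rec, truth, by = "mirna")
    expect_identical(nrow(j), nrow(truth))
    expect_identical(j$category.x, unname(cat_map[j$category.y]))
  }
  xr <- res$trend_cross_reference
  shared_truth <- merge(w$sec_trends, w$int_trends, by = "mirna")
  expect_identical(nrow(xr$table), nrow(shared_truth))
  lev <- c("increasing", "decreasing", "unchanged")
  truth_tab <- table(factor(cat_map[shared_truth$category.x], lev),
                     factor(cat_map[shared_truth$category.y], lev),
                     dnn = c("sec", "int"))
  expect_equal(unclass(xr$contingency), unclass(truth_tab), ignore_attr = TRUE)
})

test_that("secreted total signal rises with accumulation while intracellular totals stay level", {
  cfg <- zero_noise(small_config, nonlinear_probe_fraction = 0, seed = 6)
  w <- generate_world(cfg)
  sheet <- preset_designs("timecourse", cfg)
  m <- simulate_arrays(w, sheet)
  bg <- subtract_background(m, sheet)
  sec_tot <- total_signal_trajectory(bg, sheet, "sec")
  expect_true(all(diff(sec_tot$total_intensity) > 0))
  int_tot <- total_signal_trajectory(bg, sheet, "int")
  expect_lt(diff(range(int_tot$total_intensity)) / mean(int_tot$total_intensity), 0.35)

  # totals equal brute-force column sums
  ids <- sheet$sample_id[sheet$compartment == "conditioned_medium" &
                           sheet$time_min == 240 & !is.na(sheet$time_min)]
  expect_equal(sec_tot$total_intensity[sec_tot$time_min == 240],
               mean(colSums(unclass(bg)[, ids, drop = FALSE])), tolerance = 1e-12)
})
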