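#' Synthetic study configuration
#'
#' Parameters of the synthetic microarray generator. The defaults encode the
#' study design the pipeline is built around: four endothelial donor lines
#' crossed with four culture media, a six-point serial dilution of a pooled
#' isolate spanning 12.5-150 ng around the 100 ng protocol standard, a
#' five-point time course between 15 and 240 minutes in triplicate, and a
#' panel of paired serum/plasma samples plus white-blood-cell cultures.
#'
#' @param n_mirnas number of miRNA probes on the array.
#' @param overlap_design named counts `c(int_only=, sec_only=, shared=)` of
#'   miRNAs exclusive to the intracellular pool, exclusive to the secretory
#'   pool, and shared; their sum is the endothelial miRNA universe.
#' @param donors,media HUVEC donor line and culture-medium labels.
#' @param timecourse_donor,timecourse_medium donor line and medium of the
#'   time-course arm (the trend construction is anchored to these, see
#'   [generate_world()]).
#' @param blood_donors,wbc_donors donor labels of the blood panel and the
#'   white-blood-cell cultures.
#' @param dilution_grid strictly increasing RNA inputs (ng) of the serial
#'   dilution.
#' @param time_grid time points (minutes) of the time-course arm.
#' @param replicates technical replicates per time point.
#' @param donor_effect_sd,medium_effect_sd SDs of the per-(miRNA, donor) and
#'   per-(miRNA, medium) log-normal abundance multipliers. The medium effect
#'   is larger by default, reproducing the dominance of culture conditions
#'   over genetic background in sample clustering.
#' @param noise_cv multiplicative measurement noise (Gaussian, SD =
#'   `noise_cv` x deterministic signal).
#' @param noise_floor_sd additive Gaussian noise floor (intensity units);
#'   signals are floored at 0 after noise.
#' @param censor_floor scanner sensitivity floor (intensity units): measured
#'   values below it read as 0 (absent). Part of the measurement-noise
#'   model -- it is what makes low-abundance probes appear stepwise along a
#'   dilution series; noise-free simulations disable it together with the
#'   noise terms.
#' @param nonlinear_probe_fraction fraction of probes whose response
#'   saturates instead of growing linearly with input (the QC-filterable
#'   minority).
#' @param saturation_ng input (ng) at which non-linear probes saturate; below
#'   the dilution minimum by default, so their dose response is flat.
#' @param slope_meanlog,slope_sdlog log-normal parameters of the per-probe
#'   signal-per-unit-abundance slopes.
#' @param dirichlet_conc Dirichlet concentration of compartment abundance
#'   profiles (1 = realistic sparse spread).
#' @param pool_conc Dirichlet concentration of the pooled dilution isolate
#'   (same spread as single compartments by default, keeping a realistic
#'   low-abundance tail at the detection limit).
#' @param wbc_int_support,wbc_sec_support,other_support support sizes of the
#'   WBC intracellular/secretory pools and the unattributed "other" blood
#'   pool.
#' @param serum_weights,plasma_weights convex mixture weights of blood
#'   samples over the `endo_sec`, `wbc_sec`, `wbc_int` and `other` pools;
#'   serum carries the larger endothelial-secretome weight.
#' @param background_level blank-medium intensity added to every probe of
#'   conditioned- and blank-medium arrays.
#' @param intercept per-probe additive offset (0 by default: feature
#'   extraction output is already spot-level background corrected).
#' @param intensity_scale overall signal scale; defaults to `n_mirnas` so a
#'   probe of average abundance at 100 ng reads in the hundreds of units.
#' @param sec_trend_fractions,int_trend_fractions named fractions
#'   `c(up=, down=, flat=)` of secretory/intracellular miRNAs assigned each
#'   time trend (rounded to counts over the pool support).
#' @param trend_strength relative fraction change of an up-trending miRNA
#'   over the full time course (1 = doubling).
#' @param default_input_ng RNA input assumed for samples whose sheet omits
#'   `input_ng` (the 100 ng protocol standard).
#' @param seed integer RNG seed; a fixed seed makes [generate_world()] fully
#'   reproducible.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_mirnas = 800L,
                             overlap_design = c(int_only = 155L, sec_only = 166L, shared = 253L),
                             donors = c("1302", "1308", "1309", "1314"),
                             media = c("MCDB", "MCDB-S", "HIM-V", "EGM-2MV"),
                             timecourse_donor = "1332",
                             timecourse_medium = "MCDB",
                             blood_donors = paste0("BD", 1:4),
                             wbc_donors = paste0("WD", 1:3),
                             dilution_grid = c(12.5, 25, 50, 75, 100, 150),
                             time_grid = c(15, 30, 60, 120, 240),
                             replicates = 3L,
                             donor_effect_sd = 0.15,
                             medium_effect_sd = 0.30,
                             noise_cv = 0.10,
                             noise_floor_sd = 0.10,
                             censor_floor = 0.5,
                             nonlinear_probe_fraction = 0.027,
                             saturation_ng = 10,
                             slope_meanlog = 0,
                             slope_sdlog = 0.3,
                             dirichlet_conc = 1,
                             pool_conc = 1,
                             wbc_int_support = 600L,
                             wbc_sec_support = 450L,
                             other_support = 300L,
                             serum_weights = c(endo_sec = 0.75, wbc_sec = 0.10, wbc_int = 0.05, other = 0.10),
                             plasma_weights = c(endo_sec = 0.40, wbc_sec = 0.25, wbc_int = 0.15, other = 0.20),
                             background_level = 0.5,
                             intercept = 0,
                             intensity_scale = NULL,
                             sec_trend_fractions = c(up = 0.39, down = 0.07, flat = 0.54),
                             int_trend_fractions = c(up = 0.15, down = 0.05, flat = 0.80),
                             trend_strength = 1,
                             default_input_ng = 100,
                             seed = 1L) {
  n_mirnas <- as.integer(n_mirnas)
  overlap_design <- vapply(overlap_design, as.integer, integer(1))
  if (is.null(names(overlap_design)) || !setequal(names(overlap_design),
                                                  c("int_only", "sec_only", "shared"))) {
    names(overlap_design) <- c("int_only", "sec_only", "shared")
  }
  if (any(overlap_design < 0L)) stop_input("overlap_design counts must be >= 0")
  if (sum(overlap_design) > n_mirnas) {
    stop_input("overlap_design counts (", sum(overlap_design),
               ") exceed n_mirnas (", n_mirnas, ")")
  }
  if (any(diff(dilution_grid) <= 0)) stop_input("dilution_grid must be strictly increasing")
  for (w in list(serum_weights, plasma_weights)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop_input("mixture weights must be nonnegative and sum to 1")
    }
  }
  for (f in list(sec_trend_fractions, int_trend_fractions)) {
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop_input("trend fractions must be nonnegative and sum to 1")
    }
  }
  if (nonlinear_probe_fraction < 0 || nonlinear_probe_fraction > 1) {
    stop_input("nonlinear_probe_fraction must be in [0, 1]")
  }
  structure(list(
    n_mirnas = n_mirnas, overlap_design = overlap_design,
    donors = donors, media = media,
    timecourse_donor = timecourse_donor, timecourse_medium = timecourse_medium,
    blood_donors = blood_donors, wbc_donors = wbc_donors,
    dilution_grid = dilution_grid, time_grid = time_grid,
    replicates = as.integer(replicates),
    donor_effect_sd = donor_effect_sd, medium_effect_sd = medium_effect_sd,
    noise_cv = noise_cv, noise_floor_sd = noise_floor_sd,
    censor_floor = censor_floor,
    nonlinear_probe_fraction = nonlinear_probe_fraction,
    saturation_ng = saturation_ng,
    slope_meanlog = slope_meanlog, slope_sdlog = slope_sdlog,
    dirichlet_conc = dirichlet_conc, pool_conc = pool_conc,
    wbc_int_support = min(as.integer(wbc_int_support), n_mirnas),
    wbc_sec_support = min(as.integer(wbc_sec_support), n_mirnas),
    other_support = min(as.integer(other_support), n_mirnas),
    serum_weights = serum_weights, plasma_weights = plasma_weights,
    background_level = background_level, intercept = intercept,
    intensity_scale = intensity_scale %||% as.numeric(n_mirnas),
    sec_trend_fractions = sec_trend_fractions,
    int_trend_fractions = int_trend_fractions,
    trend_strength = trend_strength,
    default_input_ng = default_input_ng,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate a synthetic world with known ground truth
#'
#' Draws compartment abundance profiles (Dirichlet on their supports), probe
#' response parameters, donor/medium log-normal effects, blood mixture
#' weights and time-trend assignments from a `generator_config`. The returned
#' world fully determines the deterministic part of [simulate_arrays()] and
#' is serialisable via [write_world_truth()] for recovery tests.
#'
#' Time trends are built directly in fraction space: down-trending miRNAs
#' (assigned to the highest-abundance secretory species, which start from
#' high proportions) transfer mass linearly in time to up-trending ones,
#' under two balance constraints -- plain mass (profiles stay on the simplex)
#' and effective-slope-weighted mass (the fraction-of-total denominator stays
#' constant, so flat miRNAs have exactly constant normalised expression).
#' The effective slopes are anchored to `timecourse_donor`/`timecourse_medium`.
#'
#' @param config a [generator_config()].
#' @return a `synthetic_world` list.
#' @export
generate_world <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_mirnas
  ids <- sprintf("miR-%04d", seq_len(n))

  shuffled <- sample(ids)
  od <- config$overlap_design
  int_only <- shuffled[seq_len(od[["int_only"]])]
  sec_only <- shuffled[od[["int_only"]] + seq_len(od[["sec_only"]])]
  shared <- shuffled[od[["int_only"]] + od[["sec_only"]] + seq_len(od[["shared"]])]
  int_support <- c(int_only, shared)
  sec_support <- c(sec_only, shared)

  profile_on <- function(support, conc) {
    p <- stats::setNames(numeric(n), ids)
    p[support] <- rdirichlet1(length(support), conc)
    p
  }
  int_profile <- profile_on(int_support, config$dirichlet_conc)
  sec_profile <- profile_on(sec_support, config$dirichlet_conc)
  wbc_int_profile <- profile_on(sample(ids, config$wbc_int_support), config$dirichlet_conc)
  wbc_sec_profile <- profile_on(sample(ids, config$wbc_sec_support), config$dirichlet_conc)
  other_profile <- profile_on(sample(ids, config$other_support), config$dirichlet_conc)
  pool_profile <- stats::setNames(rdirichlet1(n, config$pool_conc), ids)

  slopes <- stats::setNames(stats::rlnorm(n, config$slope_meanlog, config$slope_sdlog), ids)
  n_nonlinear <- round(config$nonlinear_probe_fraction * n)
  nonlinear <- stats::setNames(rep(FALSE, n), ids)
  if (n_nonlinear > 0L) nonlinear[sample(ids, n_nonlinear)] <- TRUE
  intercepts <- stats::setNames(rep(config$intercept, n), ids)

  all_donors <- unique(c(config$donors, config$timecourse_donor,
                         config$blood_donors, config$wbc_donors))
  donor_effects <- matrix(
    exp(stats::rnorm(n * length(all_donors), 0, config$donor_effect_sd)),
    nrow = n, dimnames = list(ids, all_donors))
  donor_effects <- cbind(donor_effects, pool = rep(1, n))
  medium_effects <- matrix(
    exp(stats::rnorm(n * length(config$media), 0, config$medium_effect_sd)),
    nrow = n, dimnames = list(ids, config$media))
  medium_effects <- cbind(medium_effects, none = rep(1, n))

  # Effective per-probe weight in the fraction denominator of a time-course
  # sample: slope x donor effect x medium effect x input scaling (saturated
  # probes respond to min(input, saturation) instead of the full input).
  tc_weight <- slopes *
    donor_effects[, config$timecourse_donor] *
    medium_effects[, config$timecourse_medium] *
    ifelse(nonlinear, pmin(config$default_input_ng, config$saturation_ng) /
             config$default_input_ng, 1)

  sec_trends <- assign_trends(sec_profile[sec_support], tc_weight[sec_support],
                              config$sec_trend_fractions, config$trend_strength)
  int_trends <- assign_trends(int_profile[int_support], tc_weight[int_support],
                              config$int_trend_fractions, config$trend_strength)

  structure(list(
    mirna_ids = ids,
    int_only = int_only, sec_only = sec_only, shared = shared,
    int_support = int_support, sec_support = sec_support,
    profiles = list(int = int_profile, sec = sec_profile,
                    wbc_int = wbc_int_profile, wbc_sec = wbc_sec_profile,
                    other = other_profile, pool = pool_profile),
    slopes = slopes, nonlinear = nonlinear, intercepts = intercepts,
    donor_effects = donor_effects, medium_effects = medium_effects,
    mixture_weights = list(serum = config$serum_weights,
                           plasma = config$plasma_weights),
    sec_trends = sec_trends, int_trends = int_trends,
    background_level = config$background_level,
    config = config
  ), class = "synthetic_world")
}

# Assign up/down/flat categories over a pool support and construct the
# per-miRNA fraction shifts `delta` such that fraction(t) = f + delta * tau
# with tau in [0, 1], sum(delta) = 0 and sum(weight * delta) = 0.
assign_trends <- function(f, weight, fractions, strength, cap = 0.8) {
  m <- length(f)
  out <- data.frame(mirna = names(f), category = rep("flat", m),
                    delta = rep(0, m), stringsAsFactors = FALSE)
  n_up <- round(fractions[["up"]] * m)
  n_down <- round(fractions[["down"]] * m)
  if (n_up == 0L || n_down == 0L) {
    if (n_up != n_down) {
      warning("one-sided trend request cannot conserve mass; all miRNAs set flat")
    }
    return(out)
  }
  if (n_up + n_down > m) stop_input("trend counts exceed pool support size")
  # Down-trending miRNAs decrease from initially high proportions (secreted
  # reserves), up-trending ones rise from low baselines (newly induced
  # secretion): downs take the largest base fractions, ups are drawn from
  # the low-abundance half of the remainder.
  downs <- order(f, decreasing = TRUE)[seq_len(n_down)]
  pool_rest <- setdiff(order(f), downs)
  low_half <- pool_rest[seq_len(max(ceiling(length(pool_rest) / 2), n_up))]
  ups <- low_half[sample.int(length(low_half), n_up)]

  hull <- function(idx) range(weight[idx])
  feasible <- function(u, d) {
    lo <- max(hull(u)[1], hull(d)[1]); hi <- min(hull(u)[2], hull(d)[2])
    c(lo, hi)
  }
  # The slope-balance target must lie inside the weight hull of both groups;
  # if the random up draw misses, swap up members toward the down-group mean.
  band <- feasible(ups, downs)
  tries <- 0L
  while (band[1] > band[2] && tries < 50L) {
    flats <- setdiff(seq_len(m), c(ups, downs))
    if (!length(flats)) break
    target <- mean(weight[downs])
    cand <- flats[which.min(abs(weight[flats] - target))]
    drop <- ups[which.max(abs(weight[ups] - target))]
    ups <- c(setdiff(ups, drop), cand)
    band <- feasible(ups, downs)
    tries <- tries + 1L
  }
  if (band[1] > band[2]) {
    stop_input("cannot balance trend construction: up/down slope ranges are disjoint")
  }
  # Abundance-proportional mass shares give every member the same relative
  # change; the weighted-mean-slope constraint is then met with least
  # distortion -- ups via a minimal blend toward one extreme-slope member
  # (no upper bound there), downs via a minimax allocation (bisection on the
  # peak relative loading) so that no single down member's headroom cap
  # collapses the transferable mass. The balance target sits between the two
  # groups' natural weighted means, clamped strictly inside both hulls.
  # The balance target trades off two distortions: near the down group's
  # natural mean its headroom caps less mass, near the up group's the up
  # shares stay proportional. A grid search picks the target maximising the
  # weakest up-member's relative shift.
  eps <- 1e-9 * max(band[2] - band[1], 1)
  fn_up <- f[ups] / sum(f[ups])
  fn_down <- f[downs] / sum(f[downs])
  candidate <- function(cc) {
    w_up <- alloc_mass_lower(fn_up, weight[ups], cc)
    w_down <- alloc_mass_upper(fn_down, weight[downs], cc)
    mass <- min(strength * sum(f[ups]), cap * min(f[downs] / w_down))
    list(w_up = w_up, w_down = w_down, mass = mass,
         min_rel = min(mass * w_up / f[ups]))
  }
  grid <- seq(band[1] + eps, band[2] - eps, length.out = 33)
  cands <- lapply(grid, candidate)
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "min_rel"))]]
  w_up <- best$w_up
  w_down <- best$w_down
  mass <- best$mass
  out$delta[ups] <- mass * w_up
  out$delta[downs] <- -mass * w_down
  out$category[ups] <- "up"
  out$category[downs] <- "down"
  out
}

# Mass shares w on the simplex with weighted mean sum(w * s) = cc, keeping
# w >= t * fn for the largest possible t (least distortion from the
# abundance-proportional shares fn): the residual 1 - t goes to the
# extreme-slope member on the side of the target.
alloc_mass_lower <- function(fn, s, cc) {
  c0 <- sum(fn * s)
  if (max(s) - min(s) < 1e-12 || abs(cc - c0) < 1e-12) return(fn)
  vertex <- if (cc > c0) which.max(s) else which.min(s)
  t <- (s[vertex] - cc) / (s[vertex] - c0)
  t <- min(max(t, 0), 1)
  w <- t * fn
  w[vertex] <- w[vertex] + (1 - t)
  w
}

# Mass shares w on the simplex with weighted mean cc and w <= t * fn for the
# smallest feasible t (minimax relative loading), found by bisection; the
# share vector interpolates the two greedy extreme fillings at that t.
alloc_mass_upper <- function(fn, s, cc) {
  if (length(fn) == 1L) return(1)
  c0 <- sum(fn * s)
  if (max(s) - min(s) < 1e-12 || abs(cc - c0) < 1e-12) return(fn)
  greedy <- function(t, decreasing) {
    ord <- order(s, decreasing = decreasing)
    w <- numeric(length(fn))
    rem <- 1
    for (j in ord) {
      take <- min(t * fn[j], rem)
      w[j] <- take
      rem <- rem - take
      if (rem <= 0) break
    }
    w
  }
  mean_range <- function(t) {
    c(sum(greedy(t, FALSE) * s), sum(greedy(t, TRUE) * s))
  }
  feasible <- function(t) {
    r <- mean_range(t)
    r[1] - 1e-12 <= cc && cc <= r[2] + 1e-12
  }
  lo <- 1
  hi <- 1 / min(fn)   # full concentration allowed: whole hull reachable
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  w_min <- greedy(hi, FALSE)
  w_max <- greedy(hi, TRUE)
  r <- c(sum(w_min * s), sum(w_max * s))
  a <- if (r[2] - r[1] < 1e-15) 0.5 else (cc - r[1]) / (r[2] - r[1])
  a <- min(max(a, 0), 1)
  (1 - a) * w_min + a * w_max
}

#' Simulate microarray intensities for a sample sheet
#'
#' Deterministic signal model per probe p and sample s:
#' `slope_p * input_eff * scale * abundance_p(s) * donor_mult * medium_mult *
#' accumulation(t) + intercept_p + background`, plus Gaussian noise
#' (SD = `noise_cv` x deterministic signal + `noise_floor_sd`), floored at 0.
#' Saturating (non-linear) probes respond to `min(input, saturation_ng)`
#' instead of the full input; measured values below the scanner sensitivity
#' floor (`censor_floor`) read as 0. Abundance comes from the compartment profile
#' (or the pooled profile for dilution members, or the convex blood mixture
#' for serum/plasma); conditioned media accumulate secreted signal linearly
#' in time. Blank-medium arrays carry intercept + background only.
#'
#' With all noise parameters zero the output is exactly the deterministic
#' model.
#'
#' @param world a [generate_world()] result.
#' @param sheet a [sample_sheet()]; every donor/medium referenced must exist
#'   in the world.
#' @param seed RNG seed for the noise draws (defaults to the world's seed).
#' @return a [probe_matrix()] over `world$mirna_ids` x `sheet$sample_id`.
#' @export
simulate_arrays <- function(world, sheet, seed = world$config$seed) {
  cfg <- world$config
  ids <- world$mirna_ids
  n <- length(ids)
  bad_donor <- setdiff(stats::na.omit(unique(sheet$donor)), colnames(world$donor_effects))
  if (length(bad_donor)) stop_input("donor '", bad_donor[1L], "' not present in world")
  bad_med <- setdiff(unique(sheet$culture_medium), colnames(world$medium_effects))
  if (length(bad_med)) stop_input("culture_medium '", bad_med[1L], "' not present in world")

  set.seed(as.integer(seed))
  vals <- matrix(0, nrow = n, ncol = nrow(sheet),
                 dimnames = list(ids, sheet$sample_id))
  t_max <- max(cfg$time_grid)
  t_min <- min(cfg$time_grid)
  for (k in seq_len(nrow(sheet))) {
    row <- sheet[k, ]
    x <- if (is.na(row$input_ng)) cfg$default_input_ng else row$input_ng
    A <- sample_abundance(world, row, t_min, t_max)
    d_eff <- if (is.na(row$donor)) rep(1, n) else world$donor_effects[, row$donor]
    m_eff <- world$medium_effects[, row$culture_medium]
    acc <- if (row$compartment == "conditioned_medium" && !is.na(row$time_min)) {
      row$time_min / t_max
    } else 1
    x_eff <- ifelse(world$nonlinear, pmin(x, cfg$saturation_ng), x)
    bg <- if (row$compartment %in% c("conditioned_medium", "blank_medium")) {
      world$background_level
    } else 0
    det <- world$slopes * x_eff * cfg$intensity_scale * A * d_eff * m_eff * acc +
      world$intercepts + bg
    if (cfg$noise_cv > 0 || cfg$noise_floor_sd > 0) {
      det <- det + stats::rnorm(n, 0, cfg$noise_cv * det + cfg$noise_floor_sd)
    }
    det <- pmax(det, 0)
    if (cfg$censor_floor > 0) det[det < cfg$censor_floor] <- 0
    vals[, k] <- det
  }
  probe_matrix(vals, scale_tag = "linear")
}

sample_abundance <- function(world, row, t_min, t_max) {
  if (isTRUE(row$dilution_member)) return(world$profiles$pool)
  n <- length(world$mirna_ids)
  trended <- function(pool, trends, support, time_min) {
    p <- world$profiles[[pool]]
    if (is.na(time_min)) return(p)
    tau <- (time_min - t_min) / (t_max - t_min)
    delta <- stats::setNames(numeric(n), world$mirna_ids)
    delta[trends$mirna] <- trends$delta
    p + delta * tau
  }
  switch(row$compartment,
    cell = trended("int", world$int_trends, world$int_support, row$time_min),
    conditioned_medium = trended("sec", world$sec_trends, world$sec_support, row$time_min),
    blank_medium = stats::setNames(numeric(n), world$mirna_ids),
    serum = blood_mixture(world, world$mixture_weights$serum),
    plasma = blood_mixture(world, world$mixture_weights$plasma),
    wbc = world$profiles$wbc_int,
    wbc_medium = world$profiles$wbc_sec,
    stop_input("no abundance profile for compartment '", row$compartment, "'")
  )
}

blood_mixture <- function(world, w) {
  w[["endo_sec"]] * world$profiles$sec +
    w[["wbc_sec"]] * world$profiles$wbc_sec +
    w[["wbc_int"]] * world$profiles$wbc_int +
    w[["other"]] * world$profiles$other
}

#' Preset study-design sample sheets
#'
#' @param name one of `"huvec_grid"` (donors x media cell + conditioned
#'   medium pairs plus one blank per medium), `"dilution_series"` (pooled
#'   isolate at each dilution-grid input), `"timecourse"` (time grid x
#'   replicates x cell/conditioned medium plus a blank) or `"blood_panel"`
#'   (paired serum/plasma per blood donor plus WBC pellets and media).
#' @param config a [generator_config()] supplying donors, media and grids.
#' @return a [sample_sheet()].
#' @export
preset_designs <- function(name = c("huvec_grid", "dilution_series",
                                    "timecourse", "blood_panel"),
                           config = generator_config()) {
  if (length(name) != 1L || !name %in% c("huvec_grid", "dilution_series",
                                         "timecourse", "blood_panel")) {
    stop_input("unknown preset '", paste(name, collapse = ","),
               "'; known: huvec_grid, dilution_series, timecourse, blood_panel")
  }
  rows <- switch(name,
    huvec_grid = {
      grid <- expand.grid(donor = config$donors, medium = config$media,
                          stringsAsFactors = FALSE)
      k <- seq_len(nrow(grid))
      rbind(
        data.frame(sample_id = sprintf("A%02d", k), compartment = "cell",
                   donor = grid$donor, culture_medium = grid$medium,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("B%02d", k), compartment = "conditioned_medium",
                   donor = grid$donor, culture_medium = grid$medium,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = paste0("BLANK_", config$media),
                   compartment = "blank_medium", donor = NA_character_,
                   culture_medium = config$media, stringsAsFactors = FALSE)
      )
    },
    dilution_series = data.frame(
      sample_id = sprintf("M%d", seq_along(config$dilution_grid)),
      compartment = "cell", donor = "pool", culture_medium = "none",
      input_ng = config$dilution_grid, dilution_member = TRUE,
      stringsAsFactors = FALSE),
    timecourse = {
      grid <- expand.grid(time_min = config$time_grid,
                          replicate = seq_len(config$replicates))
      rbind(
        data.frame(sample_id = sprintf("C_t%03d_r%d", grid$time_min, grid$replicate),
                   compartment = "cell", donor = config$timecourse_donor,
                   culture_medium = config$timecourse_medium,
                   time_min = grid$time_min, replicate = grid$replicate,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("D_t%03d_r%d", grid$time_min, grid$replicate),
                   compartment = "conditioned_medium", donor = config$timecourse_donor,
                   culture_medium = config$timecourse_medium,
                   time_min = grid$time_min, replicate = grid$replicate,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = "BLANK_TC", compartment = "blank_medium",
                   donor = NA_character_, culture_medium = config$timecourse_medium,
                   time_min = NA_real_, replicate = 1L, stringsAsFactors = FALSE)
      )
    },
    blood_panel = {
      nb <- seq_along(config$blood_donors)
      nw <- seq_along(config$wbc_donors)
      rbind(
        data.frame(sample_id = sprintf("S%d", nb), compartment = "serum",
                   donor = config$blood_donors, stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("P%d", nb), compartment = "plasma",
                   donor = config$blood_donors, stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("E%d", nw), compartment = "wbc",
                   donor = config$wbc_donors, stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("F%d", nw), compartment = "wbc_medium",
                   donor = config$wbc_donors, stringsAsFactors = FALSE)
      )
    }
  )
  sample_sheet(rows)
}

#' Serialise / read synthetic ground truth
#'
#' Writes the recoverable truth of a world (supports, partition design,
#' non-linear probes, trend categories and deltas, mixture weights, probe
#' slopes) as JSON next to the generated TSVs.
#'
#' @param world a `synthetic_world`.
#' @param path output JSON path.
#' @export
write_world_truth <- function(world, path) {
  truth <- list(
    n_mirnas = length(world$mirna_ids),
    overlap_design = as.list(world$config$overlap_design),
    int_only = world$int_only, sec_only = world$sec_only, shared = world$shared,
    nonlinear_probes = names(world$nonlinear)[world$nonlinear],
    sec_trends = world$sec_trends, int_trends = world$int_trends,
    mixture_weights = lapply(world$mixture_weights, as.list),
    slopes = as.list(world$slopes),
    background_level = world$background_level,
    seed = world$config$seed
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_world_truth
#' @return `read_world_truth()` returns the truth list.
#' @export
read_world_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d miRNAs (int %d | shared %d | sec %d), %d non-linear probes\n",
              length(x$mirna_ids), length(x$int_only), length(x$shared),
              length(x$sec_only), sum(x$nonlinear)))
  invisible(x)
}
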