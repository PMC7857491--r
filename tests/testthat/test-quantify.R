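test_that("baseline is the t=0 read by default, mean of first m otherwise", {
  tr <- kinetic_trace("A01", c(0, 5, 10), c(100, 105, 110), role = "sample")
  expect_equal(estimate_baseline(tr), 100)
  tr2 <- kinetic_trace("A01", c(0, 5), c(100, 102), role = "sample")
  expect_equal(estimate_baseline(tr2, m = 2), 101)
  flat <- kinetic_trace("A01", 0:4 * 5, rep(77, 5), role = "sample")
  for (m in 1:5) expect_equal(estimate_baseline(flat, m), 77)
  expect_error(estimate_baseline(tr, m = 0), "m must")
  expect_error(estimate_baseline(tr, m = 9), "m must")
})

test_that("drift estimation is whole-trace OLS restricted to control roles", {
  t <- seq(0, 720, by = 5)
  flat <- kinetic_trace("H01", t, rep(50, length(t)),
                        role = "substrate_control")
  expect_equal(as.numeric(estimate_drift(flat)), 0)
  line <- kinetic_trace("H02", t, 100 + 2 * t, role = "enzyme_control")
  est <- estimate_drift(line)
  expect_equal(as.numeric(est), 2, tolerance = 1e-12)
  expect_true(!is.null(attr(est, "se")))

  smp <- kinetic_trace("A01", t, 100 + 2 * t, role = "sample")
  expect_error(estimate_drift(smp), "control")
  short <- kinetic_trace("H01", c(0, 5), c(1, 2), role = "substrate_control")
  expect_error(estimate_drift(short), "3 reads")
})

test_that("noisy simulated control drift lands inside its own 95% CI", {
  cfg <- simulation_config(noise_sd = 2, drift_substrate = 0.5)
  tr <- simulate_trace(cfg, "substrate_control", seed = 123L)
  expect_equal(tr$n_reads, 145L)
  est <- estimate_drift(tr)
  half <- qt(0.975, attr(est, "df")) * attr(est, "se")
  expect_true(abs(as.numeric(est) - 0.5) <= half)
})

test_that("trace correction subtracts baseline and summed control drifts", {
  t <- 0:10 * 5
  const <- kinetic_trace("A01", t, rep(100, 11), role = "sample")
  expect_equal(correct_trace(const, 100, 0, 0)$corrected, rep(0, 11))

  lin <- kinetic_trace("A01", t, 100 + 5 * t, role = "sample")
  cor <- correct_trace(lin, 100, 1, 2)
  expect_equal(cor$corrected, 2 * t)
  expect_equal(cor$corrected[t == 10], 20)

  ctrl <- kinetic_trace("H01", t, rep(1, 11), role = "substrate_control")
  expect_error(correct_trace(ctrl, 0, 0, 0), "role 'sample'")
})

test_that("correction is affine: doubling intensities and baseline doubles I_C", {
  t <- 0:20 * 5
  y <- 100 + 3 * t + sin(t / 20)
  a <- correct_trace(kinetic_trace("A01", t, y, role = "sample"), 100, 1, 0.5)
  b <- correct_trace(kinetic_trace("A01", t, 2 * y, role = "sample"),
                     200, 2, 1)
  expect_equal(b$corrected, 2 * a$corrected, tolerance = 1e-12)
})

test_that("correction inverts the generator exactly on noise-free plates", {
  cfg <- clean_config()
  ds <- simulate_plate(triplet_design(1), cfg, seed = 17)
  s_S <- as.numeric(estimate_drift(ds$traces[["H01"]]))
  s_E <- as.numeric(estimate_drift(ds$traces[["H02"]]))
  smp <- ds$traces[["A01"]]
  cor <- correct_trace(smp, estimate_baseline(smp), s_S, s_E)
  S <- integrated_mm_substrate(cfg$S0, cfg$Km,
                               cfg$Vmax * modifier_factor(cfg$modifiers,
                                                          cfg$substrate),
                               smp$times)
  truth <- cfg$k_AU * (cfg$S0 - S) * cfg$volume
  expect_equal(cor$corrected, truth, tolerance = 1e-12)
  expect_lt(max(abs(cor$corrected - truth)), 1e-9)  # machine precision in AU
})

test_that("plateau estimation averages the tail and warns when still rising", {
  t <- 0:29 * 5
  y <- c(seq(0, 1000, length.out = 24), rep(1000, 6))
  tr <- kinetic_trace("A01", t, y, role = "sample")
  expect_silent(p <- estimate_plateau(tr, m = 6))
  expect_equal(p, 1000)

  rising <- kinetic_trace("A01", t, 3 * t, role = "sample")
  expect_warning(p2 <- estimate_plateau(rising, m = 6), "not plateaued")
  expect_equal(p2, mean(3 * t[25:30]))
  expect_error(estimate_plateau(tr, m = 31), "m must")
})

test_that("full digestion plateau recovers k_AU * S0 * volume", {
  cfg <- clean_config(Vmax = 1e-7)
  ds <- simulate_plate(triplet_design(1, overrides = NULL), cfg, seed = 23)
  smp <- ds$traces[["A01"]]
  cor <- correct_trace(smp, estimate_baseline(smp),
                       as.numeric(estimate_drift(ds$traces[["H01"]])),
                       as.numeric(estimate_drift(ds$traces[["H02"]])))
  expect_equal(estimate_plateau(cor), 1000, tolerance = 1e-4)
})

test_that("calibration line: exact two-point case and input validation", {
  cal <- fit_calibration(c(1e-10, 2e-10), c(1000, 2000))
  expect_equal(cal$k, 1e13)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(coef(cal), c(intercept = 0, k = 1e13), tolerance = 1e-9)

  expect_error(fit_calibration(1e-10, 1000), "2 distinct")
  expect_error(fit_calibration(c(1e-10, 1e-10), c(1, 2)), "2 distinct")
  expect_error(fit_calibration(c(1e-10, 2e-10), c(2000, 1000)),
               "invalid calibration")
  expect_error(fit_calibration(c(-1e-10, 2e-10), c(1, 2)), ">= 0")
})

test_that("simulated dilution series recovers the generative k within 0.1%", {
  concs <- c(0.25, 0.5, 1, 2) * 1e-6
  design <- c(
    lapply(seq_along(concs), function(i)
      list(well = sprintf("A%02d", i), role = "sample",
           condition = sprintf("S%g", concs[i] * 1e6),
           config = list(S0 = concs[i], Vmax = 1e-7))),
    list(list(well = "H01", role = "substrate_control"),
         list(well = "H02", role = "enzyme_control")))
  ds <- simulate_plate(design, clean_config(Vmax = 1e-7), seed = 31)
  cal <- calibrate_plate(ds)
  expect_equal(cal$k, 1e13, tolerance = 1e-3)
  expect_gt(cal$r_squared, 0.999999)
})

test_that("initial rate: exact lines, zero traces and window policies", {
  t <- 0:29 * 5
  lin <- structure(list(well_id = "A01", times = t, corrected = 3 * t,
                        baseline = 0, drift_substrate_slope = 0,
                        drift_enzyme_slope = 0), class = "corrected_trace")
  for (pol in c("initial_window", "max_rolling")) {
    r <- initial_rate(lin, policy = pol)
    expect_equal(r$slope, 3)
    expect_equal(r$r_squared, 1)
  }
  flat <- lin; flat$corrected <- rep(0, 30)
  expect_equal(initial_rate(flat)$slope, 0)

  short <- lin; short$times <- t[1:3]; short$corrected <- (3 * t)[1:3]
  expect_error(initial_rate(short), "4 reads")
  expect_warning(r2 <- initial_rate(lin, window = 60), "using all reads")
  expect_equal(r2$slope, 3)
})

test_that("initial rate matches the analytic rate at substrate excess", {
  # S0 = 10 Km keeps the early slope at k_AU V Vmax S0/(Km+S0)
  cfg <- clean_config(S0 = 1e-6, Km = 1e-7, Vmax = 1e-9,
                      drift_substrate = 0, drift_enzyme = 0)
  tr <- simulate_trace(cfg, "sample")
  cor <- correct_trace(tr, estimate_baseline(tr), 0, 0)
  r <- initial_rate(cor)
  analytic <- cfg$k_AU * cfg$volume * cfg$Vmax * cfg$S0 / (cfg$Km + cfg$S0)
  expect_equal(r$slope, analytic, tolerance = 0.02)
})

test_that("activity conversion divides the rate slope by k", {
  t <- 0:19 * 5
  cor <- structure(list(well_id = "A01", times = t, corrected = 2 * t,
                        baseline = 0, drift_substrate_slope = 0,
                        drift_enzyme_slope = 0), class = "corrected_trace")
  act <- compute_activity(cor, calib = 4)
  expect_equal(act$A, 0.5)
  expect_equal(act$rate_slope, 2)
  expect_false(act$below_detection)
  # trapezoid of 2t over [0,95] / k
  expect_equal(act$integrated_activity, 95^2 / 4)

  act2 <- compute_activity(cor, calib = 4, protein_mass = 0.0005)
  expect_equal(act2$specific_activity, 0.5 / 0.0005)
  expect_error(compute_activity(cor, calib = -1), "invalid calibration")

  falling <- cor; falling$corrected <- -2 * t
  expect_true(compute_activity(falling, calib = 4)$below_detection)
})

test_that("specific activity: 1e-12 mol/min over 0.5 ug protein", {
  t <- 0:19 * 5
  cor <- structure(list(well_id = "A01", times = t, corrected = 1e-12 * 4 * t,
                        baseline = 0, drift_substrate_slope = 0,
                        drift_enzyme_slope = 0), class = "corrected_trace")
  act <- compute_activity(cor, calib = 4, protein_mass = 0.0005)
  expect_equal(act$A, 1e-12, tolerance = 1e-9)
  expect_equal(act$specific_activity, 2e-9, tolerance = 1e-9)
})

test_that("noise-free well recovers the generative activity within 2%", {
  cfg <- clean_config()
  ds <- simulate_plate(triplet_design(1), cfg, seed = 29)
  res <- quantify_plate(ds, cfg$k_AU)
  expect_equal(res$A, generative_rate(cfg), tolerance = 0.02)
  # and much tighter with a shorter window (less depletion)
  res4 <- quantify_plate(ds, cfg$k_AU, window = 4)
  expect_equal(res4$A, generative_rate(cfg), tolerance = 0.002)
})

test_that("fluorescence units cancel: scaling k_AU leaves activity unchanged", {
  base <- clean_config()
  for (scale in c(1, 10)) {
    cfg <- update_config(base, k_AU = base$k_AU * scale)
    ds <- simulate_plate(triplet_design(1), cfg, seed = 37)
    concs <- c(0.25, 0.5, 1, 2) * 1e-6
    cal_design <- c(
      lapply(seq_along(concs), function(i)
        list(well = sprintf("B%02d", i), role = "sample",
             config = list(S0 = concs[i], Vmax = 1e-7))),
      list(list(well = "H01", role = "substrate_control"),
           list(well = "H02", role = "enzyme_control")))
    cal <- calibrate_plate(simulate_plate(cal_design, cfg, seed = 41))
    res <- quantify_plate(ds, cal)
    if (scale == 1) a_ref <- res$A else
      expect_equal(res$A, a_ref, tolerance = 1e-9)
  }
})

test_that("incomplete quenching is absorbed by the fitted calibration", {
  # with q < 1 the corrected signal scales by q, and so does the fitted k;
  # activities computed with the fitted calibration are unaffected
  cfg <- simulation_config(noise_sd = 0, quench_efficiency = 0.95)
  ds <- simulate_plate(triplet_design(1), cfg, seed = 43)
  concs <- c(0.25, 0.5, 1, 2) * 1e-6
  cal_design <- c(
    lapply(seq_along(concs), function(i)
      list(well = sprintf("B%02d", i), role = "sample",
           config = list(S0 = concs[i], Vmax = 1e-7))),
    list(list(well = "H01", role = "substrate_control"),
         list(well = "H02", role = "enzyme_control")))
  cal <- calibrate_plate(simulate_plate(cal_design, cfg, seed = 47))
  expect_equal(cal$k, 0.95 * cfg$k_AU, tolerance = 1e-3)
  res <- quantify_plate(ds, cal)
  expect_equal(res$A, generative_rate(cfg), tolerance = 0.02)
})

test_that("replicate aggregation reports mean, SEM and n per condition", {
  res <- data.frame(condition = c("a", "a", "b"),
                    A = c(2, 4, 5),
                    specific_activity = c(20, 40, 50),
                    integrated_activity = c(1, 1, 1))
  agg <- aggregate_replicates(res)
  a <- agg[agg$condition == "a", ]
  expect_equal(a$A_mean, 3)
  expect_equal(a$A_sem, 1)
  expect_equal(a$n, 2L)
  b <- agg[agg$condition == "b", ]
  expect_equal(b$A_mean, 5)
  expect_true(is.na(b$A_sem))

  same <- data.frame(condition = "x", A = c(7, 7, 7),
                     specific_activity = 1, integrated_activity = 1)
  expect_equal(aggregate_replicates(same)$A_sem, 0)
  expect_error(aggregate_replicates(res[0, ]), "no results")
})

test_that("quantification requires both control roles", {
  cfg <- clean_config()
  des <- list(list(well = "A01", role = "sample"),
              list(well = "H01", role = "substrate_control"))
  ds <- simulate_plate(des, cfg, seed = 3)
  expect_error(quantify_plate(ds, cfg$k_AU), "enzyme_control")
})
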