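test_that("force partitioning obeys Fc = Fa - Ff and exact conservation", {
  expect_equal(partition_force(661, 661), 0)     # rigid-fixator limit
  expect_equal(partition_force(661, 0), 661)     # fully consolidated limit
  expect_equal(partition_force(600, 150), 450)
  set.seed(2)
  Fa <- runif(200, -1000, 1000)
  Ff <- runif(200, -1000, 1000)
  expect_equal(Ff + partition_force(Fa, Ff), Fa)  # conservation, exact
})

test_that("skeletal force scales the GRF by the Fa/GRF ratio", {
  p <- fixator_params()
  expect_equal(skeletal_force_from_grf(0, p), 0)
  expect_equal(skeletal_force_from_grf(100, p), 322)
  expect_equal(skeletal_force_from_grf(205.28, p), 661, tolerance = 1e-3)
  expect_error(skeletal_force_from_grf(-1, p), class = "fixmon_domain_error")
})

test_that("the worked gait-load bound rounds to 661 N", {
  expect_equal(round(gait_load_bound(53.5, 1.26, 9.81)), 661)
})

test_that("peak callus stiffness is peak force over displacement", {
  # constant trace: PCS = 200/1
  ev <- distraction_event(seq(0, 120, by = 0.1), rep(200, 1201),
                          delta_d_mm = 1, day = 2)
  est <- distraction_stiffness(ev)
  expect_s3_class(est, "stiffness_estimate")
  expect_equal(est$Kc, 200)
  expect_equal(est$phase, "distraction")
  # planted peak on a simulated relaxation trace, no noise: exact recovery
  sc <- quiet_scenario(seed = 3,
                       callus_model = list(k_end_N_per_mm = 248))
  ev2 <- simulate_distraction_event(sc, 15)
  expect_equal(attr(ev2, "pcs_true"), 248)
  expect_equal(distraction_stiffness(ev2)$Kc, 248)
  # the relaxation tail is retained but does not enter the PCS
  expect_lt(ev2$ff_N[length(ev2$ff_N)], 248 * ev2$delta_d_mm)
  # short trace errors
  short <- distraction_event(seq(0, 10, by = 0.1), rep(1, 101))
  expect_error(distraction_stiffness(short),
               class = "fixmon_insufficient_data_error")
})

test_that("PCS is invariant under baseline shift of the pre-distraction rest", {
  # normalization contract: shifting the raw trace and re-normalizing leaves
  # the PCS unchanged
  sc <- quiet_scenario(seed = 8)
  ev <- simulate_distraction_event(sc, 10)
  shifted <- force_df(cbind(ev$ff_N / 4 + 2.5, ev$ff_N / 4 + 2.5,
                            ev$ff_N / 4 + 2.5, ev$ff_N / 4 + 2.5))
  rest <- force_df(matrix(2.5, nrow = 100, ncol = 4))
  norm <- apply_baseline(shifted, compute_baseline(rest))
  ev2 <- distraction_event(ev$time_s, norm$sum_N, ev$delta_d_mm, ev$day)
  expect_equal(distraction_stiffness(ev2)$Kc, distraction_stiffness(ev)$Kc,
               tolerance = 1e-9)
})

test_that("consolidation stiffness inverts the parallel-spring model", {
  p <- fixator_params()
  mk_step <- function(Fa, Ff) {
    grf <- c(0, Fa / p$fa_grf_ratio, 0)
    step_record(grf, c(0, -Ff, 0))
  }
  # Fa = 2 Ff -> Kc = Kf
  expect_equal(consolidation_stiffness(mk_step(300, 150), p)$Kc, 593)
  # direct evaluation
  expect_equal(consolidation_stiffness(mk_step(600, 150), p)$Kc,
               593 * 450 / 150)
  # monotone decreasing in Ff at fixed Fa; zero iff Fa == Ff
  kc <- vapply(c(100, 200, 300, 400, 500),
               function(ff) consolidation_stiffness(mk_step(500, ff), p)$Kc,
               numeric(1))
  expect_true(all(diff(kc) < 0))
  expect_equal(kc[5], 0)
})

test_that("planted Kc is recovered to <0.1% on noise-free steps across the bench range", {
  sc <- quiet_scenario(seed = 12)
  for (kc_true in c(103, 250, 593, 1850, 3000, 7449)) {
    step <- simulate_step(sc, kc_true, noise = FALSE)
    est <- consolidation_stiffness(step, sc$fixator)
    expect_lt(abs(est$Kc - kc_true) / kc_true, 0.001)
  }
})

test_that("steps below the fixator-load guard are degenerate, not dropped silently", {
  p <- fixator_params()
  quiet <- step_record(c(0, 100, 0), c(0, -0.5, 0))
  expect_error(consolidation_stiffness(quiet, p),
               class = "fixmon_degenerate_step_error")
  ok <- step_record(c(0, 100, 0), c(0, -80, 0))
  est <- consolidation_stiffness(list(ok, quiet, ok), p)
  expect_equal(est$n, 2L)
  expect_identical(attr(est, "degenerate"), 2L)
})

test_that("multiple steps aggregate by mean with dispersion reported", {
  sc <- synthetic_scenario(seed = 21)
  steps <- lapply(1:8, function(i) simulate_step(sc, 1000, step_index = i))
  est <- consolidation_stiffness(steps, sc$fixator)
  expect_equal(est$n, 8L)
  expect_true(is.finite(est$Kc_sd) && est$Kc_sd > 0)
  expect_equal(est$Kc, 1000, tolerance = 0.1)   # noisy but unbiased-ish
})

test_that("stance peak detection finds the apex and the taller hump", {
  tri <- step_record(c(0, 1, 2, 5, 2, 1, 0), rep(-1, 7))
  expect_equal(gait_peak_detect(tri), 4L)
  sc <- synthetic_scenario(seed = 6)
  step <- simulate_step(sc, 500, noise = FALSE)
  pk <- gait_peak_detect(step)
  # generator puts the taller hump first (hump_ratio > 1)
  expect_equal(step$grf_N[pk], max(step$grf_N))
  expect_lt(pk, length(step$grf_N) / 2)
  zero <- step_record(rep(0, 10), rep(0, 10))
  expect_error(gait_peak_detect(zero), class = "fixmon_no_stance_error")
})

test_that("Young's modulus conversion is E = Kc L / A and linear", {
  geom <- callus_geometry(147.8, gap_length_mm = 15)
  expect_equal(young_modulus(0, geom), 0)
  expect_equal(young_modulus(1850, geom), 1850 * 15 / 147.8) # ~187.8 MPa
  expect_equal(young_modulus(1850, geom), 187.8, tolerance = 1e-3)
  expect_equal(young_modulus(531.6, geom), 53.95, tolerance = 1e-3)
  # linear in Kc and in gap length
  expect_equal(young_modulus(2 * 531.6, geom), 2 * young_modulus(531.6, geom))
  geom2 <- callus_geometry(147.8, gap_length_mm = 30)
  expect_equal(young_modulus(531.6, geom2), 2 * young_modulus(531.6, geom))
  est <- stiffness_estimate(1850, "consolidation")
  expect_equal(young_modulus(est, geom), young_modulus(1850, geom))
})
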