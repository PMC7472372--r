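# Synthetic bench: generates every input the pipeline consumes, with planted
# ground truth, so that each estimator can be tested against the quantity
# the generator injected rather than against itself.

#' Synthetic scenario parameters
#'
#' One object bundles everything the generators need: sensor noise, drift,
#' the viscoelastic callus model, the gait model, the fixator parameters and
#' the distraction protocol. All randomness flows from `seed`: the same
#' scenario and seed reproduce byte-identical outputs.
#'
#' Defaults are the bench's study conditions: 0.18 N per-cell in vitro noise,
#' 3.01 N aggregate in vivo noise, Kf = 593 +/- 21 N/mm, Fa/GRF = 3.22, a
#' 7-day latency followed by 15 days of distraction at 1 mm/day, end-of-
#' distraction callus stiffness 250 N/mm with single-exponential relaxation
#' (residual ratio 0.6, tau = 300 s), and a 0.6 s double-hump stance with
#' 200 N peak GRF. Drift defaults to zero (rest windows used for noise
#' budgets are drift-free); set `drift_N_per_hour` to exercise it.
#'
#' @param seed Integer seed controlling all generated randomness.
#' @param noise_sd_per_cell In vitro Gaussian noise SD per load cell, N.
#' @param noise_sd_in_vivo_sum In vivo noise SD of the four-cell sum, N
#'   (split equally in quadrature across cells).
#' @param drift_N_per_hour Slow per-cell drift slope, N/hour.
#' @param callus_model List: `k_end_N_per_mm` (stiffness at the last
#'   distraction day), `relax_residual_ratio` (late-time force / peak force),
#'   `relax_tau_s` (relaxation time constant, s).
#' @param gait_model List: `grf_peak_N`, `stance_s`, `hump_ratio`
#'   (first hump / second hump).
#' @param fixator A [fixator_params()].
#' @param protocol List: `latency_days`, `distraction_days`,
#'   `rate_mm_per_day`.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               noise_sd_per_cell = 0.18,
                               noise_sd_in_vivo_sum = 3.01,
                               drift_N_per_hour = 0,
                               callus_model = list(),
                               gait_model = list(),
                               fixator = fixator_params(),
                               protocol = list()) {
  if (noise_sd_per_cell < 0 || noise_sd_in_vivo_sum < 0) {
    stop_fixmon("domain", "noise SDs must be non-negative")
  }
  callus_model <- modifyList(
    list(k_end_N_per_mm = 250, relax_residual_ratio = 0.6,
         relax_tau_s = 300), callus_model)
  gait_model <- modifyList(
    list(grf_peak_N = 200, stance_s = 0.6, hump_ratio = 1.1), gait_model)
  protocol <- modifyList(
    list(latency_days = 7, distraction_days = 15, rate_mm_per_day = 1),
    protocol)
  if (callus_model$k_end_N_per_mm <= 0) {
    stop_fixmon("domain", "k_end_N_per_mm must be positive")
  }
  if (any(unlist(protocol) < 0)) {
    stop_fixmon("domain", "protocol values must be non-negative")
  }
  structure(list(seed = as.integer(seed),
                 noise_sd_per_cell = noise_sd_per_cell,
                 noise_sd_in_vivo_sum = noise_sd_in_vivo_sum,
                 drift_N_per_hour = drift_N_per_hour,
                 callus_model = callus_model,
                 gait_model = gait_model,
                 fixator = fixator,
                 protocol = protocol),
            class = "synthetic_scenario")
}

#' Planted callus stiffness schedule over the distraction phase
#'
#' Linear ramp from `k_end / distraction_days` on day 1 to `k_end` on the
#' last day, emulating the monotone day-on-day stiffening of the distraction
#' callus.
#'
#' @param scenario A [synthetic_scenario()].
#' @param day Distraction day (1-based).
#' @return Planted peak callus stiffness, N/mm.
#' @export
planted_pcs <- function(scenario, day) {
  p <- scenario$protocol
  scenario$callus_model$k_end_N_per_mm * day / p$distraction_days
}

#' Simulate a zero-load rest stream
#'
#' Four independent load cells carrying only Gaussian sensor noise (SD
#' `noise_sd_per_cell`) plus optional linear drift, sampled at the configured
#' rate and quantized through the ADC transfer. With independent cells the
#' summed channel has SD `2 * noise_sd_per_cell` (quadrature).
#'
#' @param scenario A [synthetic_scenario()].
#' @param duration_s Stream duration, s (> 0).
#' @param config An [acquisition_config()].
#' @return A [frame_stream()]; encode with [encode_stream()] for the wire
#'   format.
#' @export
simulate_rest_stream <- function(scenario, duration_s,
                                 config = acquisition_config()) {
  if (duration_s <= 0) stop_fixmon("domain", "duration_s must be positive")
  n <- max(1L, floor(duration_s * config$sample_rate))
  dt_ms <- 1000 / config$sample_rate
  t_s <- (seq_len(n) - 1) / config$sample_rate
  with_seed(derive_seed(scenario$seed, 1L), {
    f <- matrix(rnorm(4L * n, 0, scenario$noise_sd_per_cell),
                nrow = n, ncol = 4)
    f <- f + scenario$drift_N_per_hour * t_s / 3600
    frame_stream(round((seq_len(n) - 1) * dt_ms),
                 force_to_counts(f, config))
  })
}

# relaxation profile: peak at t = 0, single-exponential decay to the
# residual plateau (standard-linear-solid-like response to a step strain)
relaxation_profile <- function(t_s, peak, residual_ratio, tau_s) {
  r <- 1 - residual_ratio
  peak * ((1 - r) + r * exp(-t_s / tau_s))
}

#' Simulate one daily distraction event
#'
#' The 1 mm displacement loads the callus to its instantaneous peak
#' `planted_pcs(day) * delta_d`, after which the tissue relaxes along a
#' single-exponential toward the residual plateau; in vivo noise (SD
#' `noise_sd_in_vivo_sum`) is added to the summed trace. The planted PCS is
#' attached as attribute `"pcs_true"`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param day Distraction day, within `1..protocol$distraction_days`.
#' @param duration_s Observation window, s (default 1200 = 20 min).
#' @param sample_rate Hz (default 10).
#' @return A [distraction_event()] with attribute `pcs_true` (N/mm).
#' @export
simulate_distraction_event <- function(scenario, day, duration_s = 1200,
                                       sample_rate = 10) {
  p <- scenario$protocol
  if (day < 1 || day > p$distraction_days) {
    stop_fixmon("protocol",
                sprintf("day %s outside the distraction phase (1..%d)",
                        day, p$distraction_days))
  }
  cm <- scenario$callus_model
  delta_d <- p$rate_mm_per_day
  pcs <- planted_pcs(scenario, day)
  t_s <- seq(0, duration_s, by = 1 / sample_rate)
  ff <- relaxation_profile(t_s, pcs * delta_d, cm$relax_residual_ratio,
                           cm$relax_tau_s)
  ff <- with_seed(derive_seed(scenario$seed, 100L + day), {
    ff + rnorm(length(ff), 0, scenario$noise_sd_in_vivo_sum)
  })
  ev <- distraction_event(t_s, ff, delta_d_mm = delta_d, day = day)
  attr(ev, "pcs_true") <- pcs
  ev
}

# double-hump stance profile: two raised-cosine bumps (braking and push-off)
double_hump_grf <- function(t_s, stance_s, peak_N, hump_ratio) {
  bump <- function(t, center, halfwidth) {
    ifelse(abs(t - center) < halfwidth,
           0.5 * (1 + cos(pi * (t - center) / halfwidth)), 0)
  }
  g <- peak_N * bump(t_s, 0.28 * stance_s, 0.25 * stance_s) +
    (peak_N / hump_ratio) * bump(t_s, 0.72 * stance_s, 0.25 * stance_s)
  pmax(g, 0)
}

#' Simulate one gait step with a planted callus stiffness
#'
#' GRF follows a double-hump stance profile; the skeletal force is
#' `Fa = fa_grf_ratio * GRF`, and the fixator reads the parallel-spring share
#' `Ff = Fa * Kf / (Kf + Kc_true)` (stored signed, compression negative).
#' In vivo noise is added so the four-cell sum has SD
#' `noise_sd_in_vivo_sum`. The planted stiffness is attached as attribute
#' `"Kc_true"`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param Kc_true Planted callus stiffness, N/mm (>= 0).
#' @param sample_rate Hz (default 50).
#' @param noise Logical; set `FALSE` for a noise-free oracle step.
#' @param step_index Integer tag decorrelating noise across steps of one
#'   session.
#' @return A [step_record()] with attribute `Kc_true`.
#' @export
simulate_step <- function(scenario, Kc_true, sample_rate = 50, noise = TRUE,
                          step_index = 1L) {
  if (Kc_true < 0) stop_fixmon("domain", "Kc_true must be non-negative")
  gm <- scenario$gait_model
  Kf <- scenario$fixator$Kf
  lead_s <- 0.2
  t_s <- seq(0, gm$stance_s + 2 * lead_s, by = 1 / sample_rate)
  grf <- double_hump_grf(t_s - lead_s, gm$stance_s, gm$grf_peak_N,
                         gm$hump_ratio)
  Fa <- scenario$fixator$fa_grf_ratio * grf
  ff <- -Fa * Kf / (Kf + Kc_true)      # compression negative
  if (noise && scenario$noise_sd_in_vivo_sum > 0) {
    ff <- with_seed(derive_seed(scenario$seed, 1000L + step_index), {
      ff + rnorm(length(ff), 0, scenario$noise_sd_in_vivo_sum)
    })
  }
  step <- step_record(grf, ff, sample_rate = sample_rate)
  attr(step, "Kc_true") <- Kc_true
  step
}

#' Simulate a spring-bench calibration grid
#'
#' Emulates the in vitro validation: for a spring of reference stiffness
#' `Ksr`, the fixator is re-assembled `n_assemblies` times and the stiffness
#' estimated `n_repeats` times per assembly.
#'
#' Replication is modelled purely as assembly-to-assembly fixator
#' variability (SD `Kf_sd`): in consolidation the physical force split uses
#' the perturbed `Kf_a` while the estimator applies the nominal `Kf`, so one
#' re-assembly biases all its repeats by the factor `Kf / Kf_a`; in
#' distraction (where the estimate `Ff / delta_d` does not involve `Kf`) the
#' same relative variability acts as a per-assembly transmission gain.
#' Repetition noise is the sensor noise of the summed channel
#' (`2 * noise_sd_per_cell`) on the measured force. The reference relative
#' uncertainty comes from 5 simulated direct spring tests.
#'
#' @param scenario A [synthetic_scenario()].
#' @param Ksr Reference spring stiffness, N/mm.
#' @param phase `"distraction"` or `"consolidation"`.
#' @param n_assemblies,n_repeats Grid shape (defaults 4 x 5).
#' @param assembly_rel_sd Relative SD of the assembly effect; defaults to
#'   `Kf_sd / Kf`.
#' @param ref_rel_sd Relative SD of one direct reference test (default 0.01).
#' @param Fa_test Applied skeletal force in consolidation tests, N
#'   (default 661, the worked gait-load bound).
#' @param delta_d_mm Spring decompression in distraction tests, mm.
#' @param grid_index Integer tag decorrelating repeated grids.
#' @return A [spring_bench_record()] with attribute `"truth"`: the planted
#'   per-assembly effects and noise SDs.
#' @export
simulate_bench <- function(scenario, Ksr,
                           phase = c("distraction", "consolidation"),
                           n_assemblies = 4, n_repeats = 5,
                           assembly_rel_sd = NULL, ref_rel_sd = 0.01,
                           Fa_test = 661, delta_d_mm = 1,
                           grid_index = 1L) {
  phase <- match.arg(phase)
  if (Ksr <= 0) stop_fixmon("domain", "Ksr must be positive")
  fx <- scenario$fixator
  if (is.null(assembly_rel_sd)) assembly_rel_sd <- fx$Kf_sd / fx$Kf
  force_noise_sd <- 2 * scenario$noise_sd_per_cell
  with_seed(derive_seed(scenario$seed, 2000L + grid_index), {
    ref_tests <- Ksr * (1 + rnorm(5, 0, ref_rel_sd))
    Ksr_u_pct <- if (ref_rel_sd > 0) {
      100 * sd(ref_tests) / (sqrt(5) * mean(ref_tests))
    } else 0
    est <- matrix(NA_real_, n_assemblies, n_repeats)
    if (phase == "distraction") {
      gain <- 1 + rnorm(n_assemblies, 0, assembly_rel_sd)
      for (a in seq_len(n_assemblies)) {
        ff <- Ksr * delta_d_mm * gain[a] +
          rnorm(n_repeats, 0, force_noise_sd)
        est[a, ] <- ff / delta_d_mm
      }
      truth <- list(assembly_gain = gain,
                    assembly_sd_N_per_mm = Ksr * assembly_rel_sd,
                    repeat_sd_N_per_mm = force_noise_sd / delta_d_mm)
    } else {
      Kf_a <- fx$Kf * (1 + rnorm(n_assemblies, 0, assembly_rel_sd))
      for (a in seq_len(n_assemblies)) {
        ff_true <- Fa_test * Kf_a[a] / (Kf_a[a] + Ksr)
        ff_meas <- ff_true + rnorm(n_repeats, 0, force_noise_sd)
        est[a, ] <- fx$Kf * (Fa_test - ff_meas) / ff_meas
      }
      truth <- list(Kf_a = Kf_a,
                    assembly_sd_N_per_mm = Ksr * assembly_rel_sd,
                    repeat_sd_N_per_mm =
                      fx$Kf * Fa_test /
                        (Fa_test * fx$Kf / (fx$Kf + Ksr))^2 * force_noise_sd)
    }
    rec <- spring_bench_record(Ksr, est, phase, Ksr_u_pct = Ksr_u_pct)
    attr(rec, "truth") <- truth
    rec
  })
}
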