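# Bone-fixator mechanical model.
#
# During a stance the internal skeletal force Fa splits between the external
# fixator (Ff, read by the four load cells) and the bone callus (Fc):
#   Fc = Fa - Ff.
# The two load paths act as parallel springs, so at any instant
#   Kc = Kf * Fc / Ff = Kf * (Fa - Ff) / Ff,
# with Kf the axial stiffness of the assembled fixator. During distraction
# the limb is at rest (Fa = 0, Ff = Fc) and the stiffness follows directly
# from the applied displacement: Kc = Ff / delta_d; its instantaneous maximum
# before viscoelastic relaxation is the peak callus stiffness (PCS).

#' Fixator mechanical parameters
#'
#' @param Kf Axial stiffness of the assembled fixator, N/mm. The default
#'   593 N/mm is the mean of compression tests on instrumented assemblies.
#' @param Kf_sd Assembly-to-assembly standard deviation of `Kf`, N/mm
#'   (default 21), dominated by the bone/Schanz-pin interface.
#' @param n_cells Number of load cells; the frame design uses 4 bars.
#' @param fa_grf_ratio Ratio of internal skeletal force to ground reaction
#'   force during stance (default 3.22, assumed constant through
#'   consolidation). Must exceed 1: the skeleton carries more than the
#'   platform reads.
#' @param per_cell_range Measurement range of one load cell, N (0-1000).
#' @return Object of class `fixator_params`.
#' @export
fixator_params <- function(Kf = 593, Kf_sd = 21, n_cells = 4,
                           fa_grf_ratio = 3.22,
                           per_cell_range = c(0, 1000)) {
  if (Kf <= 0) stop_fixmon("config", "Kf must be positive")
  if (Kf_sd < 0) stop_fixmon("config", "Kf_sd must be non-negative")
  if (n_cells != 4) stop_fixmon("config", "the frame design uses 4 load cells")
  if (fa_grf_ratio <= 1) {
    stop_fixmon("config", "fa_grf_ratio must exceed 1")
  }
  structure(list(Kf = Kf, Kf_sd = Kf_sd, n_cells = n_cells,
                 fa_grf_ratio = fa_grf_ratio,
                 per_cell_range = per_cell_range),
            class = "fixator_params")
}

#' Partition the skeletal force between callus and fixator
#'
#' `Fc = Fa - Ff`: the load through the regenerating callus is whatever part
#' of the internal skeletal force does not pass through the fixator.
#' Vectorized; conservation `Fa = Ff + Fc` holds exactly.
#'
#' @param Fa Internal skeletal force, N.
#' @param Ff Fixator (four-cell sum) force, N.
#' @return Callus force `Fc`, N.
#' @export
partition_force <- function(Fa, Ff) Fa - Ff

#' Internal skeletal force from the ground reaction force
#'
#' Scales a platform-measured GRF to the internal skeletal force through the
#' metatarsus, `Fa = fa_grf_ratio * GRF`; the ratio (default 3.22) is treated
#' as constant across the consolidation phase.
#'
#' @param grf Ground reaction force, N (non-negative during stance).
#' @param params A [fixator_params()].
#' @return Skeletal force `Fa`, N.
#' @export
skeletal_force_from_grf <- function(grf, params = fixator_params()) {
  if (any(grf < 0)) {
    stop_fixmon("domain", "GRF must be non-negative during stance")
  }
  params$fa_grf_ratio * grf
}

#' Worked upper bound on the internal gait load
#'
#' Peak internal metatarsal forces in walking sheep reach about 1.26 times
#' body weight; for an average 53.5 kg animal this bounds the load shared by
#' the four cells at about 661 N, well inside the 0-1 kN per-cell range.
#'
#' @param body_mass_kg Body mass, kg.
#' @param load_factor Peak internal force as a multiple of body weight.
#' @param g Gravitational acceleration, m/s^2.
#' @return Peak internal force, N.
#' @export
gait_load_bound <- function(body_mass_kg = 53.5, load_factor = 1.26,
                            g = 9.81) {
  load_factor * body_mass_kg * g
}

#' Phase-tagged stiffness estimate
#'
#' @param Kc Callus stiffness, N/mm (non-negative).
#' @param phase `"distraction"` or `"consolidation"`.
#' @param day Protocol day of the measurement.
#' @param relative_uncertainty Expanded relative uncertainty, percent.
#' @param n Number of events (distractions) or steps aggregated.
#' @param Kc_sd Dispersion (SD) across aggregated steps, N/mm, or `NA`.
#' @return Object of class `stiffness_estimate`.
#' @export
stiffness_estimate <- function(Kc, phase, day = NA_integer_,
                               relative_uncertainty = NA_real_, n = 1L,
                               Kc_sd = NA_real_) {
  phase <- match.arg(phase, c("distraction", "consolidation"))
  if (!is.na(Kc) && Kc < 0) {
    stop_fixmon("domain", "Kc must be non-negative")
  }
  if (!is.na(relative_uncertainty) && relative_uncertainty < 0) {
    stop_fixmon("domain", "relative uncertainty must be non-negative")
  }
  structure(list(Kc = Kc, phase = phase, day = day,
                 relative_uncertainty = relative_uncertainty,
                 n = n, Kc_sd = Kc_sd),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("Callus stiffness (%s%s): %.1f N/mm", x$phase,
              if (is.na(x$day)) "" else sprintf(", day %s", x$day), x$Kc))
  if (!is.na(x$relative_uncertainty)) {
    cat(sprintf(" +/- %.2f%% (expanded)", x$relative_uncertainty))
  }
  cat(sprintf(" [n = %d]\n", x$n))
  invisible(x)
}

#' Distraction event record
#'
#' One daily distraction: the applied displacement and the normalized
#' fixator-sum force monitored afterwards (protocol: 1 mm/day, observed for
#' 20 min while the limb rests, so `Ff = Fc`).
#'
#' @param time_s Sample times, s, from distraction onset.
#' @param ff_N Normalized fixator-sum force trace, N (traction positive).
#' @param delta_d_mm Applied displacement, mm (> 0).
#' @param day Distraction day index.
#' @return Object of class `distraction_event`.
#' @export
distraction_event <- function(time_s, ff_N, delta_d_mm = 1, day = 1L) {
  if (delta_d_mm <= 0) stop_fixmon("domain", "delta_d_mm must be positive")
  if (length(time_s) != length(ff_N)) {
    stop_fixmon("domain", "time_s and ff_N must have equal length")
  }
  structure(list(time_s = as.numeric(time_s), ff_N = as.numeric(ff_N),
                 delta_d_mm = delta_d_mm, day = as.integer(day)),
            class = "distraction_event")
}

#' Peak callus stiffness from a distraction event
#'
#' The callus behaves viscoelastically: the reaction force peaks right after
#' the displacement is applied, then relaxes. The instantaneous peak callus
#' stiffness is `PCS = max |Ff| / delta_d`, with the peak searched over the
#' first `peak_window_s` seconds; the relaxation tail is kept in the event
#' for inspection but does not enter the PCS.
#'
#' @param event A [distraction_event()].
#' @param peak_window_s Peak-search window from distraction onset, s
#'   (default 60).
#' @param relative_uncertainty Expanded relative uncertainty attached to the
#'   estimate, percent; defaults to the distraction-phase bench average from
#'   [bench_reference_table()].
#' @return A [stiffness_estimate()] with `phase = "distraction"`.
#' @export
distraction_stiffness <- function(event, peak_window_s = 60,
                                  relative_uncertainty = NULL) {
  if (!inherits(event, "distraction_event")) {
    stop_fixmon("domain", "event must be a distraction_event")
  }
  if (length(event$time_s) == 0 ||
      max(event$time_s) < peak_window_s) {
    stop_fixmon("insufficient_data",
                "trace shorter than the peak-search window")
  }
  if (is.null(relative_uncertainty)) {
    relative_uncertainty <- phase_average(
      bench_reference_table("distraction"))$mean_U
  }
  win <- event$time_s <= peak_window_s
  pcs <- max(abs(event$ff_N[win])) / event$delta_d_mm
  stiffness_estimate(pcs, "distraction", day = event$day,
                     relative_uncertainty = relative_uncertainty, n = 1L)
}

#' Step record: one stance with synchronized GRF and fixator force
#'
#' @param grf_N Ground reaction force over the step window, N (non-negative).
#' @param ff_N Synchronized fixator-sum force, N (signed; compression
#'   negative).
#' @param sample_rate Hz; both traces share it.
#' @param stance_mask Optional logical vector marking the stance; if `NULL`
#'   it is derived as `grf > threshold_fraction * max(grf)`.
#' @param threshold_fraction Stance detection threshold (default 0.05).
#' @return Object of class `step_record`.
#' @export
step_record <- function(grf_N, ff_N, sample_rate = 50, stance_mask = NULL,
                        threshold_fraction = 0.05) {
  if (length(grf_N) != length(ff_N)) {
    stop_fixmon("domain", "grf_N and ff_N must have equal length")
  }
  if (any(grf_N < 0)) stop_fixmon("domain", "grf_N must be non-negative")
  if (is.null(stance_mask)) {
    m <- max(grf_N)
    stance_mask <- if (m > 0) grf_N > threshold_fraction * m
                   else rep(FALSE, length(grf_N))
  }
  structure(list(grf_N = as.numeric(grf_N), ff_N = as.numeric(ff_N),
                 sample_rate = sample_rate,
                 stance_mask = as.logical(stance_mask)),
            class = "step_record")
}

#' Locate the stance peak of a step
#'
#' Stance is the span where GRF exceeds `threshold_fraction` of its maximum;
#' the stance peak is the sample of maximal GRF within it (for a double-hump
#' profile, the taller hump).
#'
#' @param step A [step_record()].
#' @param threshold_fraction Stance threshold as a fraction of max GRF.
#' @return Integer index of the stance peak.
#' @export
gait_peak_detect <- function(step, threshold_fraction = 0.05) {
  if (!inherits(step, "step_record")) {
    stop_fixmon("domain", "step must be a step_record")
  }
  m <- max(step$grf_N)
  if (m <= 0) stop_fixmon("no_stance", "GRF trace contains no stance")
  mask <- step$grf_N > threshold_fraction * m
  idx <- which(mask)
  idx[which.max(step$grf_N[idx])]
}

#' Consolidation-phase callus stiffness from gait steps
#'
#' At the stance-peak instant of each step, `Fa` is obtained from the GRF via
#' [skeletal_force_from_grf()] and the parallel-spring model inverted:
#' `Kc = Kf * (Fa - Ff) / Ff` (magnitudes at the evaluated instant). Steps
#' whose fixator load at the peak falls below `min_ff_N` are degenerate —
#' the callus has stiffened beyond the measurable range — and are flagged,
#' not silently dropped; a single degenerate step (or all steps degenerate)
#' raises a `fixmon_degenerate_step_error`. Multiple steps aggregate by the
#' mean, with the dispersion reported.
#'
#' @param steps A [step_record()] or a list of them.
#' @param params A [fixator_params()].
#' @param day Consolidation day of the measurement.
#' @param min_ff_N Division guard on `|Ff|` at the stance peak, N (default 1).
#' @param threshold_fraction Stance threshold passed to [gait_peak_detect()].
#' @param relative_uncertainty Expanded relative uncertainty, percent;
#'   defaults to the consolidation-phase bench average from
#'   [bench_reference_table()].
#' @return A [stiffness_estimate()] with `phase = "consolidation"`. The
#'   indices of degenerate steps are attached as attribute `"degenerate"`.
#' @export
consolidation_stiffness <- function(steps, params = fixator_params(),
                                    day = NA_integer_, min_ff_N = 1,
                                    threshold_fraction = 0.05,
                                    relative_uncertainty = NULL) {
  if (inherits(steps, "step_record")) steps <- list(steps)
  if (!length(steps)) stop_fixmon("insufficient_data", "no steps supplied")
  if (is.null(relative_uncertainty)) {
    relative_uncertainty <- phase_average(
      bench_reference_table("consolidation"))$mean_U
  }
  kc <- numeric(0)
  degenerate <- integer(0)
  for (i in seq_along(steps)) {
    step <- steps[[i]]
    pk <- gait_peak_detect(step, threshold_fraction)
    Fa <- skeletal_force_from_grf(step$grf_N[pk], params)
    Ff <- abs(step$ff_N[pk])
    if (Ff < min_ff_N) {
      degenerate <- c(degenerate, i)
      next
    }
    kc <- c(kc, params$Kf * (Fa - Ff) / Ff)
  }
  if (!length(kc)) {
    stop_fixmon("degenerate_step",
                "fixator load below the division guard in every step: callus consolidated beyond measurable range")
  }
  est <- stiffness_estimate(max(mean(kc), 0), "consolidation", day = day,
                            relative_uncertainty = relative_uncertainty,
                            n = length(kc),
                            Kc_sd = if (length(kc) > 1) sd(kc) else NA_real_)
  attr(est, "degenerate") <- degenerate
  est
}

#' Callus cross-section geometry
#'
#' @param cross_section_area_mm2 Callus/bone cross-section, mm^2. The default
#'   147.8 mm^2 is a CT-segmented sheep metatarsus section (cortical bone and
#'   marrow).
#' @param gap_length_mm Current callus gap (cumulative distraction), mm.
#' @return Object of class `callus_geometry`.
#' @export
callus_geometry <- function(cross_section_area_mm2 = 147.8, gap_length_mm) {
  if (cross_section_area_mm2 <= 0 || gap_length_mm <= 0) {
    stop_fixmon("domain", "area and gap length must be positive")
  }
  structure(list(cross_section_area_mm2 = cross_section_area_mm2,
                 gap_length_mm = gap_length_mm),
            class = "callus_geometry")
}

#' Young's modulus of the callus from its axial stiffness
#'
#' Treating the callus as a homogeneous column of length `L` (the distraction
#' gap) and section `A`, `E = Kc * L / A` (N/mm * mm / mm^2 = MPa). Linear in
#' both `Kc` and `L`.
#'
#' @param estimate A [stiffness_estimate()] or a numeric `Kc` in N/mm.
#' @param geom A [callus_geometry()].
#' @return Young's modulus, MPa.
#' @export
young_modulus <- function(estimate, geom) {
  Kc <- if (inherits(estimate, "stiffness_estimate")) estimate$Kc
        else as.numeric(estimate)
  if (!inherits(geom, "callus_geometry")) {
    stop_fixmon("domain", "geom must be a callus_geometry")
  }
  Kc * geom$gap_length_mm / geom$cross_section_area_mm2
}
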