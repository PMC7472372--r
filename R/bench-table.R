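#' Published spring-bench calibration results
#'
#' The per-spring results of the in vitro calibration campaign this package
#' models: six reference springs per phase, each measured over 4 fixator
#' assemblies x 5 repeats. `Ksr` is the reference spring stiffness, `Ks` the
#' grand-mean estimate, `sigma_s` the SD of the 20 estimates, `e` the
#' relative error and `U` the expanded relative uncertainty (reference,
#' replication and repetition sources). Used as reference input for report
#' checks and as the default source of the phase-average uncertainties
#' attached to in vivo estimates.
#'
#' @param phase `"distraction"`, `"consolidation"` or `"both"` (default).
#' @return A `data.frame` with columns `phase, spring, Ksr, Ks, sigma_s, e,
#'   U`.
#' @export
bench_reference_table <- function(phase = c("both", "distraction",
                                            "consolidation")) {
  phase <- match.arg(phase)
  tab <- data.frame(
    phase = rep(c("distraction", "consolidation"), each = 6),
    spring = rep(1:6, 2),
    Ksr = c(16.75, 39.93, 65.45, 102.77, 175.01, 208.83,
            103.01, 208.83, 416.37, 1979.03, 5050.13, 7448.78),
    Ks = c(17.25, 35.65, 62.88, 92.15, 167.09, 192.39,
           98.79, 194.29, 398.33, 1960.38, 4572.29, 7716.09),
    sigma_s = c(1.20, 2.86, 4.03, 3.21, 4.90, 9.03,
                16.52, 14.62, 31.86, 148.25, 539.96, 567.94),
    e = c(3.01, 10.72, 3.93, 10.33, 4.52, 7.87,
          4.09, 6.96, 4.33, 0.94, 9.46, 3.59),
    U = c(8.91, 10.74, 8.29, 5.01, 3.81, 8.26,
          21.92, 9.65, 14.22, 12.15, 16.02, 10.28)
  )
  if (phase != "both") tab <- tab[tab$phase == phase, ]
  rownames(tab) <- NULL
  tab
}
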