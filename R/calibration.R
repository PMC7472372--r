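# In vitro spring-bench calibration analysis.
#
# The stiffness estimators are validated on elastic springs of known
# stiffness Ksr standing in for the callus: 16.75-208.83 N/mm for the
# distraction procedure, 103.01-7448.78 N/mm for consolidation. For each
# spring and phase the fixator is assembled 4 times (replication) and the
# stiffness estimated 5 times per assembly (repetition); Ksr itself comes
# from the mean of 5 direct tests. The uncertainty budget combines three
# relative standard uncertainties in quadrature with a coverage factor k:
#   u_ref  reference-spring characterization, SD/(sqrt(5) * Ksr)
#   u_repl between assemblies, SD(assembly means)/(sqrt(4) * Ks)
#   u_rept within assembly, pooled SD/(sqrt(5) * Ks)
#   U = k * sqrt(u_ref^2 + u_repl^2 + u_rept^2),  k = 2.

#' Spring-bench record
#'
#' @param Ksr Reference spring stiffness, N/mm (> 0).
#' @param estimates Numeric matrix of estimated stiffness, N/mm, with one row
#'   per assembly and one column per repeat (default shape 4 x 5); the grid
#'   must be complete and positive.
#' @param phase `"distraction"` or `"consolidation"`.
#' @param Ksr_u_pct Relative standard uncertainty of the reference stiffness,
#'   percent (from the 5 direct spring tests).
#' @param spring_id Optional identifier.
#' @return Object of class `spring_bench_record`.
#' @export
spring_bench_record <- function(Ksr, estimates, phase, Ksr_u_pct = 0,
                                spring_id = NA_character_) {
  phase <- match.arg(phase, c("distraction", "consolidation"))
  if (Ksr <= 0) stop_fixmon("domain", "Ksr must be positive")
  estimates <- as.matrix(estimates)
  if (any(!is.finite(estimates))) {
    stop_fixmon("insufficient_data", "estimate grid is incomplete")
  }
  if (any(estimates <= 0)) {
    stop_fixmon("domain", "all stiffness estimates must be positive")
  }
  if (Ksr_u_pct < 0) stop_fixmon("domain", "Ksr_u_pct must be non-negative")
  structure(list(Ksr = Ksr, estimates = estimates, phase = phase,
                 Ksr_u_pct = Ksr_u_pct, spring_id = spring_id),
            class = "spring_bench_record")
}

#' Relative error of a stiffness estimate
#'
#' `e = 100 * |Ks - Ksr| / Ksr`, in percent.
#'
#' @param Ksr Reference stiffness, N/mm (> 0).
#' @param Ks Estimated stiffness, N/mm.
#' @param digits If non-`NULL`, round to this many decimals (bench reports
#'   use 2).
#' @return Relative error, percent.
#' @export
relative_error <- function(Ksr, Ks, digits = NULL) {
  if (any(Ksr <= 0)) stop_fixmon("domain", "Ksr must be positive")
  e <- 100 * abs(Ks - Ksr) / Ksr
  if (!is.null(digits)) e <- round(e, digits)
  e
}

#' Combine an uncertainty budget
#'
#' Relative standard uncertainties combined in quadrature and expanded by a
#' coverage factor.
#'
#' @param u_ref,u_repl,u_rept Relative standard uncertainties, percent:
#'   reference-spring, between-assembly (replication), within-assembly
#'   (repetition).
#' @param k Coverage factor (default 2).
#' @return Object of class `uncertainty_budget` with the components and the
#'   expanded relative uncertainty `U` (percent).
#' @export
uncertainty_budget <- function(u_ref, u_repl, u_rept, k = 2) {
  if (any(c(u_ref, u_repl, u_rept) < 0) || k <= 0) {
    stop_fixmon("domain", "uncertainty components must be >= 0 and k > 0")
  }
  structure(list(u_ref = u_ref, u_repl = u_repl, u_rept = u_rept, k = k,
                 U = k * sqrt(u_ref^2 + u_repl^2 + u_rept^2)),
            class = "uncertainty_budget")
}

#' Summarize a spring-bench record into a calibration row
#'
#' Computes the grand mean `Ks`, the SD over all estimates `sigma_s`, the
#' relative error `e`, the three uncertainty components and the expanded
#' relative uncertainty `U`.
#'
#' @param record A [spring_bench_record()].
#' @param k Coverage factor for the expanded uncertainty.
#' @param digits Rounding applied to `e` and `U` in the returned row
#'   (default 2, the report convention); components are returned unrounded.
#' @return A one-row `data.frame` (class `calibration_row`) with columns
#'   `spring_id, phase, Ksr, Ks, sigma_s, e, U, u_ref, u_repl, u_rept,
#'   s_between, s_within` (the last two in N/mm, for variance-component
#'   diagnostics).
#' @export
summarize_bench <- function(record, k = 2, digits = 2) {
  if (!inherits(record, "spring_bench_record")) {
    stop_fixmon("domain", "record must be a spring_bench_record")
  }
  est <- record$estimates
  A <- nrow(est)
  r <- ncol(est)
  Ks <- mean(est)
  sigma_s <- if (length(est) > 1) sd(as.vector(est)) else 0
  assembly_means <- rowMeans(est)
  s_between <- if (A > 1) sd(assembly_means) else 0
  s_within <- if (r > 1) sqrt(mean(apply(est, 1, var))) else 0
  u_ref <- record$Ksr_u_pct
  u_repl <- 100 * s_between / (sqrt(A) * Ks)
  u_rept <- 100 * s_within / (sqrt(r) * Ks)
  budget <- uncertainty_budget(u_ref, u_repl, u_rept, k = k)
  out <- data.frame(
    spring_id = record$spring_id, phase = record$phase,
    Ksr = record$Ksr, Ks = Ks, sigma_s = sigma_s,
    e = relative_error(record$Ksr, Ks, digits = digits),
    U = round(budget$U, digits),
    u_ref = u_ref, u_repl = u_repl, u_rept = u_rept,
    s_between = s_between, s_within = s_within,
    stringsAsFactors = FALSE
  )
  class(out) <- c("calibration_row", "data.frame")
  out
}

#' Phase averages of bench error and uncertainty
#'
#' Arithmetic means of the per-spring relative error and expanded
#' uncertainty, following the report convention: per-row values are rounded
#' to `digits` decimals before averaging, and the averages rounded the same
#' way.
#'
#' @param rows A `data.frame` with columns `e` and `U` (one row per spring,
#'   single phase), e.g. stacked [summarize_bench()] rows or a slice of
#'   [bench_reference_table()].
#' @param digits Decimals for rounding (default 2).
#' @return A list with `mean_e` and `mean_U`, percent.
#' @export
phase_average <- function(rows, digits = 2) {
  if (is.null(rows) || nrow(rows) < 1) {
    stop_fixmon("insufficient_data", "phase_average needs at least one row")
  }
  list(mean_e = round(mean(round(rows$e, digits)), digits),
       mean_U = round(mean(round(rows$U, digits)), digits))
}

#' Pointwise relative error between a measured and a reference force trace
#'
#' Used to score force acquisition against a testing-machine reference during
#' a compression ramp: `100 * |measured - reference| / |reference|` per
#' sample, with samples masked out wherever the reference magnitude falls
#' below `floor_fraction` of its own maximum (divide-by-near-zero guard at
#' the start of the ramp).
#'
#' @param measured,reference Synchronized force traces, N.
#' @param floor_fraction Reference floor as a fraction of `max(|reference|)`
#'   (default 0.05).
#' @return A list with `error_pct` (full-length vector, `NA` where masked),
#'   `mean_pct` (mean over unmasked samples) and `n_used`.
#' @export
force_acquisition_error <- function(measured, reference,
                                    floor_fraction = 0.05) {
  if (length(measured) != length(reference)) {
    stop_fixmon("domain", "traces must be synchronized (equal length)")
  }
  floor_N <- floor_fraction * max(abs(reference))
  use <- abs(reference) >= floor_N & abs(reference) > 0
  if (!any(use)) {
    stop_fixmon("insufficient_data", "all samples below the reference floor")
  }
  err <- rep(NA_real_, length(reference))
  err[use] <- 100 * abs(measured[use] - reference[use]) / abs(reference[use])
  list(error_pct = err, mean_pct = mean(err[use]), n_used = sum(use))
}

#' Read a spring-bench grid CSV
#'
#' Expected columns: `spring_id, phase, Ksr, Ksr_u_pct, assembly, repeat_no,
#' Ks_est`. Returns one [spring_bench_record()] per spring/phase.
#'
#' @param path CSV path.
#' @return Named list of `spring_bench_record` objects.
#' @export
read_bench_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("spring_id", "phase", "Ksr", "Ksr_u_pct", "assembly",
            "repeat_no", "Ks_est")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_fixmon("parse", paste("bench CSV missing columns:",
                               paste(miss, collapse = ", ")))
  }
  keys <- unique(df[, c("spring_id", "phase")])
  recs <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$spring_id == keys$spring_id[i] &
              df$phase == keys$phase[i], ]
    assemblies <- sort(unique(sub$assembly))
    repeats <- sort(unique(sub$repeat_no))
    grid <- matrix(NA_real_, length(assemblies), length(repeats))
    for (j in seq_len(nrow(sub))) {
      a <- match(sub$assembly[j], assemblies)
      r <- match(sub$repeat_no[j], repeats)
      grid[a, r] <- sub$Ks_est[j]
    }
    if (any(is.na(grid))) {
      stop_fixmon("insufficient_data",
                  sprintf("incomplete grid for spring %s (%s)",
                          keys$spring_id[i], keys$phase[i]))
    }
    recs[[i]] <- spring_bench_record(sub$Ksr[1], grid, sub$phase[1],
                                     Ksr_u_pct = sub$Ksr_u_pct[1],
                                     spring_id = as.character(keys$spring_id[i]))
  }
  names(recs) <- paste(keys$spring_id, keys$phase, sep = ":")
  recs
}

#' Write a spring-bench grid CSV
#'
#' @param records List of [spring_bench_record()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bench_csv <- function(records, path) {
  if (inherits(records, "spring_bench_record")) records <- list(records)
  rows <- do.call(rbind, lapply(records, function(rec) {
    A <- nrow(rec$estimates); r <- ncol(rec$estimates)
    data.frame(spring_id = rec$spring_id, phase = rec$phase,
               Ksr = rec$Ksr, Ksr_u_pct = rec$Ksr_u_pct,
               assembly = rep(seq_len(A), times = r),
               repeat_no = rep(seq_len(r), each = A),
               Ks_est = as.vector(rec$estimates))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
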