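#' Acquisition configuration
#'
#' Describes the analog front end and framing of the acquisition device: a
#' 16-bit ADC referenced to 2.5 V reading four load cells at a configurable
#' rate between 5 and 50 samples per second. The ADC transfer is affine per
#' cell; calibration coefficients live here, not in the stream. By default the
#' full signed 16-bit span maps onto the +/- 1 kN span of the load cells
#' (scale 1000/32767 N per count, zero offset), with compression negative and
#' traction positive.
#'
#' @param sample_rate Samples per second per cell, in \[5, 50\].
#' @param adc_bits ADC resolution; fixed at 16.
#' @param reference_voltage ADC reference, volts.
#' @param per_cell_scale Numeric length 4, newtons per ADC count (> 0).
#' @param per_cell_offset Numeric length 4, newtons added after scaling.
#' @param sync_mark Raw vector of 3 bytes marking the start of every frame.
#'   The wire layout (see [encode_block()]) is a documented convention of this
#'   package: the firmware publishes only the mark width and the
#'   10-sample/150-byte framing, not the byte order.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 50,
                               adc_bits = 16,
                               reference_voltage = 2.5,
                               per_cell_scale = rep(1000 / 32767, 4),
                               per_cell_offset = rep(0, 4),
                               sync_mark = as.raw(c(0xAA, 0x55, 0xA5))) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate < 5 || sample_rate > 50) {
    stop_fixmon("config", "sample_rate must be a single value in [5, 50] Hz")
  }
  if (adc_bits != 16) stop_fixmon("config", "adc_bits must be 16")
  per_cell_scale <- rep_len(as.numeric(per_cell_scale), 4)
  per_cell_offset <- rep_len(as.numeric(per_cell_offset), 4)
  if (any(per_cell_scale <= 0)) {
    stop_fixmon("config", "per_cell_scale must be positive")
  }
  if (!is.raw(sync_mark) || length(sync_mark) != 3) {
    stop_fixmon("config", "sync_mark must be exactly 3 bytes")
  }
  structure(
    list(sample_rate = sample_rate, adc_bits = adc_bits,
         reference_voltage = reference_voltage,
         per_cell_scale = per_cell_scale,
         per_cell_offset = per_cell_offset,
         sync_mark = sync_mark),
    class = "acquisition_config"
  )
}

#' Frame stream: timestamped four-cell ADC samples
#'
#' A frame is one sync-marked acquisition instant: four signed 16-bit ADC
#' counts (one per load cell) plus a session-relative millisecond timestamp.
#' A stream holds frames in acquisition order with strictly increasing
#' timestamps. Wall-clock anchoring belongs in stream metadata
#' (see [write_stream_meta()]), not in the frames.
#'
#' @param timestamp_ms Numeric vector, milliseconds since session start;
#'   strictly increasing, in \[0, 2^32).
#' @param counts Integer matrix with one row per frame and 4 columns, each in
#'   the signed 16-bit range \[-32768, 32767\].
#' @return A `data.frame` of class `frame_stream` with columns `timestamp_ms`,
#'   `cell1` .. `cell4`.
#' @export
frame_stream <- function(timestamp_ms, counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) {
    stop_fixmon("frame", "counts must have exactly 4 columns (one per cell)")
  }
  if (nrow(counts) != length(timestamp_ms)) {
    stop_fixmon("frame", "timestamp_ms length must match number of frames")
  }
  if (any(counts < -32768 | counts > 32767)) {
    stop_fixmon("range", "ADC counts outside signed 16-bit range")
  }
  if (any(timestamp_ms < 0) || any(timestamp_ms >= 2^32)) {
    stop_fixmon("range", "timestamps must lie in [0, 2^32) ms")
  }
  if (length(timestamp_ms) > 1 && any(diff(timestamp_ms) <= 0)) {
    stop_fixmon("frame", "timestamps must be strictly increasing")
  }
  out <- data.frame(timestamp_ms = as.numeric(timestamp_ms),
                    cell1 = as.integer(round(counts[, 1])),
                    cell2 = as.integer(round(counts[, 2])),
                    cell3 = as.integer(round(counts[, 3])),
                    cell4 = as.integer(round(counts[, 4])))
  class(out) <- c("frame_stream", "data.frame")
  out
}

count_matrix <- function(stream) {
  as.matrix(stream[, c("cell1", "cell2", "cell3", "cell4")])
}

#' Convert ADC counts to forces
#'
#' Applies the affine per-cell ADC transfer `force = count * scale + offset`.
#' Compression is negative, traction positive. Vectorized over a whole stream.
#'
#' @param stream A [frame_stream()].
#' @param config An [acquisition_config()].
#' @return A `data.frame` with columns `time_s`, `cell1_N` .. `cell4_N`,
#'   `sum_N` (the fixator force, i.e. the four-cell sum).
#' @export
counts_to_force <- function(stream, config = acquisition_config()) {
  cm <- count_matrix(stream)
  f <- sweep(sweep(cm, 2, config$per_cell_scale, `*`),
             2, config$per_cell_offset, `+`)
  out <- data.frame(time_s = stream$timestamp_ms / 1000,
                    cell1_N = f[, 1], cell2_N = f[, 2],
                    cell3_N = f[, 3], cell4_N = f[, 4])
  out$sum_N <- rowSums(f)
  out
}

#' Convert forces to ADC counts
#'
#' Inverse of [counts_to_force()], used by the synthetic bench to inject
#' physical forces into the wire format. Counts are rounded to the nearest
#' integer (ADC quantization) and must stay inside the 16-bit range.
#'
#' @param forces Numeric matrix, one row per sample, 4 columns of newtons.
#' @param config An [acquisition_config()].
#' @return Integer matrix of ADC counts.
#' @export
force_to_counts <- function(forces, config = acquisition_config()) {
  forces <- as.matrix(forces)
  cm <- sweep(sweep(forces, 2, config$per_cell_offset, `-`),
              2, config$per_cell_scale, `/`)
  cm <- round(cm)
  if (any(cm < -32768 | cm > 32767)) {
    stop_fixmon("range", "force exceeds the ADC count range for this config")
  }
  storage.mode(cm) <- "integer"
  cm
}
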