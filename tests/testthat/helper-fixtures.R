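# Shared fixtures built in code.

default_config <- function(...) acquisition_config(...)

quiet_scenario <- function(seed = 1, ...) {
  synthetic_scenario(seed = seed, noise_sd_per_cell = 0,
                     noise_sd_in_vivo_sum = 0, ...)
}

# a stream of n frames with reproducible random counts and 20 ms spacing
random_stream <- function(n, seed = 1) {
  set.seed(seed)
  frame_stream(seq_len(n) * 20,
               matrix(sample(-32768:32767, 4 * n, replace = TRUE),
                      ncol = 4))
}

# force trace data.frame from per-cell matrix
force_df <- function(cells, dt_s = 0.02) {
  cells <- as.matrix(cells)
  data.frame(time_s = (seq_len(nrow(cells)) - 1) * dt_s,
             cell1_N = cells[, 1], cell2_N = cells[, 2],
             cell3_N = cells[, 3], cell4_N = cells[, 4],
             sum_N = rowSums(cells))
}
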