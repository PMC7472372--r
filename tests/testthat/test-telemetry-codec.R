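test_that("a block is exactly 150 bytes and zero readings give zero payload", {
  cfg <- default_config()
  frames <- frame_stream(0:9 * 20, matrix(0L, nrow = 10, ncol = 4))
  b <- encode_block(frames, cfg)
  expect_length(b, 150)
  # per frame: bytes 4..11 are the count payload; all zero here
  for (k in 0:9) {
    expect_true(all(b[k * 15 + 4:11] == as.raw(0)))
    expect_identical(b[k * 15 + 1:3], cfg$sync_mark)
  }
})

test_that("encode_block rejects wrong frame counts and out-of-range counts", {
  cfg <- default_config()
  nine <- frame_stream(1:9 * 20, matrix(0L, nrow = 9, ncol = 4))
  expect_error(encode_block(nine, cfg), class = "fixmon_block_size_error")
  expect_error(frame_stream(1:2, matrix(c(40000, 0, 0, 0, 0, 0, 0, 0),
                                        nrow = 2, byrow = TRUE)),
               class = "fixmon_range_error")
})

test_that("decode(encode(x)) == x over random counts and timestamps", {
  cfg <- default_config()
  for (seed in 1:25) {
    st <- random_stream(10 * sample(1:5, 1), seed = seed)
    dec <- decode_stream(encode_stream(st, cfg), cfg)
    expect_identical(dec$frames, st)
    expect_identical(dec$resync_offsets, integer(0))
    expect_identical(dec$bytes_skipped, 0L)
  }
})

test_that("single contiguous corruption loses at most 2 frames and resyncs", {
  cfg <- default_config()
  st <- random_stream(60, seed = 7)
  clean <- encode_stream(st, cfg)
  # deletions of various widths at various positions, incl. frame-straddling
  cases <- list(c(200, 7), c(301, 3), c(155, 20), c(454, 1), c(610, 14))
  for (cs in cases) {
    corrupted <- clean[-(cs[1]:(cs[1] + cs[2] - 1))]
    dec <- decode_stream(corrupted, cfg)
    lost <- nrow(st) - dec$n_frames
    expect_lte(lost, 2)
    expect_gte(length(dec$resync_offsets), 1)
    # every recovered frame is bit-exact: all are rows of the original
    recovered <- dec$frames
    expect_true(all(recovered$timestamp_ms %in% st$timestamp_ms))
    idx <- match(recovered$timestamp_ms, st$timestamp_ms)
    expect_identical(recovered$cell1, st$cell1[idx])
    expect_identical(recovered$cell4, st$cell4[idx])
  }
})

test_that("a 7-byte mid-block deletion costs exactly one frame", {
  cfg <- default_config()
  st <- random_stream(20, seed = 3)
  clean <- encode_stream(st, cfg)
  dec_ref <- decode_stream(clean, cfg)
  corrupted <- clean[-(80:86)]      # inside frame 6 (bytes 76..90)
  dec <- decode_stream(corrupted, cfg)
  expect_identical(dec$n_frames, dec_ref$n_frames - 1L)
  expect_length(dec$resync_offsets, 1)
  expect_identical(dec$frames$timestamp_ms,
                   st$timestamp_ms[st$timestamp_ms != st$timestamp_ms[6]])
})

test_that("random bytes without a sync mark decode to nothing, no error", {
  cfg <- default_config()
  set.seed(11)
  junk <- as.raw(sample(0:169, 600, replace = TRUE))  # never 0xAA
  dec <- decode_stream(junk, cfg)
  expect_identical(dec$n_frames, 0L)
  expect_identical(nrow(dec$frames), 0L)
  expect_identical(dec$bytes_skipped, 600L)
  expect_identical(decode_stream(raw(0), cfg)$n_frames, 0L)
})

test_that("ADC transfer is affine with the stated sign convention", {
  cfg <- default_config(per_cell_scale = rep(0.01, 4))
  st <- frame_stream(0, matrix(c(-5000L, 0L, 2500L, -100L), nrow = 1))
  f <- counts_to_force(st, cfg)
  expect_equal(f$cell1_N, -50)    # compression negative
  expect_equal(f$cell2_N, 0)
  expect_equal(f$cell3_N, 25)     # traction positive
  expect_equal(f$sum_N, -50 + 0 + 25 - 1)
  # default scale maps full-scale counts inside the 0-1 kN cell range
  full <- counts_to_force(frame_stream(0, matrix(c(32767L, -32767L, 0L, 0L),
                                                 nrow = 1)),
                          default_config())
  expect_equal(full$cell1_N, 1000)
  expect_equal(full$cell2_N, -1000)
})

test_that("baseline is the per-cell rest mean and subtraction is a pure shift", {
  # constant load
  rest <- force_df(matrix(3, nrow = 50, ncol = 4))
  bl <- compute_baseline(rest)
  expect_equal(unname(bl$per_cell_mean), rep(3, 4))
  expect_equal(bl$n_samples_used, 50)
  # alternating +/- 1 N averages to zero
  alt <- force_df(cbind(rep(c(1, -1), 25), 0, 0, 0))
  expect_equal(unname(compute_baseline(alt)$per_cell_mean[1]), 0)
  # empty window errors
  expect_error(compute_baseline(rest[0, ]),
               class = "fixmon_insufficient_data_error")
  # normalize then recompute -> zero; variance unchanged; step preserved
  set.seed(4)
  noisy <- force_df(matrix(rnorm(200, 5, 0.2), ncol = 4))
  norm <- apply_baseline(noisy, compute_baseline(noisy))
  expect_equal(unname(compute_baseline(norm)$per_cell_mean), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(var(norm$cell2_N), var(noisy$cell2_N))
  # shift invariance: a +10 N step after the rest window keeps its height
  flat <- force_df(matrix(5, nrow = 50, ncol = 4))
  stepped <- flat
  stepped$cell1_N <- stepped$cell1_N + c(rep(0, 25), rep(10, 25))
  norm2 <- apply_baseline(stepped, compute_baseline(flat))
  expect_equal(unique(norm2$cell1_N[1:25]), 0)
  expect_equal(unique(norm2$cell1_N[26:50]), 10)
})

test_that("rest-window mean under linear drift matches the ramp closed form", {
  # drift slope s over T seconds: mean of s*t for t in [0, T) is ~ s*T/2
  sc <- synthetic_scenario(seed = 5, noise_sd_per_cell = 0,
                           drift_N_per_hour = 36)   # 0.01 N/s
  cfg <- default_config()
  st <- simulate_rest_stream(sc, 100, cfg)
  bl <- compute_baseline(counts_to_force(st, cfg))
  expect_equal(unname(bl$per_cell_mean), rep(0.01 * 100 / 2, 4),
               tolerance = 0.02)
})

test_that("trace CSV and metadata sidecar round-trip", {
  dir <- withr::local_tempdir()
  cfg <- default_config()
  st <- random_stream(20, seed = 9)
  f <- counts_to_force(st, cfg)
  p <- write_trace_csv(f, file.path(dir, "t.csv"))
  expect_equal(read_trace_csv(p), f, tolerance = 1e-9)
  meta <- file.path(dir, "m.json")
  write_stream_meta(meta, cfg, baseline = compute_baseline(f),
                    session_start = "2026-01-01T00:00:00Z")
  got <- jsonlite::read_json(meta)
  expect_equal(got$sample_rate_hz, cfg$sample_rate)
  expect_length(got$baseline_per_cell_N, 4)
})
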