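# Framed binary wire format.
#
# One frame is 15 bytes:
#   bytes 1-3   sync mark (default 0xAA 0x55 0xA5)
#   bytes 4-11  four int16 little-endian ADC counts, cells 1..4
#   bytes 12-15 uint32 little-endian timestamp, ms since session start
# The firmware buffers 10 frames per transmission, hence the 150-byte block.
# The byte order and timestamp width are a convention of this package: the
# device documentation fixes only the 3-byte mark and the 150-byte buffer.

FRAME_BYTES <- 15L
BLOCK_FRAMES <- 10L
BLOCK_BYTES <- FRAME_BYTES * BLOCK_FRAMES

# indices of one longest strictly-increasing subsequence (patience sorting)
lis_strict <- function(x) {
  n <- length(x)
  if (n <= 1) return(seq_len(n))
  tails <- integer(0)      # index of smallest tail of an LIS of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {       # first tail position with x[tails[pos]] >= x[i]
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

# little-endian byte columns for unsigned integers held as doubles
le_bytes <- function(v, width) {
  out <- matrix(0L, nrow = width, ncol = length(v))
  for (i in seq_len(width)) {
    out[i, ] <- as.integer(v %% 256)
    v <- v %/% 256
  }
  out
}

encode_frames_raw <- function(stream, config) {
  n <- nrow(stream)
  cm <- count_matrix(stream)
  u <- cm + 65536L * (cm < 0L)              # two's complement as unsigned
  bytes <- matrix(0L, nrow = FRAME_BYTES, ncol = n)
  bytes[1:3, ] <- as.integer(config$sync_mark)
  for (j in 0:3) {
    bytes[4L + 2L * j, ] <- u[, j + 1] %% 256L
    bytes[5L + 2L * j, ] <- u[, j + 1] %/% 256L
  }
  bytes[12:15, ] <- le_bytes(stream$timestamp_ms, 4L)
  as.raw(bytes)
}

#' Encode ten frames as one 150-byte block
#'
#' Serializes exactly ten frames in the firmware's transmission unit: a
#' 150-byte buffer of ten 15-byte frames, each led by the 3-byte sync mark
#' that lets a receiver resynchronize after data loss.
#'
#' @param frames A [frame_stream()] with exactly 10 rows.
#' @param config An [acquisition_config()].
#' @return A raw vector of length 150.
#' @seealso [decode_stream()] for the inverse, [encode_stream()] for whole
#'   sessions.
#' @export
encode_block <- function(frames, config = acquisition_config()) {
  if (!inherits(frames, "frame_stream")) {
    stop_fixmon("frame", "frames must be a frame_stream")
  }
  if (nrow(frames) != BLOCK_FRAMES) {
    stop_fixmon("block_size",
                sprintf("a block holds exactly %d frames, got %d",
                        BLOCK_FRAMES, nrow(frames)))
  }
  encode_frames_raw(frames, config)
}

#' Encode a whole stream
#'
#' Frame-wise serialization of an arbitrary-length stream; every 10 frames
#' form one 150-byte block.
#'
#' @inheritParams encode_block
#' @param frames A [frame_stream()] of any length.
#' @return A raw vector of length `15 * nrow(frames)`.
#' @export
encode_stream <- function(frames, config = acquisition_config()) {
  if (!inherits(frames, "frame_stream")) {
    stop_fixmon("frame", "frames must be a frame_stream")
  }
  if (nrow(frames) == 0) return(raw(0))
  encode_frames_raw(frames, config)
}

#' Decode a (possibly corrupted) byte stream
#'
#' Recovers frames from an arbitrary byte stream by scanning for the 3-byte
#' sync mark. Corruption never raises: damaged spans are skipped and every
#' resynchronization event (an accepted frame that does not follow
#' contiguously from the previous one) is reported with its byte offset.
#'
#' A sync candidate is accepted only if its timestamp is strictly greater
#' than the last accepted frame's and no other sync mark falls inside its
#' 15-byte window (an interior mark means the frame was truncated by data
#' loss). Under this rule any single contiguous corruption costs at most the
#' two frames it touches; all later frames are recovered bit-exactly.
#'
#' @param bytes Raw vector, e.g. from [encode_stream()] or a damaged capture.
#' @param config An [acquisition_config()].
#' @return A list with elements:
#'   `frames` (a [frame_stream()], possibly empty),
#'   `resync_offsets` (integer byte offsets, 1-based, where the decoder
#'   re-acquired sync after a gap),
#'   `n_frames` (frames recovered),
#'   `bytes_skipped` (bytes not consumed as frame payload).
#' @export
decode_stream <- function(bytes, config = acquisition_config()) {
  empty <- frame_stream(numeric(0), matrix(integer(0), ncol = 4))
  if (length(bytes) < FRAME_BYTES) {
    return(list(frames = empty, resync_offsets = integer(0),
                n_frames = 0L, bytes_skipped = length(bytes)))
  }
  b <- as.integer(bytes)
  n <- length(b)
  s <- as.integer(config$sync_mark)
  last <- n - FRAME_BYTES + 1L
  cand <- which(b[seq_len(last)] == s[1] &
                b[seq_len(last) + 1L] == s[2] &
                b[seq_len(last) + 2L] == s[3])
  # any sync occurrence (incl. ones too close to the end to hold a frame)
  last3 <- n - 2L
  allsync <- which(b[seq_len(last3)] == s[1] &
                   b[seq_len(last3) + 1L] == s[2] &
                   b[seq_len(last3) + 2L] == s[3])
  if (length(cand) == 0) {
    return(list(frames = empty, resync_offsets = integer(0),
                n_frames = 0L, bytes_skipped = n))
  }

  # vectorized parse of every candidate window
  u <- matrix(0L, nrow = length(cand), ncol = 4)
  for (j in 0:3) {
    u[, j + 1] <- b[cand + 3L + 2L * j] + 256L * b[cand + 4L + 2L * j]
  }
  counts <- u - 65536L * (u > 32767L)
  ts <- b[cand + 11L] + 256 * b[cand + 12L] +
    65536 * b[cand + 13L] + 16777216 * b[cand + 14L]

  # candidates that contain another sync mark strictly inside their window
  # (allsync is sorted, so only the next occurrence needs checking)
  nxt <- allsync[findInterval(cand, allsync) + 1L]
  has_interior <- !is.na(nxt) & nxt <= cand + FRAME_BYTES - 1L

  # pass 1: greedy non-overlapping candidates whose window holds no other
  # sync mark (an interior mark means the frame was cut short by data loss)
  keep_ok <- logical(length(cand))
  last_end <- 0L
  for (i in seq_along(cand)) {
    if (cand[i] <= last_end || has_interior[i]) next
    keep_ok[i] <- TRUE
    last_end <- cand[i] + FRAME_BYTES - 1L
  }
  keep <- which(keep_ok)
  # pass 2: timestamps must be strictly increasing; take the longest
  # increasing subsequence so a single corrupted frame with an arbitrary
  # timestamp cannot shadow the frames that follow it
  keep <- keep[lis_strict(ts[keep])]

  sel <- logical(length(cand))
  sel[keep] <- TRUE
  resync <- integer(0)
  expected <- if (length(keep)) cand[keep[1]] else 0L   # clean start: no event
  for (i in keep) {
    if (cand[i] != expected) resync <- c(resync, cand[i])
    expected <- cand[i] + FRAME_BYTES
  }

  frames <- if (any(sel)) {
    frame_stream(ts[sel], counts[sel, , drop = FALSE])
  } else empty
  list(frames = frames,
       resync_offsets = resync,
       n_frames = sum(sel),
       bytes_skipped = n - FRAME_BYTES * sum(sel))
}
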