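# Audio rendering: pure tones with raised-cosine on/off ramps, and a minimal
# 16-bit PCM mono WAV writer/reader (kept in-package so rendered stimuli
# round-trip without external audio dependencies).

#' Rendering configuration
#'
#' @param sample_rate sampling frequency in Hz (default 8192, which is above
#'   the Nyquist limit for the highest 1000-Hz tone).
#' @param ramp_ms raised-cosine on/off ramp duration in ms (default 20); must
#'   not exceed half the tone duration.
#' @param bit_depth WAV bit depth; only 16 is supported.
#' @param master_gain peak linear amplitude of a full-scale tone (default 0.9).
#' @return A list of class `render_config`.
#' @export
render_config <- function(sample_rate = 8192, ramp_ms = 20, bit_depth = 16,
                          master_gain = 0.9) {
  if (sample_rate <= 2 * max(.FREQS_HZ)) {
    stop("sample_rate must exceed twice the maximum tone frequency (",
         2 * max(.FREQS_HZ), " Hz)")
  }
  if (ramp_ms < 0 || ramp_ms > .TONE_MS / 2) {
    stop("ramp_ms must lie in [0, ", .TONE_MS / 2, "]")
  }
  if (bit_depth != 16) stop("only 16-bit PCM output is supported")
  if (master_gain <= 0 || master_gain > 1) stop("master_gain must be in (0, 1]")
  structure(list(sample_rate = sample_rate, ramp_ms = ramp_ms,
                 bit_depth = bit_depth, master_gain = master_gain),
            class = "render_config")
}

# Raised-cosine (Hann-edge) gate for local times u (ms) within [0, dur).
.rc_envelope <- function(u, dur, ramp) {
  env <- as.numeric(u >= 0 & u < dur)
  if (ramp > 0) {
    on <- u >= 0 & u < ramp
    off <- u > dur - ramp & u < dur
    env[on] <- 0.5 * (1 - cos(pi * u[on] / ramp))
    env[off] <- 0.5 * (1 - cos(pi * (dur - u[off]) / ramp))
  }
  env
}

#' Render a stimulus sequence to a sampled waveform
#'
#' Each tone is a sine at its scheduled frequency, gated by a raised-cosine
#' envelope with `ramp_ms` on/off ramps, placed at its onset; the signal is
#' zero outside tone supports. Tones never overlap in valid sequences, so the
#' result equals the sample-wise sum of the individually rendered tones.
#'
#' @param seq a `stimulus_sequence` (or any list with `onset_ms`,
#'   `duration_ms`, `frequency_hz`, `total_duration_ms`).
#' @param cfg a [render_config()].
#' @param amplitude per-tone linear gain in `[0, 1]` (recycled).
#' @return Numeric vector of `ceiling(total_duration * sample_rate)` samples
#'   with attribute `sample_rate`.
#' @export
render_waveform <- function(seq, cfg = render_config(), amplitude = 1) {
  sr <- cfg$sample_rate
  n_events <- length(seq$onset_ms)
  total_ms <- if (is.null(seq$total_duration_ms)) .TOTAL_MS else seq$total_duration_ms
  n_samp <- ceiling(total_ms / 1000 * sr)
  signal <- numeric(n_samp)
  if (n_events == 0) return(structure(signal, sample_rate = sr))
  ord <- order(seq$onset_ms)
  off <- seq$onset_ms + seq$duration_ms
  if (any(seq$onset_ms[ord][-1] < off[ord][-n_events] - 1e-9)) {
    stop("cannot render overlapping tones")
  }
  amplitude <- rep_len(amplitude, n_events)
  t_ms <- (seq_len(n_samp) - 1) / sr * 1000
  for (k in seq_len(n_events)) {
    idx <- which(t_ms >= seq$onset_ms[k] & t_ms < off[k])
    u <- t_ms[idx] - seq$onset_ms[k]
    signal[idx] <- signal[idx] + cfg$master_gain * amplitude[k] *
      .rc_envelope(u, seq$duration_ms[k], cfg$ramp_ms) *
      sin(2 * pi * seq$frequency_hz[k] * u / 1000)
  }
  structure(signal, sample_rate = sr)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param signal numeric vector in `[-1, 1]`.
#' @param path output file.
#' @param sample_rate sampling frequency in Hz; defaults to the signal's
#'   `sample_rate` attribute.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, sample_rate = attr(signal, "sample_rate")) {
  if (is.null(sample_rate)) stop("sample_rate is required")
  if (max(abs(signal)) > 1 + 1e-9) stop("signal exceeds full scale [-1, 1]")
  pcm <- as.integer(round(pmax(-1, pmin(1, signal)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")      # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV written by [write_wav()]
#'
#' @param path WAV file.
#' @return Numeric signal in `[-1, 1]` with attribute `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono is supported")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", size - 8)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  structure(pcm / 32767, sample_rate = sample_rate)
}

#' Write a rendered stimulus and its event table
#'
#' Writes `<stem>.wav` (16-bit PCM at the configured sample rate, unless
#' `no_audio`) and a sidecar `<stem>_events.csv` with columns
#' `onset_ms,duration_ms,frequency_hz,group_index` (times with 3 decimal
#' places; `group_index` 0-based, -1 for ungrouped tones) that round-trips
#' through [read_stimulus_events()].
#'
#' @param seq a `stimulus_sequence`.
#' @param stem output path without extension.
#' @param cfg a [render_config()].
#' @param no_audio if `TRUE`, write only the event table.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_stimulus <- function(seq, stem, cfg = render_config(), no_audio = FALSE) {
  validate_sequence(seq)
  events_path <- paste0(stem, "_events.csv")
  ev <- as.data.frame(seq)
  ev$onset_ms <- sprintf("%.3f", ev$onset_ms)
  ev$duration_ms <- sprintf("%.3f", ev$duration_ms)
  tryCatch(
    utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("failed writing event table to ", events_path,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  paths <- c(events = events_path)
  if (!no_audio) {
    wav_path <- paste0(stem, ".wav")
    tryCatch(
      write_wav(render_waveform(seq, cfg), wav_path, cfg$sample_rate),
      error = function(e) stop("failed writing WAV to ", wav_path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    paths <- c(paths, wav = wav_path)
  }
  invisible(paths)
}

#' Read a stimulus event table written by [write_stimulus()]
#'
#' @param path the `_events.csv` sidecar.
#' @return data.frame with columns `onset_ms`, `duration_ms`, `frequency_hz`,
#'   `group_index`.
#' @export
read_stimulus_events <- function(path) {
  if (!file.exists(path)) stop("no such event table: ", path)
  utils::read.csv(path, comment.char = "#")
}
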