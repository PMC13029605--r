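#' Equal-temperament note frequency
#'
#' Converts a pitch class and octave in scientific pitch notation to a
#' frequency under twelve-tone equal temperament,
#' \eqn{f = f_{A4} \cdot 2^{s/12}}, where \eqn{s} is the semitone offset
#' from A4. Flats are accepted as synonyms of the enharmonic sharps.
#'
#' @param pitch_class One of the 12 chromatic note names
#'   (`"C"`, `"C#"`, ..., `"B"`; flats such as `"Ab"` allowed).
#' @param octave Integer octave in scientific pitch notation, between -1
#'   and 9 (A4 = 440 Hz sits in octave 4).
#' @param reference_a4 Reference tuning frequency for A4 in Hz.
#' @return Frequency in Hz (full precision; round only for display).
#' @examples
#' note_frequency("A", 4)         # 440
#' note_frequency("G#", 0)        # ~25.96, the low stimulation tone
#' note_frequency("G#", 4)        # ~415.30, the high stimulation tone
#' @export
note_frequency <- function(pitch_class, octave, reference_a4 = 440) {
  semis <- c(
    "C" = 0L, "C#" = 1L, "DB" = 1L, "D" = 2L, "D#" = 3L, "EB" = 3L,
    "E" = 4L, "F" = 5L, "F#" = 6L, "GB" = 6L, "G" = 7L, "G#" = 8L,
    "AB" = 8L, "A" = 9L, "A#" = 10L, "BB" = 10L, "B" = 11L
  )
  key <- toupper(gsub("♯", "#", gsub("♭", "b", as.character(pitch_class))))
  if (length(key) != 1L || is.na(match(key, names(semis)))) {
    stop("unknown pitch class: ", pitch_class, call. = FALSE)
  }
  octave <- as.integer(octave)
  if (is.na(octave) || octave < -1L || octave > 9L) {
    stop("octave must be an integer in [-1, 9]", call. = FALSE)
  }
  s <- (octave - 4L) * 12L + (semis[[key]] - 9L)
  reference_a4 * 2^(s / 12)
}

#' Stimulation tone presets
#'
#' Frequencies of the two G-sharp stimulation tones used throughout:
#' `AMP_LOW` is G#0 (~25.96 Hz) and `AMP_HIGH` is G#4 (~415.30 Hz).
#'
#' @format Numeric scalars, Hz.
#' @export
AMP_LOW <- 440 * 2^(-49 / 12)

#' @rdname AMP_LOW
#' @export
AMP_HIGH <- 440 * 2^(-1 / 12)

#' ON-OFF acoustic stimulation protocol
#'
#' Describes a periodic stimulation schedule: `on_s` seconds of tone
#' followed by `off_s` seconds of rest, repeated over `total_s` seconds.
#' The schedule starts in the ON phase at t = 0 and phase boundaries
#' belong to the phase they open (half-open intervals).
#'
#' @param on_s ON-phase duration in seconds (> 0).
#' @param off_s OFF-phase duration in seconds (>= 0).
#' @param total_s Total schedule duration in seconds.
#' @param tone Carrier tone: a frequency in Hz, or a list
#'   `list(note =, octave =)` resolved through [note_frequency()].
#' @param label Free-text label for reports.
#' @return A `stimulus_protocol` object.
#' @examples
#' p <- stimulus_protocol(on_s = 1, off_s = 1, total_s = 60, tone = AMP_LOW)
#' modulation_fundamental(p)  # 0.5 Hz
#' @export
stimulus_protocol <- function(on_s = 1, off_s = 1, total_s = 60,
                              tone = AMP_LOW, label = NULL) {
  if (!is.numeric(on_s) || on_s <= 0) stop("on_s must be > 0", call. = FALSE)
  if (!is.numeric(off_s) || off_s < 0) stop("off_s must be >= 0", call. = FALSE)
  if (!is.numeric(total_s) || total_s < on_s + off_s) {
    stop("total_s must be >= on_s + off_s", call. = FALSE)
  }
  if (is.list(tone)) tone <- note_frequency(tone$note, tone$octave)
  if (!is.numeric(tone) || tone <= 0) stop("tone frequency must be > 0", call. = FALSE)
  if (is.null(label)) label <- sprintf("ON %gs / OFF %gs, tone %.2f Hz", on_s, off_s, tone)
  structure(
    list(on_s = on_s, off_s = off_s, total_s = total_s,
         tone_hz = tone, label = label),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol:", x$label, "\n")
  cat(sprintf("  period %g s, fundamental %.4g Hz, total %g s\n",
              x$on_s + x$off_s, modulation_fundamental(x), x$total_s))
  invisible(x)
}

#' Protocol presets
#'
#' Shorthand for the standard experimental protocols: 1 s ON / 1 s OFF
#' over 60 s with the low (G#0) or high (G#4) tone, or no stimulation.
#'
#' @param name `"amp-low"`, `"amp-high"` or `"no-amp"`.
#' @param total_s Total duration in seconds.
#' @return A `stimulus_protocol`, or `NULL` for `"no-amp"`.
#' @export
protocol_preset <- function(name = c("amp-low", "amp-high", "no-amp"),
                            total_s = 60) {
  name <- match.arg(name)
  switch(name,
    "amp-low" = stimulus_protocol(1, 1, total_s, AMP_LOW, "AMP 1st octave"),
    "amp-high" = stimulus_protocol(1, 1, total_s, AMP_HIGH, "AMP 4th octave"),
    "no-amp" = NULL
  )
}

#' Stimulus state at a given time
#'
#' @param protocol A [stimulus_protocol()].
#' @param t Time(s) in seconds, each in `[0, total_s)`.
#' @return Character vector, `"ON"` or `"OFF"` per time point.
#' @export
stimulus_state <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(t < 0 | t >= protocol$total_s)) {
    stop("t must lie in [0, total_s)", call. = FALSE)
  }
  period <- protocol$on_s + protocol$off_s
  ifelse(t %% period < protocol$on_s, "ON", "OFF")
}

#' Fundamental modulation frequency of a protocol
#'
#' The reciprocal of the ON + OFF period; for the standard 1 s / 1 s
#' schedule this is the 0.5 Hz line expected to dominate the
#' low-frequency velocity spectrum.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Frequency in Hz.
#' @export
modulation_fundamental <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  period <- protocol$on_s + protocol$off_s
  if (period <= 0) stop("protocol period must be > 0", call. = FALSE)
  1 / period
}

#' Read / write a stimulation protocol
#'
#' Serializes to a YAML or JSON mapping with keys `on_s`, `off_s`,
#' `total_s`, `tone` (`{hz}` or `{note, octave}`) and `label`.
#'
#' @param protocol A [stimulus_protocol()].
#' @param path File path; format chosen by extension (`.json` vs YAML).
#' @return `read_protocol` returns a `stimulus_protocol`;
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  rec <- list(on_s = protocol$on_s, off_s = protocol$off_s,
              total_s = protocol$total_s,
              tone = list(hz = protocol$tone_hz),
              label = protocol$label)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rec, path)
  }
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tone <- if (!is.null(rec$tone$hz)) rec$tone$hz else list(note = rec$tone$note, octave = rec$tone$octave)
  stimulus_protocol(rec$on_s, rec$off_s, rec$total_s, tone, rec$label)
}
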