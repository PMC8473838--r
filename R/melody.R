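#' The 32-tone duet melody template
#'
#' Returns the fixed rhythm/pitch template that every performance in this
#' package is scored against: the round "Frere Jacques" in C major, 32 tones
#' long, in binary (4/4) meter, comprising 20 quarter notes, 4 half notes and
#' 8 eighth notes (32 beats in total). The first 8 tones are all quarter
#' notes; they form the leader's solo count-in segment in duet trials.
#' Eighth notes occur in on-beat/off-beat pairs.
#'
#' @return A tibble with one row per melody event and columns
#'   \describe{
#'     \item{event}{event index 1..32}
#'     \item{pitch}{MIDI note number (G3 = 55 .. A4 = 69)}
#'     \item{beat_value}{duration in beats: 0.5 (eighth), 1 (quarter), 2 (half)}
#'     \item{is_on_beat}{`TRUE` if the onset falls on an integer beat}
#'     \item{beat}{cumulative onset position in beats, 0-based}
#'   }
#'   plus attributes `n_events` (32) and `total_beats` (32).
#' @examples
#' m <- make_melody_spec()
#' sum(m$beat_value)          # 32 beats
#' table(m$beat_value)        # 8 eighths, 20 quarters, 4 halves
#' @export
make_melody_spec <- function() {
  C4 <- 60; D4 <- 62; E4 <- 64; F4 <- 65; G4 <- 67; A4 <- 69; G3 <- 55
  pitch <- c(
    C4, D4, E4, C4,  C4, D4, E4, C4,       # "Frere Jacques" x2 (count-in)
    E4, F4, G4,      E4, F4, G4,           # "Dormez-vous?"  x2
    G4, A4, G4, F4, E4, C4,                # "Sonnez les matines" x2
    G4, A4, G4, F4, E4, C4,
    C4, G3, C4,      C4, G3, C4            # "Ding dang dong" x2
  )
  beat_value <- c(
    rep(1, 8),
    1, 1, 2,  1, 1, 2,
    0.5, 0.5, 0.5, 0.5, 1, 1,
    0.5, 0.5, 0.5, 0.5, 1, 1,
    1, 1, 2,  1, 1, 2
  )
  beat <- cumsum(c(0, beat_value[-length(beat_value)]))
  spec <- tibble::tibble(
    event = seq_along(pitch),
    pitch = pitch,
    beat_value = beat_value,
    is_on_beat = beat %% 1 == 0,
    beat = beat
  )
  stopifnot(
    nrow(spec) == 32L,
    sum(spec$beat_value) == 32,
    all(spec$beat_value[1:8] == 1)
  )
  attr(spec, "n_events") <- 32L
  attr(spec, "total_beats") <- 32
  class(spec) <- c("melody_spec", class(spec))
  spec
}
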