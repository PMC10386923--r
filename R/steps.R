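#' Generate a random-walk step sequence
#'
#' One jitter step is applied at every display frame: a fixed-amplitude
#' lateral displacement, independently and equiprobably to the left (-1)
#' or to the right (+1). The cumulative offset is the running sum of
#' signed steps and therefore performs a simple random walk; splitting
#' many sequences by the direction of the step at one chosen frame
#' separates the group-mean offsets by exactly twice the amplitude from
#' that frame onward, which is what the reverse-correlation analysis
#' exploits.
#'
#' @param n_frames Number of display frames (>= 1).
#' @param amplitude Step amplitude, mm (>= 0).
#' @param frame_rate Display frame rate, Hz (frame k is at time
#'   `(k - 1) / frame_rate`).
#' @param seed Optional integer seed; when supplied the sequence is
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return A `step_sequence`: list with `directions` (+/-1 per frame),
#'   `amplitude`, `frame_times` (s) and `cumulative_offset` (mm).
#' @examples
#' s <- generate_step_sequence(10, 2.5, seed = 1)
#' all(abs(diff(s$cumulative_offset)) == 2.5)
#' @export
generate_step_sequence <- function(n_frames, amplitude = 2.5,
                                   frame_rate = 60, seed = NULL) {
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 1) {
    stop("generate_step_sequence: `n_frames` must be a positive count",
      call. = FALSE
    )
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("generate_step_sequence: `amplitude` must be non-negative",
      call. = FALSE
    )
  }
  n_frames <- as.integer(n_frames)
  draw <- function() sample(c(-1L, 1L), n_frames, replace = TRUE)
  directions <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(
      directions = directions,
      amplitude = amplitude,
      frame_times = (seq_len(n_frames) - 1L) / frame_rate,
      cumulative_offset = amplitude * cumsum(directions)
    ),
    class = "step_sequence"
  )
}
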