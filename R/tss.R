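# Dominant TSS selection from CAGE signal.

#' Nine-nucleotide CAGE window score (f)
#'
#' Sum of CAGE signal in a window of `window` bases centered on a candidate
#' TSS position. The window is centered (symmetric around the candidate)
#' because CAGE peak positions are inaccurate by a few bases in either
#' direction; it is truncated, not discarded, at track boundaries.
#'
#' @param track A [signal_track] (or plain numeric vector) of non-negative
#'   CAGE values.
#' @param position 1-based index of the candidate TSS within the track.
#' @param window Odd window width in bases (default 9).
#' @return The f score (sum of the windowed values).
#' @export
cage_window_score <- function(track, position, window = 9L) {
  v <- if (inherits(track, "signal_track")) track$values else as.numeric(track)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd positive")
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > length(v))
    stop("candidate position outside the track")
  h <- (window - 1L) %/% 2L
  sum(v[max(1L, position - h):min(length(v), position + h)])
}

#' Dominant TSS among annotated candidates
#'
#' Ranks annotated candidate TSS positions by their CAGE window score
#' ([cage_window_score()]) and returns the maximum. Exact ties are broken
#' towards the 5'-most candidate on the gene's strand (smallest position on
#' `+`, largest on `-`), which favours the annotated primary start and keeps
#' the choice deterministic.
#'
#' @param candidates Integer vector of 1-based candidate positions within
#'   `track` (at least one).
#' @param track CAGE [signal_track] or numeric vector.
#' @param strand Gene strand, `"+"` (default) or `"-"`.
#' @param window Window width passed to [cage_window_score()].
#' @return List with `position` (the dominant candidate) and `f_score`.
#' @export
dominant_tss <- function(candidates, track, strand = "+", window = 9L) {
  if (!length(candidates)) stop("no candidate TSSs supplied")
  f <- vapply(candidates, cage_window_score, numeric(1),
              track = track, window = window)
  best <- f == max(f)
  pos <- candidates[best]
  pick <- if (strand == "-") which.max(pos) else which.min(pos)
  list(position = pos[pick], f_score = max(f))
}
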