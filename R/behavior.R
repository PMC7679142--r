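#' Score freezing episodes from a motion-index trace
#'
#' A freezing episode is a maximal run of frames whose sliding-window mean
#' motion stays below `threshold` for at least `min_dur` seconds of
#' immobility. The window starting at frame `i` covers frames
#' `i .. i + w - 1` (w = `window * fs` frames); a run of L consecutive
#' below-threshold window starts represents `(L - 1) / fs + window` seconds
#' immobile. Episode onset is the first frame of the run.
#'
#' @param motion a [motion_trace()].
#' @param threshold motion-index threshold; the scale is tracker-specific,
#'   so this is a free parameter.
#' @param min_dur minimum immobile time in seconds (default 1 s).
#' @param window sliding-window length in seconds (default 1 s).
#' @return data.frame with columns `onset` (s), `kind`
#'   ("freezing_onset"), `duration` (s), `correctness` ("unassigned").
#' @export
score_freezing <- function(motion, threshold, min_dur = 1, window = 1) {
  stopifnot(inherits(motion, "motion_trace"))
  x <- motion$index
  fs <- motion$fs
  if (all(is.na(x))) stop("motion trace is all NA")
  w <- as.integer(round(window * fs))
  if (w < 1) stop("window shorter than one frame")
  n <- length(x)
  if (n < w)
    return(data.frame(onset = numeric(0), kind = character(0),
                      duration = numeric(0), correctness = character(0)))
  # windowed means for starts 1 .. n - w + 1
  cs <- cumsum(c(0, x))
  m <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  below <- m < threshold
  below[is.na(below)] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  need <- max(1L, as.integer(round((min_dur - window) * fs)) + 1L)
  keep <- r$values & r$lengths >= need
  onset <- (starts[keep] - 1) / fs
  duration <- (r$lengths[keep] - 1) / fs + window
  out <- data.frame(onset = onset, kind = rep("freezing_onset", sum(keep)),
                    duration = duration,
                    correctness = rep("unassigned", sum(keep)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign correct/incorrect labels to behavioral episodes
#'
#' An episode is correct when its onset falls inside the 10 s window of its
#' matching CS (port visits match R-CS, freezing onsets match F-CS);
#' anything else — before CS onset, during the mismatched CS, or in the
#' inter-trial interval — is incorrect. Episodes outside the session are
#' dropped.
#'
#' @param episodes data.frame with columns `onset` and `kind`
#'   ("port_visit" or "freezing_onset").
#' @param timeline a [session_timeline()].
#' @return `episodes` with a `correctness` column set.
#' @export
classify_episodes <- function(episodes, timeline) {
  stopifnot(inherits(timeline, "session_timeline"))
  if (nrow(episodes) == 0) {
    episodes$correctness <- character(0)
    return(episodes)
  }
  inside <- episodes$onset >= 0 &
    episodes$onset <= timeline$session_length
  if (any(!inside))
    message(sum(!inside), " episode(s) outside the session dropped")
  episodes <- episodes[inside, , drop = FALSE]
  cs <- timeline$cs_trials
  match_type <- ifelse(episodes$kind == "port_visit", "R", "F")
  correctness <- vapply(seq_len(nrow(episodes)), function(i) {
    hit <- cs$cs_type == match_type[i] &
      episodes$onset[i] >= cs$onset &
      episodes$onset[i] < cs$onset + cs$duration
    if (any(hit)) "correct" else "incorrect"
  }, "")
  episodes$correctness <- correctness
  rownames(episodes) <- NULL
  episodes
}

#' Classify CS trials as correct or incorrect
#'
#' A CS trial is correct when at least one correct episode of the matching
#' kind has its onset inside the trial's 10 s window.
#'
#' @param timeline a [session_timeline()].
#' @param episodes episode data.frame with `correctness` assigned (e.g.
#'   from [classify_episodes()]); defaults to the timeline's own episodes,
#'   classified on the fly.
#' @return the timeline's `cs_trials` with a `correct` logical column.
#' @export
classify_cs_trials <- function(timeline, episodes = NULL) {
  stopifnot(inherits(timeline, "session_timeline"))
  if (is.null(episodes))
    episodes <- classify_episodes(timeline$behavior_episodes, timeline)
  cs <- timeline$cs_trials
  cs$correct <- vapply(seq_len(nrow(cs)), function(i) {
    kind <- if (cs$cs_type[i] == "R") "port_visit" else "freezing_onset"
    any(episodes$kind == kind &
          episodes$correctness == "correct" &
          episodes$onset >= cs$onset[i] &
          episodes$onset < cs$onset[i] + cs$duration[i])
  }, logical(1))
  cs
}
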