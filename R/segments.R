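#' Partition a track into segmental movements
#'
#' Frame-to-frame displacement intervals are labelled anterograde, retrograde
#' or pause (unsigned speed below `pause_speed_threshold`), maximal runs of a
#' common label become candidate segments, and runs shorter than
#' `min_segment_frames` intervals are merged into their longer neighbour.
#' Each segment's mean unsigned speed is its net displacement magnitude over
#' its duration.
#'
#' @param track Tibble `(frame, position_um)` for one vesicle (a single track
#'   from [detect_and_link()] or [tracks_from_truth()]); frames must be
#'   strictly increasing.
#' @param pause_speed_threshold Unsigned speed below which an interval is a
#'   pause, um/s.
#' @param min_segment_frames Minimum run length, in displacement intervals.
#' @param frame_interval Seconds per frame.
#'
#' @return Tibble `(direction, start_frame, end_frame, duration_s,
#'   signed_displacement_um, mean_speed_um_s)`; zero rows with a warning when
#'   the track is shorter than `min_segment_frames + 1` frames.
#' @export
segment_track <- function(track,
                          pause_speed_threshold = 0.1,
                          min_segment_frames = 3L,
                          frame_interval = 0.2) {
  track <- dplyr::arrange(tibble::as_tibble(track), .data$frame)
  if (any(diff(track$frame) <= 0)) stopf("track frames must be strictly increasing")
  n <- nrow(track)
  empty <- tibble::tibble(direction = character(), start_frame = integer(),
                          end_frame = integer(), duration_s = numeric(),
                          signed_displacement_um = numeric(),
                          mean_speed_um_s = numeric())
  if (n < min_segment_frames + 1L) {
    warnf("track too short (%d frames) to segment; excluded", n)
    return(empty)
  }
  dtv <- diff(track$frame) * frame_interval
  disp <- diff(track$position_um)
  v <- disp / dtv
  lab <- ifelse(abs(v) < pause_speed_threshold, "pause",
                ifelse(v > 0, "anterograde", "retrograde"))

  runs <- rle(lab)
  # Merge short runs into the longest neighbour until all runs are long
  # enough (or only one run remains).
  repeat {
    if (length(runs$lengths) <= 1L) break
    short <- which(runs$lengths < min_segment_frames)
    if (length(short) == 0L) break
    i <- short[which.min(runs$lengths[short])]
    nb <- c(if (i > 1L) i - 1L, if (i < length(runs$lengths)) i + 1L)
    j <- nb[which.max(runs$lengths[nb])]
    runs$values[i] <- runs$values[j]
    # collapse equal neighbours
    runs <- rle(inverse.rle(runs))
  }

  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  purrr::map_dfr(seq_along(runs$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    p0 <- track$position_um[i0]; p1 <- track$position_um[i1 + 1L]
    dur <- (track$frame[i1 + 1L] - track$frame[i0]) * frame_interval
    tibble::tibble(direction = runs$values[k],
                   start_frame = track$frame[i0],
                   end_frame = track$frame[i1 + 1L],
                   duration_s = dur,
                   signed_displacement_um = p1 - p0,
                   mean_speed_um_s = abs(p1 - p0) / dur)
  })
}

#' Classify a vesicle as anterograde, retrograde or static
#'
#' A vesicle is static when its maximal excursion from the starting position
#' stays below `static_displacement_threshold` for the whole recording
#' (vesicles without any movement during the recording). Otherwise it takes
#' the class of the dominant direction: the one with the larger cumulative
#' unsigned displacement over the track's segments. Exact ties go to the
#' direction that occurs later in the track.
#'
#' @param track Tibble `(frame, position_um)`.
#' @param segments Output of [segment_track()] for the same track; computed
#'   on the fly when omitted.
#' @param static_displacement_threshold Micrometers.
#' @inheritParams segment_track
#' @return One of `"anterograde"`, `"retrograde"`, `"static"`.
#' @export
classify_vesicle <- function(track, segments = NULL,
                             static_displacement_threshold = 0.4,
                             pause_speed_threshold = 0.1,
                             min_segment_frames = 3L,
                             frame_interval = 0.2) {
  track <- dplyr::arrange(tibble::as_tibble(track), .data$frame)
  if (max(abs(track$position_um - track$position_um[1L])) <
      static_displacement_threshold) return("static")
  if (is.null(segments))
    segments <- segment_track(track, pause_speed_threshold,
                              min_segment_frames, frame_interval)
  da <- sum(segments$signed_displacement_um[
    segments$direction == "anterograde"])
  dr <- -sum(segments$signed_displacement_um[
    segments$direction == "retrograde"])
  if (abs(da - dr) < 1e-12) {
    moving <- segments[segments$direction != "pause", ]
    if (nrow(moving) == 0L) return("static")
    return(moving$direction[nrow(moving)])  # tie: later-occurring direction
  }
  if (da > dr) "anterograde" else "retrograde"
}

#' Summarize transport metrics for one axon window
#'
#' Computes the per-axon transport metrics over all tracks of one recording
#' window: mean segmental anterograde/retrograde speed (over all segments of
#' all tracks), counts of anterograde/retrograde/static vesicles, net
#' directional flux `(n_antero - n_retro)` normalized to a 100 um window and
#' 1 min, linear flow (summed signed net displacement per vesicle per
#' minute), and directionality `(D_antero - D_retro) / (D_antero + D_retro)`
#' computed on cumulative segmental displacements (`NA` when nothing moves).
#'
#' @param tracks Tibble `(track, frame, position_um)` covering one axon
#'   window, e.g. from [detect_and_link()] or [tracks_from_truth()].
#' @param window_length_um Analysis window length, micrometers (100 um as
#'   measured on neurites).
#' @param duration_s Recording duration, seconds.
#' @inheritParams classify_vesicle
#' @return One-row tibble of class `axq_transport_summary`.
#' @export
summarize_axon <- function(tracks,
                           window_length_um = 100,
                           duration_s = 60,
                           static_displacement_threshold = 0.4,
                           pause_speed_threshold = 0.1,
                           min_segment_frames = 3L,
                           frame_interval = 0.2) {
  tracks <- tibble::as_tibble(tracks)
  per_track <- tracks |>
    dplyr::group_by(.data$track) |>
    dplyr::group_map(function(tr, key) {
      seg <- segment_track(tr, pause_speed_threshold, min_segment_frames,
                           frame_interval)
      cls <- classify_vesicle(tr, seg, static_displacement_threshold,
                              pause_speed_threshold, min_segment_frames,
                              frame_interval)
      list(track = key$track, segments = seg, class = cls,
           net = tr$position_um[nrow(tr)] - tr$position_um[1L])
    })

  classes <- vapply(per_track, `[[`, character(1), "class")
  nets <- vapply(per_track, `[[`, numeric(1), "net")
  segs <- dplyr::bind_rows(purrr::map(per_track, "segments"))

  ant <- segs[segs$direction == "anterograde", ]
  ret <- segs[segs$direction == "retrograde", ]
  d_ant <- sum(ant$signed_displacement_um)
  d_ret <- -sum(ret$signed_displacement_um)
  n_a <- sum(classes == "anterograde")
  n_r <- sum(classes == "retrograde")

  out <- tibble::tibble(
    n_tracks = length(per_track),
    n_anterograde = n_a, n_retrograde = n_r,
    n_static = sum(classes == "static"),
    mean_speed_antero_um_s = if (nrow(ant)) mean(ant$mean_speed_um_s) else NA_real_,
    mean_speed_retro_um_s = if (nrow(ret)) mean(ret$mean_speed_um_s) else NA_real_,
    net_flux_per_100um_min = (n_a - n_r) * (100 / window_length_um) *
      (60 / duration_s),
    linear_flow_um_per_min = if (length(per_track))
      sum(nets) / length(per_track) * (60 / duration_s) else NA_real_,
    directionality = if (d_ant + d_ret > 0)
      (d_ant - d_ret) / (d_ant + d_ret) else NA_real_)
  class(out) <- c("axq_transport_summary", class(out))
  out
}
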