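#' Match detected tracks to simulator ground truth
#'
#' For each truth vesicle, the candidate track sharing the most frames with
#' mean absolute position error below `max_dist` is selected; the matched
#' track is then classified with [classify_vesicle()] so recovered classes
#' can be compared against truth classes. Used by the parameter-recovery
#' checks of the tracking pipeline.
#'
#' @param tracks Tibble `(track, frame, position_um)` from
#'   [detect_and_link()].
#' @param truth Truth list from [simulate_axonal_movie()].
#' @param max_dist Maximum mean position error for a valid match, um.
#' @param min_overlap Minimum number of shared frames.
#' @param min_truth_frames Truth vesicles visible for fewer frames are not
#'   scored (too short to track reliably).
#' @inheritParams classify_vesicle
#' @return Tibble `(vesicle, true_class, track, n_overlap, mean_error_um,
#'   recovered_class, correct)`; unmatched vesicles have `NA` track and
#'   `correct = FALSE`.
#' @export
match_tracks_to_truth <- function(tracks, truth,
                                  max_dist = 0.5,
                                  min_overlap = 5L,
                                  min_truth_frames = 20L,
                                  static_displacement_threshold = 0.4,
                                  pause_speed_threshold = 0.1,
                                  min_segment_frames = 3L,
                                  frame_interval = 0.2) {
  tracks <- tibble::as_tibble(tracks)
  track_split <- split(tracks, tracks$track)
  eligible <- dplyr::filter(truth$vesicles,
                            .data$n_frames >= min_truth_frames)
  purrr::map_dfr(seq_len(nrow(eligible)), function(i) {
    vid <- eligible$vesicle[i]
    tf <- dplyr::filter(truth$frames, .data$vesicle == vid)
    cand <- purrr::map_dfr(track_split, function(tr) {
      common <- intersect(tr$frame, tf$frame)
      if (length(common) < min_overlap) return(NULL)
      err <- mean(abs(tr$position_um[match(common, tr$frame)] -
                        tf$position_um[match(common, tf$frame)]))
      tibble::tibble(track = tr$track[1L], n_overlap = length(common),
                     mean_error_um = err)
    })
    cand <- dplyr::filter(cand, .data$mean_error_um <= max_dist)
    if (nrow(cand) == 0L)
      return(tibble::tibble(vesicle = vid,
                            true_class = eligible$class[i],
                            track = NA_integer_, n_overlap = 0L,
                            mean_error_um = NA_real_,
                            recovered_class = NA_character_,
                            correct = FALSE))
    best <- cand[which.max(cand$n_overlap), ]
    cls <- classify_vesicle(
      track_split[[as.character(best$track)]],
      static_displacement_threshold = static_displacement_threshold,
      pause_speed_threshold = pause_speed_threshold,
      min_segment_frames = min_segment_frames,
      frame_interval = frame_interval)
    tibble::tibble(vesicle = vid, true_class = eligible$class[i],
                   track = best$track, n_overlap = best$n_overlap,
                   mean_error_um = best$mean_error_um,
                   recovered_class = cls,
                   correct = identical(cls, eligible$class[i]))
  })
}
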