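# Track interchange: CSV with columns track_id, frame, t, y and optional
# ground-truth columns x, state, w emitted by the simulator. Frames are
# 0-based; floats are serialized with full round-trip precision.

#' Write tracks to CSV
#'
#' @param tracks A tibble with columns `track_id`, `frame`, `t`, `y` and
#'   optionally `x`, `state`, `w`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  req <- c("track_id", "frame", "t", "y")
  if (!all(req %in% names(tracks))) {
    stop_vjump(sprintf("tracks must have columns %s",
                       paste(req, collapse = ", ")),
               "vjump_error_tracks")
  }
  keep <- intersect(c("track_id", "frame", "t", "x", "y", "state", "w"),
                    names(tracks))
  out <- tracks[keep]
  # 17 significant digits round-trips doubles exactly (with strtod parsing)
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  utils::write.csv(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' Validates that each track has unique, monotone 0-based frames.
#'
#' @param path Path to a CSV written by [write_tracks()] (or any file with
#'   at least `track_id`, `frame`, `t`, `y`).
#' @return A tibble of tracks.
#' @export
read_tracks <- function(path) {
  tracks <- tibble::as_tibble(utils::read.csv(path))
  req <- c("track_id", "frame", "t", "y")
  missing_cols <- setdiff(req, names(tracks))
  if (length(missing_cols) > 0) {
    stop_vjump(sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "vjump_error_tracks")
  }
  check <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      dup = anyDuplicated(.data$frame) > 0,
      non_monotone = is.unsorted(.data$frame, strictly = TRUE),
      .groups = "drop"
    )
  if (any(check$dup)) {
    stop_vjump(sprintf("duplicated frame index in track(s): %s",
                       paste(check$track_id[check$dup], collapse = ", ")),
               "vjump_error_tracks")
  }
  if (any(check$non_monotone)) {
    stop_vjump(sprintf("non-monotone frames in track(s): %s",
                       paste(check$track_id[check$non_monotone],
                             collapse = ", ")),
               "vjump_error_tracks")
  }
  tracks
}

#' Noisy increments from a track table
#'
#' @param tracks A tibble of tracks.
#' @return A tibble with `track_id`, `interval` (1-based) and `dy`.
#' @export
track_increments <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe(interval = seq_len(dplyr::n() - 1L), dy = diff(.data$y))
}
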