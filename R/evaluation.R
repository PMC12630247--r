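#' Match clusters to true identities
#'
#' Finds the one-to-one cluster-to-identity mapping that maximizes
#' agreement with ground truth (Hungarian algorithm on the negated
#' contingency table). Useful for scoring synthetic scenarios, where
#' cluster numbering is arbitrary.
#'
#' @param assignments Assignment data frame with `detection_id` and
#'   `cluster` columns.
#' @param truth Data frame with `detection_id` and `identity` columns.
#' @return Named character vector mapping cluster id to identity label,
#'   usable with [apply_mapping()].
#' @export
best_identity_mapping <- function(assignments, truth) {
  idx <- match(assignments$detection_id, truth$detection_id)
  ok <- !is.na(assignments$cluster) & !is.na(idx)
  cl <- assignments$cluster[ok]
  id <- truth$identity[idx[ok]]
  clusters <- sort(unique(assignments$cluster[!is.na(assignments$cluster)]))
  ids <- sort(unique(truth$identity))
  counts <- matrix(0, length(clusters), length(ids),
                   dimnames = list(as.character(clusters), as.character(ids)))
  tab <- table(as.character(cl), as.character(id))
  counts[rownames(tab), colnames(tab)] <- tab
  if (length(clusters) > length(ids)) {
    stop("more clusters than true identities; cannot build an injective mapping")
  }
  sol <- hungarian_min_cost(-counts)
  stats::setNames(as.character(ids[sol$assignment]), as.character(clusters))
}

#' Score re-identification against ground truth
#'
#' Frames with zero detections are excluded from the accuracy
#' denominator. A frame counts as correct only when every detection in
#' it carries the right label; conflicted (`UNKNOWN`) predictions count
#' as incorrect. The confusion matrix is counted per detection
#' (true identity in rows, predicted label in columns). A detection-
#' level accuracy is reported alongside for transparency.
#'
#' @param predicted Data frame `detection_id`, `frame`, `label` (e.g.
#'   the assignments of [run_reid()] after a truth mapping).
#' @param truth Data frame `detection_id`, `identity` with the true
#'   label of every scored detection.
#' @param frames Integer vector of all evaluated frame indices
#'   (including empty ones); defaults to the frames present in
#'   `predicted`.
#' @param video_id Optional identifier copied into the score.
#' @param N Optional true number of unique individuals (for grouped
#'   summaries).
#' @return A `video_score` list: `video_id`, `N`, `cases`,
#'   `cases_excl_empty`, `n_correct`, `n_incorrect`, `accuracy`
#'   (percent, `NA` when no non-empty frame exists),
#'   `detection_accuracy` and `confusion` (matrix).
#' @export
score_video <- function(predicted, truth, frames = unique(predicted$frame),
                        video_id = NA_character_, N = NA_integer_) {
  idx <- match(predicted$detection_id, truth$detection_id)
  if (anyNA(idx)) {
    stop("ground truth missing for detection_id ",
         predicted$detection_id[which(is.na(idx))[1L]])
  }
  true_lab <- as.character(truth$identity[idx])
  pred_lab <- as.character(predicted$label)
  correct <- !is.na(pred_lab) & pred_lab != UNKNOWN_LABEL & pred_lab == true_lab
  frame_of <- predicted$frame
  nonempty <- sort(unique(frame_of))
  frame_ok <- vapply(split(correct, frame_of), all, logical(1))
  cases <- length(unique(frames))
  cases_excl_empty <- length(nonempty)
  n_correct <- sum(frame_ok)
  n_incorrect <- cases_excl_empty - n_correct
  labels <- sort(unique(c(true_lab, pred_lab)))
  confusion <- table(factor(true_lab, labels), factor(pred_lab, labels))
  structure(
    list(video_id = video_id, N = N, cases = cases,
         cases_excl_empty = cases_excl_empty,
         n_correct = n_correct, n_incorrect = n_incorrect,
         accuracy = if (cases_excl_empty > 0) 100 * n_correct / cases_excl_empty else NA_real_,
         detection_accuracy = if (length(correct)) 100 * mean(correct) else NA_real_,
         confusion = unclass(confusion)),
    class = "video_score"
  )
}

#' @export
print.video_score <- function(x, ...) {
  cat(sprintf("<video_score> %d/%d frames correct (%.1f%%), %d empty excluded\n",
              x$n_correct, x$cases_excl_empty,
              if (is.na(x$accuracy)) NaN else x$accuracy,
              x$cases - x$cases_excl_empty))
  invisible(x)
}

#' Uniform frame sampling without replacement
#'
#' @param frames Vector of frame indices.
#' @param n Number of frames to draw (`n <= length(frames)`).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Sorted integer vector of sampled frames.
#' @export
sample_frames <- function(frames, n, seed = 1L) {
  if (n > length(frames)) {
    stop("cannot sample ", n, " frames from ", length(frames))
  }
  withr::with_seed(seed, sort(sample(frames, n)))
}

#' Summarize video scores per number of individuals
#'
#' Groups per-video scores by the true number of unique individuals `N`,
#' summing the frame counts and taking the median accuracy across the
#' videos of each group (midpoint of the two central values for even
#' counts). An overall row across all videos is appended.
#'
#' @param scores List of `video_score` objects, or a data frame with
#'   columns `video_id`, `N`, `cases`, `cases_excl_empty`, `n_correct`,
#'   `n_incorrect`, `accuracy`.
#' @return Data frame, one row per `N` plus an `"all"` row: `group`,
#'   `n_videos`, `cases`, `cases_excl_empty`, `n_correct`,
#'   `n_incorrect`, `median_accuracy`.
#' @export
summarize_by_N <- function(scores) {
  if (!is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(s) {
      data.frame(video_id = s$video_id, N = s$N, cases = s$cases,
                 cases_excl_empty = s$cases_excl_empty,
                 n_correct = s$n_correct, n_incorrect = s$n_incorrect,
                 accuracy = s$accuracy)
    }))
  }
  one_row <- function(df, group) {
    data.frame(group = group, n_videos = nrow(df),
               cases = sum(df$cases),
               cases_excl_empty = sum(df$cases_excl_empty),
               n_correct = sum(df$n_correct),
               n_incorrect = sum(df$n_incorrect),
               median_accuracy = stats::median(df$accuracy, na.rm = TRUE))
  }
  groups <- sort(unique(scores$N))
  out <- do.call(rbind, lapply(groups, function(g) {
    one_row(scores[scores$N == g, , drop = FALSE], as.character(g))
  }))
  out <- rbind(out, one_row(scores, "all"))
  rownames(out) <- NULL
  out
}

#' Audit a track file for identity over-detection
#'
#' Counts the distinct track ids an external tracker produced and
#' compares against the true number of individuals. Trackers without a
#' hard identity limit tend to mint new ids after sustained occlusions,
#' so the signed difference is typically positive (over-detection).
#'
#' @param tracks Track data frame (see [read_tracks_mot()]), or a path
#'   to a MOT CSV file.
#' @param ground_truth_N True number of unique individuals.
#' @return A `track_audit` list: `ground_truth_N`,
#'   `detected_unique_ids`, `difference` (signed).
#' @export
audit_tracks <- function(tracks, ground_truth_N) {
  if (is.character(tracks)) tracks <- read_tracks_mot(tracks)
  detected <- length(unique(tracks$track_id))
  structure(
    list(ground_truth_N = as.integer(ground_truth_N),
         detected_unique_ids = detected,
         difference = detected - as.integer(ground_truth_N)),
    class = "track_audit"
  )
}

#' @export
print.track_audit <- function(x, ...) {
  cat(sprintf("<track_audit> detected %d unique ids, truth %d (difference %+d)\n",
              x$detected_unique_ids, x$ground_truth_N, x$difference))
  invisible(x)
}
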