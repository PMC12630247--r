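#' Per-identity centroid trajectories
#'
#' Builds one centroid time series per semantic label from labelled
#' assignments and the session's boxes: `cx = x_min + width/2`,
#' `cy = y_min + height/2` (pixels). Conflicted (`UNKNOWN`) detections
#' are excluded; absent frames leave gaps, never interpolation.
#'
#' @param assignments Labelled assignment data frame (from
#'   [run_reid()]).
#' @param session The `reid_session` providing the boxes.
#' @return Data frame `label`, `frame`, `cx`, `cy`, ordered by label
#'   then frame.
#' @export
centroid_tracks <- function(assignments, session) {
  det <- session$detections
  keep <- !is.na(assignments$label) & assignments$label != UNKNOWN_LABEL
  a <- assignments[keep, , drop = FALSE]
  idx <- match(a$detection_id, det$detection_id)
  out <- data.frame(
    label = a$label,
    frame = a$frame,
    cx = det$x_min[idx] + det$width[idx] / 2,
    cy = det$y_min[idx] + det$height[idx] / 2
  )
  out <- out[order(out$label, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pose event intervals from per-frame labels
#'
#' Collapses an ordered per-frame label sequence into maximal
#' constant-label intervals (event-plot segments). `UNSCORED` frames
#' and gaps in the frame sequence break runs. Runs shorter than
#' `min_duration` are merged into the neighbouring longer run (the
#' preceding run wins ties), then adjacent equal-label runs are fused;
#' this repeats until every remaining run is long enough or only one
#' remains per contiguous stretch.
#'
#' @param labels Character vector of per-frame labels (may contain
#'   `"UNSCORED"`).
#' @param frames Integer frame indices, strictly increasing; defaults to
#'   `0 .. length(labels) - 1`.
#' @param min_duration Minimum run length in frames (default 1 = no
#'   smoothing).
#' @return Data frame `label`, `start_frame`, `end_frame` (inclusive),
#'   `duration`.
#' @export
pose_event_intervals <- function(labels, frames = seq_along(labels) - 1L,
                                 min_duration = 1L) {
  stopifnot(length(labels) == length(frames))
  if (!length(labels)) {
    return(data.frame(label = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration = integer(0)))
  }
  ord <- order(frames)
  labels <- labels[ord]; frames <- frames[ord]
  scored <- labels != UNSCORED_LABEL
  # contiguous stretches: consecutive frames, all scored
  breaks <- c(TRUE, diff(frames) != 1L)
  stretch <- cumsum(breaks | c(TRUE, !scored[-length(scored)]) | !scored)
  out <- list()
  for (st in split(seq_along(labels), stretch)) {
    st <- st[scored[st]]
    if (!length(st)) next
    r <- rle(labels[st])
    lens <- r$lengths; labs <- r$values
    while (length(lens) > 1L && any(lens < min_duration)) {
      shortest <- which(lens < min_duration)
      i <- shortest[which.min(lens[shortest])]
      left <- if (i > 1L) lens[i - 1L] else -1L
      right <- if (i < length(lens)) lens[i + 1L] else -1L
      into <- if (left >= right) i - 1L else i + 1L
      labs[i] <- labs[into]
      # fuse adjacent equal labels
      r2 <- rle(rep(labs, lens))
      lens <- r2$lengths; labs <- r2$values
    }
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    out[[length(out) + 1L]] <- data.frame(
      label = labs,
      start_frame = frames[st[starts]],
      end_frame = frames[st[ends]],
      duration = lens
    )
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(label = character(0), start_frame = integer(0),
               end_frame = integer(0), duration = integer(0))
  }
  rownames(res) <- NULL
  res
}

#' Total joint variance over one session
#'
#' The movement-variability index: the sample variance (denominator
#' n - 1) of the joint's X coordinate plus that of its Y coordinate,
#' over the qualifying frames of one identity in one session. Frames are
#' excluded (and counted) when the joint is missing, or when an optional
#' frame filter is `FALSE` — typically the filter keeps only frames the
#' pose classifier labelled "sitting", so postural changes do not
#' confound the measure.
#'
#' @param skeletons List of [skeleton()] matrices, one per frame.
#' @param joint Keypoint name (default `"Neck"`) or 1-based row index.
#' @param frame_filter Optional logical vector, `TRUE` for qualifying
#'   frames (e.g. `predict_pose(...) == "sitting"`).
#' @return List with `variance_total` (pixel^2), `n_frames_used`,
#'   `n_excluded_missing`, `joint`.
#' @export
session_joint_variance <- function(skeletons, joint = "Neck",
                                   frame_filter = NULL) {
  j <- if (is.character(joint)) match(joint, body25_keypoints()) else as.integer(joint)
  if (is.na(j) || j < 1L || j > 25L) stop("unknown joint: ", joint)
  if (is.null(frame_filter)) frame_filter <- rep(TRUE, length(skeletons))
  stopifnot(length(frame_filter) == length(skeletons))
  present <- vapply(skeletons, function(s) s[j, "confidence"] > 0, logical(1))
  use <- frame_filter & present
  n_excl <- sum(frame_filter & !present)
  if (sum(use) < 2L) {
    stop("need at least 2 qualifying frames with the joint present, got ",
         sum(use))
  }
  xs <- vapply(skeletons[use], function(s) s[j, "x"], numeric(1))
  ys <- vapply(skeletons[use], function(s) s[j, "y"], numeric(1))
  list(variance_total = stats::var(xs) + stats::var(ys),
       n_frames_used = sum(use),
       n_excluded_missing = n_excl,
       joint = body25_keypoints()[j])
}

#' Cross-session trend in joint variance
#'
#' Ordinary least squares of `variance_total` on the integer session
#' index (recording order), with a two-sided t-test on the slope. This
#' is the across-weeks movement-variability trend: a significantly
#' negative slope indicates decreasing movement while seated.
#'
#' @param records Data frame with columns `session_index` and
#'   `variance_total`, one row per session (>= 3 sessions).
#' @return List with `slope` (pixel^2 per session), `intercept`,
#'   `p_value`, `n_sessions`, `method` (`"ols_t"`) and `degenerate`
#'   (`TRUE` for an exact zero-residual fit, reported with
#'   `p_value = 0`).
#' @export
variance_trend <- function(records) {
  stopifnot(all(c("session_index", "variance_total") %in% names(records)))
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 sessions for a trend, got ", n)
  fit <- stats::lm(variance_total ~ session_index, data = records)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((records$variance_total - mean(records$variance_total))^2)
  degenerate <- rss <= .Machine$double.eps * max(tss, 1)
  if (degenerate) {
    p <- 0
  } else {
    se <- summary(fit)$coefficients["session_index", "Std. Error"]
    tval <- co[["session_index"]] / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2L)
  }
  list(slope = co[["session_index"]], intercept = co[["(Intercept)"]],
       p_value = p, n_sessions = n, method = "ols_t",
       degenerate = degenerate)
}
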