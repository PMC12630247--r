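#' Simulate a sitting or standing skeleton
#'
#' Builds a 25-keypoint stick figure anchored at `anchor` (the MidHip
#' position, pixels) with torso length `scale`. Posture is encoded by
#' the legs: standing skeletons draw a hip-knee-ankle angle in
#' \[165, 180\] degrees with near-vertical thighs, giving a MidHip-to-ankle
#' vertical extent of roughly twice the torso length; sitting skeletons
#' draw a knee angle in \[80, 100\] degrees with horizontal thighs, giving
#' an extent of roughly one torso length. With zero noise the two knee
#' angle ranges never overlap, so a 130-degree threshold separates the
#' classes perfectly.
#'
#' Randomness comes from the current RNG state; seed with `set.seed()`
#' (or [withr::with_seed()]) for reproducibility.
#'
#' @param label `"sitting"` or `"standing"`.
#' @param keypoint_noise_sigma Gaussian pixel noise added independently
#'   to every keypoint coordinate.
#' @param missing_prob Probability that each keypoint is independently
#'   dropped (confidence set to 0).
#' @param scale Torso (Neck-MidHip) length in pixels; must be > 0.
#' @param anchor MidHip position `(x, y)` in full-frame pixels.
#' @param angle_noise_sigma Gaussian noise (degrees) added to the drawn
#'   knee angle.
#' @return A [skeleton()] matrix.
#' @export
simulate_skeleton <- function(label, keypoint_noise_sigma = 0,
                              missing_prob = 0, scale = 100,
                              anchor = c(640, 360),
                              angle_noise_sigma = 0) {
  label <- match.arg(label, c("sitting", "standing"))
  if (missing_prob < 0 || missing_prob > 1) {
    stop("missing_prob must lie in [0, 1]")
  }
  if (scale <= 0) stop("scale must be > 0")
  torso <- scale
  ax <- anchor[1L]; ay <- anchor[2L]

  pts <- matrix(NA_real_, 25L, 2L)
  midhip <- c(ax, ay)
  neck <- c(ax, ay - torso)
  nose <- neck + c(0, -0.3 * torso)
  pts[KP$MidHip, ] <- midhip
  pts[KP$Neck, ] <- neck
  pts[KP$Nose, ] <- nose
  pts[16L, ] <- nose + c(-0.05, -0.05) * torso   # REye
  pts[17L, ] <- nose + c(0.05, -0.05) * torso    # LEye
  pts[18L, ] <- nose + c(-0.12, 0) * torso       # REar
  pts[19L, ] <- nose + c(0.12, 0) * torso        # LEar
  rsho <- neck + c(-0.35, 0.05) * torso
  lsho <- neck + c(0.35, 0.05) * torso
  pts[3L, ] <- rsho
  pts[4L, ] <- rsho + c(-0.05, 0.45) * torso     # RElbow
  pts[5L, ] <- pts[4L, ] + c(0, 0.45) * torso    # RWrist
  pts[6L, ] <- lsho
  pts[7L, ] <- lsho + c(0.05, 0.45) * torso      # LElbow
  pts[8L, ] <- pts[7L, ] + c(0, 0.45) * torso    # LWrist
  pts[KP$RHip, ] <- midhip + c(-0.18, 0) * torso
  pts[KP$LHip, ] <- midhip + c(0.18, 0) * torso

  leg_len <- 0.9 * torso
  # thigh direction: straight down when standing, horizontal when sitting
  thigh_dir <- if (label == "standing") c(0, 1) else c(1, 0)
  rot <- function(v, deg) {
    r <- deg * pi / 180
    c(cos(r) * v[1L] - sin(r) * v[2L], sin(r) * v[1L] + cos(r) * v[2L])
  }
  for (side in c("R", "L")) {
    hip <- pts[KP[[paste0(side, "Hip")]], ]
    knee_angle <- if (label == "standing") runif(1, 165, 180) else runif(1, 80, 100)
    if (angle_noise_sigma > 0) knee_angle <- knee_angle + rnorm(1, 0, angle_noise_sigma)
    knee_angle <- min(max(knee_angle, 10), 180)
    shin_dir <- rot(thigh_dir, 180 - knee_angle)
    knee <- hip + leg_len * thigh_dir
    ankle <- knee + leg_len * shin_dir
    pts[KP[[paste0(side, "Knee")]], ] <- knee
    pts[KP[[paste0(side, "Ankle")]], ] <- ankle
    big <- ankle + c(0.2, 0.05) * torso  # feet point forward (+x)
    if (side == "R") {
      pts[23L, ] <- big; pts[24L, ] <- big + c(-0.05, 0.02) * torso
      pts[25L, ] <- ankle + c(-0.08, 0.05) * torso
    } else {
      pts[20L, ] <- big; pts[21L, ] <- big + c(-0.05, 0.02) * torso
      pts[22L, ] <- ankle + c(-0.08, 0.05) * torso
    }
  }

  if (keypoint_noise_sigma > 0) {
    pts <- pts + matrix(rnorm(50L, 0, keypoint_noise_sigma), 25L, 2L)
  }
  conf <- runif(25L, 0.6, 1)
  if (missing_prob > 0) {
    drop <- runif(25L) < missing_prob
    conf[drop] <- 0
    pts[drop, ] <- 0
  }
  skeleton(pts[, 1L], pts[, 2L], conf)
}

#' Simulate a labelled multi-session pose corpus
#'
#' Generates `n_sessions` sessions of sitting/standing skeletons for
#' leave-one-session-out evaluation. Per-session sitting proportions are
#' drawn around `class_balance` (truncated Gaussian, sd `balance_sd`) so
#' sessions differ mildly in composition while the corpus-level balance
#' stays within sampling noise of the target.
#'
#' @param n_sessions Number of sessions (>= 2).
#' @param frames_per_session Labelled frames per session.
#' @param class_balance Overall sitting probability, in (0, 1).
#' @param balance_sd Between-session standard deviation of the sitting
#'   proportion.
#' @param keypoint_noise_sigma,angle_noise_sigma,missing_prob Noise
#'   parameters forwarded to [simulate_skeleton()].
#' @param scale Torso length in pixels.
#' @param seed Integer seed.
#' @return A `pose_records` object: list with `meta` (data frame
#'   `session_id`, `identity`, `frame`, `label`) and `skeletons` (list of
#'   [skeleton()] matrices, one per row of `meta`).
#' @export
simulate_pose_dataset <- function(n_sessions = 10L, frames_per_session = 500L,
                                  class_balance = 0.5, balance_sd = 0.02,
                                  keypoint_noise_sigma = 2,
                                  angle_noise_sigma = 5,
                                  missing_prob = 0.1,
                                  scale = 100, seed = 1L) {
  if (n_sessions < 2L) stop("n_sessions must be >= 2")
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must lie strictly in (0, 1)")
  }
  withr::with_seed(seed, {
    metas <- list(); skels <- list()
    for (s in seq_len(n_sessions)) {
      session_id <- sprintf("S%02d", s)
      p_sit <- min(max(rnorm(1, class_balance, balance_sd), 0.05), 0.95)
      labels <- ifelse(runif(frames_per_session) < p_sit, "sitting", "standing")
      anchor <- c(runif(1, 200, 1000), runif(1, 250, 550))
      for (f in seq_len(frames_per_session)) {
        skels[[length(skels) + 1L]] <- simulate_skeleton(
          labels[f], keypoint_noise_sigma = keypoint_noise_sigma,
          missing_prob = missing_prob, scale = scale, anchor = anchor,
          angle_noise_sigma = angle_noise_sigma
        )
      }
      metas[[s]] <- data.frame(
        session_id = session_id,
        identity = sprintf("P%02d", s),
        frame = seq_len(frames_per_session) - 1L,
        label = labels
      )
    }
    structure(list(meta = do.call(rbind, metas), skeletons = skels),
              class = "pose_records")
  })
}

#' Attach simulated skeletons to a session scenario
#'
#' Gives every detection of a [simulate_session()] scenario a skeleton
#' anchored inside its bounding box. Each identity switches between
#' sitting and standing through a slow two-state chain (switch
#' probability `switch_prob` per frame), so pose events form sustained
#' intervals as they do in real sessions.
#'
#' @param scenario A `session_scenario`.
#' @param seed Integer seed.
#' @param switch_prob Per-frame probability of changing pose.
#' @param keypoint_noise_sigma,missing_prob Forwarded to
#'   [simulate_skeleton()].
#' @return List with `skeletons` (a `skeleton_set` aligned to the
#'   scenario's detections) and `labels` (data frame `detection_id`,
#'   `label` with the true pose of each detection).
#' @export
simulate_scenario_skeletons <- function(scenario, seed = 1L,
                                        switch_prob = 0.02,
                                        keypoint_noise_sigma = 2,
                                        missing_prob = 0.05) {
  det <- scenario$session$detections
  truth <- scenario$truth
  K <- scenario$config$K
  n <- scenario$config$n_frames
  withr::with_seed(seed, {
    # pose state per identity per frame
    state <- matrix("", n, K)
    state[1L, ] <- ifelse(runif(K) < 0.5, "sitting", "standing")
    if (n > 1L) {
      for (f in 2:n) {
        flip <- runif(K) < switch_prob
        state[f, ] <- ifelse(flip,
                             ifelse(state[f - 1L, ] == "sitting", "standing", "sitting"),
                             state[f - 1L, ])
      }
    }
    ids <- det$detection_id
    kps <- vector("list", nrow(det))
    labels <- character(nrow(det))
    for (i in seq_len(nrow(det))) {
      k <- truth$identity[match(ids[i], truth$detection_id)] + 1L
      lab <- state[det$frame[i] + 1L, k]
      labels[i] <- lab
      anchor <- c(det$x_min[i] + det$width[i] / 2,
                  det$y_min[i] + det$height[i] * 0.55)
      kps[[i]] <- simulate_skeleton(lab,
                                    keypoint_noise_sigma = keypoint_noise_sigma,
                                    missing_prob = missing_prob,
                                    scale = det$height[i] / 3.5,
                                    anchor = anchor)
    }
    names(kps) <- as.character(ids)
    list(
      skeletons = structure(
        list(index = data.frame(frame = det$frame, detection_id = ids),
             keypoints = kps),
        class = "skeleton_set"
      ),
      labels = data.frame(detection_id = ids, label = labels)
    )
  })
}

#' @export
print.pose_records <- function(x, ...) {
  cat(sprintf("<pose_records> %d skeletons, %d sessions (%s)\n",
              nrow(x$meta), length(unique(x$meta$session_id)),
              paste(sprintf("%s: %d", names(table(x$meta$label)),
                            as.integer(table(x$meta$label))), collapse = ", ")))
  invisible(x)
}
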