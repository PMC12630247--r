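#' Configuration for a synthetic multi-person session
#'
#' The generator emulates the recording setting the pipeline targets:
#' `K` people with distinct appearance centroids move around an image,
#' leave and re-enter the field of view, and emit one appearance
#' embedding per frame while visible. Presence follows an independent
#' two-state Markov chain per identity (absent -> present with
#' probability `enter_prob`, present -> absent with probability
#' `exit_prob`), so mean visible spells last `1/exit_prob` frames and
#' mean occlusion gaps `1/enter_prob` frames. Embeddings are the
#' identity's centroid plus isotropic Gaussian noise;
#' `centroid_separation / noise_sigma` is the single difficulty knob.
#'
#' @param K Number of unique identities (1-8).
#' @param n_frames Number of frames in the session.
#' @param embedding_dim Appearance embedding dimension.
#' @param centroid_separation Minimum pairwise distance between identity
#'   centroids, in embedding units.
#' @param noise_sigma Isotropic Gaussian standard deviation of the
#'   embedding noise, in embedding units.
#' @param enter_prob,exit_prob Per-frame presence transition
#'   probabilities, both in (0, 1).
#' @param confusable_pair Optional `list(i, j, reduced_separation)`
#'   (0-based identities) forcing two centroids to lie exactly
#'   `reduced_separation` apart — the "similar clothing" failure mode.
#' @param image_size `(width, height)` of the image, pixels.
#' @param box_size `(width, height)` of each person's bounding box,
#'   pixels.
#' @param motion_sigma Random-walk step standard deviation of box
#'   centres, pixels.
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(K = 2L, n_frames = 1000L, embedding_dim = 512L,
                            centroid_separation = 10, noise_sigma = 1,
                            enter_prob = 0.2, exit_prob = 0.05,
                            confusable_pair = NULL,
                            image_size = c(1280, 720),
                            box_size = c(80, 200),
                            motion_sigma = 5, seed = 1L) {
  if (K < 1L || K > 8L) stop("K must be between 1 and 8")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (enter_prob <= 0 || enter_prob >= 1 || exit_prob <= 0 || exit_prob >= 1) {
    stop("enter_prob and exit_prob must lie strictly in (0, 1)")
  }
  if (!is.null(confusable_pair)) {
    cp <- confusable_pair
    if (length(cp) != 3L) stop("confusable_pair must be list(i, j, reduced_separation)")
    names(cp) <- c("i", "j", "reduced_separation")
    if (cp$i == cp$j || cp$i < 0 || cp$j < 0 || cp$i >= K || cp$j >= K) {
      stop("confusable_pair identities must be distinct and in 0..K-1")
    }
    if (cp$reduced_separation >= centroid_separation) {
      stop("reduced_separation must be smaller than centroid_separation")
    }
    confusable_pair <- cp
  }
  if (K * prod(box_size) > prod(image_size)) {
    stop("K boxes of the requested size cannot fit in the image area")
  }
  structure(
    list(K = as.integer(K), n_frames = as.integer(n_frames),
         embedding_dim = as.integer(embedding_dim),
         centroid_separation = centroid_separation, noise_sigma = noise_sigma,
         enter_prob = enter_prob, exit_prob = exit_prob,
         confusable_pair = confusable_pair,
         image_size = image_size, box_size = box_size,
         motion_sigma = motion_sigma, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# reflect a coordinate vector into [lo, hi]
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Simulate a synthetic session with ground truth
#'
#' Draws identity centroids and rescales them so the minimum pairwise
#' distance equals `centroid_separation` (the confusable pair, when set,
#' is then placed exactly `reduced_separation` apart). Each identity's
#' presence evolves as a two-state Markov chain starting present; while
#' present it emits one detection per frame whose embedding is
#' `centroid + N(0, noise_sigma^2 I)` and whose bounding-box centre
#' follows a reflected Gaussian random walk inside the image.
#'
#' @param config A [scenario_config()].
#' @return A `session_scenario`: list with `config`, `session` (a
#'   [reid_session()]), `truth` (data frame `detection_id`, `identity`,
#'   0-based), `centroids` (K x d matrix) and `presence` (n_frames x K
#'   logical matrix).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, {
    K <- config$K; d <- config$embedding_dim; n <- config$n_frames
    centroids <- matrix(rnorm(K * d), K, d)
    if (K > 1L) {
      dm <- as.matrix(stats::dist(centroids))
      min_d <- min(dm[upper.tri(dm)])
      centroids <- centroids * (config$centroid_separation / min_d)
    }
    cp <- config$confusable_pair
    if (!is.null(cp)) {
      i <- cp$i + 1L; j <- cp$j + 1L
      dir <- centroids[j, ] - centroids[i, ]
      dir <- dir / sqrt(sum(dir^2))
      centroids[j, ] <- centroids[i, ] + cp$reduced_separation * dir
    }

    presence <- matrix(FALSE, n, K)
    presence[1L, ] <- TRUE
    if (n > 1L) {
      for (f in 2:n) {
        u <- runif(K)
        presence[f, ] <- ifelse(presence[f - 1L, ],
                                u >= config$exit_prob,   # stay present
                                u < config$enter_prob)   # re-enter
      }
    }

    # reflected random walks for box centres (advance every frame)
    W <- config$image_size[1L]; H <- config$image_size[2L]
    bw <- config$box_size[1L]; bh <- config$box_size[2L]
    cx <- matrix(0, n, K); cy <- matrix(0, n, K)
    cx[1L, ] <- runif(K, bw / 2, W - bw / 2)
    cy[1L, ] <- runif(K, bh / 2, H - bh / 2)
    if (n > 1L) {
      for (f in 2:n) {
        cx[f, ] <- reflect_into(cx[f - 1L, ] + rnorm(K, 0, config$motion_sigma),
                                bw / 2, W - bw / 2)
        cy[f, ] <- reflect_into(cy[f - 1L, ] + rnorm(K, 0, config$motion_sigma),
                                bh / 2, H - bh / 2)
      }
    }

    # one detection per (frame, present identity), ordered by frame then identity
    present_idx <- which(t(presence))           # row-major: frame-major order
    frame_of <- (present_idx - 1L) %/% K        # 0-based frame
    ident_of <- (present_idx - 1L) %% K         # 0-based identity
    n_det <- length(present_idx)
    flat <- cbind(frame_of + 1L, ident_of + 1L)
    det <- data.frame(
      detection_id = seq_len(n_det) - 1L,
      frame = frame_of,
      x_min = cx[flat] - bw / 2,
      y_min = cy[flat] - bh / 2,
      width = bw, height = bh,
      confidence = runif(n_det, 0.8, 1),
      mask_coverage = NA_real_
    )
    identity <- ident_of
    emb <- centroids[ident_of + 1L, , drop = FALSE]
    if (config$noise_sigma > 0) {
      emb <- emb + matrix(rnorm(n_det * d, 0, config$noise_sigma), n_det, d)
    }
    session <- reid_session(det, emb, n_frames = n, embedding_dim = d)
    structure(
      list(config = config, session = session,
           truth = data.frame(detection_id = det$detection_id,
                              identity = identity),
           centroids = centroids, presence = presence),
      class = "session_scenario"
    )
  })
}

#' @export
print.session_scenario <- function(x, ...) {
  cat(sprintf("<session_scenario> K = %d, %d frames, %d detections\n",
              x$config$K, x$config$n_frames, nrow(x$truth)))
  invisible(x)
}

#' Replay backend for a simulated scenario
#'
#' Wraps a [simulate_session()] result in the perception-backend
#' contract so [run_perception()] reproduces the scenario's stored
#' detections and embeddings exactly. The frame source is
#' `seq_len(n_frames)` (frame objects are just indices).
#'
#' @param scenario A `session_scenario`.
#' @return List with `backend` and `frame_source` for [run_perception()].
#' @export
scenario_backend <- function(scenario) {
  det <- scenario$session$detections
  emb <- scenario$session$embeddings
  by_frame <- split(seq_len(nrow(det)), det$frame)
  backend <- list(
    detect = function(frame) {
      rows <- by_frame[[as.character(frame - 1L)]]
      if (is.null(rows)) return(empty_detections())
      det[rows, c("x_min", "y_min", "width", "height", "confidence")]
    },
    mask = function(patch) patch,
    estimate_pose = function(masked) NULL,
    embed = function(masked) {
      rows <- by_frame[[as.character(masked$frame_index)]]
      hit <- rows[which(det$x_min[rows] == masked$box$x_min &
                          det$y_min[rows] == masked$box$y_min)[1L]]
      emb[hit, ]
    }
  )
  list(backend = backend, frame_source = as.list(seq_len(scenario$config$n_frames)))
}
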