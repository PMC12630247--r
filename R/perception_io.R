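#' Build a detection session
#'
#' A session holds every person detection of one video: one row of
#' `detections` per candidate, an aligned embedding matrix, and the frame
#' range so that empty frames (no detections) stay representable.
#' Frame indices are 0-based; bounding boxes are `(x_min, y_min, width,
#' height)` in pixels with the origin at the image top-left and y
#' increasing downward.
#'
#' @param detections Data frame with columns `detection_id` (unique
#'   integers), `frame` (0-based integer), `x_min`, `y_min`, `width`,
#'   `height`, `confidence` (in `[0, 1]`) and optionally `mask_coverage`
#'   (fraction of patch pixels kept as foreground, in `[0, 1]`, `NA` when
#'   unknown).
#' @param embeddings Numeric matrix, one row per detection row, or `NULL`
#'   when no embeddings exist. Row order follows `detections`.
#' @param n_frames Total number of frames in the session (declares the
#'   frame range `0 .. n_frames - 1`).
#' @param embedding_dim Declared embedding dimension; defaults to
#'   `ncol(embeddings)`.
#' @return A `reid_session` object.
#' @export
reid_session <- function(detections, embeddings = NULL, n_frames = NULL,
                         embedding_dim = NULL) {
  req <- c("detection_id", "frame", "x_min", "y_min", "width", "height",
           "confidence")
  missing_cols <- setdiff(req, names(detections))
  if (length(missing_cols)) {
    stop("detections is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"mask_coverage" %in% names(detections)) detections$mask_coverage <- NA_real_
  if (anyDuplicated(detections$detection_id)) {
    stop("detection_id values must be unique within a session")
  }
  if (nrow(detections)) {
    if (any(detections$frame < 0)) stop("frame indices must be >= 0")
    if (any(detections$width <= 0) || any(detections$height <= 0)) {
      stop("bounding boxes must have positive width and height")
    }
    if (any(detections$confidence < 0 | detections$confidence > 1)) {
      stop("detection confidence must lie in [0, 1]")
    }
    mc <- detections$mask_coverage
    if (any(!is.na(mc) & (mc < 0 | mc > 1))) {
      stop("mask_coverage must lie in [0, 1] when present")
    }
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections)) max(detections$frame) + 1L else 0L
  }
  if (nrow(detections) && any(detections$frame >= n_frames)) {
    stop("detections reference frames beyond the declared n_frames")
  }
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (nrow(embeddings) != nrow(detections)) {
      stop("embeddings must have one row per detection")
    }
    if (is.null(embedding_dim)) embedding_dim <- ncol(embeddings)
    if (ncol(embeddings) != embedding_dim) {
      stop("embedding matrix width does not match the declared embedding_dim")
    }
    bad <- which(!apply(embeddings, 1L, function(v) all(is.finite(v)) || all(is.na(v))))
    if (length(bad)) {
      stop("non-finite embedding for detection_id ",
           detections$detection_id[bad[1L]])
    }
    rownames(embeddings) <- detections$detection_id
  } else if (is.null(embedding_dim)) {
    embedding_dim <- 0L
  }
  # order by (frame, detection_id) so frames are contiguous
  ord <- order(detections$frame, detections$detection_id)
  detections <- detections[ord, , drop = FALSE]
  rownames(detections) <- NULL
  if (!is.null(embeddings)) embeddings <- embeddings[ord, , drop = FALSE]
  structure(
    list(detections = detections, embeddings = embeddings,
         n_frames = as.integer(n_frames),
         embedding_dim = as.integer(embedding_dim)),
    class = "reid_session"
  )
}

#' @export
print.reid_session <- function(x, ...) {
  cat(sprintf("<reid_session> %d detections over %d frames (embedding dim %d)\n",
              nrow(x$detections), x$n_frames, x$embedding_dim))
  invisible(x)
}

#' Split a session into per-frame records
#'
#' @param session A `reid_session`.
#' @return A list of length `n_frames`; element `i` holds the 0-based row
#'   indices (into `session$detections`) of frame `i - 1`. Empty frames
#'   yield `integer(0)`.
#' @export
session_frames <- function(session) {
  out <- vector("list", session$n_frames)
  idx <- split(seq_len(nrow(session$detections)), session$detections$frame)
  for (i in seq_len(session$n_frames)) out[[i]] <- integer(0)
  for (f in names(idx)) out[[as.integer(f) + 1L]] <- idx[[f]]
  out
}

json_line <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

#' Write a session to detections JSON-lines
#'
#' The first line is a header `{"n_frames": ..., "embedding_dim": ...}`;
#' each subsequent line is one detection object with its bounding box,
#' confidence, optional mask coverage and optional inline embedding.
#' Writing is deterministic, so `write -> read -> write` is byte-stable.
#'
#' @param session A `reid_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(session, path) {
  stopifnot(inherits(session, "reid_session"))
  det <- session$detections
  lines <- character(nrow(det) + 1L)
  lines[1L] <- json_line(list(n_frames = session$n_frames,
                              embedding_dim = session$embedding_dim))
  for (i in seq_len(nrow(det))) {
    emb <- if (is.null(session$embeddings)) NULL else {
      v <- session$embeddings[i, ]
      if (all(is.na(v))) NULL else I(as.numeric(v))
    }
    rec <- list(
      frame = det$frame[i],
      detection_id = det$detection_id[i],
      box = I(c(det$x_min[i], det$y_min[i], det$width[i], det$height[i])),
      confidence = det$confidence[i],
      mask_coverage = det$mask_coverage[i],
      embedding = emb
    )
    lines[i + 1L] <- json_line(rec)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a detections JSON-lines file
#'
#' @param path Path to a file produced by [write_detections()] (or any
#'   tool emitting the same schema).
#' @return A `reid_session`. Frames are ordered by frame index; all
#'   embeddings are checked for a uniform dimension.
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(reid_session(empty_detections(), NULL, n_frames = 0L, embedding_dim = 0L))
  }
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) {
               stop(sprintf("malformed JSON at line %d of %s: %s",
                            i, path, conditionMessage(e)), call. = FALSE)
             })
  }
  header <- parse_line(1L)
  n_frames <- as.integer(header$n_frames)
  d <- as.integer(header$embedding_dim)
  n <- length(lines) - 1L
  det <- empty_detections(n)
  emb <- if (d > 0L) matrix(NA_real_, n, d) else NULL
  for (i in seq_len(n)) {
    rec <- parse_line(i + 1L)
    det$detection_id[i] <- as.integer(rec$detection_id)
    det$frame[i] <- as.integer(rec$frame)
    det$x_min[i] <- rec$box[1L]; det$y_min[i] <- rec$box[2L]
    det$width[i] <- rec$box[3L]; det$height[i] <- rec$box[4L]
    det$confidence[i] <- rec$confidence
    det$mask_coverage[i] <- if (is.null(rec$mask_coverage)) NA_real_ else rec$mask_coverage
    if (!is.null(rec$embedding)) {
      if (length(rec$embedding) != d) {
        stop(sprintf("embedding dimension %d for detection_id %s does not match the declared %d",
                     length(rec$embedding), rec$detection_id, d), call. = FALSE)
      }
      emb[i, ] <- rec$embedding
    }
  }
  reid_session(det, emb, n_frames = n_frames, embedding_dim = d)
}

empty_detections <- function(n = 0L) {
  data.frame(
    detection_id = integer(n), frame = integer(n),
    x_min = numeric(n), y_min = numeric(n),
    width = numeric(n), height = numeric(n),
    confidence = numeric(n), mask_coverage = rep(NA_real_, n)
  )
}

#' Read skeletons from flattened-triplet JSON
#'
#' Reads the OpenPose-dialect layout
#' `{"frames": [{"frame": f, "people": [{"detection_id": id,
#' "pose_keypoints_2d": [75 floats]}]}]}` where each person is a
#' flattened sequence of 25 `(x, y, confidence)` triplets. When
#' `patch_offsets` is supplied, keypoints are translated from patch-local
#' to full-frame coordinates by adding the patch origin; keypoints with
#' confidence 0 are missing and left untranslated.
#'
#' @param path Path to the skeletons JSON file.
#' @param patch_offsets Optional data frame with columns `detection_id`,
#'   `x_min`, `y_min` giving each detection's patch origin.
#' @return A `skeleton_set`: list with `index` (data frame of `frame`,
#'   `detection_id`) and `keypoints` (list of [skeleton()] matrices named
#'   by detection id).
#' @export
read_skeletons <- function(path, patch_offsets = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  frames <- doc$frames
  idx_frame <- integer(0); idx_id <- integer(0)
  kps <- list()
  for (fr in frames) {
    for (person in fr$people) {
      flat <- as.numeric(unlist(person$pose_keypoints_2d))
      if (length(flat) != 75L) {
        stop(sprintf("keypoint array of length %d (expected 75) for detection_id %s",
                     length(flat), person$detection_id), call. = FALSE)
      }
      m <- matrix(flat, ncol = 3L, byrow = TRUE)
      id <- as.integer(person$detection_id)
      if (!is.null(patch_offsets)) {
        row <- match(id, patch_offsets$detection_id)
        if (is.na(row)) {
          stop(sprintf("detection_id %d has no patch offset", id), call. = FALSE)
        }
        present <- m[, 3L] > 0
        m[present, 1L] <- m[present, 1L] + patch_offsets$x_min[row]
        m[present, 2L] <- m[present, 2L] + patch_offsets$y_min[row]
      }
      idx_frame <- c(idx_frame, as.integer(fr$frame))
      idx_id <- c(idx_id, id)
      kps[[as.character(id)]] <- skeleton(m[, 1L], m[, 2L], m[, 3L])
    }
  }
  structure(
    list(index = data.frame(frame = idx_frame, detection_id = idx_id),
         keypoints = kps),
    class = "skeleton_set"
  )
}

#' Write a skeleton set to flattened-triplet JSON
#'
#' Inverse of [read_skeletons()] (without offsets); deterministic output
#' so round trips are byte-stable.
#'
#' @param skeleton_set A `skeleton_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skeletons <- function(skeleton_set, path) {
  idx <- skeleton_set$index
  frames <- sort(unique(idx$frame))
  frame_objs <- lapply(frames, function(f) {
    ids <- idx$detection_id[idx$frame == f]
    people <- lapply(ids, function(id) {
      m <- skeleton_set$keypoints[[as.character(id)]]
      list(detection_id = id,
           pose_keypoints_2d = I(as.numeric(t(unclass(m)))))
    })
    list(frame = f, people = people)
  })
  writeLines(json_line(list(frames = frame_objs)), path)
  invisible(path)
}

#' Read a track file in the MOTChallenge CSV layout
#'
#' Ten comma-separated columns per row: `frame, id, bb_left, bb_top,
#' bb_width, bb_height, conf, x, y, z`. Frame numbers are 1-based on
#' disk and converted to the package's 0-based convention.
#'
#' @param path Path to the CSV file (no header).
#' @return Data frame with columns `frame` (0-based), `track_id`,
#'   `x_min`, `y_min`, `width`, `height`, `confidence`.
#' @export
read_tracks_mot <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- data.frame(frame = integer(n), track_id = integer(n),
                    x_min = numeric(n), y_min = numeric(n),
                    width = numeric(n), height = numeric(n),
                    confidence = numeric(n))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(fields) != 10L) {
      stop(sprintf("row %d of %s has %d fields (expected 10)", i, path,
                   length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric field in row %d of %s", i, path), call. = FALSE)
    }
    out$frame[i] <- as.integer(vals[1L]) - 1L   # MOT is 1-based on disk
    out$track_id[i] <- as.integer(vals[2L])
    out$x_min[i] <- vals[3L]; out$y_min[i] <- vals[4L]
    out$width[i] <- vals[5L]; out$height[i] <- vals[6L]
    out$confidence[i] <- vals[7L]
  }
  out
}

#' Write tracks in the MOTChallenge CSV layout
#'
#' @param tracks Data frame as returned by [read_tracks_mot()].
#' @param path Output path. Frames are written 1-based; the unused world
#'   coordinates are written as `-1`.
#' @return `path`, invisibly.
#' @export
write_tracks_mot <- function(tracks, path) {
  lines <- vapply(seq_len(nrow(tracks)), function(i) {
    paste(c(tracks$frame[i] + 1L, tracks$track_id[i],
            format(c(tracks$x_min[i], tracks$y_min[i], tracks$width[i],
                     tracks$height[i], tracks$confidence[i]),
                   trim = TRUE, digits = 15),
            "-1", "-1", "-1"), collapse = ",")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read pose ground-truth labels
#'
#' @param path CSV with columns `session_id, frame, identity, pose_label`
#'   where `pose_label` is `sitting` or `standing`.
#' @return Data frame with those columns.
#' @export
read_pose_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("session_id", "frame", "identity", "pose_label")
  if (!all(req %in% names(df))) {
    stop("labels file must have columns ", paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(df$pose_label), c("sitting", "standing"))
  if (length(bad)) stop("unknown pose labels: ", paste(bad, collapse = ", "))
  df[req]
}

#' Run a perception backend over a frame source
#'
#' Drives the pluggable perception contract in the pipeline's stage
#' order: detect people per frame, mask each patch's background,
#' estimate a patch-local skeleton on the masked patch, then embed the
#' masked patch. Skeletons are translated to full-frame coordinates by
#' the patch origin. Deterministic backends yield deterministic output.
#'
#' A backend is a list of functions:
#' \describe{
#'   \item{`detect(frame)`}{data frame of boxes `x_min, y_min, width,
#'     height, confidence` (possibly 0 rows).}
#'   \item{`mask(patch)`}{returns the masked patch (opaque) plus an
#'     optional `mask_coverage` attribute in `[0, 1]`.}
#'   \item{`estimate_pose(masked_patch)`}{patch-local 25 x 3 keypoint
#'     matrix, or `NULL` for no skeleton.}
#'   \item{`embed(masked_patch)`}{numeric embedding vector of fixed
#'     dimension.}
#' }
#' A `patch` is a list with `frame_index`, `box` and `frame` (the raw
#' frame object as supplied by `frame_source`).
#'
#' @param backend Backend list as described above.
#' @param frame_source List of frame objects, one per frame, passed
#'   through to the backend untouched.
#' @param embedding_dim Optional declared embedding dimension; inferred
#'   from the first embedding when `NULL`.
#' @return List with `session` (a `reid_session`) and `skeletons` (a
#'   `skeleton_set`, full-frame coordinates).
#' @export
run_perception <- function(backend, frame_source, embedding_dim = NULL) {
  stopifnot(is.list(backend), is.function(backend$detect),
            is.function(backend$embed))
  det <- empty_detections()
  emb_rows <- list()
  sk_frame <- integer(0); sk_id <- integer(0); sk_list <- list()
  next_id <- 0L
  for (fi in seq_along(frame_source)) {
    frame_index <- fi - 1L
    boxes <- tryCatch(backend$detect(frame_source[[fi]]),
                      error = function(e) {
                        stop(sprintf("backend error at frame %d: %s", frame_index,
                                     conditionMessage(e)), call. = FALSE)
                      })
    if (is.null(boxes) || !nrow(boxes)) next
    for (b in seq_len(nrow(boxes))) {
      patch <- list(frame_index = frame_index,
                    box = boxes[b, , drop = FALSE],
                    frame = frame_source[[fi]])
      masked <- if (is.function(backend$mask)) {
        tryCatch(backend$mask(patch), error = function(e) {
          stop(sprintf("backend error at frame %d: %s", frame_index,
                       conditionMessage(e)), call. = FALSE)
        })
      } else patch
      coverage <- attr(masked, "mask_coverage")
      if (is.null(coverage)) coverage <- NA_real_
      pose <- if (is.function(backend$estimate_pose)) backend$estimate_pose(masked) else NULL
      vec <- tryCatch(backend$embed(masked), error = function(e) {
        stop(sprintf("backend error at frame %d: %s", frame_index,
                     conditionMessage(e)), call. = FALSE)
      })
      if (is.null(embedding_dim)) embedding_dim <- length(vec)
      if (length(vec) != embedding_dim) {
        stop(sprintf("backend embedding of dimension %d (expected %d) at frame %d",
                     length(vec), embedding_dim, frame_index), call. = FALSE)
      }
      det <- rbind(det, data.frame(
        detection_id = next_id, frame = frame_index,
        x_min = boxes$x_min[b], y_min = boxes$y_min[b],
        width = boxes$width[b], height = boxes$height[b],
        confidence = boxes$confidence[b], mask_coverage = coverage
      ))
      emb_rows[[length(emb_rows) + 1L]] <- as.numeric(vec)
      if (!is.null(pose)) {
        m <- as.matrix(pose)
        present <- m[, 3L] > 0
        m[present, 1L] <- m[present, 1L] + boxes$x_min[b]
        m[present, 2L] <- m[present, 2L] + boxes$y_min[b]
        sk_frame <- c(sk_frame, frame_index)
        sk_id <- c(sk_id, next_id)
        sk_list[[as.character(next_id)]] <- skeleton(m[, 1L], m[, 2L], m[, 3L])
      }
      next_id <- next_id + 1L
    }
  }
  emb <- if (length(emb_rows)) do.call(rbind, emb_rows) else NULL
  session <- reid_session(det, emb, n_frames = length(frame_source),
                          embedding_dim = if (is.null(embedding_dim)) 0L else embedding_dim)
  skels <- structure(
    list(index = data.frame(frame = sk_frame, detection_id = sk_id),
         keypoints = sk_list),
    class = "skeleton_set"
  )
  list(session = session, skeletons = skels)
}
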