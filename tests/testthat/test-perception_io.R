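test_that("empty and hand-built detection files parse to the expected frames", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), p)
  s <- read_detections(p)
  expect_equal(s$n_frames, 0L)
  expect_equal(nrow(s$detections), 0L)

  # 2 detections in frame 0, 1 in frame 3, declared range of 5 frames:
  # two non-empty frame records plus representable empty frames
  det <- data.frame(detection_id = 0:2, frame = c(0L, 0L, 3L),
                    x_min = c(1, 2, 3), y_min = c(4, 5, 6),
                    width = 10, height = 20, confidence = 0.5,
                    mask_coverage = NA_real_)
  s2 <- reid_session(det, matrix(1:6 / 7, 3, 2), n_frames = 5L)
  write_detections(s2, p)
  s3 <- read_detections(p)
  frames <- session_frames(s3)
  expect_length(frames, 5L)
  expect_equal(lengths(frames), c(2L, 0L, 0L, 1L, 0L))
})

test_that("detections round-trip exactly and byte-stably", {
  s <- tiny_session(n = 50L)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_detections(s, p1)
  r <- read_detections(p1)
  expect_equal(r$detections, s$detections)
  expect_equal(unname(r$embeddings), unname(s$embeddings))
  expect_equal(r$n_frames, s$n_frames)
  write_detections(r, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("detection reader reports offending line / detection on bad input", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"n_frames": 2, "embedding_dim": 3}',
               '{"frame": 0, "detection_id": 0, "box": [0,0,1,1], "confidence": 0.5, "mask_coverage": null, "embedding": [1,2]}'),
             p)
  expect_error(read_detections(p), "detection_id 0")
  writeLines(c('{"n_frames": 2, "embedding_dim": 3}', "{not json"), p)
  expect_error(read_detections(p), "line 2")
})

test_that("session constructor enforces the box and id invariants", {
  det <- empty_det <- data.frame(detection_id = 0L, frame = 0L, x_min = 0,
                                 y_min = 0, width = 5, height = 5,
                                 confidence = 0.5, mask_coverage = NA_real_)
  det$width <- -1
  expect_error(reid_session(det), "positive width")
  det <- empty_det; det$confidence <- 1.5
  expect_error(reid_session(det), "confidence")
  det <- rbind(empty_det, empty_det)
  expect_error(reid_session(det), "unique")
})

test_that("skeleton JSON honours patch offsets and the missing-keypoint rule", {
  flat <- rep(c(10, 20, 0.9), 25)
  flat[4:6] <- c(0, 0, 0)  # second keypoint missing
  doc <- list(frames = list(list(frame = 0L, people = list(
    list(detection_id = 0L, pose_keypoints_2d = flat),
    list(detection_id = 1L, pose_keypoints_2d = rep(c(5, 6, 0.5), 25))
  ))))
  p <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), p)

  offs <- data.frame(detection_id = 0:1, x_min = c(100, 7), y_min = c(50, 8))
  sk <- read_skeletons(p, patch_offsets = offs)
  expect_length(sk$keypoints, 2L)
  s0 <- sk$keypoints[["0"]]
  expect_equal(unname(s0[1L, ]), c(110, 70, 0.9))       # translated
  expect_equal(unname(s0[2L, ]), c(0, 0, 0))            # missing: untranslated
  expect_equal(unname(sk$keypoints[["1"]][1L, 1:2]), c(12, 14))

  # wrong triplet count and unknown offset reference are errors
  bad <- doc; bad$frames[[1L]]$people[[1L]]$pose_keypoints_2d <- flat[1:74]
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE, digits = NA), p)
  expect_error(read_skeletons(p), "74")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), p)
  expect_error(read_skeletons(p, patch_offsets = offs[1L, ]), "no patch offset")
})

test_that("skeleton files round-trip byte-stably", {
  sc <- simulate_session(scenario_config(K = 2, n_frames = 20, embedding_dim = 4,
                                         seed = 3))
  sk <- simulate_scenario_skeletons(sc, seed = 4)$skeletons
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_skeletons(sk, p1)
  rt <- read_skeletons(p1)
  expect_equal(rt$index, sk$index)
  expect_equal(rt$keypoints[["0"]], sk$keypoints[["0"]])
  write_skeletons(rt, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("MOT track files parse with the 1-to-0 frame shift and round-trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), p)
  expect_equal(nrow(read_tracks_mot(p)), 0L)

  writeLines("1,7,10,20,30,40,1,-1,-1,-1", p)
  r <- read_tracks_mot(p)
  expect_equal(r$frame, 0L)
  expect_equal(r$track_id, 7L)
  expect_equal(unlist(r[1, c("x_min", "y_min", "width", "height")],
                      use.names = FALSE), c(10, 20, 30, 40))

  writeLines(c("1,1,0,0,5,5,1,-1,-1,-1", "2,2,0,0,5,5,1,-1,-1,-1",
               "3,1,0,0,5,5,1,-1,-1,-1", "3,3,0,0,5,5,1,-1,-1,-1"), p)
  r <- read_tracks_mot(p)
  expect_equal(nrow(r), 4L)
  expect_equal(length(unique(r$track_id)), 3L)

  p2 <- withr::local_tempfile(fileext = ".csv")
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_tracks_mot(r, p2)
  write_tracks_mot(read_tracks_mot(p2), p3)
  expect_identical(readLines(p2), readLines(p3))

  writeLines("1,a,0,0,5,5,1,-1,-1,-1", p)
  expect_error(read_tracks_mot(p), "row 1")
})

test_that("run_perception replays a scenario exactly and wraps backend errors", {
  sc <- simulate_session(scenario_config(K = 2, n_frames = 30, embedding_dim = 8,
                                         seed = 5))
  bk <- scenario_backend(sc)
  out <- run_perception(bk$backend, bk$frame_source)
  expect_equal(out$session$detections, sc$session$detections)
  expect_equal(unname(out$session$embeddings), unname(sc$session$embeddings))

  # a backend that never detects: every frame empty, no embeddings
  silent <- list(detect = function(frame) NULL, embed = function(p) numeric(3))
  out2 <- run_perception(silent, as.list(1:4))
  expect_equal(nrow(out2$session$detections), 0L)
  expect_equal(out2$session$n_frames, 4L)

  # 3-frame source with 2, 0, 1 detections -> 3 embeddings
  boxes <- list(
    data.frame(x_min = c(0, 50), y_min = 0, width = 10, height = 20, confidence = 1),
    NULL,
    data.frame(x_min = 5, y_min = 5, width = 10, height = 20, confidence = 1)
  )
  counting <- list(detect = function(frame) boxes[[frame]],
                   embed = function(p) c(p$box$x_min, p$frame_index))
  out3 <- run_perception(counting, as.list(1:3))
  expect_equal(nrow(out3$session$embeddings), 3L)

  # wrong embedding dimension and raising backends carry frame context
  bad_dim <- list(detect = function(frame) boxes[[1L]],
                  embed = function(p) numeric(if (p$box$x_min == 0) 2 else 3))
  expect_error(run_perception(bad_dim, as.list(1L)), "dimension 3 \\(expected 2\\)")
  thrower <- list(detect = function(frame) stop("boom"),
                  embed = function(p) 1)
  expect_error(run_perception(thrower, as.list(1:2)), "frame 0: boom")
})

test_that("pose label files validate their label vocabulary", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session_id,frame,identity,pose_label",
               "S01,0,P01,sitting", "S01,1,P01,standing"), p)
  df <- read_pose_labels(p)
  expect_equal(df$pose_label, c("sitting", "standing"))
  writeLines(c("session_id,frame,identity,pose_label", "S01,0,P01,crouching"), p)
  expect_error(read_pose_labels(p), "crouching")
})
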