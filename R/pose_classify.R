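POSE_SCHEMA_VERSION <- "1"

angle_deg <- function(v1, v2) {
  # interior angle between two vectors, in [0, 180]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

joint_angle <- function(skel, a, b, c) {
  # angle at keypoint b between segments b->a and b->c; NA if any is missing
  if (is_missing_kp(skel, a) || is_missing_kp(skel, b) || is_missing_kp(skel, c)) {
    return(NA_real_)
  }
  angle_deg(skel[a, 1:2] - skel[b, 1:2], skel[c, 1:2] - skel[b, 1:2])
}

pose_feature_names <- function() {
  kp <- body25_keypoints()
  c(paste0(rep(kp, each = 2L), c("_x", "_y")),
    "ang_knee_r", "ang_knee_l", "ang_hip_r", "ang_hip_l", "ang_trunk",
    paste0("miss_", kp))
}

#' Extract a pose feature vector from a skeleton
#'
#' Features are translation- and scale-invariant: all keypoints are
#' centered on the MidHip and divided by the torso length (the
#' Neck-MidHip distance), then five joint angles are appended (right and
#' left knee, right and left hip, trunk inclination from vertical, all
#' in degrees in `[0, 180]`), followed by 25 missingness indicator bits.
#' Missing keypoints contribute zero coordinates and an indicator of 1;
#' angles whose constituent keypoints are missing are `NA` (the tree
#' ensemble handles missing values natively).
#'
#' @param skel A [skeleton()] matrix; `Neck` and `MidHip` must be
#'   present (they anchor the normalization) and distinct.
#' @return Named numeric vector of length 80.
#' @export
extract_features <- function(skel) {
  if (is_missing_kp(skel, KP$Neck) || is_missing_kp(skel, KP$MidHip)) {
    stop("cannot extract features: Neck or MidHip keypoint missing",
         call. = FALSE)
  }
  torso <- sqrt(sum((skel[KP$Neck, 1:2] - skel[KP$MidHip, 1:2])^2))
  if (torso <= 0) stop("torso length must be > 0", call. = FALSE)
  missing <- skel[, "confidence"] == 0
  rel <- sweep(skel[, 1:2, drop = FALSE], 2L, skel[KP$MidHip, 1:2]) / torso
  rel[missing, ] <- 0
  angles <- c(
    joint_angle(skel, KP$RHip, KP$RKnee, KP$RAnkle),
    joint_angle(skel, KP$LHip, KP$LKnee, KP$LAnkle),
    joint_angle(skel, KP$Neck, KP$RHip, KP$RKnee),
    joint_angle(skel, KP$Neck, KP$LHip, KP$LKnee),
    angle_deg(skel[KP$Neck, 1:2] - skel[KP$MidHip, 1:2], c(0, -1))
  )
  stats::setNames(c(as.numeric(t(rel)), angles, as.numeric(missing)),
                  pose_feature_names())
}

# features for a list of skeletons; rows of NA where anchors are missing
features_matrix <- function(skeletons) {
  out <- matrix(NA_real_, length(skeletons), 80L,
                dimnames = list(NULL, pose_feature_names()))
  ok <- logical(length(skeletons))
  for (i in seq_along(skeletons)) {
    f <- tryCatch(extract_features(skeletons[[i]]), error = function(e) NULL)
    if (!is.null(f)) { out[i, ] <- f; ok[i] <- TRUE }
  }
  list(features = out, scored = ok)
}

POSE_CLASSES <- c("sitting", "standing")

#' Train the sitting/standing classifier
#'
#' Fits a gradient-boosted decision-tree ensemble on pose features with
#' default hyperparameters (no tuning): 100 boosting rounds, depth 6,
#' learning rate 0.3, logistic objective. Skeletons whose anchors are
#' missing are skipped; the count of skipped frames is recorded on the
#' model.
#'
#' @param pose_records A `pose_records` object (see
#'   [simulate_pose_dataset()]), or a list with `meta` (with a `label`
#'   column) and `skeletons`.
#' @param seed Integer seed for the booster.
#' @param nrounds Boosting rounds (default 100).
#' @return A `pose_model`.
#' @export
train_classifier <- function(pose_records, seed = 1L, nrounds = 100L) {
  fm <- features_matrix(pose_records$skeletons)
  labels <- pose_records$meta$label[fm$scored]
  feats <- fm$features[fm$scored, , drop = FALSE]
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both pose classes")
  }
  if (any(table(factor(labels, POSE_CLASSES)) < 2L)) {
    stop("need at least 2 records per class")
  }
  y <- as.numeric(labels == "standing")
  dtrain <- xgboost::xgb.DMatrix(feats, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 6, eta = 0.3,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(
    list(booster = booster, classes = POSE_CLASSES,
         schema_version = POSE_SCHEMA_VERSION,
         feature_names = pose_feature_names(),
         n_skipped = sum(!fm$scored)),
    class = "pose_model"
  )
}

#' Predict sitting/standing for a batch of skeletons
#'
#' @param model A `pose_model` from [train_classifier()].
#' @param skeletons List of [skeleton()] matrices.
#' @return Character vector, one label per skeleton, in order. Skeletons
#'   whose Neck or MidHip anchor is missing get the reserved token
#'   `"UNSCORED"`.
#' @export
predict_pose <- function(model, skeletons) {
  stopifnot(inherits(model, "pose_model"))
  if (!identical(model$schema_version, POSE_SCHEMA_VERSION)) {
    stop("pose model was built with feature schema version ",
         model$schema_version, "; this package uses ", POSE_SCHEMA_VERSION)
  }
  if (inherits(skeletons, "skeleton")) skeletons <- list(skeletons)
  fm <- features_matrix(skeletons)
  out <- rep(UNSCORED_LABEL, length(skeletons))
  if (any(fm$scored)) {
    prob <- predict(model$booster,
                    xgboost::xgb.DMatrix(fm$features[fm$scored, , drop = FALSE],
                                         nthread = 1))
    out[fm$scored] <- ifelse(prob >= 0.5, "standing", "sitting")
  }
  out
}

#' Save / load a pose model
#'
#' The booster is stored in the JSON model format next to a metadata
#' file carrying the class order, feature schema version and feature
#' names.
#'
#' @param model A `pose_model`.
#' @param dir Directory to write `pose_model.json` and
#'   `pose_model_meta.json` into (or, for loading, the directory or the
#'   `pose_model.json` path itself).
#' @return The directory (saving) or the `pose_model` (loading).
#' @export
save_pose_model <- function(model, dir) {
  stopifnot(inherits(model, "pose_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "pose_model.json"))
  jsonlite::write_json(
    list(classes = model$classes, schema_version = model$schema_version,
         feature_names = model$feature_names, n_skipped = model$n_skipped),
    file.path(dir, "pose_model_meta.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname save_pose_model
#' @export
load_pose_model <- function(dir) {
  if (endsWith(dir, ".json")) dir <- dirname(dir)
  meta <- jsonlite::fromJSON(file.path(dir, "pose_model_meta.json"))
  booster <- xgboost::xgb.load(file.path(dir, "pose_model.json"))
  structure(
    list(booster = booster, classes = meta$classes,
         schema_version = as.character(meta$schema_version),
         feature_names = meta$feature_names, n_skipped = meta$n_skipped),
    class = "pose_model"
  )
}

per_class_metrics <- function(truth, pred) {
  sapply(POSE_CLASSES, function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    c(precision = precision, recall = recall, f1 = f1)
  })
}

#' Leave-one-session-out evaluation of the pose classifier
#'
#' Group-k-fold with one fold per session: the classifier is trained on
#' every labelled frame except those of one held-out session, tested on
#' that session, and the process repeats until every session has been
#' held out once. Per-class precision, recall and F1 are reported per
#' fold; the summary weights each fold by its number of scored test
#' frames, and the mean and standard deviation across folds are reported
#' alongside.
#'
#' @param pose_records A `pose_records` object.
#' @param seed Seed forwarded to [train_classifier()].
#' @param nrounds Boosting rounds per fold.
#' @return List with `folds` (data frame: `session_id`, per-class
#'   precision/recall/F1, `n_frames`) and `summary` (per class: frame-
#'   weighted precision/recall/F1 plus across-fold mean and sd).
#' @export
group_kfold_evaluate <- function(pose_records, seed = 1L, nrounds = 100L) {
  meta <- pose_records$meta
  sessions <- unique(meta$session_id)
  if (length(sessions) < 2L) stop("need at least 2 distinct sessions")
  fold_rows <- list()
  for (s in sessions) {
    test_idx <- which(meta$session_id == s)
    train_idx <- which(meta$session_id != s)
    model <- train_classifier(
      list(meta = meta[train_idx, , drop = FALSE],
           skeletons = pose_records$skeletons[train_idx]),
      seed = seed, nrounds = nrounds
    )
    pred <- predict_pose(model, pose_records$skeletons[test_idx])
    scored <- pred != UNSCORED_LABEL
    truth <- meta$label[test_idx][scored]
    m <- per_class_metrics(truth, pred[scored])
    fold_rows[[s]] <- data.frame(
      session_id = s,
      precision_sitting = m["precision", "sitting"],
      recall_sitting = m["recall", "sitting"],
      f1_sitting = m["f1", "sitting"],
      precision_standing = m["precision", "standing"],
      recall_standing = m["recall", "standing"],
      f1_standing = m["f1", "standing"],
      n_frames = sum(scored)
    )
  }
  folds <- do.call(rbind, fold_rows)
  rownames(folds) <- NULL
  metric_cols <- setdiff(names(folds), c("session_id", "n_frames"))
  summary <- lapply(stats::setNames(metric_cols, metric_cols), function(col) {
    ok <- !is.na(folds[[col]])
    list(weighted = stats::weighted.mean(folds[[col]][ok], folds$n_frames[ok]),
         mean = mean(folds[[col]], na.rm = TRUE),
         sd = stats::sd(folds[[col]], na.rm = TRUE))
  })
  list(folds = folds, summary = summary)
}
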