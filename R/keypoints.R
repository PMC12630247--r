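#' The 25-point body keypoint layout
#'
#' Skeletons use the standard 25-keypoint body convention in this fixed
#' order (0-based indices 0-24): the nose and neck first, then the right
#' and left arms, the mid-hip anchor, the legs, the face points and the
#' feet. Index 0 is `Nose`, index 1 is `Neck` and index 8 is `MidHip`;
#' these two last points anchor all pose features.
#'
#' @return Character vector of the 25 keypoint names, in layout order.
#' @export
#' @examples
#' body25_keypoints()[c(1, 2, 9)] # Nose, Neck, MidHip
body25_keypoints <- function() {
  c(
    "Nose", "Neck",
    "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist",
    "MidHip",
    "RHip", "RKnee", "RAnkle",
    "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel",
    "RBigToe", "RSmallToe", "RHeel"
  )
}

# 1-based row indices of the anchor / limb keypoints inside a skeleton matrix
KP <- list(
  Nose = 1L, Neck = 2L, MidHip = 9L,
  RHip = 10L, RKnee = 11L, RAnkle = 12L,
  LHip = 13L, LKnee = 14L, LAnkle = 15L
)

#' Construct a skeleton matrix
#'
#' A skeleton is a 25 x 3 numeric matrix with columns `x`, `y`,
#' `confidence` and one row per keypoint of [body25_keypoints()].
#' Coordinates are full-frame pixels (origin top-left, y increasing
#' downward). A missing keypoint has `confidence == 0`; its coordinates
#' carry no information and are ignored by every consumer.
#'
#' @param x,y,confidence Numeric vectors of length 25.
#' @return A `skeleton` matrix.
#' @export
skeleton <- function(x, y, confidence) {
  stopifnot(length(x) == 25L, length(y) == 25L, length(confidence) == 25L)
  if (any(!is.finite(confidence)) || any(confidence < 0) || any(confidence > 1)) {
    stop("skeleton confidences must be finite and in [0, 1]")
  }
  m <- cbind(x = as.numeric(x), y = as.numeric(y),
             confidence = as.numeric(confidence))
  rownames(m) <- body25_keypoints()
  class(m) <- c("skeleton", class(m))
  m
}

is_missing_kp <- function(skel, idx) skel[idx, "confidence"] == 0
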