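# Independent oracles and small fixture builders used across tests.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exhaustive minimum-cost injective row->column assignment
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf; best_assign <- NULL
  cols <- utils::combn(m, n, simplify = FALSE)
  for (cset in cols) {
    for (p in all_perms(n)) {
      a <- cset[p]
      total <- sum(cost[cbind(seq_len(n), a)])
      if (total < best) { best <- total; best_assign <- a }
    }
  }
  list(assignment = best_assign, cost = best)
}

# exhaustive minimum-SSE 2-partition of the rows of x
min_sse_bipartition <- function(x) {
  n <- nrow(x)
  sse <- function(rows) {
    if (!length(rows)) return(0)
    centered <- sweep(x[rows, , drop = FALSE], 2L, colMeans(x[rows, , drop = FALSE]))
    sum(centered^2)
  }
  best <- Inf; best_side <- NULL
  for (mask in 1:(2^(n - 1L) - 1L)) {   # fix point n in group 2 to kill symmetry
    side <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))))
    if (!any(side) || all(side)) next
    total <- sse(which(side)) + sse(which(!side))
    if (total < best) { best <- total; best_side <- side }
  }
  list(side = best_side, sse = best)
}

# small deterministic session fixture built by hand
tiny_session <- function(n = 50L, d = 4L, n_frames = 25L, seed = 99L) {
  withr::with_seed(seed, {
    det <- data.frame(
      detection_id = seq_len(n) - 1L,
      frame = sort(sample.int(n_frames, n, replace = TRUE)) - 1L,
      x_min = runif(n, 0, 500), y_min = runif(n, 0, 300),
      width = runif(n, 20, 80), height = runif(n, 50, 200),
      confidence = runif(n),
      mask_coverage = ifelse(runif(n) < 0.3, NA_real_, runif(n))
    )
    reid_session(det, matrix(rnorm(n * d), n, d), n_frames = n_frames)
  })
}

# a skeleton with every keypoint present, deterministic
fixed_skeleton <- function(scale = 100, anchor = c(300, 200), label = "standing") {
  withr::with_seed(7L, simulate_skeleton(label, scale = scale, anchor = anchor))
}

knee_angle_of <- function(skel, side = "R") {
  hip <- skel[paste0(side, "Hip"), 1:2]
  knee <- skel[paste0(side, "Knee"), 1:2]
  ankle <- skel[paste0(side, "Ankle"), 1:2]
  v1 <- hip - knee; v2 <- ankle - knee
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}
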