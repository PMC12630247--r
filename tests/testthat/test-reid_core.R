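test_that("k-means closed forms: K = 1 mean, duplicated points, cardinality", {
  withr::with_seed(1, x <- matrix(rnorm(40), 10, 4))
  m <- fit_kmeans(x, K = 1, seed = 2)
  expect_equal(unname(m$centroids[1, ]), unname(colMeans(x)))
  expect_equal(m$inertia, sum(sweep(x, 2, colMeans(x))^2))

  p <- c(1, 2); q <- c(5, 9)
  dup <- rbind(p, p, q, q)
  m2 <- fit_kmeans(dup, K = 2, seed = 3)
  expect_equal(m2$inertia, 0)
  cents <- m2$centroids[order(m2$centroids[, 1]), ]
  expect_equal(unname(cents), rbind(p, q), ignore_attr = TRUE)

  expect_error(fit_kmeans(dup, K = 5, seed = 1), "at least K")
})

test_that("k-means with restarts attains the exhaustive minimum-SSE bipartition", {
  # two tight groups far apart: the optimum is the generating partition
  withr::with_seed(11, {
    x <- rbind(matrix(rnorm(16, 0, 0.1), 4, 4),
               matrix(rnorm(16, 30, 0.1), 4, 4))
  })
  oracle <- min_sse_bipartition(x)
  m <- fit_kmeans(x, K = 2, seed = 5)
  expect_equal(m$inertia, oracle$sse, tolerance = 1e-10)
  expect_true(all(m$cluster[1:4] == m$cluster[1]) &&
                all(m$cluster[5:8] == m$cluster[5]) &&
                m$cluster[1] != m$cluster[5])

  # harder unstructured instances: 10 restarts reach the global optimum
  # on a clear majority (exhaustive search over all 2^9 bipartitions)
  hits <- 0L
  for (s in 1:20) {
    withr::with_seed(100 + s, y <- matrix(rnorm(20), 10, 2))
    o <- min_sse_bipartition(y)
    f <- fit_kmeans(y, K = 2, seed = s)
    if (abs(f$inertia - o$sse) <= 1e-9 * max(1, o$sse)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("k-means++ seeding follows D-squared sampling", {
  # all points distinct, K = n: every point chosen exactly once
  withr::with_seed(2, x <- matrix(rnorm(12), 6, 2))
  init <- withr::with_seed(3, kmeanspp_init(x, 6))
  expect_equal(nrow(unique(init)), 6L)
  expect_true(all(apply(init, 1, function(r) any(colSums(abs(t(x) - r)) == 0))))

  # two far groups: the second centroid lands in the opposite group
  far <- rbind(matrix(0, 5, 2), matrix(100, 5, 2))
  far <- far + matrix(seq_len(20) * 1e-3, 10, 2)  # break exact ties
  opposite <- withr::with_seed(4, {
    sum(replicate(1000, {
      init <- kmeanspp_init(far, 2)
      (init[1, 1] < 50) != (init[2, 1] < 50)
    }))
  })
  expect_gte(opposite, 990)

  # K = 1 is a uniform draw over the points
  four <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  counts <- withr::with_seed(6, {
    picks <- replicate(10000, {
      init <- kmeanspp_init(four, 1)
      which(apply(four, 1, function(r) all(r == init[1, ])))
    })
    tabulate(picks, 4)
  })
  expect_true(all(abs(counts / 10000 - 0.25) <= 0.02))

  expect_error(kmeanspp_init(four, 5), "cannot seed")
})

test_that("Hungarian assignment matches structure and the brute-force oracle", {
  ident <- 1 - diag(4)
  sol <- hungarian_min_cost(ident)
  expect_equal(sol$assignment, 1:4)
  expect_equal(sol$cost, 0)

  expect_equal(hungarian_min_cost(matrix(3.5, 1, 1))$cost, 3.5)
  expect_error(hungarian_min_cost(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(hungarian_min_cost(matrix(1, 3, 2)), "nrow <= ncol")

  # rectangular instances against exhaustive search
  withr::with_seed(9, {
    for (i in 1:30) {
      cost <- matrix(runif(12), 3, 4)
      h <- hungarian_min_cost(cost)
      b <- brute_force_assignment(cost)
      expect_equal(h$cost, b$cost, tolerance = 1e-12)
    }
  })
})

test_that("frame assignment enforces per-frame uniqueness in both modes", {
  model <- structure(list(K = 3L, centroids = diag(3) * 10,
                          inertia = 0, n_iter = 1L, seed = 1L),
                     class = "cluster_model")
  # a single detection goes to its nearest centroid
  a <- assign_frame(c(10, 0.1, 0), model, "flag")
  expect_equal(a$cluster, 0L)
  expect_equal(a$status, "assigned")
  expect_equal(a$distance, sqrt(0.1^2))

  # two detections nearest the same centroid: both marked mistaken
  two <- rbind(c(10, 1, 0), c(9, 0, 1))
  f <- assign_frame(two, model, "flag")
  expect_equal(f$status, c("conflicted", "conflicted"))
  expect_true(all(is.na(f$cluster)))

  # optimal mode resolves the collision one-to-one, minimal total cost
  # over all injective maps of the 2 detections into the 3 clusters
  o <- assign_frame(two, model, "optimal")
  expect_equal(o$status, c("assigned", "assigned"))
  expect_equal(anyDuplicated(o$cluster), 0L)
  cost23 <- t(vapply(1:2, function(i) {
    vapply(1:3, function(k) sum((two[i, ] - model$centroids[k, ])^2), numeric(1))
  }, numeric(3)))
  expect_equal(sum(o$distance^2), brute_force_assignment(cost23)$cost,
               tolerance = 1e-12)

  # 3 x 3: optimal equals brute force over all 3! permutations
  withr::with_seed(13, emb <- matrix(rnorm(9), 3, 3))
  o3 <- assign_frame(emb, model, "optimal")
  d2 <- outer(rowSums(emb^2), rowSums(model$centroids^2), "+") -
    2 * emb %*% t(model$centroids)
  best <- min(vapply(all_perms(3), function(p) sum(d2[cbind(1:3, p)]),
                     numeric(1)))
  expect_equal(sum(o3$distance^2), best, tolerance = 1e-10)

  # more detections than clusters: the surplus worst-cost ones conflict
  four <- rbind(diag(3) * 10, c(20, 20, 20))
  o4 <- assign_frame(four, model, "optimal")
  expect_equal(sum(o4$status == "conflicted"), 1L)
  expect_equal(o4$status[4], "conflicted")
  expect_equal(anyDuplicated(stats::na.omit(o4$cluster)), 0L)
})

test_that("label mapping is validated and conflicts map to UNKNOWN", {
  a <- data.frame(cluster = c(0L, 1L, NA), status = c("assigned", "assigned", "conflicted"))
  lab <- apply_mapping(a, c("0" = "Therapist", "1" = "Patient"), K = 2)
  expect_equal(lab$label, c("Therapist", "Patient", "UNKNOWN"))
  ident <- apply_mapping(a, c("0" = "0", "1" = "1"), K = 2)
  expect_equal(ident$label, c("0", "1", "UNKNOWN"))
  expect_error(apply_mapping(a, c("0" = "X"), K = 2), "cover exactly")
  expect_error(apply_mapping(a, c("0" = "X", "1" = "X"), K = 2), "injective")
})

test_that("whole-session re-identification is perfect on separable scenarios", {
  for (mode in c("flag", "optimal")) {
    sc <- simulate_session(scenario_config(K = 3, n_frames = 150,
                                           embedding_dim = 16,
                                           noise_sigma = 0, seed = 7))
    res <- run_reid(sc, K = 3, mode = mode, seed = 1)
    expect_equal(sum(res$assignments$status == "conflicted"), 0L)
    mapping <- best_identity_mapping(res$assignments, sc$truth)
    lab <- apply_mapping(res$assignments, mapping, K = 3)
    idx <- match(lab$detection_id, sc$truth$detection_id)
    expect_true(all(lab$label == as.character(sc$truth$identity[idx])))
  }

  # K = 1: everything is the same person, conflicts impossible
  sc1 <- simulate_session(scenario_config(K = 1, n_frames = 60,
                                          embedding_dim = 8, seed = 9))
  r1 <- run_reid(sc1, K = 1, seed = 1)
  expect_equal(unique(r1$assignments$label), "0")
  expect_equal(sum(r1$assignments$status == "conflicted"), 0L)
})

test_that("per-frame uniqueness and mode ordering hold on noisy scenarios", {
  sc <- simulate_session(scenario_config(K = 4, n_frames = 250, embedding_dim = 8,
                                         centroid_separation = 3, noise_sigma = 1,
                                         seed = 23))
  res_f <- run_reid(sc, K = 4, mode = "flag", seed = 2)
  res_o <- run_reid(sc, K = 4, mode = "optimal", seed = 2)
  for (res in list(res_f, res_o)) {
    assigned <- res$assignments[!is.na(res$assignments$cluster), ]
    expect_equal(anyDuplicated(paste(assigned$frame, assigned$cluster)), 0L)
  }
  # flag mode never assigns more detections in a frame than optimal mode
  n_assigned <- function(res) table(factor(res$assignments$frame[res$assignments$status == "assigned"],
                                           levels = 0:249))
  expect_true(all(n_assigned(res_f) <= n_assigned(res_o)))
  # and run_reid agrees with the per-frame operation it is built from
  emb <- l2_normalize(sc$session$embeddings)
  rows <- which(sc$session$detections$frame == sc$session$detections$frame[1])
  a <- assign_frame(emb[rows, , drop = FALSE], res_f$model, "flag")
  expect_equal(res_f$assignments$cluster[rows], a$cluster)
  expect_equal(res_f$assignments$status[rows], a$status)
})

test_that("fitted centroids recover the generating centroids on separable data", {
  sc <- simulate_session(scenario_config(K = 4, n_frames = 500, embedding_dim = 32,
                                         centroid_separation = 10, noise_sigma = 1,
                                         seed = 15))
  m <- fit_kmeans(sc$session$embeddings, K = 4, seed = 3)
  # each fitted centroid estimates a distinct true centroid to within
  # 3 standard errors of the mean: ||err|| <= 3 sigma sqrt(d / n_k)
  d2 <- outer(rowSums(m$centroids^2), rowSums(sc$centroids^2), "+") -
    2 * m$centroids %*% t(sc$centroids)
  d <- sqrt(pmax(d2, 0))
  match_ <- hungarian_min_cost(d)
  n_k <- tabulate(m$cluster + 1L, 4)
  expect_true(all(d[cbind(1:4, match_$assignment)] <= 3 * sqrt(32 / n_k)))
})

test_that("accuracy degrades as the separation-to-noise ratio shrinks", {
  seps <- c(8, 4, 2, 1, 0.5)
  mean_acc <- vapply(seps, function(sep) {
    accs <- vapply(1:6, function(s) {
      sc <- simulate_session(scenario_config(K = 3, n_frames = 120,
                                             embedding_dim = 16,
                                             centroid_separation = sep,
                                             noise_sigma = 1, seed = 40 + s))
      res <- run_reid(sc, K = 3, seed = s)
      mapping <- best_identity_mapping(res$assignments, sc$truth)
      lab <- apply_mapping(res$assignments, mapping, K = 3)
      score_video(lab, sc$truth)$accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) <= 1e-9))
})
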