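#' L2-normalize the rows of an embedding matrix
#'
#' Appearance-embedding similarity is conventionally cosine-like, so the
#' re-identification pipeline normalizes embeddings to unit length by
#' default (zero rows are left untouched).
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with unit-norm rows.
#' @export
l2_normalize <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

# squared Euclidean distances between rows of x (n x d) and rows of c (k x d)
sq_dist <- function(x, centers) {
  xn <- rowSums(x^2)
  cn <- rowSums(centers^2)
  d2 <- outer(xn, cn, "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

#' k-means++ seeding
#'
#' Picks `K` initial centroids from `points`: the first uniformly at
#' random, each subsequent one with probability proportional to its
#' squared distance to the nearest centroid chosen so far (D-squared
#' sampling). Uses the current RNG state.
#'
#' @param points Numeric matrix of candidate points (rows).
#' @param K Number of centroids.
#' @return `K x d` matrix of initial centroids.
#' @export
kmeanspp_init <- function(points, K) {
  n <- nrow(points)
  if (K > n) stop("cannot seed ", K, " centroids from ", n, " points")
  chosen <- integer(K)
  chosen[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- sq_dist(points, points[chosen[1L], , drop = FALSE])[, 1L]
    for (k in 2:K) {
      if (sum(d2) > 0) {
        chosen[k] <- sample.int(n, 1L, prob = d2)
      } else {
        # all remaining mass zero (duplicated points): fall back to uniform
        remaining <- setdiff(seq_len(n), chosen[seq_len(k - 1L)])
        chosen[k] <- if (length(remaining)) sample(remaining, 1L) else sample.int(n, 1L)
      }
      d2 <- pmin(d2, sq_dist(points, points[chosen[k], , drop = FALSE])[, 1L])
    }
  }
  points[chosen, , drop = FALSE]
}

#' Fit fixed-K k-means to session embeddings
#'
#' Lloyd iterations from k-means++ seeding, restarted `n_restarts` times
#' with the best run (lowest inertia) kept. Convergence follows the
#' relative-tolerance rule of the reference k-means implementations: the
#' run stops when the summed squared centroid shift falls below
#' `tol` times the mean per-feature variance of the data, or after
#' `max_iter` iterations. A cluster left empty after an assignment step
#' is re-seeded at the point farthest from its assigned centroid.
#'
#' @param x Numeric matrix of embeddings (one row per detection).
#' @param K Number of clusters — the known number of unique individuals.
#' @param seed Integer seed making the fit deterministic; `NULL` uses
#'   the current RNG state.
#' @param tol Relative convergence tolerance (default `1e-4`).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return A `cluster_model`: list with `K`, `centroids` (K x d),
#'   `inertia` (summed squared distances to assigned centroids),
#'   `n_iter`, `cluster` (0-based assignment per row of `x`) and `seed`.
#' @export
fit_kmeans <- function(x, K, seed = NULL, tol = 1e-4, max_iter = 300L,
                       n_restarts = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < K) stop("need at least K = ", K, " points, got ", n)
  if (!all(is.finite(x))) stop("embeddings must be finite")
  run <- function() {
    tol_abs <- tol * mean(apply(x, 2L, stats::var))
    if (!is.finite(tol_abs)) tol_abs <- 0
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_init(x, K)
      n_iter <- 0L
      assign <- NULL
      for (it in seq_len(max_iter)) {
        n_iter <- it
        d2 <- sq_dist(x, centers)
        assign <- max.col(-d2, ties.method = "first")
        # empty-cluster repair: re-seed at the farthest point
        d_assigned <- d2[cbind(seq_len(n), assign)]
        for (k in seq_len(K)) {
          if (!any(assign == k)) {
            far <- which.max(d_assigned)
            centers[k, ] <- x[far, ]
            assign[far] <- k
            d_assigned[far] <- 0
          }
        }
        new_centers <- centers
        for (k in seq_len(K)) {
          new_centers[k, ] <- colMeans(x[assign == k, , drop = FALSE])
        }
        shift <- sum((new_centers - centers)^2)
        centers <- new_centers
        if (shift <= tol_abs) break
      }
      d2 <- sq_dist(x, centers)
      assign <- max.col(-d2, ties.method = "first")
      inertia <- sum(d2[cbind(seq_len(n), assign)])
      if (is.null(best) || inertia < best$inertia) {
        best <- list(centroids = centers, inertia = inertia,
                     n_iter = n_iter, cluster = assign - 1L)
      }
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(list(K = as.integer(K)), best, list(seed = seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, inertia = %.4g, %d iterations\n",
              x$K, x$inertia, x$n_iter))
  invisible(x)
}

#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by shortest
#' augmenting paths with potentials (the Jonker-Volgenant formulation):
#' each row is matched to a distinct column so that the total cost is
#' minimal over all injective row-to-column maps.
#'
#' @param cost Numeric matrix with `nrow(cost) <= ncol(cost)` and finite
#'   entries.
#' @return List with `assignment` (integer vector: column matched to
#'   each row) and `cost` (the minimal total cost).
#' @export
hungarian_min_cost <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("cost matrix entries must be finite")
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have nrow <= ncol")
  if (n == 0L) return(list(assignment = integer(0), cost = 0))
  INF <- Inf
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)          # p[j]: row matched to column j (0 = none)
  virt <- m + 1L                # virtual start column
  for (i in seq_len(n)) {
    p[virt] <- i
    j0 <- virt
    minv <- rep(INF, m)
    way <- integer(m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m)) {
        if (used[j]) v[j] <- v[j] - delta else minv[j] <- minv[j] - delta
      }
      for (j in seq_len(m + 1L)) if (used[j]) u[p[j]] <- u[p[j]] + delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == virt) i else p[j1]
      j0 <- j1
      if (j0 == virt) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assignment[p[j]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Assign the detections of one frame to clusters
#'
#' Enforces per-frame uniqueness — no two people in one frame may carry
#' the same identity. In `"flag"` mode (the pipeline's default) each
#' detection is first assigned to its nearest centroid independently;
#' whenever two or more detections in the frame land on the same
#' cluster, all of them are marked as mistaken (`status = "conflicted"`,
#' cluster `NA`). In `"optimal"` mode a one-to-one minimum total squared
#' distance assignment is computed instead (Hungarian algorithm); when a
#' frame holds more detections than clusters, the surplus worst-cost
#' detections are marked conflicted.
#'
#' @param embeddings Numeric matrix: the frame's detection embeddings
#'   (rows), already on the scale the model was fitted on.
#' @param model A `cluster_model` from [fit_kmeans()].
#' @param mode `"flag"` or `"optimal"`.
#' @return Data frame with one row per detection: `cluster` (0-based
#'   integer or `NA`), `distance` (Euclidean distance to the assigned
#'   centroid, `NA` when conflicted) and `status` (`"assigned"` or
#'   `"conflicted"`).
#' @export
assign_frame <- function(embeddings, model, mode = c("flag", "optimal")) {
  mode <- match.arg(mode)
  embeddings <- matrix(as.numeric(embeddings), ncol = ncol(model$centroids))
  if (ncol(embeddings) != ncol(model$centroids)) {
    stop("embedding dimension does not match the cluster model")
  }
  nd <- nrow(embeddings)
  K <- model$K
  d2 <- sq_dist(embeddings, model$centroids)
  if (mode == "flag") {
    cl <- max.col(-d2, ties.method = "first")
    status <- rep("assigned", nd)
    dup_clusters <- unique(cl[duplicated(cl)])
    conflicted <- cl %in% dup_clusters
    status[conflicted] <- "conflicted"
    out_cl <- ifelse(conflicted, NA_integer_, cl - 1L)
    dist <- ifelse(conflicted, NA_real_, sqrt(d2[cbind(seq_len(nd), cl)]))
  } else {
    status <- rep("assigned", nd)
    if (nd <= K) {
      sol <- hungarian_min_cost(d2)
      cl <- sol$assignment
      out_cl <- cl - 1L
      dist <- sqrt(d2[cbind(seq_len(nd), cl)])
    } else {
      # more people than clusters: match each cluster to its best detection,
      # the (nd - K) detections left over are conflicted
      sol <- hungarian_min_cost(t(d2))
      out_cl <- rep(NA_integer_, nd)
      dist <- rep(NA_real_, nd)
      out_cl[sol$assignment] <- seq_len(K) - 1L
      dist[sol$assignment] <- sqrt(d2[cbind(sol$assignment, seq_len(K))])
      status[is.na(out_cl)] <- "conflicted"
    }
  }
  data.frame(cluster = as.integer(out_cl), distance = dist, status = status)
}

#' Map numeric clusters to semantic labels
#'
#' Replaces 0-based cluster ids by researcher-supplied labels (for
#' example `c("0" = "Therapist", "1" = "Patient")`). Conflicted
#' detections receive the reserved token `"UNKNOWN"` regardless of the
#' mapping.
#'
#' @param assignments Data frame with `cluster` and `status` columns
#'   (from [assign_frame()] or [run_reid()]).
#' @param mapping Named character vector or list: names are the cluster
#'   ids `"0" .. "K-1"`, values the labels. Must be complete and
#'   injective.
#' @param K Number of clusters the mapping must cover.
#' @return `assignments` with a `label` column added (or replaced).
#' @export
apply_mapping <- function(assignments, mapping, K = max(assignments$cluster, na.rm = TRUE) + 1L) {
  mapping <- unlist(mapping)
  expect <- as.character(seq_len(K) - 1L)
  if (!setequal(names(mapping), expect)) {
    stop("mapping must cover exactly the clusters ", paste(expect, collapse = ", "))
  }
  if (anyDuplicated(mapping)) stop("mapping must be injective")
  lab <- unname(mapping[as.character(assignments$cluster)])
  lab[is.na(assignments$cluster) | assignments$status == "conflicted"] <- UNKNOWN_LABEL
  assignments$label <- lab
  assignments
}

#' Re-identify every detection of a session
#'
#' The central offline pipeline: all embeddings of the whole session are
#' clustered at once into exactly `K` identities (there is no real-time
#' requirement, so clustering sees every example of each person's
#' appearance), then each frame's detections are assigned under the
#' per-frame uniqueness constraint, and finally numeric clusters are
#' mapped to semantic labels.
#'
#' @param x A `reid_session` or a `session_scenario`.
#' @param K Number of unique individuals in the session.
#' @param mode Uniqueness handling, `"flag"` (mark collisions mistaken)
#'   or `"optimal"` (Hungarian resolution); see [assign_frame()].
#' @param mapping Optional cluster-to-label mapping (see
#'   [apply_mapping()]); by default clusters map to their ids as strings.
#' @param seed Seed forwarded to [fit_kmeans()].
#' @param n_restarts k-means restarts.
#' @param normalize L2-normalize embeddings before clustering (default
#'   `TRUE`).
#' @param tol,max_iter Convergence controls for [fit_kmeans()].
#' @return List with `assignments` (data frame `detection_id`, `frame`,
#'   `cluster`, `label`, `status`, `distance`) and `model` (the fitted
#'   `cluster_model`).
#' @export
run_reid <- function(x, K, mode = c("flag", "optimal"), mapping = NULL,
                     seed = 1L, n_restarts = 10L, normalize = TRUE,
                     tol = 1e-4, max_iter = 300L) {
  mode <- match.arg(mode)
  session <- if (inherits(x, "session_scenario")) x$session else x
  stopifnot(inherits(session, "reid_session"))
  if (is.null(session$embeddings)) stop("session has no embeddings")
  emb <- session$embeddings
  if (anyNA(emb)) stop("every detection needs an embedding for re-identification")
  if (normalize) emb <- l2_normalize(emb)
  model <- fit_kmeans(emb, K, seed = seed, tol = tol, max_iter = max_iter,
                      n_restarts = n_restarts)
  det <- session$detections
  n <- nrow(det)
  d2 <- sq_dist(emb, model$centroids)
  nearest <- max.col(-d2, ties.method = "first")
  cluster <- nearest - 1L
  distance <- sqrt(d2[cbind(seq_len(n), nearest)])
  status <- rep("assigned", n)
  by_frame <- split(seq_len(n), det$frame)
  for (rows in by_frame) {
    cl <- nearest[rows]
    if (anyDuplicated(cl) == 0L && length(rows) <= K) next
    # collision (or surplus detections): fall back to the per-frame rule;
    # collision-free frames are already per-frame optimal in both modes
    a <- assign_frame(emb[rows, , drop = FALSE], model, mode)
    cluster[rows] <- a$cluster
    status[rows] <- a$status
    distance[rows] <- a$distance
  }
  out <- data.frame(detection_id = det$detection_id, frame = det$frame,
                    cluster = cluster, label = NA_character_,
                    status = status, distance = distance)
  if (is.null(mapping)) {
    mapping <- setNames(as.character(seq_len(K) - 1L), as.character(seq_len(K) - 1L))
  }
  out <- apply_mapping(out, mapping, K = K)
  list(assignments = out[c("detection_id", "frame", "cluster", "label",
                           "status", "distance")],
       model = model)
}

#' Export assignments as MOT-layout tracks
#'
#' @param assignments Assignment data frame from [run_reid()].
#' @param session The `reid_session` providing the boxes.
#' @return MOT track data frame (`track_id = cluster + 1`; conflicted
#'   detections are dropped).
#' @export
assignments_to_tracks <- function(assignments, session) {
  det <- session$detections
  keep <- !is.na(assignments$cluster)
  idx <- match(assignments$detection_id[keep], det$detection_id)
  data.frame(frame = assignments$frame[keep],
             track_id = assignments$cluster[keep] + 1L,
             x_min = det$x_min[idx], y_min = det$y_min[idx],
             width = det$width[idx], height = det$height[idx],
             confidence = det$confidence[idx])
}
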