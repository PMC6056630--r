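#' Pairwise Pearson correlation of sample portraits
#'
#' @param model A `som_model` (or a metagenes x samples portrait matrix).
#' @param samples Optional subset of sample IDs.
#' @return samples x samples correlation matrix (symmetric, unit diagonal).
#' @export
portrait_correlation_matrix <- function(model, samples = NULL) {
  P <- portraits_of(model)
  if (!is.null(samples)) P <- P[, samples, drop = FALSE]
  if (ncol(P) < 2) stop("need >= 2 samples", call. = FALSE)
  r <- stats::cor(P)
  diag(r) <- 1
  r
}

portraits_of <- function(x) {
  if (inherits(x, "som_model")) x$codebook else as.matrix(x)
}

# correlation of each portrait with each centroid (samples x K)
centroid_correlation <- function(P, centroids) {
  stats::cor(P, centroids)
}

#' Silhouette-style class fit scores
#'
#' The per-sample score is the Pearson correlation of the sample's portrait
#' with its own class centroid minus the best (largest) correlation with any
#' other class centroid; positive means the sample best fits its own class.
#'
#' @param portraits Metagenes x samples matrix (or a `som_model`).
#' @param labels Class labels over samples (>= 2 classes).
#' @param centroids Optional metagenes x classes centroid matrix with class
#'   labels as column names; defaults to the class-mean portraits.
#' @return Named numeric vector of per-sample scores.
#' @export
silhouette_scores <- function(portraits, labels, centroids = NULL) {
  P <- portraits_of(portraits)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(P))
  classes <- if (is.null(centroids)) sort(unique(labels)) else colnames(centroids)
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  if (is.null(centroids)) {
    centroids <- vapply(classes, function(k) {
      rowMeans(P[, labels == k, drop = FALSE])
    }, numeric(nrow(P)))
  }
  rc <- centroid_correlation(P, centroids)
  own_col <- match(labels, classes)
  own <- rc[cbind(seq_along(labels), own_col)]
  other <- vapply(seq_along(labels), function(i) {
    max(rc[i, -own_col[i]])
  }, numeric(1))
  stats::setNames(own - other, colnames(P))
}

# core classifier over an explicit portrait matrix; used by discover_classes
# and by bootstrap resampling
classify_portraits <- function(P, K, seed = 1L, max_iter = 100L) {
  n <- ncol(P)
  if (K < 2 || K > n) stop("K must satisfy 2 <= K <= number of samples", call. = FALSE)
  r <- stats::cor(P)
  diag(r) <- 1

  # K-means seeding on the rows of r (multi-start, deterministic given seed);
  # K = n degenerates to singleton classes
  set.seed(seed)
  labels <- if (K == n) seq_len(n) else {
    stats::kmeans(r, centers = K, nstart = 50, iter.max = 100)$cluster
  }

  # iterative silhouette maximization: move negative-S samples to their
  # best-matching class until convergence
  mean_s <- numeric(0)
  moved_log <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (k in seq_len(K)) {             # re-seed emptied classes
      if (!any(labels == k)) {
        # restart the centroid on the worst-fitting sample (S from the
        # previous iteration; K-means seeding never yields empty classes,
        # so S exists whenever this branch is reached)
        worst <- which.min(S)
        labels[worst] <- k
        message("class ", k, " emptied; restarted on sample ", worst)
      }
    }
    centroids <- vapply(seq_len(K), function(k) {
      rowMeans(P[, labels == k, drop = FALSE])
    }, numeric(nrow(P)))
    rc <- centroid_correlation(P, centroids)
    own <- rc[cbind(seq_len(n), labels)]
    best_other <- vapply(seq_len(n), function(i) max(rc[i, -labels[i]]), numeric(1))
    S <- own - best_other
    mean_s <- c(mean_s, mean(S))
    movers <- which(S < 0)
    if (length(movers) == 0 || iter >= max_iter) break
    new_lab <- max.col(rc[movers, , drop = FALSE], ties.method = "first")
    changed <- new_lab != labels[movers]
    if (!any(changed)) break
    labels[movers[changed]] <- new_lab[changed]
    moved_log <- moved_log + sum(changed)
  }
  list(labels = labels, S = S, centroids = centroids, iterations = iter,
       mean_s_history = mean_s, r = r, n_moves = moved_log)
}

#' Discover sample classes from portrait correlations
#'
#' Samples are seeded into `K` classes by K-means on the rows of the pairwise
#' portrait-correlation matrix (multi-start, deterministic for a fixed seed),
#' then refined by
#' iteratively re-assigning every sample with a negative silhouette score to
#' its best-matching class (centroid = class-mean portrait) until no sample
#' moves or the iteration cap is reached. Deterministic for a fixed seed.
#'
#' @param model A `som_model` (or metagenes x samples portrait matrix).
#' @param K Number of classes (default 6).
#' @param seed Integer seed for the K-means start.
#' @param samples Optional subset of sample IDs to classify.
#' @param max_iter Refinement iteration cap.
#' @return Object of class `class_assignment`: `labels` (named integer),
#'   `S` (per-sample silhouette scores), `centroids`, `iterations`,
#'   `mean_s_history` and the correlation matrix `r`.
#' @export
discover_classes <- function(model, K = 6L, seed = 1L, samples = NULL,
                             max_iter = 100L) {
  P <- portraits_of(model)
  if (!is.null(samples)) P <- P[, samples, drop = FALSE]
  fit <- classify_portraits(P, K, seed = seed, max_iter = max_iter)
  structure(list(labels = stats::setNames(fit$labels, colnames(P)),
                 K = as.integer(K),
                 S = stats::setNames(fit$S, colnames(P)),
                 centroids = fit$centroids,
                 iterations = fit$iterations,
                 mean_s_history = fit$mean_s_history,
                 r = fit$r, seed = as.integer(seed)),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat("class_assignment: K =", x$K, "(", x$iterations, "refinement iterations )\n")
  print(table(class = x$labels))
  cat("mean silhouette S =", round(mean(x$S), 3), "\n")
  invisible(x)
}

#' Bootstrap stability of a class assignment
#'
#' Resamples the samples with replacement `B` times, re-runs the class
#' discovery on each resample, matches resampled classes to the reference
#' classes one-to-one by greedy maximal centroid correlation, and returns the
#' mean percentage of in-bag draws that retain their reference label.
#' Replicates whose resample holds fewer than `K` distinct samples are
#' skipped with a message.
#'
#' @param model A `som_model` (or portrait matrix).
#' @param K Number of classes.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed (reference fit and resampling).
#' @param samples Optional subset of sample IDs.
#' @return List with `stability` (mean percentage), `per_replicate`
#'   (percentages, `NA` for skipped replicates) and the `reference`
#'   `class_assignment`.
#' @export
bootstrap_stability <- function(model, K = 6L, B = 100L, seed = 1L,
                                samples = NULL) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  P <- portraits_of(model)
  if (!is.null(samples)) P <- P[, samples, drop = FALSE]
  ref <- classify_portraits(P, K, seed = seed)
  n <- ncol(P)
  set.seed(seed)
  draws <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  per <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- draws[, b]
    if (length(unique(idx)) < K) {
      message("bootstrap replicate ", b, " has < K distinct samples; skipped")
      next
    }
    fit <- classify_portraits(P[, idx, drop = FALSE], K, seed = seed)
    map <- match_classes(fit$centroids, ref$centroids)
    per[b] <- 100 * mean(map[fit$labels] == ref$labels[idx])
  }
  list(stability = mean(per, na.rm = TRUE), per_replicate = per,
       reference = ref)
}

# one-to-one greedy matching of boot centroids to reference centroids by
# descending correlation
match_classes <- function(boot_centroids, ref_centroids) {
  K <- ncol(boot_centroids)
  rc <- stats::cor(boot_centroids, ref_centroids)
  map <- integer(K)
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(rc), dim(rc))
    map[ij[1]] <- ij[2]
    rc[ij[1], ] <- -Inf
    rc[, ij[2]] <- -Inf
  }
  map
}

#' Sample similarity network from a correlation matrix
#'
#' @param r Sample x sample correlation matrix.
#' @param rule `"threshold"` keeps edges with `r >= param`; `"knn"` connects
#'   each sample to its `param` nearest neighbours by correlation,
#'   symmetrized by union.
#' @param param Threshold value or neighbour count.
#' @return data.frame edge list (`from`, `to`, `r`), `from < to`.
#' @export
correlation_network <- function(r, rule = c("threshold", "knn"), param) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  n <- nrow(r)
  ids <- colnames(r)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  adj <- matrix(FALSE, n, n)
  if (rule == "threshold") {
    adj <- r >= param
  } else {
    k <- as.integer(param)
    if (k < 1 || k >= n) stop("knn parameter must be in [1, n - 1]", call. = FALSE)
    for (i in seq_len(n)) {
      ord <- order(r[i, -i], decreasing = TRUE)
      nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
             r = r[idx], stringsAsFactors = FALSE)
}
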