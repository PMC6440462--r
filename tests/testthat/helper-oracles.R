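# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (double loops, enumeration) and share no
# code with the package implementations they check.

dmat <- function(values, metric_id = "jsd", ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  mbstates:::new_distance_matrix(values, metric_id)
}

# Euclidean distances of 1-D points, as a distance_matrix
dmat_points <- function(x, ...) dmat(as.matrix(dist(x)), ...)

# Two well-separated blobs on a line, small within-jitter, no ties
blob_dmat <- function(n_per = 10, n_blobs = 2, gap = 1, jitter = 0.02,
                      seed = 42) {
  set.seed(seed)
  x <- as.vector(vapply(seq_len(n_blobs), function(b)
    (b - 1) * gap + runif(n_per, 0, jitter), numeric(n_per)))
  d <- as.matrix(dist(x))
  dmat(d / max(d), ids = paste0("s", seq_along(x)))
}

blob_truth <- function(n_per = 10, n_blobs = 2)
  rep(seq_len(n_blobs), each = n_per)

# random composition matrix (rows sum to 1)
random_compositions <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(n * p, shape = 0.5), n, p)
  m / rowSums(m)
}

comp_table <- function(values, ...) {
  abundance_table(values / rowSums(values), normalized = TRUE, ...)
}

# --- naive oracles -------------------------------------------------------

naive_jsd <- function(p, q) {
  m <- (p + q) / 2
  tot <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) tot <- tot + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) tot <- tot + 0.5 * q[i] * log2(q[i] / m[i])
  }
  tot
}

naive_silhouette <- function(dm, labels) {
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- Inf
    for (c in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(dm[i, labels == c]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# exhaustive k-medoids optimum: best objective over all medoid subsets
exhaustive_pam <- function(dm, k) {
  n <- nrow(dm)
  best <- Inf; best_med <- NULL
  for (med in combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(dm[, med, drop = FALSE], 1, min))
    if (obj < best - 1e-12) { best <- obj; best_med <- med }
  }
  list(objective = best, medoids = best_med)
}

# is a PAM solution 1-swap locally optimal?
is_swap_optimal <- function(dm, medoids) {
  n <- nrow(dm)
  obj <- function(med) sum(apply(dm[, med, drop = FALSE], 1, min))
  base <- obj(medoids)
  for (mi in seq_along(medoids)) for (h in setdiff(seq_len(n), medoids)) {
    cand <- medoids; cand[mi] <- h
    if (obj(cand) < base - 1e-9) return(FALSE)
  }
  TRUE
}

# naive O(n^3) UPGMA: recompute every inter-cluster mean from scratch
naive_upgma <- function(dm, k = 1) {
  clusters <- lapply(seq_len(nrow(dm)), identity)
  heights <- numeric(0)
  while (length(clusters) > k) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        h <- mean(dm[clusters[[i]], clusters[[j]], drop = FALSE])
        if (h < best - 1e-15) { best <- h; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  labels <- integer(nrow(dm))
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  list(heights = heights, labels = labels)
}

same_partition <- function(a, b) adjusted_rand_index(a, b) == 1

# hand-built assessment record for selection tests
fake_record <- function(metric, k, si, ps = NA_real_, jaccard = NA_real_,
                        sizes = rep(10, k), algorithm = "pam") {
  labels <- canonicalize_labels(stats::setNames(
    rep(seq_len(k), sizes), paste0("s", seq_len(sum(sizes)))))
  structure(list(algorithm_id = algorithm, metric_id = metric, k = k,
                 si = si, ps_mean = ps, ps_reps = 100L,
                 jaccard_per_cluster = rep(jaccard, k),
                 jaccard_mean = jaccard, boot_reps = 100L,
                 cluster_sizes = sizes, labels = labels),
            class = "assessment_record")
}
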