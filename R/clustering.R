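#' Canonicalize cluster labels
#'
#' Relabels clusters as consecutive integers 1..k in order of first
#' appearance along the sample order; partitions are unchanged as set
#' partitions.
#'
#' @param labels integer (or factor) vector of cluster assignments,
#'   optionally named by sample id.
#' @return integer labels, names preserved.
#' @export
canonicalize_labels <- function(labels) {
  nm <- names(labels)
  out <- match(labels, unique(labels))
  names(out) <- nm
  out
}

#' Partitioning around medoids (PAM)
#'
#' Deterministic k-medoids on a precomputed distance matrix.  BUILD seeds
#' the first medoid as the point minimizing total distance to all points,
#' then greedily adds the point whose inclusion maximally decreases the
#' objective.  SWAP repeatedly applies the single best-improving
#' (medoid, non-medoid) exchange until no exchange strictly decreases the
#' objective (classic best-improvement PAM).  All ties break toward the
#' lowest sample position, so repeated runs are identical.
#'
#' @param D a [distance_matrix()].
#' @param k number of clusters, `2 <= k < n` (k = 1 is allowed for
#'   degenerate internal uses).
#' @return a `clustering_solution` with fields `algorithm_id = "pam"`,
#'   `metric_id`, `k`, `labels` (named, canonicalized), `medoids` (sample
#'   ids, ascending position) and `objective`
#'   (sum of distances to assigned medoids).
#' @export
pam_cluster <- function(D, k) {
  v <- D$values
  n <- nrow(v)
  if (any(!is.finite(v))) stop("non-finite distances")
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n (k=", k, ", n=", n, ")")
  ## BUILD
  med <- which.min(colSums(v))
  dnear <- v[, med]
  while (length(med) < k) {
    gains <- colSums(pmax(dnear - v, 0))
    gains[med] <- -Inf
    j <- which.max(gains)
    med <- c(med, j)
    dnear <- pmin(dnear, v[, j])
  }
  med <- sort(med)
  ## SWAP (best improvement per pass)
  repeat {
    A <- v[, med, drop = FALSE]
    w <- max.col(-A, ties.method = "first")
    d1 <- A[cbind(seq_len(n), w)]
    if (k > 1) {
      A2 <- A
      A2[cbind(seq_len(n), w)] <- Inf
      d2 <- A2[cbind(seq_len(n), max.col(-A2, ties.method = "first"))]
    } else d2 <- rep(Inf, n)
    base <- colSums(pmin(v - d1, 0))   # column h: sum_i min(d(i,h)-d1_i, 0)
    best <- list(delta = -1e-12, m = NA, h = NA)
    for (mi in seq_len(k)) {
      ism <- w == mi
      if (!any(ism)) next
      corr <- colSums(pmin(v[ism, , drop = FALSE], d2[ism]) - d1[ism]) -
        colSums(pmin(v[ism, , drop = FALSE] - d1[ism], 0))
      delta <- base + corr
      delta[med] <- Inf
      h <- which.min(delta)
      if (delta[h] < best$delta) best <- list(delta = delta[h], m = mi, h = h)
    }
    if (is.na(best$m)) break
    med[best$m] <- best$h
    med <- sort(med)
  }
  A <- v[, med, drop = FALSE]
  w <- max.col(-A, ties.method = "first")
  w[med] <- seq_len(k)   # a medoid always anchors its own cluster
  labels <- canonicalize_labels(stats::setNames(w, D$sample_ids))
  med_by_cluster <- med[unique(w)]   # medoid of canonical cluster 1..k
  structure(list(algorithm_id = "pam", metric_id = D$metric_id, k = k,
                 labels = labels,
                 medoids = D$sample_ids[med_by_cluster],
                 medoid_idx = med_by_cluster,
                 objective = sum(A[cbind(seq_len(n), w)])),
            class = "clustering_solution")
}

#' UPGMA hierarchical clustering cut at k clusters
#'
#' Bottom-up agglomeration under size-weighted average linkage (UPGMA):
#' the distance between two clusters is the mean of all pairwise
#' inter-cluster distances, maintained with Lance-Williams updates.  Ties
#' break toward the lexicographically smallest active-cluster pair.  The
#' tree is cut by merge count: labels come from stopping after `n - k`
#' merges.
#'
#' @param D a [distance_matrix()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return a `clustering_solution` with `algorithm_id = "hclust"`, labels,
#'   and `merge_sequence` (data.frame of merged pair and exact average
#'   linkage height per step).
#' @export
upgma_cluster <- function(D, k) {
  v <- D$values
  n <- nrow(v)
  if (any(!is.finite(v))) stop("non-finite distances")
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n")
  ## active clusters live at the row index of their smallest original member;
  ## merged-away rows/columns are masked with Inf in place
  dm <- v
  diag(dm) <- Inf
  sizes <- rep(1L, n)
  parent <- seq_len(n)              # union-find style cluster membership
  mi <- mj <- integer(n - 1); mh <- numeric(n - 1)
  labels_at_k <- if (k == n) seq_len(n) else NULL
  for (step in seq_len(n - 1)) {
    h <- min(dm)
    pos <- which(dm == h)
    jj <- (pos - 1L) %/% n + 1L
    ii <- pos - (jj - 1L) * n
    o <- order(pmin(ii, jj), pmax(ii, jj))[1]
    i <- min(ii[o], jj[o]); j <- max(ii[o], jj[o])
    mi[step] <- i; mj[step] <- j; mh[step] <- h
    ## Lance-Williams UPGMA: d(new, o) = (ni d(i,o) + nj d(j,o)) / (ni + nj)
    newd <- (sizes[i] * dm[i, ] + sizes[j] * dm[j, ]) / (sizes[i] + sizes[j])
    newd[c(i, j)] <- Inf
    dm[i, ] <- newd; dm[, i] <- newd
    dm[j, ] <- Inf; dm[, j] <- Inf
    sizes[i] <- sizes[i] + sizes[j]
    parent[parent == j] <- i
    if (n - step == k) labels_at_k <- parent
  }
  labels <- canonicalize_labels(stats::setNames(labels_at_k, D$sample_ids))
  structure(list(algorithm_id = "hclust", metric_id = D$metric_id, k = k,
                 labels = labels,
                 merge_sequence = data.frame(i = mi, j = mj, height = mh)),
            class = "clustering_solution")
}

#' @export
print.clustering_solution <- function(x, ...) {
  cat(sprintf("clustering_solution: %s on %s, k = %d (sizes: %s)\n",
              x$algorithm_id, x$metric_id, x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Medoid of a set of samples
#'
#' The member minimizing the sum of distances to the other members; ties
#' break toward the lowest position in `member_idx`th order of `D`.
#'
#' @param D a [distance_matrix()].
#' @param member_idx integer positions (or sample ids) of the members.
#' @return the medoid's integer position in `D`.
#' @export
cluster_medoid <- function(D, member_idx) {
  if (is.character(member_idx))
    member_idx <- match(member_idx, D$sample_ids)
  if (!length(member_idx)) stop("empty member set")
  member_idx <- sort(member_idx)
  sums <- colSums(D$values[member_idx, member_idx, drop = FALSE])
  member_idx[which.min(sums)]
}

#' Dispatch a clustering algorithm by identifier
#'
#' @param D a [distance_matrix()].
#' @param k number of clusters.
#' @param algorithm_id `"pam"` or `"hclust"`.
#' @return a `clustering_solution`.
#' @export
cluster_samples <- function(D, k, algorithm_id = c("pam", "hclust")) {
  algorithm_id <- match.arg(algorithm_id)
  switch(algorithm_id, pam = pam_cluster(D, k), hclust = upgma_cluster(D, k))
}
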