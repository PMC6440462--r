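## Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic small sub-seed for one grid combination (< 2^31).
comb_seed <- function(seed, metric_id, algorithm_id, k, tag) {
  if (is.null(seed)) return(NULL)
  key <- paste(metric_id, algorithm_id, k, tag, sep = "|")
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Average silhouette width
#'
#' For sample i, `a(i)` is the mean distance to its own-cluster co-members
#' and `b(i)` the smallest mean distance to another cluster;
#' `s(i) = (b - a) / max(a, b)`.  Samples in singleton clusters contribute
#' `s(i) = 0`, as do samples where `max(a, b) = 0`.
#'
#' @param D a [distance_matrix()].
#' @param labels cluster assignment (integer vector, >= 2 non-empty
#'   clusters).
#' @return the mean silhouette width, in \[-1, 1\].
#' @export
average_silhouette <- function(D, labels) {
  v <- D$values
  n <- nrow(v)
  stopifnot(length(labels) == n)
  labels <- as.integer(canonicalize_labels(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette undefined for a single cluster")
  sizes <- tabulate(labels, k)
  ## mean distance from every sample to every cluster (including self terms)
  member <- outer(labels, seq_len(k), "==") + 0
  sums <- v %*% member                       # n x k total distance to cluster
  own <- sizes[labels]
  a <- ifelse(own > 1, sums[cbind(seq_len(n), labels)] / (own - 1), 0)
  meanmat <- sweep(sums, 2, sizes, "/")
  meanmat[cbind(seq_len(n), labels)] <- Inf
  b <- apply(meanmat, 1, min)
  s <- ifelse(own == 1, 0,
              ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0))
  mean(s)
}

## Medoid indices (into D) of each cluster of a solution on D.
solution_medoids <- function(D, sol) {
  if (!is.null(sol$medoid_idx)) return(sol$medoid_idx)
  vapply(seq_len(sol$k), function(c)
    cluster_medoid(D, which(sol$labels == c)), integer(1))
}

## Cluster one half and expose its medoids in global index space.
ps_half <- function(D, k, algorithm_id, idx) {
  Dh <- submatrix(D, idx)
  sol <- cluster_samples(Dh, k, algorithm_id)
  med_local <- solution_medoids(Dh, sol)
  list(sol = sol, med_global = idx[med_local],
       med_cluster = sol$labels[med_local])
}

## One prediction-strength direction: classify `test` samples by nearest
## train medoid and score the test clustering's pairs.
ps_direction <- function(D, train_half, test_half, test, aggregation) {
  cls <- max.col(-D$values[test, train_half$med_global, drop = FALSE],
                 ties.method = "first")
  cls <- train_half$med_cluster[cls]         # train-cluster id per test point
  sol_te <- test_half$sol
  per_cluster <- numeric(sol_te$k)
  pair_hits <- 0; pair_tot <- 0
  for (c in seq_len(sol_te$k)) {
    members <- which(sol_te$labels == c)
    s <- length(members)
    if (s < 2) { per_cluster[c] <- 1; next }
    cnt <- table(cls[members])
    hits <- sum(choose(cnt, 2))
    tot <- choose(s, 2)
    per_cluster[c] <- hits / tot
    pair_hits <- pair_hits + hits
    pair_tot <- pair_tot + tot
  }
  if (aggregation == "min") min(per_cluster)
  else if (pair_tot > 0) pair_hits / pair_tot else 1
}

#' Prediction strength
#'
#' Cross-validation-style cluster validity: the data are split into two
#' halves, each half is clustered into k clusters, and each half's samples
#' are classified to their nearest medoid from the other half's clustering.
#' A test cluster's score is the proportion of its sample pairs that land
#' in one training cluster; a repetition's score aggregates over test
#' clusters (minimum by default) and averages the two split directions.
#'
#' @param D a [distance_matrix()].
#' @param k number of clusters (`n >= 2k`); `k = 1` returns 1 by
#'   convention.
#' @param algorithm_id `"pam"` or `"hclust"`.
#' @param reps number of random half-splits, default 100.
#' @param seed integer seed for the splits (`NULL` uses the current RNG).
#' @param aggregation `"min"` over test clusters (default; the stricter,
#'   literature definition) or `"global"` pair frequency.
#' @param directions `"both"` (classify A against B and vice versa,
#'   averaged; default) or `"one"`.
#' @return mean prediction strength over repetitions, in \[0, 1\].
#' @export
prediction_strength <- function(D, k, algorithm_id = "pam", reps = 100,
                                seed = NULL,
                                aggregation = c("min", "global"),
                                directions = c("both", "one")) {
  aggregation <- match.arg(aggregation)
  directions <- match.arg(directions)
  n <- length(D$sample_ids)
  if (k == 1) return(1)
  if (n < 2 * k)
    stop("n = ", n, " too small for prediction strength at k = ", k,
         " (need n >= 2k)")
  with_seed(seed, {
    scores <- vapply(seq_len(reps), function(r) {
      perm <- sample.int(n)
      a <- sort(perm[seq_len(n %/% 2)])
      b <- sort(perm[(n %/% 2 + 1):n])
      ha <- ps_half(D, k, algorithm_id, a)
      hb <- ps_half(D, k, algorithm_id, b)
      s1 <- ps_direction(D, ha, hb, test = b, aggregation)
      if (directions == "one") s1
      else (s1 + ps_direction(D, hb, ha, test = a, aggregation)) / 2
    }, numeric(1))
    mean(scores)
  })
}

#' Bootstrap cluster stability (Jaccard)
#'
#' The full data are clustered once; each bootstrap resample (n draws with
#' replacement, duplicated rows included in the reclustering geometry) is
#' reclustered into k clusters.  Each original cluster, restricted to the
#' distinct samples present in the resample, is matched to its
#' best-overlapping resample cluster by Jaccard set similarity
#' `|intersection| / |union|` over distinct sample ids.  Per-cluster
#' stability is the mean over resamples; the aggregate is the mean (or
#' minimum) over clusters.
#'
#' @param D a [distance_matrix()].
#' @param k number of clusters (`n >= k`).
#' @param algorithm_id `"pam"` or `"hclust"`.
#' @param boot_reps bootstrap resamples, default 100.
#' @param seed integer seed for resampling.
#' @param aggregation `"mean"` (default) or `"min"` over clusters.
#' @param labels optional precomputed full-data labels (skips reclustering
#'   the full data).
#' @return list with `per_cluster` (length k) and `aggregate`.
#' @export
jaccard_stability <- function(D, k, algorithm_id = "pam", boot_reps = 100,
                              seed = NULL, aggregation = c("mean", "min"),
                              labels = NULL) {
  aggregation <- match.arg(aggregation)
  n <- length(D$sample_ids)
  if (n < k) stop("n < k")
  if (is.null(labels))
    labels <- cluster_samples(D, k, algorithm_id)$labels
  orig <- lapply(seq_len(k), function(c) which(labels == c))
  acc <- numeric(k); cnt <- numeric(k)
  with_seed(seed, {
    for (r in seq_len(boot_reps)) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      distinct <- unique(idx)
      if (length(distinct) < k) {
        warning("bootstrap resample ", r, " has too few distinct samples (",
                length(distinct), ") for k = ", k, "; skipped")
        next
      }
      sol <- cluster_samples(submatrix(D, idx), k, algorithm_id)
      boot_sets <- lapply(seq_len(sol$k), function(c)
        unique(idx[sol$labels == c]))
      for (c in seq_len(k)) {
        si <- intersect(orig[[c]], distinct)
        if (!length(si)) next
        jac <- vapply(boot_sets, function(bs)
          length(intersect(si, bs)) / length(union(si, bs)), numeric(1))
        acc[c] <- acc[c] + max(jac)
        cnt[c] <- cnt[c] + 1
      }
    }
  })
  per_cluster <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  aggregate <- if (aggregation == "mean") mean(per_cluster, na.rm = TRUE)
  else min(per_cluster, na.rm = TRUE)
  list(per_cluster = per_cluster, aggregate = aggregate)
}

#' Assess one grid combination
#'
#' Computes (or reuses) the distance matrix, the full-data clustering and
#' the three assessment scores for one (algorithm, metric, k) combination.
#'
#' @param table a normalized [abundance_table()].
#' @param metric_id a beta-diversity metric id.
#' @param algorithm_id `"pam"` or `"hclust"`.
#' @param k number of clusters.
#' @param config a [selection_config()].
#' @param D optional precomputed [distance_matrix()] for `metric_id`.
#' @param scores `"all"` (SI, PS, Jaccard) or `"si"` only (PS/Jaccard left
#'   NA for lazy filling during selection).
#' @return an `assessment_record` (list) with fields `algorithm_id`,
#'   `metric_id`, `k`, `si`, `ps_mean`, `ps_reps`, `jaccard_per_cluster`,
#'   `jaccard_mean`, `boot_reps`, `cluster_sizes`, `labels`.
#' @export
assess_combination <- function(table, metric_id, algorithm_id, k, config =
                                 selection_config(), D = NULL,
                               scores = c("all", "si")) {
  scores <- match.arg(scores)
  if (is.null(D)) D <- distance_matrix(table, metric_id)
  sol <- cluster_samples(D, k, algorithm_id)
  si <- average_silhouette(D, sol$labels)
  rec <- list(algorithm_id = algorithm_id, metric_id = metric_id, k = k,
              si = si, ps_mean = NA_real_, ps_reps = config$ps_reps,
              jaccard_per_cluster = rep(NA_real_, k),
              jaccard_mean = NA_real_, boot_reps = config$boot_reps,
              cluster_sizes = tabulate(sol$labels, k), labels = sol$labels)
  class(rec) <- "assessment_record"
  if (scores == "all") rec <- fill_scores(rec, D, config)
  rec
}

## Fill PS/Jaccard into a record (used eagerly or lazily).
fill_scores <- function(rec, D, config) {
  if (is.na(rec$ps_mean))
    rec$ps_mean <- prediction_strength(
      D, rec$k, rec$algorithm_id, reps = config$ps_reps,
      seed = comb_seed(config$rng_seed, rec$metric_id, rec$algorithm_id,
                       rec$k, "ps"),
      aggregation = config$ps_aggregation)
  if (is.na(rec$jaccard_mean)) {
    js <- jaccard_stability(
      D, rec$k, rec$algorithm_id, boot_reps = config$boot_reps,
      seed = comb_seed(config$rng_seed, rec$metric_id, rec$algorithm_id,
                       rec$k, "jaccard"),
      aggregation = config$jaccard_aggregation, labels = rec$labels)
    rec$jaccard_per_cluster <- js$per_cluster
    rec$jaccard_mean <- js$aggregate
  }
  rec
}

#' Tidy data.frame of assessment records
#'
#' @param records list of `assessment_record`s from [evaluate_grid()].
#' @return one row per algorithm x metric x k with si, ps_mean,
#'   jaccard_mean and cluster sizes.
#' @export
records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(algorithm_id = r$algorithm_id, metric_id = r$metric_id,
               k = r$k, si = r$si, ps_mean = r$ps_mean,
               jaccard_mean = r$jaccard_mean, ps_reps = r$ps_reps,
               boot_reps = r$boot_reps,
               cluster_sizes = paste(r$cluster_sizes, collapse = "/"),
               stringsAsFactors = FALSE)))
}
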