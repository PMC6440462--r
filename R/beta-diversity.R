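#' Beta-diversity dissimilarities
#'
#' The five abundance-based dissimilarities used as clustering distances.
#' All are symmetric, zero on identical inputs and bounded by \[0, 1\].
#'
#' `jsd` is the Jensen-Shannon divergence with base-2 logarithms,
#' `JSD(p, q) = KL(p||m)/2 + KL(q||m)/2` with `m = (p + q)/2`; the base-2
#' convention puts it on \[0, 1\].  `rjsd` is its square root (a metric).
#' `bray_curtis` is `sum |x - y| / sum (x + y)`.  `morisita_horn` is
#' `1 - 2 sum xy / ((sum x^2 / X^2 + sum y^2 / Y^2) X Y)` with
#' `X = sum x`, `Y = sum y`.  `kulczynski` is
#' `1 - (W/X + W/Y)/2` with `W = sum min(x, y)`.
#'
#' @param p,q compositions (non-negative, summing to 1 within 1e-6).
#' @param x,y non-negative abundance vectors (any positive total).
#' @return a single dissimilarity in \[0, 1\].
#' @name beta_diversity
NULL

check_composition <- function(p, name) {
  if (any(p < 0)) stop(name, " has negative entries")
  if (abs(sum(p) - 1) > 1e-6)
    stop(name, " is not a composition (sums to ", format(sum(p)), ")")
  p
}

#' @rdname beta_diversity
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch: ", length(p), " vs ",
                                   length(q))
  check_composition(p, "p"); check_composition(q, "q")
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  max(0, kl(p) / 2 + kl(q) / 2)
}

#' @rdname beta_diversity
#' @export
rjsd <- function(p, q) sqrt(jsd(p, q))

check_abundance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ",
                                   length(y))
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  if (sum(x) + sum(y) <= 0) stop("both vectors are all-zero")
  invisible(NULL)
}

#' @rdname beta_diversity
#' @export
bray_curtis <- function(x, y) {
  check_abundance(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' @rdname beta_diversity
#' @export
morisita_horn <- function(x, y) {
  check_abundance(x, y)
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("morisita_horn requires positive totals")
  1 - 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' @rdname beta_diversity
#' @export
kulczynski <- function(x, y) {
  check_abundance(x, y)
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("kulczynski requires positive totals")
  W <- sum(pmin(x, y))
  1 - (W / X + W / Y) / 2
}

#' Supported beta-diversity metric identifiers
#' @export
beta_metrics <- function() c("jsd", "rjsd", "braycurtis", "morisitahorn",
                             "kulczynski")

#' Pairwise distance matrix under one beta-diversity metric
#'
#' Computes all pairwise sample dissimilarities with vectorized formulas;
#' entries agree with the scalar functions ([jsd()] etc.) pairwise.
#'
#' @param table a normalized [abundance_table()] with at least 2 samples.
#' @param metric_id one of `jsd`, `rjsd`, `braycurtis`, `morisitahorn`,
#'   `kulczynski`.
#' @return an object of class `distance_matrix` with fields `metric_id`,
#'   `sample_ids` and the square symmetric `values` matrix.
#' @export
distance_matrix <- function(table, metric_id) {
  stopifnot(is_abundance_table(table))
  metric_id <- match.arg(metric_id, beta_metrics())
  if (!table$normalized)
    stop("distance_matrix requires a normalized table; run normalize_tss()")
  X <- table$values
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  D <- switch(metric_id,
    jsd = jsd_matrix(X),
    rjsd = sqrt(jsd_matrix(X)),
    braycurtis = {
      man <- as.matrix(stats::dist(X, method = "manhattan"))
      rs <- rowSums(X)
      man / outer(rs, rs, "+")
    },
    morisitahorn = {
      rs <- rowSums(X)
      sq <- rowSums(X^2) / rs^2
      1 - 2 * tcrossprod(X) / (outer(sq, sq, "+") * outer(rs, rs))
    },
    kulczynski = {
      man <- as.matrix(stats::dist(X, method = "manhattan"))
      rs <- rowSums(X)
      W <- (outer(rs, rs, "+") - man) / 2
      1 - (W / rs + t(W / rs)) / 2    # W/rs divides rows by rs[i]
    })
  D <- pmin(pmax((D + t(D)) / 2, 0), 1)   # symmetrize away rounding noise
  diag(D) <- 0
  dimnames(D) <- list(table$sample_ids, table$sample_ids)
  new_distance_matrix(D, metric_id)
}

jsd_matrix <- function(X) {
  # JSD(p,q) = H2(m) - (H2(p) + H2(q))/2, H2 the base-2 Shannon entropy
  n <- nrow(X)
  h <- function(M) {
    P <- M * log2(M)
    P[!is.finite(P)] <- 0
    -rowSums(P)
  }
  hx <- h(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    M <- (X[j, , drop = FALSE] + rep(X[i, ], each = length(j))) / 2
    v <- h(M) - (hx[j] + hx[i]) / 2
    D[i, j] <- v
    D[j, i] <- v
  }
  pmax(D, 0)
}

new_distance_matrix <- function(values, metric_id) {
  structure(list(metric_id = metric_id, sample_ids = rownames(values),
                 values = values), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples, metric %s\n",
              length(x$sample_ids), x$metric_id))
  invisible(x)
}

#' @rdname distance_matrix
#' @param D a `distance_matrix`.
#' @export
validate_distance_matrix <- function(D) {
  v <- D$values
  stopifnot(is.matrix(v), nrow(v) == ncol(v),
            nrow(v) == length(D$sample_ids))
  if (any(!is.finite(v))) stop("non-finite distances")
  if (max(abs(v - t(v))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(v) != 0)) stop("nonzero diagonal")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12) stop("distances outside [0, 1]")
  invisible(D)
}

submatrix <- function(D, idx) {
  v <- D$values[idx, idx, drop = FALSE]
  ids <- D$sample_ids[idx]
  if (anyDuplicated(ids))
    dimnames(v) <- list(make.unique(ids), make.unique(ids))
  structure(list(metric_id = D$metric_id, sample_ids = rownames(v),
                 values = v), class = "distance_matrix")
}
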