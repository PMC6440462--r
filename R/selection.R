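#' Configuration for the robust-state selection pipeline
#'
#' Defaults follow the published procedure: k from 2 to 10, both
#' algorithms, all five distances, silhouette gate 0.25, prediction
#' strength gate 0.80 over 100 split repetitions, Jaccard stability gate
#' 0.75 over 100 bootstrap resamples, and a minimum accepted cluster size
#' of 5.
#'
#' @param k_range integer length-2 interval of cluster numbers, default
#'   `c(2, 10)`.
#' @param metrics subset of [beta_metrics()], default all five.
#' @param algorithms subset of `c("pam", "hclust")`, default both.
#' @param si_threshold silhouette gate (strictly greater), default 0.25.
#' @param ps_threshold prediction-strength gate (strictly greater),
#'   default 0.80.
#' @param jaccard_threshold stability gate (greater or equal),
#'   default 0.75.
#' @param ps_reps,boot_reps repetitions for the two resampling scores,
#'   default 100 each.
#' @param min_cluster_size accepted solutions may not contain a smaller
#'   cluster, default 5.
#' @param rng_seed integer master seed; every resampling score derives a
#'   deterministic sub-seed from it.
#' @param ps_aggregation `"min"` over clusters (default) or `"global"`
#'   pair frequency.
#' @param jaccard_aggregation `"mean"` (default) or `"min"` over clusters.
#' @param si_pair_rule silhouette gate applies to `"both"` pair members
#'   (default) or to their `"average"`.
#' @param gate_both_members require PS/Jaccard gates on both pair members
#'   (default `FALSE`: the higher-silhouette member gates).
#' @param lazy_scores compute PS/Jaccard only for candidates actually
#'   scanned (default `TRUE`; `FALSE` scores the whole grid eagerly).
#' @return a `selection_config` list.
#' @export
selection_config <- function(k_range = c(2, 10), metrics = beta_metrics(),
                             algorithms = c("pam", "hclust"),
                             si_threshold = 0.25, ps_threshold = 0.80,
                             jaccard_threshold = 0.75, ps_reps = 100,
                             boot_reps = 100, min_cluster_size = 5,
                             rng_seed = NULL,
                             ps_aggregation = c("min", "global"),
                             jaccard_aggregation = c("mean", "min"),
                             si_pair_rule = c("both", "average"),
                             gate_both_members = FALSE,
                             lazy_scores = TRUE) {
  metrics <- match.arg(metrics, beta_metrics(), several.ok = TRUE)
  algorithms <- match.arg(algorithms, c("pam", "hclust"), several.ok = TRUE)
  stopifnot(length(k_range) == 2, k_range[1] >= 2, k_range[2] >= k_range[1],
            ps_reps >= 1, boot_reps >= 1,
            si_threshold >= 0, si_threshold <= 1,
            ps_threshold >= 0, ps_threshold <= 1,
            jaccard_threshold >= 0, jaccard_threshold <= 1)
  structure(list(k_range = as.integer(k_range), metrics = metrics,
                 algorithms = algorithms, si_threshold = si_threshold,
                 ps_threshold = ps_threshold,
                 jaccard_threshold = jaccard_threshold,
                 ps_reps = as.integer(ps_reps),
                 boot_reps = as.integer(boot_reps),
                 min_cluster_size = as.integer(min_cluster_size),
                 rng_seed = rng_seed,
                 ps_aggregation = match.arg(ps_aggregation),
                 jaccard_aggregation = match.arg(jaccard_aggregation),
                 si_pair_rule = match.arg(si_pair_rule),
                 gate_both_members = isTRUE(gate_both_members),
                 lazy_scores = isTRUE(lazy_scores)),
            class = "selection_config")
}

#' Read a selection configuration from a flat key-value file
#'
#' One `key = value` (or `key: value` / `key<TAB>value`) pair per line,
#' `#` comments allowed; keys mirror the [selection_config()] arguments.
#' List-valued keys (`metrics`, `algorithms`, `k_range`) take
#' comma-separated values.
#'
#' @param path path to the config file.
#' @return a [selection_config()].
#' @export
read_selection_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)[ \t:=]+(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad)) stop("cannot parse config line(s): ",
                        paste(bad, collapse = "; "))
  args <- stats::setNames(lapply(kv, function(m) {
    v <- strsplit(trimws(m[3]), ",[ \t]*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  }), vapply(kv, `[[`, character(1), 2))
  allowed <- names(formals(selection_config))
  unknown <- setdiff(names(args), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(selection_config, args)
}

#' Evaluate the full assessment grid
#'
#' One `assessment_record` per (algorithm, metric, k) combination in the
#' configured grid; distance matrices are computed once per metric and
#' shared.  Failed combinations are recorded (with the reason) in the
#' `failures` attribute rather than silently dropped.
#'
#' @param table a normalized [abundance_table()] with more samples than
#'   the largest k.
#' @param config a [selection_config()].
#' @param scores `"all"` scores every combination eagerly; `"si"` computes
#'   silhouettes only (PS/Jaccard filled lazily during selection).
#' @return list of records, with attributes `distances` (named list of
#'   [distance_matrix()]s) and `failures`.
#' @export
evaluate_grid <- function(table, config = selection_config(),
                          scores = if (config$lazy_scores) "si" else "all") {
  stopifnot(is_abundance_table(table))
  if (!table$normalized)
    stop("evaluate_grid requires a normalized table; run normalize_tss()")
  n <- length(table$sample_ids)
  ks <- seq(config$k_range[1], config$k_range[2])
  if (n <= max(ks))
    stop("need more samples (", n, ") than the largest k (", max(ks), ")")
  distances <- lapply(stats::setNames(config$metrics, config$metrics),
                      function(m) distance_matrix(table, m))
  records <- list()
  failures <- list()
  for (alg in config$algorithms) for (m in config$metrics) for (k in ks) {
    rec <- tryCatch(
      assess_combination(table, m, alg, k, config, D = distances[[m]],
                         scores = scores),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1]] <-
        list(algorithm_id = alg, metric_id = m, k = k,
             reason = conditionMessage(rec))
      message("grid combination failed (", alg, ", ", m, ", k=", k, "): ",
              conditionMessage(rec))
    } else records[[length(records) + 1]] <- rec
  }
  attr(records, "distances") <- distances
  attr(records, "failures") <- failures
  records
}

#' Count scored clustering executions for a grid
#'
#' Under the published defaults each combination costs 201 assessment
#' scores (1 silhouette + 100 prediction-strength + 100 bootstrap), so the
#' default grid of 90 combinations plans 18,090 scored executions.
#' `realized` counts only the scores actually computed (lazy mode scores
#' PS/Jaccard on demand).
#'
#' @param records list from [evaluate_grid()].
#' @param config the [selection_config()] used.
#' @return list with `planned` and `realized` counts.
#' @export
scored_executions <- function(records, config = selection_config()) {
  per <- 1 + config$ps_reps + config$boot_reps
  realized <- sum(vapply(records, function(r)
    1 + (!is.na(r$ps_mean)) * config$ps_reps +
      (!is.na(r$jaccard_mean)) * config$boot_reps, numeric(1)))
  list(planned = length(records) * per, realized = realized)
}

record_key <- function(alg, m, k) paste(alg, m, k, sep = ":")

#' Apply the three-criterion decision algorithm
#'
#' Candidates are all (unordered metric pair, k) whose silhouettes pass
#' the silhouette gate, ranked by pair-average silhouette (ties: smaller
#' k, then lexicographic pair).  Scanning in rank order, a candidate is
#' accepted when its higher-silhouette member passes the prediction
#' strength gate OR the Jaccard stability gate, and its full-data
#' partition contains no cluster smaller than `min_cluster_size`.  The
#' accepted member's partition supplies the state labels; if no candidate
#' passes, the outcome is the explicit `"none"`.
#'
#' @param records list from [evaluate_grid()] (>= 2 metrics for the
#'   algorithm).
#' @param config a [selection_config()].
#' @param algorithm_id which algorithm's records to select from.
#' @param distances named list of [distance_matrix()]s (needed to fill
#'   PS/Jaccard lazily; taken from `records`' attribute when present).
#' @return a `robust_states` object: `outcome` (`"selected"` or
#'   `"none"`), chosen and partner metrics, k, labels, the gate values,
#'   and the full `decision_trail` data.frame.
#' @export
select_states <- function(records, config = selection_config(),
                          algorithm_id = "pam",
                          distances = attr(records, "distances")) {
  recs <- Filter(function(r) r$algorithm_id == algorithm_id, records)
  if (!length(recs)) stop("no records for algorithm ", algorithm_id)
  idx <- stats::setNames(seq_along(recs), vapply(recs, function(r)
    record_key(r$algorithm_id, r$metric_id, r$k), character(1)))
  mets <- sort(unique(vapply(recs, `[[`, character(1), "metric_id")))
  if (length(mets) < 2)
    stop("selection needs records for at least 2 metrics")
  ks <- sort(unique(vapply(recs, `[[`, numeric(1), "k")))
  get_rec <- function(m, k) {
    i <- idx[record_key(algorithm_id, m, k)]
    if (is.na(i)) NULL else recs[[i]]
  }
  ## enumerate candidates passing the silhouette gate
  cand <- list()
  pairs <- utils::combn(mets, 2, simplify = FALSE)
  for (k in ks) for (p in pairs) {
    r1 <- get_rec(p[1], k); r2 <- get_rec(p[2], k)
    if (is.null(r1) || is.null(r2)) next
    si <- c(r1$si, r2$si)
    pass <- if (config$si_pair_rule == "both") all(si > config$si_threshold)
    else mean(si) > config$si_threshold
    if (!pass) next
    hi <- if (si[2] > si[1]) 2 else 1         # tie -> lexicographic first
    cand[[length(cand) + 1]] <- list(
      pair = p, k = k, si = si, avg = mean(si), member = p[hi],
      partner = p[-hi][1], si_member = si[hi])
  }
  trail <- data.frame()
  outcome <- NULL
  if (length(cand)) {
    ord <- order(-vapply(cand, `[[`, numeric(1), "avg"),
                 vapply(cand, `[[`, numeric(1), "k"),
                 vapply(cand, function(c) paste(c$pair, collapse = "+"),
                        character(1)))
    for (ci in ord) {
      cc <- cand[[ci]]
      members <- if (config$gate_both_members) cc$pair else cc$member
      ps_vals <- jac_vals <- rep(NA_real_, length(members))
      sizes <- NULL; accepted <- FALSE; reason <- ""
      gate_ok <- TRUE
      for (mi in seq_along(members)) {
        r <- get_rec(members[mi], cc$k)
        if (is.null(sizes)) sizes <- r$cluster_sizes
        if (min(r$cluster_sizes) < config$min_cluster_size) {
          gate_ok <- FALSE
          reason <- sprintf("cluster smaller than %d (sizes %s)",
                            config$min_cluster_size,
                            paste(r$cluster_sizes, collapse = "/"))
          break
        }
        D <- distances[[members[mi]]]
        if (is.na(r$ps_mean)) {
          if (is.null(D)) stop("distance matrix for ", members[mi],
                               " unavailable for lazy scoring")
          r <- fill_scores_ps(r, D, config)
        }
        ps_vals[mi] <- r$ps_mean
        ps_ok <- r$ps_mean > config$ps_threshold
        if (!ps_ok || mi == 1) {
          ## Jaccard: needed as fallback gate, and always reported for the
          ## gating member of a candidate that survives the PS gate
          if (is.na(r$jaccard_mean)) {
            if (is.null(D)) stop("distance matrix for ", members[mi],
                                 " unavailable for lazy scoring")
            r <- fill_scores_jaccard(r, D, config)
          }
          jac_vals[mi] <- r$jaccard_mean
        }
        recs[[idx[record_key(algorithm_id, members[mi], cc$k)]]] <- r
        jac_ok <- !is.na(jac_vals[mi]) &&
          jac_vals[mi] >= config$jaccard_threshold
        if (!(ps_ok || jac_ok)) {
          gate_ok <- FALSE
          reason <- sprintf("PS %.3f <= %.2f and Jaccard %.3f < %.2f (%s)",
                            r$ps_mean, config$ps_threshold, jac_vals[mi],
                            config$jaccard_threshold, members[mi])
          break
        }
      }
      if (gate_ok) { accepted <- TRUE; reason <- "all gates passed" }
      trail <- rbind(trail, data.frame(
        metric_1 = cc$pair[1], metric_2 = cc$pair[2], k = cc$k,
        si_1 = cc$si[1], si_2 = cc$si[2], si_average = cc$avg,
        gating_metric = cc$member, ps = ps_vals[1], jaccard = jac_vals[1],
        cluster_sizes = paste(sizes, collapse = "/"),
        accepted = accepted, reason = reason, stringsAsFactors = FALSE))
      if (accepted) {
        r <- get_rec(cc$member, cc$k)
        outcome <- list(outcome = "selected", algorithm_id = algorithm_id,
                        chosen_metric = cc$member, partner_metric = cc$partner,
                        k = cc$k, labels = canonicalize_labels(r$labels),
                        si_pair_average = cc$avg, si_member = cc$si_member,
                        ps_value = ps_vals[1], jaccard_value = jac_vals[1],
                        cluster_sizes = r$cluster_sizes)
        break
      }
    }
  }
  if (is.null(outcome))
    outcome <- list(outcome = "none", algorithm_id = algorithm_id,
                    chosen_metric = NA_character_,
                    partner_metric = NA_character_, k = NA_integer_,
                    labels = NULL, si_pair_average = NA_real_,
                    ps_value = NA_real_, jaccard_value = NA_real_)
  outcome$decision_trail <- trail
  outcome$config <- config
  attr(outcome, "records") <- recs
  class(outcome) <- "robust_states"
  outcome
}

fill_scores_ps <- function(rec, D, config) {
  rec$ps_mean <- prediction_strength(
    D, rec$k, rec$algorithm_id, reps = config$ps_reps,
    seed = comb_seed(config$rng_seed, rec$metric_id, rec$algorithm_id,
                     rec$k, "ps"),
    aggregation = config$ps_aggregation)
  rec
}

fill_scores_jaccard <- function(rec, D, config) {
  js <- jaccard_stability(
    D, rec$k, rec$algorithm_id, boot_reps = config$boot_reps,
    seed = comb_seed(config$rng_seed, rec$metric_id, rec$algorithm_id,
                     rec$k, "jaccard"),
    aggregation = config$jaccard_aggregation, labels = rec$labels)
  rec$jaccard_per_cluster <- js$per_cluster
  rec$jaccard_mean <- js$aggregate
  rec
}

#' @export
print.robust_states <- function(x, ...) {
  if (identical(x$outcome, "selected")) {
    cat(sprintf(paste0("robust_states (%s): k = %d via {%s, %s} ",
                       "(SI pair avg %.3f; PS %.3f; Jaccard %s)\n"),
                x$algorithm_id, x$k, x$chosen_metric, x$partner_metric,
                x$si_pair_average, x$ps_value,
                ifelse(is.na(x$jaccard_value), "-",
                       sprintf("%.3f", x$jaccard_value))))
    cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  } else {
    cat(sprintf("robust_states (%s): no robust states (%d candidate(s) %s)\n",
                x$algorithm_id, nrow(x$decision_trail),
                if (nrow(x$decision_trail)) "rejected" else "passed the SI gate"))
  }
  invisible(x)
}

#' Run the full state-typing pipeline
#'
#' Normalizes the table if needed, evaluates the assessment grid and
#' applies the decision algorithm separately per configured algorithm.
#' The headline outcome is PAM's whenever PAM is configured.
#'
#' @param table an [abundance_table()]; raw counts are total-sum scaled.
#' @param config a [selection_config()].
#' @return a `state_typing` list: per-algorithm `robust_states`, the
#'   record list (`records`), the scored-execution counters
#'   (`executions`), and the config.
#' @export
run_pipeline <- function(table, config = selection_config()) {
  stopifnot(is_abundance_table(table))
  if (!table$normalized) table <- normalize_tss(table)
  records <- evaluate_grid(table, config)
  distances <- attr(records, "distances")
  results <- list()
  for (alg in config$algorithms) {
    res <- select_states(records, config, alg, distances)
    ## keep lazily computed scores for the shared report
    upd <- attr(res, "records")
    keys <- vapply(records, function(r)
      record_key(r$algorithm_id, r$metric_id, r$k), character(1))
    for (r in upd)
      records[[match(record_key(r$algorithm_id, r$metric_id, r$k), keys)]] <- r
    attr(res, "records") <- NULL
    results[[alg]] <- res
  }
  attr(records, "distances") <- distances
  structure(list(results = results,
                 headline = if ("pam" %in% names(results)) results$pam
                 else results[[1]],
                 records = records,
                 executions = scored_executions(records, config),
                 config = config),
            class = "state_typing")
}

#' @export
print.state_typing <- function(x, ...) {
  cat("state_typing across", length(x$results), "algorithm(s):\n")
  for (r in x$results) { cat("  "); print(r) }
  invisible(x)
}
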