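#' Specification for synthetic state-structured datasets
#'
#' Describes a multi-subject, optionally longitudinal microbiome study
#' with `n_states` latent community states.  Each state is a
#' Dirichlet-multinomial taxon profile: a baseline Dirichlet concentration
#' `base_concentration` per taxon, multiplied by `1 + separation` on that
#' state's disjoint block of signature taxa.  Samples draw a composition
#' from their state's Dirichlet and, at finite `depth`, multinomial counts
#' that are then re-normalized.
#'
#' @param n_states number of latent states (>= 1).
#' @param samples_per_state integer vector (recycled to `n_states`).
#' @param n_taxa total number of taxa.
#' @param separation fold-enrichment of signature taxa (0 = null model:
#'   all states identically distributed).
#' @param signature_fraction fraction of taxa given to each state's
#'   signature block (blocks are disjoint).
#' @param base_concentration baseline Dirichlet concentration per taxon.
#' @param depth sequencing depth (multinomial draws per sample); `Inf`
#'   returns exact Dirichlet compositions.
#' @param longitudinal optional list `(n_subjects, timepoints,
#'   transition)` where `transition` is an `n_states` x `n_states`
#'   row-stochastic matrix; overrides `samples_per_state`.
#' @param seed integer seed; same seed, same dataset, bit for bit.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_states = 3, samples_per_state = 40,
                           n_taxa = 200, separation = 50,
                           signature_fraction = 0.1,
                           base_concentration = 0.1, depth = 1e4,
                           longitudinal = NULL, seed = 1) {
  samples_per_state <- rep_len(as.integer(samples_per_state), n_states)
  stopifnot(n_states >= 1, all(samples_per_state > 0), n_taxa >= 2,
            separation >= 0, signature_fraction >= 0,
            base_concentration > 0, depth > 0)
  if (n_states * max(1L, floor(signature_fraction * n_taxa)) > n_taxa &&
      separation > 0)
    stop("signature blocks exceed n_taxa")
  if (!is.null(longitudinal)) {
    stopifnot(all(c("n_subjects", "timepoints", "transition") %in%
                    names(longitudinal)))
    tm <- as.matrix(longitudinal$transition)
    if (nrow(tm) != n_states || ncol(tm) != n_states ||
        any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
      stop("transition matrix must be row-stochastic n_states x n_states")
  }
  structure(list(n_states = as.integer(n_states),
                 samples_per_state = samples_per_state,
                 n_taxa = as.integer(n_taxa), separation = separation,
                 signature_fraction = signature_fraction,
                 base_concentration = base_concentration, depth = depth,
                 longitudinal = longitudinal, seed = as.integer(seed)),
            class = "synthetic_spec")
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) { g <- alpha }       # guard against all-zero draws
  g / sum(g)
}

state_alphas <- function(spec) {
  block <- max(1L, floor(spec$signature_fraction * spec$n_taxa))
  alphas <- matrix(spec$base_concentration, spec$n_states, spec$n_taxa)
  if (spec$separation > 0) {
    for (s in seq_len(spec$n_states)) {
      cols <- ((s - 1) * block + 1):(s * block)
      alphas[s, cols] <- spec$base_concentration * (1 + spec$separation)
    }
  }
  alphas
}

synthetic_taxonomy <- function(n_taxa) {
  genus <- (seq_len(n_taxa) - 1) %/% 4 + 1   # 4 pseudo-species per genus
  stats::setNames(sprintf(
    "k__Bacteria;p__P%02d;c__C%02d;o__O%02d;f__F%02d;g__G%03d;s__S%04d",
    (genus - 1) %/% 16 + 1, (genus - 1) %/% 8 + 1, (genus - 1) %/% 4 + 1,
    (genus - 1) %/% 2 + 1, genus, seq_len(n_taxa)),
    sprintf("OTU%04d", seq_len(n_taxa)))
}

draw_samples <- function(spec, states, sample_ids) {
  alphas <- state_alphas(spec)
  vals <- t(vapply(states, function(s) {
    p <- rdirichlet_one(alphas[s, ])
    if (is.finite(spec$depth)) {
      cnt <- as.numeric(stats::rmultinom(1, size = spec$depth, prob = p))
      if (sum(cnt) > 0) cnt / sum(cnt) else p
    } else p
  }, numeric(spec$n_taxa)))
  rownames(vals) <- sample_ids
  colnames(vals) <- sprintf("OTU%04d", seq_len(spec$n_taxa))
  vals
}

#' Generate a cross-sectional dataset with planted states
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a normalized [abundance_table()] carrying a
#'   synthetic taxonomy) and `true_labels` (named integer vector).
#' @export
generate_states_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    states <- rep(seq_len(spec$n_states), spec$samples_per_state)
    ids <- sprintf("S%03d", seq_along(states))
    vals <- draw_samples(spec, states, ids)
    table <- abundance_table(vals, taxonomy = synthetic_taxonomy(spec$n_taxa),
                             normalized = TRUE)
    list(table = table, true_labels = stats::setNames(states, ids))
  })
}

#' Generate a longitudinal dataset with Markov state dynamics
#'
#' Each subject follows a Markov chain over the latent states (uniform
#' initial distribution); one sample per subject and timepoint.
#'
#' @param spec a [synthetic_spec()] with the `longitudinal` field set.
#' @return list with `table` (metadata carries `subject_id` and
#'   `time_index`) and `true_labels`.
#' @export
generate_longitudinal_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), !is.null(spec$longitudinal))
  lg <- spec$longitudinal
  tm <- as.matrix(lg$transition)
  with_seed(spec$seed, {
    subj <- rep(seq_len(lg$n_subjects), each = lg$timepoints)
    tidx <- rep(seq_len(lg$timepoints), lg$n_subjects)
    states <- integer(length(subj))
    for (s in seq_len(lg$n_subjects)) {
      st <- sample.int(spec$n_states, 1)
      for (t in seq_len(lg$timepoints)) {
        states[(s - 1) * lg$timepoints + t] <- st
        st <- sample.int(spec$n_states, 1, prob = tm[st, ])
      }
    }
    ids <- sprintf("S%03d.T%02d", subj, tidx)
    vals <- draw_samples(spec, states, ids)
    md <- data.frame(sample_id = ids,
                     subject_id = sprintf("subj%02d", subj),
                     time_index = tidx, stringsAsFactors = FALSE)
    table <- abundance_table(vals, taxonomy = synthetic_taxonomy(spec$n_taxa),
                             metadata = md, normalized = TRUE)
    list(table = table, true_labels = stats::setNames(states, ids))
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 means identical partitions, 0 is the expected agreement of random
#' labelings.
#'
#' @param a,b label vectors of equal length (names ignored; order
#'   aligned).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(n, 2)
  max_ <- (si + sj) / 2
  if (max_ == exp_) return(1)
  (sij - exp_) / (max_ - exp_)
}
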