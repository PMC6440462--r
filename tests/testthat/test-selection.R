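make_grid_records <- function(...) {
  recs <- list(...)
  attr(recs, "distances") <- NULL
  recs
}

test_that("the top SI pair passing PS is selected (narrative case)", {
  recs <- make_grid_records(
    fake_record("jsd", 3, 0.60, ps = 0.95, jaccard = 0.90),
    fake_record("rjsd", 3, 0.58, ps = 0.90, jaccard = 0.90),
    fake_record("braycurtis", 3, 0.20, ps = 0.50, jaccard = 0.50),
    fake_record("morisitahorn", 3, 0.20, ps = 0.50, jaccard = 0.50),
    fake_record("kulczynski", 3, 0.20, ps = 0.50, jaccard = 0.50),
    fake_record("jsd", 2, 0.24, ps = 0.99, jaccard = 0.99),
    fake_record("rjsd", 2, 0.24, ps = 0.99, jaccard = 0.99))
  out <- select_states(recs, selection_config(), "pam")
  expect_equal(out$outcome, "selected")
  expect_equal(out$k, 3)
  expect_equal(out$chosen_metric, "jsd")       # higher-SI pair member
  expect_equal(out$partner_metric, "rjsd")
  expect_equal(out$si_pair_average, 0.59)
  expect_equal(out$ps_value, 0.95)
  expect_identical(out$labels,
                   recs[[1]]$labels)
  expect_true(any(out$decision_trail$accepted))
})

test_that("no candidate above the SI gate yields the explicit none", {
  recs <- make_grid_records(
    fake_record("jsd", 2, 0.25, ps = 0.99, jaccard = 0.99),
    fake_record("rjsd", 2, 0.20, ps = 0.99, jaccard = 0.99))
  out <- select_states(recs, selection_config(), "pam")
  expect_equal(out$outcome, "none")
  expect_equal(nrow(out$decision_trail), 0)
  expect_error(select_states(make_grid_records(
    fake_record("jsd", 2, 0.5)), selection_config(), "pam"), "2 metrics")
})

test_that("a failed gate falls through to the next candidate in the trail", {
  recs <- make_grid_records(
    fake_record("jsd", 3, 0.60, ps = 0.50, jaccard = 0.60),
    fake_record("rjsd", 3, 0.58, ps = 0.50, jaccard = 0.60),
    fake_record("braycurtis", 4, 0.50, ps = 0.60, jaccard = 0.80),
    fake_record("morisitahorn", 4, 0.45, ps = 0.60, jaccard = 0.60))
  out <- select_states(recs, selection_config(), "pam")
  expect_equal(out$outcome, "selected")
  expect_equal(out$k, 4)
  expect_equal(out$chosen_metric, "braycurtis")  # accepted via Jaccard
  expect_equal(out$jaccard_value, 0.8)
  tr <- out$decision_trail
  expect_equal(nrow(tr), 2)
  expect_false(tr$accepted[1])
  expect_match(tr$reason[1], "PS")
  expect_true(tr$accepted[2])
})

test_that("solutions containing a cluster smaller than 5 are rejected", {
  recs <- make_grid_records(
    fake_record("jsd", 3, 0.60, ps = 0.95, jaccard = 0.95,
                sizes = c(20, 6, 4)),
    fake_record("rjsd", 3, 0.58, ps = 0.95, jaccard = 0.95,
                sizes = c(20, 6, 4)),
    fake_record("jsd", 2, 0.40, ps = 0.95, jaccard = 0.95,
                sizes = c(20, 10)),
    fake_record("rjsd", 2, 0.35, ps = 0.95, jaccard = 0.95,
                sizes = c(20, 10)))
  out <- select_states(recs, selection_config(), "pam")
  expect_equal(out$k, 2)
  expect_match(out$decision_trail$reason[1], "smaller than 5")
  # the gate is configurable
  out2 <- select_states(recs, selection_config(min_cluster_size = 1), "pam")
  expect_equal(out2$k, 3)
})

test_that("threshold monotonicity: stricter gates never invent a selection", {
  recs <- make_grid_records(
    fake_record("jsd", 3, 0.45, ps = 0.82, jaccard = 0.70),
    fake_record("rjsd", 3, 0.40, ps = 0.70, jaccard = 0.70),
    fake_record("jsd", 2, 0.30, ps = 0.60, jaccard = 0.60),
    fake_record("rjsd", 2, 0.28, ps = 0.60, jaccard = 0.60))
  loose <- select_states(recs, selection_config(), "pam")
  expect_equal(loose$outcome, "selected")
  # raising PS and Jaccard gates can only flip selected -> none, and the
  # full rejection trail then exposes the whole candidate set
  strict_cfg <- selection_config(ps_threshold = 0.99,
                                 jaccard_threshold = 0.99)
  strict <- select_states(recs, strict_cfg, "pam")
  expect_equal(strict$outcome, "none")
  expect_gte(nrow(strict$decision_trail), nrow(loose$decision_trail))
  # lowering the SI threshold never shrinks the candidate set
  looser_si <- select_states(recs, selection_config(
    si_threshold = 0.1, ps_threshold = 0.99, jaccard_threshold = 0.99),
    "pam")
  expect_gte(nrow(looser_si$decision_trail), nrow(strict$decision_trail))
})

test_that("a flat key-value file round-trips into a selection_config", {
  f <- withr::local_tempfile(lines = c(
    "# thresholds", "si_threshold = 0.3", "ps_threshold: 0.9",
    "k_range = 2, 5", "metrics = jsd, braycurtis", "algorithms = pam",
    "ps_reps\t7", "rng_seed = 99"))
  cfg <- read_selection_config(f)
  expect_equal(cfg$si_threshold, 0.3)
  expect_equal(cfg$ps_threshold, 0.9)
  expect_equal(cfg$k_range, c(2L, 5L))
  expect_equal(cfg$metrics, c("jsd", "braycurtis"))
  expect_equal(cfg$algorithms, "pam")
  expect_equal(cfg$ps_reps, 7L)
  expect_equal(cfg$rng_seed, 99)
  bad <- withr::local_tempfile(lines = "frobnicate = 1")
  expect_error(read_selection_config(bad), "unknown config key")
})

test_that("evaluate_grid covers the configured grid and counts executions", {
  ds <- generate_states_dataset(synthetic_spec(
    n_states = 2, samples_per_state = 8, n_taxa = 50, seed = 6))
  cfg <- selection_config(k_range = c(2, 3), metrics = c("jsd", "braycurtis"),
                          algorithms = "pam", ps_reps = 4, boot_reps = 4,
                          rng_seed = 2, lazy_scores = FALSE)
  recs <- evaluate_grid(ds$table, cfg)
  expect_length(recs, 4)   # 1 algorithm x 2 metrics x 2 k values
  ex <- scored_executions(recs, cfg)
  expect_equal(ex$planned, 4 * (1 + 4 + 4))
  expect_equal(ex$realized, ex$planned)
  # lazy mode realizes only silhouettes until selection asks for more
  cfg2 <- selection_config(k_range = c(2, 3),
                           metrics = c("jsd", "braycurtis"),
                           algorithms = "pam", ps_reps = 4, boot_reps = 4,
                           rng_seed = 2)
  recs2 <- evaluate_grid(ds$table, cfg2)
  expect_equal(scored_executions(recs2, cfg2)$realized, 4)
  expect_error(evaluate_grid(ds$table, selection_config(k_range = c(2, 20))),
               "largest k")
})

test_that("run_pipeline is reproducible and reports per algorithm", {
  ds <- generate_states_dataset(synthetic_spec(
    n_states = 3, samples_per_state = 10, n_taxa = 80, seed = 12))
  cfg <- selection_config(ps_reps = 10, boot_reps = 10, rng_seed = 42)
  res <- run_pipeline(ds$table, cfg)
  expect_named(res$results, c("pam", "hclust"))
  expect_equal(res$headline$algorithm_id, "pam")
  expect_equal(res$headline$outcome, "selected")
  expect_equal(res$headline$k, 3)
  expect_gte(adjusted_rand_index(res$headline$labels, ds$true_labels), 0.9)
  res2 <- run_pipeline(ds$table, cfg)
  expect_identical(res$headline$labels, res2$headline$labels)
  expect_identical(res$results$pam$decision_trail,
                   res2$results$pam$decision_trail)
})
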