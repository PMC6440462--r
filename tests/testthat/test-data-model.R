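test_that("abundance_table enforces its invariants", {
  m <- matrix(1:6, 2, 3)
  t1 <- abundance_table(m, sample_ids = c("a", "b"))
  expect_equal(dim(t1), c(2, 3))
  expect_error(abundance_table(matrix(c(1, -1, 0, 2), 2)), "negative")
  expect_error(abundance_table(matrix(c(1, NA, 0, 2), 2)), "non-finite")
  expect_error(abundance_table(m, sample_ids = c("a", "a")), "duplicate")
  expect_error(abundance_table(m, taxon_ids = c("x", "x", "y")), "duplicate")
  expect_error(
    abundance_table(m, metadata = data.frame(sample_id = "zz")), "unknown")
  expect_error(abundance_table(m, normalized = TRUE), "row sums")
})

test_that("normalize_tss rescales, is idempotent, and rejects zero rows", {
  t1 <- abundance_table(rbind(c(2, 3, 5), c(4, 6, 0)))
  n1 <- normalize_tss(t1)
  expect_equal(unname(n1$values[1, ]), c(0.2, 0.3, 0.5))
  expect_true(n1$normalized)
  expect_equal(normalize_tss(n1)$values, n1$values)
  expect_equal(n1$values[, colnames(t1$values)][2, 1], 0.4)  # order preserved
  t0 <- abundance_table(rbind(c(1, 1), c(0, 0)), sample_ids = c("ok", "bad"))
  expect_error(normalize_tss(t0), "bad")
})

test_that("filter_dominance thresholds on mean abundance and partitions taxa", {
  v <- rbind(c(0.65, 0.34, 0.01), c(0.55, 0.45, 0.00))
  tab <- abundance_table(v, taxon_ids = c("t1", "t2", "t3"),
                         normalized = TRUE)
  # means: 0.60, 0.395, 0.005
  dom <- filter_dominance(tab, 0.01, "dominant", renormalize = FALSE)
  nd <- filter_dominance(tab, 0.01, "nondominant", renormalize = FALSE)
  expect_equal(dom$taxon_ids, c("t1", "t2"))
  expect_equal(nd$taxon_ids, "t3")
  expect_setequal(c(dom$taxon_ids, nd$taxon_ids), tab$taxon_ids)
  # unrenormalized outputs are submatrices of the input
  expect_equal(dom$values, tab$values[, 1:2])
  # renormalized rows sum to 1
  expect_equal(rowSums(filter_dominance(tab, 0.01, "dominant")$values),
               c(S1 = 1, S2 = 1))
  expect_error(filter_dominance(tab, 0.99, "dominant"), "empty selection")
  expect_error(filter_dominance(normalize_tss(abundance_table(v * 7))),
               NA)  # raw input normalized first is fine
  expect_error(filter_dominance(abundance_table(v * 7)), "normalized")
})

test_that("aggregate_taxa sums lineages, conserves mass, handles gaps", {
  v <- rbind(c(0.2, 0.3, 0.5), c(0.1, 0.1, 0.8))
  taxo <- c(t1 = "k__B;p__P1;c__C;o__O;f__F;g__A;s__x",
            t2 = "k__B;p__P1;c__C;o__O;f__F;g__A;s__y",
            t3 = "k__B;p__P1;c__C;o__O;f__F;g__B;s__z")
  tab <- abundance_table(v, taxon_ids = names(taxo), taxonomy = taxo,
                         normalized = TRUE)
  g <- aggregate_taxa(tab, "genus")
  expect_equal(ncol(g$values), 2)
  expect_equal(unname(g$values[1, ]), c(0.5, 0.5))
  expect_equal(unname(g$values[2, ]), c(0.2, 0.8))
  # all taxa in one phylum collapses to a single total-mass taxon
  p <- aggregate_taxa(tab, "phylum")
  expect_equal(unname(p$values[, 1]), c(1, 1))
  # unannotated taxa: dropped mass is renormalized away, or pooled
  taxo2 <- taxo; taxo2["t3"] <- "k__B;p__P1;c__C;o__O;f__F;g__;s__"
  tab2 <- abundance_table(v, taxon_ids = names(taxo2), taxonomy = taxo2,
                          normalized = TRUE)
  g2 <- aggregate_taxa(tab2, "genus", renormalize = FALSE)
  expect_equal(unname(g2$values[1, ]), 0.5)  # annotated mass conserved
  g2p <- aggregate_taxa(tab2, "genus", unannotated = "pool")
  expect_true("unclassified" %in% g2p$taxon_ids)
  expect_equal(rowSums(g2p$values), c(S1 = 1, S2 = 1))
  # no taxonomy at all
  tab3 <- abundance_table(v, normalized = TRUE)
  expect_error(aggregate_taxa(tab3, "genus"), "taxonomic data")
})

test_that("BIOM and TSV files round-trip values and ids", {
  fix <- system.file("extdata", "minimal.biom", package = "mbstates")
  tab <- read_abundance(fix)
  expect_equal(dim(tab), c(2, 3))
  expect_equal(tab$sample_ids, c("SampleA", "SampleB"))
  expect_equal(tab$taxon_ids, c("OTU1", "OTU2", "OTU3"))
  expect_equal(unname(tab$values["SampleA", ]), c(5, 3, 2))
  expect_false(tab$normalized)
  expect_match(tab$taxonomy[["OTU1"]], "Blautia")

  tmp <- withr::local_tempdir()
  # TSV round trip
  p1 <- file.path(tmp, "t.tsv")
  write_abundance_tsv(tab, p1)
  back <- read_abundance(p1)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(back$taxonomy[["OTU3"]], tab$taxonomy[["OTU3"]])
  # BIOM (JSON dialect) round trip
  p2 <- file.path(tmp, "t.biom")
  write_abundance_biom(tab, p2)
  back2 <- read_abundance(p2)
  expect_equal(back2$values[tab$sample_ids, tab$taxon_ids], tab$values,
               tolerance = 1e-12)
  # rows summing to 1 are flagged normalized
  p3 <- file.path(tmp, "n.tsv")
  write_abundance_tsv(normalize_tss(tab), p3)
  expect_true(read_abundance(p3)$normalized)
  # negative value rejected, garbage rejected
  writeLines("taxon_id\tS1\tS2\nOTU1\t-1\t2", file.path(tmp, "neg.tsv"))
  expect_error(read_abundance(file.path(tmp, "neg.tsv")), "negative")
  writeLines("{not biom", file.path(tmp, "bad.biom"))
  expect_error(read_abundance(file.path(tmp, "bad.biom")), "BIOM")
})

test_that("metadata merges by sample id with empty rows for the unlisted", {
  tab <- abundance_table(matrix(1:4, 2), sample_ids = c("a", "b"))
  md <- data.frame(sample_id = c("b", "zz"), subject_id = c("s1", "s9"),
                   time_index = c(3L, 1L))
  expect_warning(tab2 <- attach_metadata(tab, md), "zz")
  expect_equal(tab2$metadata$subject_id, c(NA, "s1"))
  expect_equal(tab2$metadata$time_index, c(NA, 3L))
})

test_that("write_assignments canonicalizes and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  labs <- stats::setNames(c(2L, 2L, 1L), c("x", "y", "z"))
  write_assignments(labs, tmp)
  back <- read.csv(tmp)
  expect_equal(names(back), c("sampleID", "clusterID"))
  expect_equal(back$clusterID, c(1, 1, 2))   # first-appearing cluster is 1
  expect_equal(back$sampleID, c("x", "y", "z"))
  none <- structure(list(outcome = "none"), class = "robust_states")
  expect_error(write_assignments(none, tmp), "no robust states")
  expect_error(write_assignments(integer(0), tmp), "empty")
})
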