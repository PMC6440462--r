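#' Construct an abundance table
#'
#' The single input currency of the package: a samples x taxa matrix of
#' non-negative abundances (raw counts or relative abundances), with
#' optional taxonomy per taxon and per-sample metadata.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.  Row and
#'   column names, when present, seed `sample_ids` / `taxon_ids`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param taxon_ids character vector of unique taxon identifiers.
#' @param taxonomy optional named character vector or list mapping taxon id
#'   to a semicolon-delimited ranked lineage (kingdom..species).
#' @param metadata optional data.frame with a `sample_id` column and free
#'   additional columns; `subject_id` and `time_index` are understood by the
#'   longitudinal tooling.
#' @param normalized logical; `TRUE` declares every row sums to 1.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values), taxonomy = NULL,
                            metadata = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  storage.mode(values) <- "double"
  dimnames(values) <- list(sample_ids, taxon_ids)
  if (!is.null(taxonomy)) {
    taxonomy <- vapply(taxonomy, paste, character(1), collapse = ";")
    if (is.null(names(taxonomy)) && length(taxonomy) == length(taxon_ids))
      names(taxonomy) <- taxon_ids
    taxonomy <- taxonomy[names(taxonomy) %in% taxon_ids]
  }
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  }
  obj <- structure(list(values = values, sample_ids = sample_ids,
                        taxon_ids = taxon_ids, taxonomy = taxonomy,
                        metadata = metadata, normalized = isTRUE(normalized)),
                   class = "abundance_table")
  validate_abundance_table(obj)
  obj
}

#' @rdname abundance_table
#' @param x object to validate / test.
#' @export
validate_abundance_table <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  v <- x$values
  if (any(!is.finite(v)))
    stop("abundance table contains non-finite entries")
  if (any(v < 0))
    stop("abundance table contains negative entries")
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  if (anyDuplicated(x$taxon_ids))
    stop("duplicate taxon ids: ",
         paste(unique(x$taxon_ids[duplicated(x$taxon_ids)]), collapse = ", "))
  if (nrow(v) != length(x$sample_ids) || ncol(v) != length(x$taxon_ids))
    stop("matrix dimensions do not match id lists")
  if (!is.null(x$metadata)) {
    if (!"sample_id" %in% names(x$metadata))
      stop("metadata lacks a sample_id column")
    bad <- setdiff(x$metadata$sample_id, x$sample_ids)
    if (length(bad))
      stop("metadata refers to unknown sample ids: ",
           paste(bad, collapse = ", "))
  }
  if (x$normalized) {
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-9))
      stop("table flagged normalized but row sums deviate from 1 by up to ",
           format(max(abs(rs - 1))))
  }
  invisible(x)
}

#' @rdname abundance_table
#' @export
is_abundance_table <- function(x) inherits(x, "abundance_table")

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              length(x$sample_ids), length(x$taxon_ids),
              if (x$normalized) "relative abundances" else "raw values"))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy for %d taxa\n", length(x$taxonomy)))
  extra <- setdiff(names(x$metadata), "sample_id")
  if (length(extra))
    cat("  metadata columns:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Total-sum scaling to relative abundances
#'
#' Divides every sample row by its total so compositions sum to 1.
#' Idempotent on already normalized tables.
#'
#' @param table an [abundance_table()].
#' @return the table with `normalized = TRUE`.
#' @export
normalize_tss <- function(table) {
  stopifnot(is_abundance_table(table))
  rs <- rowSums(table$values)
  zero <- which(rs <= 0)
  if (length(zero))
    stop("cannot normalize all-zero sample(s): ",
         paste(table$sample_ids[zero], collapse = ", "))
  table$values <- table$values / rs
  table$normalized <- TRUE
  validate_abundance_table(table)
  table
}

subset_taxa_table <- function(table, keep, renormalize) {
  table$values <- table$values[, keep, drop = FALSE]
  table$taxon_ids <- colnames(table$values)
  if (!is.null(table$taxonomy))
    table$taxonomy <- table$taxonomy[names(table$taxonomy) %in% table$taxon_ids]
  if (renormalize) {
    table <- normalize_tss(table)
  } else {
    table$normalized <- FALSE
  }
  table
}

#' Filter taxa by dominance
#'
#' Keeps the dominant taxa (mean relative abundance across samples at or
#' above `threshold`) or the complementary non-dominant set.  The two modes
#' partition the taxon set exactly.
#'
#' @param table a normalized [abundance_table()].
#' @param threshold dominance cutoff on the chosen statistic, default 0.01
#'   (the "1%" convention).
#' @param mode `"dominant"` keeps taxa passing the cutoff, `"nondominant"`
#'   the complement.
#' @param statistic abundance summary compared to the cutoff: mean (default)
#'   or max across samples.
#' @param renormalize re-scale rows to sum 1 after subsetting (default
#'   `TRUE`); `FALSE` preserves raw subset mass for sensitivity checks.
#' @return filtered abundance table.
#' @export
filter_dominance <- function(table, threshold = 0.01,
                             mode = c("dominant", "nondominant"),
                             statistic = c("mean", "max"),
                             renormalize = TRUE) {
  stopifnot(is_abundance_table(table))
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (!table$normalized)
    stop("filter_dominance requires a normalized table; run normalize_tss()")
  stat <- switch(statistic,
                 mean = colMeans(table$values),
                 max = apply(table$values, 2, max))
  keep <- if (mode == "dominant") stat >= threshold else stat < threshold
  if (!any(keep))
    stop("empty selection: no taxa ", if (mode == "dominant") "reach " else
         "fall below ", "the ", threshold, " ", statistic, "-abundance cutoff")
  subset_taxa_table(table, which(keep), renormalize)
}

rank_names <- c("kingdom", "phylum", "class", "order", "family",
                "genus", "species")

split_lineage <- function(lin) {
  parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
  # strip greengenes-style rank prefixes such as "g__"
  parts <- sub("^[a-zA-Z]__", "", parts)
  parts
}

#' Aggregate taxa at a taxonomic rank
#'
#' Sums abundances of taxa sharing the same lineage down to `level`.
#' Taxa lacking an annotation at that rank are dropped by default or pooled
#' into a single `"unclassified"` aggregate.
#'
#' @param table an [abundance_table()] with taxonomy.
#' @param level target rank, one of kingdom, phylum, class, order, family,
#'   genus, species (or a 1-based rank depth).
#' @param unannotated `"drop"` (default) or `"pool"` into "unclassified".
#' @param renormalize re-scale rows to sum 1 afterwards (default `TRUE`).
#' @return aggregated abundance table; aggregate taxon ids are the lineage
#'   prefixes down to `level`.
#' @export
aggregate_taxa <- function(table, level = "genus",
                           unannotated = c("drop", "pool"),
                           renormalize = TRUE) {
  stopifnot(is_abundance_table(table))
  unannotated <- match.arg(unannotated)
  if (is.character(level)) {
    depth <- match(tolower(level), rank_names)
    if (is.na(depth)) stop("unknown taxonomic rank: ", level)
  } else depth <- as.integer(level)
  if (is.null(table$taxonomy) || !length(table$taxonomy))
    stop("not enough taxonomic data: table carries no taxonomy")
  lineages <- lapply(table$taxon_ids, function(id) {
    lin <- table$taxonomy[[id]]
    if (is.null(lin) || is.na(lin)) character(0) else split_lineage(lin)
  })
  key <- vapply(lineages, function(p) {
    if (length(p) >= depth && nzchar(p[depth]))
      paste(p[seq_len(depth)], collapse = ";") else NA_character_
  }, character(1))
  if (all(is.na(key)))
    stop("not enough taxonomic data: no taxon annotated at rank ", level)
  if (unannotated == "pool") key[is.na(key)] <- "unclassified"
  keep <- !is.na(key)
  groups <- factor(key[keep], levels = unique(key[keep]))
  agg <- t(rowsum(t(table$values[, keep, drop = FALSE]), groups))
  colnames(agg) <- levels(groups)
  out <- table
  out$values <- agg
  out$taxon_ids <- colnames(agg)
  out$taxonomy <- stats::setNames(colnames(agg), colnames(agg))
  out$normalized <- FALSE
  if (renormalize) out <- normalize_tss(out)
  validate_abundance_table(out)
  out
}
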