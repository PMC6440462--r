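#' Read an abundance table from BIOM or TSV
#'
#' Accepts BIOM v1 (JSON) and v2 (HDF5) files, or a plain TSV OTU table
#' with taxa as rows, samples as columns, and an optional trailing
#' `taxonomy` column of semicolon-delimited ranks.  Counts are flagged
#' normalized only when every sample already sums to 1 within 1e-6.
#'
#' @param path path to the abundance file.
#' @param metadata_path optional TSV of per-sample metadata with a
#'   mandatory `sample_id` column (optional `subject_id`, `time_index`).
#' @param format `"auto"` (by extension, then content), `"biom"` or `"tsv"`.
#' @return an [abundance_table()] (samples x taxa).
#' @export
read_abundance <- function(path, metadata_path = NULL,
                           format = c("auto", "biom", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext == "biom") "biom" else if (ext %in% c("tsv", "txt", "tab"))
      "tsv" else "biom"
  }
  tab <- if (format == "biom") read_abundance_biom(path) else
    read_abundance_tsv(path)
  if (!is.null(metadata_path)) {
    md <- read_sample_metadata(metadata_path)
    tab <- attach_metadata(tab, md)
  }
  rs <- rowSums(tab$values)
  tab$normalized <- all(abs(rs - 1) <= 1e-6)
  if (tab$normalized) tab$values <- tab$values / rs
  validate_abundance_table(tab)
  tab
}

read_abundance_biom <- function(path) {
  b <- tryCatch(biomformat::read_biom(path), error = function(e)
    stop("cannot parse '", path, "' as BIOM (JSON or HDF5 dialect): ",
         conditionMessage(e)))
  m <- as(biomformat::biom_data(b), "matrix")   # taxa x samples
  taxonomy <- NULL
  om <- tryCatch(suppressWarnings(biomformat::observation_metadata(b)),
                 error = function(e) NULL)
  if (!is.null(om)) {
    lin <- if (is.data.frame(om)) apply(om, 1, function(r)
      paste(r[!is.na(r) & nzchar(r)], collapse = ";"))
    else vapply(om, function(r) paste(unlist(r), collapse = ";"), character(1))
    if (length(lin) == nrow(m)) taxonomy <- stats::setNames(lin, rownames(m))
  }
  abundance_table(t(m), taxonomy = taxonomy)
}

read_abundance_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#(?!OTU)", lines, perl = TRUE)]
  lines <- sub("^#OTU ?ID", "taxon_id", lines)
  if (!length(lines)) stop("cannot parse '", path, "' as TSV: empty file")
  df <- tryCatch(
    utils::read.delim(text = lines, check.names = FALSE, row.names = NULL,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "' as a TSV OTU table: ",
                             conditionMessage(e)))
  if (ncol(df) < 2) stop("cannot parse '", path,
                         "' as a TSV OTU table: fewer than 2 columns")
  taxa <- as.character(df[[1]])
  df <- df[-1]
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- stats::setNames(as.character(df[[ncol(df)]]), taxa)
    df <- df[-ncol(df)]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("cannot parse '", path,
                           "' as a TSV OTU table: non-numeric abundances")
  rownames(m) <- taxa
  abundance_table(t(m), taxonomy = taxonomy)
}

#' Read a sample metadata TSV
#'
#' @param path TSV with a mandatory `sample_id` column.
#' @return data.frame; `time_index` is coerced to integer when present.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md))
    stop("metadata file lacks a sample_id column: ", path)
  md$sample_id <- as.character(md$sample_id)
  if ("time_index" %in% names(md))
    md$time_index <- as.integer(md$time_index)
  md
}

#' Attach sample metadata to an abundance table
#'
#' Merged by sample id; samples missing from the metadata keep an empty
#' (all-NA) metadata row.  Metadata rows for unknown samples are dropped
#' with a warning.
#'
#' @param table an [abundance_table()].
#' @param metadata data.frame with a `sample_id` column.
#' @return the table with merged metadata.
#' @export
attach_metadata <- function(table, metadata) {
  stopifnot(is_abundance_table(table), "sample_id" %in% names(metadata))
  unknown <- setdiff(metadata$sample_id, table$sample_ids)
  if (length(unknown)) {
    warning("dropping metadata for unknown sample ids: ",
            paste(unknown, collapse = ", "))
    metadata <- metadata[!metadata$sample_id %in% unknown, , drop = FALSE]
  }
  base <- data.frame(sample_id = table$sample_ids, stringsAsFactors = FALSE)
  md <- merge(base, metadata, by = "sample_id", all.x = TRUE, sort = FALSE)
  md <- md[match(table$sample_ids, md$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  table$metadata <- md
  validate_abundance_table(table)
  table
}

#' Write an abundance table
#'
#' `write_abundance_tsv` writes the TSV OTU-table dialect (taxa rows x
#' sample columns, optional trailing taxonomy column);
#' `write_abundance_biom` writes BIOM v1 (JSON).
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_abundance_tsv <- function(table, path) {
  stopifnot(is_abundance_table(table))
  m <- t(table$values)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy) && length(table$taxonomy))
    df$taxonomy <- unname(table$taxonomy[table$taxon_ids])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
write_abundance_biom <- function(table, path) {
  stopifnot(is_abundance_table(table))
  om <- NULL
  if (!is.null(table$taxonomy) && length(table$taxonomy)) {
    om <- data.frame(taxonomy = unname(table$taxonomy[table$taxon_ids]),
                     row.names = table$taxon_ids, stringsAsFactors = FALSE)
  }
  b <- biomformat::make_biom(data = t(table$values),
                             observation_metadata = om)
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Write sample-to-state assignments
#'
#' CSV with header `sampleID,clusterID`; cluster ids are renumbered so the
#' first-appearing cluster (in sample order) is 1.
#'
#' @param states a `robust_states` outcome from [select_states()] /
#'   [run_pipeline()], or a named vector of cluster labels.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_assignments <- function(states, path) {
  labels <- if (inherits(states, "robust_states")) {
    if (!identical(states$outcome, "selected"))
      stop("no robust states were selected; nothing to write ",
           "(inspect the decision trail, relax thresholds, or filter taxa)")
    states$labels
  } else states
  if (!length(labels)) stop("empty labeling; nothing to write")
  labels <- canonicalize_labels(labels)
  df <- data.frame(sampleID = names(labels), clusterID = unname(labels),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a distance matrix as square TSV
#'
#' @param D a [distance_matrix()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  m <- as.matrix(D$values)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
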