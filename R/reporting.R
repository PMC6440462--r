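#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates on
#' the axes with positive eigenvalue, scaled by the square root of the
#' eigenvalue.  Axis signs are fixed by making each axis's
#' largest-magnitude loading positive, so results are reproducible.
#'
#' @param D a [distance_matrix()].
#' @param dims number of coordinate axes to return (default 2; fewer when
#'   fewer positive eigenvalues exist).
#' @return list with `points` (n x dims matrix, rownames = sample ids),
#'   `eigenvalues` (all n, non-increasing) and `variance_explained` for
#'   the returned axes (relative to the positive eigenvalues).
#' @export
pcoa <- function(D, dims = 2) {
  v <- D$values
  n <- nrow(v)
  if (n < 2) stop("need at least 2 samples")
  B <- -0.5 * v^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- B + mean(-0.5 * v^2)
  ## equivalent to -J (D^2/2) J with J the centering matrix
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-10)
  ndim <- min(dims, length(pos))
  if (ndim == 0) {
    pts <- matrix(0, n, dims)
  } else {
    pts <- e$vectors[, pos[seq_len(ndim)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(ndim)]]), ndim)
    for (j in seq_len(ndim))
      if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
    if (ndim < dims) pts <- cbind(pts, matrix(0, n, dims - ndim))
  }
  rownames(pts) <- D$sample_ids
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  ve <- if (length(pos)) e$values[pos[seq_len(ndim)]] /
    sum(e$values[e$values > 0]) else rep(0, dims)
  list(points = pts, eigenvalues = e$values, variance_explained = ve)
}

metric_palette <- function(metrics) {
  pal <- c(jsd = "#1b9e77", rjsd = "#d95f02", braycurtis = "#7570b3",
           morisitahorn = "#e7298a", kulczynski = "#66a61e")
  out <- pal[metrics]
  out[is.na(out)] <- "grey40"
  stats::setNames(out, metrics)
}

#' Three-panel assessment plot
#'
#' Silhouette, prediction strength and Jaccard stability versus k, one
#' colored line per beta-diversity metric, with dashed gates at the
#' configured thresholds (SI additionally shows the 0.50 "strong cluster"
#' reference).  Missing scores gap the lines.
#'
#' @param records list from [evaluate_grid()] (one algorithm is plotted;
#'   filter or pass `algorithm_id`).
#' @param config a [selection_config()] supplying the threshold lines.
#' @param algorithm_id which algorithm's records to draw.
#' @return invisibly, the tidy data.frame behind the panels.
#' @export
plot_assessment <- function(records, config = selection_config(),
                            algorithm_id = "pam") {
  df <- records_to_df(records)
  df <- df[df$algorithm_id == algorithm_id, , drop = FALSE]
  if (!nrow(df)) stop("no records for algorithm ", algorithm_id)
  mets <- intersect(beta_metrics(), unique(df$metric_id))
  cols <- metric_palette(mets)
  panels <- list(
    list(var = "si", ylab = "Average silhouette width",
         thr = c(config$si_threshold, 0.5), ylim = c(-0.2, 1)),
    list(var = "ps_mean", ylab = "Prediction strength",
         thr = config$ps_threshold, ylim = c(0, 1)),
    list(var = "jaccard_mean", ylab = "Jaccard stability",
         thr = config$jaccard_threshold, ylim = c(0, 1)))
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  for (p in panels) {
    graphics::plot(NA, xlim = range(df$k), ylim = p$ylim, xlab = "k",
                   ylab = p$ylab,
                   main = paste0(toupper(algorithm_id), ""))
    graphics::abline(h = p$thr, lty = 2, col = "grey40")
    for (m in mets) {
      sub <- df[df$metric_id == m, , drop = FALSE]
      sub <- sub[order(sub$k), , drop = FALSE]
      graphics::lines(sub$k, sub[[p$var]], col = cols[m], type = "o",
                      pch = 16, cex = 0.7)
    }
    if (p$var == "si")
      graphics::legend("topright", legend = mets, col = cols[mets], lty = 1,
                       pch = 16, cex = 0.7, bty = "n")
  }
  invisible(df)
}

#' Ordination scatter of samples colored by state
#'
#' @param D a [distance_matrix()] (typically the chosen metric's).
#' @param labels integer state labels named by sample id (e.g. from a
#'   `robust_states`); `NULL` draws uncolored points.
#' @param main plot title.
#' @return invisibly, the [pcoa()] result.
#' @export
plot_ordination <- function(D, labels = NULL, main = NULL) {
  ord <- pcoa(D, dims = 2)
  pts <- ord$points
  col <- "grey30"; pch <- 16
  if (!is.null(labels)) {
    labels <- labels[D$sample_ids]
    pal <- grDevices::hcl.colors(max(labels, na.rm = TRUE), "Dark 3")
    col <- pal[labels]
  }
  graphics::plot(pts[, 1], pts[, 2], col = col, pch = pch,
                 xlab = sprintf("PCo1 (%.0f%%)",
                                100 * ord$variance_explained[1]),
                 ylab = sprintf("PCo2 (%.0f%%)",
                                100 * ord$variance_explained[2]),
                 main = if (is.null(main))
                   paste("PCoA,", D$metric_id) else main)
  invisible(ord)
}

#' Longitudinal state-sequence diagram
#'
#' One row per subject, one column per time index, cells colored by state
#' and grey where the subject lacks a sample at that time point.
#'
#' @param states a `robust_states` with `outcome = "selected"`, or a named
#'   label vector.
#' @param metadata data.frame with `sample_id`, `subject_id`,
#'   `time_index`.
#' @return invisibly, the subjects x time state matrix (NA = missing).
#' @export
plot_state_sequence <- function(states, metadata) {
  labels <- if (inherits(states, "robust_states")) {
    if (!identical(states$outcome, "selected"))
      stop("no robust states selected; nothing to draw")
    states$labels
  } else states
  need <- c("sample_id", "subject_id", "time_index")
  if (!all(need %in% names(metadata)))
    stop("metadata must provide sample_id, subject_id and time_index; ",
         "for non-longitudinal data use plot_ordination() instead")
  md <- metadata[stats::complete.cases(metadata[need]), need, drop = FALSE]
  md <- md[md$sample_id %in% names(labels), , drop = FALSE]
  if (!nrow(md)) stop("no samples with temporal metadata and state labels")
  subjects <- unique(md$subject_id)
  times <- sort(unique(md$time_index))
  grid <- matrix(NA_integer_, length(subjects), length(times),
                 dimnames = list(subjects, times))
  grid[cbind(match(md$subject_id, subjects), match(md$time_index, times))] <-
    labels[md$sample_id]
  k <- max(grid, na.rm = TRUE)
  pal <- grDevices::hcl.colors(k, "Dark 3")
  graphics::image(x = seq_along(times), y = seq_along(subjects),
                  z = t(grid)[, rev(seq_along(subjects)), drop = FALSE],
                  col = pal, zlim = c(1, k), xlab = "time point",
                  ylab = "", axes = FALSE, main = "State sequences")
  graphics::axis(1, at = seq_along(times), labels = times)
  graphics::axis(2, at = seq_along(subjects), labels = rev(subjects),
                 las = 2, cex.axis = 0.7)
  ## grey cells for missing samples
  miss <- which(is.na(grid), arr.ind = TRUE)
  if (nrow(miss))
    graphics::rect(miss[, 2] - 0.5, length(subjects) - miss[, 1] + 0.5,
                   miss[, 2] + 0.5, length(subjects) - miss[, 1] + 1.5,
                   col = "grey85", border = NA)
  graphics::box()
  invisible(grid)
}
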