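# Dataset-level reporting: per-mouse prevalence with SEM, Pearson
# correlations, and aggregation of per-synapse results into one summary.

#' Per-mouse prevalence of a feature, with SEM across mice
#'
#' Per mouse: 100 x (tomograms of the compartment with the feature) /
#' (tomograms of the compartment scored). The mean and the standard error
#' (sample sd / sqrt(n_mice)) are taken across mice, the biological
#' replicates.
#'
#' @param table data.frame with at least `tomogram_id`, `mouse_id`,
#'   `compartment` and the feature column (logical or 0/1).
#' @param feature name of the feature column.
#' @param compartment compartment to score (`"PreSM"`, `"PoSM"`,
#'   `"vicinal"`).
#' @return a `prevalence_result`: list with `per_mouse` (data.frame
#'   mouse_id/n/percent), `mean`, `sem`, `n_mice`.
#' @export
prevalence <- function(table, feature, compartment) {
  if (!feature %in% names(table)) {
    stop_synquant(paste0("unknown feature column: ", feature),
                  "synquant_schema_error")
  }
  sub <- table[table$compartment == compartment, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_synquant(paste0("no rows for compartment: ", compartment),
                  "synquant_schema_error")
  }
  f <- as.logical(sub[[feature]])
  per <- stats::aggregate(f, by = list(mouse_id = sub$mouse_id),
                          FUN = function(v) 100 * mean(v))
  names(per)[2] <- "percent"
  per$n <- as.integer(table(sub$mouse_id)[as.character(per$mouse_id)])
  n_mice <- nrow(per)
  structure(list(per_mouse = per[, c("mouse_id", "n", "percent")],
                 mean = mean(per$percent),
                 sem = if (n_mice > 1) stats::sd(per$percent) / sqrt(n_mice)
                       else 0,
                 n_mice = n_mice),
            class = "prevalence_result")
}

#' Pearson correlation with a two-sided p-value
#'
#' Closed-form Pearson r with the two-sided p-value from the t-distribution
#' with n - 2 degrees of freedom, plus the least-squares regression line
#' reported alongside it.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list with `r`, `p_two_sided`, `n`, `slope`, `intercept`.
#' @export
correlate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 3L) {
    stop_synquant("x and y must have equal length >= 3",
                  "synquant_input_error")
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop_synquant("correlation undefined for zero-variance input",
                  "synquant_undefined_correlation")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  slope <- r * sy / sx
  list(r = r, p_two_sided = p, n = n,
       slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Aggregate per-synapse results into one dataset summary
#'
#' Combines the crowding classifications, cleft summaries and cluster
#' reports of a synapse panel into a single summary: crowding class counts,
#' cleft height as both mean-of-means and pooled mean, the cluster count
#' distribution, and the fractions of synapses with any cluster and with
#' non-cleft (boundary or perisynaptic) clusters.
#'
#' @param synapse_ids unique ids, one per synapse.
#' @param crowding list of `crowding_result` (or `NULL` entries).
#' @param cleft list of `cleft_summary` (or `NULL` entries).
#' @param clusters list of `cluster_report` (or `NULL` entries).
#' @return a plain list, suitable for `jsonlite::write_json()`.
#' @export
aggregate_synapses <- function(synapse_ids, crowding = NULL, cleft = NULL,
                               clusters = NULL) {
  if (anyDuplicated(synapse_ids)) {
    stop_synquant("duplicate synapse ids", "synquant_consistency_error")
  }
  n <- length(synapse_ids)
  out <- list(n_synapses = n)
  if (!is.null(crowding)) {
    cls <- vapply(crowding, function(r) r$crowding_class, character(1))
    out$crowding_class_counts <- as.list(table(
      factor(cls, levels = c("higher", "lower", "not_different"))))
    out$crowding_higher_fraction <- mean(cls == "higher")
  }
  if (!is.null(cleft)) {
    means <- vapply(cleft, function(s) s$mean_height, 1)
    ns <- vapply(cleft, function(s) s$n, 1)
    out$cleft_mean_of_means_nm <- mean(means)
    out$cleft_pooled_mean_nm <- sum(means * ns) / sum(ns)
    out$cleft_per_synapse_range_nm <- c(min(means), max(means))
    out$cleft_fraction_in_10_45 <-
      sum(vapply(cleft, function(s) s$fraction_in_10_45 * s$n, 1)) / sum(ns)
  }
  if (!is.null(clusters)) {
    ncl <- vapply(clusters, function(r) r$n_clusters, 1L)
    sizes <- unlist(lapply(clusters, function(r) r$clusters$size))
    non_cleft <- vapply(clusters, function(r) {
      any(r$clusters$location_class %in% c("boundary", "perisynaptic"))
    }, logical(1))
    out$cluster_count_distribution <- as.list(table(ncl))
    out$mean_clusters_per_synapse <- mean(ncl)
    out$mean_receptors_per_cluster <- if (length(sizes)) mean(sizes) else NA
    out$max_receptors_per_cluster <- if (length(sizes)) max(sizes) else NA
    out$fraction_with_any_cluster <- mean(ncl > 0)
    out$fraction_with_non_cleft_cluster <- mean(non_cleft)
  }
  out
}
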