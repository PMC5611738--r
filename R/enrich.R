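#' Monte Carlo enrichment of a probe set in genomic features
#'
#' For each feature, compares the number of informative CpGs carrying the
#' feature with the count among random probe sets of the same size drawn
#' uniformly without replacement from the universe. Fold change is
#' observed count over mean null count; the empirical p-value is
#' one-sided in the observed direction with an add-one correction, so it
#' is never exactly zero: `(1 + #{null >= observed}) / (n_iter + 1)` for
#' enrichment and the mirrored count for depletion.
#'
#' @param informative Character vector of probe IDs (must be a subset of
#'   `universe`).
#' @param universe Character vector of background probe IDs.
#' @param features Long-format `data.frame` with `probe_id` and `feature`
#'   columns (see [feature_map()]).
#' @param n_iter Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @return `data.frame` with one row per feature: `feature`, `observed`,
#'   `null_mean`, `null_sd`, `null_se`, `fold_change`, `p_empirical`,
#'   `direction`, `n_iterations`.
#' @export
monte_carlo_enrichment <- function(informative, universe, features,
                                   n_iter = 10000, seed = 1) {
  universe <- unique(universe)
  informative <- unique(informative)
  if (length(informative) < 1) stop("informative set is empty")
  if (!all(informative %in% universe)) {
    stop("informative probes must be a subset of the universe")
  }
  # feature labels are kept even if all their probes fall outside the
  # universe (they then report zero counts); membership itself is
  # restricted to the universe, so null draws respect upstream exclusions
  feats <- unique(features$feature)
  features <- features[features$probe_id %in% universe, , drop = FALSE]
  member <- sapply(feats, function(f)
    universe %in% features$probe_id[features$feature == f])
  member <- matrix(member, ncol = length(feats),
                   dimnames = list(NULL, feats))
  k <- length(informative)
  obs <- colSums(member[match(informative, universe), , drop = FALSE])

  set.seed(seed)
  null_counts <- matrix(0L, nrow = n_iter, ncol = length(feats),
                        dimnames = list(NULL, feats))
  for (it in seq_len(n_iter)) {
    idx <- sample.int(length(universe), k)
    null_counts[it, ] <- colSums(member[idx, , drop = FALSE])
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2, stats::sd)
  direction <- ifelse(obs >= null_mean, "enriched", "depleted")
  p <- vapply(seq_along(feats), function(j) {
    if (direction[j] == "enriched") {
      (1 + sum(null_counts[, j] >= obs[j])) / (n_iter + 1)
    } else {
      (1 + sum(null_counts[, j] <= obs[j])) / (n_iter + 1)
    }
  }, numeric(1))
  data.frame(
    feature = feats,
    observed = as.integer(obs),
    null_mean = unname(null_mean),
    null_sd = unname(null_sd),
    null_se = unname(null_sd / sqrt(n_iter)),
    fold_change = unname(ifelse(null_mean > 0, obs / null_mean, NA_real_)),
    p_empirical = p,
    direction = unname(direction),
    n_iterations = n_iter,
    stringsAsFactors = FALSE
  )
}

#' Expected overlap between two probe lists
#'
#' Observed overlap of two probe lists (as a percentage of the first
#' list) against the overlap expected by chance, built by redrawing both
#' lists' sizes uniformly from the universe. Under this null the expected
#' overlap percentage is the hypergeometric mean `100 |B| / |U|`.
#'
#' @param list_a,list_b Character vectors of probe IDs, subsets of
#'   `universe`; `list_a` is the reference for percentages.
#' @param universe Background probe IDs.
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @return List with `observed_pct`, `expected_pct` (Monte Carlo mean),
#'   `expected_pct_exact` (hypergeometric mean), `p_empirical` (excess
#'   overlap, add-one corrected), `direction`.
#' @export
list_overlap_expected <- function(list_a, list_b, universe,
                                  n_iter = 10000, seed = 1) {
  universe <- unique(universe)
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (length(list_a) == 0) stop("list_a is empty")
  if (!all(list_a %in% universe) || !all(list_b %in% universe)) {
    stop("both lists must be subsets of the universe")
  }
  obs <- sum(list_a %in% list_b)
  n_u <- length(universe)
  set.seed(seed)
  null_ov <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    a <- sample.int(n_u, length(list_a))
    b <- sample.int(n_u, length(list_b))
    null_ov[it] <- sum(a %in% b)
  }
  enriched <- obs >= mean(null_ov)
  p <- if (enriched) (1 + sum(null_ov >= obs)) / (n_iter + 1) else
    (1 + sum(null_ov <= obs)) / (n_iter + 1)
  list(
    observed_pct = 100 * obs / length(list_a),
    expected_pct = 100 * mean(null_ov) / length(list_a),
    expected_pct_exact = 100 * length(list_b) / n_u,
    p_empirical = p,
    direction = if (enriched) "enriched" else "depleted"
  )
}

#' Enrichment of informative CpGs for mQTL-associated CpGs
#'
#' Tests whether an informative-CpG list overlaps a list of CpGs under
#' known genetic influence (methylation QTL targets) more than random
#' probe sets of the same size do. Same machinery as
#' [monte_carlo_enrichment()] with the mQTL list as the single feature.
#'
#' @param informative,mqtl_cpgs Character vectors of probe IDs, subsets
#'   of `universe`.
#' @param universe Background probe IDs.
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @return One-row `data.frame` in the [monte_carlo_enrichment()] format.
#' @export
mqtl_enrichment <- function(informative, mqtl_cpgs, universe,
                            n_iter = 10000, seed = 1) {
  if (!all(mqtl_cpgs %in% universe)) {
    stop("mQTL CpGs must be a subset of the universe")
  }
  features <- data.frame(probe_id = unique(mqtl_cpgs), feature = "mqtl",
                         stringsAsFactors = FALSE)
  monte_carlo_enrichment(informative, universe, features,
                         n_iter = n_iter, seed = seed)
}

#' Bar plot of Monte Carlo enrichment results
#'
#' Fold-change bars with standard-error whiskers derived from the null
#' count distribution.
#'
#' @param result Output of [monte_carlo_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(result) {
  r <- result
  r$se_fold <- r$null_se / pmax(r$null_mean, .Machine$double.eps)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$feature, y = .data$fold_change,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$fold_change - .data$se_fold,
      ymax = .data$fold_change + .data$se_fold), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fold change vs random CpG sets") +
    ggplot2::theme_minimal()
}
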