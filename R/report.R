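#' Per-CpG cell-composition effect
#'
#' Two complementary estimates of how strongly each CpG is affected by
#' cell composition within one tissue group:
#' \describe{
#'   \item{variance fraction}{the R-squared of a per-CpG linear model of
#'     M values on the group's cell-proportion covariates (one cell type
#'     dropped);}
#'   \item{mean absolute beta change}{the mean `|beta - beta_adjusted|`
#'     across the group's samples, where the adjusted betas come from
#'     [adjust_cell_composition()].}
#' }
#'
#' @param betas CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id`, the grouping column and
#'   `prop_*` columns.
#' @param group_value Which group to analyse (e.g. `"blood"`).
#' @param group Sheet column defining groups (default `"tissue_class"`).
#' @return `data.frame` with `probe_id`, `variance_fraction`,
#'   `mean_abs_delta`.
#' @export
cell_effect_metric <- function(betas, sheet, group_value,
                               group = "tissue_class") {
  sheet_m <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  rows <- which(sheet_m[[group]] == group_value)
  if (length(rows) == 0) stop("no samples in group '", group_value, "'")
  covars <- .prop_covariates(sheet_m, rows)
  if (length(rows) < length(covars) + 2) {
    stop("group '", group_value, "' too small for its covariates")
  }
  m <- beta_to_m(betas[, rows, drop = FALSE])
  X <- cbind(1, as.matrix(sheet_m[rows, covars, drop = FALSE]))
  qd <- qr(X)
  Q <- qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
  fitted <- m %*% Q %*% t(Q)
  centered <- m - rowMeans(m)
  ss_tot <- rowSums(centered^2)
  ss_fit <- rowSums((fitted - rowMeans(m))^2)
  r2 <- ifelse(ss_tot > 0, pmin(pmax(ss_fit / ss_tot, 0), 1), NA_real_)

  sub_sheet <- sheet_m[rows, , drop = FALSE]
  adj <- adjust_cell_composition(betas[, rows, drop = FALSE], sub_sheet,
                                 group = group)
  mad_beta <- rowMeans(abs(betas[, rows, drop = FALSE] - adj))
  data.frame(probe_id = rownames(betas),
             variance_fraction = unname(r2),
             mean_abs_delta = unname(mad_beta),
             stringsAsFactors = FALSE)
}

#' Assemble the per-CpG metrics table
#'
#' A pure join of the pipeline's per-CpG outputs into one record per
#' probe: gene and feature annotation, per-region correlations and
#' percentiles, per-tissue reference ranges, cell-composition effects in
#' blood and brain, and informative flags. Nothing is recomputed; probes
#' missing from a component get missing fields, never dropped rows.
#'
#' @param concordance A [concordance_table()].
#' @param calls An `informative_calls` object (from [call_informative()]).
#' @param annotation Probe annotation (with `probe_id`, `island_relation`)
#'   merged with an [associate_cpgs()] table, or either alone.
#' @param cell_effects Named list of [cell_effect_metric()] tables (e.g.
#'   `list(blood = ..., brain = ...)`).
#' @param max_mismatch Maximal tolerated fraction of concordance probes
#'   absent from a component before erroring (default 0.01).
#' @return `data.frame` of class `cpg_metrics`, one row per probe in the
#'   concordance table.
#' @export
build_metrics_table <- function(concordance, calls = NULL, annotation = NULL,
                                cell_effects = NULL, max_mismatch = 0.01) {
  out <- concordance
  check <- function(tab, what) {
    missing_frac <- mean(!(out$probe_id %in% tab$probe_id))
    if (missing_frac > max_mismatch) {
      stop(sprintf("%.1f%% of probes missing from %s (allowed %.1f%%)",
                   100 * missing_frac, what, 100 * max_mismatch))
    }
  }
  if (!is.null(annotation)) {
    check(annotation, "annotation")
    out <- merge(out, annotation, by = "probe_id", all.x = TRUE,
                 sort = FALSE)
  }
  if (!is.null(calls)) {
    check(calls$calls, "informative calls")
    out <- merge(out, calls$calls, by = "probe_id", all.x = TRUE,
                 sort = FALSE)
  }
  for (nm in names(cell_effects)) {
    tab <- cell_effects[[nm]]
    check(tab, paste0("cell effects (", nm, ")"))
    names(tab)[-1] <- paste0(names(tab)[-1], "_", nm)
    out <- merge(out, tab, by = "probe_id", all.x = TRUE, sort = FALSE)
  }
  out <- out[match(concordance$probe_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_metrics", "data.frame")
  out
}

#' Query the metrics table by CpG ID or gene symbol
#'
#' Returns the records matching any of the supplied keys; gene keys
#' expand to every probe associated with that gene.
#'
#' @param table A `cpg_metrics` table from [build_metrics_table()].
#' @param cpgs Character vector of probe IDs (optional).
#' @param genes Character vector of gene symbols (optional; requires a
#'   `genes` column in the table).
#' @return Subset of `table` (possibly empty, with a warning).
#' @export
query_metrics <- function(table, cpgs = NULL, genes = NULL) {
  hit <- table$probe_id %in% cpgs
  if (!is.null(genes)) {
    if (is.null(table$genes)) stop("table has no gene associations")
    glist <- strsplit(ifelse(is.na(table$genes), "", table$genes), ",")
    hit <- hit | vapply(glist, function(g) any(g %in% genes), logical(1))
  }
  if (!any(hit)) warning("no records match the query")
  out <- table[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subject methylation profiles at selected CpGs
#'
#' Inter-individual variability plot: one panel per CpG, one line per
#' subject across tissues, betas on the y axis.
#'
#' @param betas CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id`, `subject_id`, `tissue`.
#' @param probes Probe IDs to plot.
#' @return A ggplot object.
#' @export
plot_cpg_profiles <- function(betas, sheet, probes) {
  probes <- intersect(probes, rownames(betas))
  if (length(probes) == 0) stop("no requested probes in the matrix")
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  d <- do.call(rbind, lapply(probes, function(p)
    data.frame(probe_id = p, sample_id = colnames(betas),
               subject_id = sheet$subject_id,
               tissue = factor(sheet$tissue, levels = unique(sheet$tissue)),
               beta = betas[p, ], stringsAsFactors = FALSE)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tissue, y = .data$beta,
                                  group = .data$subject_id,
                                  colour = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~probe_id) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "beta", colour = "subject") +
    ggplot2::theme_minimal()
}
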