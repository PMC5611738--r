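#' Filter array probes by SNP, cross-hybridization and QC rules
#'
#' Removes probes in a fixed order: (1) probes on the SNP probe list,
#' (2) probes on the cross-hybridizing list, (3) probes with bead count
#' below `bead_min` ("no calls") in at least `nocall_sample_frac` of
#' samples, (4) probes with detection p-value above `detp_cut` in at least
#' `detp_sample_frac` of samples. A probe failing several rules is counted
#' once, under the first rule that removes it, so the report is
#' deterministic and its counts sum to the number of probes removed.
#'
#' Sample-fraction thresholds are read as "at least": a probe with a bad
#' call in exactly 5% of samples is removed at the default
#' `nocall_sample_frac = 0.05`.
#'
#' @param betas CpG x sample beta matrix with probe IDs as row names.
#' @param snp_probes,cross_hyb Character vectors of probe IDs to drop
#'   (either may be `NULL`).
#' @param bead_counts Optional matrix aligned with `betas` (non-negative
#'   integers); required when the no-call rule is active.
#' @param detection_pvalues Optional matrix aligned with `betas` (values in
#'   `[0, 1]`); required when the detection rule is active.
#' @param nocall_sample_frac Fraction of samples at which a low-bead-count
#'   probe is dropped (default 0.05).
#' @param bead_min Minimum bead count for a call (default 3).
#' @param detp_sample_frac Fraction of samples at which a high detection
#'   p-value drops a probe (default 0.01).
#' @param detp_cut Detection p-value cutoff (default 0.05).
#' @return List with `betas` (the filtered matrix, same column order) and
#'   `report`, a one-row `data.frame` with columns `input`, `snp_probes`,
#'   `cross_hybridizing`, `no_call`, `detection`, `retained`.
#' @export
filter_probes <- function(betas, snp_probes = NULL, cross_hyb = NULL,
                          bead_counts = NULL, detection_pvalues = NULL,
                          nocall_sample_frac = 0.05, bead_min = 3,
                          detp_sample_frac = 0.01, detp_cut = 0.05) {
  stopifnot(is.matrix(betas), !is.null(rownames(betas)))
  if (anyDuplicated(rownames(betas))) stop("duplicated probe identifiers")
  if (anyDuplicated(colnames(betas))) stop("duplicated sample identifiers")
  probes <- rownames(betas)
  n_samp <- ncol(betas)
  removed_by <- rep(NA_character_, length(probes))
  names(removed_by) <- probes

  mark <- function(hit, rule) {
    fresh <- hit & is.na(removed_by)
    removed_by[fresh] <<- rule
  }
  mark(probes %in% snp_probes, "snp_probes")
  mark(probes %in% cross_hyb, "cross_hybridizing")
  if (!is.null(bead_counts)) {
    stopifnot(identical(dim(bead_counts), dim(betas)))
    frac_low <- rowMeans(bead_counts < bead_min, na.rm = TRUE)
    mark(frac_low >= nocall_sample_frac, "no_call")
  }
  if (!is.null(detection_pvalues)) {
    stopifnot(identical(dim(detection_pvalues), dim(betas)))
    frac_bad <- rowMeans(detection_pvalues > detp_cut, na.rm = TRUE)
    mark(frac_bad >= detp_sample_frac, "detection")
  }

  keep <- is.na(removed_by)
  if (!any(keep)) stop("all probes removed by filtering")
  report <- data.frame(
    input = length(probes),
    snp_probes = sum(removed_by == "snp_probes", na.rm = TRUE),
    cross_hybridizing = sum(removed_by == "cross_hybridizing", na.rm = TRUE),
    no_call = sum(removed_by == "no_call", na.rm = TRUE),
    detection = sum(removed_by == "detection", na.rm = TRUE),
    retained = sum(keep)
  )
  list(betas = betas[keep, , drop = FALSE], report = report)
}

#' Associate principal components with sample variables
#'
#' Computes a PCA of the beta matrix (samples as observations, probes
#' centered) and tests each component's sample scores against each
#' sheet variable: one-way ANOVA for categorical variables, Spearman
#' correlation for continuous ones. Useful for screening technical batch
#' variables (chip, processing delays) and biological covariates before
#' batch correction. The first component, which in multi-tissue data is
#' dominated by tissue identity, is omitted by default.
#'
#' @param betas CpG x sample beta (or M) matrix.
#' @param sheet Sample sheet `data.frame` with a `sample_id` column
#'   matching `colnames(betas)`.
#' @param variables Character vector of sheet column names to test.
#' @param n_pcs Number of components to report (default 4).
#' @param include_pc1 Report PC1 as well (default `FALSE`; components
#'   2..`n_pcs`+1 are reported otherwise).
#' @return `data.frame` with columns `pc`, `variable`, `test`
#'   (`"anova"` or `"spearman"`), `statistic` and `p_value`; constant
#'   variables are skipped with a warning.
#' @export
pca_association <- function(betas, sheet, variables, n_pcs = 4,
                            include_pc1 = FALSE) {
  stopifnot(ncol(betas) >= 3, all(variables %in% names(sheet)))
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sheet does not cover all samples")
  pca <- stats::prcomp(t(betas), center = TRUE, scale. = FALSE)
  first <- if (include_pc1) 1L else 2L
  pcs <- seq(first, min(first + n_pcs - 1L, ncol(pca$x)))
  out <- list()
  for (v in variables) {
    val <- sheet[[v]]
    if (length(unique(val[!is.na(val)])) < 2) {
      warning("variable '", v, "' is constant; skipped")
      next
    }
    continuous <- is.numeric(val)
    for (pc in pcs) {
      score <- pca$x[, pc]
      if (continuous) {
        ct <- suppressWarnings(
          stats::cor.test(score, val, method = "spearman", exact = FALSE))
        row <- data.frame(pc = pc, variable = v, test = "spearman",
                          statistic = unname(ct$estimate),
                          p_value = ct$p.value)
      } else {
        fit <- stats::aov(score ~ factor(val))
        tab <- summary(fit)[[1]]
        row <- data.frame(pc = pc, variable = v, test = "anova",
                          statistic = tab[["F value"]][1],
                          p_value = tab[["Pr(>F)"]][1])
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Root-mean-squared beta difference between replicate samples
#'
#' A QC summary for technical replicates: per pair, the square root of the
#' mean squared beta difference over probes, with missing probes excluded
#' pairwise.
#'
#' @param betas CpG x sample beta matrix.
#' @param pairs Two-column matrix or `data.frame` of sample IDs (one
#'   replicate pair per row).
#' @return Numeric vector of per-pair RMSE values, named
#'   `"<idA>|<idB>"`.
#' @export
replicate_rmse <- function(betas, pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  out <- numeric(nrow(pairs))
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!all(c(a, b) %in% colnames(betas))) {
      stop("replicate pair (", a, ", ", b, ") not found in matrix")
    }
    d <- betas[, a] - betas[, b]
    d <- d[!is.na(d)]
    if (length(d) == 0) stop("pair (", a, ", ", b, ") shares no probes")
    out[i] <- sqrt(mean(d^2))
  }
  out
}

#' Reference-based cell-type deconvolution
#'
#' Estimates each sample's cell-type proportions by constrained projection:
#' a non-negative least-squares fit of the sample's beta profile onto
#' sorted-cell reference beta profiles, with the solution renormalized to
#' sum to one.
#'
#' @param betas CpG x sample beta matrix.
#' @param reference CpG x cell-type reference beta matrix; rows are matched
#'   to `betas` by row name.
#' @param min_shared Minimum number of probes shared between matrix and
#'   reference (default 100).
#' @return List with `proportions` (sample x cell-type matrix, rows summing
#'   to 1) and `residual` (per-sample Euclidean norm of the fit residual).
#' @export
estimate_cell_proportions <- function(betas, reference, min_shared = 100) {
  shared <- intersect(rownames(betas), rownames(reference))
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " probes shared with the reference (< ",
         min_shared, ")")
  }
  X <- reference[shared, , drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    warning("reference profiles are collinear; proportions may be unstable")
  }
  Y <- betas[shared, , drop = FALSE]
  k <- ncol(X)
  prop <- matrix(NA_real_, nrow = ncol(Y), ncol = k,
                 dimnames = list(colnames(Y), colnames(X)))
  resid <- stats::setNames(numeric(ncol(Y)), colnames(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    ok <- !is.na(y)
    fit <- pracma::lsqnonneg(X[ok, , drop = FALSE], y[ok])
    w <- fit$x
    if (sum(w) <= 0) stop("degenerate zero fit for sample ", colnames(Y)[j])
    prop[j, ] <- w / sum(w)
    resid[j] <- sqrt(sum((X[ok, , drop = FALSE] %*% w - y[ok])^2))
  }
  list(proportions = prop, residual = resid)
}

# Cell-proportion covariate columns for one tissue group: the prop_*
# columns that are non-missing for every sample in the group, minus one
# (dropped to break the sum-to-one degeneracy).
.prop_covariates <- function(sheet, rows) {
  pc <- grep("^prop_", names(sheet), value = TRUE)
  pc <- pc[vapply(pc, function(cl) !anyNA(sheet[[cl]][rows]), logical(1))]
  if (length(pc) < 2) {
    stop("cell proportions are not present for all samples in a group")
  }
  pc[-1]
}

#' Remove cell-composition effects from a beta matrix
#'
#' Within each tissue group, fits a per-CpG linear model of methylation
#' on the sample cell proportions (one cell type dropped to avoid the
#' sum-to-one degeneracy) and replaces the values with model residuals
#' plus the group mean. By default the model runs on the M scale, where
#' linear-model assumptions hold better; group means on the modelling
#' scale are preserved exactly. With `scale = "beta"` the residualization
#' runs directly on betas, which removes a purely compositional signal
#' (a linear mixture of cell-type profiles) exactly.
#'
#' Note that residualizing on k proportion covariates with n samples per
#' group removes about k/(n-1) of every CpG's variance in sample-specific
#' directions, so per-CpG correlations shift accordingly even for CpGs
#' unrelated to composition; this is intrinsic to covariate adjustment at
#' small n, not an artifact of the scale.
#'
#' @param betas CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id`, the grouping column, and
#'   `prop_*` cell-proportion columns covering each group.
#' @param group Sheet column defining the adjustment groups (default
#'   `"tissue_class"`, i.e. blood and brain adjusted separately).
#' @param scale Modelling scale, `"m"` (default) or `"beta"`.
#' @return Adjusted beta matrix with the same dimensions and names.
#' @export
adjust_cell_composition <- function(betas, sheet, group = "tissue_class",
                                    scale = c("m", "beta")) {
  scale <- match.arg(scale)
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sheet does not cover all samples")
  m <- if (scale == "m") beta_to_m(betas) else betas
  for (g in unique(sheet[[group]])) {
    rows <- which(sheet[[group]] == g)
    covars <- .prop_covariates(sheet, rows)
    if (length(rows) < length(covars) + 2) {
      stop("group '", g, "' has too few samples (", length(rows),
           ") for ", length(covars), " proportion covariates")
    }
    X <- cbind(1, as.matrix(sheet[rows, covars, drop = FALSE]))
    # residuals via the hat matrix, applied to all CpGs at once;
    # rank-aware so constant proportions reduce to mean-centering
    qd <- qr(X)
    Q <- qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
    sub <- m[, rows, drop = FALSE]
    fitted <- sub %*% Q %*% t(Q)
    m[, rows] <- sub - fitted + rowMeans(sub)
  }
  out <- if (scale == "m") m_to_beta(m) else m
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}
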