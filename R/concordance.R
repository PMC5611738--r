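#' Pair blood and brain samples by subject
#'
#' Builds the subject-level pairing used by the concordance functions:
#' for one brain region, the subjects that have both a blood sample and a
#' sample from that region, with the corresponding sample IDs.
#'
#' @param sheet Sample sheet with `sample_id`, `subject_id`, `tissue`.
#' @param blood_tissue Label of the surrogate tissue (default `"blood"`).
#' @param brain_tissue Label of the brain region to pair against.
#' @return `data.frame` with columns `subject_id`, `blood`, `brain`.
#' @export
tissue_pairing <- function(sheet, brain_tissue, blood_tissue = "blood") {
  bl <- sheet[sheet$tissue == blood_tissue, c("subject_id", "sample_id")]
  br <- sheet[sheet$tissue == brain_tissue, c("subject_id", "sample_id")]
  m <- merge(bl, br, by = "subject_id", suffixes = c("_blood", "_brain"))
  data.frame(subject_id = m$subject_id,
             blood = m$sample_id_blood, brain = m$sample_id_brain,
             stringsAsFactors = FALSE)
}

# Row-wise Spearman correlation between two aligned matrices.
# Ties get average ranks; rows with missing values are computed pairwise;
# zero variance in either tissue gives NA (undefined, not zero).
.row_spearman <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  n <- ncol(a)
  complete <- !(rowSums(is.na(a)) > 0 | rowSums(is.na(b)) > 0)
  rho <- rep(NA_real_, nrow(a))
  n_pairs <- rep(n, nrow(a))
  if (any(complete)) {
    ra <- t(apply(a[complete, , drop = FALSE], 1, rank))
    rb <- t(apply(b[complete, , drop = FALSE], 1, rank))
    ra <- ra - rowMeans(ra)
    rb <- rb - rowMeans(rb)
    num <- rowSums(ra * rb)
    den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
    r <- num / den
    r[den == 0] <- NA_real_
    rho[complete] <- r
  }
  for (i in which(!complete)) {
    ok <- !is.na(a[i, ]) & !is.na(b[i, ])
    n_pairs[i] <- sum(ok)
    if (n_pairs[i] >= 3 &&
        stats::sd(a[i, ok]) > 0 && stats::sd(b[i, ok]) > 0) {
      rho[i] <- stats::cor(a[i, ok], b[i, ok], method = "spearman")
    }
  }
  list(rho = rho, n_pairs = n_pairs)
}

#' Per-CpG Spearman correlation between blood and one brain region
#'
#' For every CpG, the Spearman rank correlation of methylation across the
#' subjects paired in `pairing`. Ranks are invariant to the beta/M
#' transform, so beta and M input give identical correlations; the
#' convention of computing correlations on the M scale is therefore
#' honored by construction. Subjects missing either tissue are excluded
#' pairwise; a CpG with zero variance in either tissue yields `NA`.
#'
#' @param blood,brain CpG x sample matrices sharing probe IDs.
#' @param pairing Output of [tissue_pairing()] (or any `data.frame` with
#'   `blood` and `brain` sample-ID columns).
#' @return `data.frame` with `probe_id`, `rho`, `n_pairs`.
#' @export
spearman_per_cpg <- function(blood, brain, pairing) {
  if (nrow(pairing) < 4) stop("need at least 4 paired subjects")
  shared <- intersect(rownames(blood), rownames(brain))
  if (length(shared) == 0) stop("matrices share no probes")
  a <- blood[shared, pairing$blood, drop = FALSE]
  b <- brain[shared, pairing$brain, drop = FALSE]
  rs <- .row_spearman(a, b)
  data.frame(probe_id = shared, rho = rs$rho, n_pairs = rs$n_pairs,
             stringsAsFactors = FALSE)
}

#' Reference-range variability
#'
#' The range between an upper and a lower quantile of a CpG's beta values
#' across samples (defaults: 90th minus 10th percentile). Compared with
#' the full range, this captures variability in the bulk of the samples
#' while limiting the influence of outliers. Quantiles use linear
#' interpolation between order statistics.
#'
#' @param x Numeric vector of betas, or a CpG x sample matrix (one range
#'   per row).
#' @param lower,upper Quantile probabilities (defaults 0.10 and 0.90).
#' @return Scalar or per-row numeric vector in `[0, 1]` for beta inputs.
#' @export
reference_range <- function(x, lower = 0.10, upper = 0.90) {
  stopifnot(lower < upper)
  one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("reference_range on all-missing input")
    q <- stats::quantile(v, c(lower, upper), names = FALSE, type = 7)
    q[2] - q[1]
  }
  if (is.matrix(x)) apply(x, 1, one) else one(x)
}

#' Percentile of a correlation within a distribution
#'
#' Position of each query correlation within a reference distribution:
#' `100 * #(values <= rho) / n`, with missing reference values excluded
#' and missing queries returned as missing.
#'
#' @param rho Numeric vector of query correlations.
#' @param all_rhos Reference distribution of correlations.
#' @return Percentiles in `[0, 100]`.
#' @export
correlation_percentile <- function(rho, all_rhos) {
  ref <- sort(all_rhos[!is.na(all_rhos)])
  if (length(ref) == 0) stop("empty reference distribution")
  out <- 100 * findInterval(rho, ref) / length(ref)
  out[is.na(rho)] <- NA_real_
  out
}

# Random non-identity permutation; with scheme = "derangement", no
# element keeps its place at all.
.unmatch_perm <- function(n, scheme) {
  if (n < 2) stop("unmatching needs n >= 2")
  repeat {
    p <- sample.int(n)
    keep <- if (scheme == "derangement") !any(p == seq_len(n)) else
      !all(p == seq_len(n))
    if (keep) return(p)
  }
}

#' Permutation null distribution for blood--brain correlations
#'
#' Randomly unmatches the paired samples: in each permutation the brain
#' samples are reassigned across subjects and the per-CpG Spearman
#' correlations are recomputed. The pooled distribution serves as the
#' null against which the real paired correlations are compared.
#'
#' The default scheme is a uniform shuffle with only the identity
#' permutation excluded, which leaves the null mean unbiased. Forcing a
#' full derangement (`scheme = "derangement"`, no subject keeps its own
#' brain sample) removes all residual pairing but biases the null mean
#' by about `-rho_bar / (n - 1)`, where `rho_bar` is the mean paired
#' correlation -- noticeable at 16 subjects.
#'
#' @param blood,brain CpG x sample matrices sharing probe IDs.
#' @param pairing Output of [tissue_pairing()].
#' @param n_perms Number of unmatching permutations (default 5).
#' @param seed Integer seed.
#' @param scheme `"shuffle"` (default) or `"derangement"`, see Details.
#' @return List with `perms` (list of per-permutation rho vectors),
#'   `pooled` (all null rhos), and `summary` (`data.frame` with mean, sd
#'   and 2.5/50/97.5 percent quantiles of the pooled null).
#' @export
permutation_null <- function(blood, brain, pairing, n_perms = 5, seed = 1,
                             scheme = c("shuffle", "derangement")) {
  scheme <- match.arg(scheme)
  if (n_perms < 1) stop("n_perms must be >= 1")
  if (nrow(pairing) < 4) stop("need at least 4 paired subjects")
  set.seed(seed)
  perms <- vector("list", n_perms)
  for (k in seq_len(n_perms)) {
    shuffled <- pairing
    shuffled$brain <- pairing$brain[.unmatch_perm(nrow(pairing), scheme)]
    perms[[k]] <- spearman_per_cpg(blood, brain, shuffled)$rho
  }
  pooled <- unlist(perms)
  pooled_ok <- pooled[!is.na(pooled)]
  list(
    perms = perms,
    pooled = pooled,
    summary = data.frame(
      mean = mean(pooled_ok), sd = stats::sd(pooled_ok),
      q025 = stats::quantile(pooled_ok, 0.025, names = FALSE),
      q50 = stats::quantile(pooled_ok, 0.50, names = FALSE),
      q975 = stats::quantile(pooled_ok, 0.975, names = FALSE)
    )
  )
}

#' Per-CpG concordance table across brain regions
#'
#' Convenience wrapper assembling, for every brain region in the cohort:
#' the per-CpG Spearman correlation with blood, its percentile within the
#' region's correlation distribution, and per-tissue reference ranges.
#'
#' @param betas CpG x sample beta matrix for the whole cohort.
#' @param sheet Sample sheet covering `colnames(betas)`.
#' @param blood_tissue Surrogate tissue label (default `"blood"`).
#' @param brain_tissues Brain region labels (default: all non-blood
#'   tissues in the sheet).
#' @return `data.frame` keyed by `probe_id` with columns `rho_<region>`,
#'   `pct_<region>`, `n_<region>`, `rr_<tissue>` for every tissue, and
#'   `rho_mean` (mean of available per-region correlations).
#' @export
concordance_table <- function(betas, sheet, blood_tissue = "blood",
                              brain_tissues = NULL) {
  if (is.null(brain_tissues)) {
    brain_tissues <- setdiff(unique(sheet$tissue), blood_tissue)
  }
  out <- data.frame(probe_id = rownames(betas), stringsAsFactors = FALSE)
  rho_cols <- character(0)
  for (reg in brain_tissues) {
    pairing <- tissue_pairing(sheet, reg, blood_tissue)
    sp <- spearman_per_cpg(betas, betas, pairing)
    sp <- sp[match(out$probe_id, sp$probe_id), ]
    out[[paste0("rho_", reg)]] <- sp$rho
    out[[paste0("pct_", reg)]] <- correlation_percentile(sp$rho, sp$rho)
    out[[paste0("n_", reg)]] <- sp$n_pairs
    rho_cols <- c(rho_cols, paste0("rho_", reg))
  }
  for (tis in c(blood_tissue, brain_tissues)) {
    cols <- sheet$sample_id[sheet$tissue == tis]
    out[[paste0("rr_", tis)]] <- reference_range(betas[, cols, drop = FALSE])
  }
  out$rho_mean <- rowMeans(as.matrix(out[, rho_cols, drop = FALSE]),
                           na.rm = TRUE)
  out$rho_mean[is.nan(out$rho_mean)] <- NA_real_
  out
}
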