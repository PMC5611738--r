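#' Per-CpG paired differential methylation between two tissues
#'
#' For each CpG, fits a linear mixed model on M values with fixed effects
#' for tissue, sex and (centered) age and a random intercept per subject,
#' capturing the paired structure of matched-tissue designs. The reported
#' effect is the tissue coefficient (second tissue minus first) on the M
#' scale; `delta_beta` is the difference of tissue mean betas. P-values
#' are Wald t-tests on the tissue coefficient with between--within
#' (containment) denominator degrees of freedom, which on a balanced
#' complete paired design equal the paired-t degrees of freedom.
#'
#' One model structure is estimated and refit per CpG for speed; CpGs for
#' which the model fails are reported with missing p-values and counted.
#'
#' @param betas CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id`, `subject_id`, `tissue`,
#'   `sex`, `age`.
#' @param pair Character vector of two tissue labels, effect direction
#'   `pair[2] - pair[1]`.
#' @return `data.frame` with `probe_id`, `effect` (M scale),
#'   `delta_beta`, `p_nominal`, `p_bh`, plus attribute `n_failed`.
#' @export
fit_paired_tissue_model <- function(betas, sheet, pair) {
  stopifnot(length(pair) == 2)
  sub <- sheet[sheet$tissue %in% pair, , drop = FALSE]
  sub <- sub[sub$sample_id %in% colnames(betas), , drop = FALSE]
  both <- names(which(table(sub$subject_id) == 2))
  if (length(both) < 4) stop("need at least 4 subjects with both tissues")
  sub <- sub[sub$subject_id %in% both, , drop = FALSE]
  if (!all(c("sex", "age") %in% names(sub))) stop("sheet needs sex and age")
  sub$tissue <- factor(sub$tissue, levels = pair)
  sub$sex <- factor(sub$sex)
  sub$age_c <- sub$age - mean(sub$age)
  n_fixed <- 2 + (nlevels(sub$sex) > 1) + 1  # intercept, tissue, sex?, age
  if (length(both) < n_fixed) stop("fewer subjects than model covariates")
  m <- beta_to_m(betas[, sub$sample_id, drop = FALSE])

  # containment df: observations minus fixed effects minus subject strata
  df_denom <- max(nrow(sub) - n_fixed - (length(both) - 1), 1)

  form <- if (nlevels(sub$sex) > 1) {
    y ~ tissue + sex + age_c + (1 | subject_id)
  } else {
    y ~ tissue + age_c + (1 | subject_id)
  }
  dat <- sub
  effect <- se <- rep(NA_real_, nrow(m))
  base_fit <- NULL
  n_failed <- 0L
  for (i in seq_len(nrow(m))) {
    dat$y <- m[i, ]
    if (anyNA(dat$y)) { n_failed <- n_failed + 1L; next }
    fit <- tryCatch(suppressWarnings(suppressMessages({
      if (is.null(base_fit)) {
        base_fit <- lme4::lmer(form, data = dat, REML = TRUE,
                               control = lme4::lmerControl(
                                 check.conv.singular = "ignore"))
        base_fit
      } else {
        lme4::refit(base_fit, newresp = dat$y)
      }
    })), error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    cf <- summary(fit)$coefficients
    row <- grep("^tissue", rownames(cf))[1]
    effect[i] <- cf[row, "Estimate"]
    se[i] <- cf[row, "Std. Error"]
  }
  tstat <- effect / se
  p <- 2 * stats::pt(-abs(tstat), df = df_denom)
  # zero-residual fits give se = 0; a non-zero effect is then certain
  p[is.nan(p) & !is.na(effect) & effect != 0] <- 0
  p[is.nan(p)] <- NA_real_

  a_cols <- sub$sample_id[sub$tissue == pair[1]]
  b_cols <- sub$sample_id[sub$tissue == pair[2]]
  delta_beta <- rowMeans(betas[, b_cols, drop = FALSE]) -
    rowMeans(betas[, a_cols, drop = FALSE])

  out <- data.frame(probe_id = rownames(m), effect = effect,
                    delta_beta = unname(delta_beta),
                    p_nominal = p, p_bh = bh_adjust(p),
                    stringsAsFactors = FALSE)
  attr(out, "n_failed") <- n_failed
  attr(out, "pair") <- pair
  out
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Missing values are excluded
#' and reinserted as missing.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Volcano-style differential calls
#'
#' Flags CpGs passing both the effect-size and FDR cutoffs: absolute
#' tissue beta difference at least `delta_cut` and BH-adjusted p-value
#' below `fdr_cut`.
#'
#' @param results Output of [fit_paired_tissue_model()].
#' @param delta_cut Minimum `|delta_beta|` (default 0.1).
#' @param fdr_cut Maximum BH-adjusted p (default 0.001).
#' @return List with `called` (probe IDs), `n_called`, `n_tested`, and
#'   the cutoffs used.
#' @export
volcano_calls <- function(results, delta_cut = 0.1, fdr_cut = 0.001) {
  hit <- !is.na(results$p_bh) & results$p_bh < fdr_cut &
    !is.na(results$delta_beta) & abs(results$delta_beta) >= delta_cut
  list(called = results$probe_id[hit], n_called = sum(hit),
       n_tested = sum(!is.na(results$p_bh)),
       delta_cut = delta_cut, fdr_cut = fdr_cut)
}

#' Methylome-wide tissue similarity matrix
#'
#' Spearman correlation of per-tissue mean methylation between all tissue
#' pairs: a whole-methylome indicator of how similar tissues are (brain
#' regions typically correlate more with each other than with blood).
#'
#' @param betas CpG x sample beta matrix.
#' @param sheet Sample sheet covering the samples.
#' @return Symmetric tissue x tissue correlation matrix.
#' @export
tissue_similarity <- function(betas, sheet) {
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  tissues <- unique(sheet$tissue)
  means <- sapply(tissues, function(t)
    rowMeans(betas[, sheet$sample_id[sheet$tissue == t], drop = FALSE],
             na.rm = TRUE))
  stats::cor(means, method = "spearman")
}

#' Volcano plot of a differential-methylation result
#'
#' @param results Output of [fit_paired_tissue_model()].
#' @param delta_cut,fdr_cut Cutoff lines (defaults 0.1 and 0.001).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, delta_cut = 0.1, fdr_cut = 0.001) {
  d <- results[!is.na(results$p_bh), , drop = FALSE]
  d$called <- d$p_bh < fdr_cut & abs(d$delta_beta) >= delta_cut
  d$neglog <- -log10(pmax(d$p_bh, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_beta, y = .data$neglog,
                                  colour = .data$called)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-delta_cut, delta_cut),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(fdr_cut), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey40", "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "beta difference between tissues",
                  y = "-log10 FDR-adjusted p") +
    ggplot2::theme_minimal()
}
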