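#' Fit a two-component Gaussian mixture to a correlation distribution
#'
#' Expectation--maximization for a univariate mixture of two Gaussians,
#' used to separate the "generally uncorrelated" peak of a per-CpG
#' correlation distribution from the positively correlated peak. The
#' derived informative-CpG correlation threshold is the mean of the
#' higher-mean component minus two of its standard deviations.
#'
#' Initialization is deterministic: component means at the 25th and 75th
#' percentiles of the data, common SD, equal weights. If a component
#' collapses (SD below `1e-4`) the fit restarts from seeded jittered
#' quartiles, up to 10 times.
#'
#' @param rhos Numeric vector of correlations (at least 50 finite values).
#' @param seed Integer seed for restart jitter only (the initial fit is
#'   deterministic).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood improvement
#'   (default 1e-8).
#' @param region Optional region label stored in the fit.
#' @return Object of class `gmm2_fit`: list with `weights`, `means`,
#'   `sds` (each length 2, ordered so component 2 has the larger mean),
#'   `threshold` (`means[2] - 2 * sds[2]`), `loglik`, `loglik_trace`,
#'   `n_iterations`, `converged`, `region`.
#' @export
fit_two_gaussian_mixture <- function(rhos, seed = 1, max_iter = 500,
                                     tol = 1e-8, region = NA_character_) {
  x <- rhos[is.finite(rhos)]
  if (length(x) < 50) stop("need at least 50 finite correlation values")

  run_em <- function(mu, sd0, w0) {
    w <- w0; mu <- mu; sdv <- sd0
    ll_old <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * stats::dnorm(x, mu[1], sdv[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], sdv[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      g <- d2 / tot                      # responsibility of component 2
      n2 <- sum(g); n1 <- length(x) - n2
      if (n1 < 1e-8 || n2 < 1e-8) {
        return(list(collapsed = TRUE))
      }
      w <- c(n1, n2) / length(x)
      mu <- c(sum((1 - g) * x) / n1, sum(g * x) / n2)
      sdv <- sqrt(c(sum((1 - g) * (x - mu[1])^2) / n1,
                    sum(g * (x - mu[2])^2) / n2))
      if (any(sdv < 1e-4)) return(list(collapsed = TRUE))
      if (is.finite(ll_old) && ll - ll_old < tol) {
        return(list(collapsed = FALSE, w = w, mu = mu, sd = sdv,
                    loglik = ll, trace = trace, n_iter = it,
                    converged = TRUE))
      }
      ll_old <- ll
    }
    list(collapsed = FALSE, w = w, mu = mu, sd = sdv, loglik = ll_old,
         trace = trace, n_iter = max_iter, converged = FALSE)
  }

  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sd_init <- rep(stats::sd(x), 2)
  fit <- run_em(q, sd_init, c(0.5, 0.5))
  if (isTRUE(fit$collapsed)) {
    set.seed(seed)
    for (r in seq_len(10)) {
      jit <- q + stats::rnorm(2, 0, stats::sd(x) / 4)
      fit <- run_em(jit, sd_init, c(0.5, 0.5))
      if (!isTRUE(fit$collapsed)) break
    }
    if (isTRUE(fit$collapsed)) {
      stop("mixture fit collapsed after 10 seeded restarts")
    }
  }
  if (!fit$converged) {
    warning("EM did not converge within ", max_iter,
            " iterations; returning best fit")
  }
  ord <- order(fit$mu)                   # component 2 = higher mean
  structure(list(
    weights = fit$w[ord], means = fit$mu[ord], sds = fit$sd[ord],
    threshold = fit$mu[ord][2] - 2 * fit$sd[ord][2],
    loglik = fit$loglik, loglik_trace = fit$trace,
    n_iterations = fit$n_iter, converged = fit$converged,
    region = region
  ), class = "gmm2_fit")
}

#' @export
print.gmm2_fit <- function(x, ...) {
  cat("2-component Gaussian mixture",
      if (!is.na(x$region)) paste0("(", x$region, ")"), "\n")
  cat(sprintf("  weights %.3f / %.3f  means %.3f / %.3f  sds %.3f / %.3f\n",
              x$weights[1], x$weights[2], x$means[1], x$means[2],
              x$sds[1], x$sds[2]))
  cat(sprintf("  threshold (upper mean - 2 sd): %.4f  [%s, %d iterations]\n",
              x$threshold,
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  invisible(x)
}

#' Probe set anchoring the threshold derivation
#'
#' Two modes for selecting the CpGs whose correlation distribution
#' anchors the mixture fit:
#' \describe{
#'   \item{snp_sex}{the union of polymorphic CpGs and CpGs on the sex
#'     chromosomes -- the classes expected to be the most variable and
#'     most blood--brain correlated, since genotype and sex are constant
#'     across a subject's tissues. These probes guide the thresholds but
#'     are excluded from informative calling itself.}
#'   \item{top_variable}{CpGs whose blood reference range passes a strict
#'     variability cut (supplied via `concordance` and `strict_cut`).}
#' }
#'
#' @param annotation Probe annotation with `probe_id`, `polymorphic`,
#'   `chromosome`.
#' @param mode `"snp_sex"` (default) or `"top_variable"`.
#' @param concordance For `top_variable`: a [concordance_table()] with an
#'   `rr_blood` column.
#' @param strict_cut For `top_variable`: the blood reference-range cut
#'   (default 0.2).
#' @return Character vector of probe IDs (duplicates removed).
#' @export
derive_seed_set <- function(annotation, mode = c("snp_sex", "top_variable"),
                            concordance = NULL, strict_cut = 0.2) {
  mode <- match.arg(mode)
  if (mode == "snp_sex") {
    sel <- annotation$polymorphic | annotation$chromosome %in% c("chrX", "chrY")
    out <- unique(annotation$probe_id[sel])
  } else {
    if (is.null(concordance) || is.null(concordance$rr_blood)) {
      stop("top_variable mode needs a concordance table with rr_blood")
    }
    out <- concordance$probe_id[!is.na(concordance$rr_blood) &
                                  concordance$rr_blood >= strict_cut]
  }
  if (length(out) == 0) stop("seed set is empty")
  out
}

#' Fit per-region correlation thresholds
#'
#' Fits [fit_two_gaussian_mixture()] to each region's correlation values
#' restricted to a seed probe set (see [derive_seed_set()]).
#'
#' @param concordance A [concordance_table()].
#' @param seed_probes Probe IDs whose correlations anchor the fits.
#' @param regions Region labels (default: all `rho_*` columns).
#' @param seed Integer seed passed to the mixture fit.
#' @return Named list of `gmm2_fit` objects, one per region.
#' @export
fit_region_thresholds <- function(concordance, seed_probes, regions = NULL,
                                  seed = 1) {
  rho_cols <- grep("^rho_", names(concordance), value = TRUE)
  rho_cols <- setdiff(rho_cols, "rho_mean")
  if (is.null(regions)) regions <- sub("^rho_", "", rho_cols)
  sel <- concordance$probe_id %in% seed_probes
  fits <- list()
  for (reg in regions) {
    fits[[reg]] <- fit_two_gaussian_mixture(
      concordance[[paste0("rho_", reg)]][sel], seed = seed, region = reg)
  }
  fits
}

#' Call informative CpGs
#'
#' A CpG is informative for a brain region when its blood methylation is
#' both variable (blood reference range at or above `variability_cut`)
#' and correlated with that region beyond the region's mixture-derived
#' threshold. The threshold applies symmetrically: `rho >= threshold`
#' gives a positive call, `rho <= -threshold` a negative call. Probes in
#' `exclude` (typically the polymorphic/sex-chromosome seed set) are
#' never called.
#'
#' @param concordance A [concordance_table()].
#' @param fits Per-region list of `gmm2_fit` objects (or a named numeric
#'   vector of thresholds).
#' @param variability_cut Blood reference-range gate (default 0.1).
#' @param exclude Probe IDs excluded from calling (default none).
#' @return Object of class `informative_calls`: list with `calls` (a
#'   `data.frame` keyed by `probe_id` with per-region flag columns
#'   `call_<region>` taking values `informative_positive`,
#'   `informative_negative`, `variable_only` or `none`, plus logical
#'   `informative` for the union across regions), `thresholds` (named
#'   vector), `variability_cut`, and `region_counts` (per-region
#'   positive/negative counts).
#' @export
call_informative <- function(concordance, fits, variability_cut = 0.1,
                             exclude = character(0)) {
  thr <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$threshold, numeric(1))
  if (is.null(names(thr)) || any(!nzchar(names(thr)))) {
    stop("fits must be named by region")
  }
  regions <- names(thr)
  rr <- concordance$rr_blood
  if (is.null(rr)) stop("concordance table lacks rr_blood")
  excluded <- concordance$probe_id %in% exclude
  variable <- !is.na(rr) & rr >= variability_cut & !excluded

  calls <- data.frame(probe_id = concordance$probe_id,
                      stringsAsFactors = FALSE)
  any_inf <- rep(FALSE, nrow(calls))
  counts <- list()
  for (reg in regions) {
    rho <- concordance[[paste0("rho_", reg)]]
    flag <- rep("none", nrow(calls))
    flag[variable] <- "variable_only"
    pos <- variable & !is.na(rho) & rho >= thr[[reg]]
    neg <- variable & !is.na(rho) & rho <= -thr[[reg]]
    flag[pos] <- "informative_positive"
    flag[neg] <- "informative_negative"
    calls[[paste0("call_", reg)]] <- flag
    any_inf <- any_inf | pos | neg
    counts[[reg]] <- data.frame(region = reg, positive = sum(pos),
                                negative = sum(neg))
  }
  calls$informative <- any_inf
  structure(list(
    calls = calls,
    thresholds = thr,
    variability_cut = variability_cut,
    region_counts = do.call(rbind, counts)
  ), class = "informative_calls")
}

#' @export
print.informative_calls <- function(x, ...) {
  cat("informative CpG calls:", sum(x$calls$informative), "of",
      nrow(x$calls), "probes informative in >= 1 region\n")
  cat("  thresholds:", paste(names(x$thresholds),
                             sprintf("%.3f", x$thresholds),
                             sep = "=", collapse = ", "),
      " variability cut:", x$variability_cut, "\n")
  print(x$region_counts, row.names = FALSE)
  invisible(x)
}

#' Overlap of per-region informative sets
#'
#' Counts of CpGs informative (in the given direction) in each subset of
#' regions, the Venn-diagram breakdown of the per-region calls.
#'
#' @param calls An `informative_calls` object.
#' @param direction `"positive"` or `"negative"`.
#' @return Named integer vector; names are `+`-joined region subsets.
#' @export
informative_overlap <- function(calls, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  target <- paste0("informative_", direction)
  regs <- sub("^call_", "", grep("^call_", names(calls$calls), value = TRUE))
  member <- sapply(regs, function(r) calls$calls[[paste0("call_", r)]] == target)
  member <- matrix(member, ncol = length(regs),
                   dimnames = list(NULL, regs))
  pattern <- apply(member, 1, function(z)
    paste(regs[z], collapse = "+"))
  tab <- table(pattern[pattern != ""])
  stats::setNames(as.integer(tab), names(tab))
}
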