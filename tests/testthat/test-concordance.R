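# Small aligned matrices for direct correlation checks.
pair_mats <- function(blood_rows, brain_rows) {
  n <- ncol(blood_rows)
  list(
    blood = matrix(blood_rows, nrow = nrow(blood_rows),
                   dimnames = list(sprintf("cg%07d", seq_len(nrow(blood_rows))),
                                   paste0("bl", seq_len(n)))),
    brain = matrix(brain_rows, nrow = nrow(brain_rows),
                   dimnames = list(sprintf("cg%07d", seq_len(nrow(brain_rows))),
                                   paste0("br", seq_len(n)))),
    pairing = data.frame(subject_id = paste0("S", seq_len(n)),
                         blood = paste0("bl", seq_len(n)),
                         brain = paste0("br", seq_len(n)))
  )
}

test_that("per-CpG Spearman matches known and hand-computed values", {
  x <- pair_mats(rbind(c(1, 2, 3, 5), c(1, 2, 3, 5), c(1, 2, 2, 4)),
                 rbind(c(2, 4, 6, 9), c(9, 6, 4, 2), c(1, 3, 2, 4)))
  sp <- spearman_per_cpg(m_to_beta(x$blood / 3), m_to_beta(x$brain / 3),
                         x$pairing)
  expect_equal(sp$rho[1], 1)   # monotone increasing
  expect_equal(sp$rho[2], -1)  # monotone decreasing
  # ties: Pearson correlation of average ranks
  expect_equal(sp$rho[3], 0.9487, tolerance = 1e-4)
  expect_equal(sp$rho[3], cor(c(1, 2, 2, 4), c(1, 3, 2, 4),
                              method = "spearman"), tolerance = 1e-12)
  expect_equal(sp$n_pairs, rep(4L, 3))
})

test_that("Spearman is invariant to increasing transforms and flags zero variance", {
  set.seed(8)
  b <- matrix(runif(40, 0.1, 0.9), nrow = 5)
  r <- matrix(runif(40, 0.1, 0.9), nrow = 5)
  b[4, ] <- 0.42  # zero variance in blood
  x <- pair_mats(b, r)
  on_beta <- spearman_per_cpg(x$blood, x$brain, x$pairing)
  on_m <- spearman_per_cpg(beta_to_m(x$blood), beta_to_m(x$brain), x$pairing)
  expect_identical(on_beta$rho, on_m$rho)
  expect_true(is.na(on_beta$rho[4]))  # undefined, not zero
})

test_that("missing samples are excluded pairwise with n_pairs recorded", {
  set.seed(9)
  b <- matrix(runif(60, 0.1, 0.9), nrow = 6)
  r <- matrix(runif(60, 0.1, 0.9), nrow = 6)
  b[2, 1] <- NA
  x <- pair_mats(b, r)
  sp <- spearman_per_cpg(x$blood, x$brain, x$pairing)
  expect_equal(sp$n_pairs[2], 9L)
  expect_equal(sp$rho[2],
               cor(x$blood[2, -1], x$brain[2, -1], method = "spearman"),
               tolerance = 1e-12)
  expect_error(spearman_per_cpg(x$blood, x$brain, x$pairing[1:3, ]),
               "at least 4")
})

test_that("reference range matches interpolated quantile differences", {
  expect_equal(reference_range(rep(0.4, 10)), 0)
  expect_equal(reference_range(seq(0, 1, by = 0.1)), 0.8)
  v <- runif(37)
  expect_equal(reference_range(v),
               unname(diff(quantile(v, c(0.1, 0.9)))), tolerance = 1e-12)
  # translation equivariance and monotonicity under spread increase
  expect_equal(reference_range(v * 0.5 + 0.2), 0.5 * reference_range(v),
               tolerance = 1e-12)
  expect_error(reference_range(c(NA_real_, NA_real_)), "all-missing")
  # matrix input gives per-row ranges
  m <- rbind(a = seq(0, 1, by = 0.1), b = rep(0.3, 11))
  expect_equal(unname(reference_range(m)), c(0.8, 0))
})

test_that("correlation percentile follows the at-or-below convention", {
  ref <- c(-0.5, -0.1, 0.2, 0.4, 0.9)
  expect_equal(correlation_percentile(0.9, ref), 100)
  expect_equal(correlation_percentile(-0.5, ref), 20)
  expect_equal(correlation_percentile(c(0.2, NA), ref), c(60, NA))
  expect_equal(correlation_percentile(-0.9, ref), 0)
  # ties count all values at or below the query
  expect_equal(correlation_percentile(0.2, c(0.2, 0.2, 0.5, 0.7)), 50)
})

test_that("unmatching permutations exclude the identity and can derange", {
  set.seed(1)
  for (i in 1:20) {
    p <- methcord:::.unmatch_perm(2, "shuffle")
    expect_equal(p, c(2L, 1L))  # the only non-identity shuffle at n = 2
    d <- methcord:::.unmatch_perm(6, "derangement")
    expect_true(all(d != 1:6))
    s <- methcord:::.unmatch_perm(6, "shuffle")
    expect_false(all(s == 1:6))
  }
  # reversing the pairing flips the sign of monotone CpGs
  x <- pair_mats(rbind(c(0.1, 0.2, 0.3, 0.4)), rbind(c(0.2, 0.4, 0.6, 0.8)))
  rev_pairing <- x$pairing
  rev_pairing$brain <- rev(rev_pairing$brain)
  expect_equal(spearman_per_cpg(x$blood, x$brain, x$pairing)$rho, 1)
  expect_equal(spearman_per_cpg(x$blood, x$brain, rev_pairing)$rho, -1)
})

test_that("permutation null is centred and paired rhos skew positive", {
  co <- simulate_cohort(sim_config(
    n_cpgs_per_class = c(concordant = 800, discordant = 400,
                         polymorphic = 200, sex_linked = 100), seed = 31))
  pairing <- tissue_pairing(co$sheet, "BA7")
  null <- permutation_null(co$betas, co$betas, pairing, n_perms = 5, seed = 2)
  expect_equal(length(null$perms), 5)
  expect_lt(abs(null$summary$mean), 0.02)
  paired <- spearman_per_cpg(co$betas, co$betas, pairing)
  conc <- truth_class(co, paired$probe_id) == "concordant"
  expect_gt(median(paired$rho[conc]), null$summary$q50)
})

test_that("null tail frequencies match the exact permutation distribution", {
  # exact Spearman distribution at n = 7 by exhaustive enumeration
  n <- 7
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  base <- 1:n
  exact_rho <- apply(perms, 1, function(p) cor(base, p))
  p_tail_exact <- mean(abs(exact_rho) >= 0.9)

  set.seed(4)
  n_cpg <- 400
  blood <- matrix(runif(n_cpg * n), nrow = n_cpg,
                  dimnames = list(sprintf("cg%07d", 1:n_cpg),
                                  paste0("bl", 1:n)))
  brain <- matrix(runif(n_cpg * n), nrow = n_cpg,
                  dimnames = list(sprintf("cg%07d", 1:n_cpg),
                                  paste0("br", 1:n)))
  pairing <- data.frame(subject_id = paste0("S", 1:n),
                        blood = paste0("bl", 1:n), brain = paste0("br", 1:n))
  null <- permutation_null(blood, brain, pairing, n_perms = 25, seed = 6)
  frac <- mean(abs(null$pooled) >= 0.9)
  mc_sd <- sqrt(p_tail_exact * (1 - p_tail_exact) / length(null$pooled))
  # wide Monte Carlo band: permutations are shared across CpGs within a draw
  expect_lt(abs(frac - p_tail_exact), max(6 * mc_sd, 0.01))
})

test_that("concordance table assembles per-region metrics", {
  co <- small_cohort(seed = 12)
  ct <- concordance_table(co$betas, co$sheet)
  expect_equal(nrow(ct), nrow(co$betas))
  regs <- c("BA7", "BA10", "BA20")
  expect_true(all(paste0("rho_", regs) %in% names(ct)))
  expect_true(all(paste0("rr_", c("blood", regs)) %in% names(ct)))
  ok <- !is.na(ct$rho_BA7)
  expect_true(all(abs(ct$rho_BA7[ok]) <= 1))
  expect_true(all(ct$rr_blood >= 0 & ct$rr_blood <= 1))
  expect_true(all(ct$pct_BA7[ok] >= 0 & ct$pct_BA7[ok] <= 100))
  # percentile of the region maximum is 100
  expect_equal(ct$pct_BA7[which.max(ct$rho_BA7)], 100)
  # mean correlation averages available regions
  expect_equal(ct$rho_mean,
               rowMeans(cbind(ct$rho_BA7, ct$rho_BA10, ct$rho_BA20),
                        na.rm = TRUE))
})
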