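test_that("beta/M transform matches closed forms and inverts", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0), log2(1e-6 / (1 - 1e-6)))
  expect_equal(beta_to_m(0), -19.93157, tolerance = 1e-6)
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  expect_error(beta_to_m(-0.1), "\\[0, 1\\]")
  # inverse bijection on the clipped interval
  b <- seq(1e-6, 1 - 1e-6, length.out = 201)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  # strictly increasing
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("probe filtering removes listed and QC-failing probes in order", {
  m <- toy_betas(10, 20)
  probes <- rownames(m)
  # 2 on the SNP list, 1 on the cross-hyb list, none failing QC
  res <- filter_probes(m, snp_probes = probes[1:2], cross_hyb = probes[3])
  expect_equal(nrow(res$betas), 7)
  expect_equal(res$report$snp_probes, 2)
  expect_equal(res$report$cross_hybridizing, 1)
  expect_equal(res$report$retained + sum(res$report[, 2:5]), res$report$input)

  # a probe overlapping both lists counts once, under the first rule
  res2 <- filter_probes(m, snp_probes = probes[1:2], cross_hyb = probes[2:3])
  expect_equal(res2$report$snp_probes, 2)
  expect_equal(res2$report$cross_hybridizing, 1)
  expect_equal(nrow(res2$betas), 7)
})

test_that("sample-fraction thresholds are read as at-least", {
  m <- toy_betas(5, 20)
  bc <- matrix(10L, nrow = 5, ncol = 20, dimnames = dimnames(m))
  bc[2, 1] <- 2L  # bead count < 3 in exactly 1/20 = 5% of samples
  res <- filter_probes(m, bead_counts = bc)
  expect_false(rownames(m)[2] %in% rownames(res$betas))
  expect_equal(res$report$no_call, 1)
  # just under the fraction: kept
  bc19 <- bc[, 1:19]
  res2 <- filter_probes(m[, 1:19], bead_counts = bc19,
                        nocall_sample_frac = 0.06)
  expect_true(rownames(m)[2] %in% rownames(res2$betas))
})

test_that("all-pass filtering is the identity, and filtering is idempotent", {
  m <- toy_betas(8, 10)
  dp <- matrix(0.001, nrow = 8, ncol = 10, dimnames = dimnames(m))
  res <- filter_probes(m, detection_pvalues = dp)
  expect_identical(res$betas, m)
  expect_true(all(res$report[, 2:5] == 0))

  dp[1, ] <- 0.9
  once <- filter_probes(m, detection_pvalues = dp)
  twice <- filter_probes(once$betas,
                         detection_pvalues = dp[rownames(once$betas), ])
  expect_identical(once$betas, twice$betas)
  expect_true(all(twice$report[, 2:5] == 0))
  expect_error(filter_probes(m, snp_probes = rownames(m)), "all probes")
})

test_that("PCA association detects planted structure and self-association", {
  set.seed(31)
  n <- 40
  # two clusters shifted on many probes -> separation lands on a top PC
  cluster <- rep(c("a", "b"), each = n / 2)
  m <- matrix(rnorm(300 * n, 0, 0.3), nrow = 300)
  m[1:150, cluster == "b"] <- m[1:150, cluster == "b"] + 2
  m <- m_to_beta(m)
  rownames(m) <- sprintf("cg%07d", 1:300)
  colnames(m) <- sprintf("s%02d", 1:n)
  sheet <- data.frame(sample_id = colnames(m), cluster = cluster,
                      stringsAsFactors = FALSE)
  res <- pca_association(m, sheet, "cluster", n_pcs = 3, include_pc1 = TRUE)
  expect_lt(min(res$p_value), 1e-6)
  expect_true(all(res$test == "anova"))

  # continuous variable equal to PC scores -> rho 1
  pca <- prcomp(t(m), center = TRUE)
  sheet$score <- pca$x[, 2]
  res2 <- pca_association(m, sheet, "score", n_pcs = 1)
  expect_equal(res2$statistic[res2$pc == 2], 1)
  expect_true(all(res2$test == "spearman"))
})

test_that("PCA association p-values are calibrated for independent variables", {
  set.seed(77)
  m <- m_to_beta(matrix(rnorm(200 * 24), nrow = 200,
                        dimnames = list(sprintf("cg%07d", 1:200),
                                        sprintf("s%02d", 1:24))))
  hits <- replicate(100, {
    sheet <- data.frame(sample_id = colnames(m), v = rnorm(24))
    res <- pca_association(m, sheet, "v", n_pcs = 1)
    res$p_value > 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("constant sheet variables are skipped with a warning", {
  m <- toy_betas(20, 6)
  sheet <- data.frame(sample_id = colnames(m), flat = 1)
  expect_warning(res <- pca_association(m, sheet, "flat"), "constant")
  expect_null(res)
})

test_that("replicate RMSE matches hand-computed values", {
  m <- matrix(c(0.2, 0.5, 0.2, 0.5, 0.3, 0.6, 0.5, 0.9), nrow = 2,
              dimnames = list(c("cg1", "cg2"), c("r1", "r2", "r3", "r4")))
  expect_equal(unname(replicate_rmse(m, cbind("r1", "r2"))), 0)
  expect_equal(unname(replicate_rmse(m, cbind("r1", "r3"))), 0.1)
  # diffs 0.3 and 0.4 -> sqrt((0.09 + 0.16)/2)
  expect_equal(unname(replicate_rmse(m, cbind("r1", "r4"))),
               sqrt((0.09 + 0.16) / 2))
  expect_error(replicate_rmse(m, cbind("r1", "nope")), "not found")
  m[, "r2"] <- NA
  expect_error(replicate_rmse(m, cbind("r1", "r2")), "no probes")
})

test_that("deconvolution recovers exact and mixed memberships", {
  set.seed(5)
  ref <- matrix(runif(600, 0.05, 0.95), nrow = 150,
                dimnames = list(sprintf("cg%07d", 1:150), paste0("ct", 1:4)))
  # a sample equal to one reference column
  y1 <- ref[, 2, drop = FALSE]
  colnames(y1) <- "s1"
  est <- estimate_cell_proportions(y1, ref)
  expect_equal(unname(est$proportions[1, ]), c(0, 1, 0, 0), tolerance = 1e-9)
  # noise-free 50/50 mixture
  y2 <- matrix(0.5 * ref[, 1] + 0.5 * ref[, 3], dimnames = list(rownames(ref), "s2"))
  est2 <- estimate_cell_proportions(y2, ref)
  expect_equal(unname(est2$proportions[1, ]), c(0.5, 0, 0.5, 0),
               tolerance = 1e-6)
  expect_lt(est2$residual[1], 1e-9)
  # rows sum to one
  expect_equal(unname(rowSums(est2$proportions)), 1)
  # shared-probe floor
  expect_error(estimate_cell_proportions(y2[1:50, , drop = FALSE], ref),
               "shared")
  # collinear reference columns warn
  ref_bad <- cbind(ref, ct5 = ref[, 1])
  expect_warning(estimate_cell_proportions(y2, ref_bad), "collinear")
})

test_that("deconvolution recovers simulated proportions under noise", {
  cfg <- sim_config(n_cpgs_per_class = c(cell_driven = 300), noise_sd = 0.2,
                    missing_last_region = TRUE, seed = 17)
  co <- simulate_cohort(cfg)
  prof <- simulate_reference_profiles(cfg)
  err <- c()
  for (tc in c("blood", "brain")) {
    cols <- co$sheet$sample_id[co$sheet$tissue_class == tc]
    est <- estimate_cell_proportions(co$betas[, cols], prof[[tc]])
    err <- c(err, abs(est$proportions - co$truth$proportions[[tc]][cols, ]))
  }
  expect_equal(ncol(co$betas), 63)
  expect_lt(mean(err), 0.05)
})

test_that("cell adjustment removes compositional variance", {
  cfg <- sim_config(n_cpgs_per_class = c(concordant = 60, cell_driven = 60),
                    noise_sd = 0, batch_sd = 0, seed = 23)
  co <- simulate_cohort(cfg)
  cd <- names(co$truth$class)[co$truth$class == "cell_driven"]
  blood <- co$sheet$sample_id[co$sheet$tissue == "blood"]
  v_pre <- apply(co$betas[cd, blood], 1, var)
  # beta-scale residualization removes a linear mixture signal exactly
  adj_b <- adjust_cell_composition(co$betas, co$sheet, scale = "beta")
  v_post_b <- apply(adj_b[cd, blood], 1, var)
  expect_true(all(v_post_b < 1e-6 * v_pre))
  # M-scale residualization removes it up to logit curvature
  adj_m <- adjust_cell_composition(co$betas, co$sheet)
  v_post_m <- apply(adj_m[cd, blood], 1, var)
  expect_true(all(v_post_m < 0.05 * v_pre))
})

test_that("cell adjustment leaves the concordance distribution in place", {
  # one proportion covariate per group, so the sample-specific variance
  # removed per CpG is small (about 1/15 at 16 subjects)
  cfg <- sim_config(n_cpgs_per_class = c(concordant = 60, cell_driven = 60),
                    noise_sd = 0, batch_sd = 0, seed = 23,
                    n_cell_types = c(blood = 2, brain = 2))
  co <- simulate_cohort(cfg)
  adj <- adjust_cell_composition(co$betas, co$sheet)
  p <- tissue_pairing(co$sheet, "BA7")
  conc <- names(co$truth$class)[co$truth$class == "concordant"]
  rho_pre <- spearman_per_cpg(co$betas[conc, ], co$betas[conc, ], p)$rho
  rho_post <- spearman_per_cpg(adj[conc, ], adj[conc, ], p)$rho
  expect_lt(abs(median(rho_pre) - median(rho_post)), 0.05)
  expect_lt(mean(abs(rho_pre - rho_post)), 0.1)
})

test_that("cell adjustment preserves group means and handles degenerate input", {
  co <- small_cohort(seed = 3)
  adj <- adjust_cell_composition(co$betas, co$sheet)
  for (tc in c("blood", "brain")) {
    cols <- co$sheet$sample_id[co$sheet$tissue_class == tc]
    expect_equal(rowMeans(beta_to_m(adj[, cols])),
                 rowMeans(beta_to_m(co$betas[, cols])), tolerance = 1e-6)
  }
  # identical proportions in a group: output equals input
  sheet <- co$sheet
  pc <- grep("^prop_", names(sheet))
  for (j in pc) sheet[[j]] <- ifelse(is.na(sheet[[j]]), NA, 0.5)
  adj2 <- adjust_cell_composition(co$betas, sheet)
  expect_equal(adj2, co$betas, tolerance = 1e-9)
  # too-small group errors
  tiny <- co$sheet$sample_id[1:3]
  expect_error(adjust_cell_composition(co$betas[, tiny],
                                       co$sheet[1:3, ]), "too few samples")
})
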