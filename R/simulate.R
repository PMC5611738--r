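#' Configuration for a synthetic matched blood/brain cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' emulate a matched-tissue 450K-style study design: 16 subjects sampled in
#' whole blood and three cortical Brodmann areas (BA7, BA10, BA20), giving
#' 64 samples (63 when `missing_last_region = TRUE`, which drops the last
#' brain region of the last subject).
#'
#' Six ground-truth CpG classes are simulated:
#' \describe{
#'   \item{concordant}{a per-subject latent methylation level shared across
#'     tissues; cross-tissue correlation rises with `concordance_strength`.}
#'   \item{discordant}{tissues drawn independently.}
#'   \item{invariant}{near-constant betas (blood reference range < 0.05).}
#'   \item{polymorphic}{a SNP under Hardy--Weinberg equilibrium at `maf`
#'     drives trimodal betas (about 0.9 / 0.5 / 0.1 for genotypes 0/1/2),
#'     identical in every tissue.}
#'   \item{sex_linked}{mean beta differs by subject sex, identical in every
#'     tissue.}
#'   \item{cell_driven}{betas are convex combinations of cell-type-specific
#'     profiles weighted by each sample's true cell proportions.}
#' }
#'
#' @param n_subjects Number of subjects (default 16).
#' @param tissues Ordered tissue labels; the first is the surrogate (blood)
#'   tissue, the rest are brain regions.
#' @param n_cpgs_per_class Named integer vector of CpG counts for the six
#'   classes listed above.
#' @param concordance_strength Correlation parameter in `[0, 1]` for the
#'   concordant class: the fraction of the subject-level M-scale signal that
#'   is shared across tissues (1 = identical latent, 0 = independent).
#' @param noise_sd Measurement noise SD on the M scale (invariant CpGs use
#'   half this value so their betas stay within a 0.05 reference range).
#' @param maf Minor-allele frequency for the polymorphic class, in (0, 0.5].
#' @param subject_sd SD of the per-subject latent signal on the M scale for
#'   the concordant and discordant classes.
#' @param n_cell_types Named vector with elements `blood` and `brain`:
#'   number of reference cell types per tissue class (default 6 and 2).
#' @param batch_levels Number of chip (array) labels cycled over samples.
#' @param batch_sd SD of the additive per-chip, per-CpG shift on the M
#'   scale; set to 0 for batch-free data.
#' @param missing_last_region If `TRUE`, the last subject is missing the
#'   last brain region (63 samples in the default design).
#' @param seed Integer seed; identical configurations give bit-identical
#'   cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16,
                       tissues = c("blood", "BA7", "BA10", "BA20"),
                       n_cpgs_per_class = c(concordant = 500, discordant = 500,
                                            invariant = 200, polymorphic = 150,
                                            sex_linked = 100, cell_driven = 200),
                       concordance_strength = 0.8,
                       noise_sd = 0.3,
                       maf = 0.3,
                       subject_sd = 1,
                       n_cell_types = c(blood = 6, brain = 2),
                       batch_levels = 4,
                       batch_sd = 0.2,
                       missing_last_region = FALSE,
                       seed = 1) {
  classes <- c("concordant", "discordant", "invariant", "polymorphic",
               "sex_linked", "cell_driven")
  full <- stats::setNames(rep(0L, length(classes)), classes)
  if (is.null(names(n_cpgs_per_class)) ||
      !all(names(n_cpgs_per_class) %in% classes)) {
    stop("n_cpgs_per_class must be named with classes among: ",
         paste(classes, collapse = ", "))
  }
  full[names(n_cpgs_per_class)] <- as.integer(n_cpgs_per_class)
  if (any(full < 0) || sum(full) == 0) {
    stop("CpG class counts must be non-negative, with at least one positive")
  }
  stopifnot(
    n_subjects >= 2,
    length(tissues) >= 2, !anyDuplicated(tissues),
    concordance_strength >= 0, concordance_strength <= 1,
    noise_sd >= 0, subject_sd >= 0, batch_sd >= 0,
    maf > 0, maf <= 0.5,
    all(c("blood", "brain") %in% names(n_cell_types)),
    all(n_cell_types >= 1),
    batch_levels >= 1
  )
  structure(list(
    n_subjects = as.integer(n_subjects),
    tissues = tissues,
    n_cpgs_per_class = full,
    concordance_strength = concordance_strength,
    noise_sd = noise_sd,
    maf = maf,
    subject_sd = subject_sd,
    n_cell_types = c(blood = as.integer(n_cell_types[["blood"]]),
                     brain = as.integer(n_cell_types[["brain"]])),
    batch_levels = as.integer(batch_levels),
    batch_sd = batch_sd,
    missing_last_region = isTRUE(missing_last_region),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_subjects, "subjects x",
      length(x$tissues), "tissues;",
      sum(x$n_cpgs_per_class), "CpGs (",
      paste(names(x$n_cpgs_per_class), x$n_cpgs_per_class,
            sep = "=", collapse = ", "), ")\n")
  cat("  concordance_strength =", x$concordance_strength,
      " noise_sd =", x$noise_sd, " maf =", x$maf,
      " batch_sd =", x$batch_sd, " seed =", x$seed, "\n")
  invisible(x)
}

# Dirichlet draw: one row per sample. alpha sets both mean and spread.
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Reference cell-type beta profiles for the cell_driven class, one matrix
# per tissue class (blood, brain). Drawn with its own derived seed so
# simulate_reference_profiles() can reproduce them independently of the
# rest of the cohort's random draws.
.cell_profiles <- function(config) {
  n_cd <- config$n_cpgs_per_class[["cell_driven"]]
  probe_ids <- .probe_ids(config)$cell_driven
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  out <- list()
  for (tc in c("blood", "brain")) {
    k <- config$n_cell_types[[tc]]
    prof <- matrix(stats::runif(n_cd * k, 0.05, 0.95), nrow = n_cd,
                   dimnames = list(probe_ids, paste0(tc, "_ct", seq_len(k))))
    out[[tc]] <- prof
  }
  out
}

# Probe identifiers per class, in class block order.
.probe_ids <- function(config) {
  counts <- config$n_cpgs_per_class
  ids <- sprintf("cg%07d", seq_len(sum(counts)))
  split(ids, rep(names(counts), counts))[names(counts)]
}

#' Cell-type reference profiles used by the simulator
#'
#' Returns the exact cell-type-specific beta profiles that
#' [simulate_cohort()] mixes (by each sample's true cell proportions) to
#' generate the `cell_driven` CpG class. These play the role of sorted-cell
#' reference epigenomes for testing reference-based deconvolution.
#'
#' @param config A [sim_config()].
#' @return Named list with elements `blood` and `brain`, each a CpG-by-cell-type
#'   beta matrix with `cell_driven` probe IDs as row names. Tissues with a
#'   single cell type yield a single-column matrix.
#' @export
simulate_reference_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cpgs_per_class[["cell_driven"]] == 0) {
    stop("cell_driven class count is zero; no reference profiles exist")
  }
  .cell_profiles(config)
}

#' Simulate a matched blood/brain methylation cohort
#'
#' Generates a CpG-by-sample beta matrix covering all tissues, a sample
#' sheet, a probe annotation and the ground-truth labels, following the
#' class-generative models described in [sim_config()]. All latent signals
#' and noise are generated on the M scale and converted to betas (clipped
#' to the open unit interval), keeping additive noise well-defined near the
#' 0/1 boundaries. Per-chip batch effects are additive M-scale shifts.
#'
#' @param config A [sim_config()].
#' @return A list of class `meth_cohort` with elements:
#' \describe{
#'   \item{betas}{numeric CpG x sample matrix in (0, 1).}
#'   \item{sheet}{sample sheet `data.frame`: `sample_id`, `subject_id`,
#'     `tissue`, `tissue_class` (blood/brain), `sex`, `age`, `chip`, and
#'     `prop_*` columns with the true cell proportions (blood cell types for
#'     blood samples, brain cell types for brain samples; the other block
#'     is `NA`).}
#'   \item{annotation}{probe annotation `data.frame`: `probe_id`,
#'     `chromosome`, `position`, `polymorphic` flag, `island_relation`.}
#'   \item{truth}{list with `class` (named per-probe class labels),
#'     `genotypes` (polymorphic CpG x subject matrix in 0/1/2),
#'     `profiles` (the [simulate_reference_profiles()] output),
#'     `proportions` (sample x cell-type true proportions per tissue class).}
#' }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$n_cpgs_per_class
  ids_by_class <- .probe_ids(config)
  probe_ids <- unlist(ids_by_class, use.names = FALSE)
  class_of <- rep(names(counts), counts)
  names(class_of) <- probe_ids

  profiles <- if (counts[["cell_driven"]] > 0) .cell_profiles(config) else NULL
  # sections use derived sub-seeds so that, e.g., changing the number of
  # cell types perturbs only the proportion draws and the cell_driven class
  sect_seed <- function(k) set.seed((config$seed + k) %% .Machine$integer.max)
  sect_seed(1L)

  ## ---- samples ----
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  sex <- rep_len(c("female", "male"), config$n_subjects)
  age <- round(stats::runif(config$n_subjects, 20, 80), 1)
  sheet <- expand.grid(tissue = config$tissues, subject_id = subjects,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- sheet[, c("subject_id", "tissue")]
  if (config$missing_last_region) {
    drop <- sheet$subject_id == subjects[config$n_subjects] &
      sheet$tissue == config$tissues[length(config$tissues)]
    sheet <- sheet[!drop, , drop = FALSE]
  }
  sheet$sample_id <- paste(sheet$subject_id, sheet$tissue, sep = "_")
  sheet$tissue_class <- ifelse(sheet$tissue == config$tissues[1],
                               "blood", "brain")
  sheet$sex <- sex[match(sheet$subject_id, subjects)]
  sheet$age <- age[match(sheet$subject_id, subjects)]
  # randomized balanced chip assignment: chips are confounded with neither
  # tissue nor subject, so batch shifts cannot masquerade as either effect
  sheet$chip <- paste0("chip", sample(rep_len(seq_len(config$batch_levels),
                                              nrow(sheet))))
  n_samp <- nrow(sheet)

  ## ---- true cell proportions ----
  blood_alpha <- c(11, 3, 2, 2, 1.4, 0.6)[seq_len(config$n_cell_types[["blood"]])]
  brain_alpha <- c(7, 13, 2, 2, 1, 1)[seq_len(config$n_cell_types[["brain"]])]
  prop_cols <- list(
    blood = paste0("prop_", colnames(profiles$blood %||%
      matrix(nrow = 0, ncol = config$n_cell_types[["blood"]],
             dimnames = list(NULL, paste0("blood_ct",
               seq_len(config$n_cell_types[["blood"]])))))),
    brain = paste0("prop_", colnames(profiles$brain %||%
      matrix(nrow = 0, ncol = config$n_cell_types[["brain"]],
             dimnames = list(NULL, paste0("brain_ct",
               seq_len(config$n_cell_types[["brain"]]))))))
  )
  sect_seed(2L)
  props <- list(
    blood = .rdirichlet(sum(sheet$tissue_class == "blood"), blood_alpha),
    brain = .rdirichlet(sum(sheet$tissue_class == "brain"), brain_alpha)
  )
  rownames(props$blood) <- sheet$sample_id[sheet$tissue_class == "blood"]
  rownames(props$brain) <- sheet$sample_id[sheet$tissue_class == "brain"]
  colnames(props$blood) <- sub("^prop_", "", prop_cols$blood)
  colnames(props$brain) <- sub("^prop_", "", prop_cols$brain)
  for (tc in c("blood", "brain")) {
    for (j in seq_along(prop_cols[[tc]])) {
      sheet[[prop_cols[[tc]][j]]] <- NA_real_
      sheet[[prop_cols[[tc]][j]]][match(rownames(props[[tc]]), sheet$sample_id)] <-
        props[[tc]][, j]
    }
  }

  ## ---- M-scale signal per class ----
  m <- matrix(NA_real_, nrow = length(probe_ids), ncol = n_samp,
              dimnames = list(probe_ids, sheet$sample_id))
  subj_idx <- match(sheet$subject_id, subjects)
  s <- config$concordance_strength

  if (counts[["concordant"]] > 0) {
    sect_seed(11L)
    n <- counts[["concordant"]]
    mu <- stats::rnorm(n, 0, 1)
    z <- matrix(stats::rnorm(n * config$n_subjects), nrow = n)
    e <- matrix(stats::rnorm(n * n_samp), nrow = n)
    m[ids_by_class$concordant, ] <- mu +
      config$subject_sd * (s * z[, subj_idx, drop = FALSE] +
                             sqrt(1 - s^2) * e)
  }
  if (counts[["discordant"]] > 0) {
    sect_seed(12L)
    n <- counts[["discordant"]]
    # per-subject draws are independent in every tissue (no cross-tissue
    # correlation); mean levels differ between blood and brain only, so
    # planted differential signal is blood:brain, never brain:brain
    mu_bl <- stats::rnorm(n, 0, 1)
    mu_br <- stats::rnorm(n, 0, 1)
    e <- matrix(stats::rnorm(n * n_samp), nrow = n)
    mu <- cbind(blood = mu_bl, brain = mu_br)
    m[ids_by_class$discordant, ] <-
      mu[, ifelse(sheet$tissue_class == "blood", 1L, 2L), drop = FALSE] +
      config$subject_sd * e
  }
  if (counts[["invariant"]] > 0) {
    sect_seed(13L)
    n <- counts[["invariant"]]
    mu <- sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 3.5, 5)
    m[ids_by_class$invariant, ] <- mu  # noise added below at half SD
  }
  geno <- NULL
  if (counts[["polymorphic"]] > 0) {
    sect_seed(14L)
    n <- counts[["polymorphic"]]
    geno <- matrix(stats::rbinom(n * config$n_subjects, 2, config$maf),
                   nrow = n, dimnames = list(ids_by_class$polymorphic, subjects))
    geno_m <- beta_to_m(c(0.9, 0.5, 0.1))  # genotype 0 / 1 / 2
    m[ids_by_class$polymorphic, ] <-
      matrix(geno_m[geno[, subj_idx, drop = FALSE] + 1L], nrow = n)
  }
  if (counts[["sex_linked"]] > 0) {
    n <- counts[["sex_linked"]]
    sex_m <- beta_to_m(c(female = 0.75, male = 0.25))
    m[ids_by_class$sex_linked, ] <-
      matrix(rep(sex_m[sheet$sex], each = n), nrow = n)
  }
  if (counts[["cell_driven"]] > 0) {
    betas_cd <- matrix(NA_real_, nrow = counts[["cell_driven"]], ncol = n_samp,
                       dimnames = list(ids_by_class$cell_driven, sheet$sample_id))
    for (tc in c("blood", "brain")) {
      sel <- sheet$tissue_class == tc
      betas_cd[, sel] <- profiles[[tc]] %*% t(props[[tc]][sheet$sample_id[sel], ,
                                                          drop = FALSE])
    }
    m[ids_by_class$cell_driven, ] <- beta_to_m(betas_cd)
  }

  ## ---- measurement noise (invariant CpGs at half SD) ----
  sect_seed(3L)
  noise <- matrix(stats::rnorm(length(m), 0, config$noise_sd), nrow = nrow(m))
  inv_rows <- class_of == "invariant"
  noise[inv_rows, ] <- noise[inv_rows, ] / 2
  m <- m + noise

  ## ---- additive per-chip batch shifts ----
  if (config$batch_sd > 0 && config$batch_levels > 1) {
    sect_seed(4L)
    shift <- matrix(stats::rnorm(nrow(m) * config$batch_levels, 0,
                                 config$batch_sd), nrow = nrow(m))
    chip_idx <- as.integer(sub("^chip", "", sheet$chip))
    m <- m + shift[, chip_idx, drop = FALSE]
  }

  betas <- m_to_beta(m)
  betas <- pmin(pmax(betas, 1e-6), 1 - 1e-6)

  ## ---- probe annotation ----
  sect_seed(5L)
  autosomes <- paste0("chr", 1:22)
  chrom <- sample(autosomes, length(probe_ids), replace = TRUE)
  chrom[class_of == "sex_linked"] <- sample(c("chrX", "chrY"),
                                            sum(class_of == "sex_linked"),
                                            replace = TRUE, prob = c(0.9, 0.1))
  annotation <- data.frame(
    probe_id = probe_ids,
    chromosome = chrom,
    position = sample.int(2e8, length(probe_ids), replace = TRUE),
    polymorphic = class_of == "polymorphic",
    island_relation = sample(c("island", "shore", "shelf", "open_sea"),
                             length(probe_ids), replace = TRUE,
                             prob = c(0.3, 0.25, 0.1, 0.35)),
    stringsAsFactors = FALSE
  )

  structure(list(
    betas = betas,
    sheet = sheet[, c("sample_id", "subject_id", "tissue", "tissue_class",
                      "sex", "age", "chip",
                      prop_cols$blood, prop_cols$brain)],
    annotation = annotation,
    truth = list(class = class_of, genotypes = geno,
                 profiles = profiles, proportions = props),
    config = config
  ), class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("meth_cohort:", nrow(x$betas), "CpGs x", ncol(x$betas), "samples (",
      length(unique(x$sheet$subject_id)), "subjects,",
      length(unique(x$sheet$tissue)), "tissues )\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
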