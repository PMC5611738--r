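#' Read and write the pipeline's plain-text formats
#'
#' Beta matrices travel as TSV (first column `probe_id`, one column per
#' sample), sample sheets and annotations as CSV, probe lists as
#' newline-delimited text.
#'
#' @param betas CpG x sample beta matrix.
#' @param path File path.
#' @return `read_beta_matrix` returns a numeric matrix with probe row
#'   names; writers return the path invisibly.
#' @name meth_io
NULL

#' @rdname meth_io
#' @export
write_beta_matrix <- function(betas, path) {
  df <- data.frame(probe_id = rownames(betas), betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname meth_io
#' @param sheet A sample-sheet or annotation `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname meth_io
#' @export
read_probe_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write a simulated cohort to a directory
#'
#' Writes `betas.tsv`, `sample_sheet.csv`, `probe_annotation.csv`,
#' `truth_classes.csv` and (when present) `truth_genotypes.csv` under
#' `outdir`.
#'
#' @param cohort A `meth_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$betas, file.path(outdir, "betas.tsv"))
  write_sample_sheet(cohort$sheet, file.path(outdir, "sample_sheet.csv"))
  write_sample_sheet(cohort$annotation,
                     file.path(outdir, "probe_annotation.csv"))
  write_sample_sheet(
    data.frame(probe_id = names(cohort$truth$class),
               class = unname(cohort$truth$class)),
    file.path(outdir, "truth_classes.csv"))
  if (!is.null(cohort$truth$genotypes)) {
    g <- data.frame(probe_id = rownames(cohort$truth$genotypes),
                    cohort$truth$genotypes, check.names = FALSE)
    write_sample_sheet(g, file.path(outdir, "truth_genotypes.csv"))
  }
  invisible(outdir)
}

#' Write and re-read a metrics table
#'
#' The metrics table is stored as TSV with a versioned comment header;
#' floating point columns round-trip to full double precision.
#'
#' @param table A `cpg_metrics` table.
#' @param path File path.
#' @return `read_metrics_table` returns the table; the writer returns
#'   the path invisibly.
#' @export
write_metrics_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# methcord cpg_metrics v",
                    as.character(utils::packageVersion("methcord"))), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  out <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  class(out) <- c("cpg_metrics", "data.frame")
  out
}
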