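#' Read gene models from a BED file
#'
#' Loads transcript models (BED6 or BED12) and returns them as 1-based
#' closed intervals suitable for comparison with array-manifest probe
#' positions. The BED name field is split as `gene|transcript` when a
#' `|` is present, otherwise the name serves as both gene symbol and
#' transcript ID.
#'
#' @param path Path to a BED file.
#' @return `data.frame` with `gene`, `transcript`, `chromosome`, `strand`,
#'   `start`, `end` (1-based, closed).
#' @export
read_gene_models_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- as.character(gr$name)
  has_tx <- grepl("\\|", nm)
  gene <- ifelse(has_tx, sub("\\|.*$", "", nm), nm)
  tx <- ifelse(has_tx, sub("^.*\\|", "", nm), nm)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("gene models must be stranded")
  out <- data.frame(
    gene = gene, transcript = tx,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr),   # GRanges import is already 1-based
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("malformed intervals in gene models")
  out
}

#' Associate CpGs with genes and genomic features
#'
#' Inclusive multi-gene, multi-feature assignment: for every probe and
#' every transcript on the same chromosome, the probe is
#' \describe{
#'   \item{promoter}{within `[TSS - promoter_up, TSS + promoter_down]`,
#'     strand-aware;}
#'   \item{intragenic}{within the transcript body;}
#'   \item{three_prime}{within `[transcript end, end + three_prime_down]`,
#'     strand-aware.}
#' }
#' A probe may accumulate several features and several genes across
#' transcripts; a gene is associated if any of its transcripts is
#' (transcript-level union). Probes matching nothing are `intergenic`.
#'
#' @param probes `data.frame` with `probe_id`, `chromosome`, `position`
#'   (1-based).
#' @param genes Gene models as returned by [read_gene_models_bed()] (or
#'   any `data.frame` with the same columns, 1-based closed).
#' @param promoter_up,promoter_down Promoter window around the TSS in bp
#'   (defaults 1500 upstream, 300 downstream).
#' @param three_prime_down Extent of the 3' window beyond the transcript
#'   end in bp (default 300).
#' @return `data.frame` keyed by `probe_id` with logical columns
#'   `promoter`, `intragenic`, `three_prime`, `intergenic` and a
#'   comma-separated `genes` column (empty for intergenic probes).
#' @export
associate_cpgs <- function(probes, genes, promoter_up = 1500,
                           promoter_down = 300, three_prime_down = 300) {
  stopifnot(all(c("probe_id", "chromosome", "position") %in% names(probes)),
            all(c("gene", "chromosome", "strand", "start", "end") %in%
                  names(genes)))
  if (any(genes$start > genes$end)) stop("malformed gene intervals")
  pg <- GenomicRanges::GRanges(probes$chromosome,
                               IRanges::IRanges(probes$position, width = 1))
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  tes <- ifelse(plus, genes$end, genes$start)
  windows <- list(
    promoter = IRanges::IRanges(
      start = ifelse(plus, tss - promoter_up, tss - promoter_down),
      end = ifelse(plus, tss + promoter_down, tss + promoter_up)),
    intragenic = IRanges::IRanges(genes$start, genes$end),
    three_prime = IRanges::IRanges(
      start = ifelse(plus, tes, tes - three_prime_down),
      end = ifelse(plus, tes + three_prime_down, tes))
  )
  out <- data.frame(probe_id = probes$probe_id, promoter = FALSE,
                    intragenic = FALSE, three_prime = FALSE,
                    stringsAsFactors = FALSE)
  gene_sets <- vector("list", nrow(probes))
  for (feat in names(windows)) {
    w <- windows[[feat]]
    # clip windows running off the contig start
    w <- IRanges::IRanges(pmax(IRanges::start(w), 1L), IRanges::end(w))
    gg <- GenomicRanges::GRanges(genes$chromosome, w)
    hits <- GenomicRanges::findOverlaps(pg, gg)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    out[[feat]][unique(qi)] <- TRUE
    for (k in seq_along(qi)) {
      gene_sets[[qi[k]]] <- c(gene_sets[[qi[k]]], genes$gene[si[k]])
    }
  }
  out$intergenic <- !(out$promoter | out$intragenic | out$three_prime)
  out$genes <- vapply(gene_sets, function(g)
    paste(sort(unique(g)), collapse = ","), character(1))
  out
}

#' Long-format feature map from a probe association table
#'
#' Expands an [associate_cpgs()] table into one row per (probe, feature),
#' the layout used by the enrichment functions.
#'
#' @param assoc Output of [associate_cpgs()]; extra logical columns (for
#'   example island-relation indicators) are included as features too.
#' @return `data.frame` with columns `probe_id`, `feature`.
#' @export
feature_map <- function(assoc) {
  feats <- setdiff(names(assoc)[vapply(assoc, is.logical, logical(1))],
                   character(0))
  out <- lapply(feats, function(f)
    data.frame(probe_id = assoc$probe_id[assoc[[f]]],
               feature = rep(f, sum(assoc[[f]])),
               stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Genes with many informative CpGs
#'
#' Genes associated with at least `min_cpgs` informative CpGs, the
#' gene-level summary of an informative-CpG list.
#'
#' @param assoc Output of [associate_cpgs()] covering the informative set.
#' @param informative Character vector of informative probe IDs.
#' @param min_cpgs Minimum informative-CpG count per gene (default 10).
#' @return `data.frame` with `gene` and `n_informative`, sorted by count.
#' @export
informative_genes <- function(assoc, informative, min_cpgs = 10) {
  sub <- assoc[assoc$probe_id %in% informative & nzchar(assoc$genes), ,
               drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(gene = character(0), n_informative = integer(0)))
  }
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(sub)), function(i)
    data.frame(probe_id = sub$probe_id[i],
               gene = strsplit(sub$genes[i], ",")[[1]],
               stringsAsFactors = FALSE))))
  tab <- table(pairs$gene)
  tab <- tab[tab >= min_cpgs]
  out <- data.frame(gene = names(tab), n_informative = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_informative, out$gene), , drop = FALSE]
}
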