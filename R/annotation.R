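# Gene models and GFF3 annotation. Internal coordinates are 0-based
# half-open; GFF3 is 1-based inclusive, converted only at the I/O boundary.

#' Construct a gene model
#'
#' A gene is described by its exons; introns are derived as exactly the gaps
#' between consecutive exons, and a promoter window extends upstream of the
#' transcription start site (TSS). Exon and intron numbering follows the
#' direction of transcription, so intron 1 of a minus-strand gene is the gap
#' with the highest genomic coordinates.
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix of 0-based half-open `[start, end)` exon
#'   intervals, ordered by genomic coordinate, non-overlapping.
#' @param promoter_width width (bp) of the upstream promoter window; the
#'   window abuts the TSS and never overlaps the transcribed region.
#' @return An object of class `gene_model` with fields `exons`, `introns`,
#'   `promoter`, `tss`, `span`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, promoter_width = 2000L) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("gene ", gene_id, ": empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("gene ", gene_id, ": overlapping exons")
  n <- nrow(exons)
  introns <- if (n > 1)
    cbind(exons[-n, 2], exons[-1, 1]) else matrix(numeric(0), 0, 2)
  span <- c(exons[1, 1], exons[n, 2])
  tss <- if (strand == "+") span[1] else span[2]
  promoter <- if (strand == "+")
    c(span[1] - promoter_width, span[1]) else c(span[2], span[2] + promoter_width)
  if (promoter[1] < 0)
    stop("gene ", gene_id, ": promoter window extends past the chromosome start")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = tss, exons = exons, introns = introns,
                 promoter = promoter, span = span,
                 promoter_width = promoter_width),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exons\n", x$gene_id,
              x$chrom, x$span[1], x$span[2], x$strand, nrow(x$exons)))
  invisible(x)
}

#' Feature intervals of a gene
#'
#' Lists the promoter, exons and introns of a gene as genomic intervals
#' labelled in transcription order (`promoter`, `exon_1`, `intron_1`, ...).
#'
#' @param gene a [gene_model()].
#' @return `data.frame` with columns feature, chrom, start, end (0-based
#'   half-open).
#' @export
gene_features <- function(gene) {
  n <- nrow(gene$exons)
  # transcription order: reverse genomic order on the minus strand
  ex_ord <- if (gene$strand == "+") seq_len(n) else rev(seq_len(n))
  in_ord <- if (gene$strand == "+") seq_len(max(n - 1, 0)) else rev(seq_len(max(n - 1, 0)))
  feats <- rbind(
    data.frame(feature = "promoter", start = gene$promoter[1],
               end = gene$promoter[2]),
    data.frame(feature = paste0("exon_", order(ex_ord)),
               start = gene$exons[, 1], end = gene$exons[, 2]),
    if (n > 1)
      data.frame(feature = paste0("intron_", order(in_ord)),
                 start = gene$introns[, 1], end = gene$introns[, 2])
  )
  feats$chrom <- gene$chrom
  feats[, c("feature", "chrom", "start", "end")]
}

#' Build an annotation collection
#'
#' @param genes list of [gene_model()]s.
#' @return An object of class `gene_annotation`; genes retrievable by id with
#'   `ann$genes[[id]]`, insertion order irrelevant for queries.
#' @export
gene_annotation <- function(genes) {
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene ids in annotation")
  names(genes) <- ids
  structure(list(genes = genes[order(ids)]), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation>", length(x$genes), "genes\n")
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon features with ID/Parent links, 1-based
#' inclusive coordinates.
#'
#' @param annotation a [gene_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  rows <- lapply(annotation$genes, function(g) {
    n <- nrow(g$exons)
    gr <- GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = c(g$span[1], g$span[1], g$exons[, 1]) + 1L,
                                end = c(g$span[2], g$span[2], g$exons[, 2])),
      strand = g$strand)
    gr$type <- c("gene", "mRNA", rep("exon", n))
    gr$ID <- c(g$gene_id, paste0(g$gene_id, ".1"),
               paste0(g$gene_id, ".1.exon", seq_len(n)))
    gr$Parent <- c(NA_character_, g$gene_id, rep(paste0(g$gene_id, ".1"), n))
    gr
  })
  gr <- do.call(c, unname(rows))
  gr$Parent <- IRanges::CharacterList(lapply(gr$Parent, function(p)
    if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon features and rebuilds [gene_model()]s with derived
#' introns and promoter windows. GFF3 1-based inclusive coordinates are
#' converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @param promoter_width promoter window width in bp (not stored in GFF3).
#' @return A [gene_annotation()].
#' @export
read_gff3 <- function(path, promoter_width = 2000L) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes_gr <- gr[type == "gene"]
  mrna_gr <- gr[type == "mRNA"]
  exon_gr <- gr[type == "exon"]
  # map exon -> gene, possibly through an mRNA
  mrna_parent <- setNames(vapply(mrna_gr$Parent, `[`, character(1), 1),
                          mrna_gr$ID)
  exon_parent <- vapply(exon_gr$Parent, `[`, character(1), 1)
  exon_gene <- ifelse(exon_parent %in% names(mrna_parent),
                      mrna_parent[exon_parent], exon_parent)
  genes <- lapply(seq_along(genes_gr), function(i) {
    gid <- genes_gr$ID[i]
    ex <- exon_gr[exon_gene == gid]
    if (length(ex) == 0L) stop("gene ", gid, " has no exons")
    ex_start <- GenomicRanges::start(ex) - 1L
    ex_end <- GenomicRanges::end(ex)
    g_start <- GenomicRanges::start(genes_gr[i]) - 1L
    g_end <- GenomicRanges::end(genes_gr[i])
    if (any(ex_start < g_start) || any(ex_end > g_end))
      stop("gene ", gid, ": exon outside the gene span")
    gene_model(gid, as.character(GenomicRanges::seqnames(genes_gr[i])),
               as.character(GenomicRanges::strand(genes_gr[i])),
               matrix(c(ex_start, ex_end), ncol = 2),
               promoter_width = promoter_width)
  })
  gene_annotation(genes)
}
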