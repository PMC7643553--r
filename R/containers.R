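#' Annotation set: reference gene models
#'
#' Container for reference annotation: gene spans with strand and biotype,
#' their ordered exon intervals, and chromosome lengths. Coordinates are
#' 1-based closed throughout, the GFF/GTF and IRanges convention.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, `biotype`
#'   (`"protein_coding"` or `"pseudogene"`).
#' @param exons data.frame with columns `gene_id`, `start`, `end`; each
#'   exon must lie within its gene span and exons of one gene must be
#'   non-overlapping.
#' @param seqlengths named integer vector of chromosome lengths.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(genes, exons, seqlengths) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  if (!all(req %in% names(genes)))
    stop("genes must have columns: ", paste(req, collapse = ", "))
  if (!all(c("gene_id", "start", "end") %in% names(exons)))
    stop("exons must have columns gene_id, start, end")
  genes <- genes[req]
  exons <- exons[c("gene_id", "start", "end")]
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand symbol in gene table: ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  if (!all(genes$biotype %in% c("protein_coding", "pseudogene")))
    stop("biotype must be protein_coding or pseudogene")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids")
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exon references unknown gene id")
  if (!all(genes$chrom %in% names(seqlengths)))
    stop("gene on chromosome absent from seqlengths")
  if (any(genes$start < 1L) || any(genes$end > seqlengths[genes$chrom]))
    stop("gene span outside chromosome bounds")
  # sort exons within gene and check containment / non-overlap
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  idx <- match(exons$gene_id, genes$gene_id)
  if (any(exons$start < genes$start[idx]) || any(exons$end > genes$end[idx]))
    stop("exon outside gene span")
  if (any(exons$end < exons$start)) stop("exon end before start")
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (ii in by_gene) {
    if (length(ii) > 1L &&
        any(exons$start[ii][-1L] <= exons$end[ii][-length(ii)]))
      stop("overlapping exons within gene ", exons$gene_id[ii[1L]])
  }
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons,
                 seqlengths = setNames(as.integer(seqlengths),
                                       names(seqlengths))),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "protein_coding"), "protein-coding,",
      sum(x$genes$biotype == "pseudogene"), "pseudogene ) on",
      length(x$seqlengths), "sequences\n")
  invisible(x)
}

#' @rdname annotation_set
#' @param x an `AnnotationSet`.
#' @export
genes_granges <- function(x) {
  stopifnot(inherits(x, "AnnotationSet"))
  gr <- GenomicRanges::GRanges(
    seqnames = x$genes$chrom,
    ranges = IRanges::IRanges(x$genes$start, x$genes$end),
    strand = x$genes$strand,
    gene_id = x$genes$gene_id,
    biotype = x$genes$biotype)
  GenomeInfoDb::seqlengths(gr) <- x$seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' @rdname annotation_set
#' @export
exons_granges <- function(x) {
  stopifnot(inherits(x, "AnnotationSet"))
  idx <- match(x$exons$gene_id, x$genes$gene_id)
  GenomicRanges::GRanges(
    seqnames = x$genes$chrom[idx],
    ranges = IRanges::IRanges(x$exons$start, x$exons$end),
    strand = x$genes$strand[idx],
    gene_id = x$exons$gene_id)
}

#' Transcript set: assembled transcript models
#'
#' Container for assembled transcripts: per-transcript exon intervals
#' (1-based closed), derived spans and spliced lengths, and an optional
#' abundance (FPKM) value per transcript for the discovery sample.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (one row per exon).
#' @param fpkm optional named numeric vector of abundances; names are
#'   transcript ids. Missing transcripts get `NA`.
#' @return An object of class `TranscriptSet` with elements `transcripts`
#'   (one row per transcript: span, exon count, spliced length, fpkm)
#'   and `exons`.
#' @export
transcript_set <- function(exons, fpkm = NULL) {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  req <- c("transcript_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(exons)))
    stop("exons must have columns: ", paste(req, collapse = ", "))
  if (!all(exons$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(exons$strand, c("+", "-"))), collapse = ", "))
  if (any(exons$end < exons$start)) stop("exon end before start")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  tx <- data.frame(
    transcript_id = names(sp),
    chrom = vapply(sp, function(i) exons$chrom[i[1L]], ""),
    strand = vapply(sp, function(i) exons$strand[i[1L]], ""),
    start = vapply(sp, function(i) min(exons$start[i]), 0),
    end = vapply(sp, function(i) max(exons$end[i]), 0),
    n_exons = lengths(sp),
    spliced_length = vapply(sp, function(i)
      sum(exons$end[i] - exons$start[i] + 1), 0),
    stringsAsFactors = FALSE)
  for (i in sp) {
    if (length(unique(exons$chrom[i])) > 1L ||
        length(unique(exons$strand[i])) > 1L)
      stop("transcript ", exons$transcript_id[i[1L]],
           " mixes chromosomes or strands")
  }
  fp <- rep(NA_real_, nrow(tx))
  names(fp) <- tx$transcript_id
  if (!is.null(fpkm)) {
    if (is.null(names(fpkm))) stop("fpkm must be named by transcript id")
    if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM must be non-negative")
    keep <- intersect(names(fpkm), tx$transcript_id)
    fp[keep] <- fpkm[keep]
  }
  tx$fpkm <- unname(fp)
  rownames(tx) <- NULL
  structure(list(transcripts = tx, exons = exons), class = "TranscriptSet")
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat("TranscriptSet:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' @rdname transcript_set
#' @param x a `TranscriptSet`.
#' @export
transcripts_granges <- function(x) {
  stopifnot(inherits(x, "TranscriptSet"))
  GenomicRanges::GRanges(
    seqnames = x$transcripts$chrom,
    ranges = IRanges::IRanges(x$transcripts$start, x$transcripts$end),
    strand = x$transcripts$strand,
    transcript_id = x$transcripts$transcript_id)
}

#' @rdname transcript_set
#' @export
transcript_exons_granges <- function(x) {
  stopifnot(inherits(x, "TranscriptSet"))
  GenomicRanges::GRanges(
    seqnames = x$exons$chrom,
    ranges = IRanges::IRanges(x$exons$start, x$exons$end),
    strand = x$exons$strand,
    transcript_id = x$exons$transcript_id)
}

#' Genotype table: biallelic SNP calls
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `allele_a`, `allele_b` (single nucleotide letters).
#' @param calls character matrix, SNPs in rows (rownames = snp ids),
#'   individuals in columns; entries `"AA"`, `"AB"`, `"BB"` or `NA`.
#' @return An object of class `GenotypeTable`.
#' @export
genotype_table <- function(snps, calls) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(req %in% names(snps)))
    stop("snps must have columns: ", paste(req, collapse = ", "))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(snps)) stop("calls rows must match snp table")
  if (is.null(colnames(calls))) stop("calls must name individuals")
  rownames(calls) <- snps$snp_id
  ok <- calls %in% c("AA", "AB", "BB") | is.na(calls)
  if (!all(ok)) stop("calls must be AA/AB/BB or NA")
  rownames(snps) <- NULL
  structure(list(snps = snps, calls = calls), class = "GenotypeTable")
}

#' @export
print.GenotypeTable <- function(x, ...) {
  cat("GenotypeTable:", nrow(x$snps), "SNPs x", ncol(x$calls),
      "individuals\n")
  invisible(x)
}

#' Genotype dosage matrix
#'
#' Converts calls to counts of the B allele (0/1/2), `NA` for missing.
#'
#' @param gt a `GenotypeTable`.
#' @return Integer matrix, SNPs x individuals.
#' @export
genotype_dosage <- function(gt) {
  stopifnot(inherits(gt, "GenotypeTable"))
  d <- matrix(NA_integer_, nrow(gt$calls), ncol(gt$calls),
              dimnames = dimnames(gt$calls))
  d[gt$calls == "AA"] <- 0L
  d[gt$calls == "AB"] <- 1L
  d[gt$calls == "BB"] <- 2L
  d
}

#' Expression matrix of FPKM values
#'
#' Features in rows, samples in columns; values are non-negative FPKM.
#'
#' @param values numeric matrix with rownames (features) and colnames
#'   (samples).
#' @return A numeric matrix of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)))
    stop("expression matrix needs feature rownames")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%02d", seq_len(ncol(values)))
  if (any(values < 0, na.rm = TRUE)) stop("FPKM must be non-negative")
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' Per-feature maximum FPKM across samples
#'
#' @param x an expression matrix (features x samples).
#' @return Named numeric vector of row maxima (FPKM_max).
#' @export
fpkm_max <- function(x) {
  apply(unclass(x), 1L, max)
}
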