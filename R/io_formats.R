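# Readers/writers for the standard formats the pipeline touches.
# All genomic coordinates are 1-based closed, the GFF/GTF convention,
# and are kept that way internally (IRanges native).

.validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop("malformed annotation line ", i, ": expected >= 8 tab-separated ",
           "fields, got ", length(f))
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L]))))
      stop("malformed annotation line ", i, ": non-numeric coordinates")
    if (!f[7L] %in% c("+", "-", ".", "?"))
      stop("malformed annotation line ", i, ": unknown strand symbol '",
           f[7L], "'")
  }
  lines
}

.seqlengths_from_directives <- function(lines) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) return(NULL)
  parts <- strsplit(trimws(sr), "\\s+")
  setNames(vapply(parts, function(p) as.integer(p[4L]), 0L),
           vapply(parts, function(p) p[2L], ""))
}

#' Read reference annotation from GFF3 or GTF
#'
#' Gene features (types `gene` and `pseudogene`, or a `biotype`/
#' `gene_biotype` attribute) and their exons are collected into an
#' [annotation_set()]. Chromosome lengths are taken from
#' `##sequence-region` directives when present, otherwise from the
#' right-most annotated coordinate per chromosome.
#'
#' @param path a GFF3 (`.gff`/`.gff3`) or GTF (`.gtf`) file.
#' @return An `AnnotationSet`.
#' @export
read_annotation <- function(path) {
  lines <- .validate_gff_lines(path)
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  m <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(m)) as.character(m$gene_id)
         else as.character(m$ID)
  bio <- rep("protein_coding", length(gr))
  for (col in c("biotype", "gene_biotype"))
    if (col %in% names(m)) {
      v <- as.character(m[[col]])
      bio[!is.na(v)] <- v[!is.na(v)]
    }
  is_gene <- as.character(m$type) %in% c("gene", "pseudogene")
  bio[as.character(m$type) == "pseudogene"] <- "pseudogene"
  if (!any(is_gene)) stop("no gene features in ", path)
  gstrand <- as.character(BiocGenerics::strand(gr))
  if (any(gstrand[is_gene] == "*"))
    stop("gene feature without strand in ", path)
  genes <- data.frame(
    gene_id = gid[is_gene],
    chrom = as.character(GenomeInfoDb::seqnames(gr))[is_gene],
    strand = gstrand[is_gene],
    start = BiocGenerics::start(gr)[is_gene],
    end = BiocGenerics::end(gr)[is_gene],
    biotype = bio[is_gene],
    stringsAsFactors = FALSE)
  is_exon <- as.character(m$type) == "exon"
  ex_gid <- gid[is_exon]
  if ("Parent" %in% names(m)) {
    par <- as.character(S4Vectors::unstrsplit(m$Parent[is_exon], ","))
    ex_gid[nzchar(par)] <- par[nzchar(par)]
  }
  exons <- data.frame(
    gene_id = ex_gid,
    start = BiocGenerics::start(gr)[is_exon],
    end = BiocGenerics::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  sl <- .seqlengths_from_directives(lines)
  if (is.null(sl)) {
    sl <- tapply(genes$end, genes$chrom, max)
    sl <- setNames(as.integer(sl), names(sl))
  }
  annotation_set(genes, exons, sl)
}

#' Write an AnnotationSet as GFF3
#'
#' @param x an `AnnotationSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "AnnotationSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", names(x$seqlengths),
                     x$seqlengths), con)
  g <- x$genes
  gtype <- ifelse(g$biotype == "pseudogene", "pseudogene", "gene")
  writeLines(sprintf("%s\tlncpalm\t%s\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                     g$chrom, gtype, g$start, g$end, g$strand, g$gene_id,
                     g$biotype), con)
  e <- x$exons
  idx <- match(e$gene_id, g$gene_id)
  writeLines(sprintf("%s\tlncpalm\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                     g$chrom[idx], e$start, e$end, g$strand[idx],
                     e$gene_id), con)
  invisible(path)
}

#' Read assembled transcripts from GTF
#'
#' Exon features carrying a `transcript_id` attribute are assembled into a
#' [transcript_set()]. An `FPKM` attribute (on transcript or exon rows,
#' StringTie style) supplies the discovery-sample abundance.
#'
#' @param path a GTF file.
#' @return A `TranscriptSet`.
#' @export
read_transcripts <- function(path) {
  .validate_gff_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% names(m))
    stop("GTF lacks transcript_id attributes: ", path)
  is_exon <- as.character(m$type) == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)
  exons <- data.frame(
    transcript_id = as.character(m$transcript_id)[is_exon],
    chrom = as.character(GenomeInfoDb::seqnames(gr))[is_exon],
    strand = as.character(BiocGenerics::strand(gr))[is_exon],
    start = BiocGenerics::start(gr)[is_exon],
    end = BiocGenerics::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  fpkm <- NULL
  if ("FPKM" %in% names(m)) {
    v <- suppressWarnings(as.numeric(as.character(m$FPKM)))
    keep <- !is.na(v) & !is.na(m$transcript_id)
    if (any(keep))
      fpkm <- tapply(v[keep], as.character(m$transcript_id)[keep],
                     function(z) z[1L])
  }
  transcript_set(exons, fpkm = fpkm)
}

#' Write a TranscriptSet as GTF
#'
#' @param x a `TranscriptSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(x, path) {
  stopifnot(inherits(x, "TranscriptSet"))
  con <- file(path, "w")
  on.exit(close(con))
  tx <- x$transcripts
  fp <- ifelse(is.na(tx$fpkm), "",
               sprintf(' FPKM "%s";', sprintf("%.17g", tx$fpkm)))
  writeLines(sprintf(
    '%s\tlncpalm\ttranscript\t%d\t%d\t.\t%s\t.\ttranscript_id "%s";%s',
    tx$chrom, tx$start, tx$end, tx$strand, tx$transcript_id, fp), con)
  e <- x$exons
  writeLines(sprintf(
    '%s\tlncpalm\texon\t%d\t%d\t.\t%s\t.\ttranscript_id "%s";',
    e$chrom, e$start, e$end, e$strand, e$transcript_id), con)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column holds feature ids; remaining columns are numeric FPKM per
#' sample. Scientific notation (e.g. `1.49E-09`) is accepted.
#'
#' @param path a TSV file.
#' @return An `ExpressionMatrix` (features x samples).
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs id column plus samples")
  ids <- as.character(df[[1L]])
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !all(is.na(vals[[j]])))
      stop("non-numeric expression value in column '", names(vals)[j], "'")
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m)
}

#' Write an expression matrix (or any results table) as TSV
#'
#' Numeric values are written with 17 significant digits so a write/read
#' round trip preserves doubles exactly.
#'
#' @param x an `ExpressionMatrix` or data.frame.
#' @param path output path.
#' @param id_column name for the feature-id column when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "feature_id") {
  m <- unclass(x)
  df <- data.frame(rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_column
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  write_results(df, path)
}

#' @rdname write_expression
#' @param records a data.frame of results; columns are written in the order
#'   given.
#' @export
write_results <- function(records, path) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

.decode_call <- function(call) {
  # -> two allele letters, or NA for missing; NULL if undecodable
  if (is.na(call) || call %in% c(".", "", "NA", "N", "./.", ".|."))
    return(NA_character_)
  call <- toupper(trimws(call))
  if (nchar(call) == 1L) {
    if (call %in% c("A", "C", "G", "T"))
      return(paste0(call, call))
    if (call %in% names(.IUPAC_HET))
      return(.IUPAC_HET[[call]])
    return(NULL)
  }
  call <- gsub("[/|]", "", call)
  if (nchar(call) == 2L && grepl("^[ACGT]{2}$", call))
    return(call)
  NULL
}

.normalize_site <- function(decoded, snp_id) {
  # decoded: vector of two-letter strings / NA. Returns list(alleles, calls)
  # or NULL when the site is not biallelic.
  letters2 <- strsplit(decoded[!is.na(decoded)], "")
  obs <- sort(unique(unlist(letters2)))
  if (length(obs) > 2L) {
    warning("skipping site ", snp_id, ": more than two alleles (",
            paste(obs, collapse = ","), ")")
    return(NULL)
  }
  a <- obs[1L]
  b <- if (length(obs) == 2L) obs[2L] else NA_character_
  calls <- vapply(decoded, function(d) {
    if (is.na(d)) return(NA_character_)
    n_b <- if (is.na(b)) 0L else
      sum(strsplit(d, "")[[1L]] == b)
    c("AA", "AB", "BB")[n_b + 1L]
  }, "", USE.NAMES = FALSE)
  list(allele_a = a, allele_b = b, calls = calls)
}

#' Read a genotype table from TSV or minimal VCF
#'
#' Two layouts are accepted. A TSV with columns `snp_id`, `chrom`, `pos`
#' followed by one column per individual, whose calls may be two-letter
#' allele pairs (`"AG"`), single homozygote letters (`"A"`), IUPAC
#' ambiguity letters for heterozygotes (`"R"` = A/G, ...), or `"."`/empty
#' for missing. Or a minimal VCF (detected by its `##fileformat=VCF`
#' header) with biallelic sites and a GT field. Sites with more than two
#' alleles are skipped with a warning; missing calls are preserved.
#'
#' @param path input file.
#' @return A `GenotypeTable`; allele A is the alphabetically first
#'   observed allele (or the VCF REF allele).
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF"))
    .read_genotypes_vcf(path)
  else
    .read_genotypes_tsv(path)
}

.read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  req <- c("snp_id", "chrom", "pos")
  if (!all(req %in% names(df)))
    stop("genotype TSV must have columns snp_id, chrom, pos then ",
         "individual columns")
  ind <- setdiff(names(df), req)
  if (!length(ind)) stop("genotype TSV names no individuals")
  keep_snps <- list(); keep_calls <- list()
  for (i in seq_len(nrow(df))) {
    decoded <- vapply(ind, function(col) {
      d <- .decode_call(df[[col]][i])
      if (is.null(d))
        stop("undecodable genotype call '", df[[col]][i], "' at site ",
             df$snp_id[i], ", individual ", col)
      d
    }, "")
    site <- .normalize_site(decoded, df$snp_id[i])
    if (is.null(site)) next
    keep_snps[[length(keep_snps) + 1L]] <- data.frame(
      snp_id = df$snp_id[i], chrom = df$chrom[i],
      pos = as.integer(df$pos[i]),
      allele_a = site$allele_a, allele_b = site$allele_b,
      stringsAsFactors = FALSE)
    keep_calls[[length(keep_calls) + 1L]] <- site$calls
  }
  if (!length(keep_snps)) stop("no usable biallelic sites in ", path)
  calls <- do.call(rbind, keep_calls)
  colnames(calls) <- ind
  genotype_table(do.call(rbind, keep_snps), calls)
}

.read_genotypes_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("VCF lacks #CHROM header: ", path)
  cols <- strsplit(sub("^#", "", lines[hdr[1L]]), "\t")[[1L]]
  if (length(cols) < 10L) stop("VCF names no individuals: ", path)
  ind <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1L])]
  body <- body[nzchar(body)]
  keep_snps <- list(); keep_calls <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) stop("malformed VCF line ", hdr[1L] + i)
    if (grepl(",", f[5L], fixed = TRUE)) {
      warning("skipping site ", f[3L], ": more than two alleles")
      next
    }
    gt_idx <- match("GT", strsplit(f[9L], ":", fixed = TRUE)[[1L]])
    if (is.na(gt_idx)) stop("VCF line ", hdr[1L] + i, " lacks GT field")
    calls <- vapply(f[-(1:9)], function(s) {
      gt <- strsplit(s, ":", fixed = TRUE)[[1L]][gt_idx]
      al <- strsplit(gt, "[/|]")[[1L]]
      if (any(al == ".")) return(NA_character_)
      n_b <- sum(al == "1")
      if (any(!al %in% c("0", "1")))
        stop("non-biallelic GT '", gt, "' on VCF line ", hdr[1L] + i)
      c("AA", "AB", "BB")[n_b + 1L]
    }, "", USE.NAMES = FALSE)
    keep_snps[[length(keep_snps) + 1L]] <- data.frame(
      snp_id = f[3L], chrom = f[1L], pos = as.integer(f[2L]),
      allele_a = f[4L], allele_b = f[5L], stringsAsFactors = FALSE)
    keep_calls[[length(keep_calls) + 1L]] <- calls
  }
  if (!length(keep_snps)) stop("no usable biallelic sites in ", path)
  calls <- do.call(rbind, keep_calls)
  colnames(calls) <- ind
  genotype_table(do.call(rbind, keep_snps), calls)
}

#' Write a GenotypeTable as TSV
#'
#' Calls are written as two-letter allele pairs; missing as `"."`.
#'
#' @param gt a `GenotypeTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "GenotypeTable"))
  s <- gt$snps
  two <- function(code, a, b) {
    out <- rep(".", length(code))
    out[!is.na(code) & code == "AA"] <- paste0(a, a)[!is.na(code) & code == "AA"]
    out[!is.na(code) & code == "AB"] <- paste0(a, b)[!is.na(code) & code == "AB"]
    out[!is.na(code) & code == "BB"] <- paste0(b, b)[!is.na(code) & code == "BB"]
    out
  }
  df <- data.frame(snp_id = s$snp_id, chrom = s$chrom, pos = s$pos,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(gt$calls)))
    df[[colnames(gt$calls)[j]]] <-
      two(gt$calls[, j], s$allele_a, s$allele_b)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' First column names individuals; remaining columns are numeric traits.
#'
#' @param path a TSV file.
#' @return data.frame with individual rownames and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- as.character(df[[1L]])
  df <- df[-1L]
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) && !all(is.na(df[[j]])))
      stop("non-numeric phenotype value in column '", names(df)[j], "'")
    df[[j]] <- v
  }
  df
}
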