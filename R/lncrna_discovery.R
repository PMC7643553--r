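# Candidate lncRNA filtering, four-class classification (lincRNA / NAT /
# intronic / sense), six NAT geometry subtypes, and merging of transcripts
# into loci.

LNC_CLASSES <- c("lincRNA", "NAT", "intronic", "sense")
NAT_SUBTYPES <- c("I", "II", "III", "IV", "V", "VI")

#' Spliced sequence of a transcript
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' for minus-strand transcripts, so the result reads 5' to 3'.
#'
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param ts a `TranscriptSet`.
#' @param transcript_id one transcript id.
#' @return A character string over A/C/G/T/N.
#' @export
spliced_sequence <- function(genome, ts, transcript_id) {
  stopifnot(inherits(ts, "TranscriptSet"))
  e <- ts$exons[ts$exons$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(e)) stop("unknown transcript id: ", transcript_id)
  chr <- genome[[e$chrom[1L]]]
  parts <- vapply(seq_len(nrow(e)), function(i)
    as.character(Biostrings::subseq(chr, e$start[i], e$end[i])), "")
  s <- paste(parts, collapse = "")
  if (e$strand[1L] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Longest open reading frame, in amino acids
#'
#' Scans the three forward frames of a spliced transcript sequence for
#' ATG-initiated, stop-terminated open reading frames and returns the
#' longest one's length in amino acids, counting the initiator Met through
#' the last codon before the stop. Returns 0 when no complete ORF exists.
#' Codons containing N never match the start or a stop.
#'
#' @param seq nucleotide string over A/C/G/T/N (U accepted, read as T).
#' @return Integer amino-acid length of the longest ORF.
#' @export
max_orf_aa <- function(seq) {
  .longest_orf(seq)$aa
}

# longest ATG-initiated stop-terminated ORF over the three forward
# frames; returns aa length plus the frame (0-2) and 1-based spliced
# position of the start codon (NA when no ORF)
.longest_orf <- function(seq) {
  seq <- chartr("u", "t", tolower(seq))
  if (!grepl("^[acgtn]*$", seq))
    stop("sequence contains non-nucleotide symbols")
  n <- nchar(seq)
  best <- list(aa = 0L, frame = NA_integer_, start = NA_integer_)
  for (frame in 0:2) {
    m <- (n - frame) %/% 3L
    if (m < 2L) next
    codons <- substring(seq, frame + 1L + 3L * (seq_len(m) - 1L),
                        frame + 3L * seq_len(m))
    starts <- which(codons == "atg")
    stops <- which(codons %in% c("taa", "tag", "tga"))
    if (!length(starts) || !length(stops)) next
    for (s in starts) {
      nxt <- stops[stops > s]
      if (length(nxt) && nxt[1L] - s > best$aa)
        best <- list(aa = nxt[1L] - s, frame = frame,
                     start = frame + 1L + 3L * (s - 1L))
    }
  }
  best$aa <- as.integer(best$aa)
  best
}

#' Basic candidate lncRNA filters
#'
#' Applies the four candidate rules to every transcript: spliced length
#' strictly greater than `min_length` nt, more than one exon, abundance
#' `FPKM >= min_fpkm`, and no open reading frame longer than `max_orf`
#' amino acids. A transcript passes only if every rule passes; a missing
#' FPKM leaves that rule indeterminate and the verdict fails.
#'
#' @param ts a `TranscriptSet`.
#' @param genome optional `DNAStringSet`; needed to evaluate the ORF rule
#'   unless `orf_aa` is given.
#' @param orf_aa optional named integer vector of precomputed longest-ORF
#'   lengths per transcript.
#' @param min_length,min_fpkm,max_orf filter constants (defaults 200 nt,
#'   0.1 FPKM, 50 aa).
#' @return A `FilterReport` data.frame: per-rule outcomes
#'   (`"pass"`/`"fail"`/`"indeterminate"`) and a logical `pass` verdict.
#' @export
basic_filters <- function(ts, genome = NULL, orf_aa = NULL,
                          min_length = 200, min_fpkm = 0.1, max_orf = 50) {
  stopifnot(inherits(ts, "TranscriptSet"))
  tx <- ts$transcripts
  if (is.null(orf_aa)) {
    if (is.null(genome))
      stop("either genome or precomputed orf_aa is required")
    orf_aa <- vapply(tx$transcript_id, function(id)
      max_orf_aa(spliced_sequence(genome, ts, id)), 0L)
  }
  orf_aa <- orf_aa[tx$transcript_id]
  rule <- function(ok) ifelse(is.na(ok), "indeterminate",
                              ifelse(ok, "pass", "fail"))
  r_len <- tx$spliced_length > min_length
  r_ex <- tx$n_exons > 1L
  r_fpkm <- tx$fpkm >= min_fpkm
  r_orf <- orf_aa <= max_orf
  verdict <- !is.na(r_len) & r_len & r_ex &
    !is.na(r_fpkm) & r_fpkm & !is.na(r_orf) & r_orf
  data.frame(
    transcript_id = tx$transcript_id,
    spliced_length = tx$spliced_length,
    n_exons = tx$n_exons,
    fpkm = tx$fpkm,
    orf_aa = unname(orf_aa),
    rule_length = rule(r_len),
    rule_exons = rule(r_ex),
    rule_fpkm = rule(r_fpkm),
    rule_orf = rule(r_orf),
    pass = verdict,
    stringsAsFactors = FALSE)
}

.check_bounds <- function(ts, annot) {
  tx <- ts$transcripts
  sl <- annot$seqlengths
  bad <- !(tx$chrom %in% names(sl)) | tx$start < 1L |
    tx$end > ifelse(tx$chrom %in% names(sl), sl[tx$chrom], -Inf)
  if (any(bad))
    stop("transcript beyond chromosome bounds: ",
         paste(tx$transcript_id[bad], collapse = ", "))
}

#' Classify transcripts against reference annotation
#'
#' Assigns each transcript a one-letter relation to the reference gene
#' models, in the spirit of assembly class codes:
#' \describe{
#'   \item{x}{an exon overlaps an exon of an opposite-strand gene
#'     (cis-antisense).}
#'   \item{o}{an exon overlaps an exon of a same-strand pseudogene
#'     (sense overlap).}
#'   \item{i}{wholly contained in one intron of a same-strand
#'     protein-coding gene.}
#'   \item{u}{span overlaps no gene span on either strand (intergenic).}
#'   \item{coding_overlap_sense_exonic}{an exon overlaps an exon of a
#'     same-strand protein-coding gene; excluded from the lncRNA set.}
#'   \item{other}{any residual layout (e.g. same-strand span overlap that
#'     is neither exonic nor intron-contained); also excluded.}
#' }
#' `coding_overlap_sense_exonic` is decided first; among the remaining
#' codes precedence is x > o > i > u.
#'
#' @param ts a `TranscriptSet`.
#' @param annot an `AnnotationSet`.
#' @return Character vector of codes, named by transcript id.
#' @export
classify_class_code <- function(ts, annot) {
  stopifnot(inherits(ts, "TranscriptSet"), inherits(annot, "AnnotationSet"))
  .check_bounds(ts, annot)
  tx_gr <- transcripts_granges(ts)
  txe_gr <- transcript_exons_granges(ts)
  g_gr <- genes_granges(annot)
  ge_gr <- exons_granges(annot)
  n <- length(tx_gr)
  code <- rep("other", n)
  names(code) <- ts$transcripts$transcript_id
  ex_of <- match(txe_gr$transcript_id, names(code))

  # exon-level overlaps, strand-aware bookkeeping done by hand
  hits <- GenomicRanges::findOverlaps(txe_gr, ge_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- as.character(BiocGenerics::strand(txe_gr))[qh] ==
    as.character(BiocGenerics::strand(ge_gr))[sh]
  sub_bio <- annot$genes$biotype[match(ge_gr$gene_id[sh], annot$genes$gene_id)]
  is_x <- !same
  is_coding <- same & sub_bio == "protein_coding"
  is_o <- same & sub_bio == "pseudogene"
  x_tx <- unique(ex_of[qh[is_x]])
  coding_tx <- unique(ex_of[qh[is_coding]])
  o_tx <- unique(ex_of[qh[is_o]])

  # intron containment: same-strand protein-coding introns
  pc <- annot$genes$biotype == "protein_coding"
  intron_list <- list()
  for (gi in which(pc)) {
    g <- annot$genes[gi, ]
    ex <- annot$exons[annot$exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ex) < 2L) next
    ex <- ex[order(ex$start), , drop = FALSE]
    istart <- ex$end[-nrow(ex)] + 1L
    iend <- ex$start[-1L] - 1L
    keep <- iend >= istart
    if (any(keep))
      intron_list[[length(intron_list) + 1L]] <- GenomicRanges::GRanges(
        seqnames = g$chrom,
        ranges = IRanges::IRanges(istart[keep], iend[keep]),
        strand = g$strand)
  }
  i_tx <- integer(0)
  if (length(intron_list)) {
    introns <- do.call(c, intron_list)
    wi <- GenomicRanges::findOverlaps(tx_gr, introns, type = "within",
                                      ignore.strand = FALSE)
    i_tx <- unique(S4Vectors::queryHits(wi))
  }

  # intergenic: no span overlap with any gene span, either strand
  span_hits <- GenomicRanges::findOverlaps(tx_gr, g_gr, ignore.strand = TRUE)
  u_tx <- setdiff(seq_len(n), unique(S4Vectors::queryHits(span_hits)))

  code[u_tx] <- "u"
  code[i_tx] <- "i"
  code[o_tx] <- "o"
  code[x_tx] <- "x"
  code[coding_tx] <- "coding_overlap_sense_exonic"
  code
}

#' Classify the geometry subtype of a NAT lncRNA against its partner gene
#'
#' Genic-overlap subtypes (spans intersect): `I` partial overlap at the
#' lncRNA's 5' end (head-to-head / divergent); `II` partial overlap at the
#' lncRNA's 3' end (tail-to-tail / convergent); `III` lncRNA wholly inside
#' the gene span; `IV` gene wholly inside the lncRNA span. Flanking
#' subtypes (no span overlap): `V` gene within the promoter-side
#' (upstream, 5') window of the lncRNA; `VI` gene within the downstream
#' (3') window. Orientation is taken from the lncRNA strand.
#'
#' @param lnc_start,lnc_end,lnc_strand lncRNA span and strand.
#' @param gene_start,gene_end,gene_strand partner gene span and strand;
#'   the gene must lie on the opposite strand.
#' @param window flank window in nt (default 2000, inclusive).
#' @return One of `"I"` ... `"VI"`, or `NA` when the gene is farther than
#'   `window` from a non-overlapping lncRNA.
#' @export
classify_nat_subtype <- function(lnc_start, lnc_end, lnc_strand,
                                 gene_start, gene_end, gene_strand,
                                 window = 2000) {
  if (lnc_strand == gene_strand)
    stop("partner gene is on the same strand: not a NAT relation")
  overlaps <- gene_start <= lnc_end && gene_end >= lnc_start
  if (overlaps) {
    lnc_inside <- gene_start <= lnc_start && gene_end >= lnc_end
    gene_inside <- lnc_start <= gene_start && lnc_end >= gene_end
    if (lnc_inside) return("III")
    if (gene_inside) return("IV")
    # partial overlap: which lncRNA terminus is covered?
    at_left <- gene_start <= lnc_start  # overlap includes lncRNA left end
    at_5prime <- (lnc_strand == "+" && at_left) ||
      (lnc_strand == "-" && !at_left)
    return(if (at_5prime) "I" else "II")
  }
  gap <- if (gene_end < lnc_start) lnc_start - gene_end - 1L
         else gene_start - lnc_end - 1L
  if (gap > window) return(NA_character_)
  gene_left <- gene_end < lnc_start
  upstream <- (lnc_strand == "+" && gene_left) ||
    (lnc_strand == "-" && !gene_left)
  if (upstream) "V" else "VI"
}

# deterministic partner choice: largest span overlap, then smallest
# distance, then lexicographic gene id
.pick_partner <- function(t_start, t_end, cand) {
  ov <- pmin(t_end, cand$end) - pmax(t_start, cand$start) + 1L
  ov <- pmax(ov, 0L)
  dist <- ifelse(ov > 0L, 0L,
                 ifelse(cand$end < t_start, t_start - cand$end - 1L,
                        cand$start - t_end - 1L))
  ord <- order(-ov, dist, cand$gene_id)
  list(row = cand[ord[1L], , drop = FALSE], overlap = ov[ord[1L]],
       distance = dist[ord[1L]])
}

#' Assign lncRNA classes from class codes
#'
#' Maps surviving transcripts to the four lncRNA classes: `x` becomes NAT
#' (subtype I-IV from span geometry against the chosen partner gene), `i`
#' intronic, `o` sense, and `u` becomes NAT subtype V/VI when an
#' opposite-strand gene lies within `window` nt, otherwise lincRNA. The
#' partner gene is the candidate with the largest span overlap, ties
#' broken by smallest distance then lexicographic gene id.
#'
#' @param ts a `TranscriptSet` (already filtered).
#' @param codes class codes from [classify_class_code()].
#' @param annot an `AnnotationSet`.
#' @param window flank window in nt for NAT subtypes V/VI (default 2000).
#' @return data.frame: transcript_id, code, class, nat_subtype,
#'   partner_gene. Transcripts with code `coding_overlap_sense_exonic` or
#'   `other` get class `NA` (excluded).
#' @export
assign_lncrna_class <- function(ts, codes, annot, window = 2000) {
  tx <- ts$transcripts
  codes <- codes[tx$transcript_id]
  g <- annot$genes
  out <- data.frame(transcript_id = tx$transcript_id,
                    code = unname(codes),
                    class = NA_character_,
                    nat_subtype = NA_character_,
                    partner_gene = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tx))) {
    code <- codes[k]
    if (is.na(code) || code %in% c("coding_overlap_sense_exonic", "other"))
      next
    t_chrom <- tx$chrom[k]; t_strand <- tx$strand[k]
    t_start <- tx$start[k]; t_end <- tx$end[k]
    if (code == "x") {
      cand <- g[g$chrom == t_chrom & g$strand != t_strand &
                  g$start <= t_end & g$end >= t_start, , drop = FALSE]
      p <- .pick_partner(t_start, t_end, cand)
      out$class[k] <- "NAT"
      out$partner_gene[k] <- p$row$gene_id
      out$nat_subtype[k] <- classify_nat_subtype(
        t_start, t_end, t_strand, p$row$start, p$row$end, p$row$strand,
        window = window)
    } else if (code == "i") {
      cand <- g[g$chrom == t_chrom & g$strand == t_strand &
                  g$biotype == "protein_coding" &
                  g$start <= t_start & g$end >= t_end, , drop = FALSE]
      p <- .pick_partner(t_start, t_end, cand)
      out$class[k] <- "intronic"
      out$partner_gene[k] <- p$row$gene_id
    } else if (code == "o") {
      cand <- g[g$chrom == t_chrom & g$strand == t_strand &
                  g$biotype == "pseudogene" &
                  g$start <= t_end & g$end >= t_start, , drop = FALSE]
      p <- .pick_partner(t_start, t_end, cand)
      out$class[k] <- "sense"
      out$partner_gene[k] <- p$row$gene_id
    } else if (code == "u") {
      cand <- g[g$chrom == t_chrom & g$strand != t_strand &
                  g$start <= t_end + window & g$end >= t_start - window, ,
                drop = FALSE]
      if (nrow(cand)) {
        p <- .pick_partner(t_start, t_end, cand)
        out$class[k] <- "NAT"
        out$partner_gene[k] <- p$row$gene_id
        out$nat_subtype[k] <- classify_nat_subtype(
          t_start, t_end, t_strand, p$row$start, p$row$end, p$row$strand,
          window = window)
      } else {
        out$class[k] <- "lincRNA"
      }
    }
  }
  out
}

.majority <- function(x, precedence) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  precedence[precedence %in% winners][1L]
}

#' Merge classified transcripts into lncRNA loci
#'
#' Same-chromosome, same-strand transcripts whose spans overlap by at
#' least 1 bp are merged into one locus (transitively, so a chain of
#' pairwise overlaps forms one locus). Merging is idempotent and
#' independent of input order. The locus class is the majority class of
#' its members, ties broken by precedence NAT > intronic > sense >
#' lincRNA; the NAT subtype and partner gene are the majority among
#' members of the winning class, ties broken by subtype order I..VI and
#' lexicographic gene id.
#'
#' @param ts a `TranscriptSet` of surviving transcripts.
#' @param class_df output of [assign_lncrna_class()] for those
#'   transcripts; rows with `NA` class are dropped.
#' @return A list of class `LncRnaLociSet`: `loci` (locus_id, chrom,
#'   strand, span, class, nat_subtype, partner_gene, n_transcripts) and
#'   `members` (locus_id, transcript_id).
#' @export
merge_transcripts_to_loci <- function(ts, class_df) {
  keep <- class_df$transcript_id[!is.na(class_df$class)]
  tx <- ts$transcripts[ts$transcripts$transcript_id %in% keep, ,
                       drop = FALSE]
  if (!nrow(tx)) {
    return(structure(list(
      loci = data.frame(locus_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), class = character(0),
                        nat_subtype = character(0),
                        partner_gene = character(0),
                        n_transcripts = integer(0),
                        stringsAsFactors = FALSE),
      members = data.frame(locus_id = character(0),
                           transcript_id = character(0),
                           stringsAsFactors = FALSE)),
      class = "LncRnaLociSet"))
  }
  gr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end),
                               strand = tx$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = FALSE)
  red <- BiocGenerics::sort(red, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, red, ignore.strand = FALSE)
  grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  locus_id <- sprintf("LNC_LOC_%04d", seq_along(red))
  info <- class_df[match(tx$transcript_id, class_df$transcript_id), ]
  loci <- data.frame(
    locus_id = locus_id,
    chrom = as.character(GenomeInfoDb::seqnames(red)),
    strand = as.character(BiocGenerics::strand(red)),
    start = BiocGenerics::start(red),
    end = BiocGenerics::end(red),
    class = NA_character_, nat_subtype = NA_character_,
    partner_gene = NA_character_,
    n_transcripts = as.integer(table(factor(grp, seq_along(red)))),
    stringsAsFactors = FALSE)
  for (j in seq_along(red)) {
    mem <- which(grp == j)
    cls <- .majority(info$class[mem],
                     c("NAT", "intronic", "sense", "lincRNA"))
    loci$class[j] <- cls
    of_cls <- mem[info$class[mem] %in% cls]
    if (identical(cls, "NAT"))
      loci$nat_subtype[j] <- .majority(info$nat_subtype[of_cls],
                                       NAT_SUBTYPES)
    if (!identical(cls, "lincRNA")) {
      pg <- info$partner_gene[of_cls]
      pg <- pg[!is.na(pg)]
      if (length(pg))
        loci$partner_gene[j] <- .majority(pg, sort(unique(pg)))
    }
  }
  members <- data.frame(locus_id = locus_id[grp],
                        transcript_id = tx$transcript_id,
                        stringsAsFactors = FALSE)
  members <- members[order(members$locus_id, members$transcript_id), ]
  rownames(members) <- NULL
  structure(list(loci = loci, members = members), class = "LncRnaLociSet")
}

#' @export
print.LncRnaLociSet <- function(x, ...) {
  cat("LncRnaLociSet:", nrow(x$loci), "loci (",
      paste(names(table(x$loci$class)), table(x$loci$class),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Exon intervals of lncRNA loci
#'
#' Union of member-transcript exons per locus; used for exon/intron
#' context of SNPs.
#'
#' @param loci an `LncRnaLociSet`.
#' @param ts the `TranscriptSet` the loci were built from.
#' @return data.frame: locus_id, chrom, strand, start, end.
#' @export
locus_exons <- function(loci, ts) {
  stopifnot(inherits(loci, "LncRnaLociSet"))
  out <- list()
  for (j in seq_len(nrow(loci$loci))) {
    lid <- loci$loci$locus_id[j]
    txs <- loci$members$transcript_id[loci$members$locus_id == lid]
    e <- ts$exons[ts$exons$transcript_id %in% txs, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
    out[[j]] <- data.frame(locus_id = lid, chrom = loci$loci$chrom[j],
                           strand = loci$loci$strand[j],
                           start = BiocGenerics::start(ir),
                           end = BiocGenerics::end(ir),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-chromosome class count table
#'
#' Builds the standard genomic-distribution table of lncRNA loci: one row
#' per anchored chromosome plus an `"others"` row for unplaced scaffolds,
#' columns for the four classes plus `Total`, and a `Total` row.
#'
#' @param loci an `LncRnaLociSet`, or a data.frame with `chrom` and
#'   `class` columns.
#' @param chromosomes chromosome names treated as anchored, in display
#'   order; defaults to those matching `^Chr`.
#' @return data.frame with rownames `chromosomes`, `"others"`, `"Total"`
#'   and columns `LincRNA`, `NAT-lncRNA`, `Intronic-lncRNA`,
#'   `Sense-lncRNA`, `Total`.
#' @export
class_count_table <- function(loci, chromosomes = NULL) {
  df <- if (inherits(loci, "LncRnaLociSet")) loci$loci else loci
  if (is.null(chromosomes)) {
    chromosomes <- sort(unique(grep("^Chr", df$chrom, value = TRUE)))
    num <- suppressWarnings(as.integer(sub("^Chr", "", chromosomes)))
    if (!anyNA(num)) chromosomes <- chromosomes[order(num)]
  }
  row <- ifelse(df$chrom %in% chromosomes, df$chrom, "others")
  counts <- table(factor(row, c(chromosomes, "others")),
                  factor(df$class, LNC_CLASSES))
  tab <- as.data.frame.matrix(counts)
  names(tab) <- c("LincRNA", "NAT-lncRNA", "Intronic-lncRNA",
                  "Sense-lncRNA")
  summarize_class_counts(tab)
}

#' Add totals to a per-chromosome class count table
#'
#' Given per-chromosome counts of the four classes (rows = chromosomes,
#' optionally ending in an `"others"` row), appends a `Total` column (row
#' sums over the four classes) and a `Total` row (column sums).
#'
#' @param tab data.frame of class counts; rownames are chromosomes.
#' @return The table with `Total` column and row appended.
#' @export
summarize_class_counts <- function(tab) {
  tab <- as.data.frame(tab)
  tab <- tab[!rownames(tab) %in% "Total", , drop = FALSE]
  tab$Total <- rowSums(tab)
  tab["Total", ] <- colSums(tab)
  tab
}

#' Totals of a class count table
#'
#' @param tab output of [class_count_table()] or
#'   [summarize_class_counts()].
#' @return Named vector: `total` (all loci) and `chromosome_anchored`
#'   (loci on named chromosomes, excluding `"others"`).
#' @export
count_table_totals <- function(tab) {
  body <- tab[!rownames(tab) %in% "Total", , drop = FALSE]
  c(total = sum(body$Total),
    chromosome_anchored = sum(body$Total[!rownames(body) %in% "others"]))
}

#' End-to-end lncRNA discovery
#'
#' Runs the candidate filters, classifies survivors against the
#' annotation, merges them into loci and tabulates the per-chromosome
#' class counts.
#'
#' @inheritParams basic_filters
#' @param annot an `AnnotationSet`.
#' @param window flank window for NAT subtypes V/VI (default 2000 nt).
#' @param chromosomes passed to [class_count_table()].
#' @return List: `loci` (`LncRnaLociSet`), `filter_report`,
#'   `transcript_classes` (per surviving transcript), `class_table`.
#' @export
discover_lncrnas <- function(ts, annot, genome = NULL, orf_aa = NULL,
                             window = 2000, chromosomes = NULL,
                             min_length = 200, min_fpkm = 0.1,
                             max_orf = 50) {
  report <- basic_filters(ts, genome = genome, orf_aa = orf_aa,
                          min_length = min_length, min_fpkm = min_fpkm,
                          max_orf = max_orf)
  keep <- report$transcript_id[report$pass]
  sub <- transcript_set(
    ts$exons[ts$exons$transcript_id %in% keep, , drop = FALSE],
    fpkm = setNames(ts$transcripts$fpkm, ts$transcripts$transcript_id))
  if (!nrow(sub$transcripts)) {
    loci <- merge_transcripts_to_loci(sub, data.frame(
      transcript_id = character(0), class = character(0),
      stringsAsFactors = FALSE))
    return(list(loci = loci, filter_report = report,
                transcript_classes = data.frame(),
                class_table = class_count_table(loci,
                                                chromosomes = chromosomes)))
  }
  codes <- classify_class_code(sub, annot)
  classes <- assign_lncrna_class(sub, codes, annot, window = window)
  loci <- merge_transcripts_to_loci(sub, classes)
  list(loci = loci,
       filter_report = report,
       transcript_classes = classes,
       class_table = class_count_table(loci, chromosomes = chromosomes))
}
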