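# Cis target prediction (overlap or 2-kb flanking window) and trans
# prediction by antiparallel RNA-RNA duplex energy with a simplified
# nearest-neighbour stack table.

.spliced_from_exons <- function(genome, chrom, starts, ends, strand) {
  chr <- genome[[chrom]]
  ord <- order(starts)
  parts <- vapply(ord, function(i)
    as.character(Biostrings::subseq(chr, starts[i], ends[i])), "")
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Cis target genes of lncRNA loci
#'
#' For every locus, returns each protein-coding gene whose span overlaps
#' the locus span (`cis_overlap`, with overlap length and sense/antisense
#' strand relation) or whose span lies within `window` nt of either locus
#' end on either strand (`cis_flank`, with the gap distance; the boundary
#' at exactly `window` nt is inclusive). The `transcript_overlap` flag
#' records whether locus exons overlap gene exons, distinguishing
#' exon-level from span-only overlaps.
#'
#' @param loci an `LncRnaLociSet`.
#' @param annot an `AnnotationSet`.
#' @param ts the `TranscriptSet` the loci were built from (for exon-level
#'   overlap); optional, flag is `NA` without it.
#' @param window flank window in nt (default 2000).
#' @return data.frame of `TargetPair` records: locus_id, gene_id,
#'   mechanism, strand_relation, overlap_nt, distance_nt,
#'   transcript_overlap.
#' @export
cis_targets <- function(loci, annot, ts = NULL, window = 2000) {
  stopifnot(inherits(loci, "LncRnaLociSet"),
            inherits(annot, "AnnotationSet"))
  if (window < 0) stop("window must be non-negative")
  g <- annot$genes[annot$genes$biotype == "protein_coding", , drop = FALSE]
  lx <- if (!is.null(ts)) locus_exons(loci, ts) else NULL
  out <- list()
  for (j in seq_len(nrow(loci$loci))) {
    l <- loci$loci[j, ]
    cand <- g[g$chrom == l$chrom &
                g$start <= l$end + window + 1L &
                g$end >= l$start - window - 1L, , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmax(0L, pmin(l$end, cand$end) - pmax(l$start, cand$start) + 1L)
    dist <- ifelse(ov > 0L, NA_integer_,
                   ifelse(cand$end < l$start, l$start - cand$end - 1L,
                          cand$start - l$end - 1L))
    keep <- ov > 0L | (!is.na(dist) & dist <= window)
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    ov <- ov[keep]; dist <- dist[keep]
    mech <- ifelse(ov > 0L, "cis_overlap", "cis_flank")
    rel <- ifelse(cand$strand == l$strand, "sense", "antisense")
    tov <- rep(NA, nrow(cand))
    if (!is.null(lx) && any(ov > 0L)) {
      le <- lx[lx$locus_id == l$locus_id, , drop = FALSE]
      for (q in which(ov > 0L)) {
        ge <- annot$exons[annot$exons$gene_id == cand$gene_id[q], ,
                          drop = FALSE]
        tov[q] <- nrow(le) > 0L && nrow(ge) > 0L &&
          any(IRanges::overlapsAny(IRanges::IRanges(le$start, le$end),
                                   IRanges::IRanges(ge$start, ge$end)))
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      locus_id = l$locus_id, gene_id = cand$gene_id, mechanism = mech,
      strand_relation = rel, overlap_nt = ifelse(ov > 0L, ov, NA_integer_),
      distance_nt = dist, transcript_overlap = tov,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(locus_id = character(0), gene_id = character(0),
                      mechanism = character(0),
                      strand_relation = character(0),
                      overlap_nt = integer(0), distance_nt = integer(0),
                      transcript_overlap = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- duplex energy -------------------------------------------------------

# Simplified nearest-neighbour stack energies (kcal/mol at 37C).
# Watson-Crick stack values follow the standard RNA nearest-neighbour set;
# stacks containing GU wobble pairs carry flat values. A stack is keyed by
# its two base pairs read 5'->3' along the first strand, canonicalised so
# that reading the duplex from the other strand gives the same energy.
.WC_STACKS <- c(
  "AU,AU" = -0.93, "AU,UA" = -1.10, "UA,AU" = -1.33,
  "CG,UA" = -2.08, "CG,AU" = -2.11, "GC,UA" = -2.24,
  "GC,AU" = -2.35, "CG,GC" = -2.36, "GC,GC" = -3.26, "GC,CG" = -3.42)
.WOBBLE_ONE <- -1.2
.WOBBLE_TWO <- -0.5
# helix initiation penalty per contiguous paired stretch (kcal/mol);
# a stretch contributes only when its stacks outweigh the initiation cost
.HELIX_INIT <- 4.09

.flip_pair <- function(p) paste0(substr(p, 2L, 2L), substr(p, 1L, 1L))

.stack_energy <- function(p1, p2) {
  # canonical form: (p1,p2) is equivalent to (flip(p2), flip(p1))
  wob1 <- p1 %in% c("GU", "UG")
  wob2 <- p2 %in% c("GU", "UG")
  if (wob1 && wob2) return(.WOBBLE_TWO)
  if (wob1 || wob2) return(.WOBBLE_ONE)
  k1 <- paste(p1, p2, sep = ",")
  k2 <- paste(.flip_pair(p2), .flip_pair(p1), sep = ",")
  e <- .WC_STACKS[k1]
  if (is.na(e)) e <- .WC_STACKS[k2]
  unname(e)
}

# integer encodings for the vectorized scan: bases A/C/G/U -> 1..4,
# base pair (a,b) -> (a-1)*4 + b in 1..16, stack -> (p1-1)*16 + p2
.BASES <- c("A", "C", "G", "U")
.PAIR_OK16 <- local({
  ok <- rep(FALSE, 16)
  for (p in list(c("A", "U"), c("U", "A"), c("C", "G"), c("G", "C"),
                 c("G", "U"), c("U", "G")))
    ok[(match(p[1], .BASES) - 1L) * 4L + match(p[2], .BASES)] <- TRUE
  ok
})
.STACK256 <- local({
  e <- rep(0, 256)
  valid <- c("AU", "UA", "CG", "GC", "GU", "UG")
  for (p1 in valid) for (p2 in valid) {
    c1 <- (match(substr(p1, 1, 1), .BASES) - 1L) * 4L +
      match(substr(p1, 2, 2), .BASES)
    c2 <- (match(substr(p2, 1, 1), .BASES) - 1L) * 4L +
      match(substr(p2, 2, 2), .BASES)
    e[(c1 - 1L) * 16L + c2] <- .stack_energy(p1, p2)
  }
  e
})

.duplex_energy_at <- function(s, b, off) {
  # s, b: integer base codes; s[i] pairs b[off + i]
  n <- length(s)
  i1 <- max(1L, 1L - off)
  i2 <- min(n, length(b) - off)
  if (i2 - i1 < 1L) return(0)
  pc <- (s[i1:i2] - 1L) * 4L + b[(i1:i2) + off]
  ok <- .PAIR_OK16[pc]
  m <- length(pc)
  both <- ok[-m] & ok[-1L]
  if (!any(both)) return(0)
  evec <- .STACK256[(pc[-m] - 1L) * 16L + pc[-1L]]
  evec[!both] <- 0
  # each maximal run of stacked positions is one helix; keep a helix only
  # when its stacks beat the initiation penalty
  nb <- length(both)
  starts <- which(both & !c(FALSE, both[-nb]))
  ends <- which(both & !c(both[-1L], FALSE))
  cs <- cumsum(evec)
  hsum <- cs[ends] - c(0, cs)[starts]
  sum(pmin(hsum + .HELIX_INIT, 0))
}

#' Normalized lncRNA-mRNA duplex energy
#'
#' Slides the shorter sequence antiparallel along the longer one. At each
#' offset, contiguous stretches of paired bases (Watson-Crick plus GU
#' wobble; a mismatch breaks the stack) are scored with the shipped
#' nearest-neighbour stack-energy table plus a helix initiation penalty
#' of +4.09 kcal/mol per stretch; a stretch counts only when its stacks
#' outweigh the initiation cost, so scattered chance pairings do not
#' accumulate. The minimum total energy over all offsets is divided by
#' the shorter sequence length. More negative means stronger predicted
#' hybridization; a pair is typically called a trans target when
#' `ndG <= cutoff` (default cutoff -0.1).
#'
#' @param seq1,seq2 nucleotide strings (A/C/G/T/U), each at least 50 nt
#'   unless `min_length` is lowered.
#' @param min_length minimum accepted sequence length (default 50 nt).
#' @return Normalized duplex energy in kcal/mol/nt (<= 0).
#' @export
trans_duplex_ndG <- function(seq1, seq2, min_length = 50) {
  for (s in c(seq1, seq2))
    if (!grepl("^[ACGTUacgtu]+$", s))
      stop("sequence contains non-nucleotide symbols")
  if (nchar(seq1) < min_length || nchar(seq2) < min_length)
    stop("sequences must be at least ", min_length, " nt")
  a <- chartr("Tt", "Uu", toupper(seq1))
  b <- chartr("Tt", "Uu", toupper(seq2))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  s <- match(strsplit(a, "")[[1L]], .BASES)
  # antiparallel: s[i] pairs the reversed partner at matching index
  brev <- rev(match(strsplit(b, "")[[1L]], .BASES))
  best <- 0
  for (off in seq(-(length(s) - 2L), length(brev) - 2L)) {
    e <- .duplex_energy_at(s, brev, off)
    if (e < best) best <- e
  }
  best / length(s)
}

#' Predict cis and trans targets for a set of lncRNA loci
#'
#' Cis targets are computed for every locus with [cis_targets()]. Trans
#' candidates are scored with [trans_duplex_ndG()] against spliced
#' protein-coding gene sequences; by default only loci with no cis target
#' are scanned (the scan is quadratic in sequence length). Records are
#' de-duplicated per (locus, gene, mechanism).
#'
#' @inheritParams cis_targets
#' @param genome a `DNAStringSet` named by chromosome; required for the
#'   trans scan.
#' @param trans_candidates optional data.frame (`locus_id`, `gene_id`)
#'   restricting the trans scan; `NULL` scans cis-orphan loci against all
#'   protein-coding genes; `NA` skips the trans scan.
#' @param ndg_cutoff trans call threshold on ndG (default -0.1
#'   kcal/mol/nt).
#' @return List: `pairs` (all `TargetPair` records, with `ndg` for trans
#'   records), `unique_genes` (unique target gene ids), `class_summary`
#'   (unique target genes per lncRNA class).
#' @export
predict_targets <- function(loci, annot, genome = NULL, ts = NULL,
                            window = 2000, trans_candidates = NULL,
                            ndg_cutoff = -0.1) {
  cis <- cis_targets(loci, annot, ts = ts, window = window)
  cis$ndg <- rep(NA_real_, nrow(cis))
  trans <- NULL
  skip_trans <- length(trans_candidates) == 1L && !is.data.frame(trans_candidates) &&
    is.na(trans_candidates)
  if (!skip_trans && !is.null(genome)) {
    pc <- annot$genes[annot$genes$biotype == "protein_coding", ,
                      drop = FALSE]
    if (is.null(trans_candidates)) {
      orphan <- setdiff(loci$loci$locus_id, cis$locus_id)
      trans_candidates <- expand.grid(locus_id = orphan,
                                      gene_id = pc$gene_id,
                                      stringsAsFactors = FALSE)
    }
    if (nrow(trans_candidates)) {
      lx <- locus_exons(loci, ts)
      lnc_seq <- sapply(unique(trans_candidates$locus_id), function(lid) {
        e <- lx[lx$locus_id == lid, , drop = FALSE]
        .spliced_from_exons(genome, e$chrom[1L], e$start, e$end,
                            e$strand[1L])
      })
      gene_seq <- sapply(unique(trans_candidates$gene_id), function(gid) {
        gi <- pc[pc$gene_id == gid, , drop = FALSE]
        ge <- annot$exons[annot$exons$gene_id == gid, , drop = FALSE]
        if (!nrow(ge)) ge <- data.frame(start = gi$start, end = gi$end)
        .spliced_from_exons(genome, gi$chrom, ge$start, ge$end, gi$strand)
      })
      ndg <- mapply(function(lid, gid)
        trans_duplex_ndG(lnc_seq[[lid]], gene_seq[[gid]]),
        trans_candidates$locus_id, trans_candidates$gene_id)
      hit <- ndg <= ndg_cutoff
      if (any(hit))
        trans <- data.frame(
          locus_id = trans_candidates$locus_id[hit],
          gene_id = trans_candidates$gene_id[hit],
          mechanism = "trans_duplex", strand_relation = NA_character_,
          overlap_nt = NA_integer_, distance_nt = NA_integer_,
          transcript_overlap = NA, ndg = ndg[hit],
          stringsAsFactors = FALSE)
    }
  }
  pairs <- rbind(cis, trans)
  if (nrow(pairs)) {
    pairs <- pairs[!duplicated(pairs[c("locus_id", "gene_id",
                                       "mechanism")]), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  cls <- loci$loci$class[match(pairs$locus_id, loci$loci$locus_id)]
  class_summary <- vapply(LNC_CLASSES, function(cl)
    length(unique(pairs$gene_id[cls %in% cl])), 0L)
  list(pairs = pairs,
       unique_genes = unique(pairs$gene_id),
       class_summary = class_summary)
}
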