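# Independent brute-force oracles used by unit and property tests.
# These deliberately share no code with the package internals.

# longest ATG..stop ORF by scanning every position codon-by-codon
oracle_max_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  i <- 1L
  while (i + 5L <= n) {
    if (substr(seq, i, i + 2L) == "ATG") {
      j <- i + 3L
      while (j + 2L <= n) {
        cod <- substr(seq, j, j + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (j - i) %/% 3L)
          break
        }
        j <- j + 3L
      }
    }
    i <- i + 1L
  }
  best
}

.ov <- function(s1, e1, s2, e2) min(e1, e2) >= max(s1, s2)

# all-pairs interval/strand oracle for the class code of one transcript.
# genes: list of list(strand, start, end, biotype, exons = 2-col matrix)
# tx: list(strand, start, end, exons = 2-col matrix)
oracle_class_code <- function(tx, genes) {
  exon_overlap <- function(g) {
    for (i in seq_len(nrow(tx$exons)))
      for (j in seq_len(nrow(g$exons)))
        if (.ov(tx$exons[i, 1], tx$exons[i, 2], g$exons[j, 1],
                g$exons[j, 2]))
          return(TRUE)
    FALSE
  }
  in_one_intron <- function(g) {
    ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
    if (nrow(ex) < 2L) return(FALSE)
    for (j in seq_len(nrow(ex) - 1L)) {
      is <- ex[j, 2] + 1; ie <- ex[j + 1L, 1] - 1
      if (ie >= is && tx$start >= is && tx$end <= ie) return(TRUE)
    }
    FALSE
  }
  span_ov <- vapply(genes, function(g) .ov(tx$start, tx$end, g$start,
                                           g$end), NA)
  for (g in genes)
    if (g$strand == tx$strand && g$biotype == "protein_coding" &&
        exon_overlap(g))
      return("coding_overlap_sense_exonic")
  for (g in genes)
    if (g$strand != tx$strand && exon_overlap(g)) return("x")
  for (g in genes)
    if (g$strand == tx$strand && g$biotype == "pseudogene" &&
        exon_overlap(g))
      return("o")
  for (g in genes)
    if (g$strand == tx$strand && g$biotype == "protein_coding" &&
        in_one_intron(g))
      return("i")
  if (!any(span_ov)) return("u")
  "other"
}

# enumeration oracle for NAT geometry subtype
oracle_nat_subtype <- function(ls, le, lstrand, gs, ge, window = 2000) {
  if (.ov(ls, le, gs, ge)) {
    if (gs <= ls && ge >= le) return("III")
    if (ls <= gs && le >= ge) return("IV")
    covered_left <- gs <= ls
    five_prime <- if (lstrand == "+") covered_left else !covered_left
    return(if (five_prime) "I" else "II")
  }
  gap <- if (ge < ls) ls - ge - 1 else gs - le - 1
  if (gap > window) return(NA_character_)
  left <- ge < ls
  up <- if (lstrand == "+") left else !left
  if (up) "V" else "VI"
}

# union-find oracle: cluster ids for spans under pairwise >= 1 bp overlap
oracle_overlap_clusters <- function(starts, ends) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j && .ov(starts[i], ends[i], starts[j], ends[j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  vapply(seq_len(n), find, 0L)
}

# correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# tiny hand-built annotation: one chromosome, arbitrary genes
tiny_annotation <- function(genes, chrom_len = 100000L, chrom = "Chr1") {
  gdf <- do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    data.frame(gene_id = sprintf("G%02d", i), chrom = chrom,
               strand = g$strand, start = g$start, end = g$end,
               biotype = g$biotype, stringsAsFactors = FALSE)
  }))
  edf <- do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    data.frame(gene_id = sprintf("G%02d", i), start = g$exons[, 1],
               end = g$exons[, 2], stringsAsFactors = FALSE)
  }))
  annotation_set(gdf, edf, setNames(chrom_len, chrom))
}

tiny_transcripts <- function(txs, chrom = "Chr1", fpkm = NULL) {
  edf <- do.call(rbind, lapply(seq_along(txs), function(i) {
    t <- txs[[i]]
    id <- if (!is.null(t$id)) t$id else sprintf("T%02d", i)
    data.frame(transcript_id = id, chrom = chrom, strand = t$strand,
               start = t$exons[, 1], end = t$exons[, 2],
               stringsAsFactors = FALSE)
  }))
  transcript_set(edf, fpkm = fpkm)
}

# random non-degenerate gene/transcript layout for property tests
random_layout <- function() {
  n_genes <- sample(1:3, 1)
  genes <- lapply(seq_len(n_genes), function(i) {
    s <- sample(1000:8000, 1)
    w <- sample(300:3000, 1)
    n_ex <- sample(1:3, 1)
    bounds <- sort(sample(seq(s, s + w), 2L * n_ex))
    exons <- cbind(bounds[seq(1, 2 * n_ex, 2)],
                   bounds[seq(2, 2 * n_ex, 2)])
    exons[1, 1] <- s; exons[n_ex, 2] <- s + w
    list(strand = sample(c("+", "-"), 1), start = s, end = s + w,
         biotype = sample(c("protein_coding", "pseudogene"), 1,
                          prob = c(0.7, 0.3)),
         exons = exons)
  })
  s <- sample(500:9000, 1)
  w <- sample(250:2500, 1)
  n_ex <- sample(1:3, 1)
  bounds <- sort(sample(seq(s, s + w), 2L * n_ex))
  exons <- cbind(bounds[seq(1, 2 * n_ex, 2)], bounds[seq(2, 2 * n_ex, 2)])
  exons[1, 1] <- s; exons[n_ex, 2] <- s + w
  tx <- list(strand = sample(c("+", "-"), 1), start = s, end = s + w,
             exons = exons)
  list(genes = genes, tx = tx)
}
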