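# Cis window geometry and trans duplex-energy scoring.

make_loci <- function(start, end, strand = "+", chrom = "Chr1") {
  ts <- tiny_transcripts(list(list(id = "t1", strand = strand,
                                   exons = cbind(start, end))),
                         chrom = chrom)
  cls <- data.frame(transcript_id = "t1", class = "lincRNA",
                    nat_subtype = NA, partner_gene = NA,
                    stringsAsFactors = FALSE)
  list(ts = ts, loci = merge_transcripts_to_loci(ts, cls))
}

test_that("cis window boundary at exactly 2000 nt is inclusive", {
  l <- make_loci(10000, 11000)
  annot <- tiny_annotation(list(
    list(strand = "+", start = 7000, end = 7999,
         biotype = "protein_coding", exons = cbind(7000, 7999)),   # 2000 away
    list(strand = "-", start = 13002, end = 14000,
         biotype = "protein_coding", exons = cbind(13002, 14000)), # 2001 away
    list(strand = "-", start = 10701, end = 12000,
         biotype = "protein_coding", exons = cbind(10701, 12000)))) # overlap
  tp <- cis_targets(l$loci, annot, ts = l$ts)
  expect_setequal(tp$gene_id, c("G01", "G03"))
  flank <- tp[tp$gene_id == "G01", ]
  expect_equal(flank$mechanism, "cis_flank")
  expect_equal(flank$distance_nt, 2000L)
  ov <- tp[tp$gene_id == "G03", ]
  expect_equal(ov$mechanism, "cis_overlap")
  expect_equal(ov$strand_relation, "antisense")
  expect_equal(ov$overlap_nt, 11000L - 10701L + 1L)
  expect_equal(ov$overlap_nt, 300L)
  expect_true(ov$transcript_overlap)
  expect_error(cis_targets(l$loci, annot, window = -5), "window")
})

test_that("cis overlap equals the brute-force intersection length", {
  set.seed(61)
  for (rep in 1:50) {
    ls <- sample(5000:9000, 1); le <- ls + sample(200:2000, 1)
    gs <- sample(1000:14000, 1); ge <- gs + sample(200:4000, 1)
    l <- make_loci(ls, le)
    annot <- tiny_annotation(list(
      list(strand = "-", start = gs, end = ge,
           biotype = "protein_coding", exons = cbind(gs, ge))),
      chrom_len = 50000L)
    tp <- cis_targets(l$loci, annot)
    want_ov <- max(0L, min(le, ge) - max(ls, gs) + 1L)
    gap <- if (want_ov > 0L) NA_integer_
           else if (ge < ls) ls - ge - 1L else gs - le - 1L
    if (want_ov > 0L) {
      expect_equal(tp$overlap_nt, want_ov)
    } else if (gap <= 2000L) {
      expect_equal(tp$distance_nt, gap)
      expect_true(tp$distance_nt >= 0 && tp$distance_nt <= 2000)
    } else {
      expect_equal(nrow(tp), 0L)
    }
  }
})

test_that("perfect reverse complement minimizes ndG; homopolymers score 0", {
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  perfect <- trans_duplex_ndG(s, rc)
  for (k in 1:5) {
    other <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    expect_lte(perfect, trans_duplex_ndG(s, other))
  }
  expect_equal(trans_duplex_ndG(strrep("A", 80), strrep("A", 80)), 0)
  expect_error(trans_duplex_ndG(strrep("A", 80), "AXX"), "non-nucleotide")
  expect_error(trans_duplex_ndG("ACGT", strrep("A", 80)), "at least 50")
})

test_that("ndG is symmetric and monotone under window extension", {
  set.seed(81)
  for (k in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(60:150, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(60:150, 1), TRUE),
               collapse = "")
    expect_equal(trans_duplex_ndG(a, b), trans_duplex_ndG(b, a),
                 tolerance = 1e-9)
  }
  # growing a perfect complementary window in fixed-length sequences
  # never increases ndG
  base <- strrep("A", 100)
  rcwin <- function(w) {
    win <- strrep("GC", w %/% 2)
    lnc <- paste0(strrep("A", (100 - nchar(win)) %/% 2), win,
                  strrep("A", 100 - nchar(win) - (100 - nchar(win)) %/% 2))
    mr <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(win)))
    mrna <- paste0(strrep("A", (100 - nchar(mr)) %/% 2), mr,
                   strrep("A", 100 - nchar(mr) - (100 - nchar(mr)) %/% 2))
    trans_duplex_ndG(lnc, mrna)
  }
  vals <- vapply(c(10, 20, 30, 40), rcwin, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("a planted 20-nt GC window scores its hand-summed stack energy", {
  win <- strrep("GC", 10)                       # pairs GC,CG alternating
  lnc <- paste0(strrep("A", 20), win, strrep("A", 20))
  mrna <- paste0(strrep("A", 20),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(win))),
                 strrep("A", 20))
  # 19 stacks: 10 x (GC,CG) at -3.42 and 9 x (CG,GC) at -2.36, one
  # helix initiation at +4.09
  expected <- (10 * -3.42 + 9 * -2.36 + 4.09) / 60
  expect_equal(trans_duplex_ndG(lnc, mrna), expected, tolerance = 1e-12)
})

test_that("predict_targets unions mechanisms and deduplicates", {
  annot <- tiny_annotation(list(
    list(strand = "-", start = 10500, end = 11500,
         biotype = "protein_coding", exons = cbind(10500, 11500)),
    list(strand = "+", start = 12500, end = 13000,
         biotype = "protein_coding", exons = cbind(12500, 13000)),
    list(strand = "+", start = 40000, end = 41000,
         biotype = "protein_coding", exons = cbind(40000, 41000))))
  l <- make_loci(10000, 11000)
  tg <- predict_targets(l$loci, annot, ts = l$ts, trans_candidates = NA)
  expect_equal(nrow(tg$pairs), 2L)   # one overlap + one flank
  expect_setequal(tg$pairs$mechanism, c("cis_overlap", "cis_flank"))
  expect_lte(length(tg$unique_genes), nrow(tg$pairs))
  # a locus with nothing within reach yields no records
  far <- make_loci(70000, 70500)
  expect_equal(nrow(predict_targets(far$loci, annot, ts = far$ts,
                                    trans_candidates = NA)$pairs), 0L)
})

test_that("trans scan flags a planted complementary gene", {
  set.seed(91)
  chrom_len <- 60000L
  lnc_seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(lnc_seq)))
  genome_str <- paste(sample(c("A", "C", "G", "T"), chrom_len, TRUE),
                      collapse = "")
  substr(genome_str, 10000, 10399) <- lnc_seq
  substr(genome_str, 30000, 30399) <- rc
  genome <- Biostrings::DNAStringSet(c(Chr1 = genome_str))
  annot <- tiny_annotation(list(
    list(strand = "+", start = 30000, end = 30399,
         biotype = "protein_coding", exons = cbind(30000, 30399)),
    list(strand = "+", start = 50000, end = 50400,
         biotype = "protein_coding", exons = cbind(50000, 50400))),
    chrom_len = chrom_len)
  l <- make_loci(10000, 10399)
  tg <- predict_targets(l$loci, annot, genome = genome, ts = l$ts)
  hits <- tg$pairs[tg$pairs$mechanism == "trans_duplex", ]
  expect_true("G01" %in% hits$gene_id)
  expect_true(all(hits$ndg <= -0.1))
})
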