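# Candidate filters, class codes, NAT subtypes and locus merging.

test_that("max_orf_aa handles start/stop boundary cases", {
  expect_equal(max_orf_aa("ATGTGA"), 1L)          # Met then stop
  expect_equal(max_orf_aa("CCCCCCTAA"), 0L)       # no ATG
  expect_equal(max_orf_aa("ATGAAACCC"), 0L)       # no stop: not an ORF
  expect_equal(max_orf_aa("ATGNNNTAA"), 2L)       # N codon is not a stop
  expect_error(max_orf_aa("ATGX"), "non-nucleotide")
})

test_that("an ORF of exactly 50 aa passes the candidate filter", {
  set.seed(11)
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1, paste,
                         collapse = ""),
                   c("TAA", "TAG", "TGA", "ATG"))
  seq50 <- paste0("ATG", paste(sample(sense, 49, TRUE), collapse = ""),
                  "TAA")
  expect_equal(oracle_max_orf(seq50), 50L)
  expect_equal(max_orf_aa(seq50), 50L)
})

test_that("max_orf_aa agrees with a positional brute-force scan", {
  set.seed(21)
  for (k in 1:60) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(30:400, 1),
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    expect_equal(max_orf_aa(s), oracle_max_orf(s), info = s)
  }
})

test_that("basic filters apply the documented boundary conventions", {
  ts <- tiny_transcripts(list(
    list(id = "short", strand = "+", exons = rbind(c(1, 99), c(200, 299))),
    list(id = "mono", strand = "+", exons = cbind(1000, 1500)),
    list(id = "boundary", strand = "+",
         exons = rbind(c(2000, 2249), c(2400, 2650))),
    list(id = "nofpkm", strand = "+",
         exons = rbind(c(3000, 3200), c(3300, 3500)))),
    fpkm = c(short = 5, mono = 5, boundary = 0.1))
  orf <- c(short = 10L, mono = 10L, boundary = 50L, nofpkm = 10L)
  rep <- basic_filters(ts, orf_aa = orf)
  rep <- rep[match(c("short", "mono", "boundary", "nofpkm"),
                   rep$transcript_id), ]
  expect_equal(rep$pass, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(rep$rule_length, c("fail", "pass", "pass", "pass"))
  expect_equal(rep$rule_exons, c("pass", "fail", "pass", "pass"))
  # FPKM exactly at 0.1 and ORF exactly 50 aa pass; missing FPKM is
  # indeterminate and the verdict fails
  expect_equal(rep$rule_fpkm[3], "pass")
  expect_equal(rep$rule_orf[3], "pass")
  expect_equal(rep$rule_fpkm[4], "indeterminate")
  # strict length boundary: spliced length exactly 200 fails
  ts200 <- tiny_transcripts(list(
    list(id = "len200", strand = "+", exons = rbind(c(1, 99), c(200, 300)))),
    fpkm = c(len200 = 1))
  expect_equal(ts200$transcripts$spliced_length, 200)
  expect_false(basic_filters(ts200, orf_aa = c(len200 = 1L))$pass)
})

test_that("class codes match the layout oracle on planted cases", {
  annot <- tiny_annotation(list(
    list(strand = "+", start = 1000, end = 3000,
         biotype = "protein_coding",
         exons = rbind(c(1000, 1400), c(2600, 3000))),
    list(strand = "-", start = 6000, end = 7000,
         biotype = "protein_coding", exons = cbind(6000, 7000)),
    list(strand = "+", start = 9000, end = 9800,
         biotype = "pseudogene", exons = cbind(9000, 9800))))
  ts <- tiny_transcripts(list(
    list(id = "intergenic", strand = "+", exons = cbind(4000, 4500)),
    list(id = "intronic", strand = "+",
         exons = rbind(c(1500, 1700), c(2000, 2200))),
    list(id = "antisense1bp", strand = "+", exons = cbind(5500, 6000)),
    list(id = "senseover", strand = "+", exons = cbind(9500, 10200)),
    list(id = "codingover", strand = "+", exons = cbind(1300, 1600))))
  code <- classify_class_code(ts, annot)
  expect_equal(unname(code[c("intergenic", "intronic", "antisense1bp",
                             "senseover", "codingover")]),
               c("u", "i", "x", "o", "coding_overlap_sense_exonic"))
})

test_that("class codes match the brute-force oracle on random layouts", {
  set.seed(31)
  n_bad <- 0L
  for (rep in 1:300) {
    lay <- random_layout()
    annot <- tiny_annotation(lay$genes)
    ts <- tiny_transcripts(list(c(lay$tx, list(id = "T01"))))
    got <- unname(classify_class_code(ts, annot)["T01"])
    want <- oracle_class_code(lay$tx, lay$genes)
    if (!identical(got, want)) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 0L)
})

test_that("NAT subtype geometry matches the enumeration oracle", {
  # convergent pair from the documented example
  expect_equal(classify_nat_subtype(1000, 2000, "+", 1500, 3000, "-"),
               "II")
  expect_equal(classify_nat_subtype(1000, 2000, "+", 1200, 1800, "-"),
               "IV")
  expect_equal(classify_nat_subtype(1000, 2000, "+", 500, 2500, "-"),
               "III")
  # gene ending 500 bp upstream on the opposite strand: promoter side
  expect_equal(classify_nat_subtype(5000, 6000, "+", 4000, 4500, "-"),
               "V")
  expect_error(classify_nat_subtype(1, 10, "+", 5, 20, "+"),
               "same strand")
  set.seed(41)
  for (rep in 1:700) {
    ls <- sample(3000:5000, 1); le <- ls + sample(200:2000, 1)
    gs <- sample(1000:8000, 1); ge <- gs + sample(200:3000, 1)
    lstrand <- sample(c("+", "-"), 1)
    want <- oracle_nat_subtype(ls, le, lstrand, gs, ge)
    got <- classify_nat_subtype(ls, le, lstrand, gs, ge,
                                gene_strand = if (lstrand == "+") "-"
                                              else "+")
    expect_identical(got, want,
                     info = sprintf("lnc [%d,%d]%s gene [%d,%d]",
                                    ls, le, lstrand, gs, ge))
  }
})

test_that("locus merging matches a union-find oracle and is stable", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    starts <- sample(1:5000, n)
    ends <- starts + sample(50:800, n, replace = TRUE)
    ids <- sprintf("t%02d", seq_len(n))
    ts <- transcript_set(data.frame(
      transcript_id = ids, chrom = "Chr1", strand = "+",
      start = starts, end = ends))
    cls <- data.frame(transcript_id = ids, class = "lincRNA",
                      nat_subtype = NA, partner_gene = NA,
                      stringsAsFactors = FALSE)
    loci <- merge_transcripts_to_loci(ts, cls)
    want <- oracle_overlap_clusters(starts, ends)
    expect_equal(nrow(loci$loci), length(unique(want)))
    # same-cluster oracle pairs share a locus
    got <- loci$members$locus_id[match(ids, loci$members$transcript_id)]
    expect_equal(outer(got, got, "=="), outer(want, want, "=="),
                 ignore_attr = TRUE)
    # order invariance
    perm <- sample(n)
    ts2 <- transcript_set(data.frame(
      transcript_id = ids[perm], chrom = "Chr1", strand = "+",
      start = starts[perm], end = ends[perm]))
    loci2 <- merge_transcripts_to_loci(ts2, cls)
    expect_equal(loci2$loci[c("start", "end", "n_transcripts")],
                 loci$loci[c("start", "end", "n_transcripts")])
  }
})

test_that("transcripts 1 bp apart stay separate; chains merge", {
  cls <- function(ids) data.frame(transcript_id = ids, class = "lincRNA",
                                  nat_subtype = NA, partner_gene = NA,
                                  stringsAsFactors = FALSE)
  apart <- transcript_set(data.frame(
    transcript_id = c("a", "b"), chrom = "Chr1", strand = "+",
    start = c(1, 102), end = c(100, 200)))
  expect_equal(nrow(merge_transcripts_to_loci(apart, cls(c("a", "b")))$loci),
               2L)
  chain <- transcript_set(data.frame(
    transcript_id = c("a", "b", "c"), chrom = "Chr1", strand = "+",
    start = c(1, 80, 160), end = c(100, 180, 260)))
  m <- merge_transcripts_to_loci(chain, cls(c("a", "b", "c")))
  expect_equal(nrow(m$loci), 1L)
  expect_equal(m$loci$n_transcripts, 3L)
  # opposite strands never merge
  anti <- transcript_set(data.frame(
    transcript_id = c("a", "b"), chrom = "Chr1", strand = c("+", "-"),
    start = c(1, 50), end = c(100, 150)))
  expect_equal(nrow(merge_transcripts_to_loci(anti, cls(c("a", "b")))$loci),
               2L)
})

test_that("count table adds consistent totals and anchors", {
  df <- data.frame(chrom = c("Chr1", "Chr1", "Chr2", "scaffold_9"),
                   class = c("lincRNA", "NAT", "NAT", "sense"))
  tab <- class_count_table(df)
  expect_equal(tab["Total", "Total"], 4)
  expect_equal(unname(count_table_totals(tab)),
               c(4, 3))
  expect_equal(tab["Chr1", "Total"], 2)
  # empty input gives an all-zero table
  empty <- class_count_table(data.frame(chrom = character(0),
                                        class = character(0)))
  expect_equal(empty["Total", "Total"], 0)
})
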