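# Synthetic study generator: a small genome with strand-annotated gene
# models, planted lncRNAs of all four classes and six NAT geometry
# subtypes, filter-violating decoys, log-normal FPKM matrices with
# planted coexpressed pairs, structured genotypes (admixed
# subpopulations) and phenotypes generated under the Q+K mixed model.
# Every stage is driven by one integer seed; sub-stage seeds are derived
# deterministically so stages can be re-run independently.

.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

#' Simulation configuration
#'
#' Defaults emulate the design of a typical oil palm lncRNA study: 18
#' expression samples, 200 genotyped individuals in five admixed
#' subpopulations, planted lncRNAs of all four classes with two of each
#' NAT subtype, and a heavy-tailed log-normal FPKM distribution under
#' which most lncRNAs are lowly expressed.
#'
#' @param seed integer master seed.
#' @param chrom_lengths named integer vector of sequence lengths; names
#'   starting `Chr` are anchored chromosomes, others are scaffolds.
#' @param n_genes background protein-coding genes.
#' @param n_lincrna,n_intronic,n_sense planted lncRNA counts per class.
#' @param nat_per_subtype planted NAT lncRNAs per geometry subtype I-VI.
#' @param n_decoys_each decoys per violated filter (length, exon count,
#'   FPKM, ORF, coding overlap).
#' @param intergenic_spacing minimum gap between planted cassettes (nt);
#'   4 kb by default so the 2-kb cis window is unambiguous.
#' @param n_samples expression samples T.
#' @param expr_meanlog,expr_sdlog log-normal FPKM parameters for
#'   background features (defaults place about 80 percent of values
#'   below FPKM 1).
#' @param pair_r target correlation of planted coexpressed pairs.
#' @param low_fraction fraction of background features rescaled so their
#'   FPKM_max falls below 1.
#' @param n_individuals,n_snps,n_subpops,fst genotype structure; `fst` is
#'   the Balding-Nichols divergence of subpopulation allele frequencies.
#' @param maf_range ancestral minor-allele-frequency range (subset of
#'   (0, 0.5]).
#' @param missing_rate missing-call rate (completely at random).
#' @param h2 narrow-sense heritability of simulated phenotypes.
#' @param q_effect per-subpopulation fixed phenotype shifts (recycled to
#'   the subpopulation count).
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(Chr1 = 250000L, Chr2 = 250000L,
                                         scaffold_1 = 120000L),
                       n_genes = 10L, n_lincrna = 6L, nat_per_subtype = 2L,
                       n_intronic = 4L, n_sense = 4L, n_decoys_each = 2L,
                       intergenic_spacing = 4000L,
                       n_samples = 18L, expr_meanlog = -1.5,
                       expr_sdlog = 1.8, pair_r = 0.9,
                       low_fraction = 0.6,
                       n_individuals = 200L, n_snps = 1000L,
                       n_subpops = 5L, fst = 0.1,
                       maf_range = c(0.05, 0.5), missing_rate = 0.05,
                       h2 = 0.4, q_effect = 0) {
  stopifnot(n_genes > 0, n_lincrna > 0, nat_per_subtype > 0,
            n_intronic > 0, n_sense > 0, n_samples > 0,
            n_individuals > 0, n_snps > 0, n_subpops > 0)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (abs(pair_r) >= 1) stop("pair_r must be inside (-1, 1)")
  if (maf_range[1] >= maf_range[2] || maf_range[1] <= 0 ||
      maf_range[2] > 0.5)
    stop("maf_range must be a non-degenerate subset of (0, 0.5]")
  structure(as.list(environment()), class = "SimulationConfig")
}

# ---- annotation / transcript layout ------------------------------------

# A cassette is built in local coordinates [1, width]; genes and
# transcripts are shifted to the placement position. Mirroring (for
# random orientation) reflects coordinates and flips strands, which
# preserves NAT geometry relative to the lncRNA's 5' end.
.mirror_cassette <- function(cs) {
  w <- cs$width
  flip <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    s <- df$start
    df$start <- w - df$end + 1L
    df$end <- w - s + 1L
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df[order(df$start), , drop = FALSE]
  }
  cs$genes <- flip(cs$genes)
  cs$gene_exons <- if (!is.null(cs$gene_exons) && nrow(cs$gene_exons)) {
    ge <- cs$gene_exons
    s <- ge$start
    ge$start <- w - ge$end + 1L
    ge$end <- w - s + 1L
    ge[order(ge$start), , drop = FALSE]
  } else cs$gene_exons
  cs$tx_exons <- if (!is.null(cs$tx_exons) && nrow(cs$tx_exons)) {
    te <- cs$tx_exons
    s <- te$start
    te$start <- w - te$end + 1L
    te$end <- w - s + 1L
    te$strand <- ifelse(te$strand == "+", "-", "+")
    te[order(te$transcript_id, te$start), , drop = FALSE]
  } else cs$tx_exons
  cs
}

.gene_row <- function(id, start, end, strand, biotype = "protein_coding")
  data.frame(gene_id = id, start = start, end = end, strand = strand,
             biotype = biotype, stringsAsFactors = FALSE)

.exon_rows <- function(id, starts, ends, key = "gene_id")
  setNames(data.frame(id, starts, ends, stringsAsFactors = FALSE),
           c(key, "start", "end"))

.tx_exon_rows <- function(id, starts, ends, strand)
  data.frame(transcript_id = id, start = starts, end = ends,
             strand = strand, stringsAsFactors = FALSE)

.nat_cassette <- function(subtype, gid, tid) {
  # built with the lncRNA on "+"; caller may mirror
  g <- function(s, e) .gene_row(gid, s, e, "-")
  ge <- function(s, e) .exon_rows(gid, s, e)
  switch(subtype,
    I = list(width = 3200L, genes = g(1L, 2000L), gene_exons = ge(1L, 2000L),
             tx_exons = .tx_exon_rows(tid, c(1500L, 2400L),
                                      c(2100L, 3000L), "+")),
    II = list(width = 3200L, genes = g(1000L, 3000L),
              gene_exons = ge(1000L, 3000L),
              tx_exons = .tx_exon_rows(tid, c(1L, 700L),
                                       c(500L, 1500L), "+")),
    III = list(width = 4200L, genes = g(1L, 4000L),
               gene_exons = ge(1L, 4000L),
               tx_exons = .tx_exon_rows(tid, c(1000L, 1800L),
                                        c(1500L, 2200L), "+")),
    IV = list(width = 4200L, genes = g(1000L, 2500L),
              gene_exons = ge(1000L, 2500L),
              tx_exons = .tx_exon_rows(tid, c(1L, 2200L),
                                       c(1800L, 4000L), "+")),
    V = list(width = 4600L, genes = g(1L, 2500L), gene_exons = ge(1L, 2500L),
             tx_exons = .tx_exon_rows(tid, c(3000L, 3900L),
                                      c(3600L, 4500L), "+")),
    VI = list(width = 4600L, genes = g(2000L, 4000L),
              gene_exons = ge(2000L, 4000L),
              tx_exons = .tx_exon_rows(tid, c(1L, 900L),
                                       c(600L, 1500L), "+")),
    stop("unknown NAT subtype ", subtype))
}

#' Simulate annotation, genome and transcripts with truth labels
#'
#' Lays out background protein-coding genes, planted lncRNAs of all four
#' classes (with `nat_per_subtype` NAT lncRNAs per geometry subtype
#' I-VI), and decoy transcripts violating each candidate filter (too
#' short, mono-exonic, FPKM below threshold, an ORF longer than 50 aa,
#' and same-strand exonic overlap with a coding gene). Cassettes are
#' separated by at least `intergenic_spacing` nt. Planted lncRNA
#' sequences are regenerated until they contain no ORF longer than 50
#' aa; the ORF decoy gets an in-frame 61-codon ORF written into its
#' first exon. Two lincRNA loci receive a second overlapping transcript
#' to exercise locus merging.
#'
#' @param config a [sim_config()].
#' @return List: `annotation` (`AnnotationSet`), `genome`
#'   (`DNAStringSet`), `transcripts` (`TranscriptSet` with
#'   discovery-sample FPKM), `truth` (per-transcript truth labels:
#'   class, NAT subtype, violated filter, partner gene).
#' @export
simulate_annotation_and_transcripts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.stage_seed(config$seed, "annotation"))
  cassettes <- list()
  truth <- list()
  add_truth <- function(tid, class, subtype = NA, fail = NA, partner = NA)
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = tid, truth_class = class, truth_subtype = subtype,
      truth_fail = fail, partner_gene = partner, stringsAsFactors = FALSE)

  # background protein-coding genes (3 exons)
  for (k in seq_len(config$n_genes)) {
    gid <- sprintf("GENE_%03d", k)
    strand <- sample(c("+", "-"), 1L)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 4500L,
      genes = .gene_row(gid, 1L, 4200L, strand),
      gene_exons = .exon_rows(gid, c(1L, 1500L, 3400L),
                              c(900L, 2400L, 4200L)),
      tx_exons = NULL)
  }

  # NAT lncRNAs, one partner gene each
  for (st in NAT_SUBTYPES) for (k in seq_len(config$nat_per_subtype)) {
    gid <- sprintf("GENE_NAT%s_%d", st, k)
    tid <- sprintf("TX_NAT%s_%d", st, k)
    cs <- .nat_cassette(st, gid, tid)
    if (runif(1) < 0.5) cs <- .mirror_cassette(cs)
    cassettes[[length(cassettes) + 1L]] <- cs
    add_truth(tid, "NAT", subtype = st, partner = gid)
  }

  # lincRNAs (first two loci get a second overlapping transcript)
  for (k in seq_len(config$n_lincrna)) {
    tid <- sprintf("TX_LINC_%d", k)
    strand <- sample(c("+", "-"), 1L)
    te <- .tx_exon_rows(tid, c(1L, 800L), c(600L, 1400L), strand)
    if (k <= 2L) {
      tid2 <- paste0(tid, "b")
      te <- rbind(te, .tx_exon_rows(tid2, c(300L, 1000L), c(900L, 1700L),
                                    strand))
      add_truth(tid2, "lincRNA")
    }
    cassettes[[length(cassettes) + 1L]] <- list(width = 1800L,
                                                genes = NULL,
                                                gene_exons = NULL,
                                                tx_exons = te)
    add_truth(tid, "lincRNA")
  }

  # intronic lncRNAs inside a long intron of a same-strand gene
  for (k in seq_len(config$n_intronic)) {
    gid <- sprintf("GENE_INT_%d", k)
    tid <- sprintf("TX_INT_%d", k)
    strand <- sample(c("+", "-"), 1L)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 6200L,
      genes = .gene_row(gid, 1L, 6000L, strand),
      gene_exons = .exon_rows(gid, c(1L, 5200L), c(800L, 6000L)),
      tx_exons = .tx_exon_rows(tid, c(1500L, 2500L), c(2100L, 3000L),
                               strand))
    add_truth(tid, "intronic", partner = gid)
  }

  # sense lncRNAs over pseudogene exons, same strand
  for (k in seq_len(config$n_sense)) {
    gid <- sprintf("PSEUDO_%d", k)
    tid <- sprintf("TX_SENSE_%d", k)
    strand <- sample(c("+", "-"), 1L)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 2700L,
      genes = .gene_row(gid, 1L, 2500L, strand, biotype = "pseudogene"),
      gene_exons = .exon_rows(gid, 1L, 2500L),
      tx_exons = .tx_exon_rows(tid, c(1000L, 1700L), c(1500L, 2200L),
                               strand))
    add_truth(tid, "sense", partner = gid)
  }

  # decoys violating each filter
  for (k in seq_len(config$n_decoys_each)) {
    tid <- sprintf("TX_SHORT_%d", k)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 500L, genes = NULL, gene_exons = NULL,
      tx_exons = .tx_exon_rows(tid, c(1L, 200L), c(80L, 270L), "+"))
    add_truth(tid, "decoy", fail = "length")

    tid <- sprintf("TX_MONO_%d", k)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 900L, genes = NULL, gene_exons = NULL,
      tx_exons = .tx_exon_rows(tid, 1L, 800L, "+"))
    add_truth(tid, "decoy", fail = "exon")

    tid <- sprintf("TX_LOWFPKM_%d", k)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 1500L, genes = NULL, gene_exons = NULL,
      tx_exons = .tx_exon_rows(tid, c(1L, 700L), c(500L, 1300L), "+"))
    add_truth(tid, "decoy", fail = "fpkm")

    tid <- sprintf("TX_ORF_%d", k)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 1500L, genes = NULL, gene_exons = NULL,
      tx_exons = .tx_exon_rows(tid, c(1L, 500L), c(220L, 900L), "+"))
    add_truth(tid, "decoy", fail = "orf")

    gid <- sprintf("GENE_CODE_%d", k)
    tid <- sprintf("TX_CODE_%d", k)
    cassettes[[length(cassettes) + 1L]] <- list(
      width = 3200L,
      genes = .gene_row(gid, 1L, 3000L, "+"),
      gene_exons = .exon_rows(gid, 1L, 3000L),
      tx_exons = .tx_exon_rows(tid, c(500L, 1300L), c(1100L, 1800L), "+"))
    add_truth(tid, "decoy", fail = "coding_overlap", partner = gid)
  }

  # place cassettes round-robin across sequences
  chroms <- names(config$chrom_lengths)
  cursor <- setNames(rep(1L, length(chroms)), chroms)
  genes <- list(); gene_exons <- list(); tx_exons <- list()
  gene_chrom <- character(0)
  for (idx in seq_along(cassettes)) {
    cs <- cassettes[[idx]]
    chrom <- chroms[(idx - 1L) %% length(chroms) + 1L]
    off <- cursor[chrom] - 1L
    if (off + cs$width > config$chrom_lengths[chrom])
      stop("infeasible packing on ", chrom,
           ": increase chromosome lengths or reduce planted counts")
    shift <- function(df) {
      if (is.null(df) || !nrow(df)) return(df)
      df$start <- df$start + off
      df$end <- df$end + off
      df$chrom <- chrom
      df
    }
    if (!is.null(cs$genes)) {
      genes[[length(genes) + 1L]] <- shift(cs$genes)
      gene_exons[[length(gene_exons) + 1L]] <-
        shift(cs$gene_exons)[c("gene_id", "start", "end")]
    }
    if (!is.null(cs$tx_exons))
      tx_exons[[length(tx_exons) + 1L]] <- shift(cs$tx_exons)
    cursor[chrom] <- cursor[chrom] + cs$width + config$intergenic_spacing
  }
  genes <- do.call(rbind, genes)
  annot <- annotation_set(genes, do.call(rbind, gene_exons),
                          config$chrom_lengths)
  tx_exons <- do.call(rbind, tx_exons)
  truth <- do.call(rbind, truth)

  # genome sequence, then enforce ORF truth labels
  genome <- Biostrings::DNAStringSet(vapply(config$chrom_lengths,
    function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = ""), ""))
  names(genome) <- chroms

  fpkm <- setNames(pmax(stats::rlnorm(length(unique(tx_exons$transcript_id)),
                                      meanlog = 1, sdlog = 1), 0.15),
                   unique(tx_exons$transcript_id))
  low_ids <- truth$transcript_id[!is.na(truth$truth_fail) &
                                   truth$truth_fail == "fpkm"]
  fpkm[low_ids] <- 0.05
  ts <- transcript_set(tx_exons, fpkm = fpkm)

  need_short_orf <- truth$transcript_id[
    truth$truth_class != "decoy" |
      truth$truth_fail %in% c("length", "exon", "fpkm", "coding_overlap")]
  genome <- .enforce_orf_limit(genome, ts,
                               intersect(need_short_orf,
                                         ts$transcripts$transcript_id))
  # plant a 61-codon ORF (61 aa > 50) into each ORF decoy's first exon
  orf_ids <- truth$transcript_id[!is.na(truth$truth_fail) &
                                   truth$truth_fail == "orf"]
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste,
                  collapse = "")
  sense_codons <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  for (tid in orf_ids) {
    e <- ts$exons[ts$exons$transcript_id == tid, , drop = FALSE]
    orf <- paste0("ATG", paste(sample(sense_codons, 60L, replace = TRUE),
                               collapse = ""), "TAA")
    genome[[e$chrom[1L]]] <- Biostrings::replaceAt(
      genome[[e$chrom[1L]]],
      IRanges::IRanges(e$start[1L], e$start[1L] + nchar(orf) - 1L), orf)
  }
  list(annotation = annot, genome = genome, transcripts = ts,
       truth = truth)
}

# genomic position of spliced base s of a transcript (exons sorted by
# start; minus-strand transcripts read from the right end leftwards)
.spliced_to_genomic <- function(e, strand, s) {
  lens <- e$end - e$start + 1L
  total <- sum(lens)
  if (strand == "-") s <- total - s + 1L
  cum <- cumsum(lens)
  i <- which(s <= cum)[1L]
  e$start[i] + (s - c(0L, cum)[i]) - 1L
}

# Rewrite genome bases so that no listed transcript contains an ORF
# longer than max_aa: the longest offending ORF gets a stop codon
# written into its middle (strand-aware). Overlapping transcripts can
# perturb each other, so the whole set is iterated to a fixed point.
.enforce_orf_limit <- function(genome, ts, ids, max_aa = 50L) {
  for (pass in 1:10) {
    clean <- TRUE
    for (tid in ids) {
      e <- ts$exons[ts$exons$transcript_id == tid, , drop = FALSE]
      strand <- e$strand[1L]; chrom <- e$chrom[1L]
      for (iter in 1:200) {
        orf <- .longest_orf(spliced_sequence(genome, ts, tid))
        if (orf$aa <= max_aa) break
        clean <- FALSE
        mid <- orf$start + 3L * (orf$aa %/% 2L)
        stop_codon <- c("T", "A", "A")
        for (k in 0:2) {
          gpos <- .spliced_to_genomic(e, strand, mid + k)
          base <- stop_codon[k + 1L]
          if (strand == "-")
            base <- chartr("ACGT", "TGCA", base)
          genome[[chrom]] <- Biostrings::replaceAt(
            genome[[chrom]], IRanges::IRanges(gpos, gpos), base)
        }
        if (iter == 200L)
          stop("could not remove long ORFs from transcript ", tid)
      }
    }
    if (clean) break
  }
  genome
}

#' Simulate a log-normal FPKM matrix with planted coexpressed pairs
#'
#' Baseline features draw i.i.d. log-normal FPKM per sample. Planted
#' pairs draw from a bivariate normal on the log scale with correlation
#' `config$pair_r` (and a higher mean, so they survive the low-abundance
#' screen). A `config$low_fraction` share of the remaining features is
#' rescaled so FPKM_max falls below 1, emulating the predominance of
#' lowly expressed lncRNAs.
#'
#' @param config a [sim_config()] (needs `n_samples >= 4`).
#' @param features character vector of feature ids.
#' @param pairs optional data.frame (`lncrna_id`, `target_id`) of planted
#'   coexpressed pairs; members must be in `features`.
#' @param zero_features feature ids forced to all-zero rows.
#' @return List: `expr` (an `ExpressionMatrix`), `pairs` (the planted
#'   pairs with their target correlation).
#' @export
simulate_expression <- function(config, features, pairs = NULL,
                                zero_features = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$n_samples < 4L) stop("at least 4 samples are required")
  r <- config$pair_r
  if (abs(r) >= 1) stop("pair correlation must be inside (-1, 1)")
  set.seed(.stage_seed(config$seed, "expression"))
  T <- config$n_samples
  m <- matrix(stats::rlnorm(length(features) * T,
                            meanlog = config$expr_meanlog,
                            sdlog = config$expr_sdlog),
              nrow = length(features),
              dimnames = list(features,
                              sprintf("sample_%02d", seq_len(T))))
  paired <- character(0)
  if (!is.null(pairs) && nrow(pairs)) {
    bad <- setdiff(unique(c(pairs$lncrna_id, pairs$target_id)), features)
    if (length(bad)) stop("pair member not in features: ",
                          paste(bad, collapse = ", "))
    for (k in seq_len(nrow(pairs))) {
      u <- rnorm(T)
      v <- r * u + sqrt(1 - r^2) * rnorm(T)
      m[pairs$lncrna_id[k], ] <- exp(1 + 1 * u)
      m[pairs$target_id[k], ] <- exp(1 + 1 * v)
    }
    paired <- unique(c(pairs$lncrna_id, pairs$target_id))
  }
  free <- setdiff(features, c(paired, zero_features))
  n_low <- round(config$low_fraction * length(free))
  if (n_low > 0L) {
    low <- sample(free, n_low)
    cap <- runif(n_low, 0.05, 0.95)
    m[low, ] <- m[low, , drop = FALSE] *
      cap / pmax(apply(m[low, , drop = FALSE], 1L, max), 1e-12)
  }
  if (length(zero_features)) m[intersect(zero_features, features), ] <- 0
  list(expr = expression_matrix(m), pairs = pairs)
}

#' Simulate structured genotypes with an admixture truth Q matrix
#'
#' Balding-Nichols model: ancestral allele frequencies are drawn
#' uniformly from `config$maf_range`; subpopulation frequencies from a
#' Beta distribution with divergence `config$fst`; each individual's
#' admixture proportions (a row of Q summing to 1) mix the subpopulation
#' frequencies, and genotypes are drawn Hardy-Weinberg from the
#' individual's expected frequency. Calls go missing completely at
#' random at `config$missing_rate`.
#'
#' @param config a [sim_config()].
#' @param positions optional data.frame (`chrom`, `pos`) for the SNPs;
#'   default places them uniformly along the configured chromosomes.
#' @return List: `gt` (a `GenotypeTable`), `Q` (individuals x
#'   subpopulations, rows sum to 1), `subpop` (primary subpopulation per
#'   individual), `freq` (subpopulation allele frequencies, SNPs x
#'   subpopulations).
#' @export
simulate_genotypes <- function(config, positions = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.stage_seed(config$seed, "genotypes"))
  N <- config$n_individuals; M <- config$n_snps
  K <- config$n_subpops; F <- config$fst
  p0 <- runif(M, config$maf_range[1], config$maf_range[2])
  freq <- if (F > 0 && K > 1L)
    matrix(rbeta(M * K, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F), M, K)
  else matrix(p0, M, K)
  freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
  subpop <- rep_len(seq_len(K), N)
  alpha <- matrix(0.2, N, K)
  alpha[cbind(seq_len(N), subpop)] <- 8
  gam <- matrix(stats::rgamma(N * K, shape = alpha), N, K)
  Q <- gam / rowSums(gam)
  pf <- freq %*% t(Q)                      # SNPs x individuals
  dos <- matrix(rbinom(M * N, 2L, pf), M, N)
  if (config$missing_rate > 0)
    dos[runif(M * N) < config$missing_rate] <- NA_integer_
  if (is.null(positions)) {
    chroms <- names(config$chrom_lengths)
    pc <- sample(chroms, M, replace = TRUE)
    positions <- data.frame(
      chrom = pc,
      pos = vapply(pc, function(cn)
        sample.int(config$chrom_lengths[[cn]], 1L), 0L),
      stringsAsFactors = FALSE)
  }
  alleles <- t(vapply(seq_len(M), function(i)
    sort(sample(c("A", "C", "G", "T"), 2L)), c("", "")))
  snps <- data.frame(snp_id = sprintf("SNP_%05d", seq_len(M)),
                     chrom = positions$chrom, pos = positions$pos,
                     allele_a = alleles[, 1L], allele_b = alleles[, 2L],
                     stringsAsFactors = FALSE)
  calls <- matrix(c("AA", "AB", "BB")[dos + 1L], M, N,
                  dimnames = list(snps$snp_id,
                                  sprintf("ind_%03d", seq_len(N))))
  list(gt = genotype_table(snps, calls), Q = Q, subpop = subpop,
       freq = freq)
}

#' Simulate phenotypes under the Q+K generative model
#'
#' `y = mu + sum_s beta_s * x_s + Q v + g + e` with `g ~ N(0, sg2 *
#' K_true)` (K_true computed from the generating genotypes) and `e`
#' i.i.d. normal; `sg2 = h2` and `se2 = 1 - h2`, so the polygenic and
#' residual parts sum to unit variance and planted effects `beta` are
#' expressed in phenotype standard-deviation units (causal dosages are
#' standardized before scaling).
#'
#' @param config a [sim_config()]; `h2 = 1` is rejected (no residual
#'   variance to draw).
#' @param gt a `GenotypeTable` from [simulate_genotypes()].
#' @param Q the admixture matrix from the same call.
#' @param causal optional data.frame (`snp_id`, `beta`) of planted
#'   effects; ids must exist in `gt`.
#' @return List: `y` (named phenotype vector), `K_true`, and the truth
#'   components (`beta`, `g`, `e`, `v`).
#' @export
simulate_phenotypes <- function(config, gt, Q, causal = NULL) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(gt, "GenotypeTable"))
  if (config$h2 >= 1)
    stop("h2 = 1 leaves no residual variance; request h2 < 1")
  set.seed(.stage_seed(config$seed, "phenotypes"))
  N <- ncol(gt$calls)
  sg2 <- config$h2; se2 <- 1 - config$h2
  K_true <- kinship_matrix(gt)
  g <- if (sg2 > 0) {
    L <- chol(K_true + diag(1e-6, N))
    sqrt(sg2) * drop(t(L) %*% rnorm(N))
  } else rep(0, N)
  e <- rnorm(N, sd = sqrt(se2))
  v <- rep_len(config$q_effect, ncol(Q))
  y <- drop(Q %*% v) + g + e
  beta <- NULL
  if (!is.null(causal) && nrow(causal)) {
    idx <- match(causal$snp_id, gt$snps$snp_id)
    if (anyNA(idx)) stop("causal SNP id not in genotype table: ",
                         paste(causal$snp_id[is.na(idx)], collapse = ", "))
    dos <- .dosage_imputed(gt)
    for (k in seq_along(idx)) {
      x <- dos[idx[k], ]
      if (sd(x) == 0) stop("causal SNP ", causal$snp_id[k],
                           " is monomorphic")
      y <- y + causal$beta[k] * (x - mean(x)) / sd(x)
    }
    beta <- causal
  }
  names(y) <- colnames(gt$calls)
  list(y = y, K_true = K_true, beta = beta, g = g, e = e, v = v)
}
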