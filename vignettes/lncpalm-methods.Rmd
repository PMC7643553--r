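---
title: "lncpalm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncpalm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpalm)
```

# Scope

`lncpalm` implements a genome-wide long noncoding RNA (lncRNA) analysis
pipeline of the kind used for oil palm (*Elaeis guineensis*) transcriptome
studies: candidate filtering of assembled transcripts, classification into
four lncRNA classes and six natural-antisense (NAT) geometry subtypes,
cis/trans target-gene prediction, Pearson coexpression screening against a
significance-derived threshold, and a Q+K mixed-linear-model association
scan of SNPs located inside lncRNA loci. A synthetic-data module generates
all inputs with known ground truth, so every stage can be validated
end-to-end without sequencing data.

Upstream read processing (QC, trimming, alignment, transcript assembly)
and external coding-potential classifiers are out of scope: the pipeline
starts from assembled transcript models, a reference annotation, a genome
sequence, an expression matrix, genotypes and phenotypes.

# Candidate filters and ORF definition

A transcript is a candidate lncRNA when all four rules pass:

* spliced length strictly greater than 200 nt,
* more than one exon,
* abundance FPKM >= 0.1 (inclusive),
* no open reading frame longer than 50 amino acids (50 aa passes).

Boundary conventions follow a literal reading of the usual wording:
"more than 200 bp" and "more than one exon" are strict, "FPKM >= 0.1" is
inclusive, and an ORF "encoding more than 50 amino acids" disqualifies, so
exactly 50 passes. Length is spliced (sum of exon lengths), not genomic
span; with multi-exon transcripts the two differ and the spliced length is
the biologically relevant one for an RNA.

The ORF scan (`max_orf_aa()`) considers only the three forward frames of
the spliced sequence — the strand is known from stranded assembly — and
counts ATG-initiated, stop-terminated frames, measuring the initiator Met
through the last codon before the stop. An ORF without an in-frame stop is
not counted. Codons containing N never match the start or a stop. A
missing FPKM leaves that rule indeterminate and the transcript fails,
which is the conservative choice for discovery.

# Classification

`classify_class_code()` assigns each surviving transcript a one-letter
relation to the reference annotation, mirroring the assembly class codes
that such pipelines retain (`u`, `i`, `o`, `x`):

* `x` — an exon overlaps an exon of an opposite-strand gene;
* `o` — an exon overlaps an exon of a same-strand pseudogene;
* `i` — wholly contained in one intron of a same-strand protein-coding
  gene (introns are the gaps between consecutive annotated exons);
* `u` — the span overlaps no gene span on either strand;
* `coding_overlap_sense_exonic` — same-strand exonic overlap with a
  protein-coding gene; removed as putatively coding;
* `other` — residual layouts (e.g. same-strand span overlap that is
  neither exonic nor intron-contained); removed, as codes outside
  `u/i/o/x` were in the original pipelines.

The coding-overlap check is applied first; among the remaining codes the
precedence is `x > o > i > u`. The code set in the source conventions is
not total over all geometries, hence the explicit `other` class here.

Classes derive from codes: `x` becomes NAT, `i` intronic, `o` sense, and
`u` becomes NAT (subtype V/VI) when an opposite-strand gene lies within
the 2-kb flank window, otherwise lincRNA. The six NAT subtypes are pure
span geometry relative to the lncRNA's 5' end:

* I — partial overlap covering the lncRNA's 5' end (head-to-head,
  divergent);
* II — partial overlap covering the 3' end (tail-to-tail, convergent);
* III — lncRNA wholly inside the gene span;
* IV — gene wholly inside the lncRNA span;
* V — no overlap, gene within the 2-kb upstream (promoter-side) window;
* VI — no overlap, gene within the 2-kb downstream window.

The I-vs-II orientation mapping is a documented convention: published
figures of this classification rarely pin the orientation down in text,
and the divergent/convergent reading used here is the standard one for
head-to-head versus tail-to-tail gene pairs. "Promoter region" is taken
as 2 kb upstream — the same constant as the cis window — to avoid a
second arbitrary length. When several partner genes qualify, the one with
the largest span overlap wins, ties broken by smallest distance then
lexicographic gene id, making the choice deterministic. Equal spans
(mutual containment) are called III.

`merge_transcripts_to_loci()` merges same-chromosome, same-strand
transcripts whose spans overlap by at least 1 bp, transitively; adjacency
without overlap does not merge. The locus class is the majority class of
members with ties broken NAT > intronic > sense > lincRNA (antisense
relations being the analysis focus); subtype and partner gene are the
majority among members of the winning class. Merging is idempotent and
order-independent, which the test suite checks against a union-find
oracle.

# Target prediction

Cis targets (`cis_targets()`) are protein-coding genes whose span overlaps
the locus span (`cis_overlap`, recording overlap length and the
sense/antisense strand relation) or lies within 2000 nt of either end on
either strand (`cis_flank`, recording the gap; the boundary at exactly
2000 nt is inclusive). A `transcript_overlap` flag records whether locus
exons overlap gene exons, distinguishing exon-level from span-only
overlaps — the distinction that downstream coexpression screening uses.
The mechanism label is `cis_overlap` rather than an "antisense"-specific
name because the same rule legitimately captures same-strand overlaps,
such as an intronic lncRNA's host gene; the strand relation is a separate
column.

Trans targets are scored with a deliberately simple, fully shipped duplex
energy model (`trans_duplex_ndG()`): the shorter sequence slides
antiparallel along the longer; at each offset, maximal runs of paired
bases (Watson-Crick plus GU wobble; any mismatch breaks the run) are
scored with a nearest-neighbour stack-energy table, each run pays a helix
initiation penalty of +4.09 kcal/mol, and only runs whose stacks beat
that penalty count. The minimum total over offsets, divided by the
shorter length, is the normalized energy ndG (kcal/mol/nt); a pair is
called at ndG <= -0.1 by default, the published default of the LncTar
tool this step emulates. The Watson-Crick stack values are the standard
RNA nearest-neighbour set (AU/AU -0.93 through GC/GC -3.42 kcal/mol);
stacks containing one or two GU pairs carry flat values (-1.2, -0.5).
The table is canonicalised so reading a duplex from either strand gives
the same energy, making ndG symmetric in its arguments (to floating-point
summation order). Without the initiation penalty, scattered chance
pairings in long random sequences accumulate enough stack energy to call
essentially every pair a target; the penalty restores the intended
behaviour that only a contiguous complementary stretch of roughly a
dozen or more bases contributes. This model is *not* LncTar: it is the
package's own documented primitive in the same spirit.

Because the scan is quadratic in sequence length, the default pipeline
scans only loci with no cis target; callers can supply an explicit
candidate list instead.

# Expression and coexpression

FPKM follows the standard definition
(`fragments x 1e9 / (length x total)`), gene-level FPKM is the sum over
isoforms, and expression bins are low [0, 1), medium [1, 15],
high (15, 100], very high (> 100), with upper boundaries inclusive as
documented.

The screening threshold is the two-tailed critical value of Pearson's r:
`r_crit = t / sqrt(t^2 + df)` with `t` the `1 - alpha/2` Student-t
quantile. At `df = 16`, `alpha = 0.05` this is 0.468 (3 dp) — the
familiar threshold printed alongside "n = 16" in studies using 18
samples, which identifies the printed n as the degrees of freedom
`n_samples - 2`. The package therefore always uses
`df = n_samples - 2`.

`coexpression_screen()` excludes pairs where either member has
FPKM_max < 1 (strict) before computing r; excluded pairs carry no
correlation. Negative verdicts use the symmetric threshold `-r_crit`.
A zero-variance expression vector (possible after low-expression
filtering) leaves r undefined: the pair is reported `not_significant`
with a `zero_variance` flag and `NA`, never NaN. Fewer than 4 samples is
an error since df < 2 makes the threshold meaningless.

# Association

SNPs are filtered at MAF > 0.05 and call rate > 0.80, both strict, with
MAF computed on non-missing calls. SNPs are assigned to every locus whose
span contains them — overlapping loci yield one record each, as seen in
published tables where one position annotates two loci — with context
`exon` when the position falls in the union of member-transcript exons,
else `intron`. Observed heterozygosity is the fraction of non-missing
individuals that are heterozygous; MAF, call rate and Het are invariant
to allele relabeling.

Kinship is the VanRaden centered cross-product
`K = (X - 2p)(X - 2p)' / (2 sum p(1-p))` on mean-imputed dosages — a
documented deviation from SPAGeDi-style estimators sometimes used for
the same role, chosen because it is the standard GWAS mixed-model
kinship and pairs naturally with REML.

The mixed model is `y = Xb + g + e` with `g ~ N(0, sg2 K)` and
`e ~ N(0, se2 I)`, fixed effects being the intercept, the population
membership matrix Q (last column dropped against the intercept) and the
SNP dosage (0/1/2, missing mean-imputed). Variance components are
estimated once by REML under the null model and reused per SNP —
the EMMA/EMMAX approximation, chosen because per-SNP REML adds cost
without changing desk-scale conclusions. The profile REML likelihood in
`lambda = sg2/se2` is evaluated through the spectral decomposition of K
on a 61-point log grid spanning 1e-5 to 1e5, then refined by Brent
search in the winning bracket; a boundary check collapses to
`lambda = 0` when no genetic variance is supported. Each SNP coefficient
is Wald-tested against a t reference with `n - p` degrees of freedom
after re-estimating the residual scale, so with `sg2 = 0` the scan is
*exactly* ordinary least squares — a property the tests assert to 1e-8.
Significance uses a raw p < 1e-3 cutoff with no multiplicity
correction, matching the practice this pipeline reproduces;
`-log10 p` is reported alongside.

# The synthetic-data generator

The generator's defaults are the study conditions the package targets:
18 expression samples, 200 genotyped individuals in five admixed
subpopulations, and planted lncRNAs of all four classes with two of each
NAT subtype. What it emulates, per stage:

* **Annotation/genome/transcripts** — gene and lncRNA "cassettes" are
  laid out with at least 4 kb spacing (so the 2-kb cis window is
  unambiguous unless a test plants ambiguity deliberately) across two
  chromosomes and one unplaced scaffold, the scaffold exercising the
  "others" row of the genomic-distribution table. Each NAT subtype is
  planted with exact geometry; decoys violate each filter (151 nt
  spliced, mono-exonic, FPKM 0.05, a planted in-frame 61-codon ORF,
  same-strand exonic overlap with a coding gene). Genome sequence is
  uniform random; planted lncRNAs are then "stop-stomped" — the longest
  ORF repeatedly receives a stop codon in its middle until none exceeds
  50 aa — because rejection sampling cannot fix multi-kb transcripts.
* **Expression** — log-normal FPKM (meanlog -1.5, sdlog 1.8 by default,
  putting roughly 80% of values below FPKM 1, the proportion such
  studies report); planted coexpressed pairs are bivariate normal on the
  log scale at target correlation r* (default 0.9) with a higher mean so
  they survive the abundance screen; a configurable fraction (default
  0.6) of background features is rescaled so FPKM_max < 1.
* **Genotypes** — Balding-Nichols: ancestral frequencies uniform on the
  configured MAF range, subpopulation frequencies Beta-distributed with
  divergence Fst (default 0.1), individual admixture rows from a
  concentrated Dirichlet (rows of Q sum to 1), Hardy-Weinberg sampling
  at each individual's expected frequency, calls missing completely at
  random (default 5%). Sampling noise moves a small tail of empirical
  MAFs outside the ancestral range; the downstream MAF filter is what
  controls that, as in real data.
* **Phenotypes** — `y = Qv + sum beta_s x_s + g + e` with
  `g ~ N(0, h2 K_true)` and `e ~ N(0, 1 - h2)`, so the polygenic and
  residual parts sum to unit variance and planted effects are in
  phenotype-SD units (causal dosages standardized before scaling).
  `h2 = 1` is rejected because it leaves no residual variance to draw.

One integer seed drives everything; each stage derives its own stream
seed deterministically, so stages rerun independently and identically.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: linkage disequilibrium beyond admixture
structure, realistic gene sequence composition (decoy ORFs aside, the
genome is uniform random), read-level noise in FPKM, isoform-level
expression correlation, and assembly artifacts other than the planted
decoy types.

# Numerical choices and degenerate inputs

* Coordinates are 1-based closed throughout, the native convention of
  GFF/GTF and of the IRanges stack that supplies the interval algebra;
  no conversion layer exists to get wrong.
* Numeric TSV output uses 17 significant digits so write/read round
  trips preserve doubles exactly.
* Triallelic genotype sites are skipped with a warning, never silently
  dropped; monomorphic SNPs are skipped by the scan with a warning;
  an all-missing SNP is an error for heterozygosity.
* REML is deterministic for fixed inputs (grid + Brent, no random
  restarts); a non-finite likelihood over the whole bracket is an error
  naming the bracket.
* Partner-gene and class ties break deterministically (documented
  above), so outputs are reproducible across platforms.

# Problem sizes used in validation

The shipped validation runs use desk-scale sizes chosen to make the
statistical checks sharp while keeping a full run in minutes: oracle
comparisons on ~1000 random layouts; REML recovery at n = 500 over 50
replicates per heritability value; null calibration over ~2000 SNP
tests; power over 100 replicates at N = 200; coexpression calibration
over 100 replicate pairs at T = 18. The acceptance script
(`scripts/acceptance.R`) reruns all of these from scratch under a
user-supplied seed.

# Known limitations

* The duplex model ignores loop/bulge energetics and intramolecular
  structure; it ranks complementarity, it does not predict binding
  thermodynamics.
* The coding-potential decision is a single ORF-length rule; ensemble
  classifiers (CPC/CNCI/CPAT/Pfam) used in sequencing studies are out of
  scope, so borderline coding transcripts that only those tools catch
  would survive here.
* Kinship and the EMMAX-style single variance-component estimation are
  approximations; strong single-SNP effects inflate the null-model
  genetic variance slightly, which is conservative.
* The Q matrix is taken as input (or simulation truth); population
  structure inference itself is not reimplemented.
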