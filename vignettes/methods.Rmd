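---
title: "Methods: allelic differential expression from long-read RNA-seq in cattle x yak hybrids"
author: "hybridADE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic differential expression from long-read RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An F1 hybrid of cattle (*Bos taurus*) and yak (*Bos grunniens*) carries one
haploid genome from each species. Because the two parental genomes diverge
at roughly 1.2% of sites, a full-length transcript read of a few hundred
bases typically covers many interspecies SNPs and can be attributed to its
parental haplotype with high confidence — something short reads cannot do
per molecule. `hybridADE` quantifies, per gene and per sequenced sample,
how many full-length transcript molecules came from the cattle allele and
how many from the yak allele, tests whether the imbalance is statistically
credible (allelic differential expression, ADE), and summarizes which genes
are imbalanced in every animal of a tissue and in which direction.

The analysis makes three structural assumptions:

* reads are aligned to a cattle-coordinate reference whose SNP positions
  have been N-masked, so neither allele enjoys a mapping advantage;
* interspecies SNPs are only meaningful inside regions where the two
  genomes are one-to-one homologous; everything outside is excluded;
* the VCF orientation is fixed by contract: REF is the cattle allele and
  ALT is the yak allele.

# The model, stage by stage

## Reference scaffold

`extractHomologyBlocks()` filters whole-genome alignment records (PAF) by
block length and mapping quality, optionally restricts to a chromosome set
(autosomes in the intended design), and merges the retained target
intervals per chromosome. Merging on primary coordinates is our resolution
of conflicting overlapping alignments; the mate coordinates of a merged
block are taken from its longest contributing record, and are carried as
annotation only — nothing downstream depends on them. Defaults are
`minBlockLen = 1000` bp and `minMapq = 0`, because assembly-preset
aligners emit mapq 60 or 0 and the block-length filter does the real work;
both are exposed.

The pipeline *masks* SNP sites (`maskSnps()`) and *ignores* alignments
outside retained genes rather than excising non-homologous sequence.
Excision would change coordinates relative to the standard cattle
annotation; keeping coordinates stable is behaviourally equivalent for
counting, because reads overlapping no retained gene are discarded either
way. A gene is retained when its genomic span lies wholly inside
homologous sequence (`minOverlapFraction = 1`), the strict reading of
"genes located within homologous regions"; the threshold is exposed for
sensitivity analysis.

## Per-read origin calls

`snpObservations()` walks each primary alignment's CIGAR. A SNP is
observed only when its reference position is consumed by an aligned
(M/=/X) operation; positions under deletions or introns (D/N) yield
nothing, insertions and clips consume read only, and hard-clipped bases
are simply unobservable. Each observed base votes CATTLE, YAK, or OTHER
(base equals neither allele — a sequencing error; counted, never
decisive). `callReadOrigins()` applies the majority ("mode") rule.

Ties are called AMBIGUOUS and excluded from informative counts *and* from
proportional redistribution. This is a deliberate design choice: a
tied-vote read carries conflicting evidence about its origin, unlike a
SNP-free read which carries none. Discarding rather than guessing is the
conservative reading of the mode rule, which by itself does not define
tie behaviour.

Reads attach to the gene sharing most aligned *exonic* bases (full-length
cDNA reads are spliced), with deterministic tie-breaks: larger whole-span
overlap, then lexicographic gene ID.

## Quantification

For a gene with informative counts $c$ (cattle) and $y$ (yak), $i = c+y
> 0$, and $u$ SNP-free reads, redistribution gives final counts

$$c' = c\,(1 + u/i), \qquad y' = y\,(1 + u/i),$$

which preserves the informative ratio exactly and conserves
$c' + y' = c + y + u$. Genes with $i = 0$ keep their SNP-free reads as
`unassigned` and are excluded from testing — we use no library-wide
fallback ratio because there is no per-gene evidence to support one.
Redistribution is gene-local: "proportionally assigned according to other
known assignments" is read as the assignments of the same gene.

Expression is reported as counts per million mapped reads (CPM) with the
sample's total primary mapped reads as denominator (gene-assigned or
not). Fractional final counts are kept for CPM; integerization happens
only at the testing boundary. A gene is testable in a sample with at
least `minReads = 3` non-ambiguous reads ("more than 2 mapped transcript
sequences"). Replicate agreement is summarized by pairwise Pearson
correlation on `log2(CPM + 1)` over genes kept in both samples (raw CPM
by flag), and sequencing saturation by a rarefaction curve of distinct
genes detected under subsampling without replacement.

## ADE testing

Fisher's exact test needs a 2x2 table, and the source analysis does not
state one. We test the gene's allelic counts against the *rest of the
library's* allelic counts:

$$\begin{pmatrix} c' & y' \\ C - c' & Y - y' \end{pmatrix}$$

with $C, Y$ the sample's summed (rounded) final counts. This controls for
genome-wide assignment imbalance — if the whole library leans 52:48, a
gene leaning 52:48 is not evidence of ADE. A "test against 50:50 via
Fisher machinery" alternative is ill-formed (it fabricates a second
margin), so the sensitivity alternative offered behind
`method = "binomial"` is an honest exact binomial test against 0.5.

`fisherExactTwoSided()` implements the two-sided probability method: the
sum of hypergeometric probabilities of all tables with the observed
margins whose probability is at most that of the observed table, with a
relative tolerance of 1e-7 on the comparison (the convention of standard
implementations, protecting ties against floating-point rounding). The
test suite verifies it against full enumeration from log-binomial
coefficients for every table with total at most 60, and against
`stats::fisher.test()`.

A gene is significant when fold change (max/min of the two allele counts,
infinite for monoallelic genes) exceeds 2 *and* p < 0.05, matching the
per-gene rule of the source design; no multiple-testing correction drives
the flag, though a Benjamini-Hochberg column is emitted for users.
Counts entering the test are rounded half away from zero — Fisher needs
integers, and rounding at the last boundary minimizes distortion.

## Cross-replicate classification

A gene shows *ubiquitous* ADE in a tissue when it was tested (post-filter)
in **all** animals of that tissue and significant in every one — a gene
untested in even one animal cannot be ubiquitous. This is the strict
reading of "among the five biological replications"; the alternative
(significant in all *tested* animals) would promote weakly covered genes.
Ubiquitous genes carry a direction class: YAK or CATTLE when all their
significant per-sample results agree, VARIABLE otherwise; the three
classes partition the ubiquitous set. Tissue patterns (LUNG_ONLY,
LIVER_ONLY, BOTH, NONE) follow from the two ubiquity flags.

# The simulator

The generator emulates the study conditions end to end so that every
pipeline stage runs with no external data:

* two parental haplotypes diverged at `snpRate = 0.012` per bp inside
  homologous tracts — the estimated genomic heterozygosity of cattle x
  yak hybrids;
* one species-specific tract per chromosome totalling
  `nonHomologousFraction = 0.06` of the genome (fully divergent sequence,
  no SNP records), mirroring the ~94% autosomal homology of the real
  genomes; a couple of genes are placed inside it to exercise the
  exclusion path;
* spliced gene models (1-5 exons, log-normal transcript length around
  1.5 kb), five animals x lung and liver;
* full-length reads copied from the true haplotype's spliced transcript
  and corrupted at a 5% total per-base error rate (3.5% substitutions
  uniform over the three alternatives; 0.75% insertions and 0.75%
  deletions with geometric lengths, p = 0.7). Deletions are never placed
  over a SNP column — they shift the CIGAR instead — which keeps the
  vote-error model exactly enumerable. Reads are emitted pre-aligned
  with their true CIGAR (introns as N operations): mapping itself is
  standard tooling outside this package's scope, and truth alignments
  make every downstream accuracy claim checkable. 5'-truncation is
  available but off by default, since full-length non-chimeric selection
  retains complete molecules.

Where the study design fixes no value we chose once, on field-realistic
grounds, and did not revisit: log-normal reads per gene (meanlog
log(30), sdlog 0.8 — tens of reads per gene per sample at desk scale),
`adeFraction = 0.1` with true fold changes drawn from {2, 4, 8} (fraction
$fc/(1+fc)$ toward a Bernoulli(0.5) direction), and a quarter of ADE
genes imbalanced in one tissue only.

The simulator has two layers sharing one statistical model. The
*read-level* layer above exercises parsing, CIGAR walking, voting and
counting end to end. The *counts-level* layer
(`simulateAlleleCounts()`: Poisson depth, binomial allele split, a fixed
`uninformativeRate = 0.2` of SNP-free reads) draws per-gene tallies
directly, which makes cohorts of thousands of genes affordable for
statistical validation (type-I error at 2,000 null genes, power at 600
genes per depth, estimator bias at 800 genes). What passing these checks
shows is that the *method* behaves as designed under its own model; the
simulator does not emulate ONT-specific error profiles, isoform
diversity, PCR duplicates, or biological replicate variation in
expression level, so it cannot certify performance on real flowcell
data.

# Numerical choices and degenerate inputs

* Internal coordinates are 1-based closed (`IRanges`/`GRanges`
  convention); PAF/BED (0-based half-open) and VCF/SAM/GFF3 (1-based) are
  converted only at the format boundary, so off-by-one drift cannot
  accumulate between modules.
* Redistribution conservation is exact to 1e-9 and enforced by the
  `AlleleExpressionSet` validity method.
* Ties in gene attachment and in vote counts resolve deterministically
  (documented above); all seeded functions restore the caller's RNG
  state, and the pipeline is byte-deterministic under a fixed seed.
* Degenerate inputs fail loudly: empty homology after filtering, SNPs
  outside the genome, zero mapped reads for CPM, both-zero fold-change
  inputs, subsampling depths beyond the read count.
* Problem sizes in the tests and acceptance script (default design: 2
  chromosomes x 300 kb, 100 genes, 10 samples, roughly 40k reads;
  statistical cohorts of 600-2,000 genes at the counts level) were
  chosen as the smallest sizes at which the statistical assertions have
  useful resolution.

# Known limitations

* Proportional redistribution feeds the scaled-up (informative +
  SNP-free) counts into the exact test, so the effective sample size
  slightly exceeds the informative evidence — a mild pseudo-replication
  that can push the realized type-I rate toward (rather than below) the
  nominal level when many reads are SNP-free. This is inherent to
  counting redistributed transcripts and is shared by the analysis the
  package reproduces; at the ~1.2% interspecies divergence most
  full-length reads are informative and the effect is small.
* The two-species orientation (REF = cattle) is a contract, not inferred.
* Secondary/supplementary alignments are read but never counted; only
  primary alignments contribute.
* No isoform-level quantification, no normalization beyond CPM, no
  GO/KEGG enrichment, no cis/trans decomposition, no sex chromosomes or
  imprinting logic.
* The library-background 2x2 table is a documented choice among
  defensible alternatives; the binomial mode exists precisely so users
  can check sensitivity to it.
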