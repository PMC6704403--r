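---
title: "Identifying intergenic lncRNAs: models, sieves and specificity calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying intergenic lncRNAs: models, sieves and specificity calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsieve)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts longer than 200 nt that lack
long open reading frames. De-novo transcriptome assemblies of tissues such
as the mouse olfactory organs — the main olfactory epithelium (MOE) and the
vomeronasal organ (VNO) — contain tens of thousands of transcripts absent
from reference annotations, a mixture of genuine novel lncRNAs, mRNA
fragments (in particular stray UTR pieces emitted by assemblers), and
transcripts of structural non-coding genes. `lncsieve` implements a
three-part discovery pipeline for *intergenic* lncRNAs in such assemblies:

1. a **coding-potential classifier**: a gradient-boosted decision-tree
   ensemble over 21 intrinsic sequence features;
2. a **genomic-overlap sieve** that removes short transcripts, transcripts
   the classifier calls coding, UTR fragments (via "artificial coding
   transcripts"), and transcripts sharing loci with protein-coding genes,
   pseudogenes, or rRNA/tRNA/snoRNA/miRNA/ribozyme genes;
3. an **SPM tissue-specificity module** that normalizes TPM abundances,
   scores each transcript's specificity per tissue, and calls transcripts
   preferentially expressed in one organ, the other, or both.

A synthetic-data module generates sequence corpora, toy genome annotations
and expression matrices with machine-readable ground truth, so every stage
is testable without downloads.

## The classifier and its features

Each transcript is represented by a fixed, ordered 21-feature vector
(`feature_names()`): length and composition (`log10_length`, `gc_content`,
mononucleotide frequencies, CpG observed/expected, trinucleotide Shannon
entropy), ORF structure (longest and second-longest ORF length, ORF
coverage and length ratio, count of ORFs of at least 75 nt, codon-position
GC of the longest ORF, stop-codon density pooled over the three forward
frames), the Fickett TESTCODE statistic (full sequence and longest ORF) and
hexamer usage bias (in-frame over the longest ORF, and sliding over the
full sequence). The registry is pluggable: the classifier records the
feature order in its model file and refuses mismatched matrices, so an
alternative feature set can be swapped in without touching the training
code. This particular registry is the package's own choice of widely used
sequence-intrinsic coding-potential features; it deliberately contains no
homology or conservation features, keeping the model applicable to
unannotated transcripts.

ORFs require an `ATG` and an in-frame stop and are scanned on the forward
strand only, because assembled transcripts are already oriented; ORFs
running off the transcript end are not counted. A `both_strands` option
exists for strand-unknown transcripts. The 75 nt floor for `orf_count` is a
conventional noise threshold (25 codons). `N` bases are excluded from all
composition denominators, and hexamers containing `N` are skipped.

The hexamer table is trained as a pseudocount-smoothed log-likelihood ratio
of in-frame hexamer frequencies in a coding corpus (counted over each
sequence's longest ORF) versus a non-coding corpus; the default pseudocount
is 1.0. The Fickett statistic uses the published position/content lookup
tables verbatim; an all-`N` sequence receives the score implied by zero
counts and a warning.

The ensemble is XGBoost with `binary:logistic` loss, 500 trees, learning
rate 0.1, maximum depth 6 and subsample 1.0. Only the tree count is a
substantive modelling commitment; the remaining hyperparameters are
reasonable defaults, recorded in every saved model so experiments are
reproducible. lncRNA is the positive class, the decision threshold is 0.5,
and training is single-threaded by default so that a fixed seed gives
bit-identical models; multi-threading is available at the cost of that
guarantee.

Train/test splits are stratified: per-class test counts are
`round(class_n * fraction)`, reconciled to `round(n * fraction)` by a
largest-remainder rule. Evaluation reports the confusion matrix and
derived rates plus AUROC and AUPRC. AUROC is the Wilcoxon rank statistic —
exactly the fraction of correctly ordered (positive, negative) pairs with
0.5 credit for ties — and AUPRC is the rectangular step integral of the
precision-recall curve at every distinct score. The step (not trapezoidal)
integral is a deliberate, documented choice: the two differ in the third
decimal and silently mixing them makes results irreproducible.

## The genomic-overlap sieve

Assemblers emit UTR fragments as free-standing transcripts, and these are
easily misclassified as non-coding because UTRs are. The sieve therefore
builds **artificial coding transcripts**: each annotated CDS's exonic
intervals, with the outer boundaries extended in genomic coordinates by a
representative 5' UTR length upstream of the CDS start and 3' UTR length
downstream of the CDS end (strand-aware, clamped at the chromosome start),
merged into an unstranded mask. The packaged defaults are 160 nt (5') and
792 nt (3'), the upper quartiles of annotated mouse UTR length
distributions; `utr_extension_lengths()` recomputes both quartiles from
any annotation. The quartile uses closest-ranks linear interpolation
(`quantile` type 6), which reproduces the worked reference value
Q3({100,200,300,400}) = 375; the method is a configurable argument, not a
hard-coded constant. Extensions are applied from the genomic CDS span
endpoints rather than walked along spliced exon chains — a documented
approximation that errs on the side of a larger exclusion zone across
introns.

Sieves are applied in a fixed order, and a removed candidate carries
exactly one reason (the first failing sieve):

1. exonic length must exceed 200 nt (strictly: a 201 nt candidate passes,
   a 200 nt candidate does not);
2. the classifier's lncRNA probability must reach the threshold;
3. genomic overlap: single-exon candidates are removed on *any* overlap
   with the artificial-coding mask, multi-exon candidates only when the
   overlap exceeds 25% of their exonic length (a fraction of exactly 0.25
   passes); candidates surviving that are removed on any exon overlap with
   rRNA/tRNA/snoRNA/miRNA/ribozyme gene exons.

Two points were genuinely open and are resolved here as package decisions:
pseudogene exons are pooled with the artificial-coding mask and filtered
under the same one-exon/25% rule (they are coding-derived sequence, so the
UTR-fragment logic applies), and overlap is strand-agnostic by default (a
`stranded` flag restricts to sense overlap), following common intergenic
lncRNA practice of excluding sense and antisense overlap alike.

Coordinates are held as Bioconductor `GRanges` (1-based, closed) end to
end, the convention of the R genomics stack and of GTF itself, so GTF I/O
involves no coordinate shifting. `nearest_feature_distance()` provides the
gap-distance utility used for audits such as checking that no enhancer
lies within 5 kb of a candidate locus.

## Expression normalization and SPM

Raw transcript-level TPM matrices are normalized by median-of-ratios size
factors (each sample's factor is the median ratio to the per-transcript
geometric mean, over transcripts positive in all samples), gene-level
abundance is the sum of isoform abundances, replicates are collapsed to
tissue means by arithmetic average, and values are transformed as
`log2(x + 1)`. The collapse-then-score order (SPM on tissue means rather
than per sample) and the arithmetic-mean collapse are configuration-level
decisions recorded in run metadata.

For a transcript with tissue vector `x`, the specificity measure is the
cosine between `x` and each tissue's unit vector:

> SPM_i = x_i / sqrt(sum_j x_j^2)

so squared SPMs sum to 1 for any nonzero vector, SPM is invariant to
positive rescaling, and a transcript expressed equally in exactly two
tissues has SPM = 1/sqrt(2) ≈ 0.707 in both. The cosine form is the one
consistent with the packaged reference panel of 21 validated olfactory
lncRNAs: per-row squared organ SPMs sum to at most 1 (e.g. 0.79² + 0.60² ≈
0.98), and the two-tissue value 0.707 clears the joint cut-off below.

Preference calls use cut-offs chosen from marker genes of the olfactory
organs (*Trpc2* for VNO, *Cnga2* for MOE, *Omp* for both): a transcript is
`VNO_pref` when SPM_VNO ≥ 0.9, else `MOE_pref` when SPM_MOE ≥ 0.9, else
`VNO+MOE_pref` when min(SPM_VNO, SPM_MOE) ≥ 0.55, else `none`. The *min*
combination for the joint group is this package's operationalization (the
cut-off value itself is standard; the combination rule is not specified
anywhere authoritative). Disjointness of the three groups is guaranteed
analytically: SPM_a² + SPM_b² ≤ 1 while 0.9² + 0.55² = 1.1125 > 1, so no
profile can satisfy a single-organ rule and the joint rule at once.
Within each preference group, transcripts are split into `high`
(above the third abundance quartile), `low` (below the first) and
`medium` (inclusive interquartile range), with quartiles computed within
the group on the organ-mean normalized TPM. Single cells are called
OMP-positive when the absolute abundance of the *Omp* transcript exceeds
100 (strict).

Differential expression, pseudotime reconstruction and smoothing are out
of scope — those belong to dedicated tools — but
`intersect_candidates()` supplies the order-stable set intersection used
to combine externally produced lists (e.g. adult-enriched transcripts with
OMP-positive-enriched transcripts).

## What the synthetic data emulates — and what it does not

`make_coding_corpus()` emits sequences `5'UTR + ATG + (>=100 biased
codons) + stop + 3'UTR` (longest ORF ≥ 303 nt by construction), with
G/C-ending codons favoured 3:1 within each amino-acid group — enough bias
to give coding sequence a distinct hexamer profile without tying the
generator to one genome. `make_noncoding_corpus()` rejection-samples
AT-leaning random sequences (200–2000 nt) until the longest ORF is below
150 nt. These corpora make the classification task *cleanly separable by
design*: held-out accuracy approaching 1.0 on them demonstrates that the
feature extraction, training and evaluation machinery is correct, not that
real GENCODE-scale discrimination reaches that accuracy. Real transcripts
carry intermediate ORFs, pseudogene-derived sequence and lineage-specific
composition that the generator does not emulate.

`make_toy_annotation()` plants ten candidates on a 2 × 100 kb toy genome
covering every sieve and both boundary cases (a 201 nt keeper, a 200 nt
reject, an exactly-30% multi-exon overlap, and optionally an exactly-20%
one), and emits the expected outcome of each candidate so tests never
hand-code expectations. `make_expression_matrix()` plants five patterns
(organ-A-only, organ-B-only, shared, broad, silent) over 8 tissues × 3
replicates with multiplicative lognormal noise (σ on the natural-log
scale, default 0.1); off-target expression is exactly zero, so pure
patterns recover their group essentially always and the recovery statistic
mainly stresses the shared/broad boundary.

## Numerical choices and degenerate inputs

* ORF ties (equal length) are broken by the smaller start offset.
* An all-`N` sequence yields no ORFs (not an error); Fickett falls back to
  its zero-count score with a warning; hexamer scores of regions shorter
  than 6 nt are 0, flagged.
* Features are guaranteed finite; a non-finite feature aborts training
  with the offending transcript named.
* A candidate on a chromosome absent from the annotation passes the
  overlap stage vacuously.
* Single-class evaluation reports confusion counts but `NA` AUROC/AUPRC,
  with a warning.
* Size-factor normalization requires at least one transcript positive in
  every sample and says so when none exists.
* All generators and the pipeline are deterministic given (config, seed);
  `run.json` contains no timestamps, so identical runs are byte-identical.

## Problem sizes used by the packaged checks

The test-suite and the acceptance script exercise: the default synthetic
corpus of 2,000 + 2,000 sequences with an 80/20 stratified split and a
500-tree model; 25 random evaluation fixtures of up to 500 rows against
the ordered-pair AUROC oracle plus 1,000 random confusion tables; 200
random interval layouts against a per-base bitmap oracle on a 100 kb toy
chromosome; 10,000 random SPM profiles; the 21-row validated panel; 1,000
planted-specificity transcripts at σ = 0.1; and a double pipeline run on a
small end-to-end fixture (60 + 60 training sequences, 60 trees) for
byte-identity. These sizes were chosen to make every check statistically
meaningful while keeping a full run inside a couple of minutes on one core.

## Known limitations

* The 21-feature registry is a documented stand-in for any particular
  published feature list; swapping registries requires retraining.
* UTR extension in genomic space can mask intronic sequence between the
  CDS and a spliced UTR exon; walking the spliced chain would be tighter.
* The joint-preference rule (min of the two organ SPMs) is one of several
  defensible operationalizations; a merged-pseudo-tissue variant would
  give slightly different joint calls near the cut-off.
* The classifier is sequence-intrinsic; it cannot use conservation or
  homology evidence, by design.
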