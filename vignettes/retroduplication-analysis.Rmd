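---
title: "Detecting and characterising retroduplication variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising retroduplication variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrodup)
```

## The problem

Retroposition copies a spliced mRNA back into the genome, producing an
intronless *retrocopy* of its multi-exon parental gene. Because the copy
carries no essential function in most cases, individual genomes gain and
lose retrocopies freely: a *retroduplication variation* (RDV) is a
polymorphism in which a retrocopy is present in some genomes and absent
from others. Two processes generate RDVs — a recent retroposition that has
not fixed, and a deletion of an old, possibly ancestral retrocopy. Telling
them apart needs cross-species evidence: a retrocopy whose orthologue sits
at the corresponding position in another primate genome existed before the
human lineage split, so its polymorphic absence must be a deletion.

`retrodup` implements the full analysis chain at desk scale: retrocopy
calling from translated alignments, deletion-based RDV detection with
per-population allele frequencies, origin-lineage dating on a eutherian
species tree, discovery of retrocopies absent from the reference genome by
assembling unmapped reads, expression flagging and negative-binomial
differential expression, and qPCR quantification. A seed-deterministic
generator simulates every input with known truth.

## Retrocopy calling

`translated_align()` aligns a parental protein to genomic DNA across all
six translated frames (local alignment, BLOSUM62, gap open 11 / extend 1).
The single optimal local alignment has a failure mode specific to this
application: when a candidate locus retains an intron, the optimal
alignment will often *bridge* the translated intron between two strong exon
anchors, because the bridge costs less than the second exon scores. Bridged
junk inflates coverage and makes retained junctions look collapsed. The
aligner therefore post-processes the optimal alignment with the X-drop rule
used by seed-and-extend aligners (segments end where the running score
falls 25 below its running maximum), keeps the best-scoring segment, and
erodes segment ends until they begin with a 10-column window scoring at
least 12 — so a chance-positive run of junk glued to an end cannot pose as
aligned flank. In measurements during development, X-drop splitting plus
the junction geometry below took intron-retaining false acceptances from
6/15 to 0/60 without costing recall.

`infer_lost_introns()` scores each parental exon junction. With the
junction at CDS nucleotide `c`, the last codon fully before it is
`rA = floor(c/3)` and the first codon fully after it is `rA + 1` (junction
on a codon boundary) or `rA + 2` (straddling codon skipped, 3 bp expected
between the flanking codons). A junction counts as *lost* when the
alignment covers 10 aa immediately on both sides and the genomic distance
between the flanking codons exceeds the in-frame expectation by at most
30 bp. A retained intron either leaves a gap of its full length (>= 60 bp
here) or an unalignable far side, so it never counts. The 10 aa / 30 bp
defaults are configurable surrogates for the chained-alignment logic of
production retrocopy annotation pipelines.

`classify_retrocopy()` applies the acceptance rule — genomic span
>= 150 bp, identity > 50%, protein coverage > 50% (both strict), >= 2
introns lost — and reports the first failed criterion on rejection.
Identity is defined as matches over gap-excluded aligned columns; the
denominator is a package choice, documented because conventions differ.
`conserved_orf()` checks frame preservation (every gap run in the global
retrocopy-vs-CDS alignment divisible by 3) and the absence of internal stop
codons in the parent-anchored translation.

## RDV detection

`overlap_deletions()` pairs deletion variants with retrocopy loci when the
interval intersection removes at least 100 bp of the retrocopy — an
absolute length, not a fraction, following the wording of the rule it
implements. `allele_frequency()` divides deletion alleles by non-missing
alleles within each population; missing genotypes leave both numerator and
denominator (how missing calls were handled upstream is not documented for
the original data, so the package states its own convention).
`categorize_spread()` bins the number of affected populations into
`population_specific / 2-5 / 6-8 / 9-13 / all`, the reporting bins used for
14 populations; the 9-13 bin is kept explicit even though real datasets may
leave it empty.

## Origin lineages and ancestrality

`map_orthologs()` projects retrocopy loci through shared alignment blocks
onto block columns and joins two loci from different species when each
covers at least 50% of the other's projected extent (reciprocal overlap on
block-projected extents, not raw genomic lengths — the blocks are where
cross-species correspondence is defined). Groups are connected components
of this relation, so grouping is symmetric and transitively closed.

`assign_origin_lineage()` requires presence in at least two species — a
single observation cannot distinguish a lineage-specific insertion from
block noise, and independent retroposition of the same gene into the same
aligned position is vanishingly unlikely. The origin is the smallest named
clade containing the MRCA of the presence set: with the default
`eutherian_tree()` (14 species), {human, chimpanzee} resolves to
Hominidae, while {mouse, rat} resolves to Murinae rather than Glires.
`is_ancestral()` flags human retrocopies with an orthologue in chimpanzee,
gorilla, orangutan, macaque or marmoset; presence only outside
Euarchontoglires is flagged separately as deep conservation
(`is_deep_conserved()`), because a retrocopy shared with dog but no primate
is old yet fails the primate rule.

## Discovery of retrocopies absent from the reference

Reads that fail to map to a reference genome are the footprint of sequence
the reference lacks. `assemble_contigs()` is a deterministic greedy overlap
assembler (exact suffix-prefix overlaps >= 31 bp, both strands, reads
deduplicated and sorted first); contigs under 500 bp are discarded.
`cluster_contigs()` groups contigs across individuals at 95% identity over
70% of the shorter sequence (the coverage side of that rule is applied to
the shorter sequence; conventions vary and the choice is configurable), and
`consensus()` takes a per-column majority vote against the cluster
representative, ties resolving to the representative. `filter_sequences()`
removes consensi resembling contaminants or alternative-assembly/patch
sequence at >= 90% identity over >= 50% of the consensus; these two
thresholds are package defaults, stated here because the original
similarity cut-offs are not documented.

`locate_deletion_site()` anchors the outgroup flanks of a located contig in
the reference by unique exact 40-bp seeds placed 200 bp out, then extends
homology base by base toward the retrocopy until reference and outgroup
first disagree. The deletion site is the reference interval strictly
between the two extension endpoints: a clean deletion collapses to a 1-bp
insertion-point interval, while residual non-homologous sequence between
the anchors yields an interval of that residual's length. Ambiguous seeds
(flank duplicated in the reference) and inconsistent anchors return a
no-call with a reason code. Anchoring is exact-match based: it assumes the
outgroup flanks are essentially identical to the reference outside the
deletion, which holds for the synthetic data and for close outgroups but
will need alignment-based anchoring for diverged genome pairs — a known
limitation.

## Expression

`rpm_normalize()` and `flag_expressed()` implement the expressed-retrocopy
rule: at least 1 RPM (inclusive) in at least one sample. Count matrices are
accepted as pre-filtered input — the unique/concordant MAPQ >= 50 alignment
filter is an ingestion contract asserted by the caller, since read
alignment is out of scope.

`nb_differential_test()` is a transparent negative-binomial two-group test:
median-of-ratios size factors, group means `q_g = sum(k) / sum(s)`, pooled
method-of-moments dispersion (floored at 1e-8), and a Wald statistic on
`log(q2/q1)` referred to a t distribution with `n - 2` degrees of freedom —
the residual degrees of freedom of the dispersion estimate. The t reference
is the package's calibration choice: with a normal reference the raw test
rejects ~6.5-7% of null loci at the 5% level at 10-vs-10 samples, while the
t reference sits at ~5%. The vignette's companion test suite verifies type-I
error within [0.035, 0.065] on a 2,000-locus null simulation and >= 80%
sensitivity for planted 4-fold changes under the full calling rule
(`call_differential()`: fold change >= 2 in either direction, BH adjusted
p < 0.05, after excluding loci with mean raw count below 50). Fold changes
are reported on the linear scale with direction preserved (0.43 means
down-regulation passing the 2-fold rule). The 2-fold rule is applied to the
raw fold change; no shrinkage is used.

## qPCR quantification

`qpcr_relative_quantity()` is the exact delta-Ct form
`2^-(Ct_target - Ct_ref) * 1e6`, with targets above the Ct cut-off (32 by
default) reported as not expressed. `estimate_efficiency()` implements a
window-of-linearity fit: baseline = mean of the first three cycles, and the
best window (by R-squared of the log-linear fit) among windows above the
baseline noise floor. Two refinements matter numerically. First, when the
curve has saturated, the logistic plateau compresses the apparent slope by
`P/(P+x)`; the estimator inverts the saturation (`x = s*P/(P-s)`) before
fitting, which cut the maximum recovery error on noisy curves from ~0.05-0.13
to under 0.03. Non-saturated curves are fitted uncorrected, so a pure
exponential recovers its efficiency exactly. Second, the window is 6 cycles
rather than the 4 often quoted for window-of-linearity methods: 4-point
windows leave too much slope variance under realistic optical noise.
Efficiency is reported to 1e-6 and flagged acceptable only strictly above
1.8. `fisher_exact_2x2()` computes the two-sided exact p by the
point-probability rule (all tables with probability <= the observed one,
ties within 1e-7 relative tolerance), the common two-sided convention,
stated explicitly because two-sided definitions vary.

## What the synthetic data does and does not emulate

The generator plants: multi-exon fully-coding genes with GT..AG introns on
random genomes (both strands); retrocopies as mRNAs with the 3'-most `n`
introns spliced out, point-mutated at a uniform per-site rate (no indels by
default — frameshift and stop tests construct their own lesions), 5'
truncation optional; Hardy-Weinberg diploid deletion genotypes at planted
per-population frequencies; ortholog presence by per-branch loss on a fixed
14-species eutherian tree with one ungapped alignment block per surviving
retrocopy and sub-threshold decoy loci as negatives; NB counts with planted
log2 fold changes; uniformly-placed stranded error-bearing reads; and
logistic-clipped exponential qPCR curves (noise default 0.001 fluorescence
units against a plateau of 10, a deliberately clean optical noise level —
window-of-linearity estimation assumes an uncorrupted exponential phase).

Real data differ in ways the simulations do not capture: genomes have
repeats and GC structure (the assembler's exact-overlap greedy strategy
would misassemble repetitive loci), alignment blocks are gapped, fragmented
and sometimes wrong, deletion breakpoints are imprecise and multi-allelic,
RNA-seq counts share library artefacts that size factors only partly
remove, and unmapped-read pools contain far more contamination than two
decoy databases. Passing the synthetic suites therefore certifies the
correctness of the rules and arithmetic, not performance on genome-scale
inputs.

When losses prune an ortholog group, the planted origin node is not
identifiable from presence data alone (the MRCA of the survivors is lower);
the generator's truth table therefore records both the planted node and the
identifiable origin, and recovery is scored against the latter — they
coincide exactly in loss-free simulations.

## Problem sizes and orchestration

`run_pipeline()` chains the stages (simulate, annotate, rdv, conserve,
discover, express, stats) over a working directory with one master seed and
writes a manifest of parameters, outputs and MD5 hashes; reruns with the
same configuration are identical for all deterministic stages. The bundled
configuration uses deliberately small problem sizes — a 50 kb genome with 6
genes, 4 planted retrocopies, 140 diploid individuals in 14 populations, 40
ortholog retrocopies, a 400-locus count matrix, 2 novel retrocopies in 2
individuals at 20x coverage — chosen so a full run completes in well under
five minutes on one core while still exercising every rule; the test suite
uses larger sizes (up to 500 retrocopies, 2,000 loci, 1,400 diploids) where
a property needs them.
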