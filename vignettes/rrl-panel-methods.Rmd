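---
title: "From restriction digest to relatedness: the RRLpanel methods"
author: "RRLpanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From restriction digest to relatedness: the RRLpanel methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RRLpanel)
```

RRLpanel implements the computational backbone of a reduced-representation
SNP-discovery workflow for wildlife genetics: sizing a
reduced-representation library (RRL) from an in-silico restriction digest,
filtering putative SNPs from consensus-stack catalogs, characterizing the
surviving markers, selecting a genotyping panel, and using that panel to
infer pairwise relatedness and exclude parent-offspring relationships.
Every stage can be driven by the package's own seeded simulators, so the
full pipeline runs — and is tested — without any external sequencing data.
This vignette explains the models behind each stage, the defaults and why
they were chosen, and what the synthetic data do and do not demonstrate.

## RRL design: the exponential fragment-length model

A restriction enzyme cutting at a k-bp recognition site fragments a genome
of size $G$ into pieces whose lengths, for an effectively random genome,
are approximately exponential with mean $d$ (the observed mean digest
fragment length; about 3,100 bp for BglII on a mammalian genome). The
expected number of fragments recovered by size selection to $[a, b]$ is

$$D = \frac{G}{d}\left(e^{-a/d} - e^{-b/d}\right),$$

implemented in `expectedFragmentCount()`. With $d = 3100$, $G = 2.4$ Gbp
and a 100-700 bp window this gives $D = 131{,}910$ fragments. Sequencing
both ends of each fragment with reads of length $L$ targets $2LD$ bases,
so the genome fraction sampled is $2LD/G$ (`designSummary()` reports it as
a percent, 2 decimals) and the expected per-individual read depth is
$Y/(2LD)$ for a per-individual sequencing yield of $Y$ bases.

The per-individual yield default is $Y = 1$ Gbp — one 2x100 bp HiSeq lane
(about 10 Gbp) split across ten barcoded samples. With that yield the
calculator reproduces both the prospective design depth (38X at
$D = 131{,}910$, $G = 2.4$ Gbp) and the realized draft-genome digest depth
(53X at $D = 93{,}678$, $G = 2.28$ Gbp) after integer rounding, and the
two coverage figures (1.10% and 0.82%).

`digestSequence()` matches the recognition pattern exactly and
case-insensitively (via `Biostrings::matchPattern` with `fixed = TRUE`,
so ambiguity codes such as N never match — the conservative choice for
draft assemblies), cuts at `occurrence_start + cutOffset`, and keeps
terminal fragments, so per scaffold the fragment lengths always sum to the
scaffold length. Size-selection bounds are inclusive: "between 100 and
700 bp" is read as $[100, 700]$, configurable through `sizeSelect()`.
`percentDiff()` compares a prospective estimate against the realized value
as $(\mathrm{est}-\mathrm{act})/\mathrm{est}\times 100$ — the estimate is
the reference — which matches the published design-table convention for
the genome-size, fragment-count, fragment-size and coverage rows. The
depth row of that table was evidently computed against the realized value
instead; the package does not reproduce that one inconsistent cell.

Coordinates are 1-based inclusive inside R (`GRanges`, the Bioconductor
convention) and 0-based half-open on disk (BED), with the convention
stated in the file header.

## The SNP filter cascade

`runFilterPipeline()` applies six criteria in sequence to consensus-stack
records (nominally 100-nt consensus reads with per-individual genotype
calls) and their genome alignments:

1. **single SNP** per read — multi-SNP reads are likely sequencing error
   or hypervariable sequence;
2. **position**: the SNP must lie at least 20 nt from the 5' end and
   35 nt from the 3' end (0-based positions 20-64 on a 100-nt read), so
   assay-design flanks survive on both sides. The bounds are read as
   inclusive ("at least");
3. **individuals and classes**: at least 3 individuals called, and all
   three genotype classes (aa, ab, bb) observed;
4. **alignment**: exactly one genome hit at $\geq 99\%$ identity with no
   gap opens (one mismatch on a 100-nt read — the SNP itself — still
   passes). Identity is taken from the reported blast-tabular `pident`
   field rather than recomputed from mismatch counts;
5. **scaffold uniqueness**: every SNP on a scaffold carrying a second
   surviving SNP is dropped, on both sides, to minimize physical linkage;
6. **homopolymer flanks**: a run of one nucleotide longer than 5 within
   20 nt of the SNP on either side fails the record.

The first three criteria each examine a different facet of a record, so
they commute; the pipeline applies them sequentially and the tests assert
order-independence. Criteria 5's published counterpart was a manual
screen; here it is automated as a configurable run-length rule
(`maxHomopolymerRun = 5`, `flankScanLen = 20`), and the companion manual
check for "adequate allelic representation" is subsumed by criterion 3's
requirement that the minor genotype class be observed. All thresholds
live in `filterConfig()`.

The published intermediate survivor counts of the original study
(4,612 to 1,162 to 150) depend on its raw sequencing data and are not
reproducible on synthetic input; what the package tests instead is exact
recovery of planted outcomes: `simStackFixtures()` builds records in
labeled strata, each violating exactly one criterion, and the pipeline
must reject each stratum for exactly its planted reason, with
monotonically non-increasing survivor counts.

`findVariableSites()` is the small Sanger-side utility: given pre-aligned
equal-length sequences it returns the columns with two or more distinct
non-gap, non-N characters — the screen used to pull mtDNA SNPs out of
amplicon alignments.

## Panel statistics

`locusStats()` pools allele counts from diploid calls (2 alleles each)
and haploid/hemizygous calls (1 each); observed heterozygosity uses
diploid calls only; expected heterozygosity is $2p(1-p)$. Missing calls
are excluded locus-wise. Subpopulation-stratified statistics are obtained
by filtering on the panel's `group` column; no multiple-testing
correction is applied to HWE p-values.

`hweExact()` is the conditional exact test: given the observed allele
counts, the probability of each compatible heterozygote count follows the
standard recurrence, and the p-value sums the probabilities of all
configurations no more probable than the observed one (ties included,
with a $1+10^{-12}$ relative guard against floating-point ties). The test
suite checks it against an independent closed-form log-factorial
enumeration. Because the null distribution is discrete the test is
conservative; under simulated equilibrium genotypes ($n = 50$,
MAF 0.3) the rejection rate at $\alpha = 0.05$ sits near 0.03.

`ldDprime()` estimates two-locus haplotype frequencies from unphased
diploid genotypes by EM: only double heterozygotes are phase-ambiguous,
and the E step splits them between the cis and trans configurations in
proportion to the current haplotype-frequency products. Initialization is
at linkage equilibrium; iteration stops when the largest haplotype-
frequency change is below $10^{-9}$ (or 1000 iterations). Then
$D = p_{AB} - p_A p_B$ and $D' = |D|/D_{\max}$ with the usual
frequency-dependent bound. A monomorphic locus makes $D'$ undefined and
raises an error rather than returning 0. Simulation tests require
recovery of a planted $D' = 0.9$ within 0.05 at $n = 500$.

`detectXLinked()` flags the genotype signature of X linkage on a diploid
chip — every called male homozygous for the same allele, at least one
heterozygous female — and attaches the probability of that signature
arising autosomally by chance, $(\mathrm{maf}^2 + (1-\mathrm{maf})^2)^{n_\mathrm{males}}$
(`xTypeIError()`): with 36 males and MAF 0.31 this is one in 535 million.

`selectPanel()` fills a panel of `targetSize` markers: reserved ids
(mtDNA, Y) enter unconditionally, the rest by MAF descending. The
published selection also required visually clean Fluidigm clusters, which
is not computable from genotypes; selection here is MAF-rank only, with
deterministic tie-breaks (He descending, then locus id) so the output is
invariant to input order.

The four mtDNA markers jointly code three matrilineages —
ABAA = NorthA, AAAA = NorthB, BBBB = South — in `assignMtHaplotype()`;
any other combination is `unknown`. Two intentionally monomorphic Y
markers give `determineSex()`: both present = male, both absent = female,
discordant = inconclusive.

## Lynch-Ritland relatedness and parentage exclusion

For reference individual $x$ with alleles $(a, b)$ and proband $y$ with
$(c, d)$, the Lynch-Ritland method-of-moments estimator contributes per
locus

$$N_l = p_a(S_{bc} + S_{bd}) + p_b(S_{ac} + S_{ad}) - 4 p_a p_b, \qquad
  D_l = (1 + S_{ab})(p_a + p_b) - 4 p_a p_b,$$

with $S$ the identity-in-state indicators and $p$ the population allele
frequencies. Loci are combined as a ratio of sums,
$r_{x \to y} = \sum_l N_l / \sum_l D_l$, which weights loci by their
information content and removes the singularity of the per-locus ratio at
a heterozygous reference with $p = 0.5$; the reported $r$ averages the
two directions, making the estimator exactly symmetric. Allele
frequencies are computed from the full sample including the dyad
(`alleleFreqs()`), the common practice; a leave-out variant is available
through its `exclude` argument. Monomorphic loci and loci with a missing
call in either individual are dropped per dyad.

Confidence intervals are percentile bootstrap over loci (1000 replicates,
seeded, `bootstrapCI()`); no published interval method was available to
match, and the locus bootstrap is the standard choice for multilocus
relatedness estimators. Simulations in the test suite require the nominal
95% interval to cover $r = 0.5$ for 93-97% of simulated parent-offspring
dyads.

`classifyDyads()` reproduces the screening-and-exclusion workflow: all
pairs with $r > 0.40$ are candidate first-order relatives; a candidate is
excluded as parent-offspring if any autosomal locus shows opposite
homozygotes (a true parent and offspring share an allele by descent at
every locus, so under error-free genotypes this exclusion is sound — the
tests assert zero false exclusions over $10^4$ simulated parent-offspring
dyads); surviving mixed-sex and female-female dyads are further tested
against X-linked inheritance (son's X is maternal; daughter carries the
father's X; mother and daughter share an allele; father-son is
unconstrained). Because which member would be the parent is unknown, both
parent-child orientations compatible with the sexes are evaluated and the
dyad is excluded only if every orientation is violated. There is no
genotyping-error model in the exclusion logic: a single miscalled
homozygote can falsely exclude a true dyad, which is why the upstream
filter cascade aims for high-quality markers.

## The synthetic-data generators

`simGenome()` does not simulate a literal i.i.d. genome: it plants
recognition sites at exponential spacings (mean `meanSpacing`) on an
i.i.d. background and scrubs accidental pattern occurrences, so digest
fragment lengths are exactly exponential and the design model's
predictions can be tested sharply (a literal random genome would add
$4^{-6}$-rate background sites and blur the calibration). Collisions —
spacings shorter than the site — are redrawn.

`simPedigreePanel()` draws founder genotypes under Hardy-Weinberg
proportions at MAFs sampled uniformly from $[0.28, 0.50]$ — mean 0.39,
the mean MAF of a MAF-ranked 96-SNP panel, which is the regime the
relatedness recovery targets presume — and transmits alleles by Mendelian
rules: autosomes biparental, X maternal-only to sons (hemizygous,
single-letter calls) and biparental to daughters, mtDNA maternal, Y
paternal presence. The default marker complement mirrors the panel the
package models: 87 autosomal, 3 X, 4 mtDNA, 2 Y. Dyad relationship
classes (parent-offspring, full-sib, half-sib, unrelated) are tabulated
from the pedigree into the truth set.

`simStackFixtures()` plants one failure stratum per cascade criterion
plus a clean-pass stratum, recording each record's expected fate, so the
cascade's survivors and rejection reasons can be compared against truth
exactly. Sequencing error appears only as the planted failure strata
(e.g. multi-SNP reads, missing genotype classes); read simulation with
quality scores, stack assembly and alignment are all upstream of this
package and are not emulated.

What passing these tests shows is that the implementation is faithful to
its models: the estimators recover planted parameters under the
generators' idealized conditions (HWE founders, error-free transmission,
exact exponential spacings). Real RRL data add allele dropout,
paralogous co-assembly, reference bias and genotyping error that the
generators deliberately omit; results on real catalogs depend on those
factors in ways synthetic recovery cannot certify.

## Numerical choices and problem sizes

Simulation-backed checks in the test suite and the acceptance script use
fixed problem sizes chosen to hold Monte-Carlo error well inside each
tolerance: 500 dyads for mean-$r$ recovery (binomial SE of the mean
$\approx 0.005$ against a $\pm 0.05$ band), $10^4$ dyads for exclusion
soundness, 1000 bootstrap replicates and 500 trials for CI coverage,
$n = 500$ individuals for D' recovery, 20 seeded replicates for the
digest-calibration check, and 100 random sequences against the naive
digest oracle. All generators take explicit integer seeds and are
byte-deterministic given them.

Degenerate inputs are signaled, not silently patched: a zero-fragment
design, an all-missing locus, a monomorphic locus in D' or relatedness
denominators, a male heterozygous at an X locus, and inconsistent
catalog/hit keys all raise errors naming the offending unit.

## Limitations

- The cascade's published intermediate counts are not desk-reproducible;
  only the cascade's behavior on planted truth is verifiable.
- Panel selection ignores assay-cluster quality (a wet-lab criterion).
- Exclusion has no error model; it is exact only for error-free calls.
- The relatedness estimator assumes known allele frequencies; with few
  genotyped individuals the plug-in frequencies add variance that the
  locus bootstrap only partly reflects.
- mtDNA haplotype coding covers the three observed matrilineages; novel
  four-marker combinations return `unknown` by design.
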