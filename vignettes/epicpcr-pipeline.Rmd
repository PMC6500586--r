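---
title: "Profiling functional sub-communities from fused amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling functional sub-communities from fused amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicflow)
```

## The problem

Emulsion, paired isolation and concatenation PCR (epicPCR) links a functional
marker gene to the 16S rRNA gene of the same cell: single cells are trapped
in droplets where a fragment of the functional gene — here *dsrB*, the
β-subunit of dissimilatory sulfite reductase carried by sulfate-reducing
prokaryotes (SRP) — is fused to the cell's own 16S fragment through a
bridging primer. Sequencing the fused amplicons alongside conventional bulk
16S amplicons yields two views of the same sediment sample: the whole
prokaryotic community, and the phylogenetic identity of the sub-community
that carries the function.

`epicflow` implements the computational side of such a survey for a set of
saline-lake sediment samples: read processing for both library types, joint
OTU construction, α/β-diversity, per-factor environment–community
association testing, and classification of OTUs by their distribution across
lakes (endemism). Because raw survey reads are not required for development
or validation, the package ships a synthetic-data module that emulates the
study design with planted ground truth; every downstream stage is tested
against what was planted.

## Read processing

Both libraries go through the same stages; fused reads get one extra step.

* **Demultiplexing.** A read is assigned to a sample iff exactly one barcode
  lies within `max_mismatch` (default 1) of its 5′ prefix; ties leave the
  read unassigned. Barcode tables whose pairwise Hamming distance does not
  exceed `2 * max_mismatch` are rejected outright — assignment would be
  ambiguous by construction.
* **Primer trimming.** Primers match under IUPAC semantics (M is A/C, H is
  A/C/T, V is A/C/G, W is A/T, …) with one mismatch allowed by default. An
  ambiguous base in the *read* never matches: an N carries no evidence for
  the primer.
* **Merging.** Pairs are merged by the best ungapped overlap of at least 30
  bases, scored by mismatch fraction (ties prefer the longer overlap) with a
  ceiling of 0.25. Disagreeing overlap bases take the higher-quality call;
  the merged quality is the positional maximum. Merging is deliberately
  ungapped: an indel inside the overlap rejects the pair rather than
  producing a silently frame-shifted fragment.
* **Splitting (fused only).** The first 30 bases of a merged fused read are
  the *dsrB* fragment; the bridging primer is then expected immediately
  after (an anchored search, two mismatches allowed by default) and removed,
  leaving the 16S fragment. The anchored search reflects the fixed fusion
  layout; a global scan would invite spurious internal hits. Reads whose
  bridge cannot be located are counted separately, which distinguishes
  malformed fusion products from ordinary quality failures.
* **Quality filtering.** A five-base window slides 5′→3′ and the read is
  truncated at the first window whose mean Phred quality drops to 20 or
  below; the result is kept iff it contains no N and its length lies in
  [245, 260] — the expected 16S fragment range. The operation is idempotent.
  Filtering operates on merged fragments (for fused reads, on the 16S
  fragment after splitting), which is the natural place once merging has
  already consolidated qualities.

Every stage reports per-sample in/out counts; `validate_stage_report()`
checks the chain is conservative (each stage's input equals its output plus
its discards).

## OTU construction

The epicPCR-derived 16S fragments and the bulk amplicons are pooled with
per-read sample and provenance labels; an OTU observed in the epicPCR stream
defines the SRP sub-community. The pool is dereplicated (ties in abundance
broken lexicographically, so the scan order is fully deterministic) and
clustered greedily in decreasing-abundance order at 97% identity; a sequence
joins the first centroid reaching the threshold, else founds a new one. The
boundary is inclusive — two 100-base sequences differing at three positions
(97.0%) share an OTU. Singletons are never discarded; the representative of
an OTU is its most abundant member.

**Identity convention.** Identity is matches divided by alignment columns of
the optimal-score *global* alignment (match +1, mismatch −1, linear gap −2,
end gaps penalized), so every gap column counts against identity. An
end-gap-free variant was evaluated and rejected: with free ends and
identity taken over aligned columns only, two unrelated random templates
admit a short perfect dovetail (clip nearly everything, align a handful of
exact bases) that scores identity 1.0, which collapses unrelated taxa. For
equal-length pairs the gapless alignment is optimal under these scores near
the threshold, so the implementation takes the Hamming identity there; the
general case runs a banded dynamic program (band = length difference + 16)
with a shared-8-mer prefilter, the exact full-band form being exported as
`sequence_identity()`. The test suite checks both the identity values and
the resulting partitions against an independent quadratic
dynamic-programming oracle.

**Chimera screen.** Before clustering, a sequence is flagged as a chimera
iff some breakpoint splits it into a left flank at least 99% identical to
the *prefix* of one kept sequence at twice its abundance or more, and a
right flank at least 99% identical to the *suffix* of a different such
sequence. Two guards make the rule usable on noisy data: each flank must
reach 30 bases (a one-base "flank" matches almost anything), and a candidate
that a *single* eligible parent explains end-to-end at the same identity is
treated as a sequence variant, not a chimera — without this, every
point-error read of an abundant taxon is removed because a kept error
variant of the same taxon acts as the "different parent". The screen is
intentionally simple and fully declared; it catches clean two-parent
splices, while a chimeric read that also carries a sequencing error in its
short flank can escape and then surfaces as a rare OTU (see *Noise
behaviour* below).

**Rarefaction.** Tables are resampled without replacement to a fixed depth
(default 10,000 reads per sample). Samples below the target depth are
dropped with a warning rather than kept un-normalized: mixed depths would
bias every downstream richness comparison. Provenance-split counts are
rarefied jointly so the epicPCR/bulk decomposition stays consistent.

## Diversity

* **Shannon** uses the natural logarithm (the convention of the community
  ecology package it delegates to), zero-count categories excluded.
* **Chao1** is the bias-corrected form
  $S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$, defined even when no doubletons
  exist; the classic form is available behind a flag (and is undefined at
  $F_2 = 0$). Counts must be integers — the estimator has no meaning on
  normalized abundances.
* **Rarefaction curves** are Monte-Carlo means over without-replacement
  subsamples and are tested against the analytic hypergeometric expectation
  $E[S(d)] = \sum_i (1 - \binom{N - N_i}{d} / \binom{N}{d})$.
* **Jaccard** is the set-theoretic, presence/absence form
  $1 - |A \cap B| / |A \cup B|$ by default; the quantitative (Ružička)
  variant is a flag, because the same name covers both in common software.
* **Weighted UniFrac** follows the branch-fraction form: raw
  $\sum_b \ell_b |p_A(b) - p_B(b)|$ over branches $b$, where $p_X(b)$ is the
  fraction of sample $X$'s reads descending from $b$; the normalized form
  divides by $\sum_b \ell_b (p_A(b) + p_B(b))$ and lies in [0, 1]. On a star
  tree with unit branches the raw form equals the L1 distance between
  relative-abundance vectors and the normalized form equals half of it. A
  nonzero OTU missing from the tree is an error that names the OTU. Trees
  are consumed as Newick (`ape`); the package does not build survey trees.
* **PCoA** double-centers $-D^2/2$ and reports coordinates on axes with
  positive eigenvalues; negative eigenvalues are reported but excluded from
  the percent-variance denominator, with a Cailliez correction behind a
  flag. Recovery of a planted 2-D configuration is tested to Procrustes RMS
  below $10^{-8}$.

## Environment–community association

Environmental variables are z-scored per variable (sample SD, $n - 1$);
per-factor tests use the Euclidean distance on a single standardized column,
mirroring a per-factor association table, with an all-variable row included.
The Mantel statistic $r_M$ is the Pearson correlation of the
$n(n-1)/2$ upper-triangle entries; the p-value permutes rows and columns of
one matrix jointly, one-tailed toward positive association by default (the
ecological question is whether similar environments host similar
communities), with 999 permutations and the +1 finite-sample smoothing
$(1 + \#\{r^* \ge r\}) / (n_{perm} + 1)$. For $n \le 8$ an exhaustive mode
enumerates all $n!$ permutations (identity included, $p = \#\{r^* \ge r\} /
n!$); the $n = 4$ case is tested against a 24-permutation enumeration.
Tail choice and permutation count are exposed as arguments. α-diversity
coupling between the whole community and the SRP sub-community uses Pearson,
Kendall or Spearman correlations via the standard tests.

## Endemism

Presence of an OTU in a lake means a nonzero count in at least one sample
of that lake, so the classification is invariant to per-sample depth
scaling. OTUs present in every lake are *ubiquitous*, in exactly one lake
*lake-specific*, and otherwise *intermediate* — the third class is explicit
because the two extremes do not partition the middle. The high-abundance
filter keeps an OTU iff its within-sample relative abundance strictly
exceeds 1% somewhere (strict, following the "> 1%" convention). Presence
calls default to the rarefied table, consistent with normalizing depths
before the statistics; a pre-rarefaction mode supports sensitivity analysis.
`endemism_fractions()` reports class percentages at 0.1% resolution and at
whole-percent rounding — note that 8,463 of 12,519 is 67.6% at that
resolution.

## The synthetic study and its planted truth

The generator emulates the survey design end to end:

* **Layout.** 31 sediment samples across 10 lakes with 2–8 samples per lake
  (default `c(4, 3, 2, 5, 2, 3, 4, 2, 2, 4)`); bulk 16S fragments averaging
  253 bp (249–257), fused reads of structure
  `barcode + dsrB(30 bp) + bridging primer + 16S`; the nominal informative
  fused length 283 bp = 30 + 253 *excludes* the bridging primer, which is
  what survives processing. Primer defaults are the 515F/806R pair for the
  bulk library and a nested fusion-primer pair for the fused one.
* **Community.** 100 taxa at desk scale, 67.5% lake-specific and 2%
  ubiquitous by default (the lake-specific fraction follows the whole-
  community survey value; the ubiquitous fraction follows the SRP value,
  since 0.6% of 100 taxa would round to nothing). 20% of taxa carry a dsrB
  segment; only those emit fused reads, while bulk reads sample everything.
  One ubiquitous taxon is always SRP-flagged — the analog of a halotolerant
  sulfate reducer present everywhere — so every sample has a fused library
  to sequence. Abundances are log-normal with a per-sample floor on planted-
  present taxa.
* **Environmental drivers.** Lakes sit on a latent gradient. Monthly mean
  water temperature (MMT) maps the gradient deterministically and total
  nitrogen follows it at effect size 0.6; 80% of intermediate taxa occupy
  gradient-contiguous lake windows, which is what couples community
  composition to the drivers. Non-driver variables (pH, salinity, TOC,
  sulfate) are drawn independently *per sample* within their observed
  ranges: a lake-level random variable would inherit the lake-blocking
  signal from lake-specific taxa and test significant for spurious reasons.
  All values are clipped to the ranges observed across the ten lakes
  (pH 8.86–9.68, salinity 0.44–122.39 g/L, TN 0.07–0.88 g/kg,
  TOC 0.11–2.08%, sulfate 0.15–5.25 g/L, MMT 9.95–14.75 °C).
* **Reads.** Default depth 15,000 pairs per sample per library, so the
  10,000-read rarefaction is exercised. Counts are apportioned to the true
  abundances by largest remainder with a one-read floor for present taxa
  ("exact" mode; a multinomial mode exists): planted presence must be
  recoverable deterministically at zero noise, which is what the recovery
  tests assert. Substitution errors (default 0.005/base) are injected on an
  RNG stream seeded separately from the structural draws, so runs at
  different error rates under the same seed are positionally comparable —
  the mismatch-rate test is an exact binomial because of this. Chimeras
  (default 1% of reads) are two-parent, single-breakpoint splices of the two
  most abundant eligible taxa; 2% of pairs get a low-quality tail placed
  where it surfaces at the merged fragment's 3′ end, giving the windowed
  filter real work. The same seed yields byte-identical FASTQ.

**Noise behaviour.** At zero noise the pipeline recovers exactly the planted
taxa and their endemism classes. At default noise, escaped chimeras (those
whose short flank carries an error, defeating the 99% flank rule) and rare
taxa without any error-free read surface as rare extra OTUs — singletons and
doubletons that real pipelines usually suppress by discarding singletons,
which this pipeline deliberately does not. The tests assert this band
explicitly rather than hiding it: all planted taxa recovered, extras rare,
total count within a few OTUs of the planted number, and planted endemism
classes recovered above 95%.

**What passing tests do not show.** Templates are random sequences with
GC ≈ 0.5 and pairwise identity below 95%, so the 97% threshold separates
taxa by construction; real 16S data has phylogenetic structure, conserved
regions and much finer identity gradations. The error model is
substitution-only (no indels, no PCR amplification bias, no position- or
motif-dependent error rates), qualities are two-valued, and the UniFrac
trees used in tests are toy UPGMA or random trees, not survey phylogenies.
Passing therefore validates the pipeline's logic and its declared
conventions, not its behaviour on the full messiness of real amplicon data.

## Problem sizes

The test suite and the acceptance script run synthetic studies at reduced
depth (typically 40–400 read pairs per sample and 10–100 taxa), 1,000 null
trials for Mantel calibration (15 samples, 999 permutations) and 200
generator trials for driver power; these sizes give stable statistics while
keeping the whole suite to about a minute on one core.

## Known limitations

* The chimera screen models only two-parent, single-breakpoint chimeras and
  requires a 2× abundance skew; multi-parent or equal-abundance chimeras
  pass through (and are kept as singletons downstream).
* No indel error mode in the generator; the merger and the clustering
  identity handle indels, but they are never exercised by synthetic data.
* Taxonomy is planted, not assigned: there is no reference-database
  classification, and composition summaries rely on the simulator's labels
  (or report "unclassified").
* Rarefaction's drop policy discards real samples below depth; with very
  uneven depths this can remove a lake entirely, and the endemism
  classification will then error if only one lake remains.
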