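---
title: "Detecting deeply conserved upstream elements with cnescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting deeply conserved upstream elements with cnescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnescan)
```

## The problem

Regulatory elements that matter tend to persist. Across deeply diverged
species, the non-coding sequence upstream of orthologous genes is mostly free
to drift, so a short stretch that has *not* drifted — a phylogenetic footprint
— is a strong candidate for a functional element. `cnescan` implements a
footprinting pipeline for exactly this setting: a central species compared
pairwise against a panel of distant comparators, scanning the up-to-2 kb
region upstream of each gene's translation start site (TLS) for conserved
non-coding elements (CNEs), with the false-discovery rate controlled not by a
parametric model but by an empirical null built from *pseudo-orthologs* —
randomly re-paired upstream regions that share no ancestry.

The pipeline is exercised end to end on synthetic cohorts with planted truth,
so every stage is testable without any genome download.

## Discovery model

### Window-pair alignment

For a central region $s$ and a comparator region $t$, every pair of
fixed-length windows is aligned globally: with window length $w = 50$, that
is $(|s| - w + 1)(|t| - w + 1)$ optimal alignments — 1951² ≈ 3.8 million for
two full 2 kb regions. The score is $+1$ per match, $0$ per mismatch and
$-0.5$ per gap symbol; `N` mismatches everything, including another `N`.
Fixed-length windows avoid the shadow effect of local alignment, where one
long mediocre alignment hides several short excellent ones, and make all
scores directly comparable.

Under exactly this scoring scheme the optimal global score of two
equal-length windows satisfies a useful identity. An alignment with $M$
matches, $X$ mismatches and $G$ gap symbols has score $M - G/2$ and
corresponds to an edit script of cost $X + G$, while $M + X + G/2 = w$;
eliminating $M$ gives

$$\mathrm{score} = w - d_\mathrm{edit}(a, b),$$

so the whole grid reduces to bit-parallel edit-distance computation
(Myers' algorithm, one 64-bit word per 50 bp window). The package treats
this purely as an implementation device: the test suite pins the fast path
to the literal quadratic dynamic program on thousands of window pairs, and
any scheme other than the default falls back to the generic DP.

### From raw scores to conservation scores

Annotated repeats are applied punitively before alignment by masking them to
`N`, so repetitive similarity cannot score. Raw window scores are rescaled to
*intermediate scores* of $100 \cdot \mathrm{raw} / w$ — percent of the
maximum — and mapped to a conservation score $P \in [0, 1]$ through a
sigmoid with lower and upper bounds $L$ and $U$: 0 at or below $L$, 1 at or
above $U$, and in between a logistic curve with steepness $10/(U-L)$,
rescaled to hit the endpoints exactly and pass through $1/2$ at the midpoint.
The bounds are the only shape information available; midpoint symmetry makes
the curve fully determined and testable.

Windows above $L$ are bundled: central-species window intervals that are not
disjoint are merged transitively, supports from all comparator species that
map into the same merged interval are attached, and each species contributes
$P_i$, the maximum conservation score among its supporting windows. The
combined conservation score is

$$\mathrm{CCS} = 1 - \prod_i (1 - P_i),$$

the probability-like complement of all species failing to support the
element. It is monotone in every $P_i$, bounded below by $\max_i P_i$, and
saturates at 1 as soon as any species reaches $P = 1$.

### Calibration on pseudo-orthologs

Real non-orthologous sequence is a stricter null than shuffled sequence: it
keeps the repeat structure and compositional quirks of genuine regions. The
pipeline draws a uniformly random derangement of the gene set (no gene may
pair with its own ortholog), runs the identical machinery on those pseudo
pairs, and sets the detection threshold at the maximum pseudo CCS. Detection
is the strict inequality `CCS > threshold`, so the control set yields zero
detections *by construction* — at calibration, not asymptotically.

The protocol is two-phase. Candidates are discovered at permissive bounds
$(L{=}80, U{=}94)$ and calibrated there; survivors of the coding filter are
re-scored at the strict bounds $(L{=}87, U{=}100)$ and calibrated a second
time against the re-scored pseudo candidates. The second calibration is what
makes the protocol well-posed in the presence of strong unannotated
repetitive similarity: at the candidate bounds a pseudo pair can saturate
($P = 1$ needs only intermediate $\ge 94$), tying with true elements at
CCS $= 1$, whereas at $U = 100$ saturation requires a *perfect* 50 bp window,
which non-orthologous sequence essentially never produces. At the final
bounds the $L$/$U$ pair simply defines a confidence continuum for elements
already known to be significant.

### Coding filter

Candidates may be unannotated coding sequence or pseudogenes. The filter
threshold is derived by permuting each candidate's residues (preserving
composition), scoring the permuted set against a protein database, and
taking the minimum e-value attained — the most significant hit random
sequence of that composition is expected to produce. Any candidate whose
real hits beat that threshold is discarded. The pipeline consumes tabular
hit files; it never runs the similarity search itself. If the permuted set
produced no hits at all the threshold is $+\infty$ and every candidate with
any hit is removed; this limit case is reported loudly.

### Pseudo-CNEs

For characterization the pipeline also harvests *pseudo-CNEs*: pseudo-pair
candidates at the permissive bounds with CCS above 0.528, optionally
coding-filtered. They are high-scoring alignments that lack orthology — a
property-matched control set for asking what distinguishes genuinely
conserved elements from sequence that merely aligns well.

## Characterization

* **Composition.** GC content and CpG observed/expected
  ($\mathrm{obs}(CG) \cdot \ell / (\#C \cdot \#G)$, the standard estimator;
  undefined and flagged, not zero, when $\#C \cdot \#G = 0$), trinucleotide
  counts (including ATG), and a 50 bp / 10 bp sliding GC profile. `N`
  positions are excluded from denominators.
* **Distribution comparisons.** Each feature is compared CNE vs pseudo-CNE
  with the Wilcoxon rank-sum test: exact enumeration of all assignments for
  $n + m \le 12$ (midranks for ties), otherwise a normal approximation with
  tie correction, continuity correction and an Edgeworth kurtosis term
  ($\gamma_2 = -\tfrac{6}{5}(m^2+n^2+mn+m+n)/(mn(N+1))$). The plain
  continuity-corrected normal can deviate from the exact p by up to ~0.014
  just above the enumeration boundary; the Edgeworth term brings the worst
  case to ~0.001. A floor of $2/\binom{N}{n}$ — twice one extreme
  assignment — prevents the approximation from reporting impossible
  p-values near 0.
* **Position.** A CNE's distance to the TLS is measured from its 3' end
  (0 = abutting the TLS). Positional conservation is the Spearman rank
  correlation between central and comparator distances, with the usual t
  approximation (exact for $n \le 10$); Pearson is available as an option
  since the choice of correlation is not otherwise determined.
* **Transcribed overlap.** Each CNE is split into all overlapping 20-mers;
  a 20-mer counts as transcribed if it matches a transcript exactly on
  either strand. Exact matching replaces read-mapper alignment because a
  mapper's mismatch tolerance is configuration-dependent; a one-mismatch
  budget is available but off by default. Enrichment of transcribed overlap
  in a designated subset (by default the 20 highest-scoring CNEs) uses the
  exact upper-tail hypergeometric probability.
* **Matched controls.** Control regions preserve each CNE's length and
  TLS distance exactly, sampled upstream of uniformly chosen other genes;
  10 sets for composition work, 100 for motif statistics, with `N` positions
  mirrored from the true CNEs into their controls.

## RNA structure conservation

The structure conservation index is
$\mathrm{SCI} = E_\mathrm{consensus} / \overline{E}_\mathrm{independent}$:
the consensus-fold energy of the alignment divided by the mean energy of the
rows folded independently (rows de-gapped first). Values near 1 indicate a
conserved structure. Significance comes from 1000 column shuffles that
preserve the conservation pattern — columns may swap only within classes of
identical gap pattern and distinct-residue count — with the add-one
empirical p-value $(1 + \#\{\mathrm{SCI}_\mathrm{shuffled} \ge
\mathrm{SCI}_\mathrm{true}\}) / (n_\mathrm{valid} + 1)$, never exactly zero.
The Z score against the shuffled distribution is reported alongside, since
either summary is defensible.

Two folding engines satisfy one contract. The default built-in engine
maximizes canonical base pairs (Watson–Crick + GU, minimum hairpin loop
3 nt; energy $-1$ per pair; ties broken toward fewer pairs, then the
lexicographically smallest dot-bracket, making results exactly
reproducible); the consensus variant maximizes, over column pairs, the
summed fraction of rows able to pair. The `vienna` engine shells out to
`RNAfold`/`RNAalifold` for thermodynamic energies. Numbers from different
engines are never compared. One consequence worth knowing: for the
pair-maximization engine SCI $> 1$ is impossible — the consensus structure
restricted to any row is itself a valid structure for that row, so the
consensus score can never beat the mean of the per-row optima.
Compensatory mutations pushing SCI above 1 are therefore a thermodynamic
phenomenon and are exercised with the `vienna` engine, where a fully
compensated stem block yields SCI ≈ 1.24.

## Motif over-representation

Position weight matrices are de-duplicated by complete-linkage hierarchical
clustering on a Hellinger distance: per column
$h(p, q) = \sqrt{\tfrac12 \sum_b (\sqrt{p_b} - \sqrt{q_b})^2}$, aggregated
as the mean over the best ungapped offset (overlap at least
$\min(L_a, L_b, 5)$ columns, reverse complement considered). Each cluster is
represented by its member of (lower) median total entropy. A caveat on the
default cut height of 1.5: with mean aggregation the distance is bounded by
1, so 1.5 collapses everything into one cluster — a threshold on that scale
is only meaningful below 1, and `aggregate = "sum"` is provided for
unnormalized distances where larger cut heights behave as expected. The
package takes no position on which scale a given threshold was meant for;
clustering tests here use sub-1 cuts on the mean scale.

Scanning scores every position on both strands with log-odds against a
uniform background; a hit requires 80 % of the maximum attainable score, so
match strength is folded into the hit definition. Each matrix's hit count is
tested with an upper-tail binomial p-value whose per-position probability is
estimated from the pooled control sets; a matrix is called over-represented
only if its true-set p-value is strictly below *all* 100 control p-values
(under-represented if strictly above all) — under exchangeability each
verdict has probability 1/101 per matrix by symmetry. Matrix GC is
summarized information-weighted: each column's $p_G + p_C$ weighted by
$2 - H(\mathrm{column})$ bits.

## The synthetic cohort generator

The generator is first-class, tested code, standing in for a real multi-genome
panel. Each gene locus draws an ancestral upstream region (default 2000 bp,
GC 0.30 — an AT-rich baseline typical of insect upstream sequence); each
species evolves its copy independently on a star phylogeny (no phylogenetic
correlation, by design) with per-site substitutions at rate 0.35, indels at
rate 0.01 with geometric lengths of mean 2. Planted elements (default 90 bp,
the characteristic detected length) evolve at their own much lower rate with
*no* indels and are re-inserted at a fixed distance from the TLS in every
carrier species, so positional conservation is controlled truth. A short CDS
is appended 3' of each region, one contig per locus (a quarter of loci on
the minus strand), so that extraction from the emitted FASTA + GFF3
reproduces each region byte-for-byte — an invariant the tests assert.
Transcript sets cover a configurable 5'-anchored fraction of each element.
Directed transcript-level hit tables with decoys exercise the
reciprocal-best-hit stage. All randomness derives from one integer seed.

Pseudo-ortholog pairings are uniform random derangements, drawn by
rejection — exactly random re-pairing of real (here: synthetic) sequence,
not shuffling, since shuffling would destroy the repeat and composition
structure that makes the null stringent.

Two features of real data the generator deliberately lacks: phylogenetic
correlation between comparators (every species is independent), and any
selection model (elements are conserved by fiat, not by fitness). Passing
tests therefore demonstrate that the machinery recovers planted conservation
under the stated divergence regime — not that the regime models any
particular clade.

*Unannotated repeats.* To make pseudo-CNEs exist in a synthetic world, the
generator can plant copies of one shared repeat consensus (typically
60–80 bp at ~0.10 substitutions per copy) across loci and species, withheld
from the repeat annotation. Randomly paired loci then share high-scoring
non-orthologous similarity — the same mechanism (repetitive, AT-background
sequence) that produces pseudo-CNEs in real genomes. The divergence is
chosen between the conserved-element regime (~0.02–0.05/branch) and
background (0.35/branch): strong enough to exceed the candidate lower bound,
weak enough that elements out-conserve it after the final-bound
re-calibration.

## Numerical choices and degenerate inputs

* Scores are exact multiples of 0.5, stored as doubles and compared exactly.
* Windows merge only on strict overlap; abutting intervals stay separate.
* Detection thresholds use strict inequality throughout, so "no detection in
  the control" holds exactly at calibration.
* CpG O/E with no C or no G, SCI with an unstructured denominator, and
  overlap of a CNE shorter than $k$ are all *flagged undefined*, never
  silently zero and never an escaping exception.
* An empty candidate or CNE set propagates as empty tables with an explicit
  empty flag, distinct from failure.
* Coordinates are 0-based half-open everywhere internally; GFF3 is converted
  on read (translation start = 5'-most CDS base across transcripts, the
  only annotation-robust anchor), and BED round-trips losslessly.
* Ambiguity codes other than `N` become `N` with a warning; `N` never
  matches, never pairs, and never hits a motif.

## Problem sizes used in the test suite

Module and pipeline tests run on 600 bp regions with 4–8 loci and 3
comparators; the full-scale recovery check uses 2000 bp regions, 8 loci and
4 comparators (≈3.8 M window pairs per comparison, ~64 grids per run). SCI
null-calibration uses 200 replicate blocks of 4 × 30 columns at 199 shuffles
each; single-block significance uses the full 1000 shuffles. These sizes
were chosen so the whole suite exercises every stage, including the
quadratic-equivalence oracles, at desk scale.

## Known limitations

* The built-in folding engine is a base-pair-maximization model: good for
  contract testing and shuffling controls, not a thermodynamic prediction.
  Use the `vienna` engine for publishable energies.
* Alignment blocks for SCI are built by anchoring each support to the
  central sequence via pairwise global alignment; comparator insertions
  relative to the central row are dropped. For the low-divergence,
  indel-free elements the generator plants this is exact; for real data a
  dedicated multiple aligner would be preferable.
* Orthology is strict reciprocal-best-hit at gene level (transcripts
  collapsed by maximum bit score): duplications yield at most one pair,
  which is the intended, conservative behavior.
* The TLS is the only anchor; transcription start sites are out of scope
  until reliable TSS data exist for the genomes of interest.
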