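---
title: "Methods behind ankfam: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ankfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ankfam)
```

`ankfam` packages the computations of a genome-wide gene-family survey for
ankyrin (ANK) repeat proteins: finding family members by their tandem
~33-residue repeat, classifying them by domain architecture, mapping them
onto chromosomes, measuring selection on duplicated pairs, scanning their
promoters, and quantifying their expression. This vignette explains each
model, its assumptions and tunable parameters, the synthetic-data
generators that stand in for real plant genomes, and the numerical choices
that matter.

## Repeat detection: a log-odds profile with greedy tandem selection

The ankyrin repeat is a ~33-residue helix-turn-helix motif that occurs in
tandem arrays of 1 to ~19 copies per protein. Production surveys detect it
with profile HMMs; `ankfam` instead uses a position-specific log-odds score
matrix (PSSM) built from a gapless seed alignment:

$$\mathrm{lo}(i, a) = \log_2 \frac{(c_{ia} + \kappa\, b_a)/(n + \kappa)}{b_a}$$

where $c_{ia}$ is the count of residue $a$ at column $i$, $b_a$ the
background frequency (uniform by default), $n$ the number of seed rows and
$\kappa$ the pseudocount weight (default 1). A window's score is the sum of
33 table lookups, so the scanner is transparent and testable against a
brute-force loop. The PSSM has no insert/delete states — acceptable for
this motif because ankyrin repeats are structurally constrained to a fixed
length; divergent repeats with indels will score low and can be missed.
That trade (simplicity and oracle-checkability versus HMM sensitivity) is
deliberate.

Hits are selected greedily: windows at or above the score threshold are
taken in descending score order, ties broken by the smaller start
coordinate, and any window overlapping an accepted one is skipped. On
tandem-repeat instances the top-scoring windows are the true repeats, which
are mutually disjoint, so greedy selection agrees with exhaustive
maximum-weight selection; the test suite asserts that equivalence on
planted instances.

**Threshold.** The default score threshold is half the profile's maximal
self-score (the consensus score, ~129 bits for the packaged seed). Tying
the default to the profile rather than to a fixed bit value keeps the
operating point meaningful when users supply their own seed alignments.
With the packaged seed, planted repeats carrying 10% positional noise score
far above half-maximum while windows of shuffled sequence essentially never
reach it; the acceptance suite measures recall and precision ≥ 0.95 against
planted truth (both are ≥ 0.99 in practice).

**Significance.** Surveys of this kind retain candidates with E-value
≤ 1e-5. HMM E-values are not reproducible without the HMM, so `ankfam`
attaches an expectation-style value of its own: the rank of the hit score
among `n_null = 1000` windows drawn from shuffled copies of the same
sequence (seeded, hence reproducible), scaled by the number of windows
scanned. A rank among 1000 nulls cannot fall below ~1e-3, so when a hit
outscores every null window the tail is extended with a normal
approximation fitted to the null moments. True repeats sit many null
standard deviations above the mean and receive vanishing values; shuffled
decoys never do. The 1e-5 retention cutoff then separates members from
decoys cleanly, which the suite asserts on simulated proteomes.

**Physicochemical descriptors.** Molecular weight uses average residue
masses plus one water. The isoelectric point solves net charge = 0 by
bisection, using a single declared pKa set (EMBOSS values: N-terminus 8.6,
C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1).
Bisection iterates to machine precision (60 halvings), far past the 0.01 pH
reporting resolution, so the net charge at the reported pI is numerically
zero even for large proteins where the charge curve is steep.

## Subfamily classification

Family members are classified by the non-ANK domains they carry: none →
`ANK-U`; otherwise the highest-priority recognized label wins, with the
fixed order `TM > PK > ZnF > BTB > ACBP > GPCR > BPA > IQ > RF > TPR`; a
member carrying only unrecognized extra domains (bromodomain, STI1, G-patch,
...) is `ANK-O`. Published census tables make these classes mutually
exclusive without stating a tie-break, so the priority order here is a
declared convention, exposed as an argument, not an inference of anyone's
intent. `RF` and `TPR` stay in the vocabulary although absent in pepper,
so censuses generalize to species that have them.

Census percentages (family size as a share of the annotated proteome) are
rounded half-away-from-zero to two decimals, computed on exact integer
arithmetic; float representation of values like 0.025 would otherwise make
the boundary case platform-dependent.

## Genome structure

Gene models are 1-based inclusive throughout (the GFF3 convention); all
BED exports convert to 0-based half-open at the boundary, eliminating the
most common off-by-one source in coordinate-heavy pipelines. When a gene
has several transcripts the first in file order is taken as the
representative, keeping exon chains non-overlapping.

Scaffold-located genes are tallied separately from chromosome-located
ones; the chromosome list of the assembly can be declared explicitly, with
a name-based fallback (`scaffold`/`contig` substrings). Density clusters
are found by sliding a `window_bp = 2 Mb` window every `step_bp = 100 kb`
(grid anchored at base 1) and merging overlapping windows holding
`min_genes >= 3` gene midpoints. Published descriptions of such clusters
are qualitative, so all three parameters are exposed; the defaults give
clusters at the scale those descriptions discuss. Cluster calls equal
brute-force window enumeration on small instances (tested).

Exon/intron summaries report lengths in transcription order (reversed for
minus-strand genes), and the identity
(sum of exon lengths) + (sum of intron lengths) = span holds for every
valid model — asserted over 500 random architectures.

## Duplication pairs, NG86 Ka/Ks and dating

Candidate paralog pairs are aligned globally (BLOSUM62, affine gap open 10
/ extend 0.5 — standard protein scoring, declared in the function
signature). A pair qualifies when alignment **coverage** (columns non-gap
in both / alignment length) and **identity** (identical / aligned columns)
both exceed 70%. Qualifying pairs form a graph and only pairs inside
connected components with at least two qualifying edges are kept; this
operationalizes the "minimum of two duplication events for strongly
connected genes" criterion, which published methods state but do not
define. The component rule and both thresholds are arguments.

A pair on one chromosome with at most 5 intervening family members in
genomic order is a tandem duplication; everything else is segmental.

**Ka/Ks** uses the Nei–Gojobori (1986) counting method, chosen because it
is fully specified and checkable against an exhaustive oracle (survey
papers typically delegate to a calculator without naming the model).
Per codon, each of the nine single-base changes is classified against the
standard genetic code; synonymous thirds accumulate into fractional S
sites, with changes to stop codons counted non-synonymous, so S + N = 3L
holds exactly (the implementation accumulates integer thirds precisely so
that this identity is float-exact). Differences between codons are
averaged with equal weight over all minimal substitution pathways;
pathways through stop codons are excluded, and in the rare case where
every pathway is blocked all are used with stop-passing steps counted
non-synonymous. Proportions receive the Jukes–Cantor correction
$d = -\tfrac34 \ln(1 - \tfrac43 p)$; $p \ge 3/4$ is reported as an error
(saturation), not silently truncated. Equal pathway weighting and JC
correction are the classical NG86 choices; they undercount at high
divergence, which is why the parameter-recovery tolerances below are
stated for Ks ≤ 0.5.

Codon alignments for CDS pairs are produced by threading the coding
sequence through the protein alignment (back-translation), never by
aligning nucleotides directly, so gaps always occupy whole codons.

**Dating** applies $T = K_s / 2\lambda$ with $\lambda = 6.96 \times
10^{-9}$ synonymous substitutions per site per year, configurable. One
caveat worth stating: the published pepper paralog table's printed
duplication times are not reproducible from its own printed Ks column
under this formula with this lambda (Ks = 0.33 gives 23.7 MYA, the table
prints 1.67; the implied constant is ≈ Ks × 5.06 MYA). `ankfam`
implements the printed formula and carries the table's time column as a
fixture value rather than guessing the constant actually used.

**Selection** follows the operative convention: ω < 1 purifying, ω > 1
positive, with an optional neutral band around 1 (default width 0, so
exactly 1 is neutral). Applied to the packaged 23-pair table this yields
22 purifying and 1 positive pair, mean duplication time ≈ 1.1 MYA and
maximum 5.87 MYA — the quantities `scripts/acceptance.R` recomputes.

## Promoter cis-elements

Promoters are the 1500 bp immediately 5' of the start codon in coding
orientation (reverse-complemented for minus-strand genes), truncated with
a flag at contig edges. Scanning is exact IUPAC matching — the convention
of plant cis-element catalogs, which define elements as short degenerate
consensus strings, not weight matrices. Both strands are searched; a
minus-strand hit means the element's reverse complement occurs in the
window, and positions always refer to the leftmost matched base in
promoter-local coordinates. Palindromic patterns genuinely occur on both
strands and therefore yield two hits; deduplication is an explicit flag,
not a default. Matching is delegated to `Biostrings` and verified against
an independent regular-expression oracle on 1000 random
(sequence, pattern) pairs.

The packaged catalog holds ~30 named elements (W-box, as-1/ASF-1, GCC
core, I-box, GT-1, MYB/MYC cores, ABRE, and others) sufficient for the
packaged analyses and the tests; full catalog coverage is the user's to
supply, in the same two-column format, since the upstream databases are
not redistributable. "Common" elements are reported under both readings of
the word: elements present in *every* promoter, and per-element promoter
counts sorted descending.

## Expression

RPKM is the unit-definition formula
$10^9 \cdot c_{gs} / (\mathrm{lib}_s \cdot \mathrm{len}_g)$; gene length
is the transcript (exon-sum) length when models are supplied. Log
matrices use $\log_2(\mathrm{RPKM} + 1)$ so zero maps to zero. Heatmap
rendering is out of scope, but row/column orderings come from
average-linkage hierarchical clustering on Euclidean distance, the
default family of the common heatmap tools, so downstream figures are
reproducible. "Expressed" has no standard RPKM cutoff; the default is
strictly greater than 0 and every partition result carries the threshold
it used. Venn cells are membership patterns over samples and always sum
to the union size.

Relative qPCR expression uses $2^{-\Delta\Delta C_t}$ with arithmetic
means over replicates; the calibrator sample's fold is identically 1.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its argument list including the
seed (one `withr::with_seed` stream per call, no global state), and each
emits a truth table its stage's recovery tests consume verbatim.

* `simulate_family()` plants 1–19 consensus-derived repeats per member
  (defaults: 200 members, 200 decoys, repeat-count distribution peaked at
  2–5 copies, 60-residue flanks, 10% per-position substitution noise so
  thresholds are meaningfully exercised). Decoys are per-sequence
  shuffles: same composition, no repeat structure — the hardest
  composition-matched negatives for a PSSM. Real proteomes additionally
  contain homologous non-family repeat proteins and partial repeats;
  passing these tests therefore demonstrates correctness of the scanner,
  not database-grade sensitivity.
* `simulate_paralog_pair()` mutates an ancestral CDS by
  proposal/acceptance: proposals uniform over positions and alternative
  bases at total rate $3 L \cdot K_s$ (so expected synonymous divergence
  per synonymous site is `ks`), stop-creating proposals rejected,
  non-synonymous proposals accepted with probability `min(omega, 1)`. The
  truth ω is the acceptance ratio, not a codon-model parameter; NG86
  estimates it consistently at these divergences, with a slight downward
  pull at ω near 1 because proposals into stop codons are never realized
  while their sites count as non-synonymous. Acceptance measures the mean
  estimate over 200 pairs per regime (ω ∈ {0.2, 0.5, 1.0}, Ks = 0.3, 300
  codons): observed means are within ~0.04 of truth for ω and ~2% for Ks,
  against stated tolerances of ±0.1 and ±15%.
* `simulate_counts()` draws negative-binomial counts whose mean matches a
  truth RPKM given lengths and library sizes; zero truth gives exactly
  zero counts.
* `simulate_promoters()` splices concrete realizations of IUPAC elements
  into GC-controlled background at recorded positions and strands;
  overlapping explicit placements are an error.
* `simulate_gene_models()` places random exon chains on chromosomes and
  scaffolds for the mapping and clustering truth tests.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely from code and
small packaged text fixtures: 200 simulated pairs per selection regime at
300 codons, a 400-protein simulated proteome for recall/precision, 500
random gene models for the conservation identity, 1000 random
motif-scanning instances, and the complete 61 × 61 codon-pair oracle
comparison. These sizes were chosen to give stable stochastic means
(standard errors well inside the stated tolerances) while keeping a full
run in the order of a minute or two on one CPU. All randomness flows
through explicit seeds, so every reported number is bit-reproducible.

## Known limitations

* The PSSM scanner cannot model indels inside a repeat; strongly degraded
  repeats are undercounted relative to a profile HMM.
* NG86 with JC correction saturates near p = 3/4 and is biased at high
  divergence; for Ks beyond ~1, model-based estimators are preferable.
* The duplication-event graph rule and the tandem distance cap are
  declared conventions for criteria the survey literature leaves
  underspecified; both are parameters.
* The packaged cis-element catalog is a useful subset, not a database.
* Percent-of-proteome censuses depend on the annotated proteome size
  supplied; they are only as comparable as the annotations behind them.
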