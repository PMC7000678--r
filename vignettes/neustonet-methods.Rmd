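---
title: "Methods: diversity statistics, UVR motif scanning and median-joining networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics, UVR motif scanning and median-joining networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neustonet)
```

`neustonet` packages the computational stages of a clade-level
mitochondrial phylogeography analysis of surface-film (neustonic)
daphniids: haplotype diversity statistics, median-joining haplotype
networks, a base-composition stationarity screen, and both-strand counting
of the trinucleotide contexts that modulate UV photolesion formation. This
vignette records the models, conventions and numerical choices behind each
stage, what the bundled simulator does and does not emulate, and the known
limitations.

## Sequence handling conventions

All stages operate on a `sequence_set`: upper-case residue strings over
`A C G T N -` plus IUPAC ambiguity codes, with `U` folded to `T` at read
time. Two site-exclusion conventions appear, chosen to match the
long-standing defaults of the population-genetics and distance tools these
statistics mirror:

* **Complete deletion** (`complete_deletion()`), the default for haplotype
  collapsing and the Hd/K/Kt statistics: any column carrying a gap or
  ambiguity in *any analyzed sequence* is dropped. Applied per analyzed
  subset — not across the full alignment — so a clade's statistics do not
  depend on sequences outside the clade. The alternative (`deletion =
  "pairwise"`) is exposed on `mean_pairwise_differences()` because the
  convention used for published clade statistics is not always stated;
  analyses of real data should report both when the trailing decimals
  matter.
* **Pairwise deletion**, the standard for `p_distance_matrix()`: each pair
  is compared over the sites where both members carry a plain base. A pair
  with zero comparable sites yields `NA` with a warning rather than an
  error, so one bad record does not abort a matrix.

Motif counting requires dealigned input (`dealign()`): counting follows
the dealign-then-count order, and gap removal can in principle create
junction motifs that the biological sequence lacks. This is deliberate —
it reproduces the preprocessing convention of the analysis the counter
implements — and is surfaced in the documentation rather than silently
"fixed".

## Diversity statistics

Haplotype diversity uses Nei's unbiased estimator,
$H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, computed in the
algebraically equivalent integer form $(n^2 - \sum_i c_i^2)/(n(n-1))$ so
that the analytic endpoints are exact in floating point: an all-distinct
sample gives exactly 1 (the biased form cannot), and a monomorphic sample
exactly 0.

$K$ is the unadjusted mean number of pairwise differences
$\sum_{i<j} d(i,j)/\binom{n}{2}$; no multiple-hit correction is applied,
matching the "average number of differences" convention. $K_t$ pools two
disjoint clade subsets and recomputes complete deletion on the union, so
the pooled statistic is self-contained rather than inheriting either
clade's site set.

The per-sequence composition screen compares each sequence's A/C/G/T
counts with expectations under the pooled frequencies
($X^2 = \sum_b (o_b - e_b)^2/e_b$, 3 df). Flagging uses the uncorrected
`p < 0.05` threshold — the statistic is a per-sequence screen, not a joint
test — and a Bonferroni column is emitted alongside for transparency.
Bases absent from the pool reduce the degrees of freedom with a warning.
Because the pooled frequencies are estimated from the same data, the test
is very slightly conservative; with realistic sequence counts the type-I
rate sits at the nominal 5% within binomial error (verified on 1,000
simulated homogeneous sequences in the test suite).

## UVR-salient trinucleotide counting

UV-induced pyrimidine dimers form preferentially at TT dinucleotides, and
the 3' neighbour modulates the rate: TTA/TTT promote lesion formation,
TTC/TTG inhibit it. `count_salient()` counts all four motifs with
*overlapping* occurrences (`"TTTT"` holds two `"TTT"` words) on the plus
strand and on the reverse complement, and sums the strands; the sum is
invariant to which strand is called "plus" (counting motif $m$ both-strand
equals counting $m$ plus $\mathrm{revcomp}(m)$ on one strand, a property
the tests exercise).

Choices the underlying convention leaves open, fixed here:

* Windows containing `N` or any ambiguity code never match any motif;
  ambiguous windows therefore deflate rather than inflate counts.
* Counts are reported raw (the habitat comparison plots raw counts);
  per-kilobase columns are emitted alongside for unequal-length inputs.
* Group summaries use type-7 quantiles (linear interpolation between order
  statistics), the R default, stated because box-plot conventions differ
  across software.

## Median-joining networks

`median_joining()` follows the classic heuristic: build the
minimum-spanning-network (MSN) backbone, insert median (Steiner) vectors,
purge, iterate. The MSN is the union of all minimum spanning trees — an
edge enters iff its weight equals the smallest distance class at which its
endpoints become connected — relaxed by `epsilon`: edges up to `epsilon`
above that threshold also enter. `epsilon = 0` is the default, the common
default of haplotype-network software; the parameter is exposed because
published analyses rarely state it.

Median generation and acceptance, where implementations genuinely diverge,
is fixed as follows:

* **Candidates** are the per-site majority-consensus vectors of *all* node
  triples. Restricting candidates to linked triples (triangles, or triples
  sharing a linked node) was evaluated and rejected: both restrictions
  miss optima that require a chain of two medians proposed by weakly
  linked triples. A cheap bound (the star cost is at least half the
  triple's perimeter) rejects most triples before any median is computed.
* **Tie sites** (three distinct states) take the state of the
  lexicographically smallest sequence of the triple, making generation
  deterministic.
* **Acceptance** requires the median's star connection cost
  $d(m,u)+d(m,v)+d(m,w)$ to be *strictly* below the triple's spanning cost
  (perimeter minus largest side): only medians that genuinely shorten the
  local network enter. Per pass, only the best-improving candidates (ties
  included, in lexicographic order) are added.
* **Purging** removes inferred nodes of MSN degree < 3, iteratively. A
  candidate purged once is never re-proposed; together with the finite
  state space this guarantees termination. A node-count ceiling (default
  10× the observed haplotype count) raises a structured
  non-convergence error carrying the partial network.

On binary data the median operation is exact, and the builder reaches the
brute-force Steiner-optimal length (enumeration over all unobserved state
vectors) on every small instance tested — 160 random instances with up to
5 haplotypes × 5 sites plus wider 3–4 × 6–8 instances in the acceptance
suite. "Total network length" is assessed as the minimal spanning
structure connecting the observed haplotypes through any subset of the
retained medians, since the MSN itself legitimately carries tie cycles.

The intended regime is closely related intraspecific haplotypes
(star-like or amalgam clade networks). Highly divergent inputs make the
quasi-median region grow combinatorially; the ceiling error, not a silent
truncation, is the designed behaviour there.

## The simulator

`simulate_dataset()` emulates the statistical structure the analysis
stages assume, not sequence evolution in general:

* a single root drawn i.i.d. per site from AT-rich base frequencies
  (default A = 0.35, C = 0.15, G = 0.20, T = 0.30);
* clade ancestors separated from the root by Poisson(`between_clade_divergence`,
  default 60) substitutions along a star — several strongly divergent
  clades, as in the empirical system;
* tips = ancestor + Poisson(`within_clade_lambda`, default 5)
  substitutions at *distinct* uniformly chosen sites, so each tip's
  Hamming distance to its ancestor equals its Poisson draw exactly; the
  analytic star-genealogy expectation of $K$ is then $2\lambda$ minus a
  small cross-lineage collision correction that the ground-truth record
  lets tests compute by brute-force pair counting. Defaults give
  $K \approx 10$ and $H_d \approx 1$ over 1100 sites, the magnitude seen
  in clade-level mitochondrial samples of this kind;
* an optional habitat-linked deficit of photolesion-promoting words:
  `suppress_tt_words()` scans the plus strand of each neustonic sequence
  for overlapping TTA/TTT occurrences and destroys each *original*
  occurrence independently with probability `1 - factor` by substituting
  its third base with C or G. A single static pass suffices: substituted
  bases are never `T`, so destruction cannot create new promoter words,
  and `factor = 0` provably leaves none. The expected survivor count is
  exactly $\sum_i \text{factor}^{1+m_i}$ with $m_i$ the number of
  overlapping words starting one or two positions upstream — the oracle
  the tests use. The minus-strand deficit emerges automatically from the
  complementary words, and destroyed TT-words become TTC/TTG, so
  inhibitor counts overlap or sit slightly higher in the suppressed group,
  mirroring the qualitative empirical pattern.

What the simulator does **not** emulate: indels (its output is trivially
aligned), rate heterogeneity among sites, recombination, coalescent
within-clade genealogies (star only), or a mechanistic substitution bias
for the motif deficit — suppression edits realized sequences, which also
means a strongly suppressed clade gains extra, biologically unrealistic
within-clade divergence (each tip is edited independently). Passing tests
therefore demonstrate correctness of the statistics and network machinery
under controlled structure, not realism of any evolutionary model; the
parameter-recovery tests run with suppression off for exactly this reason.

## Problem sizes and determinism

Simulation-based checks in the test and acceptance suites use sizes chosen
to give stable Monte-Carlo behaviour at interactive runtimes: 1,000
random sequences for the motif-scan oracle, 1,000 sequence-tests for the
composition type-I rate, 200 replicates of a 50-tip clade for $K$
recovery (3-SE criterion), 100 seeded simulations for the habitat
contrast (≥ 95% direction criterion), and 20–40 binary instances for
Steiner optimality. Every stochastic path is seeded; identical
configuration and seed give byte-identical FASTA output and identical
output checksums through the pipeline.

## Known limitations

* The accession-scale statistics of the empirical system (specific Hd/K/Kt
  values of named geographic clades) require the original GenBank
  alignment and clade assignments; the package ships the machinery and its
  desk-scale validations, not that dataset.
* Median placement in real networks may differ between implementations at
  tie sites and for `epsilon > 0`; observed-node topology is robust, the
  inferred nodes are convention-dependent.
* `K` is reported without multiple-hit correction and `p`-distances
  without model correction by design; neither is appropriate for deep
  divergences.
* Nucleotide diversity per site is emitted only as the convenience column
  `pi = K / analyzed_sites`; no neutrality tests are included.
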