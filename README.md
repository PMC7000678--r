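# neustonet

Clade-level mitochondrial phylogeography tools for neustonic zooplankton.

Daphniids that live attached beneath the freshwater surface film (the
hyponeuston) occupy an extreme ultraviolet-radiation habitat. Studying their
global population structure from mitochondrial rRNA haplotypes involves a
recurring set of computations that sit between standard phylogenetics
packages: collapsing aligned sequences into haplotypes and summarizing
within-clade variation, drawing median-joining haplotype networks per
geographic clade, screening sequences for base-composition
non-stationarity, and scanning sequences for the trinucleotide contexts
that promote or inhibit UV photolesion formation. `neustonet` implements
these stages as tested, reusable functions for R users working on
intraspecific mitochondrial data, together with a clade-structured
haplotype simulator used to validate every stage.

## What it computes

* **Haplotype diversity** (Nei's unbiased gene diversity):
  `Hd = n/(n-1) * (1 - Σ p_i²)`, with `p_i` the relative frequency of
  haplotype *i*. An all-distinct sample scores exactly 1.
* **Mean pairwise differences**: `K = Σ_{i<j} d(i,j) / C(n,2)`, raw
  difference counts without multiple-hit correction; `Kt` is the same
  statistic over two clades pooled. Site exclusion uses complete deletion
  (drop any column with a gap or ambiguity in the analyzed subset) by
  default, pairwise deletion optionally.
* **p-distances**: proportion of differing sites among sites comparable per
  pair (pairwise deletion), with the minimum off-diagonal entry exposed.
* **Base-composition heterogeneity**: per-sequence chi-square against the
  pooled A/C/G/T frequencies, `X² = Σ_b (o_b − e_b)²/e_b` on 3 df, flagging
  sequences with `p < 0.05`.
* **UVR-salient trinucleotides**: overlapping counts of the
  photolesion-promoting motifs TTA/TTT and the inhibiting motifs TTC/TTG,
  summed over the plus and minus strands (`"TTTT"` contains two `"TTT"`
  words), with five-number summaries by habitat class
  (neustonic vs planktonic).
* **Median-joining haplotype networks**: minimum-spanning-network backbone
  (union of all MSTs, relaxed by an `epsilon` parameter) iteratively
  augmented with per-site majority-consensus (median) vectors that strictly
  shorten the network, purging inferred nodes of degree < 3; exported to
  GraphML/GML with node kind, frequency and sequence attributes.
* **Synthetic datasets**: star genealogies within divergent clades, AT-rich
  base composition, and a controllable habitat-linked deficit of TTA/TTT
  words, with a full ground-truth record for parameter-recovery checks.

## Worked example

```r
library(neustonet)

cfg <- sim_config(n_clades = 2, seqs_per_clade = 10, seq_length = 600,
                  tt_suppression = 0.5, seed = 7)
sim <- simulate_dataset(cfg)

diversity_by_clade(sim$sequences, sim$groups)
#>   clade  n  h Hd       K       pi analyzed_sites
#> 1     A 10 10  1 30.5556 0.050926            600
#> 2     B 10 10  1  8.5778 0.014296            600
```

Every simulated sequence is a unique haplotype (`Hd = 1`), as typical for
mitochondrial samples with a few mutations per lineage. Clade B (planktonic,
untouched by motif suppression) shows `K = 8.58`, close to the expected
`2 × within_clade_lambda = 10` for a star genealogy; clade A (neustonic)
is inflated because the per-tip motif suppression at factor 0.5 adds its
own substitutions.

```r
net <- median_joining(collapse_haplotypes(
  sim$sequences, sim$groups$id[sim$groups$clade == "B"]))
net
#> haplotype_network: 10 observed + 1 median node(s), 11 edge(s), epsilon = 0
#>   total edge length: 45 substitution(s)
write_network(net, "cladeB.graphml")   # GraphML with kind/frequency/seq
```

The UVR motif contrast mirrors the habitat comparison the simulator was
built to emulate — the suppressed (neustonic) group's promoter counts sit
far below the planktonic group's, while inhibitor counts do not show the
same deficit:

```r
summarize_by_group(count_salient(dealign(sim$sequences)), sim$groups)
#>      habitat motif_class  n min    q1 median    q3 max
#> 1  neustonic    promoter 10  35 38.25   42.5 44.75  49
#> 2  neustonic   inhibitor 10  54 55.00   56.5 57.75  63
#> 3 planktonic    promoter 10  88 89.25   90.5 91.00  92
#> 4 planktonic   inhibitor 10  39 40.00   40.0 41.00  45

p_distance_matrix(sim$sequences)
#> p_distance_matrix: 20 sequences (proportion mode), minimum off-diagonal = 0.00333333
```

Real data enter through `read_fasta()` (alignment) and `read_group_map()`
(TSV with `id`, `clade`, `habitat` columns); `run_all(pipeline_config(...))`
orchestrates every stage and writes a checksummed run manifest.

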