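---
title: "Dating MITE amplification bursts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating MITE amplification bursts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitewave)
```

## The problem

Miniature inverted-repeat transposable elements (MITEs) are short,
non-coding DNA transposons bounded by terminal inverted repeats (TIRs)
and flanked, in the Tc1/Mariner superfamily, by a `TA` target-site
duplication. A MITE family amplifies in a burst, then dies; afterwards
each copy accumulates substitutions independently. The family's history
is therefore written in its *divergence landscape* — the distribution of
copy-to-consensus distances — and in the anatomy of its consensus
sequence, which may be a mosaic of fragments from unrelated parental
elements (a Mariner-derived backbone carrying a captured SINE body, for
example).

`mitewave` implements that archaeology as a reusable pipeline: coverage
profiling of homology hits, defragmentation of hits into copies,
consensus building and Jukes–Cantor divergence, substitution-rate
calibration and activity dating, genic-context statistics, and
composite-structure dissection, all driven by a synthetic burst
simulator with complete ground truth.

## The substitution model

All divergences use the Jukes–Cantor model. The forward map from an
expected number of substitutions per site $d = s\,t$ (rate $s$, time
$t$) to the expected fraction of observably different sites is

$$p = \tfrac{3}{4}\left(1 - e^{-\frac{4}{3} d}\right),$$

and the distance estimator inverts it:

$$\hat d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}\,\hat p\right).$$

`p_distance()` uses pairwise deletion (columns with a gap or `N` in
either sequence are dropped from numerator and denominator) because
eroded copies would otherwise discard most alignment columns under
complete deletion. Inputs with $\hat p \ge 0.75$ are saturated: they are
reported as `NA` and excluded from aggregates rather than clamped.

Activity dating rests on the identity $T = D/s$. Used one way
(`calibrate_rate()`), a family's mean divergence anchored to a known
cladogenetic split time yields a family-specific substitution rate; used
the other way (`date_event()`), a divergence and a rate date an event.
The *minimum* copy-to-consensus divergence dates the end of the
amplification wave (the youngest surviving copy); the mean dates its
midpoint. Calibration uses the *unweighted* mean across per-genome
divergence values — not a copy-number-weighted mean — because the
per-genome values are the published unit of observation; this choice
reproduces the published family rates exactly (see
`scripts/acceptance.R`).

## The synthetic burst: a stated world

`simulate_burst()` generates the one scenario everything else is tested
against. Its defaults are fixed once, from the biology of the motivating
system, and are not tuned to test outcomes:

* **Element geometry** — an 865 bp master with 24 bp perfect TIRs and a
  261 bp internal deletion window at positions 300–561 defining the
  deletion-derivative variant. These are the published dimensions of a
  well-studied primate MITE pair in which the derivative differs from
  the full element only by the internal deletion.
* **Copy numbers** — 400 full + 550 derivative copies, the order of
  magnitude observed per genome for that pair.
* **Ages** — Normal(86 Myr, 10 Myr) truncated at zero. The mean places
  mean copy divergence near 19% JC at the mammalian neutral rate
  (2.2e-9 substitutions/site/year), the level typical of the published
  per-genome values; the spread is a stand-in (no within-burst age
  distribution is published) and is a configuration knob, not an
  inference claim.
* **Mutation** — each site independently flips with probability
  $p(s\,t)$ to a uniformly chosen different base. This samples the
  *observable* outcome of the Jukes–Cantor process directly, so
  realized per-copy substitution counts are Binomial and exactly
  consistent with the distance estimator.
* **Insertion** — each copy lands at a distinct background position, on
  a random strand, flanked by a duplicated `TA`. No nesting, no
  post-insertion indels other than the defining deletion: the MSA the
  simulator emits (copies padded to master coordinates, deletion as
  gaps) is exact by construction, standing in for a real aligner.
* **Fragmentation** — with probability 0.3 a copy's *hit record* (not
  its DNA) is split into up to 3 collinear fragments separated by
  5–30 bp gaps, emulating how annotation tools fragment diverged
  copies.
* **Genes** — synthetic gene models (gene/mRNA/5′UTR/CDS/3′UTR, 5 kb,
  10%/80%/10% split) cover 13% of the genome, which with ±5 kb flanks
  puts roughly 40% of insertions in genic context, matching the
  published order of magnitude.

What a green test on this world does *not* establish: robustness to
nested insertions, indel erosion, CpG-biased mutation, rate variation
across sites, or alignment error — none of which the generator
produces.

## Numerical and algorithmic choices

**Coordinates.** Everything internal is 0-based half-open (BED-style);
1-based formats (BLAST tabular, RepeatMasker `.out`, GFF3) are converted
at the I/O boundary only. Minus-strand hits keep `start < end` plus a
strand flag.

**Coverage and drops.** Coverage counts aligned spans from coordinates,
so gapped columns inside a hit count as covered — tabular input carries
no per-column gap structure; this is a documented dialect difference
from alignment-view counting. A *drop* is a maximal run of positions
below `rel_threshold` × median(nonzero coverage), at least `min_width`
wide. The default threshold 0.1 targets the genome classes where only
the deletion derivative is present and window coverage falls to zero.
In a *mixed* genome the window retains about
$n_{\mathrm{full}}/(n_{\mathrm{full}}+n_{\mathrm{derivative}})$ of the
median (≈ 45% at the default mix), so detecting the dip there requires
`rel_threshold` ≈ 0.6; the tests use exactly that value for the mixed
scenario, chosen from the known variant mix, not from results.

**Defragmentation.** Two fragments chain iff they share
family/contig/strand, the genomic gap is ≤ 500 bp (small overlaps up to
20 bp tolerated), and their query intervals are collinear with the
strand. Chains grow greedily left-to-right along the genome, each
fragment joining the nearest admissible open chain. The 500/20 defaults
span typical interruption gaps without bridging distinct copies; both
are tunable. Copies are filtered by the strict `> 50%`-of-query
coverage rule *after* merging — filtering fragments first would discard
legitimately fragmented copies — and the variant call uses
deletion-window coverage (< 10% → derivative, > 50% → full, else
ambiguous; the 10/50 thresholds are package defaults chosen for
robustness to edge erosion). Greedy chaining is optimal on
well-separated fragmented copies (the regime the simulator produces,
and the one the recovery guarantee addresses); on adversarial
interleaved same-family hits within the gap limit it is not guaranteed
optimal.

**Consensus.** Majority rule per column over `{A,C,G,T,-}`; `N` does
not vote; ties break by the fixed order A<C<G<T and a gap loses every
tie; gap-majority columns are dropped from the consensus string. When
derivative copies are the column majority, the deletion window drops
out of the consensus — exactly what species-specific consensus building
does in genomes where only the derivative survives.

**Local alignment.** `local_align()` is exact affine-gap
Smith–Waterman (Gotoh), in C++: a gap of length $k$ costs
`gap_open + k·gap_extend`, traceback ties resolve diagonal > up > left,
and the best cell is the first maximum in row-major order, so results
are deterministic. The default scores (+2/−3/−5/−2) approximate
megablast. Because the algorithm is exact, a long deletion *will* be
bridged as one internal gap whenever the flanking match gain exceeds the
gap cost: aligning the 865 bp master against its own deletion
derivative at default scores yields a single end-to-end alignment with a
261 bp gap (cost 527 < flank gain ≈ 608). Recovering the two discrete
flanking blocks instead requires penalties that make the bridge
unprofitable (e.g. `gap_extend = -5`); `segment_map()` exposes the
scoring for exactly this reason. An X-drop heuristic would mimic
BLAST's HSP splitting but would break exactness, which the test suite
verifies against an independent dynamic-programming oracle.

`segment_map()` tiles the query by iterated best-hit extraction: the
best local alignment is taken, its query interval masked (the query is
split there, so later hits can never cross a mask), and the search
repeats while hits score ≥ `min_score` over ≥ `min_length` query bases.
Score/length thresholds replace E-values, which are not reproducible
without the original database.

**TIR detection.** The 5′ terminus is compared with the reverse
complement of the 3′ terminus, extending from position 0 while the
cumulative mismatch fraction stays ≤ 0.2. Within that scan the reported
arm ends at the prefix maximising matches − 2·mismatches: without this,
a perfect TIR call would drift several random bases past the true
repeat (random extension keeps the cumulative fraction under budget for
a while). For a perfect 24 bp TIR the call is exactly 24 bp, 0
mismatches; the mismatch weight 2 still tolerates genuinely eroded TIRs
up to the 20% budget. The detector is invariant under
reverse-complementing the input.

**Genic context.** A copy is genic iff it shares ≥ 1 base
(half-open arithmetic) with a gene extended by ±5000 bp; flanks are
strand-agnostic. Independence across species uses Pearson chi-square
without continuity correction (counts are in the hundreds; the
correction is immaterial), with the post-hoc analysis as all pairwise
2×2 chi-squares under Bonferroni correction over all
$k(k-1)/2$ pairs — the published analyses name the correction but not
the pairwise statistic, so the plain 2×2 chi-square is declared.
Multi-feature transcript overlaps resolve by the priority CDS > 5′UTR >
3′UTR (an invented but fixed rule; no published multi-overlap rule
exists).

**Degenerate inputs.** Empty hit lists give all-zero profiles (not
errors); all-zero profiles give empty drop lists with a message;
saturated distances are excluded from aggregates and counted;
unchainable hits become single-fragment copies; copies on contigs
missing from the annotation count as non-genic with a warning.

## Reproducibility

Every stochastic step flows from one seed (`burst_model(seed = )`,
`run_pipeline()` configs record it), and identical configurations
produce byte-identical report directories; the MANIFEST carries the
package version, seed, and an MD5 hash over the canonical JSON of all
stage parameters. The divergence TSV, consensus FASTA, copies BED,
context table and PHYLIP distance matrix are all plain text.

## Known limitations

* The age distribution of a real burst is unknown; the truncated-Normal
  choice shapes the landscape's spread but not its mean, which is what
  the dating uses.
* Coverage is span-based, not alignment-column-based (see above).
* Greedy chaining can mis-join adversarially interleaved same-family
  copies closer than the gap limit.
* The published segment lengths and divergences of the real element's
  Mariner- and SINE-homologous blocks require the original database
  sequences and are out of scope; `segment_map()` is validated on
  constructed chimeras and simulator-derived sequences instead.
* Trees are not built; `jc_distance_matrix()` +
  `write_phylip_distances()` export the distance matrix for external
  tree software.
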