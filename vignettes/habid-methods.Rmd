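---
title: "Methods: gel-fingerprint statistics and 18S rDNA phylogenetics in habid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gel-fingerprint statistics and 18S rDNA phylogenetics in habid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habid)
```

# The problem

When a red tide hits a semi-enclosed harbor, the bloom-forming isolates
brought into culture are often hard to tell apart morphologically, and
misassignments at the class level are common. Two cheap, independent lines
of molecular evidence discriminate such harmful-algal-bloom (HAB) isolates:

1. **Gel fingerprints** — SDS-PAGE protein profiles and native-PAGE isozyme
   zymograms, scored as binary band patterns per isolate (lane), summarized
   by polymorphism statistics and lane-to-lane similarity clustering; and
2. **18S rDNA sequences** — the small-subunit ribosomal RNA gene, identified
   by percent identity against reference sequences and placed on
   distance/parsimony phylogenies with bootstrap support.

`habid` implements both tracks as a reusable, fully offline pipeline, plus a
synthetic-data module that generates inputs with known ground truth so that
every statistic can be checked end to end.

# Track one: band matrices and polymorphism

## From lanes to a binary matrix

A gel is a *band table*: one row per band with its lane, relative mobility
and/or estimated molecular weight (kDa), and relative intensity. Mobilities
convert to weights through the standard log-linear ladder fit
`log10(MW) = slope * mobility + intercept` (`calibrateLadder()`, slope
necessarily negative).

How bands were matched across lanes in the original densitometry software is
never published with such studies, so `matchBands()` fixes a transparent,
testable rule: bands whose weights differ by at most a relative tolerance
(default 2%, measured against the smaller weight) merge by **single
linkage** — the transitive closure of the pairwise-within-tolerance
relation, which in one dimension reduces to cutting the weight-sorted chain
at gaps exceeding the tolerance. A merged group containing two bands of the
same lane is physically impossible as one band, so it is split at its
largest internal gap, recursively. The test suite holds this equal to an
independent brute-force graph-closure oracle on random gels.

## Classes and the polymorphism percentage

With lanes as columns, each consensus band is

* **monomorphic** — present in every lane,
* **polymorphic** — absent from at least one lane,
* **unique** — present in exactly one lane (a subset of polymorphic).

Per lane, counting only bands present in that lane,

$$\%\,\mathrm{polymorphism} \;=\; \frac{\text{polymorphic items} \times 100}
{\text{total items}}.$$

Three reporting conventions in published polymorphism tables needed pinning
down:

* **Truncation, not rounding.** 8 polymorphic of 11 prints as 72.72 (from
  72.7272…), which is truncation. `displayPct()` truncates for display;
  report objects keep full precision.
* **Two different "averages".** Band-level tables average the per-lane
  percentages (mean of ratios); locus-level isozyme tables divide the summed
  polymorphic count by the summed total (ratio of sums, "pooled"). The two
  disagree whenever lane totals differ. A `PolymorphismReport` carries both
  (`pctMeanOfLanes`, `pctPooled`); band reports display the former, locus
  reports the latter.
* **Zero-band lanes.** 0/0 is undefined; such lanes report a missing
  percentage rather than 0, and are excluded from the mean — a silent zero
  would bias it downward.

## Zymograms count loci, not bands

In an isozyme zymogram each activity zone is interpreted as one genetic
locus, and a double-banded zone (a heterozygous pattern) is still one locus.
`zymogramStats()` therefore collapses all bands inside a zone to a single
locus presence before applying exactly the same machinery.

## The deterministic study fixture

`makeStudyFixture()` reconstructs a four-isolate data set whose statistics
reproduce a published polymorphism table exactly. The publication gives only
the table margins — per-lane (monomorphic, polymorphic, unique, total)
counts of (3,7,2,10), (3,10,5,13), (3,8,8,11), (3,11,2,14) — not the full
matrix, so the fixture is the constructed matrix consistent with all of
them. With 3 all-lane bands and 2/5/8/2 unique bands fixed, the shared
polymorphic presences per lane must be 5, 5, 0 and 9; since lane 3 carries
none, the shared bands occupy subsets of lanes {1,2,4}, and the occupancy
system $a + b + d = 5$, $a + c + d = 5$, $b + c + d = 9$ over subsets
{1,2}, {1,4}, {2,4}, {1,2,4} has the **unique** nonnegative solution
$(a,b,c,d) = (0,4,4,1)$ — verified by exhaustive search in the test suite.

The 17 unique bands sit at the published species-marker weights. Two of
them (10.8 and 11.0 kDa, in different lanes) are only 1.85% apart, inside
the default 2% tolerance, so the fixture records a scoring tolerance of
0.015 as an attribute; all monomorphic and shared band positions were
chosen with pairwise gaps above 4% so the matrix is stable in a wide
tolerance window. Note the source text also mentions 65 total protein
bands while its table margins sum to 48; the fixture satisfies the table,
which is the only self-consistent constraint set.

The zymogram fixture has three zones with zone 1 active in lanes 2–4 only,
zone 2 double-banded everywhere, zone 3 single everywhere — giving 0% /
33.3% / 33.3% / 33.3% per lane and a pooled average of 27.27%.

## Similarity and UPGMA

`similarityMatrix()` supports Dice (default), Jaccard and simple matching.
The coefficient used by the original clustering software is rarely
recorded in publications; Dice is the customary choice for dominant/binary
fingerprint data because it double-weights shared bands, and the
coefficient tag is echoed into every output so no report is ambiguous. A
lane pair with no presences at all is assigned similarity 0 (the ratio is
undefined); the diagonal is 1 by definition. `upgmaDendrogram()` clusters
on `1 - similarity` with average linkage; labels are sorted
lexicographically first so merge ties break identically on every platform.
The published dendrogram's exact similarity values (40–55%) cannot be
reproduced without the unpublished band matrix, and the package does not
claim them; the UPGMA recurrence itself is tested against an independent
textbook implementation.

# Track two: sequences

## Identification by exact global alignment

Web alignment services used for published homology percentages implement
heuristics whose parameters are unrecoverable, so `globalAlign()` uses the
exact Needleman–Wunsch/Gotoh algorithm instead (via Biostrings), with
affine gap costs: a gap of length $L$ costs `gapOpen + L * gapExtend`,
end gaps included. Defaults are match +5, mismatch −4, gap open −10, gap
extend −1 — conventional DNA scoring. Two conventions are fixed and
documented in every report: the identity denominator is the **total number
of alignment columns including gaps**, and `N` matches nothing (it scores
as a mismatch even against `N` and never counts toward identity).
`rankReferences()` sorts hits by identity with ties broken by reference id.
Scores are tested against exhaustive enumeration of all alignments on short
sequences.

## Distances, trees, support

* **Distances.** Mismatch proportion `p` with pairwise deletion of columns
  where either sequence is gapped/ambiguous; JC69 transform
  $d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$, with a hard error at
  saturation ($p \ge 0.75$) rather than a silent `NaN`.
* **Neighbor joining** (`ape::nj`) — consistent on additive matrices,
  which the tests verify to $10^{-9}$ on random trees; negative branch
  estimates are clamped to 0 with a warning.
* **UPGMA** on the same distances, merge heights halved into branch
  lengths so an ultrametric input is reproduced exactly.
* **Fitch parsimony** (`phangorn::fitch`) with gaps/`N` as missing data,
  checked against exhaustive internal-state minimization.
* **Bootstrap** (`bootstrapSupport()`): columns resampled with
  replacement, tree rebuilt per replicate, each internal bipartition of
  the point tree labelled with the percentage of successful replicates
  containing it. Replicates whose resample defeats the distance model
  (saturation, zero overlap) are skipped, counted and reported; supports
  are percentages of the replicates kept. The default of 500 replicates
  follows common practice for 18S phylogenies. Everything is driven by an
  explicit integer seed and leaves the global RNG untouched.
* **Majority-rule consensus** (`majorityConsensus()`): bipartitions kept
  when they occur in *strictly more than* the threshold fraction of trees
  (default 0.5); exact ties are excluded, so two conflicting trees yield a
  star. Kept splits are mutually compatible for thresholds ≥ 0.5 and are
  assembled directly into a multifurcating tree labelled with occurrence
  percentages. Trees built by different algorithms (NJ, UPGMA, parsimony,
  or an externally supplied maximum-likelihood tree) can be fed in
  together, which is how a cross-algorithm consensus is obtained.

**Maximum likelihood is deliberately not implemented.** An ML tree search
is out of proportion to the statistical content of this pipeline; the
consensus machinery accepts ML trees built elsewhere as plain Newick.
Likewise multiple sequence alignment is an input (validated by
`validateAlignment()`), not a stage.

# The synthetic-data generator

`simulateGel()` perturbs species band profiles with multiplicative
Gaussian noise on weights (default relative SD 0.005, i.e. run-to-run
mobility scatter well inside the 2% matching tolerance) and intensities
(default 0.05). `simulateSequences()` evolves i.i.d. sites down a given
tree under JC69 (via `phangorn::simSeq`), the same model the distance code
inverts, with default length 1000 nt — the scale of partial 18S amplicons
(roughly 0.5–1.2 kb). Both are pure functions of their inputs and seed.

What the generator emulates: band-position scatter, presence/absence
structure, locus-style zymograms, and sequence divergence that is exactly
JC69. What it does not emulate: densitometry artifacts (smiling,
co-migration of unrelated proteins, staining saturation), rate
heterogeneity across sites, base-composition bias, alignment error and
sequencing error. Passing tests therefore demonstrate correctness of the
statistics and algorithms under their own model assumptions, not
robustness of the laboratory workflow to violations of them.

# Numerical choices and problem sizes

* Truncation guard: `displayPct()` adds `1e-9` before flooring so values
  represented a hair under the decimal grid do not truncate down.
* Tie-breaks: lexicographic label ordering before UPGMA; alignment
  traceback determinism is delegated to Biostrings (only scores and
  identities are asserted); NJ tie handling is ape's deterministic
  implementation.
* Degenerate inputs error loudly with classed conditions
  (`habid_parse_error`, `habid_validation_error`, `habid_compute_error`),
  which the command-line wrapper maps to exit codes 2/3/4.
* Test-suite problem sizes were chosen to keep the whole suite around a
  minute while leaving the checks sharp: 100-instance oracle sweeps for
  alignment/NJ/Fitch/band matching, 500 bootstrap replicates on a
  200-column alignment for the calibration check, 2000-nt alignments for
  topology recovery, 10000 nt for the divergence closed form (3 binomial
  SDs).

# Known limitations

* Band matching assumes one coordinate per band; 2-D gels and
  weight-dependent staining corrections are out of scope.
* The Dice/Jaccard defaults cannot be validated against the original
  clustering software output, only flagged and made configurable.
* JC69 is the only substitution model, by design symmetry between the
  simulator and the distance transform; saturated or deeply diverged data
  need a richer model and a different tool.
* The identity ranking is exact but global; for partial overlaps of very
  unequal lengths a local or glocal strategy would rank differently.
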