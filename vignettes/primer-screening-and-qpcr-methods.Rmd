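---
title: "Methods: in-silico primer screening and qPCR quantification of soil fungi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico primer screening and qPCR quantification of soil fungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungiqpcr)
```

# Scope

`fungiqpcr` has two halves that meet in one workflow: selecting a
fungal-specific primer set by screening candidates in silico against a
taxonomically annotated 18S rRNA sequence collection, and turning real-time
qPCR plates run with the selected set into estimates of 18S rRNA gene copies
per gram of dry soil, with the ecology statistics applied to those
estimates. This vignette documents the models, the parameters that matter,
the numerical conventions, and what the validation on synthetic data does
and does not establish.

# The matching model

## Alphabet and mismatch rule

Sequences and primers live over A, C, G, T, the IUPAC ambiguity codes, and
inosine (I). Internally every symbol is a 4-bit mask (A=1, C=2, G=4, T=8);
U is normalized to T on input. Inosine pairs promiscuously with all four
bases — that is its purpose at the two inosine positions of the FR1 primer —
so it expands to {A,C,G,T} in both primer and target, and is its own
complement. No authoritative convention exists for inosine in in-silico PCR;
treating it as a universal match is the choice that reflects its chemistry,
and it is applied symmetrically.

A primer position *matches* a target position when the two base sets
intersect (*optimistic* matching, the common in-silico PCR convention: an N
in a database sequence is given the benefit of the doubt). `strict = TRUE`
switches to containment matching (target set must be inside the primer
set), which penalizes ambiguous target symbols; it is off by default.
Mismatches are substitution-only (Hamming): primer annealing length is
fixed, so indels and overhanging alignments are out of scope, as are
3′-terminal mismatch weights and thermodynamic (ΔG / melting) models.

## Scanning and strand conventions

`scan_primer()` enumerates every full-length window at every position and
keeps those with at most `k_max` mismatches. SSU gene databases store sense
strands, so the default `search_mode = "sense_only"` scans forward primers
as written and reverse primers as their reverse complement; the site's
`strand` field records the strand on which the primer's written 5′→3′ text
aligns. `auto_both` additionally scans the mirrored representations for
unoriented collections. Coordinates are 1-based and inclusive throughout —
the native R and Biostrings/IRanges convention — so an 18-mer site starting
at 101 ends at 118, and the primer-inclusive product of a forward site at
[101,118] and a reverse antisense site at [451,468] is 468 − 101 + 1 =
368 nt.

A sequence counts as *hit* by a primer when it has at least one site at ≤ k
mismatches; the minimum-mismatch site is its representative. Hit frequencies
are therefore per-sequence, never per-site.

## Amplicon pairing

`predict_amplicons()` pairs each forward site with the *nearest downstream*
antisense site of the reverse primer, requiring the two primer footprints
not to overlap; products of non-positive length are discarded. Whether a
historical implementation paired all alternative sites or only the first is
unknowable from published descriptions; nearest-downstream is this package's
declared convention, and per-sequence statistics use the shortest product,
which is the PCR-dominant one. With `auto_both`, mirror-image pairs are
predicted as well, which makes prediction invariant under
reverse-complementing a record (tested property).

# The screening pipeline

1. **Length filter on the collection.** Very short database entries carry
   too little signal; the default minimum is 900 nt for SSU collections — a
   package default, chosen as roughly half the 18S gene, and configurable.
   The applied threshold is recorded in the collection and echoed into every
   report header so denominators stay auditable. Sequences lacking a
   taxonomy assignment stay in the collection but are excluded from all
   group denominators.
2. **Per-primer yield at k = 0..3.** `primer_yield()` tabulates per-group
   hit counts and frequencies; counts are non-decreasing in k by
   construction (tested invariant).
3. **k2/k0 ratio filter.** The ratio of total fungal hits at two mismatches
   to hits at exact match, retention at ratio ≤ 1.2: a primer close to its
   ceiling cannot be improved by adding degeneracies, while a large ratio
   signals a primer whose sequence misses many targets. The total is the sum
   over fungal groups (per-group ratios are available in the yield table
   for diagnostics); primers with zero exact-match fungal hits are
   discarded with a `zero-baseline` flag rather than dividing by zero.
4. **Amplicon-length filter.** Mean product length strictly below 384 nt —
   the product length of the nu-SSU-0817/nu-SSU-1196 reference set, the
   benchmark qPCR assay this threshold is anchored to. The comparator is
   configurable; sets with no predicted product are excluded and flagged.
5. **Frequency matrix and clustering.** `frequency_matrix()` scores a set as
   hitting a sequence when it yields a predicted amplicon with both sites at
   ≤ k mismatches (`mode = "amplicon"`); `mode = "per_primer"` relaxes this
   to independent per-primer hits, since either definition could plausibly
   underlie a published hit table. The `theoretical_optimal_row()` — 100 on
   fungal columns, 0 elsewhere — is appended as the specificity/coverage
   anchor: the best real set is the one clustering closest to it.

## Clustering and cluster significance

Columns (groups) are centred and scaled across rows — the rows are the
objects being clustered, so standardization must happen per column — and
rows are clustered on the distance 1 − Pearson r with average linkage
(UPGMA) by default; single, complete and Ward linkage are selectable, as no
linkage is canonical for this kind of profile data. Rows are sorted
lexicographically by name before clustering, making the result invariant
under input row permutation. Constant columns are dropped with a warning;
a row that is constant after scaling gets a guarded correlation of 0
against all others and is effectively maximally distant.

Cluster *significance* deserves a caveat: published dendrograms of this
kind mark "significant clusters at the 5 % level" without describing a
test. This package implements seeded ordinary bootstrap support — resample
columns with replacement, rebuild the tree, count how often each original
cluster reappears — and calls a cluster significant when its support reaches
1 − α, reporting the maximal such nodes (the root is excluded as trivial).
Bootstrap proportions of this kind are known to be conservative for small
column counts; multiscale (approximately unbiased) corrections exist but
require their own machinery, and with an unstated reference test there is
no target to calibrate against. Exact reproduction of any particular
published cluster count is therefore not guaranteed, and the defaults
(`n_boot = 1000`, `alpha = 0.05`, mandatory seed) are exposed.

# The qPCR model

The threshold cycle is linear in the log of starting template:
CT = a·log10(Q) + b, fitted by ordinary least squares (base `lm`). All
logs are base 10. Derived quantities:

| Quantity | Formula | Notes |
|---|---|---|
| Efficiency | E = 10^(−1/a) − 1 | 100 % at a = −1/log10 2 ≈ −3.3219 |
| Copies per reaction | 10^((CT − b)/a) | exact inverse of the fit on noiseless data |
| Detection limit | smallest standard with mean CT ≤ min(NTC CT) − 3.3 | 3.3 cycles = one 10-fold dilution at E = 100 % |
| Replicate CV | 100 · sd/mean (n − 1 sd) | scale-invariant |
| Copies g⁻¹ dry soil | (copies/ng template) · (ng DNA per g soil) | linear in extraction yield |

Conventions for degenerate inputs: a curve needs at least three distinct
quantities; a non-negative slope flags the curve invalid rather than
producing a nonsensical efficiency; undetected CT values are missing, never
zero — they are excluded from fits and estimates, and censored at the last
cycle (default 40) only for the NTC side of the detection-limit rule.

Integer efficiency percentages are reported by *truncating* the fractional
part: a slope of −3.24 reads as 103 %, −4.47 as 67 %. Truncation rather
than rounding-to-nearest is deliberate — it is the conservative convention
consistent with how such efficiencies are quoted for these slopes — and the
continuous value is always available from `efficiency_from_slope()`.
`windowed_efficiency()` refits the curve over sliding windows of
consecutive dilution levels as a diagnostic for template-dependent
inhibition (common in soil DNA extracts); its window estimates are noisy
and make no claim to match any particular published per-dilution figure.

The downstream statistics are deliberately standard: tie-corrected
Kruskal–Wallis (`stats::kruskal.test`) across land-use types, Dunn's
rank-based z pairwise comparisons with Bonferroni adjustment (the classical
follow-up when the omnibus method is unnamed), a compact letter display
computed from maximal cliques of the not-significantly-different graph, and
two-sided Pearson tests (`stats::cor.test`) per soil variable on
pairwise-complete observations, with constant variables reported missing.
Groups with fewer than two observations are excluded from the
Kruskal–Wallis with a warning.

# The synthetic-data generators

`make_community_db()` emulates an annotated 18S collection at the level the
screening statistics care about: group structure with fungal flags, and
primer-binding sites at known positions and mismatch counts. Backgrounds
are uniform random ACGT, rejected and regenerated until they contain no
site of either primer at up to `k_guard = 3` mismatches; planted sites are
concrete realizations of the degenerate primer text, with mismatches
introduced only at non-degenerate positions and only to bases *outside* the
primer symbol's set, so the planted mismatch count is exact under
optimistic matching. After planting, each sequence is re-scanned and
regenerated if anything but the intended sites is found — the emitted truth
table is exact by construction, not in expectation. Within a group the
first `round(prop · n)` sequences carry sites, so planted proportions are
exact counts; paired sites are placed at the requested primer-inclusive
product length (default 368 nt, the FR1/FF390-scale product) at a uniform
random offset. Everything is driven by a mandatory seed; two runs with the
same seed are byte-identical (tested).

What the generator does *not* emulate: rRNA secondary structure,
phylogenetically correlated sequence similarity within groups, sequence
length variation, chimeras, or database annotation errors. Uniform random
backgrounds are maximally unlike a conserved gene, which is exactly why the
truth table can be exact. Passing the synthetic acceptance checks therefore
establishes the *correctness of the computations* — counting, pairing,
ratio and threshold logic, curve algebra — not the field performance of any
primer set on real databases, which depends on the database release and its
curation.

`make_qpcr_plate()` draws CT values from a known curve with Gaussian noise
(default sd 0.15 cycles, a typical within-assay replicate spread; the
default dilution series spans 3 × 10² to 3 × 10⁷ copies in 10-fold steps
with 3 replicates), censors CTs beyond the last cycle, and emits undetected
no-template controls. Parameter recovery and CV propagation on these plates
are stochastic checks with stated tolerances, unlike the exact screening
truth.

# Validation problem sizes

The shipped validation uses sizes at which every check runs comfortably on
a laptop: scanner-vs-brute-force agreement on 200 random 120-nt instances
across k = 0..3; screening truth recovery on a 3-group × 100-sequence
community of 600-nt records (planted proportions 0.9/0.5/0.0); and
standard-curve recovery over 200 simulated plates of 5 dilution levels × 3
replicates. The two quantities recomputed from printed study tables — the
67–103 % efficiency range implied by five dilution-series slopes, and the
r = 0.54 organic-carbon vs C∶N correlation over 24 soils — use those tables
as shipped under `inst/extdata/`.

# Known limitations

* The published 23-of-33 amplicon-length subset, the five-cluster
  classification of candidate sets, and the per-soil abundance tables live
  in the study's supplementary spreadsheets, which are not redistributable
  with the package; the corresponding checks are present in the test suite
  but cannot pass without those files, and full-scale hit frequencies
  against curated public databases (SILVA-scale) are outside desk scope.
* Cluster significance is a bootstrap-support stand-in for an unstated
  test (see above).
* The matcher is deliberately thermodynamics-free; two sequences equal in
  Hamming terms may differ greatly in annealing behavior.
* Multi-plate calibration transfer, raw fluorescence processing and melt
  curves are out of scope: the plate table is assumed to carry called CT
  values.
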