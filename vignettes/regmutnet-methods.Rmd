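---
title: "regmutnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regmutnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmutnet)
```

# Scope and model

`regmutnet` analyses disease-associated mutations against three regulatory
layers: transcription-factor (TF) interaction interfaces on proteins, TF
binding motifs on DNA, and chromatin-chromatin interactions. The package
deliberately separates *data models and statistics* (this package) from
*data acquisition* (curated mutation databases, interface modelling
pipelines, Hi-C processing), which it replaces with seeded generators.

Coordinate conventions are fixed once: mutations carry 1-based genomic
positions (the convention of curated mutation databases); every interval
inside the package is 0-based half-open; conversion happens only in
readers and writers. A mutation "is in" an interval when its position falls
inside the half-open interval; a mutation on a segment boundary therefore
belongs to the segment that contains its position, never to two adjacent
segments.

## Interface layer

Each protein carries residue intervals labelled `protein_binding`,
`dna_binding` or `double`. At load time the *double-merge rule* is applied:
a residue annotated both protein-binding and DNA-binding is reassigned to
the separate class `double`, after which the four classes (including
`none`) are mutually exclusive and every residue resolves to exactly one.
The enrichment of mutations in a class is the odds ratio of the mutation
fraction against the residue-composition fraction, with the standard
log-scale standard error
`sqrt(1/n_mut_region + 1/n_mut_other + 1/n_res_region + 1/n_res_other)`
and a two-sided normal p value on `Z = ln(OR)/SE`.

Two policies deserve note:

* **No continuity correction.** A zero cell makes the SE undefined; the
  package errors instead of silently applying a Haldane-style correction,
  because any correction changes Z and the caller should decide.
* **Restriction filter.** With `restrict = TRUE`, proteins lacking either a
  protein-binding or a DNA-binding interface are excluded before counting,
  to limit misclassification from incomplete annotation. A protein whose
  only interface is `double` is *kept*: those residues bind both protein
  and DNA, so the protein demonstrably has both interface kinds. The
  upstream convention here is unstated; this is the package's choice.
* **Residue totals** count each residue of each included protein exactly
  once, regardless of how many interaction partners the protein has.

Homology-template admissibility implements the published scoring rule
`m = SeqID1*Cov1 + SeqID2*Cov2` with a 40% cutoff. The cutoff prose
("coverage or sequence identity above 40%" for "either protein") is
ambiguous; the package requires **all four** quantities strictly above
0.40, the reading under which a template weak in any one dimension is
rejected. The cutoff is an argument (`cutoff = 0.40`) so the other reading
can be emulated.

## Region layer

Chromatin-state segmentations map raw labels to `TSS` / `enhancer` /
`other` with fixed scheme-specific label maps (`chromhmm`, `segway`,
`combined`). Same-class intervals from several cell-line tracks are merged
to disjoint intervals before length measurement, so `l_region` is a true
union length. Enrichment is `(n_mut_region * l_total)/(n_mut_total *
l_region)` with `SE(ln E) = sqrt(1/n - 1/N + 1/l - 1/L)`. `l_total` is
always the sum of supplied chromosome lengths -- never a hard-coded genome
constant -- so the statistic is meaningful on synthetic worlds of any size.

For motif territory, 4000-bp search regions are centred at each variant.
The published formula for this enrichment is typographically ambiguous
about which product is the numerator; taken literally it is the *product*
of two fractions and does not equal 1 under uniform random placement. The
package implements

    E = (n_var_motif * l_search) / (n_var_total * l_motifs)

-- the fraction of variants in at least one motif relative to the fraction
of search territory covered by motifs -- which is the orientation that is 1
under uniform placement (verified by a property test). Overlapping motif
footprints are merged before `l_motifs` is measured and clipped to the
union of search regions; double counting would inflate the denominator.
Degenerate inputs (no variant in any motif, empty footprint) yield a
flagged result with estimate 0 and undefined SE rather than an error.

## Chromatin-pair layer

Unordered non-coding mutation pairs are partitioned into four categories
with a fixed precedence: `different_chromosomes`; `same_anchor` when any
anchor contains both mutations (tested *before* `interacting`, because a
degenerate anchor can interact with itself); `interacting` when one
mutation is in an anchor and the other inside a target linked to that
anchor (direction-symmetric); otherwise `non_interacting_same_chrom`.
Interacting and non-interacting pairs are excluded unless
`min_bp < |Δpos| < max_bp` (both strict). `max_bp` is fixed at 2 Mb by the
underlying analyses; `min_bp` is a single configurable knob because the
source analyses use both a 0/2/5-kb grid and stricter 20/50-kb variants --
the package defaults to 0 and asserts neither as canonical. A mutation may
sit in several anchors; `same_anchor` fires if any anchor contains both.

Concordance per category is the fraction of pairs whose disease-ID sets
intersect (mutations can carry several phenotypes; intersection is the
package's definition of "cause the same disease"). The test against the
`non_interacting_same_chrom` reference is the upper-tail cumulative
binomial with the observed reference fraction as null probability.

SQRTVC-normalised contacts are `raw(i, j)/(v[i]*v[j])` with
`i = floor(pos0/resolution)` on 0-based positions; an absent matrix entry
is 0 contacts, and a non-positive normalisation value is an error. The
same-disease versus different-disease comparison uses the Mann-Whitney U
test; both the mean and the median of each group are reported, since
either may serve as the headline location summary. The normal
approximation applies the standard tie correction and *no* continuity
correction, so identical groups give p = 1 exactly; for n1+n2 <= 12 an
exact permutation p value over all labelings is computed as well and is
returned as `p`.

## Motif layer

The scanner scores every window of PWM width on both strands with the
summed log-likelihood ratio `sum_k log(p_k(w_k)/q(w_k))`. The reference
scanner's internals are not published, so three knobs are explicit
configuration with the following defaults: natural log (threshold grids 6,
7, 8, 9 and 8, 9, 10 are interpreted on this scale), pseudocount 0.01
added per matrix cell with column renormalisation, uniform background.
Windows containing N are skipped; a zero-probability cell with
pseudocount 0 is an error rather than a silent -Inf. Both strands are
scanned because strandedness of the reference analysis is unstated and
motif occurrence on DNA is intrinsically double-stranded.

Motif-pair categories use a fixed precedence (same motif instance and
position > same TF, different position > TFs interact > TFs do not
interact) over all combinations of the two mutations' hits; "same
position" means an identical (TF, chrom, start, end, strand) hit. Pairs
where either mutation lacks a hit are excluded.

The interacting-TF motif-pair enrichment has two nulls. Baseline 1 divides
the number of interacting TF pairs by the number of possible TF pairs
among TFs with at least one interaction; whether homodimer (self) pairs
belong in that denominator is unstated upstream, so both behaviours exist
behind `include_self_pairs` (default TRUE, counting self-edges in the
numerator symmetrically). Its p value is a Z-test on the log enrichment
with the count-based SE `sqrt(1/k_obs - 1/n_obs + 1/k_exp - 1/n_exp)`, by
direct analogy with the segment-enrichment SE. Baseline 2 scrambles the
region-interaction network with seeded double-edge swaps (10x the edge
count, rejecting self-loops and duplicates -- the standard
degree-preserving null) and reports the empirical rank of the observed
fraction.

# The synthetic world

The generators are pure functions of a `sim_config` (seed included); they
restore the caller's RNG state. Defaults are the package's stated world
and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `n_mut_coding` | 3000 | order of the curated missense set the analyses target |
| `planted_log_or` | ln 2.5 on `protein_binding` | mid-range of reported interface odds ratios; planted on a single class so the class-vs-rest OR is exactly 2.5 |
| `interface_fraction` | 0.05/0.10/0.10 | realistic interface coverage of DNA-binding proteins |
| `theta_same_anchor` | 0.8 | the reported same-anchor concordance level |
| `theta_int`, `theta_bg` | 0.4, 0.05 | planted interacting-pair signal against background |
| `n_pairs_same_anchor/interacting` | 60 | enough pairs for stable fractions at desk scale |
| `resolution` | 5000 bp | finest published contact resolution |
| `contact_mu`, `contact_decay` | 20, 1 | power-law distance decay with overdispersion (NB size 2): the minimal structure that makes SQRTVC normalisation and the rank test non-degenerate |
| `motif_width`, consensus weight | 8 bp, 0.97 | consensus-heavy PWMs whose exact matches score ~10.8 at uniform background, comfortably above threshold 6 |

Mechanisms worth knowing when interpreting green tests:

* **Disease labels.** Each mutation carries exactly one disease ID.
  Planted pairs share an ID with their category's probability; everything
  else shares at the pool rate, so `theta_bg` is realised through the pool
  size (`n_diseases = round(1/theta_bg)`). Real mutations carry several
  phenotypes and heterogeneous disease frequencies; the generator does not
  emulate that, so concordance tests validated here say nothing about
  multi-phenotype edge cases beyond the set-intersection rule itself.
* **Category purity.** Each planted pair occupies its own anchor, targets
  are disjoint intervals, and background mutations avoid anchors and
  targets entirely, so the classifier's categories contain exactly the
  planted pairs plus clean background. Real anchor lists overlap and nest;
  only the unit tests for multi-anchor membership cover that.
* **Contacts.** Negative-binomial counts with power-law decay and a
  multiplicative boost on the bin pairs of planted same-disease pairs.
  This exercises normalisation and the rank test but is not a loop-calling
  model: no TAD structure, no compartments.
* **Motif plants** are embedded without overlap (rejection sampling), so
  "planted site recovery" is well defined; saturated regions silently
  receive fewer plants.
* **Sequence background** is uniform i.i.d. ACGT; GC bias and repeats are
  not emulated, so the false-positive calibration of the scanner holds for
  uniform background only.

# Numerical choices

* Two-sided normal p values from Z throughout (the source analyses report
  one-sided-looking thresholds without stating sidedness; two-sided is
  conservative). p values are floored at the smallest positive double.
* The identity case `estimate = 1, SE = 0` (region equals the whole space)
  returns Z = 0, p = 1 rather than NA.
* Upper-tail cumulative binomial is `P(X >= k)`, exact via `pbinom`;
  `k = 0` gives p = 1.
* Exact Mann-Whitney enumerates all `choose(N, n1)` labelings up to
  N = 12 and counts deviations `|U - n1*n2/2|` at least as large as
  observed (with a 1e-12 slack against floating-point rank noise).
* PWM columns must sum to 1 within 1e-9; count matrices are renormalised.

# Limitations

* Pair enumeration is quadratic in the number of mutations; the intended
  scale is thousands of mutations (millions of pairs), not millions of
  mutations.
* Disease-name normalisation is a plain lookup table; no fuzzy or
  ontology-aware matching.
* The homology-modelling layer is represented only by its admissibility
  arithmetic; no structures are built or validated here.
* Inter-chromosomal contacts, TAD calling and Hi-C normalisation vector
  computation are out of scope; normalisation vectors are inputs.
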