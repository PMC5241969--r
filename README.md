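# regmutnet

Disease mutations on multilayer regulatory networks.

## The problem

Disease-associated mutations act through at least three interacting layers
of transcriptional regulation:

1. **Protein interfaces of transcription factors (TFs).** A missense
   mutation can disrupt a TF's protein-binding interface, its DNA-binding
   interface, or a "double" interface that mediates both.
2. **TF binding motifs on DNA.** A non-coding mutation can fall inside a
   TF's binding site and change its occupancy.
3. **Chromatin-chromatin interactions.** Distal regulatory elements contact
   their targets through chromatin loops; two non-coding mutations in the
   two anchors of one loop can break the same regulatory circuit and cause
   the same disease.

`regmutnet` implements the analysis layer for this integrated view: it maps
mutation tables onto interface annotations, chromatin interaction networks,
Hi-C contact matrices and PWM motif scans, and computes the enrichment and
disease-concordance statistics that connect the layers. Because the real
inputs (curated disease mutations, interface models, Hi-C accessions) are
large and access-controlled, the package ships seeded synthetic generators
that emulate every input format with planted, recoverable effect sizes, so
the whole pipeline is testable end to end.

## The statistics

**Interface enrichment (odds ratio).** With p₁ = n_mut,region / n_mut,total
the fraction of mutations in an interface class and p₂ = n_res,region /
n_res,total the fraction of residues in that class,

    OR = (p₁ / (1 − p₁)) / (p₂ / (1 − p₂))
    SE(ln OR) = √(1/n_mut,region + 1/n_mut,other + 1/n_res,region + 1/n_res,other)
    Z = ln(OR) / SE(ln OR)

**Segment / motif-territory enrichment.** For k of n mutations in a merged
region of length l out of total length L,

    E = (k · L) / (n · l),  SE(ln E) = √(1/k − 1/n + 1/l − 1/L)

**Pair concordance.** Unordered mutation pairs are classified against the
chromatin network (same anchor / interacting / non-interacting same
chromosome / different chromosomes; distance filter min_bp < d < 2 Mb) or
against motif hits (same motif same position / same motif different
position / motifs of interacting TFs / motifs of non-interacting TFs). Per
category the fraction of pairs whose disease-ID sets intersect is compared
with a reference category by the upper-tail cumulative binomial test.

**Contacts.** SQRTVC-normalised Hi-C contact between two positions is
raw(i, j)/(vᵢ·vⱼ); same-disease versus different-disease pairs are compared
with the Mann-Whitney U test (tie-corrected normal approximation, exact
permutation for n₁+n₂ ≤ 12).

**Motif-pair enrichment.** Across interacting region pairs, the fraction of
cross-region motif pairs whose TFs interact is compared against (1) the
fraction of interacting TF pairs among all possible pairs of
interaction-active TFs, and (2) the same quantity on a degree-preserving
scramble of the region-interaction network (seeded double-edge swaps).

## Worked example

```r
library(regmutnet)
cfg <- sim_config(seed = 1)          # the package's stated synthetic world

# layer 1: missense mutations on TF interfaces, planted odds ratio 2.5
iface  <- simulate_interface_dataset(cfg)
counts <- build_interface_counts(iface$muts, iface$imaps)
interface_odds_ratio(counts, "protein_binding")
#> estimate = 2.446  se(ln) = 0.04753  Z = 18.820  p = 5.21e-79

# layer 3: non-coding mutation pairs vs the chromatin interaction network,
# planted same-disease probabilities 0.8 / 0.4 / 0.05
chrom <- simulate_chromatin_dataset(cfg)
pairs <- classify_pairs(chrom$muts, chrom$net)
concordance_by_category(pairs)
#>                     category     n k_same fraction     sem        p
#> 1                same_anchor    60     51   0.8500 0.04610 4.30e-57
#> 2                interacting    60     24   0.4000 0.06325 3.72e-16
#> 3 non_interacting_same_chrom 28223   1412   0.0500 0.00130       NA
#> 4      different_chromosomes 37904   1872   0.0494 0.00111 7.20e-01
```

The recovered odds ratio (2.45) sits within sampling error of the planted
2.5; the same-anchor and interacting concordance fractions (0.85, 0.40)
recover the planted 0.8 and 0.4 against the background rate 0.05, and the
binomial test against the non-interacting reference is decisive for both.

A file-driven run (TSV/BED/FASTA/MEME inputs, TSV reports plus a JSON run
manifest) goes through `run_pipeline("config.yaml", outdir)` or the CLI at
`inst/cli/regmutnet`:

```sh
Rscript inst/cli/regmutnet simulate --outdir fixtures --seed 1
Rscript inst/cli/regmutnet enrich-interfaces \
    --mutations fixtures/mutations_coding.tsv \
    --interfaces fixtures/interfaces.tsv --out interface_or.tsv
```

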