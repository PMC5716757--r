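---
title: "Repeat-stabilizing knock-in design: model, parameters and validation statistics"
author: "repeatlock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-stabilizing knock-in design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatlock)
```

## The problem

Mismatch-repair-deficient (MSI) tumors accumulate slippage indels in
short tandem repeats. When such a repeat lies inside a coding sequence
— the canonical example being the (A)9 lysine tract in the C-terminal
exon of *PRDM2*, truncated by c.4467delA in HCT116 colorectal cancer
cells — a single-base deletion shifts the reading frame and truncates
the protein. Correcting the deletion by knock-in faces a specific
hazard: the restored long homopolymer is exactly as slippage-prone as
the original, so the correction can re-mutate.

The design idea implemented here is to correct the frameshift with an
insertion of a *different* base placed so that (1) the reading frame is
restored, (2) every affected codon switches to a synonymous codon, so
the protein is exactly wild-type, and (3) the long run is divided into
two shorter runs, each more stable against slippage. For a lysine tract
this works because AAA and AAG both encode lysine: inserting one G at
c.4464 into the truncated (A)8 tract yields (A)5-G-(A)3, wild-type
protein, and no run longer than five bases.

## The design procedure

`find_coding_repeats()` reports maximal single-base runs in the CDS
(default minimum length 6 — prominent clinical targets are (A)8/(A)9,
but tumor-mutated coding repeat lists extend shorter). Coordinates are
HGVS c. (1-based, c.1 = first base of the start codon); variants inside
runs are 3'-anchored by `normalize_3prime()`, the standard HGVS
convention, so the fixture's deletion is always written c.4467delA no
matter where in the run the slippage "really" occurred.

`enumerate_stabilizing_edits()` is deliberately exhaustive rather than
clever: every insertion of the deleted length (1–2 nt) at every
position in a window extending 3 nt beyond the run is applied to the
mutant sequence and kept only if the full re-translation equals the
wild-type protein and the longest residual run is shorter than the
wild-type run. Full re-translation (rather than reasoning codon-wise)
automatically captures designs that exploit degeneracy in run-flanking
codons, and the 3-nt window pad is what makes those flanking-codon
designs reachable. Candidates producing identical edited sequences are
deduplicated; the reported coordinate is the position the inserted base
occupies in the corrected sequence, preferring a position inside the
run (3'-most) when placements are equivalent — this reproduces the
field's labeling of such edits (e.g. "c.4464insG").

`rank_edits()` orders candidates by (longest residual run, |5' − 3'
run imbalance|, 5'-most coordinate). The stability objective only says
"shorter runs are more stable"; the tie-breaks are this package's
choice. On the (A)9 worked example the key uniquely ranks the 5+3
split (c.4464) above 2+6 (c.4461) and 8+0 (c.4467), matching the
design actually built in the experiment this models. All candidates
stay in the output so an alternative policy can be audited.

`assess_amenability()` folds the sequence-level result together with
construct-level feasibility into a verdict with separable reason codes
(`NO_SYNONYMOUS_SPLIT`, `RUN_BELOW_THRESHOLD`, `AMBIGUOUS_SEQUENCE`,
`ARM_DESIGN_FAIL`), mirroring how a design pipeline triages candidate
repeats. Ambiguity handling is strict: `N` bases are tolerated in the
genomic context but refused inside the repeat window, because a single
uncertain base there invalidates both the translation proof and the
residual-run arithmetic.

## Targeting-construct model

The construct layout is `HA1 – loxP – SA·IRES·Neo·polyA – loxP – HA2`,
with HA1 carrying the corrected (split-repeat) allele. Defaults:
1,000-nt arms (accepted 800–1,300), a 2.4-kb cassette, 4.7-kb rAAV
payload capacity. The cassette interior is an opaque deterministic
placeholder — only its length and the loxP geometry enter any
computation; no claim is made about a real selection cassette's
sequence. The cassette junction sits 30 nt (configurable) 3' of the
repeat: placing it immediately at the run would force the HA1-terminal
primer to bind inside the homopolymer, which is unworkable;
`design_construct_arms()` additionally sweeps arm lengths and junction
offsets within their configured ranges until both arm termini admit
primers, which is how construct boundaries are chosen in practice.

Primer cores (15–35 nt) must satisfy a 57–63 °C melting window and
35–65% GC. The Tm window is motivated by the touchdown-PCR style
protocols used for such screens; it is a configuration default, not a
measured constant. Tm is computed with the unified nearest-neighbor
thermodynamic parameters (SantaLucia 1998) with the `0.368·(N−1)·ln[Na+]`
entropy salt correction, at 50 mM Na+ and 500 nM oligo; the model name
and conditions are attached to every Tm value so reports are
self-describing. Gateway attB1/attB2 (HA1 → pDONR P1-P2) and
attB3/attB4 (HA2 → pDONR P3-P4) tails are the standard published site
sequences and are override-able.

Screening follows the knock-in genotyping logic: junction assays pair a
primer *outside* each homology arm with one inside the cassette (bands
only on targeted alleles), a wild-type assay spans the junction inside
the arms (band on the untargeted allele), the post-Cre assay's band
shrinks by exactly cassette length minus one 34-nt loxP scar, and an
RT assay spans the inserted base on cDNA. Expected sizes come from
exact-match in-silico PCR on parental / targeted / post-Cre / cDNA
templates. The cDNA template appends up to 300 nt of downstream context
to the CDS as a 3'-UTR stand-in, since a repeat near the stop codon
otherwise leaves no room for a downstream primer. Genome-wide primer
specificity is out of scope (there is no genome index here); cores are
only guaranteed unique on the supplied templates.

## Validation statistics

**Relative expression.** `relative_quantity()` implements ΔΔCt with
multiple reference genes combined by the arithmetic mean of their mean
Cts — equivalently the geometric mean of their linear quantities, the
usual multi-reference convention. RQ bounds propagate replicate spread
as `2^−(ΔΔCt ± s)` with `s` the combined standard error of the sample's
target and reference means; single replicates collapse the bounds onto
the point estimate. A global Ct shift cancels exactly; a shift applied
to only one gene does not, and is not claimed to.

**Cross-clone intersection.** `clone_intersection()` uses inclusive
thresholds (fold ≥ 1.5 up, ≤ 1/1.5 down, default threshold 1.5) and
requires concordance in *all* clones. Display rounding never feeds
decisions.

**Gene-set overlap.** `hypergeometric_overlap()` computes the upper
tail P(X ≥ k) for k of n query genes falling in a K-gene set within an
N-gene universe. N is a required argument with no default: published
overlap tables often omit the universe and mapped-query sizes, which
makes their P values qualitatively but not numerically reproducible —
so the package treats the q-from-p computation as the reproducible
surface. `bh_adjust()` takes the family size m explicitly (m = 50 for
the hallmark collection) because tabulated results often show only the
top few of m tests; the step-up minimum over a truncated ascending list
is exact whenever the unobserved p-values are too large to enter any
minimum, which holds for the bundled `prdm2_hallmark_overlaps()` rows.

**Peak summaries.** `peak_feature_summary()` classifies peaks by
any-bp overlap with priority exon > gene body > intergenic, computes a
strand-oriented TSS metaprofile from peak midpoints, and reports the
genic-fraction ratio versus a reference peak set. Intervals are 0-based
half-open internally; BED enters as-is and GFF3 is converted from
1-based inclusive by `rtracklayer`. "Exonic" and "splice-site"
enrichment are deliberately collapsed into one exon-overlap category;
a bp-resolved splice-site window is not modeled.

## Synthetic fixtures: what they emulate, and what they do not

The generators exist so that every computation above can be exercised
end-to-end with no external data, with planted truths returned for
exact scoring.

* `make_repeat_transcript()` builds a 1,500-codon CDS (4,503 nt with
  the stop) with the run's 3' base at c.4467 by default, i.e. codons
  1487–1489 = AAA AAA AAA, and 2-kb genomic flanks. Filler codons are
  drawn from the 27 A-free codons with T-weighted composition
  (P(T) = 0.5): A-free guarantees the planted run is the only A-run
  (so the worked example's candidate count is a theorem, not luck),
  and the T-weighting keeps the CDS near 50% GC so primer design
  behaves like real sequence. A fully deterministic `filler = "GGC"`
  variant exists but is ~100% GC and 3-periodic — useless for primer
  work, fine for coordinate tests. The stop codon is TGA, the only
  stop without an AA dinucleotide, keeping "no A-run ≥ 2 outside the
  planted run" exactly true. Filler homopolymers are capped at 4 nt.
* `make_expression_fixture()` plants concordant-up/-down genes with
  folds log-uniform in [1.6, 4] per clone, discordant genes strong in
  one clone only, and null genes bounded strictly inside the
  threshold, so recovery is exact by construction — this validates the
  intersection logic, *not* the noise robustness of any differential
  expression pipeline, which is out of scope.
* `make_peak_fixture()` lays out 100 non-overlapping genes on a 1-Mb
  chromosome (~25% genic), places reference peaks uniformly, and
  places test peaks genic with probability factor × (empirical genic
  fraction of the reference set), so the planted factor (default 3) is
  recovered up to binomial error (±10% comfortably at 2,000 peaks). A
  configurable fraction of genic peaks centers at TSSs (±150 nt
  jitter) to shape the metaprofile spike.
* `make_ct_fixture()` derives Ct from planted folds via
  Ct = baseline − log2(quantity) (+ optional Gaussian noise), with
  three flat reference genes; default planted folds 1.7/2.9/5.0 span
  the re-expression range reported for corrected clones.

What passing these tests shows is that the *computations* are correct
and invertible on data matching their assumptions. Real RNA-seq, ChIP
or qPCR data add alignment, normalization and biological variance that
the fixtures intentionally do not model.

## Numerical and scale choices

Problem sizes in the test-suite property sweeps were chosen to give
dense coverage while keeping the default run quick: 10,000 compact
random repeat fixtures (20–40 codons, runs of 6–10 of any base, d = 1
and d = 2 deletions) for the protein-identity/split invariants, 300
fixtures against the exhaustive enumeration oracle, exhaustive
hypergeometric checks at N ≤ 25, and 2,000-peak enrichment recovery.
Melting temperatures are deterministic; ties in ranking are broken by
coordinate so the order is total. Degenerate inputs (empty peak sets,
single replicates, empty candidate lists) return well-defined empty or
flagged results rather than errors; contract violations (unsorted
p-values, threshold ≤ 1, reference-base mismatches, N inside a repeat
window) are errors by design.

## Known limitations

Single contiguous CDS model (no exon maps or lift-over); deletions of
at most 2 nt; mononucleotide repeats only (no di-/tri-nucleotide
units); no quantitative slippage-rate model (the residual-run length is
a qualitative stability proxy); no primer specificity search,
secondary-structure or dimer screening; overlap-style gene-set testing
only (no ranked-list permutation GSEA).
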