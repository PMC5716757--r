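# repeatlock

Design toolkit for correcting frameshift mutations in **coding
mononucleotide repeats** while **stabilizing** the repaired tract, plus
the statistics used to validate edited clones.

## The problem

In mismatch-repair-deficient (MSI) tumors, slippage deletions in coding
homopolymers truncate proteins — the model case being the (A)9 lysine
tract of *PRDM2*, carrying c.4467delA in HCT116 colorectal cancer
cells. Correcting such a deletion by knock-in restores a long
homopolymer that is just as slippage-prone as the original, so the
correction is at risk of reverting. The approach implemented here
corrects the frame with a **synonymous, repeat-splitting insertion**:
insert a different base such that

1. the reading frame is restored (net insertion length = deletion length),
2. every affected codon becomes a synonymous codon — the protein is
   exactly wild-type (AAA → AAG, both Lys), and
3. the run is divided into two shorter, more stable runs.

For the (A)9/delA case the candidates are G insertions at the three
codon wobble positions; the package ranks the (A)5–G–(A)3 split
(c.4464insG) first, by the key (longest residual run, run imbalance,
5' coordinate).

The package covers the full path — repeat discovery, edit enumeration
by exhaustive re-translation, ranking, amenability verdicts, homology
arms, Gateway attB-tailed primers (nearest-neighbor Tm model),
targeting-construct GenBank output, in-silico-PCR screening assays —
and the clone-validation statistics: ΔΔCt relative expression with
multiple reference genes, strict all-clone 1.5-fold intersection,
hypergeometric gene-set overlap with Benjamini–Hochberg adjustment
over an explicit family size, and ChIP peak genic/TSS enrichment
summaries. Deterministic fixture generators emulate every input.

## Worked example

```r
library(repeatlock)

fx <- make_repeat_transcript(seed = 1)   # (A)9 tract ending at c.4467
t  <- fx$transcript
r  <- find_coding_repeats(t, min_len = 8)
r
#>   base start_c end_c length frame_offset codon_start codon_end
#> 1    A    4459  4467      9            0        1487      1489

m <- parse_hgvs_c("c.4467delA")
ranked <- rank_edits(enumerate_stabilizing_edits(t, r[1, ], m))
ranked[, c("hgvs", "five_run", "three_run", "longest_residual")]
#>         hgvs five_run three_run longest_residual
#> 1 c.4464insG        5         3                5
#> 2 c.4461insG        2         6                6
#> 3 c.4467insG        8         0                8
```

Exactly three single-G insertions restore the wild-type protein and
split the run; the top-ranked design places G at c.4464, leaving
(A)5-G-(A)3 — no run longer than five bases, a reduction of 4 from the
wild-type (A)9. `assess_amenability()` confirms a construct can be
built (`amenable: TRUE, reasons: OK`), and
`design_construct_arms()` → `targeting_construct()` →
`design_screening_assays()` produce the arm primers and the expected
genotyping bands (junction assays amplify only on the targeted allele;
the post-Cre band shrinks by cassette length − 34-nt loxP scar = 2,366 nt).

The published hallmark-overlap FDRs are reproduced from their P values
with an explicit family of 50:

```r
tab <- prdm2_hallmark_overlaps()
bh_adjust(tab$p[tab$condition == "normal"], family_size = 50)
#> [1] 0.0003833333 0.0003833333 0.0003833333 0.0005860000 0.0005860000
```

A command-line wrapper is installed at `inst/scripts/repeatlock`
(`scan`, `design`, `construct`, `validate-overlap`, `fixtures`
subcommands).

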