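# asodesignr

Design and screen analytics for antisense-oligomer (ASO) silencing of
bacteriophage genes.

Short antisense peptide nucleic acids (PNAs, typically 11-mers delivered by
a cell-penetrating peptide) silence a gene by base-pairing with the
translation initiation region (TIR) of its mRNA — the Shine–Dalgarno (SD)
sequence and start codon — so the ribosome cannot initiate. Tiling such
oligomers across the genes of a phage turns them into a functional-genomics
screen: knockdowns that suppress plaque formation flag genes essential for
propagation, even in phage–host pairs that resist genetic manipulation.
`asodesignr` implements the computations around such a screen, for
microbiologists and phage biologists who need designs and read-outs, and
for computational people who want every scoring rule explicit and testable.

## What it computes

* **TIR extraction** — `read_genome()` (FASTA+GFF3 or GenBank),
  `extract_tir()`. mRNA offsets are zeroless: +1 is the A of AUG, −1 the
  base 5′ of it, so a −37..+44 window spans 81 nt. Minus-strand genes are
  reverse-complemented; windows clipped at contig ends are flagged.
* **Candidate design** — `design_asos()` enumerates one candidate per start
  position, scores each, and filters on:
  * predicted PNA/DNA melting temperature, 45–55 °C. Two-stage model:
    nearest-neighbor DNA/DNA duplex sum (unified parameters, entropy salt
    correction), then the linear PNA correction
    *T*<sub>m</sub><sup>PNA</sup> = 20.79 + 0.83 *T*<sub>m</sub><sup>NN</sup> − 26.13 *f*<sub>pyr</sub> + 0.44 *L*,
    every coefficient held in a swappable `tm_model()`;
  * purine fraction of the oligomer, 25–35 % (anti-SD oligomers are
    pyrimidine-rich);
  * self-complementarity ≤ 5 nt (longest internal reverse-complementary
    match, exact);
  * fewer than 3 off-target TIRs within the criterion mismatch level
    (counts at 0–4 mismatches always reported).
* **Off-target scan** — `hamming_sites()`, `count_offtargets()`: minimum
  ungapped Hamming distance of the target site over every position of every
  other TIR (phage and optionally host), distinct-TIR counting, C kernel
  plus a pigeonhole-seeded accelerator that provably returns the same hits.
* **Tiling & controls** — `tile_window()` (unfiltered scored tiling of a
  wide window), `make_mismatch_control()` (central transversion mismatches,
  e.g. positions 5 and 7 of an 11-mer for *k* = 2).
* **Screen read-outs** — `titer_from_spots()` (serial-dilution spot counts
  → CFU/PFU per ml, pooled Poisson estimator, detection-limit censoring),
  `analyze_screen()` (log10 titer reduction → ordinal categories
  `-`/none/`+`/`++`/`+++`), `classify_temporal()` (early vs middle/late
  transcripts from log2FC > 2 or < −2 at −log10 adjusted P > 10),
  `knockdown_profile_matrix()`.
* **Synthetic truth** — `synth_genome()`, `synth_screen_table()`,
  `synth_expression_table()`: seeded generators with known ground truth
  that the whole pipeline is validated against.
* **Homology utility** — `percent_identity()`: global protein alignment
  percent identity with explicit denominator conventions.

Results are tibbles; fitted-result objects support `tidy()`, `glance()` and
`autoplot()`. A thin command-line front end is installed at
`system.file("cli", "aso.R", package = "asodesignr")`.

## A worked example

```r
library(asodesignr)

sg <- synth_genome(synth_spec(n_genes = 8, seed = 42))
design <- design_asos(sg$genome)
glance(design)
#> # A tibble: 1 × 10
#>   genome           n_genes n_candidates n_passing n_under_designed tm_min tm_max …
#> 1 SYNGENOME_seed42       8          280        41                1     45     55
```

280 candidates = 8 genes × 35 start positions of an 11-mer in the default
−30..+15 window (45 nt); 41 pass all four filters; one gene has fewer than
two passing oligomers and is flagged under-designed. The top passing
candidates for the first gene:

```r
d <- tidy(design)
head(d[d$passes, c("gene","site_from","site_to","aso_seq","tm_c",
                   "purine_frac","selfcomp","cum_mm2","rank")], 3)
#>   gene     site_from site_to aso_seq      tm_c purine_frac selfcomp cum_mm2 rank
#> 1 SYNG0001       -22     -12 CTGATGCCTCC  50.3       0.273        2       0    1
#> 2 SYNG0001       -16      -6 ACCCTCCTGAT  51.3       0.273        2       0    2
#> 3 SYNG0001       -18      -8 CCTCCTGATGC  52.0       0.273        2       0    3
```

Each `aso_seq` is the reverse complement of its mRNA target site
(`site_from`..`site_to` in mRNA offsets), within the Tm band, purine-poor
(3/11), with no off-target TIR within 2 mismatches. A matched negative
control two central mismatches away:

```r
make_mismatch_control("CACCTCCTATG", k = 2)
#> [1] "CACCACATATG"
```

Screen read-out from simulated spot counts with planted effects of 4.5 and
0 logs:

```r
plant <- tibble::tibble(gene = c("g1", "g2"), delta_log10 = c(4.5, 0))
analyze_screen(synth_screen_table(plant, seed = 7))
#>   gene  aso_id  delta_log10_pfu delta_log10_cfu category censored
#> 1 g1    g1_aso1          4.35                NA +++      FALSE
#> 2 g2    g2_aso1          0.0371              NA none     FALSE
```

A 4.35-log measured PFU reduction is called `+++` (very effective), the
null gene `none`.

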