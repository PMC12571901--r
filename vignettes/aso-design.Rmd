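---
title: "Designing antisense oligomers for phage gene silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing antisense oligomers for phage gene silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asodesignr)
```

## The problem

Short antisense oligomers (ASOs) -- typically 11-mer peptide nucleic acids
(PNAs) conjugated to a cell-penetrating peptide -- silence a bacterial or
bacteriophage gene by base-pairing with the translation initiation region
(TIR) of its mRNA, occluding the Shine--Dalgarno (SD) sequence and start
codon so that the ribosome cannot initiate. Because silencing acts on the
mRNA, it works in phage--host systems that are genetically intractable, and
a panel of ASOs tiled across the genes of a phage constitutes a functional
genomics screen: knockdowns that suppress plaque formation identify genes
essential for propagation.

`asodesignr` implements the computational side of such a screen:

1. extraction of strand-corrected TIR windows from annotated genomes
   (`read_genome()`, `extract_tir()`);
2. enumeration, scoring, filtering and ranking of candidate antisense
   sequences (`design_asos()`, `tile_window()`, `make_mismatch_control()`);
3. mismatch-tolerant off-target counting across all TIRs of the phage and
   host (`hamming_sites()`, `count_offtargets()`);
4. screen read-outs: serial-dilution spot counts to CFU/PFU titers and
   ordinal effect categories (`analyze_screen()`), and early vs middle/late
   transcript classification from differential-expression tables
   (`classify_temporal()`);
5. seeded synthetic genomes, spot-count tables and expression tables with
   known ground truth (`synth_genome()` and friends), which every other
   module is validated against.

## Coordinates

All mRNA offsets use the zeroless convention common in SD notation: +1 is
the A of the AUG start codon, -1 the base immediately 5' of it, and there
is no position 0. A window written $-37..+44$ therefore spans $37 + 44 = 81$
nt. Minus-strand genes are reverse-complemented during extraction so that
every TIR window reads 5'$\to$3' along the mRNA; annotations are 1-based
inclusive, and on the minus strand the start codon begins at the feature's
`end` coordinate and runs inward. Genomes are treated as linear: windows
running off a contig end are clipped and flagged `truncated` rather than
wrapped, since the reference annotations these tools consume are linear
records.

## The design filter

For each candidate site the package scores:

* **Melting temperature.** The PNA/DNA duplex $T_m$ is predicted in two
  stages. First a nearest-neighbor sum for the corresponding DNA/DNA duplex
  using the unified thermodynamic parameter set (Allawi & SantaLucia 1997),
  with terminal A/T and G/C initiation terms, the SantaLucia (1998) entropy
  salt correction at 50 mM monovalent cation, and a duplex transition
  concentration of 0.5 mM per strand -- the millimolar stock regime in
  which synthetic PNAs are standardized. Then the linear PNA correction of
  Giesen et al. (1998):
  $$T_m^{PNA} = 20.79 + 0.83\,T_m^{NN} - 26.13\,f_{pyr} + 0.44\,L,$$
  where $f_{pyr}$ is the pyrimidine fraction of the PNA strand and $L$ its
  length. All coefficients live in a `tm_model()` object recorded with the
  configuration, so alternative parameterizations are swappable; values are
  reported to 0.1 degC. Note the correction is strand-specific: the duplex
  term is symmetric in the two strands, but $f_{pyr}$ belongs to the
  oligomer. Mismatched-duplex thermodynamics are out of scope. The default
  acceptance band is 45--55 degC; empirically, tiled ASOs binding near the
  SD with $T_m$ roughly 35--58 degC inhibit translation, so the band is a
  conservative centre of that range.

* **Purine fraction.** Accepted oligomers have 25--35% purines. The
  fraction is scored on the oligomer itself (not the target): the SD region
  is purine-rich, so an effective anti-SD oligomer is pyrimidine-rich. This
  choice is deliberate and documented because "purine percentage" is
  ambiguous between the two complementary strands. A purine-rich oligomer
  also tends to aggregate, which is the practical reason for the bound.

* **Self-complementarity.** The length of the longest substring whose
  reverse complement also occurs in the oligomer (at least 2 nt, possibly
  overlapping), i.e. the longest internal self-pairing; equivalently the
  longest common substring between the sequence and its reverse complement,
  computed exactly by dynamic programming. Default tolerance is 5 nt; the
  source criterion ("low self-complementarity") names no number, so the
  threshold is configurable.

* **Off-targets.** For every other TIR in the phage (and optionally the
  host), the minimum ungapped Hamming distance of the candidate's target
  site over all positions of that TIR. Each TIR counts once, at its
  minimum distance. A candidate passes if fewer than 3 distinct off-target
  TIRs lie within the criterion mismatch level. Counts at 0..4 mismatches
  are always reported, but the "< 3" rule is applied at <= 2 mismatches by
  default rather than at the full 4-mismatch search depth: for an 11-mer
  the per-window chance-hit probability at <= 4 mismatches is
  $\sum_{k \le 4}\binom{11}{k}3^k/4^{11} \approx 7.6\times10^{-3}$, which
  across a few hundred 46-nt TIRs yields tens of chance hits and would fail
  every candidate, whereas at <= 2 mismatches the expectation is below 2
  and the criterion discriminates. The level is configurable
  (`offtarget_criterion_mm`).

Candidates that pass all bounds are ranked within each gene by a stable,
documented composite: fewest off-target TIRs at the criterion level, then
smallest $|T_m - 50|$, then smallest distance of the site centre from the
start-codon junction, then 5'-most site, then sequence -- so identical
inputs always produce byte-identical output tables. Genes with fewer than
two passing candidates (`min_asos_per_gene`) are flagged under-designed
rather than silently accepted, since screens test at least two independent
oligomers per gene to control for off-target artefacts.

Sites containing `N` are flagged and excluded from design by default.

## Tiling and mismatch controls

`tile_window()` enumerates one scored candidate per start position across a
wide window (default $-37..+44$, 81 nt, 71 candidates) without filtering --
tiling sets are for empirical testing of position effects, not selection.
`make_mismatch_control()` derives a negative control at Hamming distance
exactly $k$ from an oligomer, with substitutions placed maximally centrally
(central mismatches abolish antisense activity): odd $k$ takes the centre
base and adjacent flanks; even $k$ leaves the centre base paired and fills
outward symmetrically, so $k = 2$ on an 11-mer substitutes positions 5 and
7. Substitutions are transversions, which can neither Watson--Crick nor
wobble pair with the target base at that position.

## Off-target search

`hamming_sites()` is defined by the sliding ungapped comparison (implemented
in C); a pigeonhole-seeded accelerator (`method = "seed"`: any window within
$k$ mismatches must contain one of $k+1$ exact query chunks) returns the
identical hit set and is cross-checked against both the sliding scan and an
independent library implementation in the tests. Indels are deliberately
out of scope -- the mismatch tolerance of a PNA duplex is positional, not
gapped -- which keeps an exact brute-force oracle feasible. The search
space is TIR windows only by default, matching the specificity criterion;
host TIRs are included when a host genome is supplied, a conservative
in-silico extra given that host specificity is ultimately verified
empirically.

## Screen read-outs

`titer_from_spots()` converts serial-dilution spot counts (default 5 ul
spots, countable range 3--100) into titers. The default estimator is the
Poisson maximum-likelihood titer pooled over the informative tail of the
series: the sum of counts at all dilutions from the least dilute countable
spot outward (saturated spots excluded), divided by the summed effective
volume. The classical single-spot reading (most dilute countable spot) is
available as `method = "single"`; both are unbiased on the log scale to
first order, but the pooled estimate's variance is what makes a 0.2-log10
effect margin resolvable at the >= 95% level in the recovery tests below.
Series with zero counts everywhere are censored at the detection limit (one
unit in the least dilute spot) and the censoring propagates into the effect
call as a bound. A series with no countable spot that is not fully below
detection is an explicit ambiguity error, not a guess.

`effect_category()` maps the log10 titer reduction
$\Delta = \log_{10}(\text{control}) - \log_{10}(\text{targeting})$ onto the
ordinal labels used in screen summary tables: none below 1 log; `+` from 1;
`++` from 2; `+++` from 4 (or a censored bound of at least 4); `-` at or
below $-1$ (increased titer). The labels themselves come from screen
practice; the numeric cut-offs are this package's choice, consistent with
"multiple logs" vs "two to three orders of magnitude" phrasing, and fully
configurable. Categorization uses the PFU delta; the CFU delta is reported
alongside. A planted effect lying exactly on a cut-off is unrecoverable at
better than chance under noise, so simulation studies should plant effects
inside category bands.

`classify_temporal()` applies the published enrichment thresholds for the
late-vs-early contrast (35 vs 10 min post infection): `middle_late` if
$\log_2 FC > 2$ and $-\log_{10} p_{adj} > 10$, `early` if
$\log_2 FC < -2$ at the same significance, otherwise `unclassified` --
three disjoint, exhaustive classes. `knockdown_profile_matrix()` assembles
per-knockdown fold-change tables into a dense gene-by-knockdown matrix for
external clustering (genes missing from more than 20% of knockdowns are
dropped, remaining gaps imputed as 0); embedding methods themselves are out
of scope.

## What the synthetic generators emulate

`synth_genome()` emulates the *layout* of an annotated phage genome: CDS on
alternating strands, each led by the canonical SD motif `AGGAGG` whose last
base sits at offset $-8$ (a 7-nt spacer, canonical anti-SD spacing), in
uniform random background at a chosen GC content, with truth tables
recording every planted TIR. It does not emulate codon usage, operon
structure, overlapping genes, or a temporal expression program, so passing
recovery tests demonstrates correctness of the extraction/design machinery,
not performance on real genomes. One consequence of uniform background is
worth stating: the planted SD guarantees 6 pyrimidines in an 11-mer
antisense centred on it, but each of the 5 flanking antisense bases is a
purine with probability 1/2 regardless of GC, so the low-purine filter
(< 0.35) passes for such oligomers with probability
$P(\mathrm{Binom}(5, 1/2) \le 3) = 0.8125$ -- strongly enriched over the
~11% chance rate, but not near-certain as it is in real SD contexts, where
flanking composition is not uniform.

`synth_screen_table()` draws Poisson spot counts around planted titers;
`synth_expression_table()` draws class-conditional fold changes
(means $\mp 4$, sd 0.5) with adjusted P values on the appropriate side of
the $10^{-10}$ significance line. At these defaults, category recovery for
planted effects of 0, 1.5, 2.5, 4.5 and $-1.2$ logs exceeds 95% over 200
replicates, and temporal-class recovery exceeds 99% over 1,000 genes; both
are recomputed by `scripts/acceptance.R` and asserted in the test suite.
Problem sizes throughout (20--370 synthetic genes, 200 replicates, 1,000
genes) match the scale of the real screen -- a 370-odd-gene jumbo phage
and a 75-gene knockdown panel -- while keeping the full validation suite
fast on a laptop.

## Numerical and degenerate-input choices

* Ties in ranking are broken by explicit keys down to the sequence string;
  output tables are byte-stable.
* `N` bases are allowed in genomes; windows containing them are excluded
  from design and never match in the off-target scan (an `N` position
  always counts as a mismatch).
* Joined (multi-exon) CDS locations are collapsed to their outer span and
  flagged `joined` with a warning -- introns in phage genes are a known
  annotation hazard, and resolving them is explicitly not attempted.
* Offsets of 0 are rejected rather than silently shifted.
* Censored titers carry their bound; the effect category at a bound below
  the `+++` cut-off is flagged `censored` rather than asserted.
* Global protein percent identity reports three denominator conventions
  (`pid` over all aligned columns including gaps, `pid_ungapped`,
  `pid_shorter`) because "percent identity" is convention-sensitive; the
  alignment is end-to-end under BLOSUM62 with affine gaps (open 10,
  extend 0.5).

## Known limitations

* The $T_m$ model is a regression, not a measurement; its absolute scale
  depends on the assumed strand concentration, and the 45--55 degC band
  should be recalibrated if a different `tm_model()` is configured.
* Off-target counting is purely sequence-based (ungapped Hamming distance
  within TIR windows); no thermodynamic weighting, no RNA structure, no
  proteome-level specificity.
* Chemistry is out of scope: the package designs base sequences only -- no
  carrier-peptide design, solubility prediction, or toxicity modelling.
* The expression classifier consumes externally computed
  (log2 fold change, adjusted P) pairs; differential-expression estimation
  itself is not reimplemented here.

## A worked example

```{r example}
sg <- synth_genome(synth_spec(n_genes = 8, seed = 42))
design <- suppressWarnings(design_asos(sg$genome))
glance(design)
head(tidy(design)[, c("gene", "site_from", "site_to", "aso_seq", "tm_c",
                      "purine_frac", "selfcomp", "cum_mm2", "passes",
                      "rank")])
```

```{r screen}
plant <- tibble::tibble(gene = c("g1", "g2"), delta_log10 = c(4.5, 0))
spots <- synth_screen_table(plant, seed = 7)
analyze_screen(spots)
```
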