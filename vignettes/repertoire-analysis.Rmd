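---
title: "Characterizing immunoglobulin repertoires under a 2x2x2 factorial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing immunoglobulin repertoires under a 2x2x2 factorial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igfactorial)
```

## The problem

Bulk RNA-seq of splenic tissue captures the expressed antibody repertoire:
each annotated transcript carries germline V, (D) and J gene-segment calls,
a constant-region (isotype) call, and the CDR3 junction — the hypervariable
loop that dominates antigen binding. `igfactorial` quantifies how a 2x2x2
treatment design — antiorthostatic suspension (AOS, a hindlimb-unloading
model of spaceflight physiology), tetanus toxoid (TT, a vaccine antigen)
and CpG oligodeoxynucleotide (a TLR9 adjuvant) — shifts that repertoire:
which gene segments are used, how V/(D)/J segments pair, which isotypes
dominate, and how much of the CDR3 clonotype pool is shared between
treatment groups.

The package operates on AIRR Rearrangement TSVs (one per animal) plus a
design table mapping each animal to its `(AOS, TT, CpG)` cell. Because the
original sequencing data is not required, a seeded simulator generates
annotated cohorts with configurable effects, making every analysis stage
testable end to end.

## Record-level rules

**Functionality.** A record is *productive* when it is in frame, free of
stop codons, and carries a junction; *unknown* when frame or stop evidence
is missing or no junction was resolved (typically short reads);
*unproductive* otherwise. The tri-state `vj_in_frame`/`stop_codon` fields
(logical with `NA` = unknown) make the unknown class representable without
sequence-level reasoning.

**Junction motif.** Heavy-chain junctions must show the conserved C...W
anchors, *or* the record must be class-switched — an identifiable switched
constant region is accepted in place of the W anchor. Kappa junctions must
show C...F. Lambda records are parsed but excluded from analyses (they are
about five percent of light-chain reads).

**Class switching.** Heavy-chain records whose constant region is IgG1,
IgG2b, IgG2c, IgG3, IgA or IgE. We treat all non-IgM/IgD heavy isotypes as
switched and aggregate IgG subclasses into "IgG" at the report layer; the
isotype-usage denominator is records with an identifiable constant region.

**Fractional abundance.** A record with exactly one candidate gene
contributes 1.0 to that gene; two candidates contribute 0.5 each;
three or more (or none) contribute nothing. Percentages divide by the
total assigned weight per animal on that axis, so rows sum to 100; this
also means >2-ambiguous records leave numerator *and* denominator. Usage
is computed on productive + unknown records by default (mirroring total
assessed reads); `functionality = "productive"` restricts it.

**Undetermined segments.** For pairing (and the D/J usage axes), a D or J
segment is "U" when it was not reported, when multiple candidate genes
were reported, or — D only — when the alignment spans fewer than six
nucleotides. The length rule targets spurious short D matches; J alignments
are long and no J alignment length is carried in the data model, so the
rule is deliberately D-only. Pairing itself is restricted to productive
records with a single identified V gene; the V side is never "U".

**High-frequency segments** are features whose group-mean percent strictly
exceeds 5% in at least one focus group ("over five percent" read
literally, so a tie at exactly 5% is excluded).

**Low-frequency pair filter.** V/J pairs are dropped from factor-level
comparisons only when *every* compared level sits below 0.1% of the
repertoire; one level at or above the threshold keeps the pair.

## Statistics

Per feature, the percent of repertoire is modeled as
`y ~ AOS * TT * CpG` and the full-factorial ANOVA table is reported. On
the balanced designs this package targets, sequential sums of squares
coincide with marginal ones, so factor order is irrelevant (a tested
invariant). Zero-variance responses are flagged degenerate with p = 1.
Per-feature tests are *not* corrected across features, matching the
per-segment reporting convention; a Benjamini–Hochberg option exists but
is off by default. ANOVA is run on raw percentages without a
compositional transform — a documented limitation: usage percentages are
compositional, and strong effects on one gene necessarily perturb others.

Post-hoc contrasts use Tukey's HSD on a cell-means model. Because cell
labels are strings of `+`/`-`, contrasts are computed on safe internal
labels and reported as `"cellA vs cellB"`.

The per-animal variance statistic is the sum over features of
`(percent per animal - mean percent)^2`; whole-animal variation is
compared across cells by a least-squares-means analysis: marginal means of
a cell-means linear model with Tukey-adjusted pairwise contrasts. This is
the closest transparent analogue of the SAS LS-means procedure the field
uses; the adjustment method there is unstated, so Tukey was adopted and is
noted here.

The marker screen compares mean TPM between a factor's levels with the
larger-over-smaller signed fold-change convention (`m+/m-` or `-(m-/m+)`,
so |FC| >= 1), and a Welch test on `log2(TPM + 1)`. The flag rule is
exactly |FC| > 2 AND p < 0.05 — the p-value engine is declared, not
claimed identical to any particular differential-expression tool.

## CDR3 sharing

Clonotype identity is the full junction amino-acid string within a locus.
Group sets pool all animals of a group *before* deduplication, so a CDR3
seen in three animals of one group counts once for that group — the
semantics required for shared-by-k tables. The shared-by-k percent
denominator is the union of unique CDR3s over all groups (this reading
reproduces published shared-pool percent columns to the printed 2
decimals, using half-up rounding). Pairwise overlaps report the
intersection and both per-side shares, since the two sides differ in size.
CDR3 length is the junction length minus the two anchor residues.

## The simulator: a stated world

`sim_config()` defaults encode the cohort the package emulates:

- **4 animals per treatment cell** (32 sequenced animals, two per
  suspension trial), full 2x2x2 factorial.
- **10^4 heavy reads per animal** by default. The emulated study assessed
  ~0.8–1.1x10^5 heavy reads per animal; scale is configurable and nothing
  asserts it. Kappa records are generated at 0.8 per heavy read, lambda at
  5% of light reads.
- **Usage baselines** follow a rank power-law so a handful of genes exceed
  5% of the repertoire; D and J weights make D1-1 the most common D and
  give kappa J4 reduced usage. Isotypes are IgM-dominated with ~8%
  unidentifiable constant regions.
- **Annotation noise**: 10% two-gene and 3% three-or-more-gene V calls,
  25% missing D, 10% short (<6 nt) D alignments, 5% ambiguous D, small
  missing/ambiguous J rates, 45% unknown-functionality reads (roughly half
  of assessed reads, as in the emulated cohort) and 5% unproductive reads
  split between frameshifts and stop codons. 2% of heavy junctions lose
  the trailing W, so they stay analyzable only through class switching.
- **Public/private CDR3 model**: junction cores are drawn from a finite
  shared pool with probability `p_public` (heavy 0.05, kappa 0.30; pool
  sizes 1000 and 300), else freshly generated. Core lengths are
  `max(2, Poisson(12))` for heavy and `max(2, Poisson(9))` for kappa,
  matching the reported mean CDR3 lengths of 12 and 9 AA. This minimal
  structure makes sharing tables and overlaps nontrivial, reproduces the
  qualitative heavy-private/kappa-shared asymmetry, and shared mass is
  monotone in `p_public` (a tested property). No generative model for
  publicness is claimed beyond that monotonicity.

Effects are multiplicative reweightings (`effect_spec(factor, target,
multiplier)`) applied to `+` animals and renormalized; multiplier 1 is the
null. The generator does **not** emulate somatic hypermutation, clonal
lineages, read-level sequencing error, or heavy/light pairing — so a green
simulation-based test establishes that the pipeline recovers injected
compositional and isotype effects at realistic noise levels, not that it
reproduces any dataset-specific biology.

Determinism: identical `(config, effects, seed)` gives byte-identical
AIRR output. Animals of a treatment cell share effect-adjusted weights, so
generation is vectorized per cell; weighted draws use inverse-CDF
sampling and junction cores are substrings of a long random string
(collision rate well under 1% at these scales).

## Numerical choices

- Percentages are exact ratios; only report-layer sharing percents are
  rounded, half-up to 2 decimals (`round_half_up`), matching printed
  tables rather than banker's rounding.
- Rank ties in top-k pairing tables break lexicographically by (v, d, j)
  and are flagged, so heat maps are reproducible.
- Animals with zero assigned weight (or zero resolvable pairings) are
  excluded with a warning rather than producing NaN rows.
- Degenerate ANOVA responses report p = 1; an empty treatment cell is an
  error naming the cell.

## Worked example

```{r, eval = FALSE}
design <- sim_design(n_per_group = 4)
cfg <- sim_config(reads_per_animal = 2000, seed = 7)
effects <- list(effect_spec("CpG", "IgA", 1.8))
records <- simulate_repertoires(design, cfg, effects)

usage <- usage_table(records, axis = "V", locus = "IGH")
usage_anova(usage, design)

iso <- group_mean_usage(constant_usage(records), design, by = "CpG")
sharing_table(build_cdr3_sets(records, design, "cell", locus = "IGH"))
```

The same sequence, file-based, is available through `run_simulate()`,
`run_analyze()` and `run_report()` with a YAML/JSON config, or the
`inst/scripts/igfactorial-pipeline.R` command-line wrapper.

## Known limitations

- Compositional responses are analyzed untransformed (see above).
- Clonal deduplication is deliberately absent: counting is one record per
  sequence ID, so expression level and clone size are confounded — a
  property of the emulated protocol, not a bug.
- The simulator's i.i.d. records understate between-animal biological
  variance; type-I calibration of the ANOVA is exact under this null but
  real data would carry extra-multinomial dispersion.
- TT-specificity is never inferred; class-switched subsetting is the only
  proxy offered.
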