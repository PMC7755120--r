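---
title: "Screening mitochondrial tRNA variants: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mitochondrial tRNA variants: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtscreen)
```

## The screening problem

Human mtDNA carries 22 tRNA genes, and point substitutions in them are a
recurrent cause of maternally inherited disease.  Given a set of mtDNA
substitutions (and single-base deletions) observed in a patient cohort,
`mtscreen` separates *putative pathogenic mutations* from *polymorphisms*
with the three-criterion screen that is standard in the mt-tRNA
literature:

1. **Evolutionary conservation.**  The conservation index (CI) of the
   affected position — the percentage of aligned vertebrate species whose
   nucleotide matches the human one — must strictly exceed 75%.
2. **Rarity in controls.**  The variant must be absent from (default
   policy) or carried by fewer than 1% of control subjects.
3. **Structural or functional impact.**  The base change must be
   predicted to alter the tRNA cloverleaf: disrupt (or create) a
   Watson–Crick stem pair, or fall on a tertiary-interaction or otherwise
   functional position of a loop, junction, or the acceptor terminus.

Conserved variants that fail only the rarity bar form a middle tier
(`rare_conserved_variant`); everything not conserved, or common in
controls, is a `polymorphism`.

## The cloverleaf model

The screen needs, for every rCRS coordinate, the gene, the strand, the
conventional cloverleaf position label, the structural element, the
Watson–Crick stem partner and the partner's reference base.  These live
in a packaged, human-editable definition (`mt_trna_genes.tsv` and
`mt_trna_structure_synthetic.tsv` under `extdata`), validated on load:
complete 22-gene set, non-overlapping spans, injective position
numbering, symmetric/involutive pairing confined to stem elements, and
stems fully paired (hence of even size).

Design choices worth knowing:

* **Coordinates** are rCRS (NC_012920.1), 1-based inclusive; variants are
  written `m.POS REF>ALT` with heavy-strand alleles.  Eight genes
  (MT-TQ, MT-TA, MT-TN, MT-TC, MT-TY, MT-TS1, MT-TE, MT-TP) are
  light-strand encoded; their tRNA-level bases are complements of the
  reported alleles, with T rendered as U.  The strand set is data in the
  gene table, not code.
* **Conventional numbering** (1–73 with insertion labels such as `27a`)
  is stored as opaque labels with a numeric sort key.  We make no attempt
  to recompute canonical numbering from sequence: mt-tRNAs deviate from
  the cytosolic consensus, and published variant tables treat the
  numbering as given.  Per-gene label sets were curated so that every
  position/element assignment in the packaged cohort table is reproduced
  (see *Known data discrepancies*).
* **Two annotation overlaps** in the standard rCRS gene annotation
  (MT-TI/MT-TQ at 4329–4331, MT-TC/MT-TY at 5826) were resolved by
  trimming MT-TI to 4263–4328 and starting MT-TY at 5827, since the
  package requires unambiguous gene assignment.  No variant in the
  packaged table falls in the trimmed bases.
* **Reference bases.**  Positions constrained by the packaged cohort
  table (variant reference alleles and printed stem pairs) carry exact
  bases; the remaining bases are seeded synthetic placeholders,
  WC-consistent inside stems — hence the `_synthetic` suffix on the file.
  They matter only for rendering and for generator output, never for the
  classification of real input, which carries its own alleles.
* **Tertiary interactions** (8–14, 18–55, 19–56, 26–44, 54–58, 15–48
  where both ends exist in a gene) are a separate table, distinct from
  stem pairing; together with the functional-site list
  {8, 14, 18, 34, 37, 38, 55, 58, 73} (wobble position 34, anticodon
  flank 37/38, T-loop 55/58, discriminator 73, D-arm tertiary core) they
  drive the loop-impact rule.  The list is a user-overridable argument of
  `annotate_variants()`.

## Watson–Crick pairing calls

Canonical pairs are A-U and G-C only; **G·U wobble counts as non-WC**.
This is forced by the data the model reproduces: published calls mark
A→G opposite U as a disruption, which is only coherent if G·U does not
preserve the pair.  `wc_effect()` compares the canonical-pair status of
(ref, partner) against (alt, partner):

* WC before, non-WC after → `disrupts_pair`;
* non-WC before, WC after → `creates_pair`;
* otherwise `no_pair_change`; unpaired positions → `not_applicable`.

Pairs are reported `(variant base)-(partner base)`.  Published tables
print the same pair in either orientation, so golden tests compare the
unordered base pair plus the direction.  Deletions get no WC call; they
count as impactful only via stem placement or a tertiary/functional site.

## Conservation index

`conservation_index()` counts non-human species matching the human base
at the aligned column (uppercased, T/U-unified).  Published CI values do
not all sit on a 1/16 grid, suggesting variable denominators, so the
denominator is explicit: the default `non_gap` mode excludes species
gapped at the column; `all_species` counts them as mismatches.  CI is
kept as an exact double (a ratio of small integers); the threshold test
`is_conserved()` is a strict `>` on the unrounded value, so a CI of
exactly 75 fails.  When no alignment is supplied the pipeline accepts
per-variant CI values from the input table — that is how the packaged
cohort reproduction runs, since the original 16-species alignment
sequences are not redistributable here.

## Frequency classes and tiers

`frequency_class()` compares carrier counts to the cutoff by integer
cross-multiplication, so the 1% boundary is exact: with 485 controls,
counts 1–4 are `rare_below_1pct` and 5+ `common_1pct_or_more`; with 500
controls, 5 carriers are exactly 1% and therefore common.  The default
putative policy is `absent_only` — the tier narrative and the packaged
table's putative section (all control counts zero) define the tier that
way — while the broader "absent **or** rare" reading is available
explicitly as `policy = "rare_allowed"`, never silently.

Prevalence is the sum of per-variant case-carrier counts over the case
cohort size, under the documented assumption that no case carries two
putative variants (true of the packaged cohort, where 25 carriers of 18
variants are reported as 25 distinct subjects).

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without downloads, and
their defaults are the study conditions of the packaged screen:

* `synth_variants()` — 73 variants over 494 cases / 485 controls with an
  18/12/43 putative/rare-conserved/polymorphism mix.  Variants are placed
  on real model positions; putative placements in stems get an allele
  chosen to change pairing status, so the intended tier is recoverable by
  construction.  Screening its output recovers 100% of true tiers — an
  exact oracle for the decision logic, **not** evidence about real
  cohorts: the generator draws attributes directly from the tier
  definitions and does not simulate sequencing error, heteroplasmy,
  haplogroup structure, or ascertainment.
* `synth_alignment()` — a gapless 16-species alignment whose per-column
  CI hits requested targets exactly (targets must be multiples of
  100/n_species; anything else is rejected naming the position).
* `synth_cohort()` — subject records whose margins reproduce the
  published clinical summary exactly (403/494 male, onset bands
  129/334/31, diagnoses 146/134/214, symptom counts 415/246/234/131/140/26,
  prior medications 248/112/101/24/9) in `exact` mode, or binomially
  otherwise.  Symptoms are drawn independently; real symptom
  co-occurrence is not modelled.

All generators take a single integer seed; the same seed gives
byte-identical output.

## Known data discrepancies

The packaged cohort table is internally inconsistent in five places; the
model follows the structurally coherent reading and the golden tests
carry these as named exceptions rather than silently passing:

* m.14693A>G lists tRNA position "98", which does not exist in a
  cloverleaf; it is recorded as 54 (T-loop, adjacent to m.14692 at 55).
* m.15924/15927/15928 print location "ACC stem", but their own printed
  positions (39/42/43) and pairing partners (31/28/27) are anticodon-stem
  coordinates, and the putative-tier stem breakdown (1 AC / 5 ACC / 1 D /
  2 T) is only consistent with that reading.
* m.15932 prints position 47 with location "T-loop"; with 53 and 59 also
  in the T-loop a contiguous cloverleaf cannot place 47 there, so the
  model keeps it adjacent to the variable region.
* m.7492 (27a) and m.16000 (26) carry pairing arrows despite a printed
  junction location; the model keeps them unpaired, so the WC golden
  property covers the remaining 29 of 31 arrow rows.

Two cohort-level inconsistencies are reproduced as computed, not
adjudicated: the source reports the middle onset band as both 334 and
335, and the putative-carrier prevalence as 4.96%, 5.06% and 3.64% in
different places — the pipeline computes 25/494 = 5.06%.

## Problem sizes and numerical choices

The packaged reproduction is desk-scale (73 variants; seconds of CPU).
Property tests use 10,000 random coordinates for gene assignment, 1,000+
synthetic alignment columns for the CI oracle, and four seeds for
end-to-end tier recovery — sizes chosen to exercise every gene and
boundary while keeping the default test run fast.  Percentages are
reported to two decimals but all comparisons (CI threshold, frequency
cutoff) happen on exact values.  Ties cannot arise: both criteria are
strict inequalities on exact rationals.

## Limitations

* The structure model is a curated cloverleaf abstraction: it does not
  model modified nucleotides, alternative foldings, or free-energy
  effects, and positions not constrained by the packaged table carry
  synthetic reference bases.
* CI depends on the alignment supplied; with the packaged table the CI
  column is taken as given and only the threshold logic is recomputed.
* The screen is rule-based triage, not a pathogenicity proof; it
  performs no association statistics (none are applicable to carrier
  counts of this size) and no haplogroup or pedigree analysis.
* The "previously reported" flag is consumed from a catalog file, not
  computed against live databases.
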