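---
title: "Methods: variant classification and carrier-prevalence estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant classification and carrier-prevalence estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierprev)
```

## The problem

How common are carriers of pathogenic alleles in a hereditary cancer gene,
in populations where no dedicated case series exist? Large sequencing
aggregates (gnomAD-style exome collections, national reference panels such
as the Korean KOVA and KRGDB databases) publish per-population allele
counts for every observed variant. If one can decide *which* of those
variants are disease-causing, the carrier frequency follows from elementary
population genetics. `carrierprev` implements both halves of that argument
as a reusable pipeline, with the *PALB2* breast/ovarian/pancreatic cancer
susceptibility gene as its worked example.

## Classification model

Variants are classified into the five ACMG/AMP tiers (pathogenic, likely
pathogenic, uncertain significance, likely benign, benign) by assigning
evidence codes and combining them with the 2015 combining-criteria table.
Only evidence computable from a population database is auto-assigned:

* **PVS1** (loss of function), through a reduced ClinGen-SVI-style decision
  tree. Nonsense and frameshift variants are checked against the 50-nt
  nonsense-mediated-decay rule: a premature termination codon more than
  50 nt upstream of the last exon–exon junction is predicted to trigger NMD
  and earns *very strong*; NMD-escaping truncations are downgraded to
  *strong*. Canonical ±1/2 splice variants keep *very strong* when the
  SpliceAI Δ score supports spliceogenicity (Δ ≥ 0.2) or is unavailable,
  and are downgraded to *strong* otherwise. Initiation-codon variants earn
  *moderate*. In-frame exon-skipping rescue analysis is deliberately out of
  scope; the transcript model is a toy exon-length/CDS structure sufficient
  for the NMD rule.
* **PP3/BP4** (computational), calibrated from REVEL for missense variants
  using the Pejaver et al. (2022) interval estimates — pathogenic side
  ≥ 0.644 / 0.773 / 0.932 for supporting / moderate / strong, benign side
  ≤ 0.290 / 0.183 / 0.016 / 0.003 for supporting / moderate / strong /
  very strong — and from SpliceAI for non-canonical splice-region variants
  (supporting, on either side of the 0.2 threshold). Tier boundaries are
  inclusive on both sides: a score exactly at a cutoff earns that tier.
  Scores in the uncalibrated middle zone contribute nothing.
* **PM2** (rarity), when the population-maximum allele frequency (maximum
  of ac/an over populations with an > 0; zero when absent everywhere) is at
  or below a configurable cutoff, by default 1e-4 at *supporting* strength,
  the common ClinGen-style downgrade.

Evidence that needs family, functional or case-control data (PS2–PS4,
PM1/PM3/PM6, PP1/PP4, BS2–BS4, ...) is never fabricated; pre-annotated
assignments can be merged in through `classify_all(extra_evidence = )`.

The combiner implements the 2015 table with strength-modified counting:
codes count at their *assigned* strength. One deliberate convention extends
the literal table: additional very-strong assignments beyond the first
count as strong. The published table has no multi-very-strong row, and a
literal reading would classify {very strong, very strong} below
{very strong, strong}; the convention restores monotonicity (adding
pathogenic evidence never lowers the class), which the test suite verifies
exhaustively together with a rule-row enumeration oracle. Contradictory
pathogenic and benign rule hits resolve to uncertain significance.

Classification is only one of three qualification routes. For prevalence
purposes a variant qualifies under a source when it is

* `acmg` — classified pathogenic or likely pathogenic by the engine;
* `clinvar` — asserted Pathogenic/Likely_pathogenic in a ClinVar-style
  table (Conflicting and VUS excluded — the conflict policy is a config
  decision, recorded here because assertion aggregators do not state one);
* `hgmd` — asserted DM in an HGMD-style table. DM? ("likely disease
  causing") is excluded by default; whether such entries should count is
  genuinely open, and the filter is a one-line change in
  `qualify_by_source()`.

## Prevalence model

For a cohort of $n$ diploid individuals with $k$ qualifying alleles pooled
over variants, the minor (disease) allele frequency is $q = k / 2n$ and,
under Hardy–Weinberg equilibrium ($1 = p^2 + 2pq + q^2$), heterozygous
carriers of an autosomal-dominant allele occur at frequency $2pq$ with
$p = 1 - q$. Homozygotes ($q^2$) are excluded exactly; no small-$q$
approximation is applied. The denominator is always twice the cohort size,
not the per-variant AN (which is retained for QC): published tables divide
printed allele totals by cohort size, and mixing per-variant denominators
would make the pooled arithmetic irreproducible.

Summaries follow the conventions of published carrier tables:

* percentages are rendered at two decimals, half rounded away from zero;
* "one carrier in every N" is $\lfloor 1 / 2pq \rfloor$. This floor
  reproduces the printed reciprocal for every published cell we checked
  except one: for 2 alleles in 1,909 Koreans the exact reciprocal is
  955.0003, so the package reports 955 where the original table printed
  954 (consistent with the source having rounded $q$ to three significant
  digits before inverting). We keep the exact computation.
* national carrier projections apply the *rounded* percentage to a census
  population and round to the nearest thousand (0.13% of 51.8 M ≈ 67,000),
  matching how such figures are quoted.

**Confidence intervals.** A CI for $q$ is computed from $k$ successes in
$2n$ trials and both bounds are mapped through the carrier transform
$f(q) = 2q(1-q)$, which is monotone for $q \le 0.5$ (bounds are capped
there; all realistic inputs are far below). The default method is the
exact Clopper–Pearson interval (beta quantiles), with Wilson score and
exact Poisson intervals available. The sources this pipeline emulates do
not state their CI procedure, and their printed intervals are not exactly
reproduced by any standard method on either the allele or the carrier
scale; CI correctness is therefore established by properties — agreement
with a binomial tail-sum search oracle to four significant figures,
order preservation under the monotone transform, and empirical coverage.
At the simulation conditions used throughout (cohorts of 10,000
individuals, planted carrier frequency 0.002, 600 replicates) the exact
interval's true coverage is 95.7%, inside the 93–97% band the tests
assert.

## Synthetic data

`simulate_cohort_table()` draws each variant's allele count as
Binomial($2n$, af) per cohort in the rare-variant regime (af ≤ 0.01),
attaches excluding quality flags at a configurable rate, and emits a truth
table of planted classes and frequencies. The generator emulates the
count structure of population databases; it does not model linkage,
genotype-level data, sequencing error, founder structure or classification
drift — so passing recovery and coverage tests demonstrates correctness of
the estimation arithmetic, not robustness to real-data artefacts.

The packaged PALB2 fixtures (`palb2_fixture_bundle()`, shipped as TSVs
under `inst/extdata/` with `_synthetic` in every file name) are engineered,
not sampled: per-variant per-population counts are fixed so that the
qualifying-allele sums reproduce every published PALB2 total simultaneously
(227/214/277 global ACMG/ClinVar/HGMD alleles, 8 East Asian, 44 Finnish,
2 + 10 + 0 Korean, ...), together with the named-variant structure — the
Finnish-enriched c.1592del founder frameshift at 46 alleles and absent in
East Asians, the Latino-predominant c.2167_2168del as the only Korean
variant also seen elsewhere, c.2968G>T confined to non-Korean East Asians,
c.1048C>T as the most frequent of ten distinct Korean variants. Where only
marginal sums are published the allocation is arbitrary but fixed.
Coordinates and alleles are placeholders on the toy transcript.

Two engineering constraints are worth recording. First, the fixtures ship
their own threshold configuration (`palb2_fixture_thresholds()`): PM2 at
*moderate* with a popmax cutoff of 2e-3. Under the strict 2015 table,
PVS1 + PM2(supporting) is only uncertain significance, so a
population-database pipeline that assigns nothing beyond PVS1 and PM2
needs PM2 at moderate for loss-of-function variants to reach likely
pathogenic; and the founder frameshift's popmax frequency (1.4e-3) must
still pass the rarity cutoff. The package defaults remain the conservative
1e-4 / supporting. Second, because the gnomAD-style Korean column must
contribute zero HGMD-DM alleles while KOVA contributes six, DM assertions
are placed only on variants absent from the gnomAD Korean column.

## Numerical and interface choices

* Coordinates are 1-based VCF-style with anchor-base indels. Cross-database
  identity is the normalized `chrom:pos:ref:alt` key — shared-base
  trimming always, plus left-alignment through repeat tracts when flanking
  reference sequence is supplied — never the HGVS string, which drifts
  between sources and is carried as annotation only.
* Multi-allelic VCF rows are decomposed into biallelic records by the
  reader; downstream code assumes biallelic input.
* Records failing the quality filters (default `InbreedingCoeff`, `AC0`,
  `RF`) never reach classification or aggregation; the exclusion count is
  reported for audit.
* Sources publishing frequencies instead of counts are converted with
  `af_to_counts()` (ac = round(af · 2n)).
* Reports are deterministic: cohorts in registry order, sources in fixed
  order, so identical inputs give byte-identical outputs.

Problem sizes throughout the test suite are chosen for exactness rather
than scale: the combining table is checked against its oracle over all
1,386 evidence multisets of size ≤ 6, CI coverage uses 600 simulated
cohorts of 10,000 individuals, and the fixture tables hold ~36 variants —
enough to pin every published cell while classifying in milliseconds.

## Known limitations

* The PVS1 tree is the reduced form: no in-frame exon-skipping rescue, no
  gene-specific VCEP overrides.
* Large (>50 bp) structural events and CNVs are outside the variant model,
  so prevalence from SNV/indel tables alone may understate the truth.
* Penetrance is not modelled; a carrier frequency is not a disease
  incidence.
* CI methods operate on the pooled allele count and ignore classification
  uncertainty (a variant is either in or out of the qualifying set).
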