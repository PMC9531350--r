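---
title: "Individualised polygenic risk scores: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualised polygenic risk scores: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prspipe)
library(tibble)
```

prspipe turns published polygenic risk scores (PRS) into individual-level
risk assessments. A published PRS arrives as a *scoring file*: a table of
variants, each with an effect allele and a per-allele weight. Applying it to
one person requires a chain of decisions — which scores are trustworthy
enough to apply, which of their variants can be reconciled with a reference
panel, how to count risk alleles out of a whole-genome call set, and how to
turn the resulting number into something interpretable. This vignette
documents the model at each stage, the conventions chosen where published
practice is ambiguous, and what the synthetic-data generator does and does
not emulate.

## The score

For a phenotype with $M$ reported variants, of which the harmonised subset
$R$ survives panel matching, the raw score of individual $j$ is

$$ S_j \;=\; \frac{1}{M} \sum_{i \in R} w_i \, d_{ij}, $$

where $w_i$ is the published per-allele effect weight and
$d_{ij} \in \{0,1,2\}$ the number of effect-allele copies in the genotype
call. Three conventions are deliberate:

* **Allele-count weighting.** A homozygous risk genotype contributes its
  weight twice — the standard additive model.
* **Denominator $M$, not $|R|$ and not $2M$.** Variants lost at
  harmonisation contribute nothing to the numerator but stay in the
  denominator, so missingness shrinks scores slightly instead of silently
  renormalising them. Because an individual is always compared against a
  background cohort scored with the *same* $R$ and $M$, this choice does not
  move percentiles; it is configurable (`denominator` argument of
  `compute_prs()`) for users who prefer the retained-count or
  allele-count normalisations.
* **No centring or variance standardisation of raw scores.** Raw scores are
  only ever interpreted through percentiles; z-scores appear solely where a
  published risk metric is expressed per standard deviation.

## Harmonisation

Scoring-file variants are matched against a reference panel by (chromosome,
position) and exact allele string equality: the effect allele must equal the
panel REF (`matched_ref`) or one of the ALTs (`matched_alt`). Anything else
is *missing* — either `missing_absent` (no panel record) or
`missing_allele_mismatch`. There is **no strand flipping, reverse-complement
rescue or imputation**: an allele that matches neither annotation is treated
as evidence of a strand or annotation inconsistency and dropped. Multi-allelic
panel sites match on any alternate allele. Indels fall under the same
string-equality rule without left-alignment; the curated scores are SNP
catalogues, so this path is exercised only by unusual inputs.

A phenotype remains usable when at least 95% of its reported variants are
retained. The missing percentage is rounded **half-up to two decimals** and
the gate is `missing_pct <= 5.00` — rounding first makes the printed report
and the gate decision consistent with each other, and a phenotype at exactly
5.00% passes ("at least 95%"). Half-up (rather than banker's) rounding is
what reproduces conventional printed missingness values such as 1/24 =
4.17%.

## Dosage extraction from whole genomes

Inputs are whole-genome call sets, so an absent VCF record is interpreted as
a homozygous-reference call rather than unknown. This has an asymmetric
consequence that is easy to get wrong: at a `matched_ref` variant the
*reference* allele is the effect allele, so an absent record contributes
dosage **2**, not 0. A record that exists but carries a fully missing
genotype (`./.`) contributes 0 and increments a warning counter — the record
was called and rejected, which is weaker evidence of homozygous reference
than no record at all, and the conservative contribution is zero. Half-calls
(`./1`) count only the observed allele. Phased and unphased calls are
equivalent. A retained effect allele that is absent from the genotype
record's own REF/ALT set raises a consistency error rather than guessing
which annotation to trust.

## Curation

Design-level curation is a pure function of hand-encoded metadata: the
underlying GWAS must be traceable, the score trained with a published
method, validated in a large independent cohort, and its performance metric
available and at or above a threshold (default 0.60 on AUC and C-index
values as printed). Two places needed a policy decision:

* **Variance-explained metrics.** $R^2$ values live on a different scale
  from AUC/C-index; a single 0.60 threshold would reject every
  variance-explained score. A separate configurable threshold (default
  0.10) is applied to $R^2$ entries. No conversion between metric families
  is attempted — they are compared only against their own thresholds.
* **Duplicates.** When several eligible scores target one phenotype the
  default rule keeps the highest performance value. A per-phenotype
  override can force a different winner (recorded as `judgement_override`),
  expressing whole-study judgement such as preferring a consistently
  validated source; losers are labelled `lower_performance_duplicate` or,
  when they out-performed the override winner,
  `validation_not_preferred_cohort`.

An exception list admits named phenotypes below threshold. Scores containing
X/Y-chromosome variants are parsed but excluded at the bioinformatic gate:
sex-chromosome dosage conventions differ between males and females, and the
panel-matching model here is autosomal.

## Percentiles, quintiles and bands

A tested individual is placed in a background distribution of cohort scores
by midrank counting:

$$ P = 100 \cdot \frac{\#\{s < S\} + \tfrac12\,\#\{s = S\}}{n}, $$

with the individual **never added to the background**. With continuous
scores this yields values on the grid $\{100k/n\}$, which is why percentiles
computed against cohorts of, say, 107 or 503 samples recur at granularities
like $0.93$ or $0.20$. Midrank tie handling is a documented choice; ties are
negligible for continuous scores. Quintiles use half-open bins
$[0,20), [20,40), [40,60), [60,80), [80,100]$ — a percentile of exactly 80
falls in quintile 5. Risk bands mark the distribution tails: `top5`
($P \ge 95$), `high` ($80 < P < 95$; "high risk" means *strictly above* the
80th percentile), and symmetric `bottom5`/`low` bands.

Two placements of the same score in different backgrounds are *inconsistent*
when the percentile moves by more than 20 points **and** the quintile
changes; either alone is tolerated. Requiring both keeps a wide move inside
one quintile, and a 1-point step across a bin edge, from being flagged.

## Risk translation

Published risk metrics (odds or hazard ratios with confidence intervals)
are **inputs, never recomputed**. For top-tail entries ("top $k\%$ vs
rest"), an individual is eligible for every tail containing them and the
deepest such tail supplies the metric — someone in the top 3% is better
described by the top-5% ratio than the top-20% one. For per-standard-
deviation entries the metric is attributed when the individual's z-score
against the chosen background exceeds 1. A percentile below every reported
threshold yields no assignment (a blank cell, not zero risk). Phenotypes
whose sex applicability excludes the individual still have their metric
computed but are flagged not expressible. The background used for z-scores
defaults to the same (primary) background used for reporting percentiles —
published per-SD metrics do not state which cohort should supply the SD, so
one consistent choice is made and exposed as configuration.

## Family analysis

Under additive transmission the expected offspring score is the mid-parent
value. The family report classifies each child as `averaging` when
$|P_{child} - (P_{father}+P_{mother})/2| \le 20$ percentile points, else
`divergent_high`/`divergent_low`. The default tolerance of 20 matches the
quintile granularity used everywhere else and is configurable; the
mid-parent expectation holds exactly for *raw scores* (verified by
simulation in the test suite), while percentiles are a monotone but
non-linear transform, so generous tolerance on the percentile scale is
appropriate.

## Clinical-grade QC

Variant-file quality metrics are computed per sample over calls carrying at
least one alternate allele within coding intervals (BED input, converted
from 0-based half-open to 1-based closed): median depth, percent of calls
with genotype quality above 40, homozygous-alternate/heterozygous ratio,
and transition/transversion ratio over biallelic SNVs with multi-allelic
records decomposed per carried alternate. Star thresholds: coverage median
*strictly above* 40; GQ percentage *strictly above* 95; hom/het in
$[0.5, 0.61]$ and ts/tv in $[2.71, 3.08]$, both inclusive. Degenerate inputs
(no DP/GQ fields, zero transversions, zero heterozygotes) yield `NA`
metrics, never 0. Coverage-type metrics are reported at one decimal; no
finer rounding convention is imposed.

## The synthetic-data generator

Real reference cohorts and family genomes are access-controlled, so the
package ships a seeded generator that emulates the *structure* of such a
study: per-variant ancestral allele frequencies uniform on $[0.05, 0.95]$,
per-population frequencies from the Balding–Nichols beta distribution
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$ with
divergence $F$, Hardy–Weinberg genotypes given the population frequency,
Mendelian trios (one allele per parent, chosen uniformly and
independently), and exact-count injection of harmonisation failures
(panel-absent and allele-mismatched variants) with a truth record for
assertions. Balding–Nichols was chosen because it has two parameters, known
moments, and is the standard stratification model for this kind of
property testing. Weights default to $\mathcal{N}(0, 0.05)$ — typical of
log-odds effect sizes in large published scores.

What it does **not** model: linkage disequilibrium (scores are additive, so
LD affects realism, not the correctness of the arithmetic being tested),
realistic per-disease effect-size architectures, sequencing error, or
sex chromosomes. Consequently, passing tests demonstrate that the pipeline's
accounting, matching, scoring, placement and inheritance logic are correct —
not that any particular published score is well calibrated for a given
ancestry.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make the statistical checks sharp while staying desk-scale:
scoring-oracle agreement over 1,000 random fixtures of up to $10^4$
variants; percentile-oracle agreement for backgrounds up to $n = 500$;
mid-parent averaging over 2,000 simulated trios of $M = 1000$ variants
(the paired design makes three standard errors a tight bound); and
background-sensitivity over 500 replicates of two populations at $F = 0.2$
with 100 samples each, where a target drawn from the matched population
must be uniformly placed (Kolmogorov–Smirnov at $\alpha = 0.01$) while
placement against the diverged population is detectably non-uniform —
pooling across replicate frequency draws makes the diverged-background
deviation systematic rather than seed-dependent. Score comparisons allow
$10^{-12}$ relative tolerance for summation-order effects; everything
discrete (counts, percentages, flags) is checked exactly.

## A worked micro-example

```{r example}
sf <- read_scoring_file(system.file("extdata", "example_scoring.tsv",
                                    package = "prspipe"))
panel <- tibble(chrom = c("1", "1"), pos = c(100L, 200L),
                ref = c("A", "T"), alts = c("G", "C"))
h <- harmonize_phenotype(sf, panel)   # rs3 is absent from the panel
glance(h)

g <- genotype_set(
  tibble(chrom = "1", pos = c(100L, 200L), ref = c("A", "T"),
         alt = c("G", "C")),
  matrix(c("1/1", "0/1"), 2, 1, dimnames = list(NULL, "S1"))
)
d <- extract_dosages(g, "S1", h)      # effect alleles: A (REF), C (ALT)
compute_prs(d, M = h$n_total, sample_id = "S1", phenotype_id = sf$phenotype_id)
```

The score is $(0.1 \cdot 0 + (-0.2) \cdot 1)/3$: rs1's effect allele is the
reference allele and the sample is homozygous alternate (dosage 0), rs2
contributes one effect-allele copy, and rs3 stays in the denominator despite
being unscorable.

## Known limitations

* Metadata-driven curation is only as good as the hand-encoded metadata;
  nothing is mined from the literature.
* Allele matching is deliberately strict; legitimately strand-flipped
  scoring files will show inflated missingness rather than being rescued.
* Hard genotype calls only — no genotype likelihoods or dosage (DS) fields.
* Nested background populations (a subpopulation inside its continental
  group inside the full cohort) are supported as data but percentiles
  across them are correlated, which the consistency check treats
  qualitatively, not inferentially.
* No genome-build liftover: inputs must already share one build.
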