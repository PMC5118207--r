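---
title: "Methods: capture-adjusted rare-variant burden testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capture-adjusted rare-variant burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneburden)
```

## The problem and the model

Genome-wide association studies of primary open-angle glaucoma (POAG) and
its endophenotypes (intraocular pressure, optic disc morphology, central
corneal thickness) implicate loci through common variants of small effect.
Whether *rare* coding variants in the same genes also contribute to disease
cannot be read off a SNP array: rare alleles are in poor linkage
disequilibrium with common tags. The design this package implements answers
that question with exome sequencing: collapse the rare, predicted-pathogenic
variants of each candidate gene into a single per-gene burden, and compare
that burden between cases and controls.

The complication the method exists for is *heterogeneous capture*. When a
case cohort and an external control cohort are sequenced on different
capture platforms, the denominator of an allele frequency differs site by
site: a variant may be callable in 98% of cases but only 75% of external
controls. Comparing raw allele counts against `2n` would then manufacture
spurious enrichment in the better-captured cohort. The burden statistic
used here is therefore the **capture-adjusted mutational load** of gene
$g$ in cohort $c$:

$$
L_{g,c} \;=\; \frac{\sum_{v \in Q_g} \mathrm{AC}_{v,c}}
                   {\overline{N}_{g,c}},
\qquad
\overline{N}_{g,c} = \frac{1}{|Q_g|} \sum_{v \in Q_g} N_{v,c},
$$

where $Q_g$ is the gene's set of qualifying variants,
$\mathrm{AC}_{v,c}$ the QC-passing alternate-allele count of variant $v$,
and $N_{v,c} = 2 \times (\text{samples with a QC-passing call at } v)$ the
*captured alleles* at $v$. With complete capture
$\overline{N} = 2n$ and the load reduces to the ordinary aggregate allele
frequency; with differential capture, missing calls shrink the denominator
rather than masquerading as reference alleles.

The load's numerator and (rounded) denominator form the allele-level
$2\times2$ table

|            | alt alleles | ref alleles |
|------------|-------------|-------------|
| cases      | $a$         | $b$         |
| controls   | $c$         | $d$         |

tested with a two-sided Fisher exact test, the sample odds ratio
$\widehat{OR} = ad/bc$, and Bonferroni correction over the genes actually
tested. Carrier rates (fraction of samples with $\geq 1$ qualifying allele)
are reported descriptively alongside: the headline test is allele-level
because the load is.

### Qualifying variants

A variant qualifies when all three hold:

1. **Coding or splice-site.** Consequence in {synonymous, missense,
   stop-gain, stop-loss, frameshift, in-frame indel, splicing}; everything
   else (`other`) is excluded as non-coding. (Synonymous and in-frame
   changes pass this gate but fail the pathogenicity gate below.)
2. **Rare wherever known.** Excluded if *any* populated population
   database (1000 Genomes, ESP, ExAC, dbSNP) reports MAF strictly above
   `maf_threshold` (default 1%). A variant absent from every database
   passes: absence of evidence of commonness is how novel pathogenic
   variants look.
3. **Predicted pathogenic.** Stop-gain, stop-loss and frameshift are
   retained as loss-of-function; splice-site variants are retained
   (flagged with a distinct `splicing` reason for audit); missense is
   retained iff damaging by SIFT (score $< 0.05$, strict) **or**
   PolyPhen-2 HVAR (score $> 0.909$, strict). The OR-logic is deliberate:
   a missense tolerated by one predictor but damaging by the other still
   qualifies. Missense with both scores missing, synonymous variants and
   in-frame indels never qualify.

Genotype-level QC is a single knob: a call contributes to allele counts,
captured-allele denominators and carrier status only when its Genotype
Quality is at least `gq_threshold` (default 20, *inclusive* — "a threshold
of 20" is read as GQ ≥ 20). A gene's qualifying set is additionally
restricted to variants observed with at least one QC-passing alternate
allele somewhere in the joint cohort — unobserved annotation rows are not
evidence.

### External summary controls

A public reference cohort is often available only as per-variant allele
counts (AC/AN), not genotypes. `associate_vs_summary()` builds the control
cells as $c = \sum_v \mathrm{AC}_v$ and
$d = \operatorname{round}(\overline{\mathrm{AN}}) - c$. A qualifying
variant absent from the reference contributes $\mathrm{AC} = 0$ with AN
imputed as the median AN of the present variants: in a reference of tens
of thousands of exomes, absence is evidence the allele was not seen, not
that the site was uncaptured. Carrier counts are unavailable in this mode
and reported as `NA`.

### Random control gene sets

To benchmark the false-positive behaviour empirically,
`draw_control_sets()` samples mutually disjoint gene sets (default five)
of the panel's size from a background universe, *excluding* the target
panel so genuine signal cannot leak into the null; `evaluate_control_sets()`
re-runs the association within each set with the Bonferroni denominator
fixed at the set size. "Independent groups" is interpreted as disjointness
plus target exclusion; exclusion can be disabled by passing an empty
`exclude`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `maf_threshold` | 0.01 | frequency | conventional rare-variant cutoff; strict `>` so exactly 1% still passes |
| `gq_threshold` | 20 | Phred-like GQ | standard joint-calling QC floor; inclusive |
| `alpha` | 0.05 | — | family-wise level after Bonferroni |
| `n_genes_tested` | genes with a testable table | count | Bonferroni denominator; fixable (e.g. 86) when the analysed panel is larger than the genes a given comparison can test |

## Numerical choices

- **Fisher two-sided p** is the point-probability definition: the sum of
  hypergeometric point probabilities $\leq$ the observed one, compared
  with a relative tolerance of $1+10^{-7}$ so floating-point ties are not
  misclassified. The unit tests verify exact equality (to $10^{-12}$)
  against an independent `lchoose`-based enumerator on every table with
  total $\leq 40$, and against `stats::fisher.test` on random tables.
- **Odds ratio** is the sample $ad/bc$; any zero cell triggers the
  Haldane–Anscombe correction (0.5 to all cells). The 95% interval is
  Wald on the log scale with the conventional 1.96 multiplier. (The
  conditional-MLE estimator of `fisher.test` is deliberately *not* used:
  the reported estimator is the table's cross-product ratio.)
- **Rounding.** `mean_captured` is rounded half-up before table
  construction (Fisher needs integers; banker's rounding would be
  surprising on `.5` boundaries). If an allele count exceeds the rounded
  capture, the reference cell clamps at 0 with a warning.
- **Degenerate inputs.** A gene with no qualifying variants has load 0,
  carriers 0 and an undefined denominator, and is omitted from the testing
  family; a variant with zero passing calls still enters the capture
  average (with $N_v = 0$) so capture failure is visible rather than
  silently dropped; a cohort whose every qualifying variant has zero calls
  has an undefined (missing) load. Tables with an all-zero margin give
  p = 1.
- **Trait contrasts** between carriers and non-carriers use Welch's
  t-test; with a single carrier (Welch undefined) the test falls back to
  an exact permutation of group labels (Monte-Carlo above 50 000
  assignments), and two constant identical groups give p = 1.
- **Ties in output.** Result files order rows by raw p, then gene symbol.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` generates the full study shape with known truth:
187 cases and 103 screened local controls on a high-capture platform
(per-site call rate 0.98), 993 external controls on a lower-capture
platform (0.75, emulating ~75% 10× coverage), a target panel of 86 genes
plus 600 background genes, ~20 variants per gene, and one planted gene
whose case carrier odds are `planted_or` (default 13.2) times the per-gene
control carrier odds `q` (default 0.003). The planted case carrier
probability solves $p/(1-p) = OR \cdot q/(1-q)$; with the defaults
$p = 0.0382$. Carriers are heterozygous singleton-style (one qualifying
variant each, chosen by fixed per-variant weights), matching how a handful
of rare alleles across distinct carriers actually presents. Genotype
quality is Normal(60, 25) clipped to 0–99, putting about 5% of calls under
the GQ-20 floor — so both missingness channels (capture failure: absent
call; QC failure: present but filtered) are exercised. HTG status is
assigned to 122/187 of cases with max IOP drawn above 21 mmHg (NTG at or
below); ages at diagnosis are Normal(44.4, 10.4). The common mass of the
MAF spectrum (15%) is drawn from [0.0112, 0.30] and always reported by at
least one database, so a "common" draw is excluded with certainty and the
qualifying fraction among rare variants has the closed form
$p_\text{lof} + p_\text{splice} + p_\text{missense} \cdot
p_\text{damaging}$ used by the calibration tests. The summary control
draws $\mathrm{AC} \sim \mathrm{Binomial}(2 \times 33370, f_v)$ at each
variant's control frequency.

Not emulated: linkage disequilibrium, population stratification,
joint-calling artefacts, read-level error, relatedness, and
platform-correlated *variant discovery* (every annotated variant exists on
both platforms; only callability differs). Passing truth-recovery tests
therefore demonstrates the pipeline's arithmetic and filtering logic, not
robustness to confounding that real cohorts can carry.

## Problem sizes used by the test suite

The suite validates at the study's own scale where that is what is being
claimed — truth recovery and the null type-I bound run one full 187/1096
cohort (86 target genes and 500 null genes respectively), parameter
recovery runs 200 full-size cohorts on a 3-gene panel, and the random
control sets are 100 seeded draws of 86 genes from a 200-gene null
universe — and at reduced sizes for generic properties (a 12-gene panel,
~200 samples) where the property does not depend on scale.

## Known limitations

- The per-variant capture denominators of a real joint-called study are
  not reconstructible from published per-gene loads, so a published odds
  ratio computed on unpublished denominators can differ from the
  cross-product of the published rounded counts; this package reports the
  table it actually built alongside the estimate.
- Bonferroni over genes is conservative for correlated tests; no
  permutation-based family-wise alternative is provided.
- Allele-level Fisher tests treat alleles as exchangeable, which
  understates variance if carriers were related or homozygous carriers
  were common; the design assumes unrelated samples and rare,
  heterozygous carriers.
- The weighted and kernel burden families (frequency-weighted collapsing,
  SKAT) and covariate-adjusted regression are out of scope.
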