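---
title: "Methods: HLA carrier association, phasing and residue fine mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA carrier association, phasing and residue fine mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaassoc)
```

## The model

`hlaassoc` analyses case-control cohorts typed for HLA class II loci at
two-field resolution. Every analysis level — allele, serological group,
genotype class, DRB1-DQB1 haplotype, diplotype, amino-acid residue — reduces
to the same primitive: a 2×2 carrier table under the dominant model, in
which an individual is a carrier when at least one of their two alleles (or
haplotypes, or residue-encoding alleles) matches the unit, and homozygotes
are counted once. Gene-dosage questions are deliberately pushed to the
genotype and diplotype scans, where homozygous and heterozygous classes are
separate units; the carrier scans stay strictly dominant.

The statistics attached to each table are:

* **Odds ratio.** The cross-product ratio $ad/bc$. When any cell is zero,
  0.5 is added to all four cells before the ratio (Haldane–Anscombe). The
  correction is *conditional*: tables with all cells positive are left
  untouched. This keeps common, well-estimated units exact while giving
  finite, sign-preserving estimates for structural zeros (rare alleles
  absent from one arm, diplotypes unseen in controls).
* **Woolf confidence interval.**
  $\exp(\ln \mathrm{OR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d})$, computed on
  the corrected cells whenever the correction was applied.
* **Two-sided Fisher exact P**, point-probability rule: the sum of
  hypergeometric probabilities of all tables with the observed margins whose
  point probability does not exceed that of the observed table. This is the
  convention of mainstream implementations (`stats::fisher.test` among
  them); ties are accepted with a relative tolerance of $10^{-7}$ so that
  floating-point noise cannot drop an exactly tied table from the sum.
* **Bonferroni-corrected P.** $P_c = \min(1, P \times m)$ where $m$ is the
  number of units tested at that level — the number of distinct alleles
  observed at the locus for allele scans (the default recomputes it from the
  combined cohort; `m` can be overridden), and the number of
  (position, residue) units for residue scans. Genotype, serogroup,
  haplotype and diplotype results carry no corrected P by default, matching
  how such tables are conventionally reported; the `ns` column additionally
  flags units whose uncorrected P is already ≥ 0.05.

### Numerical conventions

Two small conventions matter for reproducing published tables digit for
digit. First, the 95% Woolf interval uses $z = 1.96$ — the two-decimal
quantile that applied analyses almost universally plug in — rather than
$\Phi^{-1}(0.975) = 1.9599\ldots$; at other confidence levels the exact
quantile is used. The difference is invisible for narrow intervals but
shifts the second decimal of very wide ones (upper bounds in the hundreds).
Second, corrected P values are capped at 1; a printed "NS" in the reference
tables the regression suite checks corresponds exactly to the cap being hit.

## Haplotype phasing by direct counting

DRB1 and DQB1 are in strong linkage disequilibrium, so two-locus phase can
be resolved by counting rather than by probabilistic model fitting. Any
sample homozygous at either locus has a single possible phasing. Doubly
heterozygous samples have exactly two candidate phasings and are resolved
in two steps:

1. **Catalog rule.** If a catalog of permitted haplotypes is supplied and
   exactly one candidate consists solely of catalogued haplotypes, that
   candidate wins.
2. **Iterative frequency rule.** Haplotype counts are initialised from the
   unambiguously phased samples; each remaining sample is assigned to the
   candidate with the larger product of current counts, counts are updated,
   and the sweep repeats to a fixed point (cap 100 sweeps, far more than
   ever needed). Haplotypes not yet seen enter the product with a
   pseudocount of 0.5, so a candidate sharing one observed haplotype beats
   a candidate made of two unseen ones — without the pseudocount both
   products are zero and the information in the shared haplotype is lost.
   Genuinely symmetric configurations still tie; tied samples are flagged
   ambiguous, excluded from haplotype counts and from haplotype/diplotype
   scan denominators, and their number is always reported.

This is a hard-assignment scheme, not an EM with fractional counts: under
the strong-LD regime it targets, candidate products typically differ by
orders of magnitude and fractional assignment would change nothing, while
hard assignment keeps every downstream count an integer and the whole
procedure auditable. Phase uncertainty is not propagated into P values — the
ambiguity count is the honesty device.

## Residue fine mapping

Residue scans translate allele carriage into amino-acid carriage through a
lookup table (`allele`, `position`, `residue`; mature-protein coordinates,
position 1 = first residue after the signal peptide, matching the
11/13/33/57/70–74/96 numbering used for the DRβ chain). A sample carries
residue *r* at position *p* iff at least one of its alleles encodes it; the
statistics stack is identical to the allele scan. A residue encoded by
exactly one allele therefore inherits that allele's result field for field —
the property that lets residue signals be traced back to the allele driving
them, and the anchor of the residue test suite.

Scans can also run from pre-aggregated allele carrier counts: residue
carriers are then the sum of the carrier counts of the encoding alleles,
capped at the arm total. This is exact for single-allele residues and an
upper bound otherwise (a sample carrying two alleles that encode the same
residue is counted twice); per-sample input is exact in all cases.

The bundled DRβ/DQβ tables are an implementer-curated two-field consensus
restricted to the scanned positions, shipped so the pipeline runs
end-to-end out of the box; they are flagged as curated in their headers and
should be replaced by tables derived from the current IMGT/HLA protein
alignments for biological interpretation. No test depends on their
correctness — all residue assertions use synthetic tables.

## Heterodimer enumeration

A DRB1-DQB1 diplotype implies four DQα-β molecules once each haplotype's
DQA1 allele is known: two *cis* pairs (α and β from the same chromosome)
and two *trans* pairs (opposite chromosomes). The DQA1 assignment is data,
not code: the bundled linkage map contains exactly the three presumed
assignments relevant to the high-risk Japanese AIH diplotypes and nothing
inferred beyond them. Stability of a DQα-β pairing is likewise a free-text
annotation from a user-supplied lookup; the package never computes it. Two
invariants hold by construction and are property-tested: the cis and trans
sets conserve the DQA1 and DQB1 multisets, and homozygous diplotypes give
cis = trans.

## The synthetic cohort generator

The generator exists so every pipeline stage is testable without any
external download. It draws each individual's diplotype as two independent
haplotypes from a frequency vector (Hardy–Weinberg equilibrium), which
makes DRB1-DQB1 linkage disequilibrium structural — the haplotype is the
sampling unit, mirroring the assumption that justifies direct counting.
Disease status follows a carrier odds model: an individual's disease odds
are a baseline (default 0.1) times the product of the multipliers of every
effect unit carried, with effect units keyed by allele, haplotype, genotype
class or diplotype class. A multiplicative odds model is the simplest one
consistent with odds-ratio-only reporting, and for a binary carrier
covariate the multiplier *is* the population odds ratio, which case-control
sampling preserves — so configured effects are directly recoverable as
estimated carrier ORs. Sampling is by rejection until both arm sizes are
met, fully reproducible under `(config, seed)`.

Default haplotype frequencies are back-solved from the control carrier
frequencies of the bundled haplotype table under HWE
($f = 1 - \sqrt{1 - \mathrm{cf}}$; e.g. carrier frequency 19.1% gives
haplotype frequency 0.101), completed by a residual synthetic "other"
haplotype (`DRB1*99:01-DQB1*99:01`) so the vector sums to 1. Phenotype
fields are smoke-test settings mimicking published carrier contrasts
(immunoglobulin G shifted by about +470 mg/dl and the anti-smooth-muscle
antibody rate raised from about 19% to 55% in carriers of the flagged
allele, neutral demographics); means and rates only, with no claim of
distributional fidelity.

What the generator does *not* emulate: genotyping error, population
structure and admixture, deviation from HWE in controls, more than two
loci, and real linkage patterns beyond the catalog supplied. Passing
simulation tests therefore demonstrates the correctness and calibration of
the statistical machinery under the stated model, not robustness of the
scientific conclusions to artefacts of real data.

## Validation design and problem sizes

The test suite validates on four axes, with sizes chosen to keep the full
run around half a minute:

* **Print regression** — every OR, CI bound, P and corrected P recomputed
  from the bundled allele (30 + 3 rows), genotype (14 rows) and
  haplotype/diplotype (15 rows) count tables is compared with the published
  value at printed precision.
* **Oracle equivalence** — the exact-test P is compared with a brute-force
  enumeration over all tables with margins up to 30 (about 164,000 tables).
* **Simulation calibration** — phasing recovery on 20 cohorts of n = 1000
  under the six-haplotype strong-LD catalog; odds-ratio recovery and Woolf
  coverage over 200 cohorts of 360 cases/413 controls with a carrier effect
  of OR 4.3 at control haplotype frequency 0.101; type-I error of the
  carrier scan over 100 null cohorts of the same size.
* **Structural properties** — allele-conservation of phasing, unique-residue
  equivalence, heterodimer multiset conservation, arm-swap symmetry of the
  exact test, monotone narrowing of the Woolf interval.

## Known limitations

* Fisher's exact test is conservative for very rare units; the type-I rate
  pooled over units sits slightly below the nominal 5%.
* The Bonferroni default treats the observed allele count as the family
  size; users scanning hand-picked unit subsets should pass `m` explicitly.
* Phasing hard-assigns; in weak-LD settings (not its design regime) an EM
  with fractional counts would be preferable.
* Count-fixture residue scans upper-bound carrier counts when a residue is
  shared by multiple alleles (exact from per-sample data).
* The odds-ratio point estimate is finite-sample biased away from the null;
  calibration is asserted on the mean over replicates and on interval
  coverage, not on unbiasedness.
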