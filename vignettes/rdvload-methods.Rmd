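---
title: "Rare deleterious variant burden and load: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare deleterious variant burden and load: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdvload)
```

## The scientific problem

Rare germline variants (minor allele frequency well below 1%) that damage
protein function can carry large cancer risks, but any single variant is too
rare to test on its own. `rdvload` implements the standard remedy — *carrier
collapsing*: a gene or gene-set is reduced to one binary exposure per
participant (carries at least one qualifying rare deleterious variant, RDV,
in the unit, or does not), and the case-control association of that exposure
is tested. Two quantities organize the analysis:

* **RDV burden** — the cohort-level excess of carriers among cases for a
  unit, summarized as a covariate-adjusted odds ratio; and
* **RDV load** — the per-individual count of *distinct genes* within a
  gene-set harboring an RDV, grouped as 0 / 1 / >1, whose dose-response
  association with risk, age of onset, tumor mutational burden (TMB), tumor
  immune composition and survival is the second analysis axis.

Everything upstream of those tests (genotype and site QC, relative pruning,
ancestry gating, classification) exists to make the carrier indicator
trustworthy, and everything here is driven by a seeded synthetic-cohort
generator so the full path is testable without access-controlled genotype
data.

## The core estimator: Firth-penalized logistic regression

Carrier collapsing routinely produces sparse 2x2 margins (a handful of
carriers, sometimes none in one arm), where ordinary logistic regression
diverges under separation. The package therefore fits

$$\ell^*(\beta) \;=\; \ell(\beta) + \tfrac12 \log\det\!\big(X^\top W(\beta)\,X\big),
\qquad W = \mathrm{diag}\{\pi_i(1-\pi_i)\},$$

Firth's penalized log-likelihood, by Fisher scoring on the modified score
$U^*(\beta) = X^\top\!\big(y - \pi + h \odot (\tfrac12 - \pi)\big)$ (with $h$
the hat diagonals), with step-halving. The penalty guarantees finite
estimates under complete separation; on a saturated 2x2 design it is exactly
equivalent to adding 1/2 to every cell, which the test suite exploits as a
closed-form oracle.

Inference defaults to the *profile penalized likelihood*: the p-value is the
penalized likelihood-ratio test of the exposure coefficient against zero
(the null fit keeps the full design in the penalty), and the 95% limits are
the coefficient values where the profile drops by
$\chi^2_{1,0.95}/2$. Wald inference is available via `method = "wald"`. The
choice of profile inference as the default mirrors the convention of the
`logistf` approach that this estimator re-implements; which flavor produced
any given published interval is usually unknowable, so both are exposed.
Convergence is declared at a maximum modified-score component below `1e-6`
(configurable), with 50 iterations and step-halving; profile roots are
bracketed within ±20 on the log-odds scale, beyond which an open interval
is reported and flagged.

Burden covariates are the *synonymous background load* (the number of genes
in which a participant carries an ultra-rare synonymous variant — a proxy
for platform and coverage differences between arms, which inflate apparent
burden symmetrically for deleterious and neutral variation) and the first
two ancestry principal components, recomputed on the gated cohort. Gender
enters only in a sensitivity mode, in which participants with missing gender
are first removed. Scans over unit catalogs append Benjamini-Hochberg
q-values; targeted gene-set tests are read at p <= 0.05 with OR > 1, the
convention for pre-specified hypotheses.

## Quality control

Thresholds (all in `qc_thresholds()`, all overridable) follow the usual
GATK-style exome pipeline: genotype calls need GQ >= 20, DP >= 10,
alternate-allele depth >= 4, and heterozygous calls an alternate-allele
fraction in [0.30, 0.70]; sites need QUAL >= 50, QD >= 2, MQ >= 40,
ReadPosRankSum > -3, MQRankSum > -10, and a VQSR tranche below 99%
sensitivity. Two conventions deserve note:

* **Boundary semantics are literal**: ">="-style rules are inclusive,
  ">"-style rules strict; an allele balance of exactly 0.30 or 0.70 is
  retained. The inclusive reading of "between 0.30 and 0.70" is a choice,
  made once and configurable.
* **Order of operations**: samples with >= 15% missing genotypes are removed
  first, then per-call masks are applied, then site screens (differential
  case/control missingness <= 0.05 and >= 88% completeness per arm) are
  evaluated *on the masked matrix*. Order matters because masking changes
  missingness fractions; evaluating completeness after masking is the
  stricter and more honest reading, and the cascade is idempotent under it.

Absent rank-sum statistics never fail a site (they are undefined for
invariant-signal sites), and a FILTER string fails only when it names a
tranche whose lower sensitivity bound is >= 99; `PASS` always passes.

## Sample QC: kinship and ancestry

Relatedness uses the KING-robust estimator on a common-SNP panel
(biallelic, MAF >= 0.05, call rate >= 0.99, greedily LD-pruned at pairwise
r² > 0.2 in 50-SNP windows, step 5):

$$\hat\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}},$$

which is 0.5 for duplicates, ~0.25 for first-degree and ~0.125 for
second-degree pairs, independent of allele frequencies. Pairs with
$\hat\phi > 0.0884$ (the conventional second-degree bound) are flagged, and
from each flagged pair the member with more missing data is removed (ties
break lexicographically on participant id, deterministically). The panel
needs to be reasonably large for this: with ~1000 informative SNPs the
null-pair standard deviation of $\hat\phi$ is ~0.02, comfortably below the
flag threshold; the generator's default 2000-SNP common panel is sized
accordingly.

Ancestry structure is handled by "gating": PCA on the standardized
common-panel dosages ($(g-2\hat p)/\sqrt{2\hat p(1-\hat p)}$, residual
missingness mean-imputed, SVD), followed by a rectangular gate on (PC1,
PC2) retaining the largest homogeneous cluster. The gate is a configured
rectangle, or can be derived from reference-population scores (centroid
± 3 SD) when a labeled reference panel is co-decomposed. Covariate PCs are
recomputed on the gated participants only. Component signs are fixed by
making each component's largest-magnitude loading positive, so permuting
participants cannot flip scores.

## RDV classification

A QC-passed variant is **rare** unless (a) its MAF exceeds 2% in *both*
arms (being common in only one arm is evidence, not noise), or (b) it
exceeds 1% in either of two reference populations (ExAC non-TCGA NFE,
gnomAD ASJ). A reference frequency absent from the annotation is treated as
0 — the variant was not observed there — with an exclusion mode available.
The 2% boundary itself is kept (<= is rare), and a 1% sensitivity mode is a
configuration switch; by construction its RDV set is a subset of the
default, which is asserted property-style in the tests.

A variant is **deleterious** if ClinVar lists it as pathogenic or likely
pathogenic, or if it is truncating (stopgain/frameshift) and lies **5'** of
a ClinVar pathogenic loss-of-function record in the same gene — the
rationale being that a premature stop upstream of a known-pathogenic stop
removes at least as much protein. "5' of" is evaluated in coding-sequence
coordinates, so transcript strand is absorbed by the CDS mapping and no
strand-specific branch exists to get wrong; with several anchors, the most
3' one defines the boundary, and the boundary itself does not qualify
(strictly smaller CDS position). Likely-pathogenic LOF records anchor the
rule by default (configurable), and truncating variants lacking a CDS
coordinate are skipped for the rule with a message rather than guessed at.

Carrier coding is dominant: a homozygous alternate genotype counts once. The
synonymous background covariate counts *genes* (not variants) with at least
one carried autosomal synonymous variant at ExAC global MAF <= 0.005% and
cohort MAF <= 0.05%.

## Load groups and phenotype associations

`assign_load_groups()` counts distinct carrier genes per set and maps 0/1/>=2
to zero/one/multi; the three groups partition the cohort by construction.
Risk dose-response contrasts one-vs-zero and multi-vs-zero with the same
Firth machinery and covariates as the burden tests; monotonicity is
reported, never enforced, and an empty multi group drops that contrast with
a message (at realistic carrier frequencies the multi group is small — this
is a power statement, not an error).

Continuous phenotypes (age at diagnosis, TMB, immune fractions) are compared
across load groups with rank tests. The Mann-Whitney U test uses midranks
for ties; with both groups at size <= 8 the two-sided p-value is computed by
exhaustive enumeration of all $\binom{n_1+n_2}{n_1}$ assignments (two-sided:
assignments at least as far from $n_1 n_2/2$ as observed), otherwise a
normal approximation with tie-corrected variance and a continuity
correction. With the continuity correction disabled, the two-group case
agrees exactly with the Kruskal-Wallis chi-square p-value — a useful
consistency check, verified numerically in the tests. The Kruskal-Wallis
test itself delegates to `stats::kruskal.test()`.

TMB is the stated arithmetic: (missense + nonsense + frameshift + inframe
somatic mutations) / 38 Mb of exome; synonymous mutations are excluded by
the consequence list, and "inframe" covers insertions and deletions alike.
Relative immune fractions (22 cell types summing to 1 per tumor) are scaled
by the leukocyte fraction to absolute tissue fractions; survival on the
absolute M1 macrophage fraction uses a stratified Cox model via
`survival::coxph()` with Breslow tie handling (a choice, documented here,
made once). Strata without events are dropped with a message; a covariate
without variation yields a flagged, undefined hazard ratio rather than a
spurious one. Survival p-values are reported without multiplicity
correction, with BH available for scans.

## The synthetic cohort generator

`simulate_cohort()` draws, from one integer seed, everything the pipeline
consumes: a multi-sample VCF-shaped genotype container with per-call
GQ/DP/AD and per-site QUAL/QD/MQ/rank-sum/FILTER fields, an annotation
table, covariates, a tumor-phenotype table and a truth table. The
generative model:

* **Rare variants** take MAFs from a point-mass spectrum (default 0.01% to
  0.5%); genotypes are Hardy-Weinberg within stratum. Each gene carries
  planted deleterious variants — a configurable fraction labeled P/LP
  directly, the rest unlabeled truncating variants placed 5' of a pathogenic
  LOF anchor record, so both classification branches are exercised — plus
  benign and reference-common distractors for the filter branches.
* **Case status** is retrospective: candidates are drawn, their case
  probability is logistic in the planted per-gene-set carrier indicators
  (log-odds = `planted_logor`), and arms are filled to quota. This makes the
  empirical carrier odds ratio converge to `exp(planted_logor)`, which the
  tests verify. Defaults plant the published gene-set effect sizes
  (OR 1.46–2.05) on four cancer gene-sets in a 6371 + 6647 cohort.
* **Synonymous background** variants are ultra-rare (MAF 1–3e-4) and drawn
  independently of status at a configured mean rate of genes per
  participant. Note a small-cohort artifact: with fewer than ~1000
  participants even a singleton exceeds the 0.05% cohort-MAF gate, so the
  covariate collapses to zero and is dropped by the pipeline with a message.
* **Ancestry strata** shift common-panel allele frequencies on the logit
  scale by a per-stratum dispersion; rare-variant frequencies are shared, so
  stratification confounds only through the common panel (sufficient for
  gating tests, not a model of real differentiated rare variation).
* **Relatives** are planted among controls: duplicates copy genotypes,
  first-degree pairs share one Mendelian gamete, second-degree pairs share
  a gamete with probability 1/2 — the minimal scheme with the right expected
  kinship coefficients (0.5 / 0.25 / 0.125).
* **Tumor phenotypes** shift with the true load group of one configured
  gene-set: onset ages shift down by configured years (clipped at a floor,
  with a message), somatic counts are Poisson with a load multiplier,
  immune fractions are Dirichlet with the expected M1 fraction shifted
  additively, and survival is exponential with hazard log-linear in the
  absolute M1 fraction, uniformly censored.

What the generator does **not** emulate: linkage disequilibrium beyond what
pruning needs, realistic site-frequency spectra, sequencing-error or
read-level processes, admixed ancestry, and pleiotropy between the planted
effect and the phenotype links other than through load group. Passing tests
therefore demonstrate that the machinery is correct and calibrated under the
stated generative model — not that any particular real-cohort estimate is
right.

## Calibration and the problem sizes used

The statistical acceptance checks run at the following sizes, chosen to
make Monte Carlo error small relative to the tolerances while keeping the
default test run quick: null calibration uses one 2000 + 2000 cohort with
1000 null genes at per-gene carrier frequencies of roughly 1–4% (enough
carriers that the penalized LRT p-value is effectively continuous; type-I
error is checked within 3 binomial SEs of 0.05 and uniformity by a
Kolmogorov-Smirnov test at alpha 0.01). Confidence-interval coverage uses
500 replicates of a 5000 + 5000 cohort with a planted carrier OR of 1.5 and
a ~5% control carrier frequency, checked within 3 binomial SEs of 95%.
Generator effect fidelity uses a single 10000 + 10000 draw. Kinship targets
use 10,000-SNP Mendelian simulations.

## Known limitations

Annotation is taken as given, one transcript per gene; no in-silico
deleteriousness scores are consulted, so genes without ClinVar pathogenic
records are invisible to the classifier by design. Variance-component tests
(SKAT-family) are out of scope — the collapsing test is powerful for
unidirectional effects and weak under effect heterogeneity within a unit.
The Cox fit reports a single-covariate hazard ratio and makes no attempt at
time-varying effects. Multi-allelic VCF records are expected to be
decomposed upstream.
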