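---
title: "Methods: medication-use trajectories and their genetic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication-use trajectories and their genetic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(medtraj)
```

# The problem

Drug purchase registries code every dispensed prescription with a date
and an ATC code. Because treatment of hyperlipidemia, hypertension and
type 2 diabetes is lifelong, the purchase stream of one person is a
trajectory: when treatment started, how intensively it was refilled,
whether the molecule or the combination changed, and whether it stopped.
`medtraj` turns such trajectories into twelve analyzable phenotypes and
carries them through a complete statistical-genetics workflow. This
vignette documents the models, the parameters that matter, the numerical
choices, and what the built-in simulator can and cannot stand in for.

# Phenotype derivation

Matching is uppercase prefix matching on the ATC string; the code system
itself is hierarchical, so no lookup table is needed. Each registry row
is one purchase: two purchases on one day are two rows and count twice.

Decisions taken where the verbal definitions leave room:

* **End of follow-up** for the discontinuation phenotypes is
  `min(death date, window end)` per person. Counting purchase-free time
  against the global registry end would misclassify people who died
  shortly after their last purchase as discontinuers; per-person
  censoring is the conservative reading.
* **"One year"** is 365 days with a strict inequality
  (`free days > 365`).
* **Ambiguous statin starters** — two different statin molecules on the
  person's first statin day — are excluded from the switching analysis.
  Any tie-break by row order would make the phenotype depend on registry
  sort order; exclusion keeps every derivation order-invariant (a
  property the test suite asserts by shuffling).
* **SGLT2 inhibitors** are matched as `A10BK`. One variant spelling of
  the class (`A10JK`) circulates but is not a valid ATC class; `A10BK`
  is the WHO code.
* Non-users are kept at zero in the quantitative counts and excluded
  from the binary phenotypes; eligibility (alive and at least 10 years
  old at the window start, so that age-related medicine-free follow-up
  does not dilute the counts) applies to the quantitative phenotypes.
* Case percentages are reported at one decimal. Published cohort tables
  mix one-decimal and three-significant-figure precision; one decimal
  reproduces every percentage this package asserts, and
  `case_percentage(..., digits = )` serves callers needing more.

The partition invariant — for every binary phenotype, cases + controls +
excluded equals the cohort — and the nesting of the antihypertensive
thresholds (`all 5 ⊆ >3 ⊆ >2 ⊆ >1`) hold by construction and are tested
against an independent brute-force oracle on small registries.

# Association model

Quantitative counts are heavily skewed (most users refill a handful of
times; some accumulate hundreds of purchases), so scans use the
rank-based inverse normal transformation with the Blom offset 3/8:
`INT(y) = qnorm((rank − 3/8) / (n − 3/4 + 1))`, average ranks for ties.
The offset is configurable; 3/8 is the default of the `rankNorm`
convention this transformation follows. With n = 3 the quantiles are
0.192/0.5/0.808 — note that the denominator is `n − 2c + 1`, not `n`.

Each variant is fit by ordinary least squares (after the
Frisch–Waugh–Lovell residualization against the covariates, which is
algebraically identical to the full `lm` fit and vectorizes over
variants) or by per-variant logistic IRLS. Wald z and two-sided normal
P values are reported; the normal approximation keeps `p` and `z`
mutually consistent, which downstream Bayes-factor code relies on.
Mixed-model machinery (as used on real biobanks with relatedness) is
deliberately absent: the simulator draws unrelated individuals, so a
fixed-effects fit is the correct model here, not an approximation.

Filters: monomorphic variants and MAF < 1e-4 are dropped everywhere;
the MAF < 0.005 filter applies only to INT-transformed quantitative
scans, where rare variants inflate type-I error. Genotyping-batch
covariates are only kept for batches with at least 10 cases and 10
controls (`pool_small_batches()`); smaller batches join a pooled
reference level.

Loci merge genome-wide significant variants (P < 5×10⁻⁸) within 1.5 Mb
by transitive closure along the chromosome; the lead is the smallest P
over all analyses, ties broken by phenotype name then position so output
is deterministic. Interaction scans dichotomize age or follow-up at the
sample median while retaining the continuous covariate, and use
0.05/(number of lead variants) as the significance line.

# Meta-analysis

Fixed-effect inverse-variance weighting after harmonizing each cohort to
the reference cohort's ref/alt orientation (swapped records: β and af
reflected; incompatible allele pairs dropped and counted). No
heterogeneity statistics are computed — the workflow this package
implements reports none. Variants present in a single cohort are carried
through unpooled but flagged. Candidate loci (lead P < 5×10⁻⁶) are
declared significant at the stricter P < 5×10⁻⁹. The direction
concordance test is an exact binomial tail; its null probability is a
**required argument** because the correct null depends on how variants
were selected (0.5 for a sign-agnostic null over two cohorts, 0.25 for
full concordance across three, etc.) and published analyses rarely state
it.

# Fine-mapping

Regions are ±1.5 Mb around each significant lead, merged when
overlapping; LD is the empirical dosage correlation. Per-variant
evidence is Wakefield's ABF with prior effect variance `W = 0.04`
(prior SD 0.2 on either the INT or the log-odds scale — the standard
default for this ABF family), computed in log space; posteriors are the
softmax over the region under a uniform causal prior. The 95% credible
set is the minimal posterior-sorted prefix reaching 0.95, ties broken by
genomic position. Purity is the exact minimum pairwise |r| over set
members (1 for singletons); sets below 0.5 fail the filter. Sets larger
than ten variants mark members below 0.01 posterior as unreported while
retaining the full set internally.

Multiple signals use iterative Bayesian single-effect regression on
z-scores: effect *l* sees the residual `z − R Σ_{k≠l} α_k μ_k`, is
refit as a single-effect posterior, and the cycle repeats until the
largest posterior change falls below `tol = 1e-3` or 100 iterations.
Effects whose average Bayes factor does not beat the null
(log mean ABF ≤ 0) are dropped, so null regions yield zero sets and
`L = 1` reduces exactly to the single-signal computation. `L = 5` is the
usual ceiling for 3 Mb regions at this scale. Only multiplications by
the LD matrix are needed, so positive-definiteness is not required; the
matrix is symmetrized defensively. Enrichment flags orient both
frequency columns to the sample's minor allele before taking the fold;
a zero reference frequency yields an infinite, flagged fold.

# Cross-trait model comparison

For a lead variant with effects in the medication scan, a risk-factor
GWAS and a CAD GWAS, four priors on the (risk, CAD) z-scores are
compared: both null (MED ONLY), one on (RISK / CAD) and both on with
prior correlation ρ (CAD+RISK). The medication effect is conditioned on
throughout — the variant was selected for it — so it contributes no
discriminating evidence and is omitted from the Bayes factor. `W = 0.04`
as in fine-mapping; `ρ = 0.9` encodes "fixed or highly correlated"
(values up to 0.999 approximate exactly fixed; at ρ = 0 the joint ABF
factorizes into the two single-trait ABFs, a tested identity). Uniform
model prior; support requires posterior ≥ 0.6; the CAD inclusion
probability is posterior(CAD) + posterior(CAD+RISK).

# PRS evaluation

Scores are plain weighted sums of lead-variant dosages (shrinkage
methods are out of scope — the evaluation protocol, not the weighting,
is implemented). The evaluation mirrors standard practice: decile /
percentile profiles against a reference bin, top-decile and
top-1%-vs-middle-quintile contrasts (odds ratios for binary outcomes,
with separation flagged rather than silently capped), Nagelkerke
pseudo-R² from null and full log-likelihoods, the Davidson–MacKinnon
J-test (each model's fitted values inserted into the rival model;
collinear scores are rejected), and the mean AUC over 100 random 75/25
train/validation splits. Splits producing a single-class validation set
are redrawn and counted, keeping exactly the requested number of valid
rounds; the split seed is explicit, so results are reproducible.

# The synthetic cohort

One latent liability per risk factor drives everything, which is the
smallest mechanism that reproduces the qualitative correlation structure
real registries show: initiation hazard `h₀ exp(0.5 L)` (earlier
treatment onset with higher genetic load), purchase rate
`4 exp(0.2 L)` per year with negative-binomial overdispersion,
fast-discontinuation probability `plogis(qlogis(0.10) − 0.5 L)`
(so purchases and changes correlate positively with each other and
negatively with discontinuation), simvastatin start probability 0.59
with liability-increasing switching, 1 + Binomial(4, plogis(qlogis(0.25)
+ 0.4 L)) antihypertensive groups, and liability-dependent second-line
and insulin progression. Baseline hazards (0.022, 0.045, 0.008 per year
for lipid/hypertension/T2D medication) were chosen once to give
realistic lifetime-use fractions (~40%, ~65%, ~16% over the 24-year
window); the intercepts above target the approximate published
prevalences of the binary patterns (10% fast discontinuation, 40%
switching). Genotypes are Binomial(2, maf) through a block-wise Gaussian
copula (block size 20, latent ρ = 0.8, blocks independent), which gives
controllable LD sufficient to exercise purity filters without coalescent
machinery. Defaults are 20,000 individuals × 2,000 variants — minutes on
one CPU; tests and the demo configuration scale down to 500–5,000
individuals and 60–2,000 variants, sizes chosen so the full suite runs
in a few minutes while keeping Monte-Carlo bands meaningful.

What the generator does **not** emulate: relatedness and population
structure (so mixed models are unnecessary by design), realistic
inter-purchase interval distributions (the stream model is a stand-in,
not a calibration target), dosage strengths, reimbursement rules, and
X-chromosome dosage. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative model, not
robustness to confounding present in real biobank data.

# Degenerate inputs and determinism

Empty person tables yield empty registries; empty significant sets yield
empty locus lists; single-variant regions have purity 1; flat regions
return the 95%-of-variants set flagged low-resolution; constant
interaction modifiers, non-positive standard errors, non-nested
likelihoods and collinear J-test scores raise errors rather than
returning numbers. Every simulation output is a pure function of its
configuration including the seed; the pipeline writes the full parameter
set into `manifest.json` and rejects unknown configuration keys before
any compute.

# Known limitations

* Binary-phenotype scans loop per-variant logistic fits; at biobank
  scale one would use score tests. At the package's design scale
  (≤ 10⁴ individuals × 10³ variants) this is a non-issue.
* The multi-signal fine-mapper fixes the prior variance rather than
  estimating it; with more than ~3 true signals per region its sets can
  overlap.
* The novelty annotation is only as good as the supplied
  known-association table; no live catalog queries are made.
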