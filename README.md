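# medtraj

Genetic analysis of lifelong medication-use trajectories derived from
ATC-coded drug purchase registries.

Nationwide prescription registries record every dispensed drug purchase
with a date and a WHO ATC code. Over decades of follow-up these events
trace how people are treated for the common cardiometabolic risk factors
— hyperlipidemia, hypertension and type 2 diabetes: how many purchases
they accumulate, whether they switch from simvastatin to another statin,
how many distinct antihypertensive classes they combine, whether they
abandon treatment after one or two purchases, and whether type-2-diabetes
treatment escalates to second-line agents or insulin. `medtraj`
implements, for statistical geneticists and pharmacoepidemiologists, the
full path from such a registry to genetics: phenotype derivation,
genome-wide association, meta-analysis, fine-mapping, cross-trait model
comparison and polygenic-score evaluation — together with a synthetic
registry + genotype generator with exported ground truth, so that every
stage is testable without access-restricted biobank data.

## What it computes

**Phenotypes (Table-1 style).** Three quantitative counts (purchases of
C10, C02/C03/C07/C08/C09, A10B drugs; non-users kept at 0; persons dead
or under 10 years old at the start of follow-up excluded) and nine binary
patterns with case/control/excluded statuses: statin switching,
fast discontinuation (1–2 purchases with >365 purchase-free days before
the person's end of follow-up), four antihypertensive combination
thresholds (>1, >2, >3, all 5 groups), second-line T2D agents
(A10BD/A10BH/A10BJ/A10BK) and progression to insulin.

**Association.** Quantitative counts are rank-inverse-normal transformed,
`INT(y) = Φ⁻¹((r − 3/8)/(n − 3/4 + 1))`, and scanned per variant with
linear regression `INT(y) ~ g + age + age² + follow-up + sex (+ batch)`;
binary patterns use logistic regression. Quantitative scans drop variants
with MAF < 0.005. Genome-wide significant variants (P < 5×10⁻⁸) within
1.5 Mb merge transitively into loci; G×age and G×follow-up interactions
are tested via median-split dummies at a Bonferroni threshold of
0.05/loci.

**Meta-analysis.** Fixed-effect inverse-variance pooling
`β̂ = Σ βᵢ/seᵢ² / Σ 1/seᵢ²`, `se = (Σ 1/seᵢ²)^(-1/2)` after allele
harmonization; candidate loci at P < 5×10⁻⁶ declared significant at the
stricter P < 5×10⁻⁹; exact binomial tests of cross-cohort direction
concordance.

**Fine-mapping.** Wakefield's approximate Bayes factor
`ABF = √(se²/(se²+W)) · exp(z²W / 2(se²+W))` with prior variance
W = 0.04, normalized over 3 Mb regions into 95% credible sets; purity
(min pairwise |r|) must reach 0.5; up to L = 5 signals via iterative
Bayesian single-effect regression on LD-residualized z-scores; >2-fold
minor-allele enrichment flags against a reference population.

**Cross-trait model comparison.** For each lead variant, bivariate
normal Bayes factors on the (risk-factor, CAD) z-scores compare MED ONLY
/ RISK / CAD / CAD+RISK hypotheses (shared-effect prior correlation
ρ = 0.9, uniform model prior); a model is supported at posterior ≥ 60%.

**PRS evaluation.** Weighted-sum scores of locus lead variants;
percentile/decile profiles with top-vs-bottom-decile and
top-1%-vs-middle-quintile contrasts; Nagelkerke pseudo-R²; the
Davidson–MacKinnon J-test between competing scores; mean AUC over 100
random 75/25 train/validation splits.

## Worked example

```r
library(medtraj)
cfg <- sim_config(n_individuals = 2000, n_variants = 200,
                  n_causal = c(lipid = 6, htn = 6, t2d = 6),
                  h2 = c(lipid = 0.4, htn = 0.4, t2d = 0.4),
                  maf_range = c(0.05, 0.5), seed = 42)
sim  <- simulate_cohort(cfg)
phen <- derive_phenotypes(sim$registry, sim$persons)
summarize_cohort(phen)
```

```
         phenotype    n cases controls excluded pct_cases
1  purchases_lipid 1967   644       NA       33        NA
4    statin_switch  372   124      248     1628      33.3
5      statin_disc  632    50      582     1368       7.9
6          htn_gt1 1458  1101      357      542      75.5
9         htn_all5 1458    22     1436      542       1.5
11  t2d_secondline  544   289      255     1456      53.1
12     t2d_insulin  538   106      432     1462      19.7
```

(excerpt) — 1,967 of 2,000 simulated persons are eligible for the
quantitative phenotypes (33 were dead or under 10 at the start of
follow-up); 33.3% of simvastatin starters switched statin; 7.9% of
statin users discontinued fast; 75.5% of antihypertensive users combined
more than one drug class. The same functions applied to the cases and
universes of a real nationwide registry reproduce its printed
percentages exactly, e.g. `case_percentage(19228, 45134)` → `42.6`.

Downstream, on the same objects:

```r
stats <- run_scan(sim$genotypes, phen$purchases_lipid[phen$eligible],
                  covariates = data.frame(age = phen$age_end[phen$eligible],
                                          sex = sim$persons$sex[phen$eligible]),
                  family = "linear")
loci  <- define_loci(stats)                        # 1.5 Mb merged windows
wakefield_abf(0.5, 0.1, W = 0.04)                  # log ABF = 9.195281
```

`run_pipeline(demo_config(seed = 1), "out/")` chains all nine stages
(simulate → phenotype → scan → loci → meta → finemap → compare →
annotate → prs) and writes per-stage TSVs, a parameter manifest and a
JSON summary. A command-line wrapper lives at
`inst/scripts/medtraj.R` (`simulate`, `phenotype`, `run` subcommands).

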