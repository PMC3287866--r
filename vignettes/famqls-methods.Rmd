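---
title: "Methods: kinship-aware score tests and rare-variant collapsing in families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship-aware score tests and rare-variant collapsing in families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`famqls` tests case-control association of rare variants in pedigree data.
This vignette is the package's account of its statistical model, the
simulator that defines its study conditions, and the numerical and design
choices a maintainer would want to know about.

## The model

### Genotype covariance in a pedigree

Genotypes are minor-allele half-counts $Y_i \in \{0, \tfrac12, 1\}$. Writing
$p$ for the minor allele frequency, $h_i$ for individual $i$'s inbreeding
coefficient and $\phi_{ij}$ for the kinship coefficient of $i$ and $j$, the
first two moments of $Y$ under the null (no association, random mating
founders drawn from the population) are

$$E[Y_i] = p, \qquad \operatorname{Var}(Y_i) = p(1-p)\,\tfrac{1+h_i}{2},
\qquad \operatorname{Cov}(Y_i, Y_j) = p(1-p)\,\phi_{ij},$$

i.e. $\operatorname{Var}(Y) = p(1-p)\,\Phi$ with $\Phi$ the kinship matrix
under the convention $\Phi_{ii} = (1+h_i)/2$. `kinship_matrix()` computes
$\Phi$ by the standard recursion in a parents-first topological order, per
family block (cross-family kinship is exactly zero); pedigree files may list
children before parents. Founders are assumed mutually unrelated and
non-inbred — the standard convention when nothing is known about founder
ancestry. $\Phi$ of any valid pedigree is positive definite, which the code
asserts by Cholesky factorization (all solves use the factor; no inverse is
ever formed).

### Quasi-likelihood score tests

Only the mean and covariance above are assumed — no full genotype
likelihood. The null allele frequency is the GLS estimate
$\hat p = (1'\Phi^{-1}Y)/(1'\Phi^{-1}1)$, which down-weights large sibships
relative to the naive mean. Two score tests are provided, both referred to
$\chi^2_1$:

* **MQLS** uses the prevalence-centred contrast $V = Z - k\,1$, so cases
  carry weight $1-k$ and controls $-k$: an affected individual is more
  informative when the disease is rare. $U = V'(Y - \hat p 1)$ with
  $\operatorname{Var}(U) = \hat p(1-\hat p)\left[V'\Phi V -
  (V'1)^2/(1'\Phi^{-1}1)\right]$; the subtracted term accounts exactly for
  estimating $\hat p$ from the same data.
* **WQLS** is the GLS score test of $E[Y] = p1 + rZ$ at $r=0$:
  $U = Z'\Phi^{-1}(Y - \hat p 1)$ with the analogous variance in
  $\Phi^{-1}$-quadratic forms. It needs no prevalence.

Both reduce algebraically to the classical allelic chi-square for unrelated
samples (MQLS when $k$ equals the sample case fraction); the test suite
verifies this to $10^{-10}$ against an independent `chisq.test()` oracle and
checks the 4-individual hand-computed example ($U = 0.5$,
$\operatorname{Var}(U) = 0.09375$, statistic $2.6667$).

### Collapsing

The gene indicator is deliberately the simplest burden variable: $G_n = 1$
iff subject $n$ carries at least one rare allele at any member SNP of the
gene. No MAF or functional weighting is applied — there is no consensus
that any particular weighting wins, and the dichotomous indicator flows
through the score tests unchanged as a pseudo-marker with dosage $G/2$
(a "SNP" with no homozygous-rare genotypes; with genuinely rare alleles the
homozygous carrier state is negligible and deliberately adds nothing beyond
presence). Member sets can be restricted to nonsynonymous variants
(`class_filter = "nonsynonymous_only"`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` (rare filter) | 0.01 | strict MAF cut: a variant is rare iff MAF < threshold |
| MAF source | `population_maf` | falls back to founder-only observed frequency, since offspring inflate allele correlation |
| `k` (prevalence) | none — required | MQLS contrast weight; no default is defensible, so it must be supplied |
| significance threshold | 0.05 | power counts replicates with p strictly below it |
| Bonferroni denominator | gene count | `bonferroni_threshold(0.05, 3205)` = 1.56e-5 for a 3,205-gene mini-exome |
| `VAR_TOL` | 1e-12 | relative to $\hat p(1-\hat p)$: below it a variance is degenerate and the unit untestable |

## Degenerate inputs and numerical choices

* Monomorphic markers, constant phenotype vectors (all-case or all-control
  subsets) and degenerate variances produce a *status flag* and no p-value,
  never an error or a silent drop. The constant-phenotype guard is applied
  to both tests uniformly (for WQLS the variance is algebraically zero; for
  MQLS it is not, but a test within an all-case family estimates nothing).
* Missing genotypes: individuals missing the tested marker (or, for a
  collapsed gene, missing a member SNP without an observed carrier
  genotype) are dropped listwise for that test with a warning; their kinship
  rows are dropped too. The original method's weighting of genotyped
  relatives of unphenotyped affected individuals is **not** implemented — a
  documented limitation, not an approximation of it.
* $\hat p$ is clamped to $[0,1]$ against floating-point drift; p-values are
  upper-tail $\chi^2_1$ with no continuity correction; an advisory is
  emitted when fewer than 30 individuals are analysed.
* All replicate-scale computation (`test_replicates()`) runs on one
  Cholesky factorization with BLAS-level cross-products; the per-replicate
  fallback is used whenever genotypes or phenotypes contain missing values.

## The simulator

`gene_drop()` draws each founder haplotype allele independently as
Bernoulli(MAF) and transmits one uniformly chosen allele per parent per
marker — the mechanism that concentrates a founder's rare variant inside
one family. Markers are dropped independently: no within-gene LD and no
recombination model, on the grounds that distinct rare variants essentially
always ride distinct haplotypes and the collapsing indicator uses no LD.

`simulate_phenotypes()` uses an additive liability threshold model:
$L_{ir} = \sum_j \beta_j (2 Y_{ij}) + \epsilon_{ir}$,
$\epsilon_{ir} \sim N(0,1)$ i.i.d., redrawn per replicate with genotypes
held fixed (the replicate-phenotype design). The affection threshold is the
empirical $(1-k)$ quantile per replicate, giving *exactly* `round(k n)`
cases; a fixed theoretical threshold would randomize the case count and add
pure noise to power estimates at desk scale. One integer seed drives
pedigree, founder alleles, transmissions and each replicate through a
documented sub-seed scheme, so any single replicate can be regenerated in
isolation.

What the simulator does **not** emulate: genotyping error, missingness,
ascertainment of families through affected probands, covariates or
polygenic background, population structure, X-linked inheritance,
quantitative traits. Tests passing on simulated data therefore demonstrate
correctness of the statistics under the stated model, not robustness to
those real-data features.

### Canned scenarios

* `gaw17_like_scenario()`: 8 three-generation families of 17–82 members
  (340 individuals — a deliberate desk-scale analogue of a ~700-subject
  8-family mini-exome), 40 genes / ~128 rare SNPs with MAF drawn from
  0.001–0.01, prevalence 0.3, 200 replicates. Causal structure: one
  CFTR-like gene with six distinct causal variants ($\beta = 1.2$ each,
  chosen so a carrier's case probability is ≈ 0.75 and single-variant power
  stays away from 1), one private causal variant ($\beta = 1.5$), one
  three-variant causal gene, the rest neutral; all causal variants
  nonsynonymous.
* `collapsing_contrast_scenario()`: the two-gene design that exhibits both
  directions of the collapsing trade-off — `PRIV` (3 causal variants
  guaranteed private to three different families with 4–10 carriers each,
  so all three families contribute real, comparable signal) and `DILUT`
  (one strong causal variant, $\beta = 2.2$, guaranteed 5–10 carriers so
  its single-SNP test has substantial power, among 20 neutral rare
  members). Effect sizes were fixed from the liability arithmetic at design
  time. The carrier bands are part of the scenario's definition: a draw
  where a "private multi-family" gene is really one dominant variant plus
  negligible ones, or where the "strong" causal SNP has two carriers, is a
  different phenomenon than the one the scenario is named for. Because
  gene-drop markers are independent, each conditioned variant is
  rejection-sampled on its own column, which is statistically identical to
  conditioning the joint draw.
* `null_calibration()` / `null_scenario()`: the same family structure with
  all $\beta = 0$.

Scenarios whose *definition* includes realized features of the genotype
draw (variants private to distinct families, an untransmitted founder
variant, carrier counts in a stated band) obtain them by bounded,
seed-deterministic rejection sampling over gene-drop draws. This is part of
the scenario's definition — conditioning the gene-drop distribution on the
features the scenario is about — not an alteration of the transmission
model, and every accepted draw is still an exact Mendelian gene drop.

## Calibration design

Two facts shaped the null-calibration harness, both measurable with the
package itself:

1. **Genotypes must be redrawn per replicate.** With one genotype draw held
   fixed, a single marker's across-replicate p-values follow that draw's
   *permutation* distribution (case labels are the only randomness), which
   can sit far from uniform for clustered rare-variant carriers even though
   the test is correctly calibrated unconditionally. `null_calibration()`
   therefore draws fresh founder alleles and transmissions as well as fresh
   phenotypes each replicate (batched gene drops keep 5,000 replicates
   under a minute), and reports type-I error pooled per test × unit class.
2. **The $\chi^2_1$ body is asymptotic in the carrier count.** A rare SNP
   with a handful of carriers yields a visibly discrete statistic: its tail
   (type-I error at 0.05) is calibrated, but no continuous reference can
   match its body, and a Kolmogorov–Smirnov test with thousands of draws
   will detect that discreteness. The harness therefore carries sparse
   single SNPs and small collapsed genes for *tail* calibration, plus a
   designated carrier-rich collapsed unit (8 members at MAF 0.008, median
   realized carrier count ≈ 40) on which the *distributional* check (KS
   against $\chi^2_1$, uniformity of p-values) is meaningful. Of the two
   tests, WQLS tends to run very slightly anticonservative on carrier-sparse
   units (its $\Phi^{-1}$ weights vary more across a family than MQLS's
   flat contrast), which the per-class type-I summaries make visible.

## The combined-versus-single-family comparison

For a variant private to one family, the combined-sample MQLS score is
exactly $U = \sum_i V_i Y_i$ (the global contrast sums to zero when the
case fraction equals $k$), so combined and single-family analyses differ
only through second-order terms: the $(1-\hat p)$ variance factor (favours
the single family, whose $\hat p$ is larger) versus the within-family
centering penalty under case enrichment (favours the combined analysis,
increasingly so as the effect strengthens). The comparison is therefore
intrinsically near-balanced, and which side "wins" in most replicates is
largely decided by the realized carrier configuration of the particular
genotype draw. The package reports the proportion directly
(`per_family_tests()` against `test_markers()`, computed by the acceptance
machinery over 100 replicates); users should expect it to vary widely
across draws and should not read a single draw's majority as a general law.
Aggregations over many causal SNPs that take each SNP's *best* family —
which gives multi-family SNPs several chances — favour the single-family
side by construction and are a different quantity.

## Problem sizes

Chosen as the package's study conditions: 8 families / 340 individuals for
all scenario work; 5,000 fresh-draw replicates for calibration; 200
replicates for power tables; 100 replicates for the per-family comparison;
50 random datasets of 20–200 unrelated individuals for the allelic
chi-square equivalence; $10^5$ labelled gene drops for the Monte-Carlo
kinship oracle in the test suite.

## Known limitations

* No weighting for unphenotyped or ungenotyped relatives (the affected-
  relative enhancement of the original method); listwise deletion instead.
* Autosomal only; `sex` is parsed but unused.
* No covariate adjustment and no quantitative traits.
* The simulator's liability model is a stand-in with a single additive
  term; it is not a reconstruction of any particular published simulation
  model.
* Multiallelic sites and VCF input are out of scope (convert upstream).
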