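---
title: "Assessing homing gene drives: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing homing gene drives: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivesim)
```

This vignette is the package's own account of the science it implements:
the inheritance model, how drive parameters are derived from
single-generation cross counts, the population model and its calibration,
and the design decisions taken where more than one defensible choice
existed.

## The inheritance model

The drive locus carries three alleles in the population model: wild-type
`W`, the homing drive `H` (Cas9, its sgRNA and a fluorescent marker on one
cassette), and a single resistance class `R` representing every
gene-drive-blocking indel (GDBI). Because the target is intergenic, `R` is
assumed cost-free, which is why the two resistance classes that generic
homing-drive cubes distinguish (costly and cost-free) are merged into one.
A fourth allele, the eCFP-marked "blocked drive" balancer `E`, exists only
in cross *designs*: its insertion destroys the protospacer, so it cannot be
cut, and it never appears in the population cube.

Germline cutting acts only on `W` alleles in genotypes that also carry `H`
(the cassette carries both Cas9 and the sgRNA, so `WR` and `WW` parents
never cut). For a hemizygous `WH` parent of sex $s$ the gamete
distribution is

$$P(H) = \tfrac12\,(1 + c_s\,ch_s),\qquad
  P(W) = \tfrac12\,(1 - c_s),\qquad
  P(R) = \tfrac12\,c_s\,cr_s,$$

with $c_s$ the cutting probability, $ch_s$ the homing (HDR) resolution
probability and $cr_s = 1 - ch_s$ the resistance resolution probability.
All other genotypes segregate Mendelian.

Maternal deposition acts after fertilisation: when the mother carries `H`,
each `W` allele of the zygote is cut by carried-over Cas9-RNP with
probability $d_F$ and resolves to `H` with probability $dh_F$ or `R` with
probability $dr_F$. Embryos lack a homology template, so the package (like
the study design it reflects) fixes $dh_F = 0$, $dr_F = 1$. Two modelling
choices here were genuinely open:

* **Deposition acts on both zygotic `W` alleles**, including a maternally
  inherited `W` that escaped germline cutting. The assay that measures
  $d_F$ can only observe the paternal allele (the balancer design makes the
  maternal allele uncleavable), but deposited RNP in the embryo has no way
  to distinguish allele origin, so restricting deposition to the paternal
  allele would be an assay artifact, not biology. This is a modelled
  generalisation and is flagged as such.
* **Per-allele independence**: each `W` allele resolves independently with
  the same $(dh_F, dr_F)$ split.

`build_cube()` assembles the mother × father × offspring tensor over the
six unordered genotypes `WW, WH, WR, HH, HR, RR`; every parental slice is a
probability distribution (row sums within $10^{-12}$ of 1), and the
`c = 0, d_F = 0` limit reproduces `mendelian_cube()` exactly. Genotypes are
unordered — no parent-of-origin state is kept beyond the deposition step —
matching the six-genotype state space of sex-aware homing-drive cubes.

## Estimating parameters from pooled cross counts

`estimate_cut_params()` reproduces the pooled arithmetic used in the study.
Within each line × parent-sex group, "low"- and "high"-drive pools are
combined: marker-positives $P$ (reconstructed as
$\mathrm{round}(\text{rate} \times n)$ where only percentages are printed;
raw counts bypass the rounding), estimated GDBI carriers
$G = \sum_p (n_p - P_p)\, g_p/t_p$ from the per-pool fraction of sequenced
marker-negative larvae with indels, and then

$$c = \frac{P + G}{N}, \qquad ch = \frac{P}{P+G}, \qquad cr = 1 - ch .$$

The GDBI fraction is applied **per pool** where that pool was sequenced,
with the pooled fraction as fallback for unsequenced pools; this preserves
the low/high structure that motivated the pooling. When no GDBI are
observed at all, $ch = 1$ and $cr = 0$.

### Two parameter scales

A subtlety documented here because it affects round-trip testing: the
pooled arithmetic attributes *every* marker-positive offspring to a cutting
event, so under the gamete model above, applying it to data generated from
the cube returns $(1 + c)/2$, not $c$ — a Mendelian cross (cube $c = 0$)
yields estimate $c = 0.5,\ ch = 1$. The estimator is exactly unbiased under
a different generative reading, in which the hemizygote parent transmits
`H` with probability $c\,ch$, `R` with probability $c\,cr$ and `W` with
probability $1 - c$. `synth_cross_dataset()` therefore offers both
generative models (`transmission = "cube"` and `"estimation"`); parameter
recovery is tested under the estimation model, and the simulation consumes
the estimated (paper-scale) parameters in the cube unchanged — exactly the
composition the study used. Users comparing modelled inheritance rates to
observed pooled rates should keep the scale difference in mind.

`estimate_deposition()` is the mean over replicates of the per-replicate
fraction of eCFP-class (balancer-inheriting, hence drive-free) larvae with
Cas9 activity at the drive locus. `derive_lifecycle()` converts fitness
summaries: $betaK = \text{fecundity} \times 4 / 11$ eggs/female/day (four
blood meals over an 11-day urban adult lifespan), `tLarva` as the rounded
larva-to-pupa time, a pupation-success modifier
$\xi = 1 + \Delta\text{viability}$ for drive carriers only when the deficit
is negative *and* flagged significant (the flag is an explicit input, not
an internal hypothesis test), and a 10% fertility reduction
(`fertility_mult = 0.9`) for drive-carrying genotypes.

## The population model

`simulate_release()` advances a daily, stage-structured state: egg cohorts
(`tEgg` days), larval cohorts (`tLarva` days), sexed pupal cohorts
(`tPupa` days), adult males, mated females (indexed by own and mate
genotype) and unmated females. Each day applies, in order: adult mortality;
retry-mating of unmated females; oviposition (Poisson egg numbers, genotypes
multinomial from the cube row of each mated pair); and aquatic aging with
emergence, where new males join the mating pool before newly emerged
females choose mates in proportion to male abundance. Females mate exactly
once; there is no remating or sperm competition. Offspring sex is assigned
1:1 at the larva–pupa transition (distributionally identical to assignment
at emergence, but it lets the per-sex pupation modifiers $\xi_F/\xi_M$ act
at pupation, which is where the viability cost is measured). The fertility
multiplier scales egg output of drive-carrying mothers; a `fertility_scope
= "both"` switch extends it to the mate's genotype, since the study's
source for the 10% figure does not attribute it to one sex.

Density dependence follows a Beverton–Holt-style daily crowding factor
applied to larvae only: survival is multiplied by
$\gamma / (\gamma + L_{\text{total}})$. Writing $s_A = 1 - \mu_{AD}$ and
$t_{Aq} = t_{Egg} + t_{Larva} + t_{Pupa}$, `calibrate_equilibrium()` fixes
the density-independent daily aquatic survival $s$ by requiring the
low-density per-generation growth
$R_0 = \frac{betaK\, s_A}{2 \mu_{AD}} s^{t_{Aq}}$ to equal `popGrowth`,
which forces the equilibrium crowding factor
$D^\* = popGrowth^{-1/t_{Larva}}$ and yields $\gamma$ in closed form from
the equilibrium larval census. The closed form solves the same fixed-point
condition a numerical root-solve would, exactly: a deterministic run seeded
from the calibrated state holds adults at $N_{eq}$ indefinitely, and the
suite checks the 2% contract over 365 days for randomly drawn valid
parameter sets. Calibration fails informatively when `popGrowth <= 1` or
when no daily survival in $(0,1)$ can deliver the required growth (e.g.
$\mu_{AD} \to 1$).

### Demographic defaults and provenance

| Parameter | Default | Why |
|---|---|---|
| `tEgg`, `tPupa` | 5 d, 2 d | standard laboratory rearing observations |
| `tLarva` | 6 d | rounded mean larva-to-pupa time (fitness table) |
| `betaK` | 27.3 eggs/♀/day | fecundity ≈ 75 × 4 blood meals / 11-day lifespan |
| `muAD` | 0.123 /day | literature default for urban *Ae. aegypti* |
| `popGrowth` | 1.175 /generation | literature default, low-density growth |
| `N_eq` | 10,000 adults | release-scenario population size, 1:1 sex ratio |
| release | 2,000 `HH` males, day 25 | 20% of the equilibrium population |

The per-line fitness inputs (fecundity, larval viability, larva-to-pupa
days) are shipped as `line_fitness_synthetic()` — a clearly labelled
synthetic stand-in, since the underlying life-table summaries are not part
of the package's printed inputs. Values were chosen once as realistic for
laboratory-reared material: wild-type viability 0.823 against 0.723 for the
*nanos* line (a significant deficit of 0.100, giving $\xi = 0.90$) and
0.831 for the *zpg* line (not significant, $\xi = 1$). The timing of late
drive decline is quite sensitive to this deficit: with $\xi = 0.9$ and the
10% fertility cost, carrier fitness is ≈ 0.86 per generation, and the
drive's final extinction stretches over many hundreds of days; a deficit
twice as large would roughly halve the tail. Conclusions about *when* a
drive is fully lost therefore inherit the uncertainty of the fitness
inputs, while the qualitative sequence — wild-type elimination, coverage
peak, resistance takeover, drive exhaustion — is robust across these
choices, and is what the property suite asserts.

### Stochasticity and reproducibility

Stochastic mode draws every transition (binomial survival and sex splits,
Poisson egg numbers, multinomial genotypes and mate choice), keeping all
counts non-negative integers; deterministic mode propagates expectations.
Each replicate derives its own seed from the run seed and replicate index,
so runs are reproducible and replicates independent. Simulated horizons in
the shipped tests and scripts (460 days for coverage questions, ~2,500 days
for extinction questions, 20–100 replicates) were chosen as the smallest
sizes at which the assessed quantities are stable to within their stated
tolerances.

### Outcome summaries

`effector_coverage()` reports the fraction of adult females with at least
one `H` allele — the proxy for carrying a linked antiviral effector — and
`summary_metrics()` reports first-passage days in days post-release:
wild-type elimination, coverage peak and its date, the closing of the
protection window (first post-peak day below 50% coverage), and drive
elimination. Elimination means "fewer than one individual (or allele)", a
definition that carries over to the real-valued deterministic mode; the
drive-allele census includes every life stage *and* the sperm genotypes
stored by mated females, since those can still found drive-carrying
offspring. Events that never occur in a replicate are reported as `NA`,
never as day 0.

## Amplicon indel summaries

Per-read edit classifications (a flattened CRISPResso-style table) are
summed into a single indel class — insertions, deletions and substitutions,
the latter treated as composite deletion/insertion events at the cut site,
with a switch to exclude them for sensitivity analysis. In pools of
outcrossed drive-negative larvae at most half of all amplicons can carry an
indel (each individual has one untouched balancer-side allele), so
`chimera_flag()` marks proportions above 50% as likely PCR-chimera
artifacts; the threshold is a parameter because drive-positive
contamination of a pool shifts the ceiling. `size_spectrum()` reports
read-weighted size histograms, the fraction of events within ±50 bp of the
cut site, and extreme sizes.

## What the synthetic generators do and do not emulate

`synth_cross_dataset()` reproduces the sampling structure of the cross
tables: family sizes from a truncated negative binomial matched to the
observed ranges/means (20–142, mean 59 for female parentals; 21–415, mean
91 for male parentals; dispersion fixed at a moderate 8, the exact
distribution being unstated), multinomial offspring genotypes, and a GDBI
assay that subsamples marker-negatives without replacement. It identifies
sequence-level GDBI with `R` alleles one-to-one, and it does not emulate
assay dropout (failed PCRs), genotyping error, or between-family rate
heterogeneity beyond binomial noise. `synth_amplicons()` inflates apparent
indel reads by converting unmodified reads with the chimera rate, giving
expectation $p + \text{chimera}\,(1-p)$; real chimera formation depends on
template mixing in ways this one-parameter model only caricatures. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated sampling model, not robustness to these unmodelled features of
real data.

## Numerical conventions

Probabilities are validated to $[0,1]$ with $10^{-9}$ slack on simplex
constraints; cube rows must sum to 1 within $10^{-12}$; cube CSVs print 15
significant digits. Marker-positive counts are reconstructed by rounding to
the nearest integer only when rates rather than counts are supplied.
Medians and quartiles use the linear-interpolation convention
(`quantile(type = 7)`) so box-plot summaries match other implementations.
Families with fewer than 20 scored offspring are excluded *before* any
pooling or summarising. Percentages are stored as fractions internally and
rendered as percentages only at report boundaries.

## Known limitations

* Single well-mixed patch: no migration, spatial structure or seasonality.
* One release scenario class (adult males at a scheduled day).
* The estimation-scale vs cube-scale tension described above is inherited
  from the pooled arithmetic; both scales are exposed, but the simulated
  inheritance under paper-scale parameters is stronger than the raw pooled
  marker rates imply.
* Fitness costs enter only through pupation success and fecundity; adult
  longevity and mating-competitiveness costs are not modelled.
* Drive-extinction *timing* is sensitive to the synthetic fitness
  stand-ins (see above); coverage and takeover dynamics are much less so.
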