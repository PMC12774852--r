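# phantomepi

Genealogical assessment of **phantom epistasis** — spurious SNP-by-SNP
interaction signals created by an unobserved, purely additive causal
variant.

## The problem and who this is for

Pairwise interaction tests fit `y ~ x1 + x2 + x1:x2` and report pairs with
a significant interaction coefficient.  If a third variant `z`, absent from
the genotype data, has an additive effect and is correlated with the
interaction term `s = x1 ∘ x2` conditional on `x1` and `x2`, the omission
biases the interaction estimate and produces a false positive.  Because `z`
is unobserved, this cannot be checked in the study data.  It *can* be
checked genealogically: any set of haplotypes that could share an
unsequenced variant is a **clade** of the ancestral recombination graph
(ARG), with a well-defined genomic span.  Given a reconstructed panel ARG,
a recombination map and the pair's summary statistics — no individual-level
study data needed — the package reports, per existing clade and per genomic
position, the minimum effect size `b` (in phenotype SD units) an omitted
variant would need to explain the interaction.  Small minima mean the
interaction cannot be distinguished from phantom epistasis.

The intended users are statistical-genetics researchers triaging reported
cis interactions, and methodologists studying interaction-test robustness.

## The statistic

For a clade with carrier indicator `z`, let `β_{z,s|x}` be the coefficient
of `s` in the regression of `z` on `{1, x1, x2, s}` over the panel
haplotypes, and `σ̂_s` the (genotype-only) standard error of the study's
interaction estimate.  An omitted variant of effect `b` shifts the
interaction Z-statistic to mean `m = b·β_{z,s|x}/σ̂_s`, so the probability
of a false rejection at level `α` (critical value `C = Φ⁻¹(1−α/2)`) is

    P(b) = Φ(−C − m) + 1 − Φ(C − m).

- **Test 1A** inverts `P(b) = P*` for a grid of probabilities (headline
  `P* = 0.5`) and reports the minimum `b` over clades within ±1 cM of each
  SNP.
- **Test 1B** reports `b = max(0, |t̂| − C)·σ̂_s/|β_{z,s|x}|`, the omitted
  effect at which the observed statistic `t̂` stops being significant.
- **Test 2** scores *hypothetical* clades (perturbations of the target sets
  `S = X1∩X2`, `K1`, `K2`, `O`) and keeps, per position, the smallest score
  among candidates compatible (nested-or-disjoint) with every clade
  observed there — a per-position map of where an unreconstructed
  problematic clade could still hide.

A neutral-coalescent null, `clade_probability(n, k) =
2(n−k)/[(k+1)(n−1)·choose(n−2, k−1)]`, calibrates how easily a fixed
`k`-of-`n` set forms a clade by chance.

## Worked example

```r
library(phantomepi)
fx  <- make_fixture("eight_sample")     # 8 haplotypes, 2 local trees, 3 SNPs
fit <- phantom_epistasis(fx$ts, snp1 = 20, snp2 = 70, study_N = 5000,
                         p_value = 1e-8)
summary(fit)
#> SNP pair 20 / 70
#>   target set sizes: S=2 K1=2 K2=2 O=2
#>   clades tested: 10 (sigma_s = 0.0566)
#>   min b  Test 1A: 0  (SNP-supported: 0)
#>          Test 1B: 0
#>          Test 2 : 0.111
#>   top SNP: 52
```

The joint-carrier set `S = {2,5}` is genuinely subtended by a branch of the
second local tree, so Tests 1A/1B report 0: an unsequenced variant on that
branch would explain the interaction exactly (the model including it would
be unidentifiable), and this pair's interaction should not be trusted.
Test 2's 0.111 is the smallest effect a *hypothetical* clade one edit away
from a target set would need, minimised over positions; `plot(fit)` draws
the per-position profile with hotspot regions.

Batch runs over a SNP-pair table, with per-pair failure isolation and TSV
output, go through `phantom_epistasis_batch()` (see also the wrapper script
in `inst/scripts/phantomepi-run.R`).  The simulation study —
`phantom_sim_study()` — simulates phantom and true-epistasis instances end
to end (SMC coalescent with recombination, masked-variant phenotypes,
LD-pruned Bonferroni interaction scan, Tests 1A/1B on the hits) and
evaluates how well the minimum `b` discriminates the two (ROC/AUC).

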