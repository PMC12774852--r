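---
title: "Assessing phantom epistasis with genealogies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing phantom epistasis with genealogies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomepi)
```

## The problem

A pairwise test for gene-by-gene interaction fits, over individuals $i$,

$$ y_i = \beta_1 x_{1i} + \beta_2 x_{2i} + \beta_{12}\, x_{1i} x_{2i} + \varepsilon_i $$

and calls the pair epistatic when the interaction coefficient $\beta_{12}$ is
significant.  *Phantom epistasis* is the failure mode in which a third,
unobserved variant $z$ with a purely **additive** effect $b$ on the phenotype
is correlated with the interaction term $s = x_1 \circ x_2$ after
conditioning on $x_1, x_2$; omitting $z$ then biases $\hat\beta_{12}$ and
produces a spurious interaction.  The variant $z$ is by definition not in the
data, so this cannot be tested directly on the study genotypes.

The package's approach is genealogical.  Haplotypes that share an unobserved
variant are exactly the descendants of some branch of the local genealogical
tree — a *clade* of the ancestral recombination graph (ARG).  A
reconstructed ARG for a reference panel from the same population therefore
enumerates, with genomic coordinates, every set of haplotypes that *could*
share an unsequenced variant.  For each such clade the package quantifies
how strong the hypothetical omitted variant would need to be to explain the
observed interaction, and reports the minimum over clades: a small minimum
means phantom epistasis cannot be ruled out.

## The test statistic under an omitted variant

Let $z$ be the carrier indicator of a candidate clade over the panel
haplotypes, and $\beta_{z,s|x}$ the coefficient of $s$ in the population
regression of $z$ on $\{1, x_1, x_2, s\}$ (equivalently the partial
covariance of $z$ and $s$ given $x_1, x_2$ over the partial variance of
$s$).  If the true model is $y = b z + \varepsilon$, the interaction
Z-statistic is asymptotically $\mathcal N(m, 1)$ with
$m = b\,\beta_{z,s|x} / \hat\sigma_s$, where $\hat\sigma_s$ is the standard
error of $\hat\beta_{12}$ in the study regression.  The probability of
(falsely) rejecting the no-interaction null at level $\alpha$, with
$C = \Phi^{-1}(1-\alpha/2)$, is

$$ P(b) \;=\; \Phi(-C - m) \;+\; 1 - \Phi(C - m). $$

`rejection_probability()` implements this; the acceptance suite verifies it
against simulated interaction scans (empirical rejection rates at
$m \in \{0, 0.5, 1, 2, 3\}$, 2,000 replicates of $n = 5{,}000$, agreeing
within three binomial standard errors; at $m = 0$ the value is exactly
$\alpha$).

Two inversions of this formula are reported per clade:

* **Test 1A** (`test1a_b_for_probability`): the effect size $b$ at which
  $P(b)$ equals a chosen probability (default grid
  $\{0.1, 0.3, 0.5, 0.7, 0.9\}$; headline value at $P = 0.5$).  Solved by
  bisection on $m \ge 0$ ($P$ is strictly increasing there), absolute
  tolerance $10^{-10}$ on $P$; then $b = m\hat\sigma_s/|\beta_{z,s|x}|$.
* **Test 1B** (`test1b_b_threshold`): given the original study's statistic
  $\hat t$, the threshold $b = \max(0, |\hat t| - C)\,\hat\sigma_s /
  |\beta_{z,s|x}|$ at which the observed statistic would sit exactly on the
  rejection boundary of the shifted null.  Non-significant inputs clamp
  to 0.

$b$ is reported as a magnitude, in phenotype standard-deviation units
(residual variance is fixed at 1; the phenotype is treated as
variance-standardised, the polygenic small-effect regime).  $\hat\sigma_s$
is approximated from panel genotypes only:
$\hat\sigma_s = \sqrt{[(M^\top M / n)^{-1}]_{ss} / N}$ with $M$ the centred
panel design $(x_1, x_2, s)$ and $N$ the study sample size.  A Monte-Carlo
test (resampling 5,000 study haplotypes from a 500-haplotype panel, 2,000
OLS fits of pure noise) confirms this within 5%.

**Degenerate proxies.**  The design's column space is exactly the functions
constant on the four target cells $S = X_1 \cap X_2$, $K_1 = X_1 \setminus
X_2$, $K_2 = X_2 \setminus X_1$, $O$ (the complement), linked by
$s = x_1 - k_1 = x_2 - k_2 = x_1 + x_2 + o - 1$.  A clade whose carrier set
is a union of cells has an exact representation $a_0 + a_1 x_1 + a_2 x_2 +
a_s s$; when $a_s \neq 0$ (for example a clade equal to a target set),
including it would make the model unidentifiable and the clade is reported
with $b = 0$ and an `unidentifiable` flag — the strongest possible phantom
signal.  When $a_s = 0$ (for example the SNPs' own clades, which are always
present), the proxy has no leverage on the interaction at all and the
infinite sentinel is reported.  This distinction matters: treating every
span member as $b=0$ would flag every pair as phantom through its own SNPs.

## Clade enumeration

`enumerate_clades()` walks the local trees left to right using incremental
edge differences (insertions and removals of parent-child edges between
adjacent trees), maintaining each node's descendant sample set and closing a
span whenever a set changes.  Identity is the sample set, not the node: a
set that disappears and re-forms is one clade with multiple spans, and
adjacent intervals with identical sets merge.  Supporting mutations are the
ARG mutations that fall on a branch subtending exactly that set inside its
span.  Correctness is defined — and tested, over 20 seeded ARGs of 30
samples and roughly 100 trees each — by a brute-force oracle that rebuilds
every local tree independently.

Conventions: positions are 0-based with half-open intervals, matching the
tree-sequence table format; the root clade and singleton clades are
excluded by default (the former cannot drive phantom epistasis conditional
on the intercept, the latter are absorbed per individual); `min_frequency`
defaults to 0.  An optional `samples` argument projects descendant sets
onto a subset, which is how a reference-panel ARG embedded in a larger
simulation is analysed without an explicit simplify step.  Any node
subtending two or more (projected) samples defines a clade, so polytomies
and unary nodes in reconstructed ARGs are handled by construction.

Because no tree-sequence reader exists for R, the package defines a
plain-text table format (`#nodes`, `#edges`, `#sites`, `#mutations`
sections with tskit column semantics) read and written by
`read_tree_seq()` / `write_tree_seq()`; binary `.trees` files can be
converted to it by dumping the four tables as text.

## Test 2: evidence against unobserved clades

Tests 1A/1B only score clades present in the reconstructed ARG.  Test 2
(`generate_candidates()`, `test2_profile()`) quantifies the residual risk
from clades that *could* exist despite not being reconstructed: candidate
carrier sets within a symmetric-difference radius of each target set
(conditional correlation with the target decays with edit distance), each
scored by its Test 1A effect size.  At a genomic position, a candidate
survives if it is laminar-compatible — nested or disjoint — with every
clade observed there: two sets can be clades of one rooted tree exactly
when neither partially overlaps the other, a rule tested exhaustively
against constructive tree embedding for all subset pairs at $n = 6$.  The
per-position minimum of surviving candidates' required effect sizes is
piecewise constant between observed-span breakpoints (evaluated there
exactly, plus a uniform grid for plotting), and *hotspot regions* collect
maximal runs within 5% (configurable) of the global minimum.  Compatibility
uses topology only — no branch lengths or mutation counts — and all four
target sets are processed, with the profile taking the minimum across them.

Defaults: `phantom_epistasis()` uses `test2_max_edit = 1`, which keeps the
candidate count at $1 + k + (n-k)$ per target and the profile cheap;
`generate_candidates()` itself chooses the radius adaptively up to a
$10^5$-candidate cap when `max_edit = NULL`.  Exact survival counts are
computed up to 20,000 candidates; beyond that only the minimum is tracked.
Candidates are scored once (the score depends on genotype moments, not
position); only survival varies along the genome.  An optional
coalescent-prior annotation is available through `clade_probability()` but
candidates are never filtered on it.

## The coalescent null for chance clades

Whether a matching clade is *surprising* depends on how easily a fixed set
of $k$ out of $n$ haplotypes forms a clade by chance.  Under the neutral
coalescent (uniform over labelled histories) this is

$$ P(n, k) = \frac{2\,(n-k)}{(k+1)(n-1)\binom{n-2}{k-1}}, \qquad 2 \le k \le n-1, $$

with $P(n,n)=1$ and, by convention, $P(n,1)=1$ (a terminal branch trivially
subtends its leaf; a flag treats singletons as non-clades instead).  The
closed form was derived against an exhaustive oracle — exact recursion over
the merge process, cross-checked by raw enumeration of all merge histories
for $n \le 5$ — and the tests pin it to that oracle for all $n \le 8$ and
to simulated topologies at $n = 50$.  Note $P(n,k)$ is *not* monotone in
$k$ all the way to $n-1$ (e.g. $P(5,3) = 1/12 < P(5,4) = 1/10$): near
$k = n$ the complement becomes small and chance clades get easier again.
Over moderate $k$ at realistic $n$ it decays extremely fast, which is why
only small target sets can be matched by chance.

## The simulator and the scaled discrimination study

`sim_tree_seq()` simulates the genealogy of $n$ haplotypes over a
recombining sequence under a constant-size coalescent with the sequentially
Markov approximation: a standard coalescent tree at the left edge, then
recombination events at rate proportional to total branch length detach a
lineage at a uniformly chosen point and re-coalesce it into the remaining
tree.  Output is an ordinary tree sequence (persistent node ids, edge spans)
so clade spans emerge naturally.  `sim_mutations()` adds Poisson
infinite-sites mutations (continuous positions).  Structural validity
(single root per tree), seeded determinism and Watterson's segregating-site
expectation are tested.

`phantom_sim_study()` reproduces the validation design at desk scale.
Study conditions (defaults): 2,000 diploid study individuals and a 200
haplotype held-out panel drawn from one ARG; constant $N_e = 10^4$;
mutation rate $2.36\times10^{-8}$, recombination $10^{-8}$ per bp per
generation (1 cM/Mb); effect size 0.2 with $h^2 = 0.01$ (the residual
variance is set so the genetic term explains exactly $h^2$, honouring both
numbers); causal/joint frequency in $[0.05, 0.25]$; true pairs 500 kb
apart; clade search within $\pm 1$ cM.  Each replicate uses a 1.2 Mb
sequence — enough for the pair separation plus scan windows — and 20
replicates per condition.  Phantom replicates mask the causal variant and
scan the surrounding 400 kb (study-MAF $\ge 0.05$, greedy LD pruning with
window 50 / step 5 / $r^2 \le 0.7$, a 150-variant cap after pruning,
Bonferroni over tested pairs).  True replicates plant a purely epistatic
pair (zero main effects, pairwise $r^2 \le 0.7$, non-nested carriers) and
regression-test that pair.

**Desk-scale power and the "hits" convention.**  With $N = 2{,}000$ and
$h^2 = 0.01$ the expected interaction Z-statistic is only about 3.3 (the
heritability budget refers to the raw product term, while the test sees its
partial variance given the main effects), so Bonferroni-corrected
detections are rare — at the full scale of tens of thousands of individuals
the same design yields $|Z| \approx 7$ and near-certain detection.  The
study therefore evaluates the tests on the top ten ranked scan pairs per
phantom replicate, keeping the case's smallest $b$ (the scaled analogue of
taking the minimum over that case's significant hits), and on the planted
pair for true replicates; Bonferroni significance is still recorded
truthfully in the `detected` column, and `require_significant = TRUE`
restores strict gating.  Diploid dosages are formed by pairing consecutive
haplotypes; the interaction is the dosage product.  All randomness flows
from one seed via pre-drawn per-replicate seeds.

ROC curves (`roc_evaluation()`) sweep an upper bound on a "reasonable"
effect size: instances whose minimum $b$ falls at or below the bound are
classified phantom.  Test 1A separates the two conditions cleanly at this
scale; Test 1B is less informative here because non-significant statistics
clamp to $b = 0$ by design, and at desk scale many true instances are not
significant.

What the generator does *not* emulate: realistic human demography
(expansion and admixture raise rare-variant loads and shift clade-size
spectra), ARG reconstruction error (the panel ARG here is the true
simulated genealogy, so robustness to topology errors in reconstructed
ARGs is not exercised), population
structure, genotyping error, and imputation. Passing the scaled study shows
the machinery discriminates masked-additive from purely epistatic signals
under neutral panmixia — not that the discrimination thresholds transfer
to any particular cohort.

## Numerical and degenerate-input choices

* Bisection for Test 1A brackets geometrically and stops at $10^{-10}$ on
  the probability; the inverse round-trips to $10^{-8}$ in the tests.
* p-values are converted to $|\hat t|$ through the upper-tail normal
  quantile, so values down to the smallest representable double convert to
  finite statistics; $p = 0$ is floored there with a warning.
* Rank-deficient interaction designs (nested SNP carrier sets make
  $s \equiv x_1$) raise a classed `unidentifiable design` error naming the
  collinear columns; the batch runner records the reason and moves on.
* LD pruning breaks ties deterministically (drop the lower-variance member,
  then the later index).  Scans skip rank-deficient pair designs and count
  them.
* Recombination-map lookups are piecewise linear; positions outside the map
  extrapolate with the terminal rates (with a warning), flat map segments
  invert to their leftmost base pair, and windows clamp to the map and
  sequence bounds.
* A study-versus-panel allele-frequency mismatch beyond 0.05 (absolute)
  triggers a warning, since frequency differences change the target-set
  composition.

## Worked example

```{r example}
fx <- make_fixture("eight_sample")
fit <- phantom_epistasis(fx$ts, snp1 = 20, snp2 = 70, study_N = 5000,
                         p_value = 1e-8)
summary(fit)
```

Here the joint-carrier set S = \{2, 5\} is genuinely subtended in the second
local tree, so Test 1A reports a minimum of 0 — an unsequenced variant on
that branch would explain the interaction outright, and the model including
it would be unidentifiable.

## Known limitations

* The $\hat\sigma_s$ approximation assumes a variance-standardised,
  polygenic phenotype and transfers second moments from panel to study; it
  is validated by resampling, not derived for arbitrary designs.
* Test 2's candidate space is a symmetric-difference neighbourhood; exotic
  problematic sets far from every target set are out of reach by design.
* Small panels flag small target sets aggressively (a handful of joint
  carriers almost always admits a compatible clade); interpret minima for
  low-frequency pairs together with `clade_probability()`.
* The simulator is SMC-approximate and constant-size; it is a study design,
  not a demographic inference tool.
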