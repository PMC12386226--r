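---
title: "Methods: heterotic grouping and combining-ability analysis in sorghum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterotic grouping and combining-ability analysis in sorghum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorghet)
```

## The problem

Hybrid sorghum breeding rests on heterosis: F1s between a cytoplasmic
male-sterile (CMS) seed parent and a fertility-restoring pollen parent can
outyield both parents. Two practical questions drive the analyses in this
package. First, can genome-wide SNP data sort a breeding panel into
heterotic groups, so that crosses are made between rather than within
groups? Second, how well do molecular genetic distance, phenotypic
distance, and combining ability each predict the heterosis a cross will
actually show in the field?

The package implements the complete chain: identity-by-state (IBS)
distance from SNP dosages, neighbor-joining (NJ) grouping with bootstrap
support, allele-frequency differentiation and FST between the groups, the
line × tester combining-ability model, heterosis statistics, and the
correlation of heterosis with each candidate predictor. A seeded
simulator supplies data with known ground truth for every stage.

## Molecular distance and grouping

For inbred lines coded as alternate-allele dosages $x \in \{0, 1, 2\}$,
the IBS p-distance between samples $i$ and $j$ is

$$d_{ij} = \frac{1}{|L_{ij}|} \sum_{l \in L_{ij}} \frac{|x_{il} - x_{jl}|}{2},$$

over the loci $L_{ij}$ where both are non-missing (pairwise-complete
deletion; a pair with no shared locus is an error rather than a guess).
This is a metric on complete data, lies in $[0,1]$, and is invariant to
locus order and to a consistent ref/alt swap. The absolute scale of any
SNP distance depends on the marker set and the distance model, so the
package treats the scale as implementation-defined and downstream steps
use only the relative structure.

Grouping builds a Saitou–Nei NJ tree (exact on additive distances;
negative branch lengths, which NJ can produce on noisy input, are clamped
to zero and logged) and removes the $k-1$ longest internal edges; the
connected components are the heterotic groups. With CMS metadata, the
component richer in restorers is labelled group I, matching breeding
convention where the restorer pool and the sterile/maintainer pool form
the two heterotic sides. Ties fall back to component size and then to a
lexicographic rule so the assignment is deterministic. Bootstrap support
resamples loci with replacement and counts, per internal bipartition of
the full-data tree, the share of replicate trees that contain it. Finer
subgroups (e.g. maturity classes within the restorer group) use the same
edge-cutting on the induced subtree with a configurable $k$.

## Differentiation between groups

Per locus, the alt/ref allele counts of the two groups form a 2×2 table
tested by the continuity-corrected chi-square test, with Fisher's exact
test whenever any observed or expected count is below 5 (a fixed
difference between small inbred panels is exactly the sparse case where
the exact test matters). Monomorphic loci get $p = 1$ by convention and
are logged. No multiple-testing correction is applied by default because
the flagging threshold is a plain per-locus $\alpha$; a Benjamini–Hochberg
column is available but off by default. Each fully inbred line contributes
two identical allele copies under the default coding; `inbred_haploid`
halves the counts for users who prefer to count each line once (the
two-copy default roughly doubles the evidence per line and so flags more
aggressively — a documented coding choice, not a statistical free lunch).

FST uses the Weir–Cockerham estimator by default, with the per-locus
variance components $a$ (between groups), $b$, $c$ and the multilocus mean
taken as the ratio of sums $\sum a / \sum(a+b+c)$ — the standard way to
average a ratio estimator without giving undue weight to uninformative
loci. Per-locus values may legitimately be negative; a clipped copy is
provided for reporting. Nei's $G_{ST} = (H_T - H_S)/H_T$ from unweighted
group frequencies is included because its closed form makes it directly
testable by hand arithmetic. A loci subset argument supports comparing a
QTL region's mean FST against the genome-wide mean.

## The line × tester model

`linetester()` fits the incomplete-diallel (NC II) decomposition to
plot-level data. With cell means $\bar x_{ij}$ for female $i$ × male $j$:

$$\hat g_i = \bar x_{i.} - \bar x_{..}, \qquad
  \hat g_j = \bar x_{.j} - \bar x_{..}, \qquad
  \hat s_{ij} = \bar x_{ij} - \bar x_{i.} - \bar x_{.j} + \bar x_{..}.$$

Effects are zero-sum and reconstruct every cell mean exactly; both
identities are enforced by tests at $10^{-9}$. With $r \ge 2$ replicates,
the two-way ANOVA mean squares give the variance components

$$\sigma^2_e = MS_e,\quad
  \sigma^2_{SCA} = \frac{MS_{fm} - MS_e}{r},\quad
  \sigma^2_{GCA_f} = \frac{MS_f - MS_{fm}}{mr},\quad
  \sigma^2_{GCA_m} = \frac{MS_m - MS_{fm}}{fr}.$$

Negative estimates are truncated to zero for the percentage and
heritability summaries (standard practice) while the raw values are kept
in the output. GCA% and SCA% are computed from the variance components —
not from mean squares — as shares of $\sigma^2_{GCA} + \sigma^2_{SCA}$,
so they always sum to 100.

Heritability conventions differ across the line × tester literature, so
the additive-variance multiplier is exposed: with fully inbred parents
the default is $\sigma^2_A = 2\,\sigma^2_{GCA}$ and
$\sigma^2_D = \sigma^2_{SCA}$, giving
$h^2 = 100\,\sigma^2_A/(\sigma^2_A + \sigma^2_D + \sigma^2_e)$ and
$H^2 = 100\,(\sigma^2_A + \sigma^2_D)/(\sigma^2_A + \sigma^2_D + \sigma^2_e)$.
Significance of the female, male and interaction terms uses the ANOVA
F-tests against the pooled error, with no across-trait correction.

The "comprehensive" (across-trait) GCA of a parent averages its per-trait
GCA effects after dividing each trait's GCA vector by its standard
deviation across parents, so a trait measured in centimetres cannot
dominate one measured in tons. A raw mean and custom weights are offered.
The published comprehensive-GCA column this mirrors is not reproducible
as a plain mean of its printed rows, so the standardized mean is fixed
here as the package's definition.

Missing cells are an error by default; under `allow_missing = TRUE` they
are filled with the grand mean and logged, which biases SCA toward zero
for those cells — acceptable for exploratory runs, not for the variance
components. Unbalanced replication is rejected rather than silently
reweighted.

## Heterosis statistics

Per cross and trait, with parental per-se means $P_1, P_2$:

- mid-parent heterosis $= 100\,(F_1 - MP)/MP$, $MP = (P_1 + P_2)/2$;
- high-parent heterosis $= 100\,(F_1 - HP)/HP$, $HP = \max(P_1, P_2)$;
- heterosis index $= (F_1 - \mathrm{check})/\mathrm{check}$ against an
  explicit check value or a named check cross.

A zero mid- or high-parent value leaves the statistic undefined (flagged,
not fabricated). Ranking uses the index when a check exists, otherwise
MPH, with ties broken by F1 mean and then cross name. Internally
everything is kept at full precision; the conventional display rounding
(two decimals for the index, one for percentages) happens only at output.

## Correlating heterosis with its predictors

For each trait the per-cross heterosis response (MPH by default; HPH or
the index by option) is correlated with four cross-level predictors:
molecular GD between the parents, phenotypic GD, $g_i + g_j$ (the additive
prediction of the cross mean — the natural cross-level summary of "GCA"),
and $s_{ij}$. Pearson's $r$ with $t = r\sqrt{(n-2)/(1-r^2)}$ and a
two-sided $t$ p-value is used throughout; the t-based p agrees with a
permutation p within ±0.01 at $n = 20$ in the test suite. A stratified
variant splits crosses at a GD threshold and reports $r$ separately below
and above, the pattern used to ask whether distance only predicts
heterosis once parents are sufficiently diverged. Whether such grids
should use per-cross values or per-parent-pair aggregates is ambiguous in
the source literature; this package uses per-cross values ($n$ = number
of crosses) and reports $n$ in every cell.

Phenotypic genetic distance standardizes each trait to mean 0 and unit
*population* standard deviation across parents and takes the Euclidean
norm of the difference vector; the population convention makes the
two-parent case sit exactly $\pm 1$ sd apart (distance 2) and the result
is invariant to any per-trait affine rescaling. Zero-variance traits are
dropped with a warning. Mahalanobis-type correlation-adjusted distance is
deliberately out of scope.

## The simulator and what it does (not) show

`simulate_study()` emulates the study design at desk scale: two panels of
8 fully inbred parents (defaults; 16 + 16 for FST calibration runs), 2000
biallelic SNPs, an 8 × 8 diallel with 3 replicates, and 10 traits named
by the usual agronomic abbreviations (GY, PWT, TKW, PL, PH, SD, DF, DM,
TL, BIY). Ancestral allele frequencies are uniform on $[0.1, 0.9]$; each
panel's frequency comes from the Balding–Nichols beta distribution with
parameter FST = 0.3 by default, and inbred dosages are drawn 0/2. One
shared QTL set (60 loci) carries trait-specific additive effects
$a \sim N(0, 1)$ and directional dominance $d = (d/a)\,|a|$, with the
dominance ratio positive for yield-type traits and negative for DF and DM
so that hybrids flower and mature earlier — the qualitative pattern the
field data show. Plot noise is $N(0, 2^2)$ on a baseline of 100. These
defaults were chosen once as a realistic sorghum-like configuration and
are not tuned per test.

The stored ground truth includes the true group labels, panel allele
frequencies, per-parent additive values, per-cross dominance deviations,
and the realized GCA-variance share of the noise-free F1 table, computed
by the same two-way decomposition with sum-of-squares divisors
$(f-1)$, $(m-1)$, $(f-1)(m-1)$ — the variance-component analogue the
ANOVA estimates. Recovery tests compare estimates against this realized
truth, not against nominal inputs, which is the honest comparison when
effects are drawn at random.

Two subtleties the simulator makes visible:

- *Dominance leaks into GCA* unless allele frequencies are exactly ½, so
  a "purely non-additive" architecture cannot be produced by setting
  additive effects to zero; the SCA-dominance test instead constructs
  balanced QTL (half of each panel carrying each allele) for which the
  leak is exactly zero.
- *Under pure additivity MPH carries no genetic signal* ($F_1$ equals the
  mid-parent exactly in the noise-free run), so additive predictors can
  only be validated against a response in which additive variation
  expresses, such as the heterosis index against a fixed check.

What passing simulations do **not** show: real sorghum panels have
linkage, historic admixture between the CMS and restorer pools,
epistasis, and genotype-by-environment interaction, none of which are
generated. The simulator validates the estimators' arithmetic and their
behaviour under the stated model, not the biology of any particular
panel.

## Numerical choices and degenerate inputs

- Distance: pairwise-complete deletion; error (naming the pair) at zero
  overlap.
- NJ: negative branch lengths clamped to 0 with a log entry; edge-length
  ties in group cutting broken by edge index; group-label ties by size
  then lexicographic tip label.
- Variance components: negatives truncated for summaries, raw retained;
  $r = 1$ designs fit effects but skip components with a warning.
- Correlations: constant vectors yield NA with a warning rather than an
  arbitrary zero; $|r| = 1$ reports $p = 0$ exactly.
- Differentiation: monomorphic loci $p = 1$, logged; FST undefined (error)
  when every locus is monomorphic.
- All randomness flows from explicit seeds; identical configurations give
  byte-identical written outputs.

## Problem sizes used in the tests

The suite runs the estimator-on-simulator loops at 200–2000 loci, 16–32
parents, and 10–50 seeds per property (the FST calibration uses 16 + 16
lines × 2000 loci × 20 seeds; group recovery 8 + 8 × 300 loci × 20 seeds;
GCA-share recovery 30–50 seeded diallels), sizes chosen so the whole
suite exercises every stage end-to-end in well under a minute of compute
per property while keeping Monte-Carlo noise far from the asserted
bounds.

## Worked example

```{r example, eval = FALSE}
st <- simulate_study(sim_config(seed = 42))
d  <- ibs_distance(st$geno)
tr <- nj_tree(d)
grp <- assign_groups(tr, k = 2, meta = st$geno$meta)
fst_estimate(st$geno, grp)

fit <- linetester(GY ~ female * male, st$pheno)
summary(fit)

ht <- heterosis_table(st$pheno, st$parents, check_value = 100)
heterosis_correlations(ht, gd_mol = d, ca = combining_ability(st$pheno))
```

## Known limitations

- NJ replaces likelihood-based tree building; for two-group cutting this
  is adequate (and exact on additive distances) but the tree itself is
  not a phylogeny estimate of publishable quality.
- Griffing's full-diallel methods (selfs, reciprocals) and REML/mixed
  models are out of scope; the ANOVA estimator requires a complete,
  balanced grid.
- The differentiation scan reports per-chromosome flagged fractions only
  descriptively; no enrichment inference is attached.
- The bundled reference tables validate arithmetic (index, ratios,
  zero-sums, extrema); the underlying field data and marker genotypes are
  not public, so genotype-dependent published values (distance range,
  group sizes, scan counts) are covered by the simulation properties
  instead.
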