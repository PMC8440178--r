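---
title: "Cross-disorder concordance of brain structural effect-size profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-disorder concordance of brain structural effect-size profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroconcord)
```

## The question

Large imaging consortia publish, for each neuropsychiatric disorder, a
vector of case–control effect sizes (covariate-adjusted Cohen's *d*,
case minus control) over a fixed set of brain phenotypes: cortical
thickness and surface area for the 34 Desikan–Killiany parcels and the
volumes of 7 subcortical structures, hemispheres averaged — 75
phenotypes over 41 regions.  Genome-wide association studies of the same
disorders yield genetic correlations ($r_g$) between disorder pairs.
`neuroconcord` asks two questions:

1. How similar are the *structural* alteration profiles of two
   disorders?  (the correlation of their Cohen's *d* vectors over shared
   phenotypes)
2. Is the matrix of imaging similarities related to the matrix of
   genetic similarities?  (the rank correlation between the two vectors
   of pairwise coefficients — the "correlation of correlations")

## The model and its pieces

**Pairwise profile correlation.**  For disorders $a, b$ with effect
vectors $d_a, d_b$ over the $n$ phenotypes present in both, the package
reports $r = \mathrm{cor}(d_a, d_b)$ (Pearson by default; Spearman
available) with

* analytic standard error $\mathrm{se} = \sqrt{(1-r^2)/\mathrm{df}}$,
  $\mathrm{df} = n - 2$;
* a two-sided Student-*t* p value from
  $t = r\sqrt{\mathrm{df}/(1-r^2)}$;
* a Bonferroni-adjusted p over the $D(D-1)/2$ pairs;
* an empirical permutation p from randomly shuffling one profile
  (default 10,000 shuffles), using the add-one estimator
  $(1 + \#\{|r^*| \ge |r_\mathrm{obs}|\})/(n_\mathrm{perm}+1)$, whose
  floor at the default setting is $1/10001 < 10^{-4}$.

Published cross-disorder tables print Pearson coefficients while the
rank statistic is conventional for the downstream correlation of
correlations; both methods are therefore implemented everywhere, with
Pearson the default for the pairwise table and Spearman the default for
the concordance statistic.  The Bonferroni denominator defaults to the
number of pairs (21 in the 7-disorder design) and is configurable via
`m_tests`; a threshold based on 22 tests circulates in the literature
for this design, but the printed adjusted p values are consistent with
21, which the package treats as authoritative.

**Per-phenotype statistics.**  Across disorders, each phenotype gets

* an exact binomial sign test of direction concordance (null 0.5;
  doubled smaller tail capped at 1; zero effect sizes excluded and
  reported separately — with 7 disorders, unanimity gives
  $p = 2 \cdot 0.5^7 \approx 0.016 < 0.05$, the working criterion for
  "sign homogeneity");
* Cochran's $Q = \sum_k w_k (d_k - \bar d_w)^2$ with inverse-variance
  weights $w_k = 1/v_k$ and the standard large-sample SMD variance
  $v = \frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2(n_1+n_2)}$, compared to
  $\chi^2_{k-1}$.  Sample sizes are carried per measure type (thickness,
  surface area, subcortical volume can come from different subsamples);
  when a disorder lacks counts for a measure it is excluded from that
  phenotype's $Q$, and phenotypes left with fewer than two contributors
  are skipped and logged, never silently defaulted.

**Genetic correlations.**  Given GWAS summary statistics
(SNP/CHR/BP/A1/A2 with Z, or BETA+SE or OR+SE converted to $z$), the
package applies the conventional pre-regression filters — drop INFO
< 0.90 (records without INFO are kept and counted), drop the MHC region
(hg19 chr6:25–35 Mb, bounds inclusive), keep markers with reference
panel MAF ≥ 5% — and runs a deliberately lightweight LD-score
regression: weighted least squares of $z^2$ (or $z_1 z_2$) on the LD
score $\ell$ with a free intercept and fixed weights $1/\max(\ell, 1)$;
the slope maps to $h^2 = \beta M/\bar N$ (or genetic covariance
$\rho_g = \beta M/\sqrt{\bar N_1 \bar N_2}$), and
$r_g = \rho_g/\sqrt{h^2_1 h^2_2}$.  Standard errors jackknife the full
ratio over 200 contiguous position-sorted blocks (the published
method's convention; reducible for small simulations).  Simplifications
relative to the reference software — single LD component, no iterative
reweighting, no explicit sample-overlap term beyond the free bivariate
intercept, no liability-scale conversion — are intentional: the
estimator is desk-scale and fully testable, and simulation tests verify
that its estimand matches (true $r_g \in \{0, 0.68\}$ recovered within
3 jackknife SEs in ≥95% of replicates at $M = 20{,}000$,
$N = 50{,}000$, $h^2 = 0.3$).  Alleles are reconciled before the
bivariate fit ($z$ negated for swapped A1/A2; strand-ambiguous A/T and
C/G markers dropped).  Published $r_g$ tables can be supplied directly
via `read_rg_table()`, bypassing the regression.

**Correlation of correlations.**  The two pair-indexed vectors are
aligned by disorder labels (never by position; mismatches raise an
error naming the offending pairs) and rank-correlated.  The p value
uses the *t* approximation on $n_\mathrm{pairs} - 2$ df by default,
with an exact/Monte-Carlo permutation over pair labels as an option;
because imaging pairs share disorders (and often control subjects), the
analytic p should be read as descriptive.  `leave_one_out()` recomputes
the statistic with each pair removed to flag single-pair leverage.

## The simulators and what they do (not) emulate

`gen_effect_panel()` draws, independently for each phenotype, a
$D$-vector from a multivariate normal with per-disorder means, scales,
and a target correlation matrix, then applies per-disorder missingness
masks.  The default scenario reproduces the published study's shape:

* 7 disorders (ADHD, ASD, BD, epilepsy, MDD, OCD, SCZ);
* target correlations equal to the published pairwise matrix, projected
  to the nearest positive-semidefinite correlation matrix (eigenvalue
  clipping at $10^{-8}$, diagonal rescaling);
* means and scales from the published per-disorder profile summaries
  (SCZ −0.22, epilepsy −0.12, BD −0.097, MDD −0.018; the three
  disorders without printed summaries set to field-plausible values
  near −0.05, scales back-computed as $\mathrm{SE}\sqrt{n}$);
* epilepsy missing all surface-area phenotypes (41 present) and OCD
  missing exactly one.  The published degrees of freedom force that
  missing phenotype to be a *surface-area* phenotype: the
  epilepsy–OCD row prints df = 39, which requires the OCD gap to lie
  inside the surface-area block epilepsy already lacks.  Which surface
  area is unknowable from the published table, so the first registry
  entry is used;
* measure-specific case/control counts from the published
  sample-demographics table.

`gen_gwas_pair()` draws LD scores from a shifted gamma (minimum 1,
mean ≈ 61) and, per SNP, a bivariate normal $z$ pair with exactly the
expectation model LD-score regression fits.  SNPs are independent given
their LD score — there is no realized inter-SNP correlation, no
allele-frequency spectrum, and no ancestry structure.  This matches the
regression's estimand while staying desk-scale, so passing tests
certify the estimator, not genome realism.

`gen_joint_scenario()` couples the two layers: the target imaging
correlations are a monotone (tanh) map of a latent vector
$a\,z(r_g) + \sqrt{1-a^2}\,\varepsilon$, with $a = 2\sin(\pi\rho/6)$
chosen so the expected Spearman correlation with $r_g$ equals the
requested coupling; PSD projection follows, and the post-projection
("achieved") coupling is reported.  At the published-scale coupling of
0.44, the mean recovered end-to-end concordance over 500 simulated
studies is within ±0.1 of the target (panel sampling attenuates it by
roughly 0.03).  At coupling 0, a single recovered rho still scatters
with the null Spearman sd of $1/\sqrt{20} \approx 0.22$ — the expected
*absolute* value of a null rho over 21 pairs is about 0.18 for any
correct implementation — so the null check asserts that the *mean*
recovered rho over 200 replicates is near zero (|mean| < 0.15), which
is the attainable and diagnostic reading of "distributed around 0".
The default $r_g$ vector is synthetic, chosen once at literature scale
(high for SCZ–BD, near zero for epilepsy–psychiatric pairs); no
published per-pair $r_g$ values were available to copy.

## Numerical and reproducibility choices

* One master seed drives everything; each disorder pair derives a
  private 31-bit permutation stream from (seed, sorted pair labels), so
  results are independent of evaluation order and of panel orientation
  (pairs are processed in sorted-label order internally).
* Generators save and restore the caller's RNG state.
* Exhaustive permutation mode (n ≤ 8) returns the exact proportion over
  all $n!$ permutations, identity included; ties on $|r^*|$ are counted
  as extreme with a $10^{-12}$ guard band.
* Effect tables are written at `%.17g`, so read/write round-trips are
  bit-identical; report TSVs are byte-stable across reruns with the
  same configuration and seed (p values additionally printed at 3
  significant digits, matching the published table's style).
* Degenerate inputs fail loudly: zero-variance profiles, < 3 shared
  phenotypes, constant LD scores, nonpositive heritabilities,
  mismatched pair sets, non-PSD targets (reported with the smallest
  eigenvalue).

The test suite's problem sizes — 200 replicates of the 2-disorder
recovery band, 100 LDSC replicates at $M = 20{,}000$, 500 + 200
replicates of the coupling scenarios — were chosen as the smallest
designs whose Monte-Carlo error is comfortably below the tested
tolerances.

## Limitations

Real consortium tables come with site heterogeneity, overlapping
control samples and spatial autocorrelation between neighboring
regions; none of these are modeled.  In particular, both the analytic
and the permutation p values for pairwise correlations ignore spatial
coherence of the cortical maps (a spatially constrained null is not
implementable on two fully overlapping cortical maps), and the
concordance p ignores dependence between pairs sharing a disorder.  The
LDSC stage is a simplified estimator and should not be used for
publication-grade heritability estimates on real data.

## A worked run

```{r, eval = FALSE}
js <- gen_joint_scenario(coupling = 0.44, seed = 7)
rg <- data.frame(disorder1 = sub("\\|.*", "", names(js$rg)),
                 disorder2 = sub(".*\\|", "", names(js$rg)),
                 rg = unname(js$rg), se = 0.1)
bundle <- run_pipeline(run_config(scenario = js$scenario, rg_table = rg,
                                  n_perm = 10000, seed = 7))
bundle$pairwise[1:3, c("pair", "r", "df", "se", "p", "p_bonf", "p_perm")]
bundle$concordance
write_report(bundle, "results/")
```
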