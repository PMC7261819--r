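---
title: "Count-dependent variance moderation: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-dependent variance moderation: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In shotgun proteomics a protein is quantified by summarizing the PSMs (or,
for label-free data, the peptides) assigned to it. The number of such rows
varies from one to hundreds per protein, and the precision of the summary
varies with it: within-group standard deviations of single-PSM proteins are
several-fold those of deeply covered proteins. A flat empirical-Bayes prior
on the variance — one prior distribution shared by all proteins — therefore
shrinks low-count proteins toward a variance that is too small (inflating
false positives exactly where quantification is weakest) and high-count
proteins toward a variance that is too large (costing power where
quantification is best).

This package makes the prior variance a function of quantification depth.

## The model

Per protein $g$, a one-factor linear model over $k$ groups gives group means,
the pooled within-group variance
$s_p^2 = \sum_i (n_i-1) s_i^2 / \sum_i (n_i-1)$,
and residual degrees of freedom $d_g = N - k$, shared by all proteins because
the input matrix is complete-case. The log sample variance is, up to a
constant, Fisher's-Z distributed:
$$e_g = \log s_p^2 - \psi(d_g/2) + \log(d_g/2), \qquad
  E(e_g) = \log s_0^2 - \psi(d_0/2) + \log(d_0/2),$$
$$\mathrm{var}(e_g) = \psi'(d_g/2) + \psi'(d_0/2),$$
with $\psi$, $\psi'$ the digamma and trigamma functions, $s_0^2$ the prior
variance and $d_0$ the prior degrees of freedom.

The package estimates $E(e_g)$ *per protein* from a local regression
(`loess`, tricube weights) of $\log s_p^2$ on the covariate $x$:

* `covariate_mode = "count"` — $x = \log_2(\text{PSM or peptide count})$,
  the core method;
* `covariate_mode = "intensity"` — $x$ = mean of the matrix values per
  protein, treating them as log2 intensities (the limma-trend style fit
  that suits label-free intensity matrices);
* `covariate_mode = "constant"` — a flat prior; the classic limma-style
  moderation, used as the internal baseline.

Solving the moment equations with the fitted curve substituted for
$E(\log VAR)$ gives the per-protein prior variance
$s_0^2 = \exp[\mathrm{pred}(e_g) + \psi(d_0/2) - \log(d_0/2)]$
and the shared prior df from
$\psi'(d_0/2) = \mathrm{mean}[(e_g - \mathrm{pred}(e_g))^2] - \psi'(d_g/2)$.
The posterior variance
$(d_g s_p^2 + d_0 s_0^2)/(d_g + d_0)$
feeds moderated t (per contrast, sign = first group minus second) and
moderated F statistics on $d_g + d_0$ degrees of freedom, with
Benjamini-Hochberg correction per contrast.

## Estimation choices

**$d_0$ grid.** The moment equation is solved by scanning
$d_0 = k \cdot 0.1$ and stopping at the first increase of the absolute
discrepancy. The absolute value matters: the signed discrepancy is monotone
in $d_0$, so "stops decreasing" is only meaningful for $|\cdot|$. The grid
is capped at $d_0 = 500$; if the discrepancy is still shrinking there, or if
the observed scatter of $e_g$ does not exceed the sampling noise
$\psi'(d_g/2)$ at all, the prior is treated as infinitely informative
($d_0 = \infty$): the posterior variance equals the prior and the moderated
statistics use the normal (t) and $\chi^2/(k-1)$-type (F) limits. Note that
on data whose variance is an exact function of the count this limit is the
*correct* answer, and finite samples from a no-scatter regime can also
legitimately return a large finite $d_0$ — the excess-scatter estimate
fluctuates around zero.

A Newton-iteration trigamma inverse (`trigamma_inverse()`, on the
nearly-linear transform $1/\psi'$, converged to $|\psi'(x)-y| < 10^{-8}$) is
provided as a numerical primitive for non-grid estimation.

**loess settings.** Span 0.75, degree 2, tricube weights, no robustness
iterations — the reference local-regression defaults. Replicated covariate
values (many proteins share a count) are handled natively; predictions for
covariates outside the fitted range (possible for proteins excluded from
fitting) are clamped to the boundary fit. With fewer distinct covariate
values than `degree + 1` the fit falls back to the flat prior with a
warning — which also makes the count-covariate fit collapse exactly onto
the constant-covariate fit when every protein has the same count.

**Logs.** The Fisher's-Z algebra uses natural logs throughout; only the
covariate uses log2 (counts roughly double in information per doubling of
PSMs, and log2 is the field's reporting scale).

**Zero variances.** Proteins whose replicates are numerically identical
have $s_p^2 = 0$ and no defined log variance; they are excluded from the
trend and $d_0$ estimation but retained in the output with posterior
variance equal to the prior variance at their covariate.

**Ordinary t.** The unpooled (Welch) statistic is reported with a
Welch-Satterthwaite p-value. The pooled-variance route is available through
the ANOVA F (for $k = 2$, $F = t_{\text{pooled}}^2$ exactly) and through
moderation with $d_0 = 0$.

**ANOVA F.** The between-group sum of squares is divided by $k - 1$ so that
the statistic is referred to $F(k-1, d_g)$ with a uniform null p-value
distribution; for $k = 2$ this agrees with the squared pooled t either way.

## Summarization

`median_sweep()` implements the four-step median sweeping normalization:
log2, subtract each PSM row's median, per protein take the per-sample
median over its rows, subtract each column's median. Output column medians
are exactly zero and the count equals the number of rows used. One nuance
worth knowing: because the row sweep precedes the column sweep, rescaling
one sample's intensities is *not* an exact invariance of the procedure for
more than two samples — a column shift can move individual row medians by
row-dependent amounts. It is exact for two-sample tables and whenever the
rescaling leaves every row's median element untouched; in practice the
residual effect is small because a global instrument drift moves all
columns coherently. Rescaling a whole PSM row (ionization efficiency) is
removed exactly.

`reference_ratio()` covers internal-reference TMT designs: each row is
divided by the (mean of the) reference channel(s), protein ratios are the
per-sample medians of row ratios, then log2. Reference columns leave the
output.

For data spanning several TMT sets, each batch is summarized on its own
columns and the matrices are inner-joined on protein id (a protein must be
quantified in every batch). The per-batch counts are unified by
`combine_counts()`; the default and recommended metric is the **minimum**
count across batches — the weakest experiment dominates a protein's
quantification error, and `count_metric_rss()` lets a user verify on their
own data that `min` minimizes the residual sum of squares of the variance
trend. All rows assigned to a protein are used (no unique-peptide
filtering), and even-length medians are the mean of the two central order
statistics.

## What the generators emulate

`simulate_null()` draws each protein's log2 ratios i.i.d.
$N(0, v(c))$ with the count $c$ assigned by group — by default 6000
proteins, 9 samples, 30 equal groups with counts 1–30. The variance law
$v(c) = v_\infty + a\,c^{-b}$ (defaults $0.02 + 0.20\,c^{-0.8}$) is a
monotone stand-in for curves fitted to deep TMT cell-line data: single-PSM
log2-ratio standard deviations near 0.47 falling to about 0.17 at 30 PSMs.
`enumerate_null_splits()` builds the null comparisons: for 9 samples and
triples, each of the $\binom{9}{3} = 84$ first triples is one comparison,
the opposing triple being the lexicographically smallest triple of the
remaining six samples. (Enumerating *all* unordered disjoint triple pairs
would give 840 comparisons; that variant is available as
`scheme = "all-disjoint"`, but 84 is the count consistent with the
two-groups-of-three design.) `null_fpr_experiment()` then reports false
positive rates for the ordinary t, flat-prior and count-prior fits.

`simulate_spikein()` emulates spike-in benchmarks: background proteins at
constant abundance, spike proteins shifted by $\log_2(\text{ratio})$ in the
second condition, counts from a truncated geometric on 1–30, per-row
ionization offsets, and per-row lognormal noise whose log2-scale sd is
$\sqrt{c\,v(c)}$ so that the median-aggregated protein values have
count-dependent within-group variance on the scale of $v$ (the median of
$c$ rows carries an extra factor approaching $\pi/2$ at large $c$, which
preserves the monotone structure the benchmark needs). With a spike
fraction under ~20% the median sweep's column centering absorbs only a
small part of the spike signal; fold-change recovery to within 0.1 of
truth holds in the low-noise regime, while at realistic noise the
attenuation grows with the spike fraction.

`simulate_multibatch()` emulates a deep multi-TMT design: 3 batches, 9
groups with one replicate of each group per batch ($d_g = 18$), per-protein
base counts $4 + \mathrm{Geom}(0.10)$ capped at 30 with lognormal
batch-to-batch jitter (sd 0.2 on the log scale), and with probability 0.4
one batch dropping to a weak count of 1–3 PSMs. A sample's quantification
error is governed by its batch's count, so the pooled variance mixes the
per-batch variances and the weak batch dominates — the structure that makes
the minimum count the informative summary. Shallow-coverage designs do not
separate the metrics: when base counts are already small, every metric
carries nearly the same information and the $\chi^2$ scatter of the
log variances swamps the differences.

What the generators deliberately do not model: missing values and their
censoring mechanism, ratio compression from isotopic impurity or
co-isolation in TMT, compositional shifts from large spike amounts,
between-batch normalization artifacts, and correlated (shared-peptide)
quantification across proteins. Passing tests on these generators show the
estimation machinery is correct and calibrated under the stated model, not
that real data meet the model.

## Benchmarking conventions

`pauc()` computes the partial area under the ROC curve for specificity
above a floor (default 0.95), with tied scores grouped into single
threshold steps and the boundary handled by linear interpolation, then
normalizes by the maximum attainable area $1 - \text{floor}$ and reports a
percentage. Under this normalization a perfect ranking scores 100, but the
chance level is *not* 50: an uninformative ROC is the diagonal, its area
over the restricted range is $(1-\text{floor})^2/2$, and the normalized
chance level is $50\,(1-\text{floor})$ percent — about 2.5% at a 0.95
floor, because at high specificity an uninformative classifier has found
almost no true positives yet.

## Problem sizes used by the shipped experiments

The package's own test experiments use scaled configurations chosen to
make Monte-Carlo bands tight enough to be meaningful while keeping a full
run comfortable on a laptop: null calibration on 2000 proteins and 20 of
the 84 splits; d0 recovery at 5000 proteins and 20 seeds per truth value;
spike-in ranking at 3600 proteins and 20 seeds; count-metric comparison at
2000 proteins and 10 seeds. The same configurations are what
`scripts/acceptance.R` re-runs.

## Known limitations

* One grouping factor only: no covariates, blocking or mixed effects.
* Complete-case matrices: a single shared $d_g$; proteins with missing
  values are dropped at read time rather than modelled.
* A single $d_0$/$s_0^2$ fit is shared by all contrasts of a design.
* The count covariate is a single integer per protein; within-protein
  heterogeneity of PSM quality is not modelled.
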