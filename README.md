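# psmvar

Differential protein expression analysis for quantitative mass-spectrometry
proteomics, with an empirical-Bayes variance prior that depends on how
deeply each protein was quantified.

## Why

In shotgun proteomics every protein is quantified by summarizing the
peptide-spectrum matches (PSMs) — or, label-free, the peptides — assigned
to it, and the number of such rows spans two orders of magnitude across
proteins. Within-group variability shrinks sharply with that number:
single-PSM proteins are several-fold noisier than proteins seen twenty
times. Classic moderated-t analysis (limma-style) shrinks every protein's
variance toward one common prior, which understates the variance of
shallow proteins (false positives) and overstates that of deep ones (lost
power). The usual workaround — discarding single-peptide proteins — throws
away 10–20% of the proteome, mostly low-abundance proteins.

`psmvar` keeps them all: the prior variance of protein $g$ follows a local
regression (loess) of $\log s_p^2$ on $\log_2(\mathrm{count}_g)$. With
pooled variance $s_p^2$ on $d_g$ residual df, prior variance $s_0^2(g)$
from the fitted trend and prior df $d_0$ solved from the Fisher's-Z moment
equation $\psi'(d_0/2) = \mathrm{mean}[(e_g-\mathrm{pred}(e_g))^2] -
\psi'(d_g/2)$, the moderated statistic is

$$t_g = \frac{\bar Y_{G1} - \bar Y_{G2}}
  {s_{p[\mathrm{mod}]}(g)\sqrt{1/n_1 + 1/n_2}},\qquad
  s^2_{p[\mathrm{mod}]}(g) = \frac{d_g s_p^2(g) + d_0 s_0^2(g)}{d_g + d_0},$$

referred to a t distribution on $d_g + d_0$ df, with Benjamini-Hochberg
FDR control. A moderated ANOVA F covers multi-group designs.

The package also provides the surrounding workflow: median-sweeping and
reference-channel summarization of PSM tables to protein log2-ratio
matrices, count unification across TMT batches (minimum/mean/median/sum/
maximum, with a residual-sum-of-squares diagnostic showing why *minimum*
is the right choice), variance-by-count profiles, partial-AUC
benchmarking, and synthetic null / spike-in / multi-batch generators with
known ground truth.

## Worked example

A simulated TMT spike-in: 2000 background proteins, 400 spiked at ratio 3
into condition B, triplicates, summarized by median sweeping and tested
with the count-dependent prior.

```r
library(psmvar)
sk <- simulate_spikein(n_background = 2000, n_spike = 400, ratio = 3, seed = 7)
pm <- median_sweep(sk$quant)
lf <- fit_group_means(pm, sk$design)
eb <- spectra_count_ebayes(lf, pm, contrasts = list(c("B", "A")))
res <- as.data.frame(eb)
head(res[order(res$p_B.vs.A), c("protein", "count", "logFC_B.vs.A",
     "t_mod_B.vs.A", "p_B.vs.A", "p_adj_B.vs.A")], 5)
```

```
      protein count logFC_B.vs.A t_mod_B.vs.A p_B.vs.A p_adj_B.vs.A
 protein02044    20         1.47        10.66 1.39e-12     3.33e-09
 protein02123    16         1.59        10.39 2.78e-12     3.34e-09
 protein02051    13         1.59        10.04 7.01e-12     5.43e-09
 protein02014    30         1.05         9.88 1.05e-11     5.43e-09
 protein02382    17         1.42         9.81 1.27e-11     5.43e-09
```

The fit reports `d0 = 31.3` prior df, i.e. strong but count-specific
shrinkage. The top hits are true spikes (`logFC` near $\log_2 3 = 1.58$,
attenuated slightly by the median sweep's column centering). At a 1% FDR
cutoff this run reports 358 significant proteins of which 354 are true
spikes, and ranking by $|t|$ gives a partial AUC (specificity > 95%) of
96.2% for the count-dependent prior versus 95.7% for a flat prior on the
same data. On null data the count-dependent fit stays calibrated
(empirical false positive rate ≈ the nominal p-threshold) while being no
looser than the flat-prior fit.

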