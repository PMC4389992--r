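---
title: "Methods: pathway de-regulation scores and cancer-specific survival"
author: "dpes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway de-regulation scores and cancer-specific survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `dpes`: the paired
differential-expression test, the DGES/DPES scoring construct, the survival
models, the synthetic-data generator that backs the test suite, and the
numerical conventions and design choices where the method left room for
interpretation.

## The analysis question

Given paired tumor and adjacent-normal RNA-seq libraries for each subject in
a colon-cancer cohort with registry follow-up, the analysis asks whether the
*extent of pathway de-regulation* in a tumor — how many of a pathway's genes
are far from their normal expression in that particular patient — predicts
cancer-specific survival. The chain is: find robustly differentially
expressed (DE) genes by cross-validation over two matched discovery groups;
find the pathways those genes overrepresent; quantify each subject's
per-pathway de-regulation with a quartile-sum score; and model
cancer-specific mortality on score tertiles.

## Paired differential expression

**Model-free paired test.** For each gene the unit of analysis is the
within-subject difference between the tumor and normal library. No
distributional model is assumed for counts; inference is by permutation,
with the within-pair tissue-label flip as the null group (exchangeability of
the two tissue labels within a subject under no differential expression).

**Depth-equalizing thinning.** Sequencing depth is a technical confounder of
count comparisons. Each library of depth $d_j$ is binomially thinned to the
minimum depth $d_0$: every count $c$ is replaced by a
$\mathrm{Binomial}(c, d_0/d_j)$ draw. This is repeated `nResamples` times
(default 20) and the statistic is averaged over resamples, trading a little
information for exact depth comparability. Note that thinning is a
*total-count* equalization: a global shift in expression (most genes up)
partially re-enters individual genes as apparent opposite-direction change.
This is inherent to depth equalization, not an implementation artifact, and
is why test fixtures that need a clean per-gene signal equalize depths by
construction.

**Statistic.** Within a resample, the Wilcoxon signed-rank statistic of the
differences is standardized by its exact null moments under independent sign
flips: zero differences are dropped, tied absolute differences receive
mid-ranks $r_i$, and
$$T = \sum_i r_i\,\mathrm{sign}(d_i) \Big/ \sqrt{\sum_i r_i^2},$$
which has mean 0 and variance 1 under the null for any tie pattern. The
reported statistic is the mean of $T$ over resamples. If every difference is
zero in every resample the statistic is 0 and flagged degenerate.

**Permutation null.** Null statistics flip each pair's label independently
and recompute the averaged statistic *on the same thinning resamples*
(common random numbers), so resampling noise cancels between observed and
null values instead of inflating the null variance. With $n$ pairs at most
$2^n$ distinct flips exist; for $n \le 10$ all of them are enumerated and
$p = \#\{|T_{perm}| \ge |T_{obs}|\}/2^n$ (the identity flip makes $p > 0$).
Otherwise `nPerm` flips (default 1,000) are sampled with replacement and the
add-one rule $p = (1 + \#\{|T_{null}| \ge |T_{obs}|\})/(nPerm + 1)$ keeps
$p \ge 1/(nPerm+1)$. The test is two-sided; Benjamini–Hochberg q-values are
reported alongside.

**Fold change and selection.** Fold change is the ratio of mean tumor to
mean normal expression on the counts-per-million scale, with pseudocount 0.5
added to both means (raw-count means would be biased by depth; the
pseudocount keeps zero-expression genes finite). A gene is selected when
$p < 0.05$ *and* the fold change exceeds 2 (or is below 1/2), in the same
direction, in both discovery groups. The thresholds, 20 resamples and 1,000
permutations are the method's canonical operating point and are all
configurable.

## Discovery groups

Because the cohort contains more survivors than deaths, DE discovery on the
full cohort would be dominated by survivors' tumors. The deceased
(cancer-death) subjects are therefore split at random into groups A and B
whose death counts differ by at most one, and each deceased subject is
matched where possible to a distinct alive subject of the same sex and age
category (5-year bins from 30 to 80+, configurable), the match inheriting
the group. Matching is uniform random within the exact stratum, which is an
exact maximum matching there; per-stratum shortfalls are logged. Two
interpretive choices are deliberate: "died" means death from the cancer
(other-cause deaths and unknown vital status stay out of the split, since
the balancing exists for the survival endpoint), and unmatched subjects
remain unassigned but still enter the full-cohort survival and stage
analyses.

## Overrepresentation

Selected genes are tested against a GMT collection with the upper-tail
hypergeometric law, $p = P(X \ge k)$ for $k$ selected members of a $K$-gene
set within an $N$-gene universe and $n$ selected genes. The universe is the
*analyzable* space — the features surviving the coding/known-function/
expressed filter — not the whole genome; using the genome would overstate
every enrichment. Set members are intersected with the universe before
testing; sets entirely outside it are skipped with a warning. Pathways with
BH-adjusted $p < 0.05$ are carried into scoring. The commercial
pathway-analysis stack this stands in for adds curated-network context that
a plain set intersection cannot reproduce; this is a declared fidelity
limitation, and specific pathway identities are not a validation target.

## DGES and DPES

The per-subject, per-gene differential expression is
$\delta_{ig} = \log_2\!\big((t_{ig} + c)/(n_{ig} + c)\big)$ with $c = 0.5$
on normalized counts. Two conventions matter here:

**Orientation.** Scores must mean "distance from normal" for both up- and
down-regulated genes — the bottom quartile is "closest to normal" either
way. Each gene's $\delta$ column is therefore multiplied by the gene's
cohort-level direction sign before binning. This is the single most
consequential interpretation in the package: without it, a strongly
down-regulated gene would score its most de-regulated subjects as 1.

**Normalization.** The default scale is median-of-ratios size factors (the
DESeq estimator) rather than CPM. With a net-up-regulated tumor
transcriptome, total-count scaling deflates the tumor-side values of every
*unchanged* gene, so a subject's global DE load leaks into the profile of
pathways that are not de-regulated at all; after orientation this
manufactures pathway–outcome associations for null pathways. Size factors
anchored on the unchanged majority of genes remove the bias (in simulation,
the correlation between a null pathway's score and the latent de-regulation
level drops from ~0.3 to <0.06). `normalization = "cpm"` is retained for
comparison.

Binning uses linear-interpolation sample quantiles (R type 7) of the
oriented values over the full analysis cohort (not per discovery group — the
score feeds a full-cohort survival model): score 1 strictly below the 25th
percentile, 3 strictly above the 75th, 2 otherwise. Boundary equality falls
in the middle bin, so when a gene's values are all equal everyone scores 2.
DPES is the sum of DGES over a pathway's scored member genes, hence lies in
$[G, 3G]$ for $G$ genes and is additive over disjoint pathways. Tertiles cut
at the 33.3rd and 66.7th percentiles of the cohort DPES distribution with
ties going to the *lower* tertile, making T3 ("most de-regulated")
conservative; a pathway whose scores are all identical yields a single
degenerate tertile and a warning.

## Survival and stage models

Cancer death is the event; other-cause deaths, survivors and
unknown-vital-status subjects are censored at last contact (a cause-specific
hazard analysis — competing-risks quantities such as subdistribution hazards
are out of scope). The Cox model uses tertile indicators with T1 as
referent, adjusted for age (continuous, years), sex, AJCC stage (indicator
contrasts vs stage 1) and the four molecular phenotypes (0/1), with the
Efron approximation for ties since month-resolution times guarantee them.
Wald 95% intervals are exponentiated; coefficients above 10 in absolute
value trigger a separation warning. Subjects with missing follow-up or
unknown stage are dropped with a logged count. Kaplan–Meier curves per
tertile use the product-limit estimator. Stage summaries report per-stage
DPES means/SDs and a Welch two-sample t-test of stage 1 vs stage 4 (the
stage comparison's test was an open choice; Welch avoids the equal-variance
assumption at very unequal stage sizes).

## The synthetic-data generator

`SimulationConfig()` defaults describe the population-based cohort the
package targets: 175 subjects, 17,141 genes, 10% of genes truly DE with fold
changes uniform on (2, 6) and 62% up-regulated, negative-binomial counts
(dispersion 0.2, the typical bulk RNA-seq scale), expected library depths
uniform on 1–3 million reads, 30 pathways of 16 genes, and a clinical
mixture of ~22% cancer deaths, ~10% other-cause deaths, ~9% lost to
follow-up and the rest administratively censored at 120 months, with stage
probabilities (0.23, 0.32, 0.33, 0.12), molecular-phenotype prevalences
(TP53 0.44, KRAS 0.27, MSI 0.18, CIMP 0.26), 54% male, and age
N(65.2, 10.2²) years.

Per-gene relative abundances are log-normal; for DE genes the tumor mean is
the normal mean times $\mathrm{fc}^{\pm m_i}$, where $m_i \sim U(1-w, 1+w)$
($w = 0.5$) is a per-subject de-regulation multiplier. A closed-form
calibration constant $K = (\mathrm{fc}^w - \mathrm{fc}^{-w})/(2w\ln
\mathrm{fc})$ divides the tumor mean so the *cohort-level* expected fold
change equals the nominal value exactly despite the heterogeneity. The
subject's true tertile is the tertile of $m_i$, and survival times are
exponential with hazard $h_i = h_0 \exp(\beta_{tier(i)})$, default
$\beta = (-0.9, -1.1)$ for tertiles 2 and 3 — hazard ratios ~0.41 and ~0.33,
the scale of the reported pathway effects. The exponential baseline is
chosen for closed-form checkability; the Cox fit is baseline-agnostic, so
nothing is lost in generality. Survival-linked pathways draw 90% (default)
of their members from DE genes; background pathways draw none. Pathway
overlap is off by default (an `allowOverlap` flag exists because real
canonical pathways share genes heavily).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: FFPE degradation and other library-quality
artifacts; isoform-level effects; field effects in adjacent-normal tissue;
correlation between stage and de-regulation (stage is drawn independently of
$m_i$, so simulated cohorts show no stage gradient in DPES, unlike a real
cohort); correlated DE beyond the single global multiplier; and overlapping
pathway membership under the default settings.

## Reproducibility and numerical conventions

All randomness flows from integer seeds: the generator's counts, clinical
and gene-set draws use `seed`, `seed + 1`, `seed + 2`; the pipeline derives
per-stage substreams from the global seed so stage-level reruns are
reproducible, and every run writes a manifest with md5 checksums of each
artifact. Identical configuration and seed give byte-identical outputs.
Permutation comparisons use an absolute tolerance of $10^{-12}$ when
comparing $|T_{null}|$ to $|T_{obs}|$ so that ties of equal magnitude count
as exceedances rather than being lost to floating-point noise.

The test suite and acceptance script run at deliberately moderated problem
sizes chosen to exercise each operating characteristic: the permutation
test's size is measured on a 2,000-feature, 30-pair null cohort with 200
permutations; Cox coverage uses 50 replicates of 2,000-subject cohorts; and
the end-to-end direction check uses ten 1,000-subject cohorts of 300 genes
with enrichment weight 1.0 — the strong-signal regime in which a
survival-linked pathway should be recovered nearly always while a null
pathway shows no protective association.

## Known limitations

- The enrichment stand-in cannot reproduce proprietary curated-network
  statistics; pathway identities and counts from the original analysis are
  not comparable targets.
- Cause-specific censoring answers the etiological question; cumulative
  incidence in the presence of competing deaths would need a Fine–Gray
  model.
- The quartile/tertile constructs make the score robust but coarse;
  alternative pathway activity scores (ssGSEA, PLAGE) are possible
  extensions, not implemented.
- With few events per tertile (small cohorts), the adjusted Cox model can
  separate; the fit flags this rather than silently reporting inflated
  intervals.
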