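# dpes

Pathway de-regulation scoring and survival analysis for paired tumor/normal
RNA-seq.

Colon tumors de-regulate hundreds to thousands of genes relative to the
adjacent normal mucosa, and — perhaps counterintuitively — patients whose
tumors carry *more* de-regulated genes in key pathways can show *better*
cancer-specific survival. `dpes` provides a tested, reusable implementation
of the full analysis chain behind that kind of finding, for statisticians and
computational biologists working with paired tumor/normal count data and
registry follow-up:

1. **Cohort QC and discovery split** — feature filtering to the analyzable
   protein-coding space, subject-level QC requiring both tissues to pass, and
   a balanced split of the deceased into discovery groups A/B with alive
   subjects matched on age category and sex
   (`filterFeatures`, `qcSubjects`, `splitDiscoveryGroups`).
2. **Paired differential expression** — a nonparametric paired two-class
   test: libraries are binomially thinned to a common depth (default 20
   resamples), the standardized Wilcoxon signed-rank statistic of the
   within-pair differences is averaged across resamples, and a two-sided
   permutation p-value is obtained by flipping tumor/normal labels within
   pairs (default 1,000 permutations; exact enumeration for ≤ 10 pairs).
   Genes are selected when *P* < 0.05 with a > 2-fold change, in the same
   direction, in **both** discovery groups
   (`runPairedDE`, `selectDEFeatures`).
3. **Gene-set overrepresentation** — upper-tail hypergeometric tests of the
   selected genes against a GMT collection with Benjamini–Hochberg control
   and per-pathway up/down composition (`hypergeometricEnrichment`).
4. **DGES / DPES scoring** — the core construct. For each selected gene *g*
   and subject *i*, the differential gene expression score is

       DGES_ig = 1  if oriented delta_ig < Q25(delta_g)     (closest to normal)
                 2  if Q25 <= oriented delta_ig <= Q75
                 3  if oriented delta_ig > Q75(delta_g)     (most de-regulated)

   where `delta_ig = log2((t_ig + c) / (n_ig + c))` on size-factor-normalized
   counts, oriented by the gene's cohort-level direction so that larger
   always means more de-regulated. The differential pathway expression score
   sums DGES over a pathway's member genes,

       DPES_ip = sum over g in pathway p of DGES_ig  ∈ [G, 3G],

   and is categorized into cohort tertiles T1 < T2 < T3
   (`computeDeltaProfile`, `assignDGES`, `computeDPES`, `dpesTertiles`).
5. **Outcome models** — cause-specific Cox proportional-hazards models of
   DPES tertiles on cancer mortality (other deaths censored), adjusted for
   age, sex, AJCC stage and tumor molecular phenotype (TP53, KRAS, MSI,
   CIMP), with Kaplan–Meier curves and per-stage DPES summaries including a
   Welch test of stage 1 vs stage 4
   (`buildSurvivalRecords`, `fitCoxTertiles`, `kmByTertile`, `stageSummary`).
6. **Synthetic cohorts with known truth** — a negative-binomial paired-count
   simulator whose survival times follow an exponential proportional-hazards
   model driven by each subject's true de-regulation tertile
   (`SimulationConfig`, `simulateCohort`), so every downstream stage is
   testable without access to patient data.

A YAML-driven orchestrator (`validateConfig`, `runPipeline`; thin CLI at
`inst/scripts/run_pipeline.R`) runs any subset of stages reproducibly and
writes a manifest with md5 checksums of every artifact.

## Worked example

Simulate a 300-subject cohort in which two of four pathways are truly
de-regulated and survival-linked, then run the whole analysis:

```r
library(dpes)

cfg <- SimulationConfig(nSubjects = 300L, nGenes = 400L, nPathways = 4L,
                        genesPerPathway = 12L, enrichmentWeight = 1.0,
                        seed = 42L)
cohort <- simulateCohort(cfg)

split <- splitDiscoveryGroups(cohort$clinical, seed = 43L)
de <- lapply(c("A", "B"), function(g)
    runPairedDE(subsetSubjects(cohort$experiment,
                               split$subject_id[split$group == g]),
                nResamples = 20, nPerm = 200, seed = 44L))
sel <- selectDEFeatures(de[[1]], de[[2]])
enr <- hypergeometricEnrichment(c(sel$up, sel$down),
                                rownames(cohort$experiment),
                                cohort$geneSets, up = sel$up, down = sel$down)
enr[, c("set_name", "overlap", "set_size", "p_bh", "n_up", "n_down")]
#>   set_name overlap set_size         p_bh n_up n_down
#>  pathway01      12       12 3.652556e-13    8      4
#>  pathway04      10       12 2.113120e-09    5      5
#>  pathway02       0       12 1.000000e+00    0      0
#>  pathway03       0       12 1.000000e+00    0      0
```

38 genes (20 up, 18 down) pass the two-group rule, and exactly the two
truly de-regulated pathways are enriched. Score them and fit the
cause-specific Cox model for the top pathway:

```r
sig   <- enr$set_name[enr$p_bh < 0.05]
delta <- computeDeltaProfile(cohort$experiment)
selected <- intersect(colnames(delta), c(sel$up, sel$down))
dirs  <- setNames(de[[1]]$direction, de[[1]]$feature_id)
dges  <- assignDGES(delta[, selected], dirs[selected])
dpes  <- computeDPES(dges, cohort$geneSets[sig])
tert  <- dpesTertiles(dpes)

rec <- buildSurvivalRecords(cohort$clinical,
                            setNames(tert[, sig[1]], rownames(tert)))
round(fitCoxTertiles(rec)[, c("hr", "lower", "upper", "p")], 3)
#>       hr lower upper     p
#> T2 0.467 0.234 0.931 0.031
#> T3 0.414 0.188 0.913 0.029
```

Subjects in the upper DPES tertiles — the most de-regulated tumors — have
less than half the cancer-specific mortality hazard of tertile 1, with 95%
confidence intervals excluding 1: the simulator's protective tertile effect
(log hazard ratios −0.9 and −1.1) is recovered from raw counts through the
entire pipeline.

## Package layout

- `R/` — S4 classes (`PairedCountExperiment`, `GeneSetCollection`,
  `SimulationConfig`) and the module functions listed above.
- `vignettes/dpes-methods.Rmd` — the statistical methods, modelling
  assumptions, parameter choices and known limitations.
- `tests/testthat/` — unit, property and acceptance tests with brute-force
  oracles (sign-flip enumeration, exhaustive hypergeometric draws,
  hand-computed product-limit tables).
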