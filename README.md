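# diracr

Rank-conservation analysis of omics modules: quantifies how consistently
the *relative ordering* of analyte abundances within a biological module
(a GO biological-process term, a co-expression module, any gene set) is
conserved across the samples of a group, and tests how interventions
change that conservation.

The package is for systems-biology analysts working with processed
log-scale proteomics/transcriptomics matrices who want module-level,
distribution-free statements like "this intervention tightened the
regulation of fatty-acid oxidation" — plus the downstream screening of
predicted metabolic-flux tables for intervention-shifted subsystems.

## The statistic

For a module of $m$ analytes, each sample is encoded as the binary vector
over all $\binom{m}{2}$ analyte pairs $(i,j)$, $i<j$: bit $=1$ iff
$x_i > x_j$. A group's **rank consensus** $T_g$ is the per-pair majority
vote over its samples. The **rank matching score** of sample $s$ against a
consensus $T$ is

$$\mathrm{RMS}(s, T) = \frac{\#\{\text{pairs where } s \text{ agrees with } T\}}{\binom{m}{2}} \in [0, 1],$$

and the **rank conservation index** of group $g$ is
$\mathrm{RCI}_g = \mathrm{mean}_{s \in g}\, \mathrm{RMS}(s, T_g)$ — high
RCI = tight regulation, low = loose. Under the i.i.d. null
$\mathbb{E}[\mathrm{RCI}] = \mathbb{E}[\max(K, n-K)]/n$ with
$K \sim \mathrm{Bin}(n, 1/2)$ (≈ 0.613 at $n = 12$), and own-consensus RCI
is always ≥ 1/2.

On top of the scores sit the study statistics: Mann–Whitney tests of the
overall RCI shift per intervention, per-module one-way ANOVA
(RMS ~ group) with Benjamini–Hochberg FDR, Welch post-hoc
tightened/loosened calls, cross-consensus similarity classification
(is an intervention's pattern the *same* tightened pattern as another
group's?), and a flux stage (Mann–Whitney reaction screen at nominal
p < 0.05, hypergeometric subsystem overrepresentation).

Everything is exercised end-to-end on a seeded synthetic-data generator
with known ground truth; see `vignettes/rank-conservation-methods.Rmd`
for the model, parameter choices, calibration results and limitations.

## Worked example

The `analysis/` drivers run the whole workflow on the reference synthetic
study (four groups × 12 samples, planted tightening structure):

```sh
Rscript analysis/01_simulate.R      # draw + serialize the study
Rscript analysis/02_preprocess.R    # covariate regression, robust Z-scores
Rscript analysis/03_dirac.R         # module filter + RMS/RCI
Rscript analysis/04_module_stats.R  # tightening + similarity analysis
Rscript analysis/05_flux_enrichment.R
Rscript analysis/06_calibration.R   # null calibration, bias demonstration
```

`03_dirac.R` reports the group-level conservation (Control is generated
loose, the interventions tighten a subset of modules):

```
DIRAC: 7680 RMS rows, 160 RCI rows
Group mean RCI (own consensus):
    group       rci
1   17aE2 0.8634673
2     ACA 0.8630952
3 Control 0.7924107
4    Rapa 0.8374256
```

`04_module_stats.R` then recovers the planted structure — 16 modules pass
the ANOVA FDR gate (exactly the 16 with planted tightening), 10 are
tightened by all three interventions, and the similarity classifier keeps
exactly the 6 whose tightened ordering is shared rather than
group-specific:

```
ANOVA: 16 of 40 modules significant at FDR < 0.05

Tightened per intervention:
      n_tested    tightened_ACA  tightened_17aE2   tightened_Rapa
            16               16               16               10
n_tightened_all  n_tightened_all_similar
            10                        6

Recovery: sensitivity 1.00, false discovery rate 0.00
```

`05_flux_enrichment.R` finds the subsystem carrying the planted flux
shifts:

```
Enriched subsystems (FDR < 0.05):
  intervention    subsystem k  K        p_adj
1          ACA Subsystem 01 8 12 4.638637e-07
```

The same machinery is available programmatically:

```r
library(diracr)
study <- simulate_intervention_study(seed = 1)
res <- run_pipeline(study$abundance, study$metadata, study$modules,
                    control = "Control", flux = study$flux,
                    out_dir = "results/run1")
res$summary$tightened_all_similar
```

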