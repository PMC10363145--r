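---
title: "Differential rank conservation of omics modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential rank conservation of omics modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the statistic

Many biological contrasts show up not as shifts in the mean abundance of
single molecules but as changes in how *consistently* a process is
regulated. DIRAC (Differential Rank Conservation) quantifies this: within a
module of $m$ analytes (a GO biological-process term, a co-expression
module, any a priori gene set), each sample is reduced to the binary vector
of its $\binom{m}{2}$ pairwise orderings — bit $(i,j)$, $i<j$ in a fixed
analyte order, is 1 iff analyte $i$'s value strictly exceeds analyte $j$'s.
A sample group's **rank consensus** is the majority vote over these vectors.
The **rank matching score** (RMS) of a sample against a consensus is the
fraction of agreeing pairs, and a group's **rank conservation index** (RCI)
is the mean RMS of its samples under the group's own consensus. High RCI
means a strongly shared within-module ordering ("tight" regulation); RCI
near the null expectation means unpatterned behavior ("loose").

Because only orderings enter, the statistic is invariant under any strictly
monotone per-sample transformation of the data — normalization choices that
act sample-wise cannot change it (property-tested in the suite).

Scoring one group's samples against *another* group's consensus asks a
different question: has an intervention moved its samples toward that
group's canonical pattern? This drives the similarity classification below
and extends to scoring a foreign cohort against templates built from a
separate dataset.

## Conventions and tie rules

The data are continuous, so ties have measure zero; the conventions below
matter only for degenerate inputs but are fixed for determinism:

* analyte pairs are enumerated with $i<j$ in byte-order-sorted analyte-id
  order (any fixed order is equivalent);
* a sample's bit is 1 only for a *strict* `>` (a tied pair scores 0);
* a majority-vote tie at even group size resolves to 1.

These choices keep an exact lower bound: per pair the template agrees with
$\max(k, n-k) \ge n/2$ of the $n$ group samples, so own-consensus RCI is
always $\ge 1/2$.

## The analytic null

For i.i.d. continuous data, the per-pair agreement count is
$\max(K, n-K)$ with $K \sim \mathrm{Binomial}(n, 1/2)$, so by linearity

$$\mathbb{E}[\mathrm{RCI}] = \frac{\mathbb{E}[\max(K, n-K)]}{n}$$

for *any* module size: 0.75 at $n=3$, 0.6875 at $n=4$, 0.612793 at $n=12$.
`expected_null_rci()` evaluates the closed form; the acceptance suite
verifies the Monte Carlo agreement within three standard errors on $10^4$
simulated modules per group size. This is also why own-consensus RCI is
biased above 1/2 under the null: the consensus is fit on the same samples
it scores. The package keeps this optimistic bias (it cancels in
between-group comparisons of own-consensus scores) rather than introducing
leave-one-out variants.

# Preprocessing

The pipeline's fixed order is: (1) covariate regression, (2) complete-case
analyte filtering, (3) per-sample robust Z-score, (4) per-analyte robust
Z-score referenced to the control group.

**Covariate regression.** Samples are pooled per group downstream, so sex
and age (categorical at month resolution) are regressed out per analyte by
ordinary least squares on dummy codes. Each analyte is standardized first
and the residuals are multiplied back by the analyte's original standard
deviation and shifted by its original mean, so the output remains in
log-scale units and a covariate-independent analyte passes through exactly.
Covariates with a single level drop out of the design automatically, so
single-age and multi-age designs share one code path. Rank-deficient
designs fall back to the pivoting least-squares solver with a warning;
zero-variance analytes pass through flagged.

**Missingness.** No imputation: analytes not observed in every sample are
removed. This is deliberately conservative — rank comparisons on imputed
values would manufacture pair orderings out of the imputation model.

**Robust Z-scores.** Both stages use the median and the median absolute
deviation. The raw MAD is the default; the 1.4826 Gaussian consistency
factor is a flag (`consistency`), and since both stages apply positive
per-sample or per-analyte scale factors, the flag cannot change any
downstream rank statistic's per-sample step — it exists for faithful
intermediate tables. A sample whose MAD is zero cannot be normalized and is
an error; an analyte with zero control MAD is dropped with a reason code.

## Finite-sample bias of the control-referenced step

The per-*sample* robust Z is strictly monotone within each sample and
provably cannot change DIRAC output. The per-*analyte* Z referenced to the
control group is different: it rescales analytes relative to one another,
and pair orderings compare across analytes. With an infinite control
cohort the step would be harmless, but at realistic group sizes the control
median and MAD are noisy estimates, and subtracting them injects a shared
pseudo-ordering into *every* group — built from the control group's own
sampling noise. The consequence, demonstrated by `analysis/06_calibration.R`
on data where all four groups are generated identically: the control
group's own-consensus RCI is systematically depressed (its deviations are
negatively correlated with the injected ordering) while every other group's
is inflated. Group comparisons of rank conservation through this step are
therefore biased toward "tightened" calls at $n = 12$.

The package keeps the full prescribed order as the default
(`control_reference = TRUE`) for fidelity, and exposes
`control_reference = FALSE` to stop after the per-sample step. All
calibration and recovery benchmarks (`anova_null_calibration()`,
`recovery_benchmark()`) use the latter, since their premise is group
exchangeability under the null. Analyses that care about the direction of
tightening calls should do the same.

# Module sets

Annotated modules arrive as GMT files. A module is only interpretable in a
dataset that measured enough of it: after intersecting members with the
measured analytes, a module is retained iff at least
$\max(4, \lceil \mathrm{background}/2 \rceil)$ members remain, where the
background size is the annotated membership before intersection. "At least
half" is read inclusively, rounding up for odd backgrounds; the retention
decision is tested exhaustively against a one-line oracle for all
backgrounds up to 20. Modules may overlap freely (GO terms share genes);
no parent–child pruning is attempted, and the flat BH adjustment below is
consequently conservative. For cross-dataset or cross-omics designs,
`restrict_to_shared_modules()` intersects module *ids* while keeping each
dataset's own measured members.

# The statistical framework

All tests are two-sided; all multiple-testing adjustment is
Benjamini–Hochberg within explicit families:

| stage | test | family |
|---|---|---|
| overall shift | Mann–Whitney U on module RCIs, control vs each intervention | the interventions compared |
| module screen | one-way ANOVA, own-consensus RMS ~ group | all tested modules (or modules × datasets) |
| tightening call | Welch's t, intervention vs control RMS | per module, the intervention comparisons |
| similarity | Welch's t under a foreign consensus | per module, comparisons × consensus groups |
| flux subsystems | hypergeometric upper tail | subsystems containing a changed reaction |

A module is **tightened** by an intervention when it passes the ANOVA FDR
gate *and* the post-hoc adjusted p is below threshold with the intervention
mean above control (loosened: below). For **similarity**, each consensus
group X contributes tests of control vs each intervention Y ≠ X on RMS
under X's template, with X's own samples excluded from both sides — their
own-consensus scores follow the optimistically biased distribution above
and must not contaminate the comparison; X can therefore never be the
control group or a compared group in its own cell. `"higher"` means Y
matches X's pattern better than control does (similarly changed),
`"lower"` dissimilarly. A module is *consistently tightened, similar* if it
is tightened by every intervention and every similarity cell among the
interventions is `"higher"`.

Numerical conventions, chosen to never drop a module silently:

* Mann–Whitney uses the exact distribution when the pooled sample is ≤ 16
  and tie-free, otherwise the normal approximation with tie and continuity
  correction.
* Welch's t with both cells numerically constant reports p = 0 when the
  means differ and p = 1 when equal, flagged as degenerate.
* ANOVA on values identical across all groups reports p = 1, flagged.
* Welch degrees of freedom are the unrounded Satterthwaite value.

## Null calibration

With groups generated exchangeably — every group shares one consensus
ordering and one noise level — the per-module ANOVA p-values are uniform
and BH positives are rare (`anova_null_calibration()`; the acceptance
suite runs 50 replicates of 500 modules at the default noise scale 0.7).
The calibration is regime-dependent in an instructive way: each group's
consensus template is fit to its own samples, and when the shared
structure is weak (or absent — spacing zero) the fit absorbs part of the
group-level fluctuation that the F statistic's numerator would otherwise
measure, making the ANOVA *conservative* (at noise scale 2.5 the nominal
5% test rejects ~3%; with pure noise, ~0.2%). Uniformity holds when the
conserved ordering is strong enough to pin every group's template to the
truth, which is the premise under which the per-module ANOVA is the right
test; departures from that premise only reduce false positives, never
inflate them.

# Flux screening and enrichment

The metabolic stage consumes a predicted flux table (reactions × samples)
— either directly or as the midpoint $(\min+\max)/2$ of per-reaction flux
variability ranges — plus a reaction → subsystem map. Model reconstruction
and flux estimation themselves are out of scope; the contract starts at the
table. Pseudo-reactions are removed first: anything unannotated, or in
subsystems matching the configurable excluded prefixes (by default
exchange/demand, miscellaneous, transport — matched case-insensitively as
prefixes so label variants are caught). Screening is per reaction and
intervention by Mann–Whitney at *nominal* p < 0.05, deliberately
unadjusted: it is the first stage of a two-stage design, and the FDR-level
inference is carried by the subsystem overrepresentation test — a
one-sided hypergeometric with the assessed (post-filter) reactions as
universe, testing only subsystems containing at least one changed reaction,
BH-adjusted across exactly those. No changed reactions yields an empty
enrichment, which is a valid outcome, not an error. For summaries, group
mean changes are centered on control and scaled per reaction by the
maximum absolute change across interventions, giving a matrix in $[-1,1]$
whose non-degenerate rows touch ±1.

# The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known truth, and it generates exactly the structure the analysis assumes.
For module M and group g with ordering $\pi_{g,M}$, member means are
$\delta$-spaced along the ordering and samples add i.i.d. Gaussian noise
$\sigma_{g,M}$; the probability that an adjacent pair inverts is
$\Phi(-\delta/(\sigma\sqrt2))$, so tightness is governed purely by
$\delta/\sigma$ — an analytic handle for power reasoning that the suite
verifies against the Gaussian closed form. Background analytes are i.i.d.
standard normal. Sex and age act additively per analyte with coefficients
drawn $N(0, \tau^2)$, and the suite checks that the regression stage
removes them to numerical precision. All randomness flows through one seed
whose state is restored afterwards; identical seeds give identical data.

The reference scenario (`simulate_intervention_study()`) fixes the study
conditions: four groups (Control, ACA, 17aE2, Rapa) × 12 samples, balanced
6F/6M and two ages; modules of 8 members with $\delta = 1$;
$\sigma = 2.5$ for loose regulation (adjacent inversion ≈ 0.39) and
$\sigma = 0.35$ for tight (≈ 0.02); $\tau = 0.3$. The module roster plants
every label the analysis can produce: 6 modules tightened by all three
interventions on the ordering *shared* with control, 4 tightened by all
three but each intervention on its *own* ordering, 6 tightened by two, 24
null, plus coverage decoys the filter must drop and 160 background
analytes. The flux companion plants shifts ($\Delta = 3$) in 8 reactions
of one subsystem for ACA and 4 of another for 17aE2, none for Rapa, among
96 functional reactions plus unannotated/excluded decoys.

Group-specific orderings are drawn with a *pairwise* Kendall-distance
band (0.55–0.75 of all pairs) against every previously drawn ordering, not
only the shared one. This matters: with a floor only against the shared
ordering, two intervention orderings can land close to each other by
chance, and "dissimilar" stops being true in the planted truth — the
similarity classifier is then scored against an ambiguous label. The
pairwise floor makes distinct mean distinct.

What the generator does *not* emulate: mass-spec missingness mechanisms,
count noise, correlated background structure, batch effects, or
annotation errors. Passing the recovery benchmarks therefore demonstrates
that the statistical machinery is correct and calibrated under its own
assumptions, not that real data meet those assumptions.

# Problem sizes and runtime

The benchmark sizes are chosen to make Monte Carlo error small relative to
the margins being tested while staying desk-scale: $10^4$ modules per
group size for the analytic-null check (MC standard error ≈ 8×10⁻⁴), 50
replicates × 500 modules for ANOVA calibration, 800 reactions for the
screen's null rate, 25 scenario draws for recovery. The DIRAC core is
$O(n\,m^2)$ per module via vectorized pair comparisons, comfortably fast
up to data-driven module sizes in the hundreds.

# Known limitations

* Consensus templates use all group samples with no leave-one-out
  correction; own-consensus RCI is optimistically biased (exactly
  quantified by the analytic null) and cross-consensus tests exclude the
  consensus group's samples for this reason.
* The flat BH families treat overlapping modules as independent tests;
  with GO-style overlap this inflates false negatives, not false
  positives.
* The control-referenced normalization bias discussed above is a property
  of the method's prescription, not of this implementation; the package
  measures it and provides the calibrated alternative.
* Mann–Whitney "exact" mode is limited to small tie-free samples; larger
  designs use the corrected normal approximation.
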