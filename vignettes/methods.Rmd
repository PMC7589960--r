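---
title: "Models and methods behind m6ARhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind m6ARhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6ARhythms)
```

m6ARhythms implements two connected analyses for the m⁶A RNA-methylation
machinery of marine plants: a comparative gene-family inventory built from
all-vs-all protein similarity, and a diel rhythm analysis of
RT-qPCR/ELISA measurements.  This vignette describes the models, the
parameters that matter, and the design choices made where the procedure
was genuinely open.

## Homology networks

**Orthologs** are inferred by bidirectional best hits (BBH): for every
query and target species, the subject with the smallest E-value is the
best hit (ties: larger bit score, then lexicographically smallest subject
ID — a fully deterministic chain), and an ortholog edge joins two proteins
that are each other's best hit.  **Paralog** edges join proteins of the
same species when hits are reported in *both* directions and the better of
the two E-values passes a species-specific cutoff.  Requiring reciprocity
is our choice — best-hit reciprocity is only defined across species — and
protects against asymmetric reporting artifacts; the alternative
(one-directional hits suffice) changes nothing on symmetric inputs.

The cutoff is selected per species by scanning a threshold grid (default
decade steps from 1e-5 to 1e-120) and counting connected components with
at least two members in the within-species paralog graph; the selected
cutoff maximises that count, with ties resolved toward the *loosest*
threshold because a looser cutoff retains more sequences in the final
inventory.  An edgeless protein is not a network, so it never inflates the
count.  The scan's purpose is to break apart families that weak,
unspecific hits would otherwise merge; tightening a cutoff can only remove
edges (a monotonicity the test suite asserts).  The selected cutoff
applies to paralog edges only: BBH is already maximally selective (one
subject per query and species), so no further filter is imposed on
ortholog edges.

Networks are connected components of the union of both edge sets,
numbered `NET_1, NET_2, …` after sorting components by size (decreasing)
and then by their lexicographically smallest member, so identifiers are
reproducible for any input order.  Network numbers in published inventories
depend on each run's full proteome complement and are not reproducible
from a subset; only the partition itself is meaningful.  Annotation is by
best-hit function transfer: each member receives a label from a controlled
vocabulary (MTA, MTB, FIP37, VIRILIZER, HAKAI, ALKBH9B, ALKBH10B, other);
unannotated members become `"unknown"` rather than failing.  A network
enters the inventory iff at least one member carries a writer or eraser
label; a single network may contribute rows for several gene names (the
MTA/MTB case) because components are taken over the union graph, not per
function label.

Numerical conventions: E-values of exactly 0 are floored at 1e-180 before
any log-scale operation; species tags are the ID prefix up to the first
underscore, overridable by a species map.

The redundancy collapse for transcriptome-derived sequence sets is a
simple greedy identity clustering (longest-first; a sequence joins the
first representative reached at ≥ 98% identity over ≥ 50% of the shorter
sequence's aligned span, BLOSUM62 local alignments).  It is deliberately
a stand-in for assembly-aware tools and is not meant to resolve true
isoform structure.

## Expression quantification

Relative abundance uses the negative ΔCT convention,
−ΔCT = CT(reference) − CT(gene of interest), computed once per biological
sample after averaging technical replicates; higher −ΔCT means more
transcript.  Technical replicates more than 0.5 cycles from their
within-sample median are dropped first — a common qPCR QC rule; with
triplicates this removes at most one well.  Samples lacking a reference
measurement are dropped with a warning rather than imputed.  Profile
standard errors are the sample SD over biological replicates divided by
√n.  Primer efficiency comes from ordinary least squares of mean CT on
log₁₀ relative concentration over at least five dilution points:
E = 10^(−1/slope), reported as (E − 1) × 100 so a perfect doubling
(slope −3.3219 cycles/decade) reads 100%.  A non-negative slope flags the
series invalid.

Daily-profile correlations are plain Pearson correlations over per-sample
−ΔCT values paired by (species, time, replicate) — with 6 time points and
3 biological replicates that is N = 18 pairs — with two-sided p-values
from the t distribution on n − 2 df.

## m⁶A quantification

The ELISA model is linear.  The standard curve is fitted through the
origin on background-subtracted OD (mean OD − NC OD vs known ng) because
the downstream formula uses only a slope and the negative-control OD; a
free intercept would be ignored by that formula and is therefore not
estimated.  Duplicate standards are averaged per level.  Sample masses are
(mean OD − NC OD)/slope, clamped at zero with a `below_background` flag
instead of erroring, so full plates always process; percentages scale by
the input RNA mass (100 ng by default).  The per-species "normalised"
daily m⁶A profiles used for plotting are z-scores across time points — an
interpretation we fixed once, since normalisation conventions differ
across instruments.

## Inferential layer

The multivariate response is the samples × genes matrix of −ΔCT values.
Variables are z-scored before Euclidean distances are taken (the standard
convention for responses on different scales; the package exposes the
flag).  The two-way PERMANOVA partitions the total sum of squares of the
Gower-centred inner-product matrix **G** = (I − J/n)(−D²/2)(I − J/n) with
the orthogonal projectors of the balanced crossed design; for each term,
SS = tr(H G) and pseudo-F = (SS/df) / (SS_res/df_res).  On univariate
Euclidean data this reduces *exactly* to the classical two-way ANOVA —
the package's primary correctness oracle, asserted to 1e-9 in the tests
and cross-checked against an independent implementation (vegan).

Permutation p-values use unrestricted permutation of observation labels,
which is exact for balanced fixed-effects designs under the global null
and far simpler than residual-permutation schemes; at these sample sizes
the difference is negligible.  The convention is p = (b + 1)/(m + 1) with
the observed statistic included.  `unique_perms` counts distinct statistic
values among the sampled permutations — an approximation to the number of
distinct relabellings.

Pairwise contrasts are one-way two-group PERMANOVAs on the subset, with
t = √pseudo-F.  When the number of distinct label splits is enumerable the
permutation p-value is exhaustive (two groups of three give only 10
distinct splits, so the permutation p cannot resolve below 0.1 and the
result is flagged low-resolution).  For these small contrasts a
Monte-Carlo p-value is provided: under the asymptotic null the numerator
and denominator quadratic forms are eigenvalue-weighted χ² sums over the
spectrum of the subset's centred matrix, so pseudo-F* is drawn as
(Σλᵢuᵢ/df₁)/(Σλᵢvᵢ/df₂) with independent χ² variates (10⁴ draws, seeded).
In the univariate case the centred matrix has rank one and this collapses
to the exact F(df₁, df₂) reference — the validation used in the tests.
Commercial implementations of this Monte-Carlo device are closed-source,
so exact numerical agreement with their output is not expected or
targeted.

Univariate responses (each gene, global m⁶A%) get classical balanced
two-way ANOVAs; the SNK post-hoc procedure orders the cell means and tests
spans stepwise with studentized-range critical values q(α, p, df), never
testing inside a span already declared non-significant, which guarantees
the homogeneous groups are coherent with every pairwise decision.
Diagnostics are Shapiro–Wilk on residuals and mean-centred Levene tests.
Degenerate inputs (zero total SS, constant responses, identical residuals)
return flagged results or errors rather than NaNs deep in the output.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* of the study inputs with known
ground truth:

- **Proteomes.**  One ancestral sequence per family (uniform over the 20
  amino acids; default 150 residues); each species' base copy mutates at
  the ortholog rate (default 0.1 substitutions/site), duplicates mutate
  from the base copy at the paralog rate (default 0.05), transcript
  variants sit < 2% from their parent.  Sites are i.i.d. with uniform
  replacement — no indels, domains, or rate heterogeneity — which is
  adequate because downstream consumes only E-values, never alignments.
  The default family complement mirrors a published four-species
  writer/eraser inventory (e.g. a six-member FIP37 expansion in one
  seagrass genome).
- **Similarity.**  Within-family E-values are anchored to realized pair
  divergence: log₁₀E = −120 + 280·d + U(0, 1), clamped to [−120, −20],
  both directions drawn independently.  We chose a divergence-anchored
  model (over i.i.d. uniform E-values on the same support) deliberately:
  real search E-values track similarity, and because duplicates radiate
  from a base copy, base–duplicate pairs are always stronger than
  duplicate–duplicate pairs, so a tightening cutoff thins a family from
  the outside in — leaves drop off as singletons — and can never cleave it
  into two multi-member networks.  Under an i.i.d. E-value model the
  cutoff scan finds and exploits cleaving thresholds, and planted families
  cannot be recovered exactly; with the divergence-anchored model recovery
  is exact for any seed, which is the property the acceptance suite
  asserts.  "Hard mode" adds between-family hits with log₁₀E in [−8, −3]
  (each ordered pair reported with probability 0.1) to exercise the scan;
  the two supports may not overlap unless explicitly allowed.
- **Diel CT series.**  CT(t) = baseline − amplitude·cos(2π(t − peak)/24)
  plus Gaussian technical noise (default sd 0.1 cycles) per well; the
  reference gene is flat by construction, emulating a validated stable
  reference.  Time is decimal hours since local midnight; no dates.  The
  published study reports no effect sizes, so the default amplitudes
  (0.4–1.2 cycles) are free parameters chosen once to make night-peaking
  patterns clearly visible against 0.1-cycle noise; they are not fitted to
  any data.  Night-time peaks for the Mediterranean species and
  afternoon/evening peaks for the other reproduce the qualitative
  asynchrony the design is meant to detect.
- **ELISA plates.**  OD = NC + slope·ng + Gaussian noise, standards in
  duplicate (default 5-point ladder, slope 0.02 OD/ng, NC 0.10 OD),
  samples in technical duplicate with 100 ng input RNA.  The m⁶A%
  ground truth follows a per-species cosinor (default baseline 0.10%,
  amplitude 0.03%).

Passing tests on these fixtures demonstrates that the *pipeline* is
correct — partitions recovered, formulas inverted, statistics calibrated —
not that real data are this clean: field samples carry biological
replicate variance, reference-gene drift, plate effects and non-linear
assay ranges that the generators intentionally omit.

## Reproducibility and problem sizes

One master seed fans out to per-stage sub-seeds through an integer mixing
function (`deriveSeed`), so stages are independently reproducible and all
p-values are bit-for-bit stable at a fixed seed.  The pipeline writes a
manifest of config hash, seed and output checksums, and re-running over
identical outputs is a no-op.

The test and acceptance suites use deliberately compact problem sizes
chosen to exercise every code path at interactive speeds: the default
four-species fixture (94 proteins, seven families), 2 × 6 × 3 and
2 × 4 × 3 crossed designs, 999–9999 permutations, 10⁴ Monte-Carlo draws,
200 cosinor-recovery replicates, 100 brute-force oracle instances and 500
null-calibration runs.

## Known limitations

- The homology stage consumes similarity tables; it does not run searches,
  alignments or trees (established external tools own those steps).
- Only balanced, fully crossed two-factor fixed-effects designs are
  supported — the designs this analysis uses.  No Type-III/unbalanced
  decompositions, random effects, or dispersion (PERMDISP) tests.
- Distances other than Euclidean (on optionally z-scored variables) are
  out of scope.
- The ELISA model is linear with an origin-forced curve; 4PL fits for
  saturating plates are not implemented.
- ΔΔCT calibration and multi-reference-gene normalisation are not
  implemented; −ΔCT is the quantity analysed throughout.
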