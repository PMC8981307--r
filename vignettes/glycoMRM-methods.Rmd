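---
title: "Models and methods behind glycoMRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycoMRM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMRM)
```

glycoMRM analyzes targeted (MRM/dMRM) serum glycoproteomics panels for
liver-disease progression markers. This vignette explains the statistical
model behind each stage, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the design choices made
where the methodology was genuinely open.

## Glycan codes and motif classes

Each N-glycan is a 4-digit composition code `[Hex][HexNAc][Fuc][Sia]`. The
digit order is fixed by the series conventions of serum MRM panels: the
65*xx* family carries six hexoses and five HexNAc, the 76*xx* family seven
and six. Motif classes derive deterministically from the composition:
`fucosylated` means fucose digit ≥ 1, the sialylation count is the fourth
digit, and antennarity follows HexNAc (4 = bi, 5 = tri, 6 = tetra,
otherwise "other"). Two caveats are inherent to composition codes: the
fucose digit counts total fucoses, so core and antennary fucosylation are
not distinguished (codes such as 5431 show the digit can exceed 1), and no
topology (linkage, branch position) is represented. Marker identifiers
follow the grammar `PROT (site[ and site2]) – code[ and code2]` for
glycopeptides — a glycopeptide spanning two sites carries both — and
`PROT – PEPTIDESEQ` for the non-glycosylated peptides that report total
protein level. Hyphen, en dash and em dash are interchangeable on input;
the en dash is canonical on output.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every downstream guarantee is demonstrated. Defaults reproduce the
targeted study design: 56 healthy controls, 23 NASH and 19 HCC sera; a
panel of 413 glycopeptides over 57 of 73 monitored serum glycoproteins,
each protein also contributing a peptide marker; study samples injected in
randomized order with a pooled reference serum at every 10th position (plus
a closing pool so the run ends bracketed).

The abundance model for marker $m$ in injection $i$ is multiplicative:

$$
\text{raw}_{m,i} = \mu_m \cdot 2^{\beta_{m,\text{phen}(i)}
  + \alpha\,(\text{age}_i - 60) + \gamma\,\mathbb{1}[\text{male}_i]}
  \cdot d(i) \cdot \varepsilon_{m,i}
$$

with per-marker baselines $\mu_m$ log-uniform over $10^4$–$10^7$ (the
dynamic range of integrated MRM peak areas), phenotype effects
$\beta$ in log2 units, a shared drift trend $d(i)$ decaying exponentially
to $1 - A$ at the final injection (default amplitude $A = 0.2$; the form of
real drift is unknown, so a smooth monotone trend was chosen and isolated
behind a config parameter with optional per-marker jitter), and lognormal
noise $\varepsilon$ with biological CV 0.30 on study samples plus technical
CV 0.05 on every injection (both mean-one). Reference pools share one fixed
composition equal to the marker baselines and receive only drift and
technical noise. Default CVs are in the range routinely reported for
triple-quadrupole peptide MRM on serum (technical a few percent, biological
tens of percent).

Default phenotype effects encode the study's qualitative finding as ground
truth: fucosylated *and* sialylated glycoforms rise (+0.5 log2 in NASH,
+0.8 in HCC) while non-fucosylated glycoforms with ≥ 2 sialic acids fall
(−0.35, −0.55); HCC effects exceed NASH effects so the progression cascade
is part of the truth table. Ages are uniform over each phenotype's printed
range (controls 23–91, NASH 45–70, HCC 32–85) and sexes follow the printed
proportions (26/56, 10/23, 15/19 male); small global age (+0.002
log2/year) and sex (+0.05 log2, male) effects give the covariate
adjustment something real to remove. An `effect_table` can override any
marker's true effect, and the returned ground truth (true log2 fold
changes, drift-free expected abundances) supports recovery testing.

What the generator does **not** emulate: missing values (off by default —
the analysis assumes complete positive areas), between-batch structure
(single-run design), marker–marker correlation beyond the shared drift,
retention-time drift, or peak-integration artifacts. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to those real-data complications.

## Drift normalization

Pools injected every 10th position are only useful for a *local-in-run*
correction, so the reference trend for each marker is the linear
interpolation between the bracketing pool measurements, flat beyond the
first/last pool, and

$$\text{norm}_{m,i} = \frac{\text{raw}_{m,i}}{\text{trend}_m(i)}
  \times \operatorname{median}_m(\text{pools})$$

which preserves the raw-area scale. The method sits behind an interface
(`method = "pool_median"` offers a run-constant alternative) so other
formulas can be swapped in. Consequences worth knowing: normalized values
equal raw values exactly when the pools are constant; each marker is pinned
to its pool median, so absolute scale is meaningful only up to that factor
(fold changes, the downstream currency, are unaffected); markers with a
nonpositive pool measurement cannot be corrected and are flagged and left
uncorrected with a warning. Quality control is leave-one-pool-out: each
pool injection is corrected using only the remaining pools, and the
per-marker CV across pools before vs after is reported.

Relative abundance divides each glycopeptide by the summed glycopeptide
signal in scope for that sample (peptide markers excluded from both sides).
`global` scope follows the literal definition and sums to 1 per sample;
`per_protein` and `per_site` scopes support within-carrier glycoform
distributions. Relative abundances are invariant to per-sample rescaling,
hence also to drift that acts equally on all markers of an injection — they
are computed from raw areas.

## Differential abundance and the progression screen

No specific per-marker test is mandated by the source methodology beyond
"fold changes … after adjusting for age and sex", so the package uses the
most direct realization: ordinary least squares of log2(abundance) on a
group indicator, age in years (untransformed) and a binary sex indicator.
The group coefficient is simultaneously the adjusted log2 fold change
(reported as $2^\beta$, oriented first-named group over second) and the
subject of a two-sided Wald $t$ test. A raw ratio-of-means variant
(`adjust = FALSE`) is available since it is not documented whether
published multiplicative differences were covariate-adjusted. The fit is
vectorized — one QR decomposition of the shared design serves all markers —
and is verified against `lm()` per marker in the tests. Collinear
covariates (e.g. sex constant within a contrast) are dropped with a
warning; groups below 3 samples are errors.

Benjamini–Hochberg q-values are computed by the package's own step-up
implementation (its equivalence to a brute-force oracle and to
`p.adjust(method = "BH")` is a test invariant). The significance cascade
reports per-contrast sets at $p < 0.05$ and FDR ≤ 0.05, the intersection of
the two control contrasts at FDR level, and protein roll-ups. The
progression screen demands strict monotonicity of the adjusted phenotype
means across control → NASH → HCC — obtained from one three-level-factor
fit per marker, so monotonicity depends only on the two phenotype
coefficients; ties fail — *and* FDR significance in both control
contrasts. NASH-vs-HCC results are computed and reported but deliberately
not part of the screen definition, which mirrors how the marker cascade
was described; whether that contrast should additionally gate the screen
is left to the caller (filter the result on its q-values).

## Motif summaries

Markers are partitioned by exact (Fuc, Sial) pairs — the default six groups
are (0,0), (0,3), (0,4), (1,2), (1,3), (1,4) — with optional series groups
fixing hexose/HexNAc (54xx, 65xx, 76xx). Overlapping specs are an error;
unmatched markers are simply unassigned. A group's per-sample value is the
sum of member relative abundances, and group-level testing reuses the same
adjusted log2 model on those sums, BH-corrected within contrast (the group
test was unspecified upstream; reusing the marker-level engine keeps one
inference path). By default all glycopeptides are summarized; restricting
to a significant subset, as some published figures do, is a matter of
passing that subset's membership.

## Classification

Features are z-scored with the population-SD convention (divide by $n$;
configurable) and the parameters are stored so held-out samples are
transformed without leakage; constant features are dropped with a warning.
PCA is delegated to `prcomp` on the scaled matrix. Classifiers are
logistic regressions — binomial for two classes, multinomial for three
(control/NASH/HCC probability scores) — with optional LASSO penalty via
glmnet. Three choices deserve explanation:

* **Regularization strength.** How the L1 strength was chosen upstream is
  not documented. The default is nested selection: an inner 5-fold
  `cv.glmnet` inside each LOOCV training fold, which avoids selection
  leakage. A non-nested option (`nested = FALSE`: strength chosen once on
  the full data) is provided and is slightly optimistic.
* **Class-balanced weights.** Observations are weighted inversely to class
  frequency (default, switchable). Beyond the usual imbalance argument
  (56 controls vs 19 HCC), this matters specifically for LOOCV: an
  unweighted intercept-only model — the limit the LASSO reaches under pure
  noise — predicts the training class proportion, which is *anti*-correlated
  with the held-out label and drives the out-of-fold AUROC far below 0.5.
  With balanced weights the intercept-only prediction is 0.5 for every
  fold. A small pessimistic LOOCV bias remains when noise features enter
  the model (null calibration sits slightly below 0.5), which is inherent
  to leave-one-out evaluation.
* **Train vs test AUROC.** The out-of-fold probabilities give the test
  AUROC; "train" AUROC is from the single full-data fit, the only
  definition available once LOOCV is the evaluation scheme.

AUROC is the midrank Mann–Whitney statistic (ties count ½), checked in the
tests against exhaustive pair counting. Folds whose training set loses a
class are flagged and excluded from coverage rather than failing the run.

## Numerical and interface choices

Strictly positive abundances are a precondition of every log2 step; zeros
or missing values are rejected at the I/O boundary rather than imputed.
CSV tables are comma-separated UTF-8 with a mandatory header; simulation
outputs carry their seed in a `# seed:` comment line which readers skip.
Residue positions are kept exactly as printed (1-based); no coordinate
arithmetic is done. All randomness flows from a single integer seed:
identical config + seed reproduces every output byte, and the run manifest
records the seed and a hash of the configuration.

Problem sizes used in the test and acceptance suites are scaled to the
question being asked: design anchors use the full default panel (486
markers, 98 study samples); Monte-Carlo calibration checks use 50–100
markers and 50 samples per arm over 5–20 seeds, which makes the binomial
standard errors of the checked rates small relative to the asserted
margins while keeping each suite run to a few minutes.

## Known limitations

The drift model (form of the trend), the per-marker test (unmoderated OLS;
no limma-style shrinkage, by design, since nothing of the sort was
specified upstream), and the composition-level treatment of fucosylation
are all simplifications documented above. Real-cohort headline numbers
from the motivating study (discovery and validation AUROCs, published
marker counts) depend on serum measurements that are not reproducible from
code; the package's guarantees are about the correctness and calibration
of the machinery under the synthetic model, which is exactly what the test
suite and `scripts/acceptance.R` compute.
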