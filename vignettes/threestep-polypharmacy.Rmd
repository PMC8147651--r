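---
title: "Three-step kernel ridge regression for polypharmacy effect prediction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-step kernel ridge regression: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trikrr)
```

## The problem and the model

Adverse effects caused by drug–drug interaction form a three-way binary
relation: drug $i$, drug $j$, effect $k$, with label $Y_{ijk} \in \{0, 1\}$.
Two structural facts are baked into every container in this package: drug
order carries no meaning ($Y_{ijk} = Y_{jik}$) and a drug cannot interact
with itself ($Y_{iik} = 0$). Labels mined from reporting systems are
*positive-only*: every unlisted triplet is taken as a zero label, which is
why a certain fraction of "zeros" are really unreported positives — the
motivation for the detection step at the end.

Three-step kernel ridge regression scores a triplet by the trilinear form
$$f(d, d', e) = \sum_{a,b,c} A_{abc}\, k_d(d, d_a)\, k_d(d', d_b)\,
k_e(e, e_c),$$
where the parameter tensor $A$ is fixed by requiring the labels to equal the
predictions of a variant whose self-similarities are inflated per mode:
$$Y = A \times_1 (K_d + \lambda_1 I) \times_2 (K_d + \lambda_2 I)
\times_3 (K_e + \lambda_3 I).$$
The model assumes that interaction propensity varies smoothly with drug and
effect similarity; everything it can express is a linear combination of
kernel profiles. Because the three shifted Gram matrices act on separate
modes, the solution is three tensor contractions with their inverses.
`threestep()` performs them through eigendecompositions of $K_d$ and $K_e$:
shifted eigenvalues are inverted, never explicit matrices. The
eigendecompositions are computed once and cached, so sweeping a
$\lambda$-grid or refitting inside cross-validation reuses them; this is the
property that makes dense grid tuning and repeated per-fold refits cheap
enough to be the default strategy.

The three regularization parameters are the model's entire interface to the
task structure. Each $\lambda_m$ shrinks along one mode; a prediction task
that must generalize to an unseen drug in slot one needs a larger
$\lambda_1$, while a task where both drugs are known profits from weak
shrinkage that lets the drug's own labels dominate. All three default ranges
are dimensionless positive reals on a log scale (see "Tuning" below).

Numerical contracts: after fitting, substituting $A$ back into the defining
equation must reproduce $Y$ to $10^{-8}$ relative Frobenius error (stored as
`fit$residual`); eigenvalues in $[-10^{-10}, 0)$ arising from floating-point
noise in a PSD kernel are clipped to zero; a shifted eigenvalue
$\le 0$ aborts with an error naming the offending mode, since $\lambda = 0$
is only admissible for a non-singular kernel.

## Kernels

**Drug kernel.** $k_d(d_i, d_j) = \exp(-\lVert d_i - d_j\rVert^2 / \gamma)$
on binary mono-drug effect profiles. The bandwidth default reads $\gamma$ as
the feature dimension — the natural squared-distance scale for binary
vectors, and consistent with describing $d_i$ as "a vector of length
$\gamma$". It is overridable (`bandwidth=`) because this reading is a
convention, not a law. Mono-drug effects are disjoint from interaction
effects by construction of the source data, so this kernel never moves label
information across folds; we use the full mono-effect vocabulary rather
than restricting to effects seen in the filtered drug set.

**Effect kernel.** Effects are represented by binary incidence vectors over
*training* drug–drug pairs and compared with
$k_e(e_k, e_l) = e_k \cdot e_l / (\lVert e_k\rVert\,\lVert e_l\rVert)$. This
printed "Tanimoto" formula is algebraically the cosine similarity; we
implement it exactly as printed (default) and expose the classical binary
Tanimoto $a \cdot b / (\lVert a\rVert^2 + \lVert b\rVert^2 - a \cdot b)$
behind `method = "tanimoto"` for users who read the name rather than the
formula. Effects incident to no training pair get zero off-diagonal
similarity, unit diagonal, and a warning — skipping them silently would bias
macro averages invisibly.

Because this kernel is label-derived, it is the one place cross-validation
can leak. Every fold therefore rebuilds it from that fold's training pairs
only. In the held-out-triplet scheme every cell is eventually a test cell,
so no single pair set is training for all folds; the fold plan splits pairs
into two halves, tests each half's cells in one half of the folds, and
builds the kernel from the opposite half (`half_fold_pair_split()`). The
cost is a kernel built from half the pairs, accepted in exchange for strict
fold safety — `audit_folds()` re-verifies the membership claims of all four
schemes by direct scans, independent of the prediction code.

## Cross-validation schemes

`make_folds()` assigns units by uniform shuffling under a recorded seed (no
stratification): triplet cells (`dde`), unordered pairs carrying all their
effects (`dd_e`), or whole drugs (`d_de`, `d_d_e`). For drug-level schemes
the training tensor is the sub-tensor over training drugs; a pair mixing a
test and a training drug is a *test* pair in `d_de` (oriented with the new
drug in mode 1, so $\lambda_1 \ne \lambda_2$ is meaningful) and *discarded*
in `d_d_e`; a pair of two test drugs is discarded in `d_de` and a test pair
in `d_d_e`. In `d_de` each cross pair is tested twice across folds, once per
orientation; the two fold scores are averaged so that pooling yields exactly
one score per canonical test triplet. For symmetric-role schemes the two
orientations of a fitted tensor are averaged, which is a no-op when
$\lambda_1 = \lambda_2$.

Out-of-fold predictions are produced by per-fold refits through the cached
eigendecompositions rather than by closed-form hold-out algebra: the
single-mode deflation identity
$\hat y_S^{(-S)} = (I - H_{SS})^{-1}(\hat y_S - H_{SS} y_S)$ is implemented
and tested (`block_deflate()`), but its three-way joint extension to pairs
and drugs held out across two symmetric modes is not derived here, and
correctness should not hinge on re-deriving it. The refit path is pinned by
an oracle-equivalence contract instead: the test suite checks, to $10^{-8}$,
that pooled predictions equal those of explicit per-fold retraining with a
dense Kronecker-expanded linear solve. Held-out cells in the cell-level
schemes are set to the zero label in the training tensor, the same
convention the data itself uses for unobserved triplets.

## Evaluation

Predictions pooled over all folds are arranged as pairs × effects and a
metric is macro-averaged per effect column (`Edd`, discriminating pairs) or
per pair row (`Ee`, picking effects). A model predicting "every effect
occurs for every known-interacting pair" illustrates why both views are
needed: it can look strong under `Edd` while `Ee` sits exactly at chance.
Pooled-then-evaluate is the default (one unambiguous distribution per unit);
single-class units are skipped, not imputed, and counted in `n_skipped` so
the choice is visible.

AUC-ROC uses the rank-sum estimator (ties one half). AUC-PR uses the
average-precision estimator with step interpolation, whose no-skill value
equals the positive prevalence — matching the 0.02 no-skill reference at the
benchmark's class balance. `rescale_pr_to_prevalence()` recomputes precision
at every ROC operating point under an assumed prevalence $\pi'$,
$\pi' TPR / (\pi' TPR + (1-\pi') FPR)$, integrating as in average precision;
with $\pi'$ equal to the empirical prevalence it reproduces `auc_pr()`
exactly, and with $\pi' = 0.5$ it maps full-data results onto the balanced
convention used by prior work.

## Tuning

`default_grid()` encodes per-task log-spaced ranges, one point per decade by
default (density is configurable; the source protocol does not print one):
$\lambda_1 = \lambda_2 \in [10^{-6}, 10^{-1}]$, $\lambda_3 \in [10^{-4},
10^{1}]$ for `dde` and `dd_e`; $\lambda_1 = \lambda_2 \in [10^{-4},
10^{1}]$, $\lambda_3 \in [10^{-4}, 10^{1}]$ for `d_d_e`; and independent
ranges $\lambda_1 \in [10^{-3}, 10^{-1}]$, $\lambda_2 \in [10^{-6},
10^{-1}]$, $\lambda_3 \in [10^{-1}, 10^{1}]$ for `d_de`. The protocol text
lists the first range pair for "`dde` and `d_de`" but then gives `d_de` its
own separate ranges; we read the first list as covering the two
symmetric-role tasks `dde` and `dd_e`, which is the only assignment
consistent with the explicit $\lambda_1 = \lambda_2$ statement.

`tune_threestep()` scores each triple by an inner cross-validation of the
same scheme on the supplied training tensor, macro-evaluated like the outer
run. Inner granularity follows the scheme: leave-one-drug-out for the
drug-level schemes (the natural unit, and cheap through shared
eigendecompositions), ten folds for the cell-level schemes where
leave-one-cell-out is not affordable. Ties are broken toward larger
$\lambda$ — when two fits are indistinguishable, prefer the more regularized
one.

## Detection

`detect_effects()` implements the 3σ rule: scores of zero-labelled test
triplets concentrate near zero; their standard deviation (population
convention, divisor $n$) times a multiplier (default 3) is the threshold,
and zero-labelled triplets above it are candidate unreported effects. Flags
are united across the supplied models with per-model provenance. Two
deliberate non-interventions: σ is the plain standard deviation (no
robust/MAD variant by default, though the report records the threshold so
users can re-threshold), and scores are *not* re-centered — the distribution
is centered near zero by construction, and silently re-centering could mask
a miscalibrated model. For the new-drug schemes all test scores form a
single distribution (no label is expected for a new drug), selection applies
to all test triplets, and detected pairs are afterwards confirmed against
the held-back labels.

## The synthetic generator

`simulate_polypharmacy()` emulates the *shape* of the benchmark data, not
its biology: drug and effect latents $u_i, v_k \sim N(0, I_r)$ (default
$r = 8$), a symmetric propensity
$s_{ijk} = \sigma(\alpha\, u_i \cdot u_j/\sqrt r + (u_i \circ u_j)^\top W
v_k)$, labels by quantile thresholding at the target prevalence (default
2%), and mono-drug features as binarized random projections of $u_i$ with a
corruption probability `feature_noise` (each corrupted bit is replaced by a
fair coin, so noise 1 is genuinely uninformative — a deterministic flip
would not be). The pair-level term $\alpha\, u_i \cdot u_j$ concentrates
positives on interacting pairs, reflecting the empirical pattern that an
interacting pair tends to show several effects at once.

`decagon_like()` additionally pins the second printed benchmark statistic:
an exact 70% of pairs (those with the highest pair propensity, hence still
feature-linked) are designated interacting, each is guaranteed its
top-propensity effect, and the remaining positive budget is filled by global
propensity rank within interacting pairs. This is deterministic given the
seed and hits both statistics exactly at the default scale (100 drugs × 50
effects). When the positive budget is smaller than the requested pair count
(at 2% prevalence this happens below 35 effects), coverage is capped at
`n_positives / n_pairs` — at 60 × 30 the realized pair fraction is 0.60.

What passing tests on this generator do and do not show: they demonstrate
that the estimator, the fold plans, the leak-free kernels, the metrics and
the detection rule behave as specified under a smooth low-rank generative
process with feature-linked structure. They do not demonstrate performance
on real pharmacovigilance data, which carries reporting biases, confounding,
non-random missingness of positives, and mono-effect profiles whose
relation to interaction structure is unknown — none of which are simulated.

## Experiment sizes and fixed choices

The heavier properties in the test suite use sizes chosen once as the
smallest scales at which each property is meaningfully exercised: oracle
equivalence of the solver on tensors up to $6 \times 6 \times 4$ across
$\lambda \in \{10^{-3}, 1, 10^{3}\}$ combinations, and of the
cross-validation pipeline on $8 \times 8 \times 3$; contamination audits up
to 50 drugs; the task-difficulty ordering on `decagon_like()` at
$100 \times 50$ with 10 folds, with $\lambda$ tuned per task (`Edd`,
AUC-ROC) on an *independent* reduced-scale realization ($60 \times 30$,
four inner folds) so that selection never touches the evaluation data;
planted-structure recovery at 60 noise-free drugs using the geometric
midpoints of the task's default grid ranges as a neutral, untuned
$\lambda$. Seeds are fixed in the tests; the generator's defaults (2%
prevalence, 70% pair coverage, latent dimension 8, 64 mono features, 5%
feature noise) are the package's standing description of a
benchmark-shaped instance and are not adjusted per experiment.

## Limitations

* The parameter tensor is dense ($n_d^2 n_e$); the package targets desk
  scale (hundreds of drugs). The full benchmark tensor (645 × 645 × 963) is
  feasible for a single fit on a well-provisioned machine but not the
  package's design point, and its headline cross-validated figures require
  that external download.
* Hold-out shortcuts are single-mode only; multi-mode holdout is refit-based
  (cheap here, but asymptotically inferior to closed-form deflation).
* Scores are unbounded reals, not probabilities; mapping to calibrated
  probabilities is out of scope.
* The label model is strictly binary and symmetric; ordinal severity,
  directional interactions, and higher-order (three-drug) combinations are
  not representable.
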