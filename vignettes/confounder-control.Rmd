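---
title: "Controlling non-neotissue confounders in NIR-based assessment of tissue-engineered constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling non-neotissue confounders in NIR-based assessment of tissue-engineered constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirconfound)
```

## The problem

Diffuse-reflectance NIR spectra (943.8–2491 nm, 256 channels here) of a
tissue-engineered construct integrate the optical response of everything in
the sample: the neotissue of interest, but also the hydrogel scaffold and
its peptide modification (HAV), growth factors supplemented to the medium
(BMP-9 or TGF-β1, never both), and the storage buffer (PBS or the M-PER
lysis reagent). If any of those constituents is (a) detectable in the
spectra and (b) unevenly distributed across the classes a model is trained
to separate, the model can learn the constituent instead of the biology.
This package provides the machinery to measure (a) with a classifier
screen, and to measure (b) by comparing maturity classifiers trained on a
deliberately confounded design against classifiers trained on a propensity
score matched design, evaluated on identical test samples.

## Data model and preprocessing

An inventory couples a strictly increasing wavelength grid, per-sample
metadata (incubation day 7/28, a control flag, four binary constituent
flags), and replicate-level spectra keyed by `(sample_id, replicate)`.
Metadata invariants are enforced at construction: BMP-9 and TGF-β1 never
co-occur, and control samples (cell-free, growth-factor-free,
unconjugated, stored in PBS) carry no constituent flags. The buffer
assignment of controls is not fixed by the study description; we default
them to PBS (`mper = FALSE`), the conservative choice that keeps controls
free of every studied constituent.

Every spectrum is preprocessed with a Savitzky–Golay first derivative:
a least-squares quadratic is fitted in a sliding 13-channel window and its
analytic first derivative evaluated at the window centre
(`signal::sgolayfilt`, p = 2, n = 13, m = 1). Numerical choices:

* **Edges.** The polynomial fitted to the first/last complete window is
  evaluated at the edge positions, so output length equals input length
  and all spectra stay aligned on the grid.
* **Units.** The derivative is per channel index, not per nm: the grid is
  treated as evenly indexed, which is what spectroscopy toolkits do and is
  harmless for classification since it rescales all spectra identically.
* **Order.** The filter is linear, so derivative-then-average equals
  average-then-derivative for technical replicates; the pipeline fixes
  the order (derivative first) anyway.

Two cleaning steps are used only where the Monte Carlo stage needs them:
channels constant across every spectrum are dropped, and samples short of
three technical replicates are completed by *simple replacement* — the
sample's first available replicate is duplicated. Simple replacement is
the plainest reading of that rule; since replicates of one sample never
straddle the train/test boundary, the duplication cannot leak
information.

## The synthetic generator

The generator exists so that every downstream stage is testable without
the original measurements. It has two halves.

**Roster.** The published design gives only per-constituent margins by
day (Day 7: n = 41 with 11 M-PER / 24 HAV / 22 BMP-9 / 14 TGF-β1; Day 28:
n = 28 with 10 / 16 / 12 / 7; plus 6 controls per day). The true joint
table is not public, so `joint_counts_from_marginals()` builds a feasible
joint allocation over (HAV × {none, BMP-9, TGF-β1} × M-PER) cells by
proportional seeding with a deterministic residual fill; any feasible
joint with the correct margins serves the purpose. Tests verify every
margin by a counting oracle, and the uncontrolled-partition arm sizes that
follow from the default roster (M-PER 10/30, BMP-9 12/19, TGF-β1 7/27,
HAV 16/17) are checked exactly.

**Spectra.** Each sample's mean curve is a scaffold baseline (Gaussian
bands at 1150/1450/1930 nm over a 0.2 offset, arbitrary reflectance
units), plus for mature cell-containing samples a broadband maturity
component (bands at 1510/2280 nm, amplitude 0.05), plus the signature of
each constituent present. The M-PER signature is a single strong band at
1050 nm (amplitude 0.05), five times the amplitude of the broadband
HAV/BMP-9/TGF-β1 signatures (0.004/0.010/0.005) — strong and localized
versus subtle and diffuse. Replicates add a smooth quadratic baseline
drift (coefficient sd 0.005), a constant offset (sd 0.002) and iid channel
noise (sd 0.01).

Two choices deserve justification:

* **Maturity heterogeneity.** The per-sample maturity amplitude is scaled
  by a truncated normal with coefficient of variation 0.4
  (`maturity_sample_cv`). Construct development is heterogeneous — some
  Day-28 constructs barely differ from Day-7 ones — and without this the
  maturity classes separate perfectly and every comparison saturates at
  F1 = 1, which no real spectroscopy study achieves. With it, controlled
  maturity classifiers land in a good-but-imperfect range while a strong
  aligned confounder still drives uncontrolled models toward zero.
* **Controls** share the immature baseline (maturity effect 0), matching
  the observation that immature constructs resemble the cell-free
  scaffolds.

One root seed drives everything; each stage (roster missingness, spectra,
fold assignment, every model fit, every Monte Carlo iteration) draws from
a sub-stream derived by hashing the root seed with stage tags, so adding a
stage never perturbs earlier draws, and two runs from one root seed
produce byte-identical CSV artifacts. Draws for skipped replicates are
still consumed, so configuring missingness never shifts other samples'
spectra.

What the generator does *not* emulate: absolute reflectance levels,
water-band physics, scatter effects, instrument drift between sessions,
or any chemical relationship between the constituents and the neotissue
signal. Passing tests on synthetic data therefore demonstrate that the
*procedure* behaves correctly (partition rules, matching, leak-free
evaluation, direction and significance of recovered confounding), not
that any particular real-data performance number will be reproduced.

## The classifier zoo

Nine families with fixed hyperparameters behind one fit/score contract:
AdaBoost (50 SAMME.R rounds over depth-1 trees, learning rate 1), gradient
boosting (100 trees, rate 0.1, depth 3), k-NN (k = 7, Euclidean, uniform
votes), ridge logistic regression (C = 1), Gaussian naive Bayes, a neural
network (one hidden layer of 100 ReLU units, full-batch Adam, 200
epochs), random forest (10 trees, minimum split 5), RBF SVM (cost 1,
tolerance 0.001, gamma = 1/(channels · var(X))) and a decision tree
(depth ≤ 10, minimum split 5, with internal nodes whose majority class
reaches 95% pruned — the "majority stop" rule, implemented by
post-pruning since CART libraries have no such stopping criterion).
Scores are positive-class probabilities, except SVM and AdaBoost which
return signed margins; class predictions threshold at 0.5 / 0
respectively. Knobs the protocol leaves implicit are pinned to the
backend defaults and written verbatim to `algorithms.lock` by every run.
Two backends are authored in-package because no installed library
provides them in the required form: the SAMME.R boosting loop and the
ReLU/Adam multilayer perceptron; both are small, deterministic and
covered by oracle tests (brute-force neighbour votes, closed-form
likelihood orderings, permuted-label leak checks).

No feature scaling is applied outside the neural network (which z-scores
its inputs for optimization conditioning, recorded in the lock file): the
derivative features share one physical unit, and the study protocol
applies none.

## Workflow A: detectability

Technical replicates are averaged to one spectrum per sample (controls
included, with their true flags), and each (constituent, algorithm) pair
is evaluated by stratified 10-fold cross-validation: within-class
shuffling, near-equal chunks, remainder chunks dealt from opposite ends
so fold sizes stay balanced. Out-of-fold predictions are pooled into a
single confusion matrix per model — the convention that matches reporting
one confusion matrix per model; whether the original analysis pooled or
averaged per-fold metrics is not stated, and pooling is the variant that
keeps every sample weighted once.

## Workflow B: controlled versus uncontrolled

**Partitions.** For constituent *c*, the uncontrolled training set is all
Day-28 samples with *c* plus all Day-7 samples without it. The controlled
training set is built once and shared across the four comparisons:
propensity scores from a logistic regression of Day-28 membership on the
four flags (ridge fallback under complete separation), greedy
nearest-neighbour matching without replacement on |logit *e*₂₈ − logit
*e*₇| with treated samples visited in descending propensity and all ties
broken by smallest sample id. The test set for *c* is every non-control
sample in neither training set; training uses replicate-level spectra,
testing uses per-sample replicate means, and no sample's replicates ever
straddle the boundary.

**Pair retention.** With 41 Day-7 candidates for 28 Day-28 samples and no
admissibility rule, every Day-28 sample gets matched — the controlled set
would absorb all mature samples and the shared test sets would contain
none, making the comparison undefined. The study's own controlled set
held 10 pairs, with the remaining treated samples failing to match under
an unstated rule. `run_step1()` therefore retains the `n_pairs` closest
pairs (default 10, reproducing the study's controlled-set size); the
matching function itself also exposes an optional caliper
(`max_distance`) for users who prefer an explicit admissibility distance.
Per metric, the nine per-algorithm differences are summarised by the mean
(controlled − uncontrolled, positive = improvement) and a two-sided
Wilcoxon rank-sum test — the unpaired test applied to paired scores, as
in the protocol; a signed-rank variant is available behind a flag for
sensitivity analysis.

**Monte Carlo (step 2).** For the top algorithm (SVM by default), 100
random train/test combinations per constituent: the uncontrolled set
takes the fixed Day-28 arm plus an equal-sized random draw (without
replacement) of eligible Day-7 samples; the controlled set takes an
equal number of randomly drawn matched pairs from the *fixed* pool
computed once on the full inventory (capped at the pool size with a
message when the arm exceeds it, as happens if fewer pairs exist than
Day-28 samples with the constituent); everything else is the test set,
left class-imbalanced as found. Per-iteration F1 differences are
summarised by a paired t-test with a 95% CI. If every iteration yields
the identical difference the t statistic is unbounded; the limiting
p-value (0 for a nonzero difference, 1 otherwise) is reported with a
degenerate CI and a message rather than an error.

## Statistical conventions

* AUC is the Mann–Whitney pair statistic (ties count ½), equal to
  trapezoidal ROC integration and exact under ties.
* The rank-sum test enumerates all rank assignments exhaustively (with
  midranks, so ties are exact) for combined n ≤ 12 — the regime of the
  nine-algorithm comparisons — and uses the tie-corrected normal
  approximation above that. Two groups of identical values give p = 1 by
  convention.
* F1 is 0 when tp = 0 with false calls present, and undefined (an error)
  when tp = fp = fn = 0.
* No multiple-testing correction is applied anywhere, matching the
  protocol.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle:
the derivative against a per-window least-squares fit; AUC against
brute-force pair counting; exact rank-sum p-values against the reference
exact distribution (tie-free) and an independent bitmask enumeration
(tied); k-NN against brute-force neighbour votes; naive Bayes against
closed-form likelihood-ratio orderings; matching against hand-enumerated
greedy outcomes. Property suites cover filter linearity, fold balance,
set-algebra disjointness, determinism of every stage, and
chance-level performance of all nine classifiers under permuted labels.

Two invariants required interpretation:

* **Imbalance reduction.** Requiring every individual flag's prevalence
  difference to shrink under matching is not a property greedy
  nearest-neighbour propensity matching guarantees — it balances the
  propensity score, not each covariate marginally, and per-flag
  violations occur regularly on random rosters. The suite instead checks
  the quantity the method controls: the absolute difference in mean logit
  propensity between matched arms never exceeds its pre-matching value
  (alongside the without-replacement and pair-count invariants).
* **Null-confounder coverage.** With all constituent amplitudes zero, the
  per-iteration CI of ΔF1 conditions on one roster's fixed Day-28 arm and
  understates between-dataset variability, so its coverage of 0 is
  erratic for any single seed even though seed-level mean ΔF1 is centred
  on 0. The null check therefore takes a 95% CI over seed-level mean ΔF1
  (5 dataset seeds × 25 iterations), which carries both variance sources.

Stochastic suites are scaled to keep the default run light: Monte Carlo
checks use 25 iterations (the comparison's direction and significance are
already unambiguous there), detectability and ranking checks use the
faster classifier subset where the property does not require all nine,
and the end-to-end byte-identity check runs the full pipeline twice with
5 folds, 5 Monte Carlo iterations and the five fast algorithms. The full
default configuration (all nine algorithms, 10 folds, 100 iterations) is
what `run_all()` executes.

## Limitations

* Synthetic spectra are phenomenological; no numeric result on them
  transfers to the deposited measurements, and the package deliberately
  does not attempt to reproduce the study's real-data performance tables.
* The retained-pair rule (`n_pairs` closest) reproduces the size, not the
  identity, of the study's matched set, since the original admissibility
  rule is unpublished.
* The rank-sum test treats the nine per-algorithm scores as independent
  samples, which they are not (all models share training data); it is
  implemented as specified, with the signed-rank variant available for
  sensitivity.
* Propensity scores use the four constituent flags only — the declared
  confounders — so unmodelled confounders (e.g. batch effects) remain
  uncontrolled.
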