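# nirconfound

Near-infrared (NIR) spectroscopy combined with machine learning is an
attractive non-destructive way to assess tissue-engineered constructs
(TECs), but NIR spectra are non-specific: they also carry the imprint of
everything in the sample that is *not* neotissue — the scaffold and its
peptide modifications, growth factors in the medium, and the buffer the
construct was stored in. When the distribution of such constituents differs
between the groups a model is trained to separate (say, immature Day-7
versus mature Day-28 constructs), they become confounders: the model learns
the buffer, not the biology.

`nirconfound` implements, as a reusable and tested R pipeline, a procedure
for detecting and controlling this confounding:

* **Detectability screen (Workflow A).** Nine fixed-hyperparameter
  classifiers (AdaBoost, gradient boosting, k-NN, ridge logistic
  regression, Gaussian naive Bayes, a ReLU/Adam neural network, random
  forest, RBF SVM, decision tree) are evaluated by stratified 10-fold
  cross-validation on classifying each constituent flag from the spectra.
  If a constituent is classifiable, it can bias downstream models.
* **Confounding assessment (Workflow B).** For each constituent, a
  deliberately *uncontrolled* training set perfectly aliases the
  constituent with maturity (every Day-28 training sample carries it, every
  Day-7 sample lacks it), while a *controlled* training set balances all
  four constituents across the two days by propensity score matching
  (logistic regression of Day-28 membership on the flags, greedy
  nearest-neighbour matching without replacement on the logit scale). Both
  models are evaluated on the same held-out samples; the paired difference
  in F1/AUC measures the confounding bias. Step 2 repeats the comparison
  over Monte Carlo cross-validation with random undersampling of the
  majority (Day-7) class, summarised by a paired t-test on the
  per-iteration F1 improvements.
* **Synthetic data generator.** A roster generator that reproduces the
  study design exactly (69 test constructs with the published
  per-constituent margins by day, 12 controls, 3 technical replicates with
  2 samples incomplete) and a phenomenological spectral model (Gaussian
  bands, a strong localized M-PER signature at 1000–1100 nm, subtle
  broadband signatures for HAV/BMP-9/TGF-β1, a heterogeneous maturity
  shift, smooth baseline drift and channel noise), so the whole pipeline is
  testable without the original measurements.

All spectra are preprocessed with a Savitzky–Golay first derivative
(second-order polynomial, 13-channel window) before any analysis, and
technical replicates of a sample always stay in the same subset (training
*or* test) to avoid the replicate trap.

The core quantities are the F1 score, `F1 = 2·TP / (2·TP + FP + FN)`; the
AUC computed as the Mann–Whitney pair statistic,
`AUC = (#{s⁺ > s⁻} + ½·#{s⁺ = s⁻}) / (n⁺ n⁻)`; the propensity score
`e(x) = P(Day-28 | mper, hav, bmp9, tgfb1)`; and the controlled-minus-
uncontrolled performance difference `ΔF1` with its 95% CI.

## Worked example

```r
library(nirconfound)

inv <- generate_dataset(generator_config(seed = 7))
inv
#> <nir_inventory> 81 samples (12 controls), 241 spectra, 256 channels (943.8-2491.0 nm)

pre <- preprocess_inventory(inv)

# is the storage buffer detectable from the spectra?
run_workflow_a(pre, constituents = "mper",
               algorithms = c("kNN", "NaiveBayes", "SVM"), seed = 11)
#> <nir_eval> pooled out-of-fold metrics
#>   constituent  algorithm AUC F1
#> 1        mper        kNN   1  1
#> 2        mper NaiveBayes   1  1
#> 3        mper        SVM   1  0

# how much does leaving it uncontrolled hurt maturity prediction?
run_mc(pre, "mper", n_iterations = 25, seed = 11)
#> <mc_result> mper: mean dF1 = 0.544 (CI95: 0.511 to 0.578), p = 1.29e-21 over 25 iterations
```

The screen says the M-PER buffer is perfectly classifiable from the spectra
(AUC 1 for all three models; the SVM ranks perfectly but its default
decision threshold never fires under this class imbalance, hence F1 0 —
the same pattern the ridge logistic model shows on imbalanced constituent
tasks). The Monte Carlo comparison quantifies the damage: with M-PER
aliased to maturity in training, controlling for it by propensity score
matching raises the test-set F1 by 0.54 on average (CI95 0.51–0.58) over
25 random train/test combinations — a large, significant confounding bias.

A single call runs everything and writes the tabular artifacts
(`table3_style.csv`, `table4_style.csv`, `fig4_style.csv`,
`group_mean_spectra.csv`, `membership.csv`, `algorithms.lock`, `MANIFEST`,
`run.log`):

```r
run_all(run_config(out_dir = "artifacts", seed = 1))
```

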