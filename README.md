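# choqfuzgcn

Survival-prognosis classification from multi-omics cohorts: patients are
labeled **short-term** (death before five years, class 1) or **long-term**
(class 0) survivors from gene-expression (GE), copy-number-alteration
(CNA) and clinical (CLN) data. The package is aimed at computational
biologists who want a fully seeded, desk-scale implementation of the
graph-plus-fuzzy-ensemble approach — including a synthetic cohort
generator, so every stage runs and is tested without any external
download.

## The method

1. **Patient-similarity graphs.** For each molecular modality, nodes are
   patients and an edge joins `i, j` when the Pearson correlation of their
   feature vectors meets a threshold (GE ≥ 0.3, CNA ≥ 0.6 by default).
   Message passing uses the symmetric-normalized propagation matrix
   `A* = D̃^{-1/2} (A + I) D̃^{-1/2}`.
2. **GCN embeddings.** A semi-supervised graph convolutional network
   `L[k+1] = ReLU(A* L[k] W[k])` (hidden sizes 200/150/100, softmax head,
   200 epochs of Adam at lr 0.001, L2 penalty) is trained with the loss
   masked to training nodes; the 100-unit last hidden layer is the
   per-modality patient embedding. Clinical covariates skip the GCN and are
   concatenated directly.
3. **Choquet fuzzy-integral ensemble.** Logistic regression, an RBF-kernel
   SVM and a 70-tree random forest are fitted on the stacked
   (SMOTE-balanced) features. Validation accuracies `s_j` become fuzzy
   densities `g_j = s_j / Σ s_j`; the interaction parameter λ solves
   `1 + λ = Π (1 + λ g_j)`; subsets combine via
   `μ(X∪Y) = μ(X) + μ(Y) + λ μ(X) μ(Y)`; and per-sample class confidences
   `s(1) ≤ … ≤ s(m)` are fused by the Choquet integral
   `Σ (s(i) − s(i−1)) · μ(A_i)` over suffix sets `A_i`. Fused class scores
   are renormalized and thresholded at 0.5.

Because the densities sum to 1, λ is exactly 0 and the fusion reduces to
an accuracy-weighted mean — an identity the test suite asserts; the
general-λ regime is available via `density_normalize = FALSE`. See
`vignettes/methods.Rmd` for every design decision and its rationale.

## Worked example

```r
library(choqfuzgcn)

co <- generate_cohort(cohort_spec(n_samples = 150, n_ge = 60, n_cna = 40,
                                  n_cln = 10, effect_size = 3, seed = 7))
cfg <- pipeline_config(n_folds = 3,
                       gcn = gcn_config(hidden_sizes = c(32, 16), epochs = 60),
                       mrmr_n = c(GE = 30, CNA = 20), seed = 3)
res <- run_cross_validation(list(GE = co$ge, CNA = co$cna, CLN = co$cln),
                            co$labels, cfg)
print(res)
#> <cv_result> 3 folds, 150 samples
#> mean metrics:
#>     Acc     Mcc     Pre      Sn      Sp Bal_Acc      F1     AUC
#>  0.9600  0.9010  0.9762  0.8810  0.9907  0.9358  0.9249  0.9987
```

The cohort plants a latent two-class signal (effect size 3 latent-sd
units) in 20% of the features of each modality; the pipeline recovers it
almost perfectly — mean balanced accuracy 0.936 and AUC 0.999 across the
three folds, with sensitivity 0.881 on the 28%-prevalence short-term
class. On label-permuted data the same pipeline scores a balanced
accuracy near 0.5 (chance), which the acceptance suite checks.

A fuzzy-measure one-liner:

```r
fm <- fuzzy_measure(c(LR = 0.80, SVM = 0.85, RF = 0.90))
fm$lam                          #> 0        (densities sum to 1)
choquet_integral(c(0.2, 0.5, 0.9), fuzzy_measure(c(0.3, 0.3, 0.4)))
#> 0.57                          (= 0.2*0.3 + 0.5*0.3 + 0.9*0.4)
```

## Command line

```sh
Rscript -e 'choqfuzgcn::cfg_cli()' simulate --out-dir cohort --seed 3 --n-samples 600 --effect-size 3
Rscript -e 'choqfuzgcn::cfg_cli()' crossval --ge cohort/ge.tsv --cna cohort/cna.tsv \
    --cln cohort/cln.tsv --labels cohort/labels.tsv --out-dir cvout --seed 1
```

`crossval` writes `metrics_per_fold.tsv`, `metrics_mean.tsv`,
`roc_points.tsv` and `fused_scores.tsv`. Subcommands `build-graph`,
`fuse` and `metrics` expose the intermediate stages; `--config` accepts a
flat `key = value` file mirroring `pipeline_config()`.

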