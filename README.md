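# zipo

Zero-inflated count autoencoders for denoising single-cell RNA-seq data.

Single-cell RNA-seq count matrices are mostly zeros — a mix of genes that
truly were not expressed and *dropouts*, transcripts present in the cell
but missed by capture and amplification. `zipo` fits a deep autoencoder to
a cells × genes count matrix under an adjustable zero-inflated Poisson
(ZIP) or negative binomial (ZINB) model. For each cell *c* and gene *g*
the model predicts

* a library size *l<sub>c</sub>* (the technical depth of the cell),
* a zero-inflation probability *z<sub>cg</sub>* = sigmoid(*r<sub>cg</sub>*),
* a normalized mean rate *μ<sub>cg</sub>* with Σ<sub>g</sub> *μ<sub>cg</sub>* = 1
  (log-softmax head), and
* optionally a dispersion *θ<sub>cg</sub>* (ZINB),

so that each count follows
*z* δ₀(*x*) + (1 − *z*) · exp *f*(*x*; *m*, *θ*) with expected expression
*m* = *l μ*. The log-likelihood is evaluated in a numerically stable
log-sigmoid form (no truncation offsets), and the training loss adds an L2
penalty α<sub>z</sub>·E[*z*²] that dials the amount of zero inflation, plus
a **scale-invariant L1/L2 penalty** on the first encoding layer,

&nbsp;&nbsp;&nbsp;&nbsp;α<sub>w</sub> · mean<sub>i</sub> [ mean<sub>g</sub>|W<sub>ig</sub>| / (mean<sub>g</sub> W<sub>ig</sub>²)<sup>1/2</sup> ],

which drives most first-layer weights toward zero without being gamed by
rescaling, so the layer can be pruned into small, interpretable gene sets.
The low-dimensional embedding is exportable for clustering and other
downstream analyses. The package includes a ground-truth ZIP/ZINB
simulator, training with learning-rate warm-down / plateau reduction /
early stopping, pruning diagnostics, multi-seed model comparison with the
λ = Φ⁻¹(0.99)/√2 ≈ 1.64 error-bar rule, hyperparameter search, and a CLI.

It is aimed at computational biologists who want count-level denoising and
imputation with explicit, inspectable distributional assumptions rather
than a black-box smoother.

## Worked example

```r
library(zipo)

# simulate a small UMI experiment with known truth
sim <- simulate_counts(sim_spec(n_cells = 500, n_genes = 200, seed = 42))
sim$counts
#> <zipo_counts> 500 cells x 200 genes; 52.8% nonzero

spec  <- model_spec(c(64, 32, 16), n_genes = 200, residuals = "full",
                    activation = "gelu")
model <- build_model(spec, seed = 42)
model
#> <zipo_model> 200 genes -> 64-32-16 (gelu, zip); 1 residual projection(s); 23,409 parameters

fit <- train_zipo(model, sim$counts,
                  cfg = train_config(max_epochs = 60, seed = 42))
fit
#> <zipo_fit> 60 epoch(s); best validation loss 4227.93

imp <- zipo_impute(fit, sim$counts)
cor(exp(imp$dist$log_l), sim$truth$true_l)   # library-size recovery
#> 0.908
mean_zero_probability(imp$dist)              # vs true mean dropout 0.193
#> 0.194
```

The predicted library sizes track the simulated truth (correlation 0.91
after a one-minute training run), and the mean predicted dropout
probability matches the generating rate. Denoised expected counts
(`l * mu`), dropout probabilities, and the latent embedding are written
with `export_denoised()` and `export_latents()`; `prune_model(fit$model,
delta = 1e-4, eval_data = ...)` zeroes small first-layer weights and
reports the NLL/MSE shift before and after.

## Command line

A thin wrapper (`inst/cli/zipo`) exposes the same functionality as
subcommands with a YAML config file and `--key value` overrides:

```sh
zipo simulate --out sim --n_cells 1000 --n_genes 500 --seed 1
zipo train    --data sim/counts.tsv --out run --encoder 512-256-128 --seed 1
zipo impute   --checkpoint run/checkpoint.rds --data sim/counts.tsv --out out
```

Every run writes a `manifest.json` with the resolved configuration, seed,
and package version. Presets `zipo-default`, `dca`, `zipDCA`, and
`tunedDCA` reproduce the standard model variants.

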