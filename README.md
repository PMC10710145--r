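# mvfuse

Predicting an expensive-to-measure continuous phenotype from several cheap
*views* of the same subjects — e.g. a panel of DXA-derived imaging features
plus genotype dosages at trait-associated variants — is a recurring problem
in radiogenomics and musculoskeletal research, where the reference
phenotype (such as a femoral fracture load from QCT-based finite element
analysis) is too costly or radiation-intensive for routine use. `mvfuse`
implements this prediction pipeline end to end for R users: variant
selection by genome-wide association, representation learning with a
multi-view variational autoencoder, closed-form product-of-experts fusion,
a linear prediction head, and leave-one-out feature importance — plus a
synthetic-data generator so every stage is testable without access to a
cohort.

## The model

Each view $x_m$ gets an MLP encoder emitting a diagonal-Gaussian posterior
$q_{\phi_m}(z \mid x_m) = N(\mu_m, \Sigma_m)$ over a shared latent space of
dimension $D$. The per-view posteriors are fused as a product of experts:
the product of Gaussians is Gaussian, with precisions $T_m = \Sigma_m^{-1}$
adding and means precision-weighted,

$$\Sigma_z = \Big(\sum_{m=1}^M T_m\Big)^{-1},\qquad
\mu_z = \Big(\sum_{m=1}^M \mu_m T_m\Big)\Big(\sum_{m=1}^M T_m\Big)^{-1}.$$

Training minimizes the negative evidence lower bound in closed form —
summed Bernoulli cross-entropy between each min–max-scaled view and its
sigmoid decoder output, plus
$D_{KL}\big(N(\mu_z,\Sigma_z)\,\|\,N(0,I)\big)
= \tfrac12\sum_d (\mu_d^2 + \sigma_d^2 - \log\sigma_d^2 - 1)$ —
with reparameterized sampling $z = \mu_z + \Sigma_z^{1/2}\odot\epsilon$.
A linear regression head maps the fused posterior mean to the phenotype.
With a single view the model reduces to a standard VAE.

Upstream, variants are ranked by the covariate-adjusted score test
$T = U^2/V$ with $U = \sum_i \tilde y_i \tilde g_i$ and
$V = \frac1N \sum_i \tilde y_i^2 \sum_i \tilde g_i^2$ (residuals taken
against age/weight/height plus genotype principal components;
$p$ from $\chi^2_1$), after quality control with missing-rate, exact
Hardy-Weinberg and minor-allele-frequency filters; the top 256 variants
form the genotype-derived view. See `vignette("mvfuse-methods")` for the
full account.

## Worked example

```r
library(mvfuse)

study <- make_study(sim_config(n_subjects = 300, n_snps = 1000, n_causal = 5,
                               causal_effect_sd = 0.6, view_dims = c(24, 32),
                               latent_dim_true = 4, seed = 42))
study
#> sim_study: 300 subjects, 1000 SNPs (5 causal), 2 views (24+32 features)

paths <- write_study(study, "demo")
cfg <- pipeline_config(
  genotype_path = paths$genotypes,
  view_paths = c(DXA = paths$view1, TBS = paths$view2),
  phenotype_path = paths$phenotype,
  output_dir = "demo/out",
  top_k = 128, n_pcs = 5,
  train = train_config(latent_dim = 32, n_layers = 1, hidden_units = 64,
                       epochs = 150, seed = 1),
  seed = 7)
res <- run_pipeline(cfg)
res$metrics
#> prediction_report: MAE 0.7812, MAPE 6.13%, RMSE 0.9251, R2 0.4058

sum(paste0("snp", study$causal_index) %in% res$selected)
#> [1] 2
head(res$importance$top[, c("view", "feature", "delta")], 3)
#>   view   feature     delta
#> 1  TBS view2_f16 0.2579305
#> 2  DXA  view1_f2 0.2444147
#> 3  DXA view1_f19 0.2341511
```

Reading the output: the held-out test set (20% of subjects) is predicted
with mean absolute error 0.78 phenotype units (6.1% in relative terms) and
$R^2 = 0.41$ — at this cohort size the views carry most of the usable
signal. Two of the five causal variants make the selected top-128 panel;
the other three were drawn with effects too small for a 300-subject scan
to rank highly, which is the expected behaviour, not a defect. The
importance table says prediction degrades most when feature 16 of the TBS
view is zeroed out.

Artifacts land in `demo/out/`: `association.tsv` (the scan, sorted by
$p$), `selected_variants.txt`, `metrics.json`, `importance.tsv`,
`model.rds` and `manifest.json` (seed + config hash; a rerun from the same
manifest reproduces every metric).

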