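# drpfuse

Multi-source similarity fusion for drug-response (IC50) prediction in
cancer cell lines.

Anti-cancer drug screens give a sparse table of IC50 values over drugs and
cell lines; the practical question is predicting the missing entries —
including for drugs or cell lines with no measurements at all (cold
start). `drpfuse` is for computational pharmacogenomics work that wants to
combine *many* heterogeneous drug descriptions instead of betting on one:
it builds **12 drug similarity views** (six molecular fingerprints, four
biological-entity association profiles, chemical–chemical combined scores,
IC50 response profiles) and **4 cell-line feature views** (expression,
mutation, copy number, response-profile similarity), completes and fuses
them, and regresses IC50 with a neural interaction model.

## The method

* Every drug feature matrix becomes a similarity view through the row-wise
  Chebyshev distance, `D(a,b) = max_c |v_ca − v_cb|`, mapped to
  `S = 1 − D` (distances are min–max scaled first when they exceed 1).
* The six fingerprint views are fused by **similarity network fusion**
  (SNF cross-diffusion, K nearest neighbours, T iterations); drugs with no
  recorded associations in a sparse view get their similarity row *and*
  column replaced by the fused fingerprint similarity. All 12 drug views
  are then fused into one matrix.
* For a pair (dᵢ, cⱼ) the model projects each view's row to a common
  dimension *s* (`g′_k = g_k G_k`, `h′_l = h_l H_l`, no bias) and forms all
  48 = 12 × 4 **outer-product interaction maps** `g′_k ⊗ h′_l` (run through
  a residual CNN with global max-pooling) and 48 **inner-product vectors**
  `g′_k ⊙ h′_l` (concatenated into a four-layer MLP). Together with MLP
  embeddings of the fused/drug/cell vectors, a four-layer head predicts
  IC50. Training: MSE loss, Adam (lr 1e-4, weight decay 3e-4), early
  stopping with patience 10. The network — forward, backward, Adam — is
  implemented in base R on BLAS matrix ops and gradient-checked against
  finite differences.
* Evaluation: random 8:1:1 splits, drug-blind (ES1) and cell-blind (ES2)
  cold-start splits, an independent-test harness, RMSE/MAE/Pearson-r
  metrics, and a 16-run leave-one-view-out ablation harness.

A synthetic benchmark generator plants a bilinear signal
`IC50(i,j) = uᵢᵀ A w_j + ε` beneath all input tables so every stage — and
the model's ability to recover signal through the similarity views — is
testable without any database downloads.

## Worked example

```r
library(drpfuse)

# a synthetic screen: 30 drugs x 40 cell lines, ~1000 IC50 values,
# noise at 10% of the planted signal scale
bundle <- generate_bundle(synthetic_config(seed = 11))

res <- run_pipeline(bundle, scheme = "random",
                    spec = small_model_spec(), seed = 11)
res$metrics
#> <metrics_report> n=102  RMSE 0.3576  MAE 0.2567  r 0.9274

# ceiling of what is recoverable from the true latent factors
planted_signal_check(bundle, res$pairs)
#> [1] 0.9946224

# cold start: drug-blind split, test drugs absent from train and val
res_es1 <- run_pipeline(bundle, scheme = "es1",
                        spec = small_model_spec(), seed = 11)
res_es1$metrics
#> <metrics_report> n=209  RMSE 1.1573  MAE 0.8125  r 0.6814
```

Reading: on the random split the model explains most of the planted signal
(r 0.93 against an oracle ceiling of 0.99; RMSE in units of the unit-sd
signal). Under the drug-blind split the response-profile view is empty for
test drugs, so prediction must flow through the structural and association
similarity views — r 0.68 shows the cold-start pathway carries real
signal, at the expected cost in RMSE.

Real data enter through the same bundle layout (`read_bundle()`): edge
lists as CSV (`drug_id, partner_id[, score]`), omics and fingerprint
matrices as CSV with ID column/header, pairs as `drug_id, cell_id, ic50`.
Precomputed fingerprints are validated against the canonical widths
(ECFP 1024, PSFP 881, DFP 2048, RDKFP 200, ESPFP 2586, ERGFP 315).

See `vignettes/multisource-drug-response.Rmd` for the full account of the
model, its assumptions and limitations.

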