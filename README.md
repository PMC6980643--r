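# oilalarm

Food-safety surveillance from business-to-business e-invoices. The
package is aimed at regulators and food-safety data scientists who have
access to transaction-level invoice streams of food manufacturers and
want an automated early-warning screen for fraud — specifically the
edible-oil scenario in which a manufacturer sells far more oil product
than the raw material it verifiably bought, because a large part of its
inputs were never invoiced as proper ingredients.

The screen runs in two stages:

1. **Text sieve.** Manufacturers sell many things besides oil, so the
   invoice stream is first reduced to edible-oil-related lines by
   classifying item names. Names are tokenized, weighted by TF–IDF and
   reduced to *m* latent-semantic topics via truncated SVD (or encoded
   by expert keyword indicators); a classifier backend — k-nearest
   neighbours, linear SVM, logistic regression, feed-forward net or
   random forest — is trained on a labeled item table with a stratified
   80/20 split and 5-fold cross-validated hyperparameters.

2. **Turnover anomaly detection.** The sieved stream is summed into
   monthly purchase (`Pur_i`, manufacturer as buyer, its *downstream*
   side `D`) and sales (`Sale_i`, manufacturer as seller, *upstream*
   `U`) totals, smoothed by a trailing 3-month moving average

   ```
   D_i = (Pur_{i-2} + Pur_{i-1} + Pur_i) / 3
   U_i = (Sale_{i-2} + Sale_{i-1} + Sale_i) / 3
   ```

   and turned into the two log turnover-ratio features

   ```
   X1 = log(U_i / D_i)        X2 = log(U_i / D_{i-1})
   ```

   (natural logs; `X2` captures the lag between buying material and
   selling product). A month record is flagged by the naive decision
   rule **suspicious iff X1 > 6 and X2 > 6** — i.e. sales exceeding
   recorded purchases more than e⁶ ≈ 403-fold over a two-month span —
   or by the same classifier backends trained on benchmark (A) versus
   problematic (B) month records. Bivariate-normal prediction ellipses
   at the 95%/99% levels describe the benchmark cloud. Unlabeled (C)
   manufacturers are screened and flagged for inspection when at least
   `k` of their months are suspicious.

Because real national e-invoice corpora are access-restricted, the
package ships a deterministic synthetic-data generator
(`generator_config()`, `generate_item_catalog()`,
`generate_invoices()`) that emulates the statistical structure those
data are reported to have: item names mixing edible-oil terms,
oil-keyword confounders (motor oil, massage oil, …) and unrelated
goods; benchmark months with `log(sales/purchases) ~ N(0, sigma_log)`;
and problematic episodes in which recorded purchases are suppressed by
`exp(-b_shift)`.

## Worked example

```r
library(oilalarm)

cfg     <- generator_config(seed = 42)        # 21 A + 6 B, 46 months
catalog <- generate_item_catalog(cfg)
corpus  <- generate_invoices(cfg, catalog)    # 18,865 invoices

sieve <- train_sieve(catalog$item_name, catalog$label,
                     method = "random-forest", split_seed = 42)
sieve$report
#> Evaluation report (random-forest)
#>   sensitivity: 100.00%  (12/12)
#>   specificity: 93.75%  (15/16)
#>   error rate:  3.57%  (1/28)

related  <- sieve_invoices(corpus$invoices, sieve$classifier)$related  # 15,103 lines
features <- turnover_features(related, corpus$manufacturers$manufacturer_id,
                              months = corpus$months)
labels   <- suspicious_record_labels(features, corpus$ground_truth)

rule_lab <- naive_rule_classify(features$X1, features$X2)
evaluate_predictions(labels, ifelse(rule_lab == "suspicious", "B", "A"),
                     positive = "B", method = "naive rule")
#> Evaluation report (naive rule)
#>   sensitivity: 89.39%  (118/132)
#>   specificity: 100.00%  (1056/1056)
#>   error rate:  1.18%  (14/1188)

screen_unlabeled(features, decision_rule())
#> Alarm screening report — naive rule (t1 = 6, t2 = 6)
#>   1188 month records, 9.93% flagged suspicious
#>   6 of 27 manufacturers flagged (>= 1 suspicious month)
#>   flagged: B01, B02, B03, B04, B05, B06
```

Reading the numbers: the sieve recovers all edible-oil item names and
misreads one held-out confounder name, so a little non-oil volume leaks
into the monthly totals; the threshold rule still finds 118 of the 132
genuinely suspicious month records while raising no false alarm on the
1,056 benchmark records, and every planted problematic manufacturer is
flagged. A flag means "inspect this manufacturer", not a finding of
wrongdoing.

`plot_alarm_features(features, labels)` draws the (X1, X2) scatter with
the benchmark prediction ellipses and the rule thresholds.

## Vignette

`vignettes/oil-invoice-alarm.Rmd` documents the model and its
assumptions, what the synthetic generator does and does not emulate,
the numerical choices (smoothing warm-up, zero-denominator clamping,
SVD sign convention), and known limitations.
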