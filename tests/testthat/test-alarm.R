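test_that("naive rule requires both strict exceedances", {
  r <- decision_rule()
  expect_equal(as.character(naive_rule_classify(6.1, 6.1, r)), "suspicious")
  expect_equal(as.character(naive_rule_classify(6.1, 5.9, r)), "benchmark")
  expect_equal(as.character(naive_rule_classify(6.0, 6.0, r)), "benchmark")
  # missing lag feature: benchmark by convention, marked partial
  out <- naive_rule_classify(c(8, 8), c(NA, 8), r)
  expect_equal(as.character(out), c("benchmark", "suspicious"))
  expect_equal(attr(out, "partial"), c(TRUE, FALSE))
  expect_error(decision_rule(t1 = Inf), "is.finite")
})

test_that("raising thresholds never increases suspicious labels", {
  set.seed(41)
  x1 <- stats::rnorm(500, 3, 4)
  x2 <- stats::rnorm(500, 3, 4)
  counts <- vapply(c(2, 4, 6, 8), function(t) {
    sum(naive_rule_classify(x1, x2, decision_rule(t, t)) == "suspicious")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("prediction ellipse matches its bivariate-normal definition", {
  set.seed(52)
  x <- cbind(stats::rnorm(500), stats::rnorm(500))
  e95 <- fit_ellipse(x, level = 0.95)
  expect_equal(e95$center, colMeans(x), ignore_attr = TRUE)
  # chi-square(2) quantile has the closed form -2 log(1 - p)
  expect_equal(e95$radius2, -2 * log(0.05), tolerance = 1e-4)
  expect_equal(fit_ellipse(x, 0.99)$radius2, -2 * log(0.01),
               tolerance = 1e-4)
  # boundary points lie on the boundary radius
  b <- ellipse_boundary(e95, n = 50)
  d <- stats::mahalanobis(b, e95$center, e95$shape)
  expect_equal(d, rep(e95$radius2, 50), tolerance = 1e-8)
  # degenerate input
  degen <- cbind(1:10, 2 * (1:10))
  expect_error(fit_ellipse(degen, 0.95), "singular")
  expect_error(fit_ellipse(x[1:2, ], 0.95), "at least 3")
})

test_that("ellipse coverage attains its nominal level", {
  set.seed(53)
  x <- cbind(stats::rnorm(800, 1, 2), stats::rnorm(800, -1, 0.5))
  for (lv in c(0.95, 0.99)) {
    e <- fit_ellipse(x, level = lv)
    fresh <- sample_ellipse(e, 10000, seed = 54)
    expect_lt(abs(mean(in_ellipse(e, fresh)) - lv), 0.01)
  }
})

test_that("all backends separate well-separated turnover regimes", {
  fx <- study_fixture()
  for (m in c("knn", "linear-svm", "logistic", "feedforward-net",
              "random-forest")) {
    fit <- train_alarm_classifier(fx$features, fx$labels, method = m,
                                  seed = 17)
    expect_gte(fit$report$sensitivity, 0.9)
    expect_gte(fit$report$specificity, 0.95)
  }
  expect_error(train_alarm_classifier(fx$features,
                                      rep("A", nrow(fx$features)),
                                      method = "knn"),
               "both A and B")
})

test_that("alarm classifier training is reproducible", {
  fx <- study_fixture()
  a <- train_alarm_classifier(fx$features, fx$labels,
                              method = "random-forest", seed = 23)
  b <- train_alarm_classifier(fx$features, fx$labels,
                              method = "random-forest", seed = 23)
  expect_equal(a$report, b$report)
})

test_that("permuted labels drop sensitivity to the flagged-fraction baseline", {
  fx <- study_fixture()
  rule_lab <- naive_rule_classify(fx$features$X1, fx$features$X2)
  flagged_frac <- mean(rule_lab == "suspicious")
  set.seed(71)
  perm <- sample(as.character(fx$labels))
  sens_perm <- mean(rule_lab[perm == "B"] == "suspicious")
  expect_lt(abs(sens_perm - flagged_frac), 0.1)
})

test_that("screening aggregates months to manufacturers with threshold k", {
  fx <- study_fixture()

  # C manufacturers generated from the benchmark regime: nothing flags
  cfg_a <- generator_config(seed = 61, n_A = 0, n_B = 0, n_C = 10,
                            c_suspicious_prob = 0, n_oil_items = 20,
                            n_confounder_items = 5, n_unrelated_items = 5)
  cat_a <- generate_item_catalog(cfg_a)
  corp_a <- generate_invoices(cfg_a, cat_a)
  rel_a <- corp_a$invoices[corp_a$invoices$item_name %in%
                             cat_a$item_name[cat_a$label == 1], ]
  f_a <- turnover_features(rel_a, corp_a$manufacturers$manufacturer_id,
                           months = corp_a$months)
  rep_a <- screen_unlabeled(f_a, decision_rule())
  expect_lte(rep_a$month_flag_fraction, 0.01)
  expect_length(rep_a$flagged_ids, 0)

  # C manufacturers from the problematic regime: almost all months flag
  cfg_b <- generator_config(seed = 62, n_A = 0, n_B = 0, n_C = 5,
                            c_suspicious_prob = 1, p_suspicious = 1,
                            n_oil_items = 20, n_confounder_items = 5,
                            n_unrelated_items = 5)
  cat_b <- generate_item_catalog(cfg_b)
  corp_b <- generate_invoices(cfg_b, cat_b)
  rel_b <- corp_b$invoices[corp_b$invoices$item_name %in%
                             cat_b$item_name[cat_b$label == 1], ]
  f_b <- turnover_features(rel_b, corp_b$manufacturers$manufacturer_id,
                           months = corp_b$months)
  rep_b <- screen_unlabeled(f_b, decision_rule())
  expect_gte(rep_b$month_flag_fraction, 0.9)
  expect_equal(sort(rep_b$flagged_ids),
               sort(corp_b$manufacturers$manufacturer_id))

  # threshold semantics: one suspicious month, k = 2 -> not flagged
  one <- data.frame(manufacturer_id = "C001",
                    month = c("2014-03", "2014-04"), month_index = 3:4,
                    D = c(1, 1), U = c(1, exp(8)),
                    X1 = c(0, 8), X2 = c(NA, 8),
                    clamped = FALSE, valid = TRUE,
                    stringsAsFactors = FALSE)
  expect_length(screen_unlabeled(one, decision_rule(), k = 2)$flagged_ids, 0)
  expect_equal(screen_unlabeled(one, decision_rule(), k = 1)$flagged_ids,
               "C001")

  # empty input gives an empty report
  expect_length(screen_unlabeled(f_a[0, ], decision_rule())$flagged_ids, 0)

  # a trained classifier can drive the same screening
  cls <- train_alarm_classifier(fx$features, fx$labels,
                                method = "logistic", seed = 5)$classifier
  rep_cls <- screen_unlabeled(f_b, cls)
  expect_gte(rep_cls$month_flag_fraction, 0.8)
})

test_that("a perfect sieve makes the pipeline equal ground-truth staging", {
  fx <- study_fixture()
  fit <- train_sieve(fx$catalog$item_name, fx$catalog$label,
                     method = "random-forest", split_seed = 29)
  sieved <- sieve_invoices(fx$corpus$invoices, fit$classifier)$related
  f_sieved <- turnover_features(sieved,
                                fx$corpus$manufacturers$manufacturer_id,
                                months = fx$corpus$months)
  expect_equal(f_sieved, fx$features)
})
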