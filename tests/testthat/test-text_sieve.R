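test_that("keyword filter is a case-folded substring sieve and a projection", {
  items <- c("olive oil", "motor oil", "rice vinegar")
  expect_equal(keyword_filter(items, "oil"), c("olive oil", "motor oil"))
  expect_equal(keyword_filter("Olive OIL", "oil"), "Olive OIL")
  expect_equal(keyword_filter(character(0), "oil"), character(0))
  expect_error(keyword_filter(items, "  "), "non-empty")
  once <- keyword_filter(items, "oil")
  expect_identical(keyword_filter(once, "oil"), once)
  # duplicates and order preserved
  expect_equal(keyword_filter(c("a oil", "b", "a oil"), "oil"),
               c("a oil", "a oil"))
})

test_that("tokenization case-folds, strips punctuation and digit tokens", {
  expect_equal(normalize_and_tokenize("Refined Soybean Oil 18L")[[1]],
               c("refined", "soybean", "oil"))
  expect_equal(normalize_and_tokenize("")[[1]], character(0))
  # idempotence: tokenizing the joined tokens reproduces them
  nm <- separable_catalog()$item_name[1:50]
  toks <- normalize_and_tokenize(nm)
  rejoined <- vapply(toks, paste, "", collapse = " ")
  expect_identical(normalize_and_tokenize(rejoined), toks)
})

test_that("term filtering honours document frequency and stoplist", {
  toks <- normalize_and_tokenize(c("olive oil", "palm oil", "rare word"))
  expect_false("rare" %in% filter_terms(toks, min_doc_freq = 2))
  expect_true("oil" %in% filter_terms(toks, min_doc_freq = 2))
  expect_false("oil" %in% filter_terms(toks, stoplist = "oil"))
  expect_setequal(filter_terms(toks), c("olive", "oil", "palm", "rare", "word"))
})

test_that("topic model has the contracted dimension and is deterministic", {
  nm <- separable_catalog()$item_name[1:200]
  tm <- build_topics(nm, m = 25, seed = 3)
  X <- featurize(tm, nm[1:10])
  expect_equal(dim(X), c(10, 25))
  tm2 <- build_topics(nm, m = 25, seed = 3)
  expect_identical(tm$basis, tm2$basis)
  # m beyond the matrix rank is refused with advice
  tiny <- c("olive oil", "palm oil", "olive palm", "oil olive", "palm palm")
  expect_error(build_topics(tiny, m = 4), "rank")
  expect_error(build_topics(nm[1:5], m = 10), "smaller m")
})

test_that("topic features separate disjoint-vocabulary strata", {
  cat <- separable_catalog()
  set.seed(15)
  idx <- sample(nrow(cat), 400)
  fit <- train_sieve(cat$item_name[idx], cat$label[idx],
                     method = "logistic",
                     featurizer = build_topics(cat$item_name[idx], m = 10),
                     split_seed = 5)
  expect_lt(fit$report$error_rate, 0.05)
})

test_that("keyword featurization counts occurrences as binary indicators", {
  kf <- keyword_featurizer(c("olive", "oil", "soybean"))
  X <- featurize(kf, c("olive oil 5l", "rice vinegar", "olive oil soybean"))
  expect_equal(rowSums(X), c(2, 0, 3))
  expect_equal(dim(X), c(3, 3))
  expect_true(all(X %in% c(0, 1)))
})

test_that("feature selection keeps the strongest associations deterministically", {
  cat <- separable_catalog()
  # 60 keywords drawn from both vocabularies plus junk
  kws <- setdiff(unique(unlist(normalize_and_tokenize(cat$item_name))),
                 "oil")[1:58]
  kf <- keyword_featurizer(c(kws, "zzznever", "oil"))
  expect_length(kf$keywords, 60)
  sel <- select_features(kf, cat$item_name, cat$label, 31)
  expect_length(sel$indices, 31)
  expect_length(sel$featurizer$keywords, 31)
  # identity when target equals the feature count
  all_sel <- select_features(kf, cat$item_name, cat$label, 60)
  expect_identical(all_sel$featurizer$keywords, kf$keywords)
  # a never-occurring (constant) feature scores 0 and is dropped first
  expect_equal(sel$scores[which(kf$keywords == "zzznever")], 0,
               ignore_attr = TRUE)
  expect_false("zzznever" %in% sel$featurizer$keywords)
})

test_that("a feature identical to the label ranks first", {
  items <- c(paste("good stuff", 1:20),
             paste("bad stuff", 1:10), paste("ugly stuff", 1:10))
  labels <- rep(c(1L, 0L), each = 20)
  kf <- keyword_featurizer(c("bad", "good", "stuff"))
  sel <- select_features(kf, items, labels, 1)
  # "good" occurs exactly in the label-1 items: maximal association;
  # "bad" covers only half the negatives; "stuff" is constant (score 0)
  expect_equal(sel$featurizer$keywords, "good")
  expect_equal(unname(which.max(sel$scores)), 2L)
  expect_equal(unname(sel$scores["stuff"]), 0)
})

test_that("sieve training is reproducible and validates its input", {
  cat <- separable_catalog()
  idx <- c(1:150, 501:650)  # both strata
  a <- train_sieve(cat$item_name[idx], cat$label[idx], method = "knn",
                   split_seed = 11)
  b <- train_sieve(cat$item_name[idx], cat$label[idx], method = "knn",
                   split_seed = 11)
  expect_equal(a$report, b$report)
  expect_equal(a$report$n_train + a$report$n_test, 300)
  expect_error(train_sieve(cat$item_name[1:20], rep(1L, 20),
                           method = "knn"), "both labels")
  expect_error(train_sieve(cat$item_name[1:5], c(1, 0, 1, 0, 1),
                           method = "knn"), "at least 10")
})

test_that("shuffled labels give chance-level error", {
  cat <- separable_catalog()
  set.seed(77)
  idx <- sample(nrow(cat), 400)
  shuffled <- sample(cat$label[idx])
  fit <- train_sieve(cat$item_name[idx], shuffled, method = "logistic",
                     split_seed = 13)
  # minority-class-aware baseline: error ~ min(p, 1-p) of the test split
  p <- mean(shuffled)
  baseline <- min(p, 1 - p)
  expect_lt(abs(fit$report$error_rate - baseline), 0.15)
})

test_that("held-out sensitivity does not degrade as topics increase", {
  cat <- separable_catalog()
  set.seed(19)
  idx <- sample(nrow(cat), 400)
  sens <- vapply(c(10, 30, 60), function(m) {
    train_sieve(cat$item_name[idx], cat$label[idx], method = "logistic",
                featurizer = build_topics(cat$item_name[idx], m = m),
                split_seed = 3)$report$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= -0.05))
})

test_that("sieving partitions the invoice stream conservatively", {
  fx <- study_fixture()
  fit <- train_sieve(fx$catalog$item_name, fx$catalog$label,
                     method = "random-forest", split_seed = 2)
  parts <- sieve_invoices(fx$corpus$invoices, fit$classifier)
  expect_equal(nrow(parts$related) + nrow(parts$unrelated),
               nrow(fx$corpus$invoices))
  empty <- sieve_invoices(fx$corpus$invoices[0, ], fit$classifier)
  expect_equal(nrow(empty$related), 0)
  expect_equal(nrow(empty$unrelated), 0)
  # featurization is pure: same names, same predictions
  nm <- fx$catalog$item_name[1:20]
  expect_identical(predict(fit$classifier, nm), predict(fit$classifier, nm))
})
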