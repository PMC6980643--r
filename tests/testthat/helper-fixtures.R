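# Shared fixtures, built in code and cached for the duration of a test
# run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Corpus at the study conditions the pipeline is designed for:
# 21 benchmark + 6 problematic manufacturers over 46 months,
# sigma_log = 0.5, b_shift = 8, p_suspicious = 0.5.
study_fixture <- function() cached("study", {
  cfg <- generator_config(seed = 101)
  catalog <- generate_item_catalog(cfg)
  corpus <- generate_invoices(cfg, catalog)
  oil_names <- catalog$item_name[catalog$label == 1L]
  related <- corpus$invoices[corpus$invoices$item_name %in% oil_names, ]
  features <- turnover_features(related,
                                corpus$manufacturers$manufacturer_id,
                                months = corpus$months)
  labels <- suspicious_record_labels(features, corpus$ground_truth)
  list(cfg = cfg, catalog = catalog, corpus = corpus, related = related,
       features = features, labels = labels)
})

# Separable 1,000-item catalog (disjoint stratum vocabularies apart
# from the shared keyword itself).
separable_catalog <- function() cached("sep_catalog", {
  cfg <- generator_config(seed = 7, n_oil_items = 500,
                          n_confounder_items = 250,
                          n_unrelated_items = 250)
  generate_item_catalog(cfg)
})

small_config <- function(seed = 3, ...) {
  generator_config(seed = seed, n_A = 2, n_B = 1, n_C = 0, n_months = 12,
                   n_oil_items = 20, n_confounder_items = 10,
                   n_unrelated_items = 10, invoices_per_month = 3, ...)
}

# A random raw invoice table for oracle checks, independent of the
# package's generator.
random_invoice_table <- function(n, months, mfr = "M1") {
  others <- sprintf("X%02d", 1:5)
  side <- sample(c(TRUE, FALSE), n, replace = TRUE)
  data.frame(
    invoice_id = sprintf("r%04d", seq_len(n)),
    date = paste0(sample(months, n, replace = TRUE), "-",
                  sprintf("%02d", sample(28, n, replace = TRUE))),
    vendor_id = ifelse(side, mfr, sample(others, n, replace = TRUE)),
    vendee_id = ifelse(side, sample(others, n, replace = TRUE), mfr),
    item_name = "bulk cooking oil",
    amount = round(stats::runif(n, 1, 1000), 2),
    quantity = NA_real_,
    stringsAsFactors = FALSE)
}
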