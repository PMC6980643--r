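# Synthetic invoice corpora and manufacturer transaction streams with
# the statistical structure the two-stage analysis assumes. The real
# national e-invoice corpus is access-restricted; this module emulates
# its relevant features: item names mixing edible-oil terms, oil-keyword
# confounders and unrelated goods, and per-manufacturer monthly
# purchase/sales totals where benchmark months balance on the log scale
# and problematic months have sales vastly exceeding recorded purchases.

# Item-name template vocabularies. The three strata share only the
# token "oil" (between the edible and confounder strata); all other
# words are disjoint so a text classifier can in principle separate
# them perfectly.
.oil_adjs <- c("refined", "crude", "virgin", "cold pressed", "organic",
               "premium", "blended", "filtered", "pure", "light",
               "toasted", "unrefined", "fortified", "bulk", "culinary",
               "frying", "salad", "roasted", "deodorized", "winterized")
.oil_bases <- c("soybean oil", "olive oil", "canola oil", "sunflower oil",
                "peanut oil", "sesame oil", "palm oil", "coconut oil",
                "corn oil", "rice bran oil", "grapeseed oil",
                "camellia oil", "avocado oil", "safflower oil",
                "flaxseed oil", "walnut oil", "lard oil", "tallow oil",
                "cooking oil", "vegetable oil")
.conf_adjs <- c("industrial", "synthetic", "automotive", "marine",
                "hydraulic", "scented", "herbal", "mechanical",
                "antirust", "viscous", "multigrade", "detergent",
                "insulating", "cosmetic", "medicinal", "fragrant",
                "mineral", "polishing", "aromatic", "lubricant")
.conf_bases <- c("motor oil", "engine oil", "gear oil", "machine oil",
                 "lamp oil", "fuel oil", "cutting oil", "brake oil",
                 "massage oil", "baby oil", "hair oil", "bath oil",
                 "essential oil", "lubricating oil", "transmission oil",
                 "compressor oil", "chainsaw oil", "spindle oil",
                 "quench oil", "turbine oil")
.unrel_adjs <- c("classic", "golden", "village", "island", "mountain",
                 "harvest", "garden", "royal", "sunrise", "valley",
                 "homestyle", "festival", "daily", "family", "spring",
                 "ocean", "jade", "lucky", "double", "grand")
.unrel_bases <- c("malt vinegar", "soy sauce", "wheat flour", "cane sugar",
                  "sea salt", "black tea", "green tea", "instant noodles",
                  "dried mushroom", "canned tuna", "tomato paste",
                  "fish sauce", "potato starch", "milk powder", "bean curd",
                  "ginger wine", "plum juice", "barley malt", "chili paste",
                  "shrimp crackers")
# Pack-size suffixes contain digits, which the tokenizer drops, so they
# extend the unique-name space without touching the feature vocabulary.
.pack_sizes <- c("", "18l", "5l", "3l", "1l", "250ml", "500ml", "750ml",
                 "600ml", "20l")

#' Configuration for the synthetic corpus generator
#'
#' Defaults reflect the study conditions the pipeline is designed for:
#' 21 benchmark (A) and 6 problematic (B) manufacturers observed over 46
#' calendar months starting January 2014. `sigma_log` is the standard
#' deviation of the benchmark log sales-to-purchase ratio; `b_shift` is
#' the mean added to that log-ratio in a problematic manufacturer's
#' suspicious months (achieved by suppressing recorded purchases, i.e.
#' materials bought off the books), chosen well above the naive-rule
#' threshold of 6 so that a fully suspicious smoothing window is
#' detectable.
#'
#' @param seed integer master seed; identical configs and seeds give
#'   byte-identical corpora.
#' @param n_A,n_B,n_C manufacturer counts per class (benchmark /
#'   problematic / unspecified).
#' @param n_months number of consecutive calendar months (>= 3; the
#'   3-month smoothing window is unsatisfiable below that).
#' @param n_oil_items,n_confounder_items,n_unrelated_items catalog
#'   stratum sizes: edible-oil items (label 1), non-edible items whose
#'   names still contain the keyword "oil" (label 0), and items without
#'   the keyword (label 0).
#' @param sigma_log std. dev. of benchmark monthly log turnover noise.
#' @param b_shift mean log-ratio shift in suspicious months (default 8).
#' @param p_suspicious expected fraction of a B manufacturer's months
#'   that are suspicious; the suspicious months form one contiguous
#'   episode at the end of the series (a fraud regime persisting until
#'   records cease) with binomially drawn length.
#' @param c_suspicious_prob probability that an unspecified C
#'   manufacturer behaves like a problematic one rather than a
#'   benchmark one.
#' @param invoices_per_month mean number of invoice lines each monthly
#'   purchase or sales total is split into.
#' @param amount_scale currency scale of monthly totals (unitless).
#' @param start_month first calendar month, `"YYYY-MM"`.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_A = 21L, n_B = 6L, n_C = 0L,
                             n_months = 46L,
                             n_oil_items = 60L, n_confounder_items = 40L,
                             n_unrelated_items = 40L,
                             sigma_log = 0.5, b_shift = 8,
                             p_suspicious = 0.5, c_suspicious_prob = 0.05,
                             invoices_per_month = 6, amount_scale = 1e6,
                             start_month = "2014-01") {
  cfg <- list(seed = as.integer(seed), n_A = n_A, n_B = n_B, n_C = n_C,
              n_months = n_months, n_oil_items = n_oil_items,
              n_confounder_items = n_confounder_items,
              n_unrelated_items = n_unrelated_items,
              sigma_log = sigma_log, b_shift = b_shift,
              p_suspicious = p_suspicious,
              c_suspicious_prob = c_suspicious_prob,
              invoices_per_month = invoices_per_month,
              amount_scale = amount_scale, start_month = start_month)
  for (f in c("n_A", "n_B", "n_C", "n_months", "n_oil_items",
              "n_confounder_items", "n_unrelated_items",
              "invoices_per_month")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("invalid generator config: '", f, "' must be a count >= 0")
  }
  if (!is.numeric(cfg$sigma_log) || cfg$sigma_log <= 0)
    stop("invalid generator config: 'sigma_log' must be > 0")
  for (f in c("p_suspicious", "c_suspicious_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid generator config: '", f, "' must lie in [0, 1]")
  }
  if (cfg$amount_scale <= 0)
    stop("invalid generator config: 'amount_scale' must be > 0")
  if (!grepl("^[0-9]{4}-[0-9]{2}$", cfg$start_month))
    stop("invalid generator config: 'start_month' must be \"YYYY-MM\"")
  structure(cfg, class = "generator_config")
}

# Deterministic sub-stream seed per manufacturer id: stable polynomial
# string hash folded with the master seed, kept below 2^31.
.string_seed <- function(id, base_seed) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 131 + ch) %% 2147480009
  as.integer((h + (base_seed %% 2147480009) * 7919) %% 2147480009)
}

.month_seq <- function(start_month, n_months) {
  format(seq(as.Date(paste0(start_month, "-01")), by = "month",
             length.out = n_months), "%Y-%m")
}

.sample_names <- function(adjs, bases, n, what) {
  grid <- expand.grid(adj = adjs, base = bases, pack = .pack_sizes,
                      stringsAsFactors = FALSE)
  if (n > nrow(grid))
    stop("invalid generator config: '", what, "' exceeds the template ",
         "space of ", nrow(grid), " unique names")
  rows <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  trimws(paste(rows$adj, rows$base, rows$pack))
}

#' Generate a labeled item-name catalog
#'
#' Produces unique item names in three strata: edible-oil-related names
#' (label 1), confounder names that contain the keyword "oil" but are
#' not edible (label 0; motor oil, massage oil, ... — the analogue of
#' soy sauce and cosmetics sharing the oil character in the original
#' corpus), and unrelated goods without the keyword (label 0).
#'
#' @param config a [generator_config()].
#' @return data frame with columns `item_name`, `label` (integer 0/1)
#'   and `stratum` (`"edible_oil"`, `"oil_confounder"`, `"unrelated"`).
#' @export
generate_item_catalog <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  for (f in c("n_oil_items", "n_confounder_items", "n_unrelated_items"))
    if (config[[f]] < 1)
      stop("invalid generator config: '", f, "' must be > 0")
  set.seed(config$seed %% 2147480009L + 104729L)
  oil <- .sample_names(.oil_adjs, .oil_bases, config$n_oil_items,
                       "n_oil_items")
  conf <- .sample_names(.conf_adjs, .conf_bases, config$n_confounder_items,
                        "n_confounder_items")
  unrel <- .sample_names(.unrel_adjs, .unrel_bases, config$n_unrelated_items,
                         "n_unrelated_items")
  data.frame(
    item_name = c(oil, conf, unrel),
    label = c(rep(1L, length(oil)), rep(0L, length(conf) + length(unrel))),
    stratum = rep(c("edible_oil", "oil_confounder", "unrelated"),
                  c(length(oil), length(conf), length(unrel))),
    stringsAsFactors = FALSE)
}

# One manufacturer's invoices + ground truth for all months.
.gen_manufacturer <- function(id, class_label, config, months,
                              oil_items, other_items, suppliers, buyers) {
  set.seed(.string_seed(id, config$seed))
  n_m <- length(months)

  # suspicious regime: contiguous episode at the end of the series
  suspicious <- rep(FALSE, n_m)
  regime_b <- switch(class_label,
                     A = FALSE,
                     B = TRUE,
                     C = stats::runif(1) < config$c_suspicious_prob)
  if (regime_b) {
    len <- stats::rbinom(1, n_m, config$p_suspicious)
    if (len > 0) suspicious[(n_m - len + 1):n_m] <- TRUE
  }

  mfr_scale <- exp(stats::rnorm(1, 0, 0.5))
  base_pur <- config$amount_scale * mfr_scale *
    exp(stats::rnorm(n_m, 0, 0.3))
  sale_tot <- base_pur * exp(stats::rnorm(n_m, 0, config$sigma_log))
  pur_tot <- ifelse(suspicious, base_pur * exp(-config$b_shift), base_pur)

  rows <- vector("list", n_m)
  for (i in seq_len(n_m)) {
    split_amount <- function(total) {
      k <- 1L + stats::rpois(1, max(config$invoices_per_month - 1, 0))
      w <- stats::rexp(k)
      pmax(round(total * w / sum(w), 2), 0.01)
    }
    pur_amt <- split_amount(pur_tot[i])
    sale_amt <- split_amount(sale_tot[i])
    n_dis <- stats::rpois(1, max(config$invoices_per_month / 2, 0.5))
    dis_amt <- if (n_dis > 0 && length(other_items) > 0)
      pmax(round(config$amount_scale * mfr_scale *
                   exp(stats::rnorm(n_dis, 0, 1)) /
                   max(config$invoices_per_month, 1), 2), 0.01)
    else numeric(0)
    n_dis <- length(dis_amt)

    n_tot <- length(pur_amt) + length(sale_amt) + n_dis
    dis_side <- if (n_dis > 0) stats::runif(n_dis) < 0.5 else logical(0)
    vendor <- c(sample(suppliers, length(pur_amt), replace = TRUE),
                rep(id, length(sale_amt)),
                ifelse(dis_side, sample(suppliers, n_dis, replace = TRUE), id))
    vendee <- c(rep(id, length(pur_amt)),
                sample(buyers, length(sale_amt), replace = TRUE),
                ifelse(dis_side, id, sample(buyers, n_dis, replace = TRUE)))
    item <- c(sample(oil_items, length(pur_amt) + length(sale_amt),
                     replace = TRUE),
              if (n_dis > 0) sample(other_items, n_dis, replace = TRUE))
    day <- sprintf("%02d", sample(28L, n_tot, replace = TRUE))
    qty <- ifelse(stats::runif(n_tot) < 0.3,
                  sample(500L, n_tot, replace = TRUE), NA_real_)
    rows[[i]] <- data.frame(
      invoice_id = sprintf("%s-%s-%03d", id, gsub("-", "", months[i]),
                           seq_len(n_tot)),
      date = paste0(months[i], "-", day),
      vendor_id = vendor, vendee_id = vendee, item_name = item,
      amount = c(pur_amt, sale_amt, dis_amt), quantity = qty,
      stringsAsFactors = FALSE)
  }

  list(invoices = do.call(rbind, rows),
       ground_truth = data.frame(manufacturer_id = id,
                                 class_label = class_label,
                                 month = months,
                                 month_index = seq_len(n_m),
                                 suspicious = suspicious,
                                 stringsAsFactors = FALSE))
}

#' Generate a synthetic invoice corpus
#'
#' For every manufacturer and month, emits purchase invoices
#' (manufacturer is vendee) and sales invoices (manufacturer is vendor)
#' over edible-oil items, plus distractor invoices over non-edible
#' items so the text sieve is load-bearing. Benchmark (A) months have
#' `log(total sales / total purchases) ~ Normal(0, sigma_log)`;
#' suspicious months of problematic (B) manufacturers add `b_shift` to
#' that log-ratio by suppressing purchase totals (the recorded-purchase
#' deficit of illegitimate sourcing), leaving sales magnitudes
#' comparable across classes. C manufacturers follow the benchmark
#' regime or, with probability `c_suspicious_prob`, the problematic one.
#'
#' @param config a [generator_config()].
#' @param catalog item catalog from [generate_item_catalog()].
#' @return list with `invoices` (data frame, see [invoice_columns]),
#'   `manufacturers` (`manufacturer_id`, `class_label`), `ground_truth`
#'   (per manufacturer-month `suspicious` flags) and `months`.
#' @export
generate_invoices <- function(config, catalog) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(catalog) || nrow(catalog) == 0)
    stop("catalog must be non-empty")
  if (config$n_months < 3)
    stop("n_months must be at least 3: the 3-month smoothing window ",
         "is unsatisfiable")
  oil_items <- catalog$item_name[catalog$label == 1L]
  other_items <- catalog$item_name[catalog$label == 0L]
  if (length(oil_items) == 0)
    stop("catalog must contain at least one edible-oil item (label 1)")

  months <- .month_seq(config$start_month, config$n_months)
  ids <- c(sprintf("A%02d", seq_len(config$n_A)),
           sprintf("B%02d", seq_len(config$n_B)),
           sprintf("C%03d", seq_len(config$n_C)))
  classes <- rep(c("A", "B", "C"), c(config$n_A, config$n_B, config$n_C))
  if (length(ids) == 0) stop("no manufacturers requested")
  suppliers <- sprintf("SUP%03d", 1:20)
  buyers <- sprintf("DST%03d", 1:20)

  parts <- mapply(.gen_manufacturer, ids, classes,
                  MoreArgs = list(config = config, months = months,
                                  oil_items = oil_items,
                                  other_items = other_items,
                                  suppliers = suppliers, buyers = buyers),
                  SIMPLIFY = FALSE)
  invoices <- do.call(rbind, lapply(parts, `[[`, "invoices"))
  ground_truth <- do.call(rbind, lapply(parts, `[[`, "ground_truth"))
  rownames(invoices) <- rownames(ground_truth) <- NULL
  list(invoices = invoices,
       manufacturers = data.frame(manufacturer_id = ids,
                                  class_label = classes,
                                  stringsAsFactors = FALSE),
       ground_truth = ground_truth,
       months = months)
}

#' Raw monthly log turnover ratios from a corpus
#'
#' Convenience for checking the generator: per manufacturer-month,
#' `log(sales total / purchase total)` over edible-oil-related invoices
#' only (ground-truth item labels), before any smoothing.
#'
#' @param corpus result of [generate_invoices()].
#' @param catalog the catalog the corpus was generated from.
#' @return data frame `manufacturer_id`, `month`, `log_ratio`.
#' @export
raw_log_ratios <- function(corpus, catalog) {
  inv <- corpus$invoices
  inv <- inv[inv$item_name %in% catalog$item_name[catalog$label == 1L], ]
  mon <- substr(inv$date, 1, 7)
  out <- lapply(corpus$manufacturers$manufacturer_id, function(id) {
    pur <- tapply(inv$amount[inv$vendee_id == id],
                  mon[inv$vendee_id == id], sum)
    sale <- tapply(inv$amount[inv$vendor_id == id],
                   mon[inv$vendor_id == id], sum)
    m <- corpus$months
    data.frame(manufacturer_id = id, month = m,
               log_ratio = log(ifelse(m %in% names(sale), sale[m], NA) /
                               ifelse(m %in% names(pur), pur[m], NA)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
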