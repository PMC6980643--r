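# Stage 2 preprocessing: monthly aggregation of sieved invoices per
# manufacturer, 3-month moving-average smoothing, and the two log
# turnover-ratio features.
#
# Terminology follows the supply-chain convention: a manufacturer's
# purchases from other parties are its downstream (D) side, its sales
# the upstream (U) side. The smoothed series are
#   D_i = (Pur_{i-2} + Pur_{i-1} + Pur_i) / 3
#   U_i = (Sale_{i-2} + Sale_{i-1} + Sale_i) / 3
# and the features
#   X1 = log(U_i / D_i)        same-month log turnover ratio
#   X2 = log(U_i / D_{i-1})    one-month lag effect
# with natural logarithms (a threshold of 6 on X1 means sales exceed
# recorded purchases more than e^6 > 400 fold).

#' Aggregate a manufacturer's invoices into monthly totals
#'
#' `Pur_i` sums amounts of invoices where the manufacturer is the
#' vendee (buyer) in calendar month i; `Sale_i` where it is the vendor.
#' Invoices naming the manufacturer as neither party are ignored.
#' Months with no transactions inside the covered range are emitted
#' with zeros (absence of invoices is itself informative), so the
#' series is contiguous.
#'
#' @param invoices invoice data frame — normally the edible-oil-related
#'   partition from [sieve_invoices()].
#' @param manufacturer_id the manufacturer to aggregate.
#' @param months optional character vector of `"YYYY-MM"` months fixing
#'   the series range; default is the manufacturer's observed
#'   first-to-last month span.
#' @return data frame `manufacturer_id`, `month`, `month_index`,
#'   `Pur`, `Sale`.
#' @export
aggregate_monthly <- function(invoices, manufacturer_id, months = NULL) {
  mine <- invoices$vendor_id == manufacturer_id |
    invoices$vendee_id == manufacturer_id
  inv <- invoices[mine, , drop = FALSE]
  mon <- substr(inv$date, 1, 7)
  if (is.null(months)) {
    if (nrow(inv) == 0)
      return(data.frame(manufacturer_id = character(0), month = character(0),
                        month_index = integer(0), Pur = numeric(0),
                        Sale = numeric(0), stringsAsFactors = FALSE))
    months <- .month_seq(min(mon),
                         length(seq(as.Date(paste0(min(mon), "-01")),
                                    as.Date(paste0(max(mon), "-01")),
                                    by = "month")))
  }
  pur <- tapply(inv$amount[inv$vendee_id == manufacturer_id],
                mon[inv$vendee_id == manufacturer_id], sum)
  sale <- tapply(inv$amount[inv$vendor_id == manufacturer_id],
                 mon[inv$vendor_id == manufacturer_id], sum)
  get0 <- function(tab, m) ifelse(m %in% names(tab), tab[m], 0)
  data.frame(manufacturer_id = manufacturer_id, month = months,
             month_index = seq_along(months),
             Pur = as.numeric(get0(pur, months)),
             Sale = as.numeric(get0(sale, months)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 3-month moving-average smoothing
#'
#' Emits the smoothed downstream/upstream series `D_i`, `U_i` for full
#' windows only (from the third month on), exactly
#' `(x_{i-2} + x_{i-1} + x_i) / 3`.
#'
#' @param series monthly aggregate data frame from
#'   [aggregate_monthly()], ordered by month.
#' @return data frame `manufacturer_id`, `month`, `month_index`, `D`,
#'   `U`; a series of M months yields M - 2 rows.
#' @export
smooth_series <- function(series) {
  n <- nrow(series)
  if (n < 3)
    stop("need at least 3 months for the 3-month moving average")
  w <- rep(1 / 3, 3)
  D <- as.numeric(stats::filter(series$Pur, w, sides = 1))
  U <- as.numeric(stats::filter(series$Sale, w, sides = 1))
  keep <- 3:n
  data.frame(manufacturer_id = series$manufacturer_id[keep],
             month = series$month[keep],
             month_index = series$month_index[keep],
             D = D[keep], U = U[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Clamped natural log-ratio. A window with zero purchases but positive
# sales is "maximally suspicious": the ratio is conceptually +Inf and
# is clamped to +cap (far above the decision threshold) and flagged;
# symmetric for zero sales. Both zero gives no information.
.log_ratio <- function(u, d, cap) {
  if (u > 0 && d > 0) list(x = log(u / d), clamped = FALSE, valid = TRUE)
  else if (d == 0 && u > 0) list(x = cap, clamped = TRUE, valid = TRUE)
  else if (u == 0 && d > 0) list(x = -cap, clamped = TRUE, valid = TRUE)
  else list(x = NA_real_, clamped = FALSE, valid = FALSE)
}

#' Log turnover-ratio features from a smoothed series
#'
#' `X1 = log(U_i / D_i)` and `X2 = log(U_i / D_{i-1})`, natural logs.
#' The first smoothed month has no full-window `D_{i-1}`, so `X2` is
#' absent there. Zero denominators are clamped to `+/- clamp` and the
#' record flagged (`clamped`); records with both sides zero are marked
#' invalid (`valid = FALSE`, features `NA`). Features are scale
#' equivariant: multiplying all amounts by a constant leaves them
#' unchanged.
#'
#' @param smoothed data frame from [smooth_series()].
#' @param clamp cap for log-ratios with a zero denominator (default 20,
#'   far above the naive-rule threshold of 6).
#' @return data frame `manufacturer_id`, `month`, `month_index`, `D`,
#'   `U`, `X1`, `X2`, `clamped`, `valid`. M contiguous months of raw
#'   data yield M - 2 `X1` values and M - 3 `X2` values.
#' @export
compute_features <- function(smoothed, clamp = 20) {
  k <- nrow(smoothed)
  X1 <- X2 <- rep(NA_real_, k)
  clamped <- logical(k)
  valid <- rep(TRUE, k)
  for (i in seq_len(k)) {
    r1 <- .log_ratio(smoothed$U[i], smoothed$D[i], clamp)
    X1[i] <- r1$x
    clamped[i] <- r1$clamped
    valid[i] <- r1$valid
    if (i > 1) {
      r2 <- .log_ratio(smoothed$U[i], smoothed$D[i - 1], clamp)
      X2[i] <- r2$x
      clamped[i] <- clamped[i] || r2$clamped
    }
  }
  cbind(smoothed,
        data.frame(X1 = X1, X2 = X2, clamped = clamped, valid = valid))
}

#' Full feature pipeline over many manufacturers
#'
#' Aggregates, smooths and featurizes each manufacturer's invoices in
#' one call. Manufacturers with fewer than 3 observed months are
#' skipped with a warning.
#'
#' @inheritParams aggregate_monthly
#' @inheritParams compute_features
#' @param manufacturer_ids character vector of manufacturers to
#'   process.
#' @return row-bound feature data frame (see [compute_features()]).
#' @export
turnover_features <- function(invoices, manufacturer_ids, months = NULL,
                              clamp = 20) {
  out <- lapply(manufacturer_ids, function(id) {
    agg <- aggregate_monthly(invoices, id, months = months)
    if (nrow(agg) < 3) {
      warning("skipping manufacturer ", id, ": fewer than 3 months")
      return(NULL)
    }
    compute_features(smooth_series(agg), clamp = clamp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
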