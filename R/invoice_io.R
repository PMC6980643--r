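# Data model, validation and readers/writers for invoices, labeled
# items and manufacturer ground truth.

#' Canonical invoice columns
#'
#' One row per B2B transaction line: opaque invoice id, calendar date,
#' seller (`vendor_id`), buyer (`vendee_id`), free-text item name, a
#' non-negative amount, and an optional quantity (real e-invoice data
#' does not always list it; an empty field means absent).
#' @export
invoice_columns <- c("invoice_id", "date", "vendor_id", "vendee_id",
                     "item_name", "amount", "quantity")

.validate_invoices <- function(df, strict = TRUE) {
  missing_cols <- setdiff(setdiff(invoice_columns, "quantity"), names(df))
  if (length(missing_cols))
    stop("invoice schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!"quantity" %in% names(df)) df$quantity <- NA_real_

  date <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  amount <- suppressWarnings(as.numeric(df$amount))
  quantity <- suppressWarnings(as.numeric(ifelse(df$quantity == "" | is.na(df$quantity),
                                                 NA, df$quantity)))
  bad_date <- is.na(date)
  bad_amount <- is.na(amount) | amount < 0
  bad_party <- as.character(df$vendor_id) == as.character(df$vendee_id)
  bad <- bad_date | bad_amount | bad_party

  if (any(bad)) {
    reason <- ifelse(bad_date, "unparseable date",
              ifelse(bad_amount, "missing or negative amount",
                     "vendor equals vendee"))
    problems <- data.frame(line = which(bad), reason = reason[bad],
                           stringsAsFactors = FALSE)
    if (strict) {
      first <- utils::head(problems, 3)
      stop("invoice row error(s) at line(s) ",
           paste(first$line, collapse = ", "), ": ",
           paste(unique(first$reason), collapse = "; "),
           if (nrow(problems) > 3) sprintf(" (and %d more)", nrow(problems) - 3))
    }
    message(sprintf("skipping %d malformed invoice row(s)", nrow(problems)))
  } else {
    problems <- data.frame(line = integer(0), reason = character(0),
                           stringsAsFactors = FALSE)
  }

  out <- data.frame(invoice_id = as.character(df$invoice_id),
                    date = as.character(date),
                    vendor_id = as.character(df$vendor_id),
                    vendee_id = as.character(df$vendee_id),
                    item_name = as.character(df$item_name),
                    amount = round(amount, 2),
                    quantity = quantity,
                    stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- problems
  out
}

#' Read invoices from CSV or JSON-lines
#'
#' @param path file path.
#' @param format `"csv"` (canonical column order, UTF-8) or `"jsonl"`
#'   (one JSON object per line).
#' @param strict if `TRUE` (default) any malformed row (unparseable
#'   date, missing/negative amount, vendor equal to vendee) aborts with
#'   its line number; if `FALSE` malformed rows are skipped, reported
#'   via a message, and listed in the `"skipped"` attribute.
#' @return data frame of validated invoices with columns
#'   [invoice_columns]; amounts rounded to 2 decimals.
#' @export
read_invoices <- function(path, format = c("csv", "jsonl"), strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(format,
    csv = utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8"),
    jsonl = jsonlite::stream_in(file(path), verbose = FALSE))
  .validate_invoices(df, strict = strict)
}

#' Write invoices to CSV or JSON-lines
#'
#' Inverse of [read_invoices()]: canonical column order, UTF-8, empty
#' quantity field for absent quantities. Round-trips are identity at
#' 2-decimal amount precision.
#'
#' @param invoices data frame with columns [invoice_columns]
#'   (`quantity` optional).
#' @inheritParams read_invoices
#' @return the path, invisibly.
#' @export
write_invoices <- function(invoices, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!"quantity" %in% names(invoices)) invoices$quantity <- NA_real_
  invoices <- invoices[, invoice_columns]
  invoices$amount <- round(as.numeric(invoices$amount), 2)
  if (format == "csv") {
    utils::write.csv(invoices, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(invoices, con, verbose = FALSE)
  }
  invisible(path)
}

#' Read a labeled item table
#'
#' Two-column CSV `item_name,label` with binary labels
#' (1 = edible-oil-related), the training data for the text sieve.
#'
#' @param path file path.
#' @return data frame with character `item_name` and integer `label`.
#' @export
read_labeled_items <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!all(c("item_name", "label") %in% names(df)))
    stop("labeled-item schema error: need columns item_name, label")
  label <- suppressWarnings(as.integer(df$label))
  if (any(is.na(label) | !label %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  data.frame(item_name = df$item_name, label = label,
             stringsAsFactors = FALSE)
}

#' @rdname read_labeled_items
#' @param items data frame with columns `item_name` and `label`.
#' @export
write_labeled_items <- function(items, path) {
  stopifnot(all(c("item_name", "label") %in% names(items)))
  utils::write.csv(items[, c("item_name", "label")], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read manufacturer ground truth as JSON
#'
#' Serializes the generator's per-manufacturer class labels (A
#' benchmark / B problematic / C unspecified) and per-month suspicious
#' flags.
#'
#' @param ground_truth data frame with columns `manufacturer_id`,
#'   `class_label`, `month`, `month_index`, `suspicious`.
#' @param path file path.
#' @return the path (write) or the ground-truth data frame (read).
#' @export
write_ground_truth <- function(ground_truth, path) {
  split_gt <- split(ground_truth, ground_truth$manufacturer_id)
  out <- lapply(split_gt, function(g) {
    g <- g[order(g$month_index), ]
    list(manufacturer_id = g$manufacturer_id[1],
         class_label = g$class_label[1],
         months = g$month,
         suspicious = g$suspicious)
  })
  names(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    months <- unlist(raw$months[i])
    data.frame(manufacturer_id = raw$manufacturer_id[i],
               class_label = raw$class_label[i],
               month = months,
               month_index = seq_along(months),
               suspicious = unlist(raw$suspicious[i]),
               stringsAsFactors = FALSE)
  }))
}
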