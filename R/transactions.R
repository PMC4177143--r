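#' Construct a TransactionSet
#'
#' @param ids transaction identifiers (coerced to character); defaults to
#'   `"t1" ... "tn"`.
#' @param items list of character item vectors; items are de-duplicated and
#'   sorted.
#' @return a [TransactionSet-class].
#' @examples
#' transactionSet(items = list(c("A", "B"), "A", c("B", "C")))
#' @export
transactionSet <- function(ids = NULL, items) {
  items <- lapply(items, function(x) sort(unique(as.character(x))))
  if (is.null(ids))
    ids <- paste0("t", seq_along(items), recycle0 = TRUE)
  new("TransactionSet", ids = as.character(ids), items = items)
}

#' @rdname TransactionSet-class
#' @export
setMethod("transactionItems", "TransactionSet", function(object) object@items)

#' @rdname TransactionSet-class
#' @export
setMethod("transactionIDs", "TransactionSet", function(object) object@ids)

#' @rdname TransactionSet-class
#' @export
setMethod("length", "TransactionSet", function(x) length(x@items))

#' @rdname TransactionSet-class
#' @param i index vector.
#' @param j,drop,... unused.
#' @export
setMethod("[", "TransactionSet", function(x, i, j, ..., drop = TRUE) {
  new("TransactionSet", ids = x@ids[i], items = x@items[i])
})

setMethod("show", "TransactionSet", function(object) {
  n <- length(object@items)
  univ <- unique(unlist(object@items))
  cat(sprintf("TransactionSet: %d transactions, %d distinct items\n",
              n, length(univ)))
  if (n > 0L) {
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat(sprintf("  %s: {%s}\n", object@ids[i],
                  paste(object@items[[i]], collapse = ", ")))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

#' Read transactions from delimited text
#'
#' One row per transaction: `id,items` with the item tokens joined by
#' semicolons.
#'
#' @param path path to the CSV file.
#' @return a [TransactionSet-class].
#' @export
readTransactions <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("id", "items") %in% names(raw)))
    snValidationError(sprintf("%s: expected columns 'id' and 'items'", path))
  items <- strsplit(raw$items, ";", fixed = TRUE)
  items <- lapply(items, function(x) x[nzchar(x)])
  transactionSet(raw$id, items)
}

#' Write transactions as delimited text
#'
#' @param transactions a [TransactionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTransactions <- function(transactions, path) {
  df <- data.frame(
    id = transactionIDs(transactions),
    items = vapply(transactionItems(transactions), paste,
                   character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
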