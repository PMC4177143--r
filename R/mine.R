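# Association mining with exact count arithmetic. Supports are kept as
# integer counts over n transactions for as long as possible; fractions and
# two-decimal percentages are derived views, so threshold comparisons at
# e.g. exactly 30% support or 85% confidence do not hinge on float noise.

.itemsetKey <- function(items) paste(sort(items), collapse = ";")

.splitKey <- function(key) strsplit(key, ";", fixed = TRUE)[[1]]

.countItemset <- function(itemsList, itemset) {
  sum(vapply(itemsList, function(tr) all(itemset %in% tr), logical(1)))
}

# truncate (not round) a fraction to a two-decimal percentage; this is the
# convention of the printed clinical rule tables this package reproduces
# (e.g. 21/37 -> 56.75, 29/37 -> 78.37)
pctTrunc <- function(frac) floor(frac * 10000 + 1e-9) / 100

#' Support of an itemset
#'
#' Fraction of transactions containing every item of the itemset.
#'
#' @param transactions a [TransactionSet-class].
#' @param itemset character vector of item tokens (non-empty).
#' @return list with `count` (integer), `n` (transactions) and
#'   `support` (= `count / n`).
#' @examples
#' tx <- transactionSet(items = list(c("A", "B"), "A", c("A", "B")))
#' itemsetSupport(tx, c("A", "B"))$support  # 2/3
#' @export
itemsetSupport <- function(transactions, itemset) {
  if (length(transactions) == 0L)
    snValidationError("support is undefined on an empty transaction set")
  if (length(itemset) == 0L)
    snValidationError("itemset must be non-empty")
  n <- length(transactions)
  cnt <- .countItemset(transactionItems(transactions), unique(itemset))
  list(count = cnt, n = n, support = cnt / n)
}

#' Level-wise Apriori frequent-itemset mining
#'
#' Classic Apriori with downward-closure pruning: level k candidates are
#' generated by joining frequent (k-1)-itemsets sharing a (k-2)-prefix and
#' discarded when any (k-1)-subset is infrequent; the surviving candidates
#' are counted against the transactions. Returns exactly the itemsets whose
#' support reaches `minSupport`.
#'
#' @param transactions a [TransactionSet-class] (non-empty).
#' @param minSupport minimum support fraction in `(0, 1]`. An itemset is
#'   frequent when `count >= minSupport * n` (evaluated on exact counts).
#' @return `data.frame` with columns `items` (semicolon-joined sorted
#'   tokens), `size`, `count` and `support`, sorted by descending support
#'   then item key; the transaction total is attached as attribute `"n"`.
#' @examples
#' tx <- transactionSet(items = list(c("A", "B"), c("A", "B"), "B"))
#' apriori(tx, minSupport = 0.6)
#' @export
apriori <- function(transactions, minSupport) {
  if (length(transactions) == 0L)
    snValidationError("apriori is undefined on an empty transaction set")
  if (!(minSupport > 0 && minSupport <= 1))
    snConfigError("minSupport must be in (0, 1]")
  itemsList <- transactionItems(transactions)
  n <- length(itemsList)
  minCount <- minSupport * n - 1e-9  # exact-count threshold

  tab <- table(unlist(itemsList))
  level <- lapply(sort(names(tab)[tab >= minCount]), identity)
  counts <- as.integer(tab[unlist(level)])
  allSets <- level
  allCounts <- counts

  while (length(level) > 1L) {
    freqKeys <- vapply(level, .itemsetKey, character(1))
    k <- length(level[[1]]) + 1L
    cand <- list()
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        a <- level[[i]]; b <- level[[j]]
        if (k == 2L || identical(a[-(k - 1L)], b[-(k - 1L)])) {
          u <- sort(union(a, b))
          if (length(u) == k) cand[[length(cand) + 1L]] <- u
        }
      }
    }
    if (length(cand) == 0L) break
    cand <- cand[!duplicated(vapply(cand, .itemsetKey, character(1)))]
    # downward-closure pruning: every (k-1)-subset must be frequent
    keep <- vapply(cand, function(s) {
      subs <- vapply(seq_along(s), function(d) .itemsetKey(s[-d]),
                     character(1))
      all(subs %in% freqKeys)
    }, logical(1))
    cand <- cand[keep]
    if (length(cand) == 0L) break
    cnts <- vapply(cand, function(s) .countItemset(itemsList, s), numeric(1))
    ok <- cnts >= minCount
    level <- cand[ok]
    allSets <- c(allSets, level)
    allCounts <- c(allCounts, as.integer(cnts[ok]))
    if (length(level) == 0L) break
  }

  keys <- vapply(allSets, .itemsetKey, character(1))
  out <- data.frame(
    items = keys,
    size = lengths(allSets),
    count = as.integer(allCounts),
    support = allCounts / n,
    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$items), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- n
  out
}

#' Cosine correlation of two itemsets
#'
#' `support(X ∪ Y) / sqrt(support(X) * support(Y))`, the cosine interest
#' measure. This is the package's correlation column for mined rules; it is
#' an implementation choice of measure, reported alongside (never gating)
#' support and confidence.
#'
#' @param transactions a [TransactionSet-class].
#' @param antecedent,consequent disjoint non-empty itemsets.
#' @return cosine measure in `[0, 1]`.
#' @export
cosineCorrelation <- function(transactions, antecedent, consequent) {
  sx <- itemsetSupport(transactions, antecedent)
  sy <- itemsetSupport(transactions, consequent)
  if (sx$count == 0L || sy$count == 0L)
    snValidationError("cosine correlation undefined at zero support")
  sxy <- itemsetSupport(transactions, union(antecedent, consequent))
  sxy$count / sqrt(as.numeric(sx$count) * sy$count)
}

#' Generate association rules from frequent itemsets
#'
#' Enumerates every split of every frequent itemset of size >= 2 into a
#' non-empty antecedent X and non-empty consequent Y (consequents may hold
#' several items) and keeps rules with confidence
#' `support(X ∪ Y) / support(X) >= minConfidence`. All supports come from
#' the frequent-itemset table (every subset of a frequent itemset is
#' frequent), so confidence is an exact ratio of integer counts.
#'
#' @param frequent output of [apriori()] (produced at the configured
#'   minimum support).
#' @param transactions the [TransactionSet-class] the itemsets were mined
#'   from (used for the correlation measure).
#' @param minConfidence minimum confidence fraction in `(0, 1]`.
#' @return `data.frame` with columns `antecedent`, `consequent`
#'   (semicolon-joined tokens), `count_rule`, `count_antecedent`, `support`,
#'   `confidence`, `correlation` and their two-decimal percentage views
#'   `support_pct`, `confidence_pct`, `correlation_pct`; rows sorted by
#'   descending support, then descending confidence, then antecedent and
#'   consequent keys.
#' @export
generateRules <- function(frequent, transactions, minConfidence) {
  if (!(minConfidence > 0 && minConfidence <= 1))
    snConfigError("minConfidence must be in (0, 1]")
  cnt <- stats::setNames(frequent$count, frequent$items)
  rows <- list()
  big <- frequent[frequent$size >= 2L, , drop = FALSE]
  for (r in seq_len(nrow(big))) {
    z <- .splitKey(big$items[r])
    cz <- big$count[r]
    k <- length(z)
    for (mask in seq_len(2^k - 2L)) {
      inX <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      x <- z[inX]; y <- z[!inX]
      cx <- cnt[[.itemsetKey(x)]]
      if (cz < minConfidence * cx - 1e-9) next
      cy <- cnt[[.itemsetKey(y)]]
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = .itemsetKey(x), consequent = .itemsetKey(y),
        count_rule = cz, count_antecedent = cx,
        support = cz / attr(frequent, "n"),
        confidence = cz / cx,
        correlation = cz / sqrt(as.numeric(cx) * cy),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(antecedent = character(), consequent = character(),
               count_rule = integer(), count_antecedent = integer(),
               support = numeric(), confidence = numeric(),
               correlation = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out <- out[order(-out$support, -out$confidence, out$antecedent,
                   out$consequent), , drop = FALSE]
  rownames(out) <- NULL
  out$support_pct <- pctTrunc(out$support)
  out$confidence_pct <- pctTrunc(out$confidence)
  out$correlation_pct <- pctTrunc(out$correlation)
  out
}

#' Write mined rules as CSV
#'
#' Columns mirror the printed rule-table layout: antecedent, consequent and
#' the two-decimal percentage metrics.
#'
#' @param rules output of [generateRules()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRules <- function(rules, path) {
  utils::write.csv(
    rules[, c("antecedent", "consequent", "support_pct",
              "confidence_pct", "correlation_pct")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
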