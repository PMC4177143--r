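# Independent brute-force oracles. These deliberately share no code with
# the implementations they check: mining is re-done by bitmask enumeration
# over every candidate itemset, areas by explicit Gram matrices, threshold
# calibration by a dense scan.

# --- exhaustive frequent-itemset / rule oracle (universe <= ~16 items) ---

txBitmasks <- function(tx) {
  universe <- sort(unique(unlist(transactionItems(tx))))
  masks <- vapply(transactionItems(tx), function(items)
    sum(2^(match(items, universe) - 1L)), numeric(1))
  list(universe = universe, masks = masks)
}

oracleFrequent <- function(tx, minSupport) {
  bm <- txBitmasks(tx)
  p <- length(bm$universe)
  n <- length(bm$masks)
  out <- list()
  for (m in seq_len(2^p - 1L)) {
    cnt <- sum(bitwAnd(bm$masks, m) == m)
    if (cnt >= minSupport * n - 1e-9) {
      items <- bm$universe[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0]
      out[[length(out) + 1L]] <- data.frame(
        items = paste(sort(items), collapse = ";"),
        count = cnt, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(items = character(), count = integer()))
  res[order(res$items), , drop = FALSE]
}

oracleRules <- function(tx, minSupport, minConfidence) {
  bm <- txBitmasks(tx)
  n <- length(bm$masks)
  cnt <- function(items) {
    m <- sum(2^(match(items, bm$universe) - 1L))
    sum(bitwAnd(bm$masks, m) == m)
  }
  freq <- oracleFrequent(tx, minSupport)
  rows <- list()
  for (key in freq$items) {
    z <- strsplit(key, ";", fixed = TRUE)[[1]]
    k <- length(z)
    if (k < 2L) next
    cz <- cnt(z)
    for (mask in seq_len(2^k - 2L)) {
      x <- z[as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))]
      y <- setdiff(z, x)
      cx <- cnt(x)
      if (cz >= minConfidence * cx - 1e-9)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(sort(x), collapse = ";"),
          consequent = paste(sort(y), collapse = ";"),
          count_rule = cz, count_antecedent = cx,
          stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(antecedent = character(),
                                      consequent = character(),
                                      count_rule = integer(),
                                      count_antecedent = integer()))
  res[order(res$antecedent, res$consequent), , drop = FALSE]
}

randomTransactionSet <- function(nItems, nTx = 20L, density = 0.35) {
  pool <- LETTERS[seq_len(nItems)]
  items <- lapply(seq_len(nTx), function(i) {
    keep <- pool[stats::runif(nItems) < density]
    if (length(keep) == 0L) keep <- sample(pool, 1L)
    keep
  })
  transactionSet(items = items)
}

# --- Gram-determinant area oracle ---

oracleGramArea <- function(dx, dy) {
  G <- rbind(c(sum(dx * dx), sum(dx * dy)),
             c(sum(dy * dx), sum(dy * dy)))
  sqrt(max(det(G), 0))
}

# --- dense-scan threshold oracle: minimal misclassification, smallest theta ---

oracleCutpoint <- function(dA, persisted) {
  cand <- sort(unique(c(0, dA, dA + 1e-9)))
  err <- vapply(cand, function(th)
    sum(persisted & dA > th) + sum(!persisted & dA <= th), numeric(1))
  min(cand[err == min(err)])
}

# --- small builders used across SN tests ---

# ranges under which normalization is the identity map
identityRanges <- function(params = c("c1", "c2", "c3", "c4")) {
  referenceRanges(params, low = rep(-1, length(params)),
                  high = rep(1, length(params)))
}

# hand-built series from a matrix of already-normalized values
makeSeries <- function(X, times = seq_len(nrow(X)) - 1,
                       params = paste0("c", seq_len(ncol(X))),
                       states = NULL) {
  df <- data.frame(patient_id = "P1", point_index = seq_len(nrow(X)),
                   time_days = times)
  for (j in seq_len(ncol(X))) df[[params[j]]] <- X[, j]
  if (!is.null(states)) df$state <- states
  attr(df, "ranges") <- identityRanges(params)
  attr(df, "parameters") <- params
  df
}

snQuartet <- c("creatinine", "bun", "sgot", "sgpt")

# wide reference ranges: same midpoint/scale behaviour but no chance of the
# positivity floor engaging, for exact analytic checks on simulated values
wideRanges <- function() {
  referenceRanges(c(snQuartet, "haemoglobin"),
                  low = rep(100, 5), high = rep(300, 5), units = "U/L")
}
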