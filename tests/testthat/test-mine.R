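test_that("support counts transactions containing the whole itemset", {
  tx <- transactionSet(items = list(c("A", "B"), c("A", "B", "C"), "A"))
  expect_equal(itemsetSupport(tx, "A")$support, 1.0)
  expect_equal(itemsetSupport(tx, c("A", "B"))$count, 2L)
  # brute-force recount on a random set
  set.seed(101)
  rtx <- randomTransactionSet(7)
  for (s in list("A", c("A", "C"), c("B", "D", "F"))) {
    naive <- sum(vapply(transactionItems(rtx),
                        function(t) all(s %in% t), logical(1)))
    expect_equal(itemsetSupport(rtx, s)$count, naive)
  }
  expect_error(itemsetSupport(transactionSet(items = list()), "A"),
               "empty transaction set")
})

test_that("fixture supports match the printed rule-table fractions", {
  tx <- ruleTableFixture()
  expect_equal(itemsetSupport(tx, c("KFT_Creatinine=HIGH",
                                    "KFT_BUN=HIGH"))$support, 21 / 37)
  freq <- apriori(tx, 0.30)
  key <- "LFT_SGPT=HIGH;STATE=1"
  expect_equal(freq$support[freq$items == key], 30 / 37)
})

test_that("apriori equals exhaustive enumeration and respects anti-monotonicity", {
  set.seed(77)
  for (rep in 1:15) {
    tx <- randomTransactionSet(sample(4:8, 1))
    ms <- runif(1, 0.1, 0.5)
    got <- apriori(tx, ms)
    got <- got[order(got$items), c("items", "count")]
    rownames(got) <- NULL
    want <- oracleFrequent(tx, ms)
    rownames(want) <- NULL
    expect_equal(got, want)
    # every non-empty subset of a frequent itemset is frequent, with
    # support at least the superset's
    sup <- setNames(got$count, got$items)
    for (key in got$items) {
      z <- strsplit(key, ";", fixed = TRUE)[[1]]
      if (length(z) < 2) next
      for (d in seq_along(z)) {
        sk <- paste(z[-d], collapse = ";")
        expect_true(sk %in% got$items)
        expect_gte(sup[[sk]], sup[[key]])
      }
    }
  }
  # min support at the rarest single item keeps every single item
  tx <- transactionSet(items = list(c("A", "B"), c("A", "C"), "A"))
  f <- apriori(tx, 1 / 3)
  expect_true(all(c("A", "B", "C") %in% f$items))
})

test_that("rule generation matches the exhaustive split oracle with exact metrics", {
  set.seed(55)
  for (rep in 1:10) {
    tx <- randomTransactionSet(sample(4:7, 1))
    ms <- runif(1, 0.15, 0.4); mc <- runif(1, 0.4, 0.9)
    rules <- generateRules(apriori(tx, ms), tx, mc)
    got <- rules[order(rules$antecedent, rules$consequent),
                 c("antecedent", "consequent", "count_rule",
                   "count_antecedent")]
    rownames(got) <- NULL
    want <- oracleRules(tx, ms, mc)
    rownames(want) <- NULL
    expect_equal(got, want)
    # metric invariants: 0 <= support <= confidence <= 1, and
    # confidence * support(X) recovers support(XY) exactly on counts
    expect_true(all(rules$support >= 0 & rules$support <= rules$confidence))
    expect_true(all(rules$confidence <= 1))
    expect_equal(rules$confidence * rules$count_antecedent,
                 as.numeric(rules$count_rule))
    # antecedent and consequent never share items
    for (i in seq_len(nrow(rules)))
      expect_length(intersect(
        strsplit(rules$antecedent[i], ";", fixed = TRUE)[[1]],
        strsplit(rules$consequent[i], ";", fixed = TRUE)[[1]]), 0)
  }
})

test_that("raising thresholds never adds itemsets or rules", {
  set.seed(12)
  tx <- randomTransactionSet(6)
  f1 <- apriori(tx, 0.2); f2 <- apriori(tx, 0.4)
  expect_true(all(f2$items %in% f1$items))
  r1 <- generateRules(f1, tx, 0.5); r2 <- generateRules(f1, tx, 0.8)
  k1 <- paste(r1$antecedent, r1$consequent)
  k2 <- paste(r2$antecedent, r2$consequent)
  expect_true(all(k2 %in% k1))
})

test_that("cosine correlation obeys its algebraic identities", {
  # X = Y gives 1 exactly
  tx <- transactionSet(items = list(c("A", "B"), "A", c("A", "B")))
  expect_equal(cosineCorrelation(tx, "A", "A"), 1.0)
  # independence: joint = a * b gives sqrt(a * b)
  items <- lapply(1:20, function(i) {
    c(if (i <= 10) "A", if (i >= 6 && i <= 15) "B", "Z")
  })
  tx2 <- transactionSet(items = items)
  expect_equal(itemsetSupport(tx2, c("A", "B"))$support, 0.25)
  expect_equal(cosineCorrelation(tx2, "A", "B"), sqrt(0.5 * 0.5))
  # random instance: matches direct recomputation from counted supports
  set.seed(8)
  rtx <- randomTransactionSet(6)
  sx <- itemsetSupport(rtx, "A")$support
  sy <- itemsetSupport(rtx, c("B", "C"))$support
  sxy <- itemsetSupport(rtx, c("A", "B", "C"))$support
  expect_equal(cosineCorrelation(rtx, "A", c("B", "C")),
               sxy / sqrt(sx * sy))
})
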