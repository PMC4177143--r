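# Reconstruction of the motivating brain-tumour association-rule table as a
# concrete transaction set. The original per-patient transactions were never
# deposited; only the rule table (support% / confidence% per rule) is
# printed. Those percentages are exact enough to invert: each is a ratio of
# small integer counts, so scanning candidate denominators recovers the
# transaction total and the counts, from which a deterministic transaction
# layout can be rebuilt and re-mined.

#' The bundled brain-tumour rule table
#'
#' The published association rules linking HIGH kidney/liver analytes (and
#' NORMAL haemoglobin) to the tumour state, with their printed support,
#' confidence and correlation percentages. Percentages in this table are
#' truncated (not rounded) to two decimals. This table is the input that
#' [invertRuleTable()] and [ruleTableFixture()] reconstruct transactions
#' from.
#'
#' @return `data.frame` with columns `antecedent`, `consequent`
#'   (semicolon-joined item tokens), `support_pct`, `confidence_pct`,
#'   `correlation_pct`.
#' @export
referenceRuleTable <- function() {
  data.frame(
    antecedent = c(
      "KFT_Creatinine=HIGH",
      "KFT_Creatinine=HIGH",
      "KFT_BUN=HIGH",
      "KFT_BUN=HIGH;KFT_Creatinine=HIGH",
      "LFT_SGOT=HIGH",
      "LFT_SGOT=HIGH",
      "LFT_SGPT=HIGH",
      "Haemoglobin_content=NORMAL"),
    consequent = c(
      "KFT_BUN=HIGH",
      "STATE=1",
      "STATE=1",
      "STATE=1",
      "STATE=1",
      "LFT_SGPT=HIGH;STATE=1",
      "STATE=1",
      "STATE=1"),
    support_pct    = c(56.75, 56.75, 78.37, 56.75, 62.16, 62.16, 81.08, 59.45),
    confidence_pct = c(100,   100,   85.29, 100,   98.83, 95.83, 88.23, 100),
    correlation_pct = c(77.45, 77.77, 90.8, 79.77, 81.72, 85.71, 89.56, 81.64),
    stringsAsFactors = FALSE)
}

#' Recover the transaction denominator from printed support percentages
#'
#' Scans candidate transaction totals and keeps those for which every
#' distinct support percentage times `n / 100` lies within `tol` of an
#' integer. With two-decimal percentages and totals in the scanned window,
#' at most one `n` can satisfy all constraints.
#'
#' @param supportPct numeric vector of distinct printed support
#'   percentages; defaults to those of [referenceRuleTable()].
#' @param nRange candidate totals to scan.
#' @param tol integer-consistency tolerance on the raw count
#'   `supportPct * n / 100` (default 0.02: two-decimal truncation of a
#'   count ratio leaves at most `n * 5e-5 + 0.005` slack, under 0.02 for
#'   `n <= 60`... kept as a single conservative bound).
#' @return list with `n` (the unique consistent total) and `candidates`
#'   (all consistent totals in the window).
#' @export
recoverDenominator <- function(supportPct = unique(referenceRuleTable()$support_pct),
                               nRange = 20:60, tol = 0.02) {
  ok <- vapply(nRange, function(n) {
    raw <- supportPct * n / 100
    all(abs(raw - round(raw)) <= tol)
  }, logical(1))
  candidates <- nRange[ok]
  if (length(candidates) == 0L)
    snValidationError("no candidate transaction total is integer-consistent")
  list(n = candidates[1], candidates = candidates)
}

#' Invert a printed rule table into integer count constraints
#'
#' For each rule X => Y with printed support and confidence percentages and
#' a transaction total `n`, derives `count(X ∪ Y) = support% * n / 100` and
#' `count(X) = count(X ∪ Y) / (confidence% / 100)`. A row whose derived
#' counts are not within `tol` of an integer before rounding is flagged
#' inconsistent and contributes no constraints (in the bundled table one
#' confidence cell is inconsistent with the integer counts implied by its
#' sibling rows and is flagged as a probable misprint).
#'
#' @param rows rule table in the [referenceRuleTable()] layout.
#' @param n transaction total.
#' @param tol integer-consistency tolerance (see [recoverDenominator()]).
#' @return list with `constraints` — a `data.frame` of unique itemset count
#'   constraints (`items`, `count`) — and `rows`, the input annotated with
#'   `count_rule`, `count_antecedent` and a logical `flagged` column.
#' @export
invertRuleTable <- function(rows = referenceRuleTable(), n = NULL,
                            tol = 0.02) {
  if (is.null(n)) n <- recoverDenominator(unique(rows$support_pct))$n
  if (n < 1L) snConfigError("n must be >= 1")
  rawXY <- rows$support_pct * n / 100
  cXY <- round(rawXY)
  flagged <- abs(rawXY - cXY) > tol
  rawX <- cXY / (rows$confidence_pct / 100)
  cX <- round(rawX)
  flagged <- flagged | abs(rawX - cX) > tol
  rows$count_rule <- as.integer(cXY)
  rows$count_antecedent <- as.integer(cX)
  rows$flagged <- flagged

  cons <- list()
  addCons <- function(items, count) {
    cons[[length(cons) + 1L]] <<- data.frame(
      items = .itemsetKey(items), count = as.integer(count),
      stringsAsFactors = FALSE)
  }
  for (r in which(!flagged)) {
    x <- .splitKey(rows$antecedent[r])
    z <- sort(union(x, .splitKey(rows$consequent[r])))
    addCons(z, cXY[r])
    addCons(x, cX[r])
  }
  constraints <- do.call(rbind, cons)
  constraints <- constraints[!duplicated(constraints$items), , drop = FALSE]
  clash <- tapply(do.call(rbind, cons)$count, do.call(rbind, cons)$items,
                  function(v) length(unique(v)) > 1L)
  if (any(clash))
    snValidationError(paste("conflicting counts for itemset(s):",
                            paste(names(clash)[clash], collapse = ", ")))
  if (any(constraints$count > n))
    snValidationError("a derived count exceeds the transaction total")
  rownames(constraints) <- NULL
  list(constraints = constraints, rows = rows, n = n)
}

#' Build a deterministic transaction set satisfying count constraints
#'
#' Constructive interval layout over transactions `1..n`: the state item
#' occupies transactions `1..stateSupport`; every other single item with
#' total count `t` and in-state count `s` (taken from its pair constraint
#' with the state item, else capped at the state block) occupies
#' `1..s` and `stateSupport+1 .. stateSupport+(t-s)`. Nested antecedents
#' (e.g. creatinine HIGH inside BUN HIGH inside the state block) then
#' satisfy the higher-order joint constraints automatically. Non-state
#' transactions receive a `STATE=0` token so every transaction is
#' non-empty. Every input constraint is recounted on the built set before
#' returning; any violation is a construction failure naming the
#' constraint.
#'
#' @param constraints `data.frame` (`items`, `count`) as produced by
#'   [invertRuleTable()].
#' @param n transaction total.
#' @param stateSupport number of transactions carrying the state item. For
#'   the bundled table the row system constrains this to `[30, 32]`; the
#'   default 30 is the minimal feasible value.
#' @param stateItem the state token (default `"STATE=1"`).
#' @return a [TransactionSet-class] of `n` transactions with the verified
#'   constraint table attached as attribute `"manifest"`.
#' @export
buildTransactions <- function(constraints, n, stateSupport = 30L,
                              stateItem = "STATE=1") {
  items <- rep(list(character()), n)
  place <- function(tokens, at) {
    for (i in at) items[[i]] <<- union(items[[i]], tokens)
  }
  sets <- lapply(constraints$items, .splitKey)
  singles <- which(lengths(sets) == 1L &
                   vapply(sets, function(s) s[1] != stateItem, logical(1)))
  hasState <- any(vapply(sets, function(s) stateItem %in% s, logical(1)))
  if (hasState) place(stateItem, seq_len(stateSupport))

  for (i in singles) {
    tok <- sets[[i]][1]
    total <- constraints$count[i]
    if (!hasState) {  # no state block: plain prefix interval
      if (total > n)
        snValidationError(sprintf("constraint {%s}=%d exceeds n=%d",
                                  constraints$items[i], total, n))
      place(tok, seq_len(total))
      next
    }
    # in-state occupancy: the pair constraint {item, state} when present;
    # otherwise the tightest higher-order joint involving the state item
    # (under the nested-interval layout a triple count equals the smaller
    # in-state occupancy of its non-state members)
    pair <- match(.itemsetKey(c(tok, stateItem)), constraints$items)
    joint <- which(vapply(sets, function(s)
      tok %in% s && stateItem %in% s, logical(1)))
    inState <- if (!is.na(pair)) constraints$count[pair]
               else if (length(joint) > 0L) min(constraints$count[joint])
               else min(total, if (hasState) stateSupport else total)
    inState <- min(inState, total)
    outState <- total - inState
    if (inState > stateSupport || stateSupport + outState > n)
      snValidationError(sprintf(
        "constraint {%s}=%d infeasible at n=%d, stateSupport=%d",
        constraints$items[i], total, n, stateSupport))
    place(tok, seq_len(inState))
    if (outState > 0L) place(tok, stateSupport + seq_len(outState))
  }
  if (hasState && stateSupport < n)
    place("STATE=0", (stateSupport + 1L):n)

  tx <- transactionSet(sprintf("t%02d", seq_len(n)), items)
  # recount oracle: every constraint must hold exactly on the built set
  for (i in seq_len(nrow(constraints))) {
    got <- itemsetSupport(tx, .splitKey(constraints$items[i]))$count
    if (got != constraints$count[i])
      snValidationError(sprintf(
        "construction failure: {%s} counted %d, constraint requires %d",
        constraints$items[i], got, constraints$count[i]))
  }
  attr(tx, "manifest") <- constraints
  tx
}

#' Rebuild the rule-table transaction fixture
#'
#' End-to-end reconstruction: recover the transaction total from the
#' printed support percentages, invert the rule table into count
#' constraints, and build the deterministic transaction layout. Mining the
#' result at support >= 0.30 and confidence >= 0.85 reproduces every
#' unflagged printed support and confidence cell to two decimals.
#'
#' @param rows rule table, defaulting to [referenceRuleTable()].
#' @param n transaction total; by default recovered programmatically via
#'   [recoverDenominator()].
#' @param stateSupport see [buildTransactions()].
#' @return a [TransactionSet-class] with attributes `"manifest"` (the
#'   constraint table) and `"inversion"` (the annotated rule rows).
#' @examples
#' tx <- ruleTableFixture()
#' length(tx)  # 37
#' @export
ruleTableFixture <- function(rows = referenceRuleTable(), n = NULL,
                             stateSupport = 30L) {
  inv <- invertRuleTable(rows, n)
  tx <- buildTransactions(inv$constraints, inv$n, stateSupport)
  attr(tx, "inversion") <- inv$rows
  tx
}
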