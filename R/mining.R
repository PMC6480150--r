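# Class-association-rule mining: equal-width discretization of the feature
# table into items, and a levelwise Apriori search for all candidate class
# association rules meeting the support and confidence thresholds.
#
# Internal item coding: every (attribute, value) pair gets a unique integer
# id. Class items take the LOWEST ids so that, with itemsets kept sorted,
# the class item is always the first element; the standard prefix join of
# two frequent (k-1)-itemsets then generates every class-containing
# k-itemset whose subsets are frequent.

#' Fit an equal-width discretization scheme
#'
#' For each feature, the training range `[min, max]` is split into
#' `nBins` equal-width intervals coded 1 (very low) to 5 (very high).
#' Intervals are left-closed/right-open except the last, which is closed;
#' values outside the training range clip to the first or last bin.
#' Constant features cannot be binned and are dropped with a warning.
#'
#' @param training data.frame with a `label` column and feature columns.
#' @param features feature columns to use (default: all of
#'   [featureNames()] present in `training`).
#' @param nBins number of equal-width bins.
#' @return A list of class `"discretizationScheme"` with per-feature
#'   `breaks` (full break vectors of length `nBins + 1`) and `nBins`.
#' @examples
#' tab <- simulateFeatureTable(20, seed = 1)
#' sch <- fitDiscretizer(tab)
#' sch$breaks$Mean
#' @export
fitDiscretizer <- function(training, features = NULL, nBins = 5L) {
  if (is.null(features))
    features <- intersect(featureNames(), names(training))
  breaks <- list()
  for (f in features) {
    v <- training[[f]]
    if (!all(is.finite(v))) stop("fitDiscretizer: non-finite values in ", f)
    lo <- min(v); hi <- max(v)
    if (hi <= lo) {
      warning("fitDiscretizer: constant feature '", f, "' dropped")
      next
    }
    breaks[[f]] <- seq(lo, hi, length.out = nBins + 1L)
  }
  if (!length(breaks)) stop("fitDiscretizer: no usable features")
  structure(list(breaks = breaks, nBins = as.integer(nBins)),
            class = "discretizationScheme")
}

#' Discretize feature vectors into transactions
#'
#' Maps each retained feature to its bin code 1..nBins and the class label
#' to its class code (hypertensive = 1, normotensive = 2), yielding one
#' transaction per row: one item per attribute plus one class item.
#'
#' @param fv data.frame of feature vectors (rows) with the scheme's
#'   feature columns and, unless `requireLabel = FALSE`, a `label` column.
#' @param scheme a fitted [fitDiscretizer()] scheme.
#' @param requireLabel whether a class item is attached.
#' @return data.frame of integer bin codes, one column per feature plus
#'   (when labeled) a `class` column.
#' @export
transactionize <- function(fv, scheme, requireLabel = TRUE) {
  stopifnot(inherits(scheme, "discretizationScheme"))
  feats <- names(scheme$breaks)
  missing <- setdiff(feats, names(fv))
  if (length(missing))
    stop("transactionize: missing feature columns: ",
         paste(missing, collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(fv)))
  for (f in feats) {
    b <- scheme$breaks[[f]]
    code <- findInterval(fv[[f]], b, rightmost.closed = TRUE)
    out[[f]] <- as.integer(pmin(pmax(code, 1L), scheme$nBins))
  }
  if (requireLabel) {
    if (!"label" %in% names(fv))
      stop("transactionize: no label column")
    cc <- classCodes()[fv$label]
    if (anyNA(cc)) stop("transactionize: unknown class label")
    out$class <- as.integer(cc)
  }
  out
}

#' Support and confidence of a candidate class association rule
#'
#' `support = CandidateCount / |D|` and
#' `confidence = CandidateCount / RuleitemsCount`, where RuleitemsCount is
#' the number of transactions containing all antecedent items and
#' CandidateCount the number of those that also carry the consequent
#' class.
#'
#' @param antecedent named integer vector: feature name -> bin code.
#' @param consequent integer class code (1 or 2).
#' @param D transaction data.frame from [transactionize()] (with `class`).
#' @return List with `support`, `confidence`, `ruleItemsCount`,
#'   `candidateCount`.
#' @export
ruleSupportConfidence <- function(antecedent, consequent, D) {
  if (nrow(D) < 1L) stop("ruleSupportConfidence: empty transaction set")
  match_ante <- rep(TRUE, nrow(D))
  for (f in names(antecedent))
    match_ante <- match_ante & (D[[f]] == antecedent[[f]])
  ric <- sum(match_ante)
  cc <- sum(match_ante & D$class == consequent)
  list(support = cc / nrow(D),
       confidence = if (ric > 0) cc / ric else NA_real_,
       ruleItemsCount = ric, candidateCount = cc)
}

# ---- internal Apriori machinery --------------------------------------------

# Build the item universe for a transaction table: class items first.
.item_universe <- function(D) {
  feats <- setdiff(names(D), "class")
  classes <- sort(unique(D$class))
  attr_of <- character(0); val_of <- integer(0)
  for (cl in classes) { attr_of <- c(attr_of, "class"); val_of <- c(val_of, cl) }
  for (f in feats) {
    vals <- sort(unique(D[[f]]))
    attr_of <- c(attr_of, rep(f, length(vals)))
    val_of <- c(val_of, vals)
  }
  list(attr = attr_of, val = val_of,
       nClass = length(classes), feats = feats)
}

# Encode D as an n x k matrix of item ids (columns: class, then features).
.encode_transactions <- function(D, uni) {
  n <- nrow(D)
  cols <- c("class", uni$feats)
  M <- matrix(0L, n, length(cols))
  for (j in seq_along(cols)) {
    f <- cols[j]
    key <- which(uni$attr == f)
    M[, j] <- key[match(D[[f]], uni$val[key])]
  }
  colnames(M) <- cols
  M
}

# count transactions containing every item of each itemset (rows of `sets`)
.count_itemsets <- function(sets, M, attr_col) {
  if (!nrow(sets)) return(integer(0))
  n <- nrow(M)
  vapply(seq_len(nrow(sets)), function(i) {
    ids <- sets[i, ]
    ok <- rep(TRUE, n)
    for (id in ids) ok <- ok & (M[, attr_col[id]] == id)
    sum(ok)
  }, integer(1))
}

# prefix join: all pairs of rows agreeing on the first k-2 items,
# differing in the last; drops joins whose two last items share an attribute
.prefix_join <- function(Fk, attr_of) {
  k <- ncol(Fk)
  if (!nrow(Fk)) return(matrix(0L, 0, k + 1L))
  key <- if (k == 1L) rep("", nrow(Fk))
         else apply(Fk[, seq_len(k - 1L), drop = FALSE], 1, paste, collapse = ",")
  out <- vector("list", 0L)
  for (grp in split(seq_len(nrow(Fk)), key)) {
    if (length(grp) < 2L) next
    last <- Fk[grp, k]
    o <- order(last)
    grp <- grp[o]; last <- last[o]
    cmb <- utils::combn(seq_along(grp), 2L)
    keep <- attr_of[last[cmb[1, ]]] != attr_of[last[cmb[2, ]]]
    if (!any(keep)) next
    cmb <- cmb[, keep, drop = FALSE]
    pre <- Fk[grp[cmb[1, ]], seq_len(k - 1L), drop = FALSE]
    out[[length(out) + 1L]] <-
      cbind(pre, last[cmb[1, ]], last[cmb[2, ]])
  }
  if (!length(out)) return(matrix(0L, 0, k + 1L))
  do.call(rbind, out)
}

#' Mine all class association rules
#'
#' Levelwise Apriori rule generation: frequent 1-items seed the search;
#' candidate k-itemsets arise by joining frequent (k-1)-itemsets; only
#' itemsets containing exactly one class-derived item are candidate class
#' association rules; these are filtered first by minimum support and
#' then by minimum confidence, and the rules of all levels are pooled.
#' The result is exactly the set of rules `antecedent -> class` with
#' `support >= minSup` and `confidence >= minConf`.
#'
#' @param D transaction data.frame from [transactionize()] (feature
#'   columns of integer codes plus a `class` column).
#' @param minSup minimum support (fraction of transactions).
#' @param minConf minimum confidence.
#' @param maxLen optional cap on the number of items per rule (antecedent
#'   size + 1); `Inf` (default) mines all lengths. Low support thresholds
#'   make the search space blow up combinatorially; the cap bounds it.
#' @return data.frame with list-column `antecedent` (named integer
#'   vectors), and columns `class`, `support`, `confidence`, `nItems`,
#'   ordered by descending precedence (see [sortRules()]).
#' @examples
#' tab <- simulateFeatureTable(30, defaultEffectProfile(separation = 3), 1)
#' sch <- fitDiscretizer(tab)
#' rules <- mineCARs(transactionize(tab, sch), 0.3, 0.8, maxLen = 2)
#' head(rules[, c("class", "support", "confidence", "nItems")])
#' @export
mineCARs <- function(D, minSup = 0.3, minConf = 0.8, maxLen = Inf) {
  stopifnot(nrow(D) >= 1L, minSup > 0, minSup <= 1, minConf > 0, minConf <= 1)
  uni <- .item_universe(D)
  M <- .encode_transactions(D, uni)
  attr_col <- match(uni$attr, colnames(M))
  n <- nrow(D)

  counts1 <- .count_itemsets(matrix(seq_along(uni$attr), ncol = 1L), M, attr_col)
  F1 <- which(counts1 / n >= minSup)
  rules <- list()
  Fk <- matrix(F1, ncol = 1L)         # frequent 1-itemsets (class + feature)
  k <- 2L
  while (nrow(Fk) && k <= maxLen) {
    P <- .prefix_join(Fk, uni$attr)
    if (k == 2L) {
      # keep exactly one class item per candidate rule itemset
      isCls <- P <= uni$nClass
      P <- P[isCls[, 1] & !isCls[, 2], , drop = FALSE]
    }
    # class item ids are the smallest, so column 1 is the class item
    if (!nrow(P)) break
    cnt <- .count_itemsets(P, M, attr_col)
    keep <- cnt / n >= minSup
    Fk <- P[keep, , drop = FALSE]
    cnt <- cnt[keep]
    if (nrow(Fk)) {
      anteCnt <- .count_itemsets(Fk[, -1L, drop = FALSE], M, attr_col)
      conf <- cnt / anteCnt
      sel <- conf >= minConf
      if (any(sel)) {
        sets <- Fk[sel, , drop = FALSE]
        rules[[length(rules) + 1L]] <- data.frame(
          antecedent = I(lapply(seq_len(nrow(sets)), function(i) {
            ids <- sets[i, -1L]
            stats::setNames(uni$val[ids], uni$attr[ids])
          })),
          class = uni$val[sets[, 1L]],
          support = cnt[sel] / n,
          confidence = conf[sel],
          nItems = ncol(sets))
      }
    }
    k <- k + 1L
  }
  if (!length(rules)) {
    out <- data.frame(antecedent = I(list()), class = integer(0),
                      support = numeric(0), confidence = numeric(0),
                      nItems = integer(0))
    return(out)
  }
  out <- do.call(rbind, rules)
  rownames(out) <- NULL
  sortRules(out)
}
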