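# Database-coverage construction of the rule classifier, and prediction by
# first-match over the precedence-ordered rule list.

#' Sort class association rules by precedence
#'
#' Rule r_i precedes r_j when its confidence is higher; ties are broken by
#' higher support, then by more items (longer, more specific rules first);
#' remaining ties keep the input order (stable sort).
#'
#' @param rules data.frame of rules as produced by [mineCARs()].
#' @return The same data.frame, reordered.
#' @export
sortRules <- function(rules) {
  if (!nrow(rules)) return(rules)
  o <- order(-rules$confidence, -rules$support, -rules$nItems)
  out <- rules[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# does transaction row i of D contain every antecedent item?
.matches_antecedent <- function(ante, D) {
  ok <- rep(TRUE, nrow(D))
  for (f in names(ante)) ok <- ok & (D[[f]] == ante[[f]])
  ok
}

#' Build a CAR classifier by database coverage
#'
#' Iterates over the precedence-sorted rules; a rule is marked when it
#' correctly classifies at least one remaining training transaction
#' (antecedent contained in the transaction AND consequent equal to its
#' class). Marked rules are appended to the classifier and the
#' transactions they correctly classify are removed. The default class is
#' the majority class of the transactions left uncovered (ties favour the
#' hypertensive class -- in a screening setting a missed patient is the
#' costlier error); if every transaction is covered, the majority class
#' of the full training set is used.
#'
#' @param rules data.frame from [mineCARs()] (sorted or not; they are
#'   re-sorted here).
#' @param D training transaction data.frame from [transactionize()].
#' @param scheme the [fitDiscretizer()] scheme used to build `D` (stored
#'   in the model for prediction).
#' @param minSup,minConf the mining thresholds (stored for provenance).
#' @return A [CARClassifier-class].
#' @export
buildClassifier <- function(rules, D, scheme, minSup = 0.3, minConf = 0.8) {
  stopifnot(nrow(D) >= 1L, "class" %in% names(D))
  rules <- sortRules(rules)
  majority <- function(cls) {
    if (!length(cls)) return(NA_integer_)
    tab <- table(factor(cls, levels = c(1L, 2L)))
    if (tab[["1"]] >= tab[["2"]]) 1L else 2L
  }
  full_majority <- majority(D$class)
  remaining <- rep(TRUE, nrow(D))
  marked <- logical(nrow(rules))
  if (nrow(rules)) {
    for (i in seq_len(nrow(rules))) {
      if (!any(remaining)) break
      correct <- .matches_antecedent(rules$antecedent[[i]], D) &
        D$class == rules$class[i] & remaining
      if (any(correct)) {
        marked[i] <- TRUE
        remaining[correct] <- FALSE
      }
    }
  }
  dcls <- if (any(remaining)) majority(D$class[remaining]) else full_majority
  new("CARClassifier", rules = rules[marked, , drop = FALSE],
      defaultClass = dcls, scheme = unclass(scheme),
      minSup = minSup, minConf = minConf)
}

#' Predict classes for feature vectors
#'
#' Each subject is discretized with the model's training scheme; the
#' consequent of the first rule (in precedence order) whose antecedent is
#' contained in the subject's items is returned, or the default class
#' when no rule matches.
#'
#' @param object a [CARClassifier-class].
#' @param newdata data.frame of feature vectors (one row per subject), or
#'   an already-discretized transaction data.frame (`discretized = TRUE`).
#' @param discretized set `TRUE` when `newdata` already holds bin codes.
#' @return Integer vector of class codes (1 = hypertensive,
#'   2 = normotensive).
#' @export
setMethod("predict", "CARClassifier",
          function(object, newdata, discretized = FALSE) {
  scheme <- structure(object@scheme, class = "discretizationScheme")
  D <- if (discretized) newdata
       else transactionize(newdata, scheme, requireLabel = FALSE)
  n <- nrow(D)
  out <- rep(object@defaultClass, n)
  undecided <- rep(TRUE, n)
  rules <- object@rules
  if (nrow(rules)) {
    for (i in seq_len(nrow(rules))) {
      if (!any(undecided)) break
      hit <- .matches_antecedent(rules$antecedent[[i]], D) & undecided
      if (any(hit)) {
        out[hit] <- rules$class[i]
        undecided[hit] <- FALSE
      }
    }
  }
  as.integer(out)
})

#' Serialize a CAR classifier to JSON
#'
#' The model document carries the ordered marked rules, default class,
#' discretization break points, mining thresholds and a schema version;
#' [readCARClassifier()] restores a model that predicts identically.
#'
#' @param model a [CARClassifier-class].
#' @param path file path to write to.
#' @return `path`, invisibly.
#' @export
writeCARClassifier <- function(model, path) {
  doc <- list(
    schema = "bcgcar-model/1",
    defaultClass = model@defaultClass,
    minSup = model@minSup, minConf = model@minConf,
    scheme = model@scheme,
    rules = lapply(seq_len(nrow(model@rules)), function(i) {
      a <- model@rules$antecedent[[i]]
      list(antecedent = lapply(seq_along(a), function(j)
             list(feature = names(a)[j], bin = unname(a[j]))),
           class = model@rules$class[i],
           support = model@rules$support[i],
           confidence = model@rules$confidence[i])
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCARClassifier
#' @param path file path of a serialized model.
#' @export
readCARClassifier <- function(path) {
  doc <- jsonlite::read_json(path)
  rules <- data.frame(
    antecedent = I(lapply(doc$rules, function(r) {
      v <- vapply(r$antecedent, function(p) as.integer(p$bin), integer(1))
      names(v) <- vapply(r$antecedent, function(p) p$feature, character(1))
      v
    })),
    class = vapply(doc$rules, function(r) as.integer(r$class), integer(1)),
    support = vapply(doc$rules, function(r) as.numeric(r$support), numeric(1)),
    confidence = vapply(doc$rules, function(r) as.numeric(r$confidence),
                        numeric(1)))
  rules$nItems <- vapply(rules$antecedent, length, integer(1)) + 1L
  scheme <- list(
    breaks = lapply(doc$scheme$breaks, function(b) as.numeric(unlist(b))),
    nBins = as.integer(doc$scheme$nBins))
  new("CARClassifier", rules = rules,
      defaultClass = as.integer(doc$defaultClass), scheme = scheme,
      minSup = as.numeric(doc$minSup), minConf = as.numeric(doc$minConf))
}

#' Human-readable rule table
#'
#' Formats rules as a feature-by-rule table of bin codes 1-5, with "-"
#' for features absent from a rule's antecedent, mirroring how rule sets
#' are presented to clinicians.
#'
#' @param rules data.frame of rules (e.g. [classifierRules()] output).
#' @param features row order (default [featureNames()]).
#' @return character matrix, features as rows and rules as columns.
#' @export
ruleTable <- function(rules, features = featureNames()) {
  m <- matrix("-", length(features), nrow(rules),
              dimnames = list(features,
                              if (nrow(rules)) paste0("CAR", seq_len(nrow(rules)))
                              else character(0)))
  for (i in seq_len(nrow(rules))) {
    a <- rules$antecedent[[i]]
    m[names(a), i] <- as.character(a)
  }
  m
}
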