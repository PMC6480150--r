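# Precedence sorting, database-coverage construction, prediction,
# serialization.

mk_rules <- function(...) {
  rows <- list(...)
  data.frame(
    antecedent = I(lapply(rows, `[[`, "ante")),
    class = vapply(rows, `[[`, integer(1), "cls"),
    support = vapply(rows, `[[`, numeric(1), "sup"),
    confidence = vapply(rows, `[[`, numeric(1), "conf"),
    nItems = vapply(rows, function(r) length(r$ante) + 1L, integer(1)))
}

test_that("precedence is confidence, then support, then rule size, then stable", {
  r <- mk_rules(
    list(ante = c(A = 1L), cls = 1L, sup = 0.3, conf = 0.8),
    list(ante = c(B = 2L), cls = 2L, sup = 0.3, conf = 0.9),
    list(ante = c(C = 1L), cls = 1L, sup = 0.4, conf = 0.8),
    list(ante = c(A = 1L, B = 2L), cls = 2L, sup = 0.3, conf = 0.8),
    list(ante = c(D = 5L), cls = 1L, sup = 0.3, conf = 0.8))
  s <- sortRules(r)
  expect_equal(s$confidence[1], 0.9)                 # highest confidence first
  expect_equal(s$support[2], 0.4)                    # then support
  expect_equal(s$nItems[3], 3L)                      # then longer rule
  # stable for full ties: row 1 precedes row 5 (both 0.8/0.3/2 items)
  expect_equal(names(s$antecedent[[4]]), "A")
  expect_equal(names(s$antecedent[[5]]), "D")
})

test_that("database coverage reproduces a hand-simulated trace", {
  # eight transactions over attributes A, B with class 1/2
  D <- data.frame(A = c(1, 1, 1, 2, 2, 2, 1, 2),
                  B = c(1, 1, 2, 2, 2, 1, 2, 1),
                  class = c(1, 1, 1, 2, 2, 2, 2, 1))
  rules <- mk_rules(
    list(ante = c(A = 1L),         cls = 1L, sup = 3 / 8, conf = 0.75),
    list(ante = c(A = 1L, B = 2L), cls = 1L, sup = 1 / 8, conf = 0.50),
    list(ante = c(A = 1L, B = 1L), cls = 1L, sup = 2 / 8, conf = 1.00),
    list(ante = c(B = 1L),         cls = 1L, sup = 3 / 8, conf = 0.75),
    list(ante = c(A = 2L, B = 2L), cls = 2L, sup = 2 / 8, conf = 1.00),
    list(ante = c(A = 2L),         cls = 2L, sup = 3 / 8, conf = 0.75))
  sch <- structure(list(breaks = list(), nBins = 5L),
                   class = "discretizationScheme")
  model <- buildClassifier(rules, D, sch)
  got <- classifierRules(model)
  # hand trace: sorted order is {A1,B1}->1, {A2,B2}->2, {A1}->1, {B1}->1,
  # {A2}->2, {A1,B2}->1; coverage removes d1,d2 / d4,d5 / d3 / d8 / d6;
  # {A1,B2}->1 then matches only d7 whose class is 2, so it stays unmarked;
  # d7 is left and the default class is its class, 2.
  expect_equal(nrow(got), 5L)
  expect_equal(lapply(got$antecedent, identity),
               list(c(A = 1L, B = 1L), c(A = 2L, B = 2L),
                    c(A = 1L), c(B = 1L), c(A = 2L)))
  expect_equal(got$class, c(1L, 2L, 1L, 1L, 2L))
  expect_equal(defaultClass(model), 2L)
})

test_that("degenerate coverage cases: empty rule set, useless rule, full coverage", {
  D <- data.frame(A = c(1, 1, 2), class = c(1, 1, 2))
  sch <- structure(list(breaks = list(), nBins = 5L),
                   class = "discretizationScheme")
  empty <- mk_rules()[0, ]
  m0 <- buildClassifier(empty, D, sch)
  expect_equal(nrow(classifierRules(m0)), 0L)
  expect_equal(defaultClass(m0), 1L)                  # majority of D
  # a rule matching no transaction is never marked
  r <- mk_rules(list(ante = c(A = 9L), cls = 1L, sup = 0, conf = 1))
  expect_equal(nrow(classifierRules(buildClassifier(r, D, sch))), 0L)
  # full coverage: default falls back to the overall majority
  r2 <- mk_rules(list(ante = c(A = 1L), cls = 1L, sup = 2 / 3, conf = 1),
                 list(ante = c(A = 2L), cls = 2L, sup = 1 / 3, conf = 1))
  m2 <- buildClassifier(r2, D, sch)
  expect_equal(nrow(classifierRules(m2)), 2L)
  expect_equal(defaultClass(m2), 1L)
})

test_that("prediction is first-match over the ordered rules with a default", {
  D <- data.frame(A = c(1, 1, 2, 2), B = c(1, 1, 2, 2), class = c(1, 1, 2, 2))
  sch <- structure(list(breaks = list(), nBins = 5L),
                   class = "discretizationScheme")
  rules <- mk_rules(
    list(ante = c(A = 1L), cls = 1L, sup = 0.5, conf = 1.0),
    list(ante = c(B = 2L), cls = 2L, sup = 0.5, conf = 0.9))
  model <- buildClassifier(rules, D, sch)
  newD <- data.frame(A = c(1L, 2L, 3L), B = c(2L, 2L, 3L))
  pred <- predict(model, newD, discretized = TRUE)
  expect_equal(pred[1], 1L)   # matches both rules; the first in order wins
  expect_equal(pred[2], 2L)   # matches only the second rule
  expect_equal(pred[3], defaultClass(model))   # matches nothing
})

test_that("a serialized model predicts identically after reloading", {
  tab <- simulateFeatureTable(40, defaultEffectProfile(separation = 3),
                              seed = 17L)
  model <- trainCARClassifier(tab, minSup = 0.2, maxLen = 2)
  fresh <- simulateFeatureTable(30, defaultEffectProfile(separation = 3),
                                seed = 18L)
  path <- file.path(tempdir(), "model.json")
  writeCARClassifier(model, path)
  back <- readCARClassifier(path)
  expect_identical(predict(back, fresh), predict(model, fresh))
  expect_equal(defaultClass(back), defaultClass(model))
})

test_that("separable classes are learned and rendered as a rule table", {
  train <- simulateFeatureTable(64, defaultEffectProfile(separation = 3),
                                seed = 19L)
  test <- simulateFeatureTable(40, defaultEffectProfile(separation = 3),
                               seed = 20L)
  model <- trainCARClassifier(train, minSup = 0.2, maxLen = 3)
  pred <- predict(model, test)
  truth <- unname(classCodes()[test$label])
  expect_gte(mean(pred == truth), 0.9)
  # the classifier keeps at most as many rules as were mined
  sch <- fitDiscretizer(train)
  allRules <- mineCARs(transactionize(train, sch), 0.2, 0.8, maxLen = 3)
  expect_lte(nrow(classifierRules(model)), nrow(allRules))
  tabtxt <- ruleTable(classifierRules(model))
  expect_equal(rownames(tabtxt), featureNames())
  expect_true(all(tabtxt %in% c("-", "1", "2", "3", "4", "5")))
})
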