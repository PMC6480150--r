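# Discretization and Apriori rule mining.

test_that("equal-width discretizer places edges and handles boundaries", {
  tab <- data.frame(label = rep(c("hypertensive", "normotensive"), 3),
                    Mean = c(0, 2, 5, 7, 9, 10))
  sch <- fitDiscretizer(tab, features = "Mean")
  expect_equal(sch$breaks$Mean, c(0, 2, 4, 6, 8, 10))
  tx <- transactionize(data.frame(Mean = c(0, 10, 1.999, 2, 11, -5)),
                       sch, requireLabel = FALSE)
  expect_equal(tx$Mean, c(1L, 5L, 1L, 2L, 5L, 1L))  # min->1, max->5, clipping
  expect_warning(
    fitDiscretizer(data.frame(label = "hypertensive", Mean = c(1, 1, 1),
                              SDNN = c(1, 2, 3)),
                   features = c("Mean", "SDNN")),
    "constant")
})

test_that("transactions carry one item per feature plus the class item", {
  tab <- simulateFeatureTable(10, seed = 2L)
  sch <- fitDiscretizer(tab)
  tx <- transactionize(tab, sch)
  expect_equal(ncol(tx), length(featureNames()) + 1L)
  expect_true(all(unlist(tx[featureNames()]) %in% 1:5))
  expect_equal(tx$class, rep(c(1L, 2L), each = 10))
  # every feature at the training midpoint lands in the middle bin
  mid <- as.data.frame(lapply(sch$breaks, function(b) (b[1] + b[6]) / 2))
  expect_true(all(unlist(transactionize(mid, sch, requireLabel = FALSE)) == 3L))
  expect_error(transactionize(tab[, 1:4], sch, requireLabel = FALSE),
               "missing feature")
})

test_that("support and confidence follow their counting definitions", {
  # ten instances; three contain the antecedent, two of those the class
  D <- data.frame(A = c(1, 1, 1, 2, 2, 2, 1, 2, 2, 2),
                  B = c(3, 3, 3, 1, 1, 2, 2, 2, 3, 1),
                  class = c(5, 5, 6, 5, 6, 6, 6, 5, 6, 6))
  sc <- ruleSupportConfidence(c(A = 1, B = 3), 5, D)
  expect_equal(sc$ruleItemsCount, 3L)
  expect_equal(sc$candidateCount, 2L)
  expect_equal(sc$support, 0.20)
  expect_equal(sc$confidence, 2 / 3)
  # antecedent present in every transaction with the consequent class
  E <- data.frame(A = rep(1, 4), class = rep(1, 4))
  sc2 <- ruleSupportConfidence(c(A = 1), 1, E)
  expect_equal(c(sc2$support, sc2$confidence), c(1, 1))
  # random tables agree with exhaustive counting
  set.seed(10)
  for (r in 1:10) {
    D <- random_transactions(12, 3)
    ante <- c(A = sample(1:3, 1), B = sample(1:3, 1))
    cls <- sample(1:2, 1)
    ric <- sum(D$A == ante["A"] & D$B == ante["B"])
    cc <- sum(D$A == ante["A"] & D$B == ante["B"] & D$class == cls)
    sc <- ruleSupportConfidence(ante, cls, D)
    expect_equal(sc$ruleItemsCount, ric)
    expect_equal(sc$candidateCount, cc)
  }
})

test_that("the worked ten-instance example crosses the thresholds as described", {
  D <- data.frame(A = c(1, 1, 1, 2, 2, 2, 1, 2, 2, 2),
                  B = c(3, 3, 3, 1, 1, 2, 2, 2, 3, 1),
                  class = c(5, 5, 6, 5, 6, 6, 6, 5, 6, 6))
  key <- "A=1,B=3->5"
  found <- function(rules) {
    any(vapply(seq_len(nrow(rules)), function(i)
      rule_key(rules$antecedent[[i]], rules$class[i]) == key, logical(1)))
  }
  expect_true(found(mineCARs(D, minSup = 0.10, minConf = 0.60)))
  expect_false(found(mineCARs(D, minSup = 0.10, minConf = 0.70)))
})

test_that("the miner reproduces exhaustive enumeration on small tables", {
  set.seed(11)
  for (r in 1:25) {
    D <- random_transactions(sample(8:30, 1), sample(2:4, 1))
    minSup <- sample(c(0.1, 0.2, 0.3), 1)
    minConf <- sample(c(0.5, 0.7, 0.9), 1)
    mined <- mineCARs(D, minSup, minConf)
    oracle <- oracle_cars(D, minSup, minConf)
    keys <- if (nrow(mined))
      vapply(seq_len(nrow(mined)), function(i)
        rule_key(mined$antecedent[[i]], mined$class[i]), character(1))
    else character(0)
    expect_setequal(keys, as.character(names(oracle)))
    for (i in seq_len(nrow(mined))) {
      o <- oracle[[keys[i]]]
      expect_equal(mined$support[i], o$support)
      expect_equal(mined$confidence[i], o$confidence)
    }
  }
})

test_that("rule sets shrink monotonically in the thresholds and respect caps", {
  set.seed(12)
  D <- random_transactions(25, 4)
  keyset <- function(rules) {
    vapply(seq_len(nrow(rules)), function(i)
      rule_key(rules$antecedent[[i]], rules$class[i]), character(1))
  }
  base <- mineCARs(D, 0.1, 0.5)
  expect_true(all(keyset(mineCARs(D, 0.2, 0.5)) %in% keyset(base)))
  expect_true(all(keyset(mineCARs(D, 0.1, 0.7)) %in% keyset(base)))
  capped <- mineCARs(D, 0.1, 0.5, maxLen = 2)
  expect_true(all(capped$nItems <= 2))
  expect_setequal(keyset(capped), keyset(base)[base$nItems <= 2])
  # support must always bound confidence from below
  expect_true(all(base$support <= base$confidence + 1e-12))
})

test_that("an unsatisfiable support threshold yields an empty rule set", {
  set.seed(13)
  D <- random_transactions(10, 2)
  D$class <- rep(1:2, 5)   # no rule itemset can reach full support
  expect_equal(nrow(mineCARs(D, minSup = 1, minConf = 0.5)), 0L)
})
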