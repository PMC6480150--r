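# Metrics, stratified splitting, repeated evaluation, the t-test screen
# and the feature-group ablation.

test_that("metrics are exact rational functions of the confusion counts", {
  m <- classifierMetrics(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(m$acc, 0.7)
  expect_equal(m$pre, 0.75)
  expect_equal(m$rec, 0.6)
  perfect <- classifierMetrics(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(unlist(perfect), c(acc = 1, pre = 1, rec = 1))
  expect_equal(classifierMetrics(tp = 0, tn = 1, fp = 2, fn = 0)$pre, 0)
  expect_error(classifierMetrics(0, 0, 0, 0), "no evaluated")
})

test_that("stratified 2:1 splitting reproduces the 128-subject partition", {
  labels <- rep(c("hypertensive", "normotensive"), c(61, 67))
  sp <- stratifiedSplit(labels, seed = 5L)
  expect_equal(length(sp$train), 85L)
  expect_equal(length(sp$test), 43L)
  expect_equal(sum(labels[sp$train] == "hypertensive"), 41L)
  expect_equal(sum(labels[sp$train] == "normotensive"), 44L)
  expect_equal(sum(labels[sp$test] == "hypertensive"), 20L)
  expect_equal(sum(labels[sp$test] == "normotensive"), 23L)
  # deterministic, disjoint, exhaustive
  sp2 <- stratifiedSplit(labels, seed = 5L)
  expect_identical(sp, sp2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_error(stratifiedSplit(rep("hypertensive", 10)), "classes")
})

test_that("split proportions hold across class sizes", {
  set.seed(21)
  for (r in 1:10) {
    nh <- sample(5:60, 1); nn <- sample(5:60, 1)
    labels <- sample(rep(c("hypertensive", "normotensive"), c(nh, nn)))
    sp <- stratifiedSplit(labels, seed = r)
    expect_equal(length(sp$train), floor((nh + nn) * 2 / 3))
    frac_h <- sum(labels[sp$train] == "hypertensive") / nh
    expect_lt(abs(frac_h - 2 / 3), 0.12)
  }
})

test_that("one repeat of the harness equals a single manual split", {
  tab <- simulateFeatureTable(30, defaultEffectProfile(separation = 3),
                              seed = 22L)
  ev <- repeatedEvaluation(tab, minSup = 0.2, maxLen = 2, nRepeats = 1,
                           seed = 7L)
  sp <- stratifiedSplit(tab$label, seed = 7L)
  model <- trainCARClassifier(tab[sp$train, ], minSup = 0.2, maxLen = 2)
  pred <- predict(model, tab[sp$test, ])
  truth <- unname(classCodes()[tab$label[sp$test]])
  expect_equal(ev$mean[["acc"]], mean(pred == truth))
  expect_equal(nrow(ev$perSplit), 1L)
})

test_that("the t-test screen is calibrated under the null and powered under signal", {
  # null: identical class distributions; retained fraction ~ alpha
  null_profile <- defaultEffectProfile()
  null_profile$mean_h <- null_profile$mean_n
  set.seed(23)
  hits <- 0L; total <- 0L
  for (r in 1:60) {
    tab <- simulateFeatureTable(30, null_profile, seed = 1000L + r)
    sc <- ttestScreen(tab)
    hits <- hits + length(sc$retained)
    total <- total + sum(!is.na(sc$pvalues))
  }
  frac <- hits / total   # 840 null tests; 3 sigma of binomial ~ 0.023
  expect_lt(abs(frac - 0.05), 0.025)
  # strong signal: means 3 sd apart with 30 per class is always retained
  tab <- simulateFeatureTable(30, defaultEffectProfile(separation = 3),
                              seed = 24L)
  sc <- ttestScreen(tab)
  expect_setequal(sc$retained, featureNames())
  # constant features are skipped with a warning
  tab$Mean <- 1
  expect_warning(sc2 <- ttestScreen(tab), "constant")
  expect_false("Mean" %in% sc2$retained)
})

test_that("ablation accumulates the four feature groups in order", {
  expect_equal(unname(unlist(featureGroups())), featureNames())
  # signal only in the BCG fluctuation group
  prof <- defaultEffectProfile()
  prof$mean_h <- prof$mean_n
  bf <- prof$feature %in% featureGroups()$BF
  prof$mean_h[bf] <- prof$mean_n[bf] + 3 * prof$sd[bf]
  tab <- simulateFeatureTable(64, prof, seed = 25L)
  res <- ablation(tab, minSup = 0.2, maxLen = 2, nRepeats = 3, seed = 3L)
  expect_equal(res$combination,
               c("TD", "TD+FD", "TD+FD+ND", "TD+FD+ND+BF"))
  expect_lt(res$acc[1], 0.72)          # no usable signal in TD alone
  expect_gte(res$acc[4], 0.9)          # fluctuation features carry it
  expect_error(ablation(tab, groups = c("TD", "XX")), "unknown")
  # the full combination matches a direct run on all features
  full <- repeatedEvaluation(tab, minSup = 0.2, maxLen = 2, nRepeats = 3,
                             seed = 3L)
  expect_equal(res$acc[4], full$mean[["acc"]])
})
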