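# Independent reference implementations used to cross-check the package.
# These deliberately take the slow, literal route and share no code with
# the implementations under test.

# Sample entropy by explicit template comparison: for every ordered pair
# of template start positions i < j (both in 1..N-m), check the Chebyshev
# distance of the length-m and length-(m+1) templates against r.
oracle_sampen <- function(x, m = 2L, r_coeff = 0.15) {
  N <- length(x)
  r <- r_coeff * sd(x)
  nt <- N - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L) return(NA_real_)
  if (A == 0L) return(Inf)
  -log(A / B)
}

# Exhaustive class-association-rule enumeration: every antecedent is a
# non-empty subset of some transaction's feature items, paired with every
# class value; support/confidence by direct counting.
oracle_cars <- function(D, minSup, minConf) {
  feats <- setdiff(names(D), "class")
  classes <- sort(unique(D$class))
  n <- nrow(D)
  antes <- list()
  for (i in seq_len(n)) {
    for (sz in seq_along(feats)) {
      for (cols in utils::combn(feats, sz, simplify = FALSE)) {
        a <- vapply(cols, function(f) D[[f]][i], numeric(1))
        names(a) <- cols
        antes[[paste(cols, a, sep = "=", collapse = ",")]] <- a
      }
    }
  }
  out <- list()
  for (key in names(antes)) {
    a <- antes[[key]]
    hit <- rep(TRUE, n)
    for (f in names(a)) hit <- hit & D[[f]] == a[[f]]
    ric <- sum(hit)
    for (cl in classes) {
      cc <- sum(hit & D$class == cl)
      sup <- cc / n
      conf <- cc / ric
      if (sup >= minSup && conf >= minConf)
        out[[paste0(key, "->", cl)]] <-
          list(support = sup, confidence = conf)
    }
  }
  out
}

# canonical string key for a mined rule row, matching oracle_cars keys
rule_key <- function(ante, cls) {
  o <- order(names(ante))
  paste0(paste(names(ante)[o], ante[o], sep = "=", collapse = ","), "->", cls)
}

# a small random transaction table for property tests
random_transactions <- function(nTrans, nAttr, nVals = 3L, nClass = 2L) {
  D <- as.data.frame(lapply(seq_len(nAttr), function(j)
    sample.int(nVals, nTrans, replace = TRUE)))
  names(D) <- LETTERS[seq_len(nAttr)]
  D$class <- sample.int(nClass, nTrans, replace = TRUE)
  D
}
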