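# Raw weights of a single binary attribute realizing a 2x2 contingency table
# (rows = attribute value 0/1, cols = class T/F).
weights_of_table <- function(n00, n01, n10, n11, method) {
  x <- matrix(c(rep(0, n00 + n01), rep(1, n10 + n11)), ncol = 1,
              dimnames = list(NULL, "a"))
  y <- c(rep("T", n00), rep("F", n01), rep("T", n10), rep("F", n11))
  weight(x, y, method = method)$raw[["a"]]
}

test_that("entropy-family weights match the closed-form oracle on all small 2x2 tables", {
  methods <- c(info_gain = "ig", gain_ratio = "gain_ratio",
               chi_squared = "chi2", gini = "gini_gain",
               uncertainty = "su")
  grid <- expand.grid(n00 = 0:6, n01 = 0:6, n10 = 0:6, n11 = 0:6)
  grid <- grid[(grid$n00 + grid$n10) > 0 & (grid$n01 + grid$n11) > 0, ]
  # attribute must vary, else the weight is 0 by the constant rule
  varies <- (grid$n00 + grid$n01) > 0 & (grid$n10 + grid$n11) > 0
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    o <- oracle_contingency(g$n00, g$n01, g$n10, g$n11)
    for (m in names(methods)) {
      w <- weights_of_table(g$n00, g$n01, g$n10, g$n11, m)
      expected <- if (varies[i]) o[[methods[[m]]]] else 0
      worst <- max(worst, abs(w - expected))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("weighting reproduces hand-derived contingency examples", {
  # chi-squared of [[30,10],[10,30]]: all expected counts 20
  expect_equal(weights_of_table(30, 10, 10, 30, "chi_squared"), 20.0)
  # binary attribute identical to a balanced class: IG = 1 bit, SU = 1
  expect_equal(weights_of_table(10, 0, 0, 10, "info_gain"), 1.0)
  expect_equal(weights_of_table(10, 0, 0, 10, "uncertainty"), 1.0)
  # perfect binary split of a balanced class: Gini gain 0.5
  expect_equal(weights_of_table(10, 0, 0, 10, "gini"), 0.5)
  # independence: all four cells equal
  for (m in c("info_gain", "chi_squared", "gini", "correlation")) {
    expect_equal(weights_of_table(5, 5, 5, 5, m), 0,
                 tolerance = 1e-12)
  }
})

test_that("relief matches the brute-force oracle exactly", {
  # worked 1-D example: hits at distance 0.1; misses at 0.8 or 0.9
  x <- matrix(c(0, 0.1, 0.9, 1.0), ncol = 1, dimnames = list(NULL, "a"))
  y <- c("T", "T", "F", "F")
  expect_equal(weight(x, y, method = "relief")$raw[["a"]], 0.75)
  expect_equal(oracle_relief(x, y)[1], 0.75)

  set.seed(17)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    p <- sample(2:5, 1)
    x <- matrix(runif(n * p), n, p,
                dimnames = list(NULL, paste0("a", 1:p)))
    y <- sample(c("T", "F"), n, replace = TRUE, prob = c(0.6, 0.4))
    if (min(table(y)) < 2) next
    expect_equal(unname(weight(x, y, method = "relief")$raw),
                 oracle_relief(x, y), tolerance = 1e-12)
  }
})

test_that("normalization divides by the maximum and passes zero vectors", {
  wv <- normalize_weights(c(a = 2, b = 1, c = 0))
  expect_equal(unname(wv$weights), c(1, 0.5, 0))
  z <- normalize_weights(c(a = 0, b = 0))
  expect_equal(unname(z$weights), c(0, 0))
  expect_error(normalize_weights(c(a = NaN, b = 1)), "a")
  set.seed(3)
  for (i in 1:10) {
    raw <- runif(6)
    expect_equal(max(normalize_weights(raw)$weights), 1)
  }
})

test_that("selection is strictly greater than the threshold", {
  wv <- normalize_weights(c(a = 0.6, b = 0.5, c = 0.4) * 2) # max-normalizes
  # construct directly instead: weights exactly 0.6/0.5/0.4
  wv <- structure(list(method = "custom", raw = c(a = .6, b = .5, c = .4),
                       weights = c(a = .6, b = .5, c = .4)),
                  class = "weight_vector")
  sel <- select_attributes(wv, 0.5)
  expect_equal(sel$selected, "a")
  expect_equal(attr(sel, "at_threshold"), "b")

  all1 <- structure(list(method = "m", raw = c(a = 1, b = 1),
                         weights = c(a = 1, b = 1)), class = "weight_vector")
  expect_equal(select_attributes(all1)$selected, c("a", "b"))

  zero <- structure(list(method = "m", raw = c(a = 0), weights = c(a = 0)),
                    class = "weight_vector")
  expect_warning(sel0 <- select_attributes(zero), "no attribute")
  expect_equal(length(sel0$selected), 0)
})

test_that("every method yields weights in [0,1] with max 1 when nonzero", {
  set.seed(23)
  n <- 40
  x <- cbind(sig = c(rnorm(n / 2, 0), rnorm(n / 2, 2)),
             noise1 = rnorm(n), noise2 = runif(n),
             const = rep(0.5, n))
  x <- apply(x, 2, function(c) if (max(c) > min(c))
    (c - min(c)) / (max(c) - min(c)) else c * 0 + 0.5)
  y <- rep(c("T", "F"), each = n / 2)
  for (m in WEIGHTING_METHODS) {
    wv <- weight(x, y, method = m)
    expect_true(all(wv$weights >= 0 & wv$weights <= 1), info = m)
    if (any(wv$raw > 0)) expect_equal(max(wv$weights), 1, info = m)
    expect_equal(wv$weights[["const"]], 0, info = m)
    if (!m %in% c("deviation", "pca", "rule_oner")) {
      expect_gt(wv$weights[["sig"]], wv$weights[["noise1"]])
    }
  }
})

test_that("class-conditional methods reject single-class labels", {
  x <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  for (m in c("info_gain", "chi_squared", "relief", "svm", "correlation")) {
    expect_error(weight(x, rep("T", 10), method = m), "class",
                 ignore.case = TRUE)
  }
  # class-free methods still work
  expect_s3_class(weight(x, rep("T", 10), method = "deviation"),
                  "weight_vector")
  expect_s3_class(weight(x, rep("T", 10), method = "pca"), "weight_vector")
})

test_that("correlation weighting is invariant to attribute reflection", {
  set.seed(29)
  a <- runif(30)
  y <- sample(c("T", "F"), 30, replace = TRUE)
  x <- cbind(a = a, b = 1 - a)
  wv <- weight(x, y, method = "correlation")
  expect_equal(wv$raw[["a"]], wv$raw[["b"]], tolerance = 1e-12)
})

test_that("adding class-copy attributes never demotes a perfect predictor", {
  set.seed(31)
  y <- rep(c("T", "F"), each = 15)
  perfect <- as.numeric(y == "T")
  noise <- matrix(runif(60), 30, 2)
  x1 <- cbind(perfect = perfect, noise)
  x2 <- cbind(perfect = perfect, noise, copy1 = perfect, copy2 = perfect)
  colnames(x1) <- c("perfect", "n1", "n2")
  colnames(x2) <- c("perfect", "n1", "n2", "copy1", "copy2")
  for (m in c("info_gain", "uncertainty", "gini", "chi_squared",
              "correlation")) {
    r1 <- rank(-weight(x1, y, method = m)$weights)[["perfect"]]
    r2 <- rank(-weight(x2, y, method = m)$weights,
               ties.method = "min")[["perfect"]]
    expect_lte(r2, r1, label = m)
  }
})

test_that("the OneR rule weighting follows its leave-one-feature-out definition", {
  set.seed(37)
  y <- rep(c("T", "F"), each = 10)
  good <- as.numeric(y == "T") # zero OneR error
  weak <- c(runif(10, 0, 0.6), runif(10, 0.4, 1)) # some error
  x <- cbind(good = good, weak = weak, junk = runif(20))
  wv <- weight(x, y, method = "rule_oner")
  # removing 'good' leaves only imperfect rules: highest weight
  expect_equal(names(which.max(wv$raw)), "good")
  # accuracy fallback mode ranks by own-rule accuracy
  wacc <- weight(x, y, method = "rule_oner",
                 config = weighting_config(oner_mode = "accuracy"))
  expect_equal(names(which.max(wacc$raw)), "good")
  expect_equal(wacc$raw[["good"]], 1)
})

test_that("the suite runs all eleven methods and tolerates failures", {
  set.seed(41)
  n <- 30
  x <- cbind(sig = c(runif(20, 0, 0.4), runif(10, 0.6, 1)),
             n1 = runif(n), n2 = runif(n))
  ft <- feature_table(paste0("r", 1:n), x,
                      labels = c(rep("T", 20), rep("F", 10)))
  suite <- suppressWarnings(weighting_suite(ft))
  expect_equal(names(suite), WEIGHTING_METHODS)
  ok <- vapply(suite, function(s) is.null(s$error), logical(1))
  expect_true(all(ok))
  expect_true(all(vapply(suite[ok], function(s)
    inherits(s$weights, "weight_vector"), logical(1))))
})
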