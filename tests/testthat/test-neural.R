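test_that("the fold-size rule reproduces the 2057-record scheme exactly", {
  folds <- make_cv_folds(2057, 10, seed = 1)
  sizes <- lengths(folds)
  expect_equal(unname(sizes), c(rep(206, 9), 203))
  expect_equal(sort(unlist(folds)), 1:2057)

  even <- make_cv_folds(10, 5, seed = 2)
  expect_equal(unname(lengths(even)), rep(2, 5))

  set.seed(3)
  for (i in 1:20) {
    n <- sample(20:500, 1)
    k <- sample(2:10, 1)
    if (n < k) next
    f <- make_cv_folds(n, k, seed = i)
    expect_equal(length(f), k)
    expect_equal(sort(unlist(f)), seq_len(n))
  }
  expect_error(make_cv_folds(5, 10), "n >= k")
})

test_that("MLP reaches near-perfect training accuracy on separable data", {
  d <- make_separable_data(n = 200, margin = 0.2, seed = 5)
  m <- train_mlp(d$x, d$labels, hidden = c(10, 5),
                 config = training_config(seed = 7, epochs = 300,
                                          learning_rate = 0.5,
                                          val_fraction = 0))
  acc <- mean(net_predict(m, d$x) == d$labels)
  expect_gte(acc, 0.99)
  # same seed gives identical weights
  m2 <- train_mlp(d$x, d$labels, hidden = c(10, 5),
                  config = training_config(seed = 7, epochs = 300,
                                           learning_rate = 0.5,
                                           val_fraction = 0))
  expect_identical(m$net$W, m2$net$W)
})

test_that("training loss decreases on separable data with full-batch descent", {
  d <- make_separable_data(n = 100, margin = 0.3, seed = 6)
  m <- train_mlp(d$x, d$labels, hidden = 5,
                 config = training_config(seed = 1, epochs = 150,
                                          learning_rate = 0.3,
                                          batch_size = 100, val_fraction = 0))
  tr <- m$loss_trace
  expect_lt(tr[length(tr)], tr[1])
  expect_true(all(diff(tr) < 1e-3)) # monotone up to numerical tolerance
})

test_that("an untrained net with zero output weights is maximally uncertain", {
  d <- make_separable_data(n = 20, seed = 8)
  m <- train_mlp(d$x, d$labels, hidden = 4,
                 config = training_config(seed = 1, epochs = 1,
                                          val_fraction = 0))
  m$net$W[[2]][] <- 0
  m$net$b[[2]][] <- 0
  p <- net_predict(m, d$x, type = "prob")
  expect_true(all(abs(p - 0.5) < 1e-12))
})

test_that("Elman networks train and degenerate exactly to the MLP", {
  d <- make_separable_data(n = 200, margin = 0.2, seed = 9)
  e <- train_elman(d$x, d$labels, hidden = c(10, 5),
                   config = training_config(seed = 7, epochs = 300,
                                            learning_rate = 0.5,
                                            val_fraction = 0))
  expect_gte(mean(net_predict(e, d$x) == d$labels), 0.99)
  e2 <- train_elman(d$x, d$labels, hidden = c(10, 5),
                    config = training_config(seed = 7, epochs = 300,
                                             learning_rate = 0.5,
                                             val_fraction = 0))
  expect_identical(e$net$W, e2$net$W)

  # zero context weights + one presentation = the plain MLP, exactly
  m <- train_mlp(d$x, d$labels, hidden = c(10, 5),
                 config = training_config(seed = 7, epochs = 50,
                                          val_fraction = 0))
  deg <- elman_from_mlp(m)
  expect_identical(net_predict(deg, d$x, type = "prob"),
                   net_predict(m, d$x, type = "prob"))
})

test_that("cross-validation reports k rows plus averages with consistent sizes", {
  d <- make_separable_data(n = 120, seed = 10)
  perfect <- function(x, y) NULL
  predict_rule <- function(model, x) ifelse(x[, "x1"] < 0.5, "T", "F")
  rep <- cross_validate(d$x, d$labels, trainer = perfect,
                        predict_fn = predict_rule, k = 10, seed = 4)
  expect_equal(nrow(rep$folds), 10)
  expect_true(all(rep$folds$n_train + rep$folds$n_test == 120))
  expect_equal(rep$averages$overall, 1.0)
  expect_equal(rep$averages$accuracy_T, 1.0)

  # majority stub on 75/25 labels: overall ~ 0.75, minority accuracy 0
  y <- c(rep("T", 90), rep("F", 30))
  x <- matrix(runif(240), 120, 2, dimnames = list(NULL, c("x1", "x2")))
  stub <- cross_validate(x, y, trainer = function(x, y) NULL,
                         predict_fn = function(m, x)
                           rep("T", nrow(x)), k = 10, seed = 4)
  expect_equal(stub$averages$overall, 0.75, tolerance = 0.05)
  expect_equal(stub$averages$accuracy_F, 0)
})

test_that("stepwise 1-p screening matches aov p-values and label thresholds", {
  set.seed(12)
  n <- 60
  y <- rep(c("T", "F"), each = n / 2)
  x <- cbind(strong = c(rnorm(n / 2, 0), rnorm(n / 2, 1.5)),
             none = rnorm(n))
  rep <- stepwise_select(x, y)
  for (a in colnames(x)) {
    ref <- summary(aov(x[, a] ~ factor(y)))[[1]][["Pr(>F)"]][1]
    expect_equal(rep$p_value[rep$attribute == a], ref, tolerance = 1e-10)
  }
  expect_equal(rep$label[rep$attribute == "strong"], "important")
  expect_true(all(rep$importance == 1 - rep$p_value))
  # constant attribute inside both classes: p = 1, importance 0
  xc <- cbind(const = rep(1, n), strong = x[, "strong"])
  rc <- stepwise_select(xc, y)
  expect_equal(rc$importance[rc$attribute == "const"], 0)
})

test_that("a class-independent attribute is rarely called important", {
  set.seed(14)
  y <- rep(c("T", "F"), each = 30)
  labels <- replicate(40, {
    x <- cbind(a = rnorm(60))
    stepwise_select(x, y)$label[1]
  })
  # p is uniform under the null: 'important' needs p < 0.05
  expect_lt(mean(labels == "important"), 0.35)
  expect_gt(mean(labels == "unimportant"), 0.5)
})

test_that("feature-selected and full-table CV accuracies agree closely", {
  rec <- generate_dataset(default_thermo_config(seed = 11))
  ft <- featurize(rec)
  cleaned <- clean(ft)
  norm <- apply_min_max(cleaned$table, fit_min_max(cleaned$table))
  sw <- stepwise_select(norm)
  important <- sw$attribute[sw$label == "important"]
  expect_gt(length(important), 2)
  cfg <- training_config(seed = 3, epochs = 200, learning_rate = 0.5,
                         val_fraction = 0)
  run_cv <- function(tab) {
    cross_validate(tab, trainer = function(x, y)
      train_mlp(x, y, hidden = c(10, 5), config = cfg), k = 10, seed = 5)
  }
  cv_full <- run_cv(norm)
  cv_sel <- run_cv(ft_select(norm, important))
  expect_lt(abs(cv_full$averages$overall - cv_sel$averages$overall), 0.05)
})
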