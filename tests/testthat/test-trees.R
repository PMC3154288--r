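all_criteria <- c("gain_ratio", "info_gain", "gini_index", "accuracy")

planted_table <- function(seed = 1, n = 40) {
  set.seed(seed)
  x <- cbind(sig = c(runif(n / 2, 0.05, 0.4), runif(n / 2, 0.6, 0.95)),
             noise = runif(n))
  list(x = x, y = rep(c("T", "F"), each = n / 2))
}

test_that("pure input yields a single leaf", {
  x <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  tr <- induce_tree(x, rep("T", 10))
  expect_equal(tr$root$type, "leaf")
  expect_equal(tr$root$class, "T")
  expect_equal(sum(tr$root$counts), 10)
})

test_that("a planted threshold is recovered at depth one", {
  d <- planted_table()
  for (cr in all_criteria) {
    tr <- induce_tree(d$x, d$y, tree_config(criterion = cr))
    expect_equal(tr$root$attribute, "sig", label = cr)
    expect_gt(tr$root$threshold, 0.4)
    expect_lt(tr$root$threshold, 0.6)
    expect_equal(unname(predict_tree(tr, d$x)), d$y)
  }
})

test_that("the chosen root split matches exhaustive search on random tables", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    p <- sample(2:5, 1)
    x <- matrix(round(runif(n * p), 2), n, p,
                dimnames = list(NULL, paste0("a", 1:p)))
    y <- sample(c("T", "F"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    cr <- sample(all_criteria, 1)
    tr <- induce_tree(x, y, tree_config(criterion = cr, max_depth = 1,
                                        min_gain = 0))
    oracle <- oracle_best_split_gain(x, y, cr)
    if (tr$root$type == "leaf") {
      expect_lte(oracle, 1e-12)
    } else {
      expect_equal(tr$root$gain, oracle, tolerance = 1e-12,
                   label = paste(cr, "rep", rep))
    }
  }
})

test_that("decision stumps are the root split and cannot solve XOR", {
  d <- planted_table(seed = 2)
  st <- decision_stump(d$x, d$y)
  full <- induce_tree(d$x, d$y, tree_config("gain_ratio"))
  expect_equal(st$root$attribute, full$root$attribute)
  expect_equal(st$root$threshold, full$root$threshold)
  expect_equal(decision_stump(d$x[1:20, ], rep("T", 20))$root$type, "leaf")

  xor_x <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1)) +
    matrix(runif(8, 0, 0.01), 4, 2)
  colnames(xor_x) <- c("a", "b")
  xor_y <- c("T", "F", "F", "T")
  st_xor <- decision_stump(xor_x, xor_y, criterion = "accuracy")
  acc <- mean(predict_tree(st_xor, xor_x) == xor_y)
  expect_lte(acc, 0.75)
})

test_that("prediction descends deterministically and checks attributes", {
  d <- planted_table(seed = 3)
  tr <- induce_tree(d$x, d$y)
  leaf_only <- induce_tree(d$x[1:5, ], rep("T", 5))
  expect_equal(unname(predict_tree(leaf_only, d$x[1:3, ])),
               rep("T", 3))
  # boundary goes left
  manual <- structure(list(root = list(
    type = "node", attribute = "a", threshold = 0.5,
    left = list(type = "leaf", class = "T", counts = c(T = 1, F = 0)),
    right = list(type = "leaf", class = "F", counts = c(T = 0, F = 1)),
    counts = c(T = 1, F = 1)),
    config = tree_config(), n = 2), class = "tree_model")
  expect_equal(predict_tree(manual, c(a = 0.5)), "T")
  expect_equal(predict_tree(manual, c(a = 0.7)), "F")
  expect_error(predict_tree(manual, c(b = 1)), "a")
})

test_that("random forests are seeded and degenerate to a single tree", {
  d <- planted_table(seed = 4)
  f1 <- random_forest(d$x, d$y, n_trees = 11, seed = 9)
  f2 <- random_forest(d$x, d$y, n_trees = 11, seed = 9)
  expect_identical(predict_tree(f1, d$x), predict_tree(f2, d$x))

  single <- random_forest(d$x, d$y, n_trees = 1, seed = 1,
                          mtry = ncol(d$x), bootstrap = FALSE)
  plain <- induce_tree(d$x, d$y)
  expect_equal(predict_tree(single, d$x), predict_tree(plain, d$x))

  # forest fit is at least as good as a depth-limited single tree here
  shallow <- induce_tree(d$x, d$y, tree_config(max_depth = 1))
  expect_gte(mean(predict_tree(f1, d$x) == d$y),
             mean(predict_tree(shallow, d$x) == d$y))
})

test_that("tree models survive a JSON round trip", {
  d <- planted_table(seed = 5)
  tr <- induce_tree(d$x, d$y)
  path <- tempfile(fileext = ".json")
  tree_save(tr, path)
  back <- tree_load(path)
  expect_equal(predict_tree(back, d$x), predict_tree(tr, d$x))
  expect_equal(back$root$threshold, tr$root$threshold)
})

test_that("published stump and parallel-tree rules reproduce the printed branches", {
  expect_equal(published_rule_predict("stump_gainratio",
                                      c(dipep_freq_QN = 0.6)), "F")
  expect_equal(published_rule_predict("stump_gainratio",
                                      c(dipep_freq_QN = 0.5)), "T")
  expect_equal(published_rule_predict("parallel_2level",
    c(aa_pct_E = 0.4, class_freq_hydrophilic = 0.2)), "T")
  expect_equal(published_rule_predict("parallel_2level",
    c(aa_pct_E = 0.2, class_freq_hydrophilic = 0.6)), "F")
  expect_equal(published_rule_predict("parallel_2level",
    c(aa_pct_E = 0.2, class_freq_hydrophilic = 0.5)), "T")
})

test_that("published forest and gain-ratio tree rules reproduce the printed branches", {
  expect_equal(published_rule_predict("forest_gini_fig1",
    c(dipep_freq_NQ = 0.04, dipep_freq_NT = 0.9)), "T")
  expect_equal(published_rule_predict("forest_gini_fig1",
    c(dipep_freq_NQ = 0.06, dipep_freq_NT = 0.02)), "T")
  expect_equal(published_rule_predict("forest_gini_fig1",
    c(dipep_freq_NQ = 0.06, dipep_freq_NT = 0.05)), "undetermined")
  expect_equal(published_rule_predict("tree_gainratio_fig2",
    c(class_freq_hydrophilic = 0.7, aa_pct_Q = 0.5)), "F")
  expect_equal(published_rule_predict("tree_gainratio_fig2",
    c(class_freq_hydrophilic = 0.5, aa_pct_Q = 0.1)), "T")
  expect_equal(published_rule_predict("tree_gainratio_fig2",
    c(class_freq_hydrophilic = 0.5, aa_pct_Q = 0.3)), "undetermined")
})

test_that("published rules are total and never guess unprinted branches", {
  set.seed(11)
  grid <- as.matrix(expand.grid(v1 = seq(0, 1, 0.1), v2 = seq(0, 1, 0.1)))
  specs <- list(
    stump_gainratio = c("dipep_freq_QN", "dipep_freq_NT"),
    parallel_2level = c("aa_pct_E", "class_freq_hydrophilic"),
    forest_gini_fig1 = c("dipep_freq_NQ", "dipep_freq_NT"),
    tree_gainratio_fig2 = c("class_freq_hydrophilic", "aa_pct_Q"))
  for (m in names(specs)) {
    g <- grid
    colnames(g) <- specs[[m]]
    out <- published_rule_predict(m, g)
    expect_true(all(out %in% c("T", "F", "undetermined")), label = m)
  }
  expect_error(published_rule_predict("stump_gainratio", c(aa_pct_E = 1)),
               "dipep_freq_QN")
})
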