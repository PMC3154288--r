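# Decision-tree induction for binary T/F classification over numeric
# attributes on the [0,1] normalized scale. Candidate thresholds are the
# midpoints between consecutive distinct sorted values; the convention is
# "<= goes left". Ties between equally good splits are broken by schema
# (column) order, then by the lower threshold; a tied majority leaf is
# labelled T (the majority class of the study design). Also included: the
# four published threshold rule models as executable classifiers.

#' Tree induction configuration
#'
#' @param criterion Split criterion: `"gain_ratio"`, `"info_gain"`,
#'   `"gini_index"` or `"accuracy"` (training-accuracy gain of the split).
#' @param max_depth Maximum tree depth (root split = depth 1).
#' @param min_leaf Minimum records per leaf.
#' @param min_gain Minimum criterion gain to accept a split (pre-pruning;
#'   no other pruning is applied).
#' @return A `tree_config` list.
#' @export
tree_config <- function(criterion = c("gain_ratio", "info_gain",
                                      "gini_index", "accuracy"),
                        max_depth = 20, min_leaf = 1, min_gain = 1e-3) {
  criterion <- match.arg(criterion)
  stopifnot(max_depth >= 1, min_leaf >= 1, min_gain >= 0)
  structure(list(criterion = criterion, max_depth = max_depth,
                 min_leaf = min_leaf, min_gain = min_gain),
            class = "tree_config")
}

.h2 <- function(a, b) {
  tot <- a + b
  p <- ifelse(tot > 0, a / tot, 0)
  q <- 1 - p
  term <- function(z) ifelse(z > 0, -z * log2(z), 0)
  term(p) + term(q)
}

.g2 <- function(a, b) {
  tot <- a + b
  p <- ifelse(tot > 0, a / tot, 0)
  1 - p^2 - (1 - p)^2
}

# Best split of one attribute: returns gain and threshold (first/lowest
# threshold among maxima), or NULL when no admissible cut exists.
.best_split_one <- function(x, yT, criterion, min_leaf) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- yT[ord]
  cut_ok <- which(xs[-n] < xs[-1])
  if (length(cut_ok) == 0) return(NULL)
  cumT <- cumsum(ys)
  nT <- cumT[n]
  nF <- n - nT
  i <- cut_ok
  nL <- i
  nR <- n - i
  ok <- nL >= min_leaf & nR >= min_leaf
  if (!any(ok)) return(NULL)
  i <- i[ok]; nL <- nL[ok]; nR <- nR[ok]
  TL <- cumT[i]; FL <- nL - TL
  TR <- nT - TL; FR <- nR - TR
  gain <- switch(criterion,
    info_gain = .h2(nT, nF) - (nL / n) * .h2(TL, FL) - (nR / n) * .h2(TR, FR),
    gain_ratio = {
      ig <- .h2(nT, nF) - (nL / n) * .h2(TL, FL) - (nR / n) * .h2(TR, FR)
      hs <- .h2(nL, nR)
      ifelse(hs > 0, ig / hs, 0)
    },
    gini_index = .g2(nT, nF) - (nL / n) * .g2(TL, FL) - (nR / n) * .g2(TR, FR),
    accuracy = (pmax(TL, FL) + pmax(TR, FR)) / n - max(nT, nF) / n
  )
  best <- which.max(gain) # first maximum = lowest threshold
  list(gain = gain[best], threshold = (xs[i[best]] + xs[i[best] + 1]) / 2)
}

.leaf <- function(yT) {
  nT <- sum(yT)
  nF <- length(yT) - nT
  list(type = "leaf", class = if (nT >= nF) "T" else "F",
       counts = c(T = nT, F = nF))
}

.grow <- function(x, yT, config, depth, mtry = NULL) {
  n <- length(yT)
  nT <- sum(yT)
  if (nT == 0 || nT == n || depth > config$max_depth || n < 2 * config$min_leaf) {
    return(.leaf(yT))
  }
  cols <- seq_len(ncol(x))
  if (!is.null(mtry) && mtry < length(cols)) {
    cols <- sort(sample(cols, mtry))
  }
  best <- NULL
  for (j in cols) {
    s <- .best_split_one(x[, j], yT, config$criterion, config$min_leaf)
    if (!is.null(s) && (is.null(best) || s$gain > best$gain + 1e-12)) {
      best <- c(s, list(attribute = colnames(x)[j], col = j))
    }
  }
  if (is.null(best) || best$gain < config$min_gain) return(.leaf(yT))
  left <- x[, best$col] <= best$threshold
  list(type = "node", attribute = best$attribute, threshold = best$threshold,
       gain = best$gain, counts = c(T = nT, F = n - nT),
       left = .grow(x[left, , drop = FALSE], yT[left], config, depth + 1, mtry),
       right = .grow(x[!left, , drop = FALSE], yT[!left], config, depth + 1,
                     mtry))
}

#' Induce a decision tree
#'
#' Greedy top-down induction over numeric attributes with binary T/F labels.
#'
#' @param table A `feature_table` or numeric matrix of normalized values.
#' @param labels `"T"`/`"F"` labels (taken from a `feature_table` when
#'   `NULL`).
#' @param config A [tree_config()].
#' @return A `tree_model`: nested node/leaf structure plus the config.
#' @export
induce_tree <- function(table, labels = NULL, config = tree_config()) {
  if (inherits(table, "feature_table")) {
    x <- table$values
    if (is.null(labels)) labels <- table$labels
  } else {
    x <- as.matrix(table)
    if (is.null(colnames(x))) colnames(x) <- paste0("attr", seq_len(ncol(x)))
  }
  if (nrow(x) == 0) stop("empty table")
  if (anyNA(labels) || !all(labels %in% c("T", "F"))) {
    stop("labels must be complete 'T'/'F'")
  }
  root <- .grow(x, labels == "T", config, depth = 1)
  structure(list(root = root, config = config, n = nrow(x)),
            class = "tree_model")
}

#' Decision stump (depth-1 tree)
#'
#' @inheritParams induce_tree
#' @param criterion Split criterion, as in [tree_config()].
#' @return A `tree_model` with at most one split.
#' @export
decision_stump <- function(table, labels = NULL, criterion = "gain_ratio") {
  induce_tree(table, labels, tree_config(criterion = criterion, max_depth = 1))
}

#' Random forest of threshold trees
#'
#' Bootstrap-resampled trees with `mtry = ceiling(sqrt(p))` attributes
#' sampled per split and majority-vote prediction; fully seeded. With
#' `n_trees = 1`, `bootstrap = FALSE` and `mtry = p` the forest degenerates
#' to [induce_tree()].
#'
#' @inheritParams induce_tree
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @param mtry Attributes sampled per split (default `ceiling(sqrt(p))`).
#' @param bootstrap Draw a bootstrap sample per tree (default `TRUE`).
#' @return A `forest_model`: list of `tree_model`s plus the config.
#' @export
random_forest <- function(table, labels = NULL, config = tree_config(),
                          n_trees = 50, seed = 1L, mtry = NULL,
                          bootstrap = TRUE) {
  if (inherits(table, "feature_table")) {
    x <- table$values
    if (is.null(labels)) labels <- table$labels
  } else {
    x <- as.matrix(table)
    if (is.null(colnames(x))) colnames(x) <- paste0("attr", seq_len(ncol(x)))
  }
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(x)))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- if (bootstrap) sample.int(nrow(x), replace = TRUE)
           else seq_len(nrow(x))
    root <- .grow(x[idx, , drop = FALSE], labels[idx] == "T", config,
                  depth = 1, mtry = mtry)
    structure(list(root = root, config = config, n = length(idx)),
              class = "tree_model")
  })
  structure(list(trees = trees, config = config, mtry = mtry,
                 n_trees = n_trees, seed = seed),
            class = "forest_model")
}

.descend <- function(node, row) {
  while (node$type == "node") {
    v <- row[node$attribute]
    if (is.na(v)) stop("missing attribute '", node$attribute, "'")
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$class
}

#' Predict classes from a tree or forest
#'
#' Deterministic descent; a value equal to a node threshold goes left
#' (the `<=` branch). Forests vote by majority, ties to T.
#'
#' @param model A `tree_model` or `forest_model`.
#' @param newdata Named numeric vector, matrix or `feature_table` containing
#'   every attribute the model references.
#' @return Character vector of `"T"`/`"F"`.
#' @export
predict_tree <- function(model, newdata) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  if (inherits(model, "forest_model")) {
    votes <- sapply(model$trees, function(tr) predict_tree(tr, newdata))
    if (is.null(dim(votes))) votes <- t(as.matrix(votes))
    return(apply(votes, 1, function(v) {
      if (sum(v == "T") >= sum(v == "F")) "T" else "F"
    }))
  }
  apply(newdata, 1, function(row) .descend(model$root, row))
}

#' @export
print.tree_model <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "-> ", node$class, " (T=", node$counts[["T"]],
          ", F=", node$counts[["F"]], ")\n", sep = "")
    } else {
      cat(pad, node$attribute, " <= ", signif(node$threshold, 4), "\n",
          sep = "")
      rec(node$left, indent + 1)
      cat(pad, node$attribute, " > ", signif(node$threshold, 4), "\n",
          sep = "")
      rec(node$right, indent + 1)
    }
  }
  cat("tree_model (", x$config$criterion, ", n = ", x$n, ")\n", sep = "")
  rec(x$root, 0)
  invisible(x)
}

#' Save / load a tree model as JSON
#'
#' @param model A `tree_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `tree_load` returns the `tree_model`.
#' @export
tree_save <- function(model, path) {
  obj <- list(root = model$root, config = unclass(model$config), n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tree_save
#' @export
tree_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  fix <- function(node) {
    if (node$type == "leaf") {
      node$counts <- unlist(node$counts)
    } else {
      node$counts <- unlist(node$counts)
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  obj$root <- fix(obj$root)
  obj$config <- structure(obj$config, class = "tree_config")
  structure(obj, class = "tree_model")
}

#' The identifiers of the published rule models
#' @export
PUBLISHED_RULE_MODELS <- c("stump_gainratio", "parallel_2level",
                           "forest_gini_fig1", "tree_gainratio_fig2")

#' Apply a published threshold rule model
#'
#' Executable forms of four published decision-tree results for
#' thermostability, expressed over min-max normalized attribute values:
#'
#' * `stump_gainratio` — single stump on the Gln-Asn dipeptide frequency
#'   (`dipep_freq_QN`): above 0.500 thermostable (F), otherwise T.
#' * `parallel_2level` — two-level tree: Glu percentage (`aa_pct_E`) above
#'   0.322 is T; at or below 0.322, hydrophilic-residue frequency
#'   (`class_freq_hydrophilic`) above 0.550 is F, otherwise T.
#' * `forest_gini_fig1` — Asn-Gln dipeptide frequency (`dipep_freq_NQ`) at or
#'   below 0.050 is T; above it, Asn-Thr frequency (`dipep_freq_NT`) at or
#'   below 0.029 is T; the deeper branches were not published, so anything
#'   else is `"undetermined"`.
#' * `tree_gainratio_fig2` — hydrophilic frequency above 0.596 is F; below
#'   0.596 with Gln percentage (`aa_pct_Q`) below 0.217 is T; all other
#'   paths (including the exact 0.596 boundary) are `"undetermined"`.
#'
#' Only the printed branches are encoded; no unpublished path is guessed.
#'
#' @param model_id One of [PUBLISHED_RULE_MODELS].
#' @param features Named numeric vector, matrix or `feature_table` of
#'   normalized values containing the attributes the model needs.
#' @return Character vector over `"T"`, `"F"`, `"undetermined"`.
#' @export
published_rule_predict <- function(model_id, features) {
  model_id <- match.arg(model_id, PUBLISHED_RULE_MODELS)
  if (inherits(features, "feature_table")) features <- features$values
  if (is.null(dim(features))) features <- t(as.matrix(features))
  need <- switch(model_id,
    stump_gainratio = "dipep_freq_QN",
    parallel_2level = c("aa_pct_E", "class_freq_hydrophilic"),
    forest_gini_fig1 = c("dipep_freq_NQ", "dipep_freq_NT"),
    tree_gainratio_fig2 = c("class_freq_hydrophilic", "aa_pct_Q")
  )
  missing <- setdiff(need, colnames(features))
  if (length(missing) > 0) {
    stop("missing required attribute(s): ", paste(missing, collapse = ", "))
  }
  f <- function(name) unname(features[, name])
  switch(model_id,
    stump_gainratio = ifelse(f("dipep_freq_QN") > 0.500, "F", "T"),
    parallel_2level = ifelse(f("aa_pct_E") > 0.322, "T",
                      ifelse(f("class_freq_hydrophilic") > 0.550, "F", "T")),
    forest_gini_fig1 = ifelse(f("dipep_freq_NQ") <= 0.050, "T",
                       ifelse(f("dipep_freq_NT") <= 0.029, "T",
                              "undetermined")),
    tree_gainratio_fig2 = ifelse(f("class_freq_hydrophilic") > 0.596, "F",
                          ifelse(f("class_freq_hydrophilic") < 0.596 &
                                 f("aa_pct_Q") < 0.217, "T", "undetermined"))
  )
}
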