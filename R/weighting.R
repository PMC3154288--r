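# Eleven attribute-weighting algorithms over a numeric feature table with a
# binary T/F class, weight normalization to [0,1] (divide by the maximum),
# and strict >0.5 threshold selection.
#
# Entropy-family methods (information gain, gain ratio, chi-squared, Gini,
# symmetric uncertainty) and OneR discretize numeric attributes by
# equal-frequency binning (10 bins by default); entropies are in bits.

#' The eleven weighting method names
#' @export
WEIGHTING_METHODS <- c("info_gain", "gain_ratio", "rule_oner", "deviation",
                       "chi_squared", "gini", "uncertainty", "relief",
                       "svm", "pca", "correlation")

#' Weighting configuration
#'
#' @param n_bins Number of equal-frequency bins for discretizing numeric
#'   attributes in the entropy/chi-squared/Gini/uncertainty/OneR methods.
#' @param deviation_normalize How the deviation method scales the SD:
#'   `"average"` (SD/mean, default), `"minimum"`, `"maximum"` or `"none"`.
#' @param oner_mode `"leave_one_out"` (default): the weight of an attribute is
#'   the error rate of the best OneR model trained without it, so attributes
#'   whose absence hurts most weigh most. `"accuracy"`: the attribute's own
#'   single-rule training accuracy.
#' @param svm_cost,svm_tolerance Soft-margin cost and solver tolerance of the
#'   linear SVM used by the `svm` method.
#' @return A `weighting_config` list.
#' @export
weighting_config <- function(n_bins = 10, deviation_normalize = "average",
                             oner_mode = "leave_one_out",
                             svm_cost = 1, svm_tolerance = 1e-4) {
  stopifnot(n_bins >= 2,
            deviation_normalize %in% c("average", "minimum", "maximum", "none"),
            oner_mode %in% c("leave_one_out", "accuracy"))
  structure(list(n_bins = n_bins, deviation_normalize = deviation_normalize,
                 oner_mode = oner_mode, svm_cost = svm_cost,
                 svm_tolerance = svm_tolerance),
            class = "weighting_config")
}

# Equal-frequency binning; returns integer bin ids. Columns with at most
# n_bins distinct values keep each value as its own bin (quantile breaks
# would merge them); constant columns collapse to a single bin.
.discretize_ef <- function(x, n_bins) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) return(match(x, ux))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

.entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Contingency-table statistics for one binned attribute vs the class.
.contingency_stats <- function(bins, y) {
  tab <- table(bins, y)
  n <- sum(tab)
  hy <- .entropy_bits(colSums(tab))
  ha <- .entropy_bits(rowSums(tab))
  # conditional entropy H(Y | A)
  hyga <- sum(apply(tab, 1, function(r) sum(r) / n * .entropy_bits(r)))
  ig <- hy - hyga
  # Pearson chi-squared
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  gini_y <- 1 - sum((colSums(tab) / n)^2)
  gini_cond <- sum(apply(tab, 1, function(r) {
    sum(r) / n * (1 - sum((r / sum(r))^2))
  }))
  # floating error can push a zero gain fractionally negative
  list(ig = max(ig, 0), ha = ha, hy = hy, chi2 = chi2,
       gini_gain = max(gini_y - gini_cond, 0))
}

.require_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    stop("class-conditional weighting requires both classes present")
  }
}

.w_entropy_family <- function(x, y, method, config) {
  .require_two_classes(y)
  apply(x, 2, function(col) {
    if (max(col) == min(col)) return(0)
    st <- .contingency_stats(.discretize_ef(col, config$n_bins), y)
    switch(method,
           info_gain = st$ig,
           gain_ratio = if (st$ha == 0) 0 else st$ig / st$ha,
           chi_squared = st$chi2,
           gini = st$gini_gain,
           uncertainty = if (st$ha + st$hy == 0) 0 else
             2 * st$ig / (st$ha + st$hy))
  })
}

.w_relief <- function(x, y, config) {
  .require_two_classes(y)
  if (min(table(y)) < 2) stop("relief requires at least 2 records per class")
  n <- nrow(x)
  rng <- apply(x, 2, function(c) diff(range(c)))
  rng[rng == 0] <- Inf # constant attribute contributes 0
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  diag(d) <- Inf
  same <- outer(y, y, "==")
  hit_idx <- integer(n)
  miss_idx <- integer(n)
  for (i in seq_len(n)) {
    dh <- d[i, ]
    dh[!same[i, ]] <- Inf
    hit_idx[i] <- which.min(dh)
    dm <- d[i, ]
    dm[same[i, ]] <- Inf
    miss_idx[i] <- which.min(dm)
  }
  diff_hit <- abs(x - x[hit_idx, , drop = FALSE])
  diff_miss <- abs(x - x[miss_idx, , drop = FALSE])
  w <- colMeans(sweep(diff_miss - diff_hit, 2, rng, "/"))
  pmax(w, 0) # a negative relief weight means worse than irrelevant
}

.w_deviation <- function(x, config) {
  apply(x, 2, function(col) {
    s <- stats::sd(col)
    denom <- switch(config$deviation_normalize,
                    average = mean(col), minimum = min(col),
                    maximum = max(col), none = 1)
    if (s == 0) 0 else if (denom == 0) 0 else s / denom
  })
}

# Per-attribute OneR training error: majority class per equal-frequency bin.
.oner_errors <- function(x, y, config) {
  n <- length(y)
  apply(x, 2, function(col) {
    bins <- .discretize_ef(col, config$n_bins)
    tab <- table(bins, y)
    1 - sum(apply(tab, 1, max)) / n
  })
}

.w_rule_oner <- function(x, y, config) {
  .require_two_classes(y)
  e <- .oner_errors(x, y, config)
  constant <- apply(x, 2, function(c) max(c) == min(c))
  w <- if (config$oner_mode == "accuracy") {
    1 - e
  } else if (length(e) == 1) {
    stats::setNames(0, names(e))
  } else {
    # error of the best single rule available once this attribute is removed
    stats::setNames(vapply(seq_along(e), function(j) min(e[-j]), numeric(1)),
                    names(e))
  }
  w[constant] <- 0
  w
}

.w_svm <- function(x, y, config) {
  .require_two_classes(y)
  keep <- apply(x, 2, function(c) max(c) > min(c))
  w <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (any(keep)) {
    fit <- e1071::svm(x[, keep, drop = FALSE], factor(y),
                      kernel = "linear", cost = config$svm_cost,
                      tolerance = config$svm_tolerance, scale = FALSE)
    w[keep] <- abs(drop(crossprod(fit$coefs, fit$SV)))
  }
  w
}

.w_pca <- function(x, config) {
  keep <- apply(x, 2, function(c) max(c) > min(c))
  w <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (sum(keep) >= 1) {
    p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    w[keep] <- abs(p$rotation[, 1])
  }
  w
}

.w_correlation <- function(x, y, config) {
  .require_two_classes(y)
  y01 <- as.numeric(factor(y)) - 1
  r <- suppressWarnings(abs(as.vector(stats::cor(x, y01))))
  r[is.na(r)] <- 0
  stats::setNames(r, colnames(x))
}

#' Compute attribute weights by one method
#'
#' Runs one of the eleven weighting algorithms on a (min-max normalized)
#' numeric table with binary T/F labels and normalizes the raw weights into
#' \\[0, 1\\] by dividing by the maximum.
#'
#' @param table A `feature_table` or numeric matrix.
#' @param labels Character vector of `"T"`/`"F"` labels; taken from the table
#'   when it is a `feature_table` and `labels` is `NULL`.
#' @param method One of [WEIGHTING_METHODS].
#' @param config A [weighting_config()].
#' @return A `weight_vector`: list with `method`, `raw` and `weights` (both
#'   named numeric in column order).
#' @export
weight <- function(table, labels = NULL, method, config = weighting_config()) {
  method <- match.arg(method, WEIGHTING_METHODS)
  if (inherits(table, "feature_table")) {
    x <- table$values
    if (is.null(labels)) labels <- table$labels
  } else {
    x <- as.matrix(table)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("attr", seq_len(ncol(x)))
  if (method %in% c("info_gain", "gain_ratio", "chi_squared", "gini",
                    "uncertainty", "relief", "rule_oner", "svm",
                    "correlation")) {
    if (anyNA(labels)) stop("method '", method, "' requires complete labels")
    labels <- as.character(labels)
  }
  raw <- switch(method,
    info_gain = , gain_ratio = , chi_squared = , gini = , uncertainty =
      .w_entropy_family(x, labels, method, config),
    relief = .w_relief(x, labels, config),
    deviation = .w_deviation(x, config),
    rule_oner = .w_rule_oner(x, labels, config),
    svm = .w_svm(x, labels, config),
    pca = .w_pca(x, config),
    correlation = .w_correlation(x, labels, config)
  )
  normalize_weights(raw, method = method)
}

#' Normalize raw weights into \\[0, 1\\]
#'
#' Divides by the maximum weight; an all-zero vector passes through
#' unchanged. Raw weights must be finite and non-negative (signed methods
#' take absolute values before reaching this point).
#'
#' @param raw Named numeric vector of raw weights.
#' @param method Method name recorded in the result.
#' @return A `weight_vector` with fields `method`, `raw`, `weights`.
#' @export
normalize_weights <- function(raw, method = "custom") {
  if (any(is.na(raw))) {
    stop("NaN/NA weight for attribute(s): ",
         paste(names(raw)[is.na(raw)], collapse = ", "))
  }
  stopifnot(all(is.finite(raw)), all(raw >= 0))
  m <- max(raw)
  w <- if (m > 0) raw / m else raw
  structure(list(method = method, raw = raw, weights = w),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("weight_vector (", x$method, "): ", length(x$weights),
      " attributes, ", sum(x$weights > 0.5), " above 0.5\n", sep = "")
  invisible(x)
}

#' Select attributes whose normalized weight exceeds a threshold
#'
#' Strict inequality: a weight exactly at the threshold is excluded (and
#' flagged in the `"at_threshold"` attribute of the result). Selected names
#' keep schema (column) order.
#'
#' @param wv A `weight_vector`.
#' @param threshold Selection cutoff, default 0.5.
#' @return A `selection_result`: list with `method`, `selected`, `threshold`.
#' @export
select_attributes <- function(wv, threshold = 0.5) {
  sel <- names(wv$weights)[wv$weights > threshold]
  if (length(sel) == 0) {
    warning("no attribute exceeds the ", threshold,
            " threshold for method '", wv$method, "'")
  }
  out <- structure(list(method = wv$method, selected = sel,
                        threshold = threshold),
                   class = "selection_result")
  attr(out, "at_threshold") <- names(wv$weights)[wv$weights == threshold]
  out
}

#' Run all weighting methods and slice the per-method datasets
#'
#' Applies every requested method, selects attributes with weight > 0.5 and
#' returns, per method, the weight vector, the selection and the feature
#' table restricted to the selected attributes. A failing method is recorded
#' (with a warning) without aborting the others.
#'
#' @param table A `feature_table` (min-max normalized) with T/F labels.
#' @param methods Character vector of methods (default all eleven).
#' @param config A [weighting_config()].
#' @param threshold Selection threshold (default 0.5).
#' @return A named list per method with elements `weights`, `selection`,
#'   `table` (or `error` when the method failed).
#' @export
weighting_suite <- function(table, methods = WEIGHTING_METHODS,
                            config = weighting_config(), threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  out <- list()
  for (m in methods) {
    res <- tryCatch({
      wv <- weight(table, method = m, config = config)
      sel <- suppressWarnings(select_attributes(wv, threshold))
      list(weights = wv, selection = sel,
           table = if (length(sel$selected) > 0)
             ft_select(table, sel$selected) else NULL)
    }, error = function(e) {
      warning("weighting method '", m, "' failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
    out[[m]] <- res
  }
  out
}
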