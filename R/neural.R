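# Feed-forward and Elman networks trained by back-propagation (logistic
# hidden units, 2-unit softmax output, cross-entropy loss, seeded mini-batch
# SGD), the 10-fold cross-validation harness with its exact fold-size rule,
# and the stepwise 1-p attribute screening.
#
# The Elman variant augments the first hidden layer with context units (a
# copy of its previous activation). On static feature vectors the recurrence
# is realized by presenting each example `context_steps` times with the
# context zero-initialized; gradients treat the context as a constant input
# (no back-propagation through time).

#' Neural network training configuration
#'
#' @param learning_rate SGD learning rate (default 0.01).
#' @param epochs Training epochs (default 500).
#' @param seed Integer seed (mandatory): weight init and shuffling.
#' @param elman_context_steps Presentations per example for the Elman context
#'   (default 2).
#' @param val_fraction Fraction held out for early stopping (default 0.1;
#'   0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @param batch_size Mini-batch size.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.01, epochs = 500, seed = 1L,
                            elman_context_steps = 2, val_fraction = 0.1,
                            patience = 50, batch_size = 32) {
  stopifnot(epochs >= 1, learning_rate > 0, elman_context_steps >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 elman_context_steps = as.integer(elman_context_steps),
                 val_fraction = val_fraction, patience = patience,
                 batch_size = batch_size),
            class = "training_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.init_net <- function(p, hidden, elman) {
  sizes <- c(p, hidden, 2L)
  W <- list()
  b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan <- sizes[l]
    W[[l]] <- matrix(stats::runif(fan * sizes[l + 1], -0.5, 0.5) / sqrt(fan),
                     fan, sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  U <- if (elman) matrix(0, hidden[1], hidden[1]) else NULL
  list(W = W, b = b, U = U, hidden = hidden)
}

# Forward pass; X is n x p. Returns activations per layer and the context
# activation actually used for the first hidden layer (Elman only).
.forward <- function(net, X, context_steps = 1) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  if (is.null(net$U)) {
    h <- .sigmoid(sweep(X %*% net$W[[1]], 2, net$b[[1]], "+"))
    ctx <- NULL
  } else {
    ctx <- matrix(0, nrow(X), ncol(net$U))
    for (s in seq_len(context_steps)) {
      pre <- sweep(X %*% net$W[[1]] + ctx %*% net$U, 2, net$b[[1]], "+")
      h <- .sigmoid(pre)
      if (s < context_steps) ctx <- h
    }
  }
  A[[2]] <- h
  if (L > 1) {
    for (l in 2:L) {
      Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
      A[[l + 1]] <- if (l == L) .softmax_rows(Z) else .sigmoid(Z)
    }
  }
  list(A = A, ctx = ctx)
}

.net_loss <- function(net, X, Y01, context_steps) {
  P <- .forward(net, X, context_steps)$A[[length(net$W) + 1]]
  -mean(log(pmax(P[cbind(seq_len(nrow(X)), Y01 + 1)], 1e-12)))
}

.train_net <- function(X, labels, hidden, config, elman) {
  stopifnot(all(labels %in% c("T", "F")))
  y01 <- as.integer(labels == "F") # output unit 1 = T, unit 2 = F
  set.seed(config$seed)
  net <- .init_net(ncol(X), hidden, elman)
  steps <- if (elman) config$elman_context_steps else 1
  n <- nrow(X)
  val_idx <- integer(0)
  if (config$val_fraction > 0 && n >= 20) {
    val_idx <- sample.int(n, max(1, round(config$val_fraction * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  best <- list(loss = Inf, net = net, since = 0)
  loss_trace <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      Xb <- X[idx, , drop = FALSE]
      yb <- y01[idx]
      fw <- .forward(net, Xb, steps)
      A <- fw$A
      L <- length(net$W)
      m <- length(idx)
      Ymat <- matrix(0, m, 2)
      Ymat[cbind(seq_len(m), yb + 1)] <- 1
      delta <- (A[[L + 1]] - Ymat) / m # softmax + cross-entropy
      for (l in L:1) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(net$W[[l]])) * A[[l]] * (1 - A[[l]])
        } else if (elman) {
          net$U <- net$U - config$learning_rate * crossprod(fw$ctx, delta)
        }
        net$W[[l]] <- net$W[[l]] - config$learning_rate * gW
        net$b[[l]] <- net$b[[l]] - config$learning_rate * gb
      }
    }
    tr_loss <- .net_loss(net, X[tr_idx, , drop = FALSE], y01[tr_idx], steps)
    if (!is.finite(tr_loss)) stop("non-finite training loss at epoch ", epoch)
    loss_trace <- c(loss_trace, tr_loss)
    if (length(val_idx) > 0) {
      vl <- .net_loss(net, X[val_idx, , drop = FALSE], y01[val_idx], steps)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, net = net, since = 0)
      } else {
        best$since <- best$since + 1
        if (best$since >= config$patience) {
          net <- best$net
          break
        }
      }
    }
  }
  if (length(val_idx) > 0 && best$loss < Inf) net <- best$net
  structure(list(net = net, hidden = hidden, elman = elman,
                 context_steps = steps, config = config,
                 loss_trace = loss_trace,
                 feature_names = colnames(X)),
            class = "net_model")
}

.net_input <- function(table, labels = NULL) {
  if (inherits(table, "feature_table")) {
    list(x = table$values,
         labels = if (is.null(labels)) table$labels else labels)
  } else {
    x <- as.matrix(table)
    if (is.null(colnames(x))) colnames(x) <- paste0("attr", seq_len(ncol(x)))
    list(x = x, labels = labels)
  }
}

#' Train a feed-forward network
#'
#' @param table A `feature_table` or numeric matrix of normalized inputs.
#' @param labels `"T"`/`"F"` labels (taken from a `feature_table` when
#'   `NULL`).
#' @param hidden Integer vector of hidden layer sizes, e.g. `c(40, 20)`.
#' @param config A [training_config()].
#' @return A `net_model`.
#' @export
train_mlp <- function(table, labels = NULL, hidden = c(10, 5),
                      config = training_config()) {
  inp <- .net_input(table, labels)
  .train_net(inp$x, inp$labels, as.integer(hidden), config, elman = FALSE)
}

#' Train an Elman network
#'
#' As [train_mlp()] with the first hidden layer augmented by context units;
#' each example is presented `config$elman_context_steps` times with the
#' context starting at zero.
#'
#' @inheritParams train_mlp
#' @return A `net_model` with `elman = TRUE`.
#' @export
train_elman <- function(table, labels = NULL, hidden = c(10, 5),
                        config = training_config()) {
  inp <- .net_input(table, labels)
  .train_net(inp$x, inp$labels, as.integer(hidden), config, elman = TRUE)
}

#' Reinterpret a feed-forward model as a degenerate Elman model
#'
#' Adds zero context weights and a single presentation step; the resulting
#' model's outputs equal the original's exactly.
#'
#' @param model A `net_model` trained by [train_mlp()].
#' @return An Elman `net_model` with zero context weights.
#' @export
elman_from_mlp <- function(model) {
  stopifnot(inherits(model, "net_model"), !model$elman)
  model$net$U <- matrix(0, model$hidden[1], model$hidden[1])
  model$elman <- TRUE
  model$context_steps <- 1L
  model
}

#' Predict classes or probabilities from a trained network
#'
#' @param model A `net_model`.
#' @param newdata Matrix or `feature_table` with the training columns.
#' @param type `"class"` (default) or `"prob"` (matrix with T and F columns).
#' @return Character classes or a probability matrix.
#' @export
net_predict <- function(model, newdata, type = c("class", "prob")) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  if (!is.null(model$feature_names) && !is.null(colnames(newdata))) {
    newdata <- newdata[, model$feature_names, drop = FALSE]
  }
  P <- .forward(model$net, newdata, model$context_steps)[["A"]][[
    length(model$net$W) + 1]]
  colnames(P) <- c("T", "F")
  if (type == "prob") return(P)
  c("T", "F")[max.col(P, ties.method = "first")]
}

#' Partition indices into cross-validation folds
#'
#' The first `k - 1` folds share size `s = ceiling(n/k)` when
#' `(k - 1) * ceiling(n/k) < n`, otherwise `s = floor(n/k)`; the last fold
#' takes the remainder. For n = 2057, k = 10 this gives nine folds of 206
#' and a last fold of 203. Assignment to folds is a seeded shuffle.
#'
#' @param n Number of records.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `k` disjoint index vectors covering `1:n`.
#' @export
make_cv_folds <- function(n, k = 10, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  s <- if ((k - 1) * ceiling(n / k) < n) ceiling(n / k) else floor(n / k)
  sizes <- c(rep(s, k - 1), n - (k - 1) * s)
  set.seed(seed)
  idx <- sample.int(n)
  unname(split(idx, rep(seq_len(k), times = sizes)))
}

#' k-fold cross-validation of a classifier
#'
#' Trains on `k - 1` folds, tests on the held-out fold, and reports per-fold
#' and average accuracies: overall, on the thermostable class (F) and on the
#' mesostable class (T). A fold whose test part has only one class gets `NA`
#' for the absent class's accuracy, excluded from the average.
#'
#' @param table A `feature_table` or numeric matrix.
#' @param labels `"T"`/`"F"` labels.
#' @param trainer Function `(x, labels) -> model`; the model is applied to
#'   new rows with `predict_fn`.
#' @param predict_fn Function `(model, x) -> classes` (default
#'   [net_predict()]).
#' @param k Number of folds.
#' @param seed Integer seed for the fold shuffle.
#' @return A `cv_report`: data.frame `folds` (one row per fold: sizes and
#'   accuracies) plus an `averages` row.
#' @export
cross_validate <- function(table, labels = NULL, trainer,
                           predict_fn = net_predict, k = 10, seed = 1L) {
  inp <- .net_input(table, labels)
  x <- inp$x
  y <- inp$labels
  folds <- make_cv_folds(nrow(x), k, seed)
  rows <- lapply(seq_along(folds), function(i) {
    test <- folds[[i]]
    train <- setdiff(seq_len(nrow(x)), test)
    model <- trainer(x[train, , drop = FALSE], y[train])
    pred <- predict_fn(model, x[test, , drop = FALSE])
    truth <- y[test]
    acc_of <- function(cls) {
      if (!any(truth == cls)) return(NA_real_)
      mean(pred[truth == cls] == cls)
    }
    data.frame(fold = i, n_train = length(train), n_test = length(test),
               accuracy_F = acc_of("F"), accuracy_T = acc_of("T"),
               overall = mean(pred == truth))
  })
  folds_df <- do.call(rbind, rows)
  averages <- data.frame(
    accuracy_F = mean(folds_df$accuracy_F, na.rm = TRUE),
    accuracy_T = mean(folds_df$accuracy_T, na.rm = TRUE),
    overall = mean(folds_df$overall)
  )
  structure(list(folds = folds_df, averages = averages, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cross-validation report (", x$k, "folds )\n")
  df <- x$folds
  df[, 4:6] <- round(df[, 4:6], 3)
  print(df, row.names = FALSE)
  cat("Average: F =", round(x$averages$accuracy_F, 3),
      " T =", round(x$averages$accuracy_T, 3),
      " overall =", round(x$averages$overall, 3), "\n")
  invisible(x)
}

#' Stepwise attribute screening by 1 - p importance
#'
#' One-way ANOVA F test of each attribute against the binary class; the
#' importance score is `1 - p`. Attributes are labelled `important`
#' (importance > 0.95), `marginal` (0.90 to 0.95) or `unimportant` (< 0.90).
#' An attribute with zero variance everywhere gets p = 1.
#'
#' @param table A `feature_table` or numeric matrix.
#' @param labels `"T"`/`"F"` labels, at least two records per class.
#' @return A `stepwise_report` data.frame: `attribute`, `p_value`,
#'   `importance`, `label`.
#' @export
stepwise_select <- function(table, labels = NULL) {
  inp <- .net_input(table, labels)
  x <- inp$x
  y <- inp$labels
  stopifnot(sum(y == "T") >= 2, sum(y == "F") >= 2)
  n <- nrow(x)
  g <- y == "T"
  n1 <- sum(g)
  n2 <- n - n1
  m1 <- colMeans(x[g, , drop = FALSE])
  m2 <- colMeans(x[!g, , drop = FALSE])
  mall <- colMeans(x)
  ss_between <- n1 * (m1 - mall)^2 + n2 * (m2 - mall)^2
  ss_within <- colSums(sweep(x[g, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!g, , drop = FALSE], 2, m2)^2)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[ss_within == 0 & ss_between == 0] <- 1
  p[ss_within == 0 & ss_between > 0] <- 0
  importance <- 1 - p
  label <- ifelse(importance > 0.95, "important",
                  ifelse(importance >= 0.90, "marginal", "unimportant"))
  structure(
    data.frame(attribute = colnames(x), p_value = p, importance = importance,
               label = label, row.names = NULL),
    class = c("stepwise_report", "data.frame")
  )
}
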