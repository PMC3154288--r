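# Four clustering algorithms (k = 2 throughout the thermostability analysis,
# but k is configurable) and the cluster -> class evaluation. All distances
# are Euclidean on min-max normalized values; the categorical N-terminal
# column never enters a distance.

#' Clustering configuration
#'
#' @param k Number of clusters (default 2: T/F).
#' @param seed Integer seed for k-means++ initialization and EM restarts.
#' @param max_iter Maximum iterations (Lloyd / EM / PAM swap passes).
#' @param tol Convergence tolerance: centroid shift (k-means), log-likelihood
#'   gain (EM).
#' @param em_covariance `"diagonal"` (default; variances floored at 1e-6) or
#'   `"full"` (ridge 1e-6 on the diagonal).
#' @param svc_q Gaussian kernel width of support vector clustering
#'   (`K(x, x') = exp(-q ||x - x'||^2)`); `NULL` (default) uses the inverse
#'   median squared pairwise distance, which adapts the width to the
#'   dimensionality of the table.
#' @param svc_C Soft-margin bound on the sphere dual variables.
#' @param svc_samples Points sampled on each segment for the adjacency test.
#' @param svc_knn Neighbours per point whose connecting segments are tested
#'   (the full n^2 pair test is quadratic in kernel evaluations).
#' @param svc_max_n Hard bound on n for the quadratic sphere solver.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(k = 2, seed = 1L, max_iter = 300, tol = 1e-6,
                           em_covariance = c("diagonal", "full"),
                           svc_q = NULL, svc_C = 1, svc_samples = 10,
                           svc_knn = 10, svc_max_n = 1000) {
  em_covariance <- match.arg(em_covariance)
  stopifnot(k >= 2, max_iter >= 1, tol > 0,
            is.null(svc_q) || svc_q > 0, svc_C > 0)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 max_iter = max_iter, tol = tol,
                 em_covariance = em_covariance,
                 svc_q = svc_q, svc_C = svc_C, svc_samples = svc_samples,
                 svc_knn = svc_knn, svc_max_n = svc_max_n),
            class = "cluster_config")
}

.cluster_matrix <- function(table) {
  if (inherits(table, "feature_table")) {
    list(x = table$values, ids = table$ids)
  } else {
    x <- as.matrix(table)
    list(x = x, ids = if (!is.null(rownames(x))) rownames(x)
                      else as.character(seq_len(nrow(x))))
  }
}

.new_assignment <- function(ids, cluster, algorithm, model) {
  structure(list(ids = ids, cluster = as.integer(cluster),
                 algorithm = algorithm, model = model),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment (", x$algorithm, "): ",
      length(x$ids), " records, sizes ",
      paste(tabulate(x$cluster), collapse = "/"), "\n", sep = "")
  invisible(x)
}

# k-means++ seeding (squared-distance weighted), deterministic under seed.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (sum(d2) == 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j + 1, ])^2))
  }
  centers
}

.assign_nearest <- function(x, centers) {
  d2 <- sapply(seq_len(nrow(centers)),
               function(j) colSums((t(x) - centers[j, ])^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

#' k-means clustering (Lloyd iterations, k-means++ seeding)
#'
#' @param table A `feature_table` or numeric matrix (normalized values).
#' @param config A [cluster_config()].
#' @return A `cluster_assignment` whose `model` holds the centroids and the
#'   within-cluster sum-of-squares trace (one entry per iteration, always
#'   non-increasing).
#' @export
kmeans_cluster <- function(table, config = cluster_config()) {
  m <- .cluster_matrix(table)
  x <- m$x
  k <- config$k
  if (nrow(unique(x)) < k) {
    stop("fewer distinct rows (", nrow(unique(x)), ") than k = ", k)
  }
  set.seed(config$seed)
  centers <- .kmeanspp_init(x, k)
  trace <- numeric(0)
  for (iter in seq_len(config$max_iter)) {
    cl <- .assign_nearest(x, centers)
    # empty cluster: claim the point farthest from its centroid
    for (j in which(tabulate(cl, k) == 0)) {
      far <- which.max(rowSums((x - centers[cl, , drop = FALSE])^2))
      cl[far] <- j
    }
    new_centers <- do.call(rbind, lapply(seq_len(k), function(j) {
      colMeans(x[cl == j, , drop = FALSE])
    }))
    trace <- c(trace, sum((x - new_centers[cl, , drop = FALSE])^2))
    shift <- max(rowSums((new_centers - centers)^2))
    centers <- new_centers
    if (shift < config$tol) break
  }
  .new_assignment(m$ids, cl, "kmeans",
                  list(centers = centers, wss_trace = trace))
}

#' k-medoids clustering (PAM: build then swap)
#'
#' Deterministic (greedy build, best-improvement swaps, ties to the lower
#' index); medoids are always input rows; Euclidean distance.
#'
#' @inheritParams kmeans_cluster
#' @return A `cluster_assignment`; `model` holds medoid row indices and the
#'   cost trace across swap steps (non-increasing).
#' @export
kmedoids_cluster <- function(table, config = cluster_config()) {
  m <- .cluster_matrix(table)
  x <- m$x
  k <- config$k
  if (nrow(unique(x)) < k) {
    stop("fewer distinct rows (", nrow(unique(x)), ") than k = ", k)
  }
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  # build: first medoid minimizes total distance, then greedy additions
  medoids <- which.min(colSums(d))
  while (length(medoids) < k) {
    cur <- apply(d[, medoids, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(c) {
      if (c %in% medoids) return(-Inf)
      sum(pmax(cur - d[, c], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
  }
  cost <- function(med) sum(apply(d[, med, drop = FALSE], 1, min))
  trace <- cost(medoids)
  for (pass in seq_len(config$max_iter)) {
    best <- list(delta = 0)
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- medoids
        cand[mi] <- h
        delta <- cost(cand) - trace[length(trace)]
        if (delta < best$delta - 1e-12) best <- list(delta = delta, med = cand)
      }
    }
    if (best$delta >= 0) break
    medoids <- best$med
    trace <- c(trace, cost(medoids))
  }
  cl <- max.col(-d[, medoids, drop = FALSE], ties.method = "first")
  .new_assignment(m$ids, cl, "kmedoids",
                  list(medoid_index = medoids, medoid_ids = m$ids[medoids],
                       cost_trace = trace))
}

#' Support vector clustering
#'
#' Ben-Hur-style clustering: a minimal enclosing sphere of the data mapped by
#' a Gaussian kernel (soft margin `svc_C`), with two points adjacent when
#' every sampled point on their connecting segment lies inside the sphere.
#' Clusters are the connected components of the adjacency graph over each
#' point's `svc_knn` nearest neighbours. Bounded support vectors (outliers)
#' and singleton components are attached to the nearest assigned point and
#' flagged in `model$flagged`, so the assignment is always total.
#'
#' @inheritParams kmeans_cluster
#' @return A `cluster_assignment`; `model` holds the dual coefficients,
#'   sphere radius and flagged record ids. The number of clusters found is
#'   data-driven (not forced to `config$k`).
#' @export
svc_cluster <- function(table, config = cluster_config()) {
  m <- .cluster_matrix(table)
  x <- m$x
  n <- nrow(x)
  if (n > config$svc_max_n) {
    stop("svc_cluster is quadratic; n = ", n, " exceeds svc_max_n = ",
         config$svc_max_n)
  }
  C <- config$svc_C
  d2 <- as.matrix(stats::dist(x))^2
  q <- config$svc_q
  if (is.null(q)) {
    med <- stats::median(d2[d2 > 0])
    q <- if (is.finite(med) && med > 0) 1 / med else 1
  }
  K <- exp(-q * d2)
  sol <- tryCatch(
    kernlab::ipop(c = matrix(-1, n, 1), H = 2 * K,
                  A = matrix(1, 1, n), b = 1,
                  l = matrix(0, n, 1), u = matrix(C, n, 1), r = 0),
    error = function(e) stop("sphere QP did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  beta <- as.vector(kernlab::primal(sol))
  beta <- pmax(pmin(beta, C), 0)
  beta <- beta / sum(beta)
  bKb <- drop(t(beta) %*% K %*% beta)
  r2_of_rows <- 1 - 2 * as.vector(K %*% beta) + bKb
  eps <- 1e-6
  # sphere radius: largest radius among non-bounded points, with a small
  # slack so numerical jitter at the boundary does not sever adjacencies
  free <- beta < C - eps
  r2 <- if (any(free)) max(r2_of_rows[free]) else max(r2_of_rows)
  r2 <- r2 + 1e-7 + 1e-6 * abs(r2)
  outlier <- !free & r2_of_rows > r2
  # segment-interior radius test for each point's nearest neighbours
  xs2 <- rowSums(x^2)
  tx <- t(x)
  inside <- function(pts) {
    dd <- outer(rowSums(pts^2), xs2, "+") - 2 * pts %*% tx
    kk <- exp(-q * dd)
    r2s <- 1 - 2 * as.vector(kk %*% beta) + bKb
    r2s <= r2
  }
  knn <- min(config$svc_knn, n - 1)
  ord <- apply(d2, 1, order)
  edge_list <- vector("list", n)
  ts <- seq(0, 1, length.out = config$svc_samples + 2)[-c(1, config$svc_samples + 2)]
  for (i in seq_len(n)) {
    if (outlier[i]) next
    nb <- ord[2:(knn + 1), i]
    nb <- nb[!outlier[nb] & nb > i]
    keep <- vapply(nb, function(j) {
      pts <- outer(1 - ts, x[i, ]) + outer(ts, x[j, ])
      all(inside(pts))
    }, logical(1))
    if (any(keep)) edge_list[[i]] <- cbind(i, nb[keep])
  }
  edges <- do.call(rbind, c(edge_list, list(matrix(integer(0), ncol = 2))))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership[seq_len(n)]
  comp[outlier] <- NA
  if (all(is.na(comp))) comp[] <- 1
  # the kNN graph cannot join components whose members are not neighbours;
  # test the closest cross-component pair and merge while segments stay
  # inside the sphere (one sweep over component pairs per round)
  for (round in seq_len(config$max_iter)) {
    comps <- unique(stats::na.omit(comp))
    if (length(comps) < 2) break
    merged <- FALSE
    tested <- new.env(parent = emptyenv())
    for (ci in seq_along(comps)) {
      for (cj in seq_len(ci - 1)) {
        a <- comps[ci]
        b <- comps[cj]
        key <- paste(min(a, b), max(a, b))
        if (!is.null(tested[[key]])) next
        ii <- which(comp == a & !outlier)
        jj <- which(comp == b & !outlier)
        if (length(ii) == 0 || length(jj) == 0) next
        sub <- d2[ii, jj, drop = FALSE]
        amin <- arrayInd(which.min(sub), dim(sub))
        i <- ii[amin[1]]
        j <- jj[amin[2]]
        pts <- outer(1 - ts, x[i, ]) + outer(ts, x[j, ])
        if (all(inside(pts))) {
          comp[comp == a] <- b
          merged <- TRUE
        } else {
          tested[[key]] <- TRUE
        }
      }
    }
    if (!merged) break
  }
  # relabel components by decreasing size; attach outliers to nearest point
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- relabel[as.character(comp)]
  flagged <- which(is.na(cl))
  for (i in flagged) {
    nearest <- order(d2[i, ])
    nearest <- nearest[!is.na(cl[nearest]) & nearest != i][1]
    cl[i] <- cl[nearest]
  }
  .new_assignment(m$ids, unname(cl), "svc",
                  list(beta = beta, radius2 = r2, n_components = length(sizes),
                       flagged = m$ids[flagged]))
}

.log_dnorm_diag <- function(x, mu, var) {
  -0.5 * sum(log(2 * pi * var)) -
    0.5 * colSums((t(x) - mu)^2 / var)
}

.log_dnorm_full <- function(x, mu, sigma) {
  p <- ncol(x)
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' EM clustering with Gaussian mixtures
#'
#' Diagonal-covariance Gaussian mixture fitted by EM (variance floor 1e-6),
#' initialized from a seeded k-means run. Iterates until the log-likelihood
#' gain drops below `tol` or `max_iter` is reached; the log-likelihood trace
#' is non-decreasing. A degenerate component (vanishing responsibility mass)
#' triggers one re-seeded restart, then an error.
#'
#' @inheritParams kmeans_cluster
#' @return A `cluster_assignment`; `model` holds mixture weights, means,
#'   variances and the log-likelihood trace. Assignment is the maximum
#'   responsibility.
#' @export
em_cluster <- function(table, config = cluster_config()) {
  m <- .cluster_matrix(table)
  fit <- tryCatch(
    .em_fit(m$x, config, config$seed),
    error = function(e) {
      cfg2 <- config
      cfg2$seed <- config$seed + 1L
      tryCatch(.em_fit(m$x, cfg2, cfg2$seed),
               error = function(e2) stop("EM degenerate after restart: ",
                                         conditionMessage(e2), call. = FALSE))
    }
  )
  .new_assignment(m$ids, fit$cluster, "em", fit$model)
}

.em_fit <- function(x, config, seed) {
  k <- config$k
  n <- nrow(x)
  p <- ncol(x)
  full <- config$em_covariance == "full"
  cfg_km <- config
  cfg_km$seed <- seed
  init <- kmeans_cluster(x, cfg_km)$cluster
  pi_k <- tabulate(init, k) / n
  mu <- lapply(seq_len(k), function(j) colMeans(x[init == j, , drop = FALSE]))
  var_of <- function(rows, center) {
    pmax(colMeans(sweep(rows, 2, center)^2), 1e-6)
  }
  if (full) {
    sig <- lapply(seq_len(k), function(j) {
      xs <- sweep(x[init == j, , drop = FALSE], 2, mu[[j]])
      crossprod(xs) / nrow(xs) + diag(1e-6, p)
    })
  } else {
    sig <- lapply(seq_len(k), function(j)
      var_of(x[init == j, , drop = FALSE], mu[[j]]))
  }
  loglik <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(config$max_iter)) {
    logd <- sapply(seq_len(k), function(j) {
      log(pi_k[j]) + if (full) .log_dnorm_full(x, mu[[j]], sig[[j]])
                     else .log_dnorm_diag(x, mu[[j]], sig[[j]])
    })
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    new_loglik <- sum(lse)
    trace <- c(trace, new_loglik)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("degenerate mixture component")
    pi_k <- nk / n
    for (j in seq_len(k)) {
      mu[[j]] <- colSums(resp[, j] * x) / nk[j]
      xs <- sweep(x, 2, mu[[j]])
      if (full) {
        sig[[j]] <- crossprod(xs * sqrt(resp[, j])) / nk[j] + diag(1e-6, p)
      } else {
        sig[[j]] <- pmax(colSums(resp[, j] * xs^2) / nk[j], 1e-6)
      }
    }
    if (new_loglik - loglik < config$tol && iter > 1) break
    loglik <- new_loglik
  }
  cl <- max.col(resp, ties.method = "first")
  if (length(unique(cl)) < k) stop("degenerate mixture component")
  list(cluster = cl,
       model = list(pi = pi_k, mu = mu, sigma = sig, loglik_trace = trace))
}

#' Evaluate a 2-cluster assignment against T/F labels
#'
#' Maps clusters to classes by the accuracy-maximizing choice over the two
#' possible mappings and reports the mapped class counts and accuracy (the
#' layout of a cluster-vs-class evaluation grid: T count, F count, accuracy).
#' With all records in one cluster the mapping is still defined and accuracy
#' equals the majority fraction.
#'
#' @param assignment A `cluster_assignment`.
#' @param labels Character `"T"`/`"F"` labels, one per record.
#' @return A `confusion_table`: list with `counts` (records mapped to T and
#'   F), `accuracy`, `mapping` (cluster -> class) and the raw `table`.
#' @export
evaluate_clusters <- function(assignment, labels) {
  stopifnot(length(labels) == length(assignment$cluster), !anyNA(labels))
  cl <- assignment$cluster
  clusters <- sort(unique(cl))
  y <- factor(labels, levels = c("T", "F"))
  tab <- table(cluster = cl, label = y)
  best <- NULL
  # clusters beyond the first two (SVC may find several) are greedily mapped
  # to their majority class; the leading two get the accuracy-maximizing swap
  base_map <- apply(tab, 1, function(r) c("T", "F")[which.max(r)])
  for (perm in list(c("T", "F"), c("F", "T"))) {
    map <- base_map
    map[seq_len(min(2, length(map)))] <- perm[seq_len(min(2, length(map)))]
    correct <- sum(vapply(seq_along(clusters), function(i) {
      tab[i, map[i]]
    }, numeric(1)))
    if (is.null(best) || correct > best$correct) {
      best <- list(map = map, correct = correct)
    }
  }
  mapped <- best$map[match(cl, clusters)]
  structure(
    list(counts = c(T = sum(mapped == "T"), F = sum(mapped == "F")),
         accuracy = best$correct / length(cl),
         mapping = stats::setNames(best$map, clusters),
         table = tab),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("confusion_table: T =", x$counts[["T"]], " F =", x$counts[["F"]],
      " accuracy =", round(x$accuracy, 4), "\n")
  invisible(x)
}
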