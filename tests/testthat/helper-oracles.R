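# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive every quantity from first principles
# (closed-form contingency formulas, brute-force loops, uniroot) rather than
# calling any package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form statistics for a 2x2 attribute-value x class table:
# counts = c(n00, n01, n10, n11) with rows = attribute value (0/1),
# cols = class (T/F).
oracle_contingency <- function(n00, n01, n10, n11) {
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- n00 + n01 + n10 + n11
  row0 <- n00 + n01
  row1 <- n10 + n11
  colT <- n00 + n10
  colF <- n01 + n11
  hy <- h(c(colT, colF) / n)
  ha <- h(c(row0, row1) / n)
  hyga <- 0
  if (row0 > 0) hyga <- hyga + row0 / n * h(c(n00, n01) / row0)
  if (row1 > 0) hyga <- hyga + row1 / n * h(c(n10, n11) / row1)
  ig <- hy - hyga
  gr <- if (ha == 0) 0 else ig / ha
  su <- if (ha + hy == 0) 0 else 2 * ig / (ha + hy)
  chi2 <- 0
  for (cell in list(c(n00, row0, colT), c(n01, row0, colF),
                    c(n10, row1, colT), c(n11, row1, colF))) {
    e <- cell[2] * cell[3] / n
    if (e > 0) chi2 <- chi2 + (cell[1] - e)^2 / e
  }
  gini <- function(cnt) {
    s <- sum(cnt)
    if (s == 0) 0 else 1 - sum((cnt / s)^2)
  }
  gini_gain <- gini(c(colT, colF)) -
    row0 / n * gini(c(n00, n01)) - row1 / n * gini(c(n10, n11))
  list(ig = ig, gain_ratio = gr, su = su, chi2 = chi2, gini_gain = gini_gain)
}

# O(n^2) brute-force Relief: full pass, k = 1, Manhattan nearest neighbours,
# per-attribute diff scaled by the attribute range, negatives floored at 0.
oracle_relief <- function(x, y) {
  n <- nrow(x)
  p <- ncol(x)
  rng <- apply(x, 2, function(c) diff(range(c)))
  w <- numeric(p)
  for (i in seq_len(n)) {
    best_hit <- NULL
    best_miss <- NULL
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sum(abs(x[i, ] - x[j, ]))
      if (y[j] == y[i]) {
        if (is.null(best_hit) || dij < best_hit$d) best_hit <- list(d = dij, j = j)
      } else {
        if (is.null(best_miss) || dij < best_miss$d) best_miss <- list(d = dij, j = j)
      }
    }
    for (a in seq_len(p)) {
      if (rng[a] == 0) next
      w[a] <- w[a] +
        abs(x[i, a] - x[best_miss$j, a]) / rng[a] -
        abs(x[i, a] - x[best_hit$j, a]) / rng[a]
    }
  }
  pmax(w / n, 0)
}

# Exhaustive split search: best criterion gain over every (attribute,
# midpoint between consecutive distinct values) pair, by direct counting.
oracle_best_split_gain <- function(x, y, criterion) {
  n <- nrow(x)
  h <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log2(p))
  }
  gini <- function(cnt) {
    if (sum(cnt) == 0) return(0)
    1 - sum((cnt / sum(cnt))^2)
  }
  nT <- sum(y == "T")
  nF <- n - nT
  best <- -Inf
  for (a in seq_len(ncol(x))) {
    vals <- sort(unique(x[, a]))
    if (length(vals) < 2) next
    for (v in seq_len(length(vals) - 1)) {
      thr <- (vals[v] + vals[v + 1]) / 2
      left <- x[, a] <= thr
      TL <- sum(y[left] == "T"); FL <- sum(left) - TL
      TR <- nT - TL; FR <- nF - FL
      nL <- TL + FL; nR <- TR + FR
      gain <- switch(criterion,
        info_gain = h(c(nT, nF)) - nL / n * h(c(TL, FL)) -
          nR / n * h(c(TR, FR)),
        gain_ratio = {
          ig <- h(c(nT, nF)) - nL / n * h(c(TL, FL)) - nR / n * h(c(TR, FR))
          hs <- h(c(nL, nR))
          if (hs == 0) 0 else ig / hs
        },
        gini_index = gini(c(nT, nF)) - nL / n * gini(c(TL, FL)) -
          nR / n * gini(c(TR, FR)),
        accuracy = (max(TL, FL) + max(TR, FR)) / n - max(nT, nF) / n)
      if (gain > best) best <- gain
    }
  }
  best
}

# Frozen copy of the package's pinned EMBOSS pKa set; an independent
# net-charge expression solved with uniroot instead of bisection.
oracle_pI <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  cnt <- function(r) sum(ch == r)
  charge <- function(ph) {
    1 / (1 + 10^(ph - 8.6)) +
      cnt("K") / (1 + 10^(ph - 10.8)) +
      cnt("R") / (1 + 10^(ph - 12.5)) +
      cnt("H") / (1 + 10^(ph - 6.5)) -
      1 / (1 + 10^(3.6 - ph)) -
      cnt("D") / (1 + 10^(3.9 - ph)) -
      cnt("E") / (1 + 10^(4.1 - ph)) -
      cnt("C") / (1 + 10^(8.5 - ph)) -
      cnt("Y") / (1 + 10^(10.1 - ph))
  }
  stats::uniroot(charge, c(0, 14), tol = 1e-8)$root
}

# Frozen copy of the ExPASy average residue masses, summed independently.
oracle_mw <- function(sequence) {
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  ch <- strsplit(sequence, "")[[1]]
  sum(masses[ch[ch %in% names(masses)]]) + 18.01524
}

# Frozen ExPASy extinction coefficients, non-reduced convention.
oracle_eps280 <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  1490 * sum(ch == "Y") + 5500 * sum(ch == "W") + 125 * (sum(ch == "C") %/% 2)
}

random_peptide <- function(len, alphabet = AA_STANDARD) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Two well-separated 2-D Gaussian classes with a margin around x1 = 0.5.
make_separable_data <- function(n = 200, margin = 0.2, seed = 1) {
  set.seed(seed)
  n1 <- n %/% 2
  n2 <- n - n1
  x <- rbind(
    cbind(runif(n1, 0, 0.5 - margin / 2), runif(n1)),
    cbind(runif(n2, 0.5 + margin / 2, 1), runif(n2))
  )
  colnames(x) <- c("x1", "x2")
  list(x = x, labels = c(rep("T", n1), rep("F", n2)))
}
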