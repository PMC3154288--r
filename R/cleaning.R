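# Data cleaning in a fixed order -- duplicate records, useless (low-SD)
# attributes, correlated attributes -- followed by min-max normalization.
# SD screening happens on raw (pre-normalization) values; correlation removal
# keeps the earlier attribute in schema order, and a dropped attribute is
# never used to drop others.

#' Cleaning configuration
#'
#' @param sd_threshold Attributes with sample standard deviation less than or
#'   equal to this (on raw values) are removed as useless. Default 0.1.
#' @param corr_threshold Attribute pairs with `|Pearson r|` greater than this
#'   have the later attribute removed. Default 0.9.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(sd_threshold = 0.1, corr_threshold = 0.9) {
  stopifnot(sd_threshold >= 0, corr_threshold >= 0)
  structure(list(sd_threshold = sd_threshold, corr_threshold = corr_threshold),
            class = "cleaning_config")
}

#' Remove duplicate records
#'
#' Two records are duplicates when all numeric attribute values are equal;
#' the first in input order is kept.
#'
#' @param ft A `feature_table`.
#' @return List with the reduced `table` and a `removed` character vector of
#'   dropped record ids.
#' @export
remove_duplicate_records <- function(ft) {
  stopifnot(nrow(ft$values) > 0)
  dup <- duplicated(as.data.frame(ft$values))
  list(table = ft_rows(ft, !dup), removed = ft$ids[dup])
}

#' Remove useless (near-constant) attributes
#'
#' Numeric attributes whose sample standard deviation is less than or equal
#' to the threshold are removed. Computed on raw values, before any
#' normalization.
#'
#' @param ft A `feature_table` with at least two records.
#' @param sd_threshold SD cutoff (default 0.1).
#' @return List with the reduced `table` and `removed` attribute names.
#' @export
remove_useless_attributes <- function(ft, sd_threshold = 0.1) {
  stopifnot(nrow(ft$values) >= 2)
  sds <- apply(ft$values, 2, stats::sd)
  drop <- colnames(ft$values)[sds <= sd_threshold]
  list(table = ft_select(ft, setdiff(colnames(ft$values), drop)),
       removed = drop)
}

#' Remove correlated attributes
#'
#' Scans attribute pairs in schema order; whenever `|r|` exceeds the
#' threshold, the later attribute is dropped and the earlier kept. A dropped
#' attribute takes no further part in the scan, so it never causes other
#' removals.
#'
#' @param ft A `feature_table`; zero-SD columns must already be removed.
#' @param corr_threshold Absolute Pearson correlation cutoff (default 0.9).
#' @return List with the reduced `table` and a `removed` data.frame
#'   (`dropped`, `kept`, `r`).
#' @export
remove_correlated_attributes <- function(ft, corr_threshold = 0.9) {
  cn <- colnames(ft$values)
  cm <- suppressWarnings(abs(stats::cor(ft$values)))
  dropped <- logical(length(cn))
  rec <- list()
  for (i in seq_along(cn)) {
    if (dropped[i]) next
    j <- which(!dropped & seq_along(cn) > i & cm[i, ] > corr_threshold)
    if (length(j) > 0) {
      dropped[j] <- TRUE
      rec[[length(rec) + 1]] <- data.frame(
        dropped = cn[j], kept = cn[i], r = cm[i, j], row.names = NULL)
    }
  }
  removed <- if (length(rec) > 0) do.call(rbind, rec) else
    data.frame(dropped = character(0), kept = character(0), r = numeric(0))
  list(table = ft_select(ft, cn[!dropped]), removed = removed)
}

#' Clean a feature table
#'
#' Composite cleaning in fixed order: duplicate records, useless attributes
#' (SD threshold on raw values), correlated attributes. Idempotent.
#'
#' @param ft A `feature_table`.
#' @param config A [cleaning_config()].
#' @return List with the cleaned `table` and a `cleaning_report`.
#' @export
clean <- function(ft, config = cleaning_config()) {
  n_rec0 <- nrow(ft$values)
  n_att0 <- ncol(ft$values)
  s1 <- remove_duplicate_records(ft)
  s2 <- remove_useless_attributes(s1$table, config$sd_threshold)
  s3 <- remove_correlated_attributes(s2$table, config$corr_threshold)
  report <- structure(
    list(removed_duplicate_records = s1$removed,
         removed_useless = s2$removed,
         removed_correlated = s3$removed,
         n_records_before = n_rec0, n_records_after = nrow(s3$table$values),
         n_attributes_before = n_att0,
         n_attributes_after = ncol(s3$table$values)),
    class = "cleaning_report"
  )
  list(table = s3$table, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning report:\n",
      " records:   ", x$n_records_before, "->", x$n_records_after,
      " (", length(x$removed_duplicate_records), "duplicates )\n",
      " attributes:", x$n_attributes_before, "->", x$n_attributes_after,
      " (", length(x$removed_useless), "useless,",
      nrow(x$removed_correlated), "correlated )\n")
  invisible(x)
}

#' Fit min-max normalization parameters
#'
#' @param ft A `feature_table` with at least two records.
#' @return A `min_max_params` object (per-attribute min and max). Attributes
#'   with `max == min` raise an error: they should have been removed as
#'   useless.
#' @export
fit_min_max <- function(ft) {
  stopifnot(nrow(ft$values) >= 2)
  mins <- apply(ft$values, 2, min)
  maxs <- apply(ft$values, 2, max)
  if (any(maxs == mins)) {
    stop("constant attribute(s) cannot be min-max normalized: ",
         paste(colnames(ft$values)[maxs == mins], collapse = ", "))
  }
  structure(list(min = mins, max = maxs), class = "min_max_params")
}

#' Apply min-max normalization
#'
#' Transforms each attribute to `(x - min) / (max - min)` with the fitted
#' parameters. Values from new data falling outside the fitted range are
#' clipped to \\[0, 1\\], so printed thresholds remain applicable to fresh
#' sequences.
#'
#' @param ft A `feature_table` whose columns are a subset of the fitted ones.
#' @param params A `min_max_params` from [fit_min_max()].
#' @return The transformed `feature_table`.
#' @export
apply_min_max <- function(ft, params) {
  cn <- colnames(ft$values)
  missing <- setdiff(cn, names(params$min))
  if (length(missing) > 0) {
    stop("no normalization parameters for: ", paste(missing, collapse = ", "))
  }
  v <- sweep(ft$values, 2, params$min[cn], "-")
  v <- sweep(v, 2, (params$max - params$min)[cn], "/")
  v[v < 0] <- 0
  v[v > 1] <- 1
  feature_table(ft$ids, v, ft$nterm, ft$labels, ft$schema)
}
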