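# End-to-end orchestration: featurize -> clean -> normalize -> weight/select
# -> clustering grid (4 algorithms x FCdb + per-method datasets) -> trees ->
# neural CV, with a vote tally over the per-method selections and a stage
# manifest. "FCdb" names the full cleaned-and-normalized dataset, the
# baseline column of the clustering grid.

#' Pipeline configuration
#'
#' Bundles and validates every stage's configuration before any stage runs.
#'
#' @param cleaning A [cleaning_config()].
#' @param weighting A [weighting_config()].
#' @param weighting_methods Methods to run (default all eleven).
#' @param clustering A [cluster_config()].
#' @param cluster_algorithms Clusterers for the grid (subset of
#'   `"kmeans"`, `"kmedoids"`, `"svc"`, `"em"`).
#' @param tree A [tree_config()] (the tree stage runs all four criteria;
#'   this sets depth/leaf/gain limits).
#' @param training A [training_config()] for the neural stage.
#' @param nn_hidden Hidden layer sizes for the neural stage.
#' @param stages Stages to run, in order, from
#'   `c("clean", "weight", "cluster", "trees", "nn")`.
#' @param seed Master seed; stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cleaning = cleaning_config(),
                            weighting = weighting_config(),
                            weighting_methods = WEIGHTING_METHODS,
                            clustering = cluster_config(),
                            cluster_algorithms = c("kmeans", "kmedoids",
                                                   "svc", "em"),
                            tree = tree_config(),
                            training = training_config(),
                            nn_hidden = c(10, 5),
                            stages = c("clean", "weight", "cluster",
                                       "trees", "nn"),
                            seed = 1L) {
  stopifnot(inherits(cleaning, "cleaning_config"),
            inherits(weighting, "weighting_config"),
            inherits(clustering, "cluster_config"),
            inherits(tree, "tree_config"),
            inherits(training, "training_config"),
            all(weighting_methods %in% WEIGHTING_METHODS),
            all(cluster_algorithms %in% c("kmeans", "kmedoids", "svc", "em")),
            all(stages %in% c("clean", "weight", "cluster", "trees", "nn")))
  structure(list(cleaning = cleaning, weighting = weighting,
                 weighting_methods = weighting_methods,
                 clustering = clustering,
                 cluster_algorithms = cluster_algorithms,
                 tree = tree, training = training, nn_hidden = nn_hidden,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Tally attribute selection votes across weighting methods
#'
#' Counts, per attribute, how many weighting methods selected it, sorted by
#' decreasing vote count with ties in schema order. Attributes selected by no
#' method are absent.
#'
#' @param selections A list of `selection_result`s, or the output of
#'   [weighting_suite()].
#' @param schema_order Optional character vector fixing the tie-break order
#'   (defaults to first-seen order).
#' @return A `data.frame` with `attribute` and `votes`.
#' @export
votes_tally <- function(selections, schema_order = NULL) {
  sels <- lapply(selections, function(s) {
    if (inherits(s, "selection_result")) s$selected
    else if (!is.null(s$selection)) s$selection$selected
    else character(0)
  })
  all_attrs <- unique(unlist(sels))
  if (!is.null(schema_order)) {
    all_attrs <- schema_order[schema_order %in% all_attrs]
  }
  votes <- vapply(all_attrs, function(a) {
    sum(vapply(sels, function(s) a %in% s, logical(1)))
  }, integer(1))
  ord <- order(-votes, match(all_attrs, all_attrs))
  data.frame(attribute = all_attrs[ord], votes = unname(votes[ord]),
             row.names = NULL)
}

.run_clusterer <- function(algo, table, config) {
  switch(algo,
         kmeans = kmeans_cluster(table, config),
         kmedoids = kmedoids_cluster(table, config),
         svc = svc_cluster(table, config),
         em = em_cluster(table, config))
}

#' Run the full analysis pipeline
#'
#' Featurizes the records, cleans and min-max normalizes the table, runs the
#' weighting suite and selection, evaluates every requested clusterer on the
#' full cleaned dataset (FCdb) and on each per-method selected dataset,
#' induces decision trees under all four criteria, and cross-validates a
#' feed-forward network. A stage failure is recorded in the manifest without
#' aborting independent stages. Fully seeded.
#'
#' @param records A record table ([protein_records()] / [read_fasta()]) with
#'   complete T/F labels.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `features`, `cleaned`, `normalized`,
#'   `cleaning_report`, `minmax`, `weighting` (per-method suite output),
#'   `votes`, `grid` (data.frame: algorithm x dataset with mapped T/F counts
#'   and accuracy), `trees` (per criterion), `cv` (a `cv_report`) and
#'   `manifest`.
#' @export
run_full <- function(records, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (anyNA(records$label)) stop("all records must be labelled")
  result <- list()
  manifest <- list()
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    manifest[[name]] <<- list(
      stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 2),
      ok = !inherits(out, "stage_error"),
      error = if (inherits(out, "stage_error")) out$message else NULL)
    out
  }

  features <- log_stage("featurize", featurize(records))
  result$features <- features

  normalized <- NULL
  if ("clean" %in% config$stages && !inherits(features, "stage_error")) {
    cleaned <- log_stage("clean", clean(features, config$cleaning))
    if (!inherits(cleaned, "stage_error")) {
      result$cleaned <- cleaned$table
      result$cleaning_report <- cleaned$report
      result$minmax <- fit_min_max(cleaned$table)
      normalized <- apply_min_max(cleaned$table, result$minmax)
      result$normalized <- normalized
    }
  }

  suite <- NULL
  if ("weight" %in% config$stages && !is.null(normalized)) {
    suite <- log_stage("weight", weighting_suite(
      normalized, config$weighting_methods, config$weighting))
    if (!inherits(suite, "stage_error")) {
      result$weighting <- suite
      result$votes <- votes_tally(suite,
                                  schema_order = colnames(normalized$values))
    } else {
      suite <- NULL
    }
  }

  if ("cluster" %in% config$stages && !is.null(normalized)) {
    datasets <- list(FCdb = normalized)
    if (!is.null(suite)) {
      for (m in names(suite)) {
        if (!is.null(suite[[m]]$table)) datasets[[m]] <- suite[[m]]$table
      }
    }
    grid <- log_stage("cluster", {
      cells <- list()
      for (algo in config$cluster_algorithms) {
        for (ds in names(datasets)) {
          cell <- tryCatch({
            assign <- .run_clusterer(algo, datasets[[ds]], config$clustering)
            ev <- evaluate_clusters(assign, datasets[[ds]]$labels)
            data.frame(algorithm = algo, dataset = ds,
                       n_T = ev$counts[["T"]], n_F = ev$counts[["F"]],
                       accuracy = ev$accuracy)
          }, error = function(e) {
            data.frame(algorithm = algo, dataset = ds,
                       n_T = NA_integer_, n_F = NA_integer_,
                       accuracy = NA_real_)
          })
          cells[[paste(algo, ds)]] <- cell
        }
      }
      do.call(rbind, c(cells, list(make.row.names = FALSE)))
    })
    if (!inherits(grid, "stage_error")) result$grid <- grid
  }

  if ("trees" %in% config$stages && !is.null(normalized)) {
    trees <- log_stage("trees", {
      crits <- c("gain_ratio", "info_gain", "gini_index", "accuracy")
      stats::setNames(lapply(crits, function(cr) {
        cfg <- config$tree
        cfg$criterion <- cr
        induce_tree(normalized, config = cfg)
      }), crits)
    })
    if (!inherits(trees, "stage_error")) result$trees <- trees
  }

  if ("nn" %in% config$stages && !is.null(normalized)) {
    cv <- log_stage("nn", {
      tcfg <- config$training
      cross_validate(
        normalized,
        trainer = function(x, y) train_mlp(x, y, config$nn_hidden, tcfg),
        k = 10, seed = config$seed)
    })
    if (!inherits(cv, "stage_error")) result$cv <- cv
  }

  result$manifest <- manifest
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:\n")
  for (m in x$manifest) {
    cat(sprintf("  %-10s %s (%.2f s)%s\n", m$stage,
                if (m$ok) "ok" else "FAILED", m$seconds,
                if (!m$ok) paste0(" - ", m$error) else ""))
  }
  invisible(x)
}
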