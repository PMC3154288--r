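#!/usr/bin/env Rscript
# Data cleaning in the fixed order (duplicate records, useless attributes
# with SD <= 0.1 on raw values, correlated attributes with |r| > 0.9) and
# min-max normalization. The cleaned, normalized table is the "FCdb" baseline
# every downstream model consumes.

suppressMessages(library(thermoprofile))

ft <- read_feature_table("results/features.tsv")
res <- clean(ft, cleaning_config(sd_threshold = 0.1, corr_threshold = 0.9))
print(res$report)

params <- fit_min_max(res$table)
norm <- apply_min_max(res$table, params)
write_feature_table(norm, "results/fcdb.tsv")
jsonlite::write_json(
  list(min = as.list(params$min), max = as.list(params$max)),
  "results/minmax.json", auto_unbox = TRUE, digits = NA)
jsonlite::write_json(
  list(removed_duplicate_records = res$report$removed_duplicate_records,
       removed_useless = res$report$removed_useless,
       removed_correlated = res$report$removed_correlated,
       n_records = c(res$report$n_records_before,
                     res$report$n_records_after),
       n_attributes = c(res$report$n_attributes_before,
                        res$report$n_attributes_after)),
  "results/cleaning.json", auto_unbox = TRUE)

cat("normalized table: every value in [",
    min(norm$values), ",", max(norm$values), "] -> results/fcdb.tsv\n")
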