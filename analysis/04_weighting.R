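#!/usr/bin/env Rscript
# Run all eleven attribute-weighting algorithms on the cleaned table, select
# attributes with normalized weight > 0.5 per method, and tally how many
# methods vote for each attribute.

suppressMessages(library(thermoprofile))

norm <- read_feature_table("results/fcdb.tsv")
suite <- suppressWarnings(weighting_suite(norm))
dir.create("results/weights", showWarnings = FALSE)

for (m in names(suite)) {
  wv <- suite[[m]]$weights
  if (is.null(wv)) next
  utils::write.table(
    data.frame(attribute = names(wv$weights), raw = wv$raw,
               normalized = wv$weights),
    file.path("results/weights", paste0(m, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-12s selected %d attributes\n", m,
              length(suite[[m]]$selection$selected)))
}

votes <- votes_tally(suite, schema_order = colnames(norm$values))
utils::write.table(votes, "results/votes.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("\ntop of the vote tally (methods selecting each attribute):\n")
print(head(votes, 10))
planted <- planted_attributes()
cat("\nmethods whose selection hits a planted attribute:",
    sum(vapply(suite, function(s) any(s$selection$selected %in% planted),
               logical(1))), "of", length(suite), "\n")
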