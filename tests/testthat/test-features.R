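test_that("amino acid composition uses the two documented denominators", {
  q <- composition_counts("QQQQ")
  expect_equal(q$count[["Q"]], 4)
  expect_equal(q$freq[["Q"]], 1.0)
  expect_equal(q$pct[["Q"]], 100)

  m <- composition_counts("ACDX")
  expect_equal(m$other_count, 1)
  expect_equal(m$other_freq, 0.25)
  expect_equal(m$pct[["A"]], 100 / 3)
  expect_equal(m$freq[["A"]], 0.25)

  u <- composition_counts("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(u$freq - 0.05) < 1e-12))
  expect_equal(sum(u$freq), 1)

  expect_error(composition_counts(""), "non-empty")
})

test_that("dipeptide counts use overlapping windows and skip nonstandard", {
  d <- dipeptide_counts("QNQN")
  expect_equal(d$count[["QN"]], 2)
  expect_equal(d$count[["NQ"]], 1)
  expect_equal(d$freq[["QN"]], 2 / 3)

  aa <- dipeptide_counts("AA")
  expect_equal(aa$count[["AA"]], 1)
  expect_equal(aa$freq[["AA"]], 1.0)

  ax <- dipeptide_counts("AXA")
  expect_true(all(ax$count == 0))

  single <- dipeptide_counts("A")
  expect_true(all(single$count == 0) && all(single$freq == 0))
})

test_that("elemental composition is residue formulas plus one water", {
  g <- element_composition("G")
  expect_equal(unname(g$count[c("C", "H", "N", "O", "S")]), c(2, 5, 1, 2, 0))
  gg <- element_composition("GG")
  expect_equal(unname(gg$count[c("C", "H", "N", "O")]), c(4, 8, 2, 3))
  set.seed(11)
  for (i in 1:5) {
    e <- element_composition(random_peptide(30))
    expect_equal(sum(e$freq), 1)
  }
})

test_that("molecular weight matches the average-mass table and is additive", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01)
  expect_equal(molecular_weight("GG"), molecular_weight("G") + 57.05,
               tolerance = 0.01)
  expect_error(molecular_weight(""), "non-empty")
  set.seed(21)
  for (i in 1:10) {
    s1 <- random_peptide(sample(3:30, 1))
    s2 <- random_peptide(sample(3:30, 1))
    expect_equal(molecular_weight(paste0(s1, s2)),
                 molecular_weight(s1) + molecular_weight(s2) - 18.01524,
                 tolerance = 1e-6)
  }
  # independent reference: seqinr's average-mass computation
  set.seed(22)
  for (i in 1:10) {
    s <- random_peptide(sample(5:50, 1))
    ref <- seqinr::pmw(strsplit(s, "")[[1]])
    expect_equal(molecular_weight(s), unname(ref), tolerance = 0.05)
  }
})

test_that("net charge is strictly decreasing and pI is its root", {
  set.seed(31)
  grid <- seq(0, 14, by = 0.5)
  for (i in 1:20) {
    s <- random_peptide(sample(5:60, 1))
    ch <- net_charge(s, grid)
    expect_true(all(diff(ch) < 0))
    expect_lt(abs(net_charge(s, isoelectric_point(s))), 1e-3)
  }
  expect_gt(isoelectric_point("KKKKK"), isoelectric_point("DDDDD"))
})

test_that("pI matches an independent uniroot oracle with the same pKa table", {
  expect_equal(isoelectric_point("DDDDD"), oracle_pI("DDDDD"),
               tolerance = 0.01)
  set.seed(41)
  for (i in 1:20) {
    s <- random_peptide(sample(5:60, 1))
    expect_equal(isoelectric_point(s), oracle_pI(s), tolerance = 0.01)
  }
})

test_that("aliphatic index follows the mole-percent formula", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("AV"), 50 + 2.9 * 50)
  expect_equal(aliphatic_index("GGGG"), 0)
})

test_that("extinction at 280 nm counts Tyr, Trp and complete cystines", {
  expect_equal(extinction_280("W")$epsilon, 5500)
  expect_equal(extinction_280("C")$epsilon, 0)
  expect_equal(extinction_280("CC")$epsilon, 125)
  expect_equal(extinction_280("CC", reduced = TRUE)$epsilon, 0)
  w <- extinction_280("W")
  expect_equal(w$absorbance, 5500 / molecular_weight("W"))
})

test_that("hydropathy and charge classes partition as pinned", {
  r <- class_composition("RKH")
  expect_equal(r$count[["positive"]], 3)
  expect_equal(r$freq[["positive"]], 1)
  h <- class_composition("AVLIMFC")
  expect_equal(h$freq[["hydrophobic"]], 1)
  expect_equal(h$freq[["hydrophilic"]], 0)
  set.seed(51)
  for (i in 1:10) {
    s <- random_peptide(40)
    cc <- class_composition(s)
    expect_equal(cc$freq[["hydrophilic"]] + cc$freq[["hydrophobic"]], 1)
  }
})

test_that("featurize assembles the schema and satisfies its invariants", {
  set.seed(61)
  seqs <- c(vapply(1:8, function(i)
    random_peptide(sample(10:80, 1)), character(1)),
    vapply(1:4, function(i)
      random_peptide(sample(10:60, 1), alphabet = c(AA_STANDARD, "X", "B")),
      character(1)))
  rec <- protein_records(paste0("p", seq_along(seqs)), seqs,
                         label = rep(c("T", "F"), 6))
  ft <- featurize(rec)
  schema <- feature_schema()
  expect_equal(ncol(ft$values), sum(schema$kind == "numeric"))
  expect_equal(nrow(ft$values), 12)
  expect_equal(colnames(ft$values), schema$name[schema$kind == "numeric"])

  aa_cnt <- ft$values[, paste0("aa_count_", AA_STANDARD)]
  # conservation: standard counts + other count = length
  expect_equal(unname(rowSums(aa_cnt) + ft$values[, "other_count"]),
               unname(ft$values[, "length"]))
  # frequencies sum to one with other_freq
  aa_frq <- ft$values[, paste0("aa_freq_", AA_STANDARD)]
  expect_equal(unname(rowSums(aa_frq) + ft$values[, "other_freq"]),
               rep(1, 12), tolerance = 1e-9)
  # dipeptide frequencies sum to 1 for all-standard sequences
  std <- !grepl("[XB]", seqs)
  dp <- ft$values[, grep("^dipep_freq_", colnames(ft$values))]
  expect_equal(unname(rowSums(dp[std, ])), rep(1, sum(std)),
               tolerance = 1e-9)
  # pct relation
  l_std <- rowSums(aa_cnt)
  expect_equal(unname(ft$values[, "aa_pct_A"]),
               unname(100 * aa_cnt[, "aa_count_A"] / l_std))
  # determinism
  ft2 <- featurize(rec)
  expect_identical(ft$values, ft2$values)
})

test_that("featurize names the failing record", {
  rec <- data.frame(id = c("ok", "bad"), sequence = c("ACDE", "AC-E"),
                    opt_temp = NA, label = "T")
  expect_error(featurize(rec), "bad")
})

test_that("feature tables round-trip through TSV with a schema manifest", {
  set.seed(71)
  rec <- protein_records(c("a", "b"), c(random_peptide(30), random_peptide(40)),
                         label = c("T", "F"))
  ft <- featurize(rec)
  path <- tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  expect_true(file.exists(paste0(path, ".schema.json")))
  back <- read_feature_table(path)
  expect_equal(back$ids, ft$ids)
  expect_equal(back$labels, ft$labels)
  expect_equal(back$values, ft$values, tolerance = 1e-12)
})
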