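# Per-sequence attribute calculators and the featurize() assembler.
#
# Denominator conventions (these keep the coexisting "frequency" and
# "percentage" attribute families non-identical):
#   * frequencies divide by the full sequence length L (all letters);
#   * percentages divide by the number of standard-20 residues L_std;
#   * dipeptide frequencies divide by L - 1; a window containing a
#     nonstandard letter contributes to no dipeptide.
# Nonstandard letters (B, Z, X, U, O, J) appear only in the other_count /
# other_freq attributes and are excluded from molecular weight, isoelectric
# point, elemental composition and the hydropathy/charge classes.

.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  ch <- strsplit(toupper(sequence), "")[[1]]
  bad <- !ch %in% .aa_alphabet()
  if (any(bad)) {
    stop("invalid residue letter(s): ", paste(unique(ch[bad]), collapse = ", "))
  }
  ch
}

#' Amino acid composition of a sequence
#'
#' Counts, frequencies and percentages of the 20 standard residues, plus the
#' count and frequency of nonstandard ("other") letters. Frequencies use the
#' full length as denominator; percentages use the number of standard
#' residues, so the two families differ whenever nonstandard letters occur.
#'
#' @param sequence A single amino acid sequence string.
#' @return A list with `count` (named integer, 20), `freq`, `pct` (named
#'   numeric, 20), `other_count` and `other_freq`.
#' @export
composition_counts <- function(sequence) {
  ch <- .check_sequence(sequence)
  L <- length(ch)
  count <- tabulate(match(ch, AA_STANDARD), nbins = 20L)
  names(count) <- AA_STANDARD
  l_std <- sum(count)
  pct <- if (l_std > 0) 100 * count / l_std else count * 0
  list(
    count = count,
    freq = count / L,
    pct = pct,
    other_count = L - l_std,
    other_freq = (L - l_std) / L
  )
}

#' Dipeptide composition of a sequence
#'
#' Counts of all 400 ordered standard residue pairs over overlapping windows,
#' and their frequencies with denominator `length - 1`. Windows containing a
#' nonstandard letter are skipped entirely. Sequences of length 1 return all
#' zeros.
#'
#' @inheritParams composition_counts
#' @return A list with `count` and `freq`, each a named numeric vector of
#'   length 400 (names like `"AC"` = Ala followed by Cys).
#' @export
dipeptide_counts <- function(sequence) {
  ch <- .check_sequence(sequence)
  L <- length(ch)
  pair_names <- dipeptide_names()
  count <- stats::setNames(numeric(400), pair_names)
  if (L >= 2) {
    a <- ch[-L]
    b <- ch[-1]
    ok <- a %in% AA_STANDARD & b %in% AA_STANDARD
    if (any(ok)) {
      idx <- match(paste0(a[ok], b[ok]), pair_names)
      tab <- tabulate(idx, nbins = 400L)
      count[] <- tab
    }
    freq <- count / (L - 1)
  } else {
    freq <- count
  }
  list(count = count, freq = freq)
}

#' Canonical ordered dipeptide names
#'
#' @return Character vector of 400 two-letter names, first residue varying
#'   slowest, both in the canonical [AA_STANDARD] order.
#' @export
dipeptide_names <- function() {
  as.vector(t(outer(AA_STANDARD, AA_STANDARD, paste0)))
}

#' Elemental composition of a sequence
#'
#' Molecular formula as the sum of the standard-residue formulas plus one
#' water; nonstandard letters contribute nothing. Frequencies are element
#' counts over the total atom count.
#'
#' @inheritParams composition_counts
#' @return A list with `count` and `freq`, named numeric vectors over
#'   C, H, N, O, S.
#' @export
element_composition <- function(sequence) {
  ch <- .check_sequence(sequence)
  std <- ch[ch %in% AA_STANDARD]
  count <- WATER_FORMULA
  if (length(std) > 0) {
    count <- count + colSums(RESIDUE_FORMULA[std, , drop = FALSE])
  }
  list(count = count, freq = count / sum(count))
}

#' Average molecular weight of a sequence
#'
#' Sum of average residue masses (standard residues only) plus one water
#' (18.01524 Da).
#'
#' @inheritParams composition_counts
#' @return Weight in daltons.
#' @export
molecular_weight <- function(sequence) {
  ch <- .check_sequence(sequence)
  std <- ch[ch %in% AA_STANDARD]
  sum(RESIDUE_MASS[std]) + WATER_MASS
}

#' Net charge of a sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable side chains (C, D, E, H, K,
#' R, Y) and the two termini, with the pinned EMBOSS pKa set. Strictly
#' decreasing in pH.
#'
#' @inheritParams composition_counts
#' @param pH pH value (vectorized).
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(sequence, pH) {
  ch <- .check_sequence(sequence)
  n_pos <- c(Nterm = 1,
             K = sum(ch == "K"), R = sum(ch == "R"), H = sum(ch == "H"))
  n_neg <- c(Cterm = 1,
             D = sum(ch == "D"), E = sum(ch == "E"),
             C = sum(ch == "C"), Y = sum(ch == "Y"))
  vapply(pH, function(p) {
    pos <- sum(n_pos / (1 + 10^(p - PKA_TABLE$positive)))
    neg <- sum(n_neg / (1 + 10^(PKA_TABLE$negative - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point
#'
#' The pH in \\[0, 14\\] at which [net_charge()] is zero, found by bisection to
#' a tolerance of 1e-4 pH units. A root always exists because the charge is
#' strictly decreasing in pH and the termini guarantee a sign change.
#'
#' @inheritParams composition_counts
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence) {
  lo <- 0
  hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Aliphatic index
#'
#' Ikai's index: `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` where X is the
#' mole percent of the residue among standard residues.
#'
#' @inheritParams composition_counts
#' @return Dimensionless index.
#' @export
aliphatic_index <- function(sequence) {
  comp <- composition_counts(sequence)
  x <- comp$pct
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Molar extinction coefficient and specific absorbance at 280 nm
#'
#' ExPASy coefficients: 1490 per Tyr, 5500 per Trp, and (non-reduced only)
#' 125 per cystine, counting `floor(nCys / 2)` cystines, i.e. all possible
#' disulfide pairs. Absorbance is the extinction coefficient divided by the
#' molecular weight (the absorbance of a 1 g/l solution).
#'
#' @inheritParams composition_counts
#' @param reduced If `TRUE`, cysteines are assumed reduced and contribute
#'   nothing.
#' @return A list with `epsilon` (1/(M cm)) and `absorbance`.
#' @export
extinction_280 <- function(sequence, reduced = FALSE) {
  ch <- .check_sequence(sequence)
  eps <- EPS280[["Tyr"]] * sum(ch == "Y") + EPS280[["Trp"]] * sum(ch == "W")
  if (!reduced) eps <- eps + EPS280[["cystine"]] * floor(sum(ch == "C") / 2)
  list(epsilon = eps, absorbance = eps / molecular_weight(sequence))
}

#' Charge- and hydropathy-class composition
#'
#' Counts and full-length frequencies of positively charged (R, K, H),
#' negatively charged (D, E), hydrophilic (Kyte-Doolittle hydropathy < 0) and
#' hydrophobic (KD > 0) residues. The two hydropathy sets partition the
#' standard 20.
#'
#' @inheritParams composition_counts
#' @return A list with `count` and `freq`, named over
#'   positive/negative/hydrophilic/hydrophobic.
#' @export
class_composition <- function(sequence) {
  ch <- .check_sequence(sequence)
  L <- length(ch)
  count <- c(
    positive = sum(ch %in% CHARGE_POSITIVE),
    negative = sum(ch %in% CHARGE_NEGATIVE),
    hydrophilic = sum(ch %in% KD_HYDROPHILIC),
    hydrophobic = sum(ch %in% KD_HYDROPHOBIC)
  )
  list(count = count, freq = count / L)
}

#' The canonical feature schema
#'
#' Ordered registry of every attribute the featurizer emits: name, family and
#' kind. The order is fixed and determines tie-breaking in all downstream
#' stages (correlation cleaning, split search, vote tallies).
#'
#' @return A `data.frame` with columns `name`, `family`, `kind`.
#' @export
feature_schema <- function() {
  dp <- dipeptide_names()
  elements <- c("C", "H", "N", "O", "S")
  classes <- c("positive", "negative", "hydrophilic", "hydrophobic")
  physchem <- c("length", "mol_weight", "pI", "aliphatic_index",
                "eps280_nonreduced", "abs280_nonreduced",
                "eps280_reduced", "abs280_reduced")
  rows <- rbind(
    data.frame(name = paste0("aa_count_", AA_STANDARD), family = "aa_count"),
    data.frame(name = paste0("aa_freq_", AA_STANDARD), family = "aa_freq"),
    data.frame(name = paste0("aa_pct_", AA_STANDARD), family = "aa_pct"),
    data.frame(name = "other_count", family = "other_count"),
    data.frame(name = "other_freq", family = "other_freq"),
    data.frame(name = paste0("dipep_count_", dp), family = "dipep_count"),
    data.frame(name = paste0("dipep_freq_", dp), family = "dipep_freq"),
    data.frame(name = paste0("element_count_", elements),
               family = "element_count"),
    data.frame(name = paste0("element_freq_", elements),
               family = "element_freq"),
    data.frame(name = paste0("class_count_", classes), family = "class_count"),
    data.frame(name = paste0("class_freq_", classes), family = "class_freq"),
    data.frame(name = physchem, family = "physchem")
  )
  rows$kind <- "numeric"
  rows <- rbind(rows,
                data.frame(name = "nterm", family = "nterm",
                           kind = "categorical"))
  rows
}

.featurize_one <- function(sequence) {
  comp <- composition_counts(sequence)
  dip <- dipeptide_counts(sequence)
  elem <- element_composition(sequence)
  cls <- class_composition(sequence)
  mw <- molecular_weight(sequence)
  e_nr <- extinction_280(sequence, reduced = FALSE)
  e_r <- extinction_280(sequence, reduced = TRUE)
  c(comp$count, comp$freq, comp$pct,
    comp$other_count, comp$other_freq,
    dip$count, dip$freq,
    elem$count, elem$freq,
    cls$count, cls$freq,
    nchar(sequence), mw, isoelectric_point(sequence),
    aliphatic_index(sequence),
    e_nr$epsilon, e_nr$absorbance, e_r$epsilon, e_r$absorbance)
}

#' Compute the full feature table for a set of records
#'
#' Applies every attribute calculator to every record and assembles the
#' result in canonical schema order. The N-terminal residue is carried as a
#' separate categorical column, excluded from all numeric downstream stages.
#'
#' @param records A record table from [protein_records()] or [read_fasta()].
#' @return A `feature_table` object: list with `ids`, `values` (numeric
#'   matrix, records x attributes), `nterm` (character), `labels`
#'   (`"T"`/`"F"`/`NA`) and `schema`.
#' @export
featurize <- function(records) {
  stopifnot(nrow(records) > 0)
  schema <- feature_schema()
  numeric_names <- schema$name[schema$kind == "numeric"]
  values <- matrix(NA_real_, nrow = nrow(records),
                   ncol = length(numeric_names),
                   dimnames = list(records$id, numeric_names))
  for (i in seq_len(nrow(records))) {
    row <- tryCatch(
      .featurize_one(records$sequence[i]),
      error = function(e) stop("record '", records$id[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
    values[i, ] <- row
  }
  feature_table(
    ids = records$id,
    values = values,
    nterm = substr(toupper(records$sequence), 1, 1),
    labels = records$label,
    schema = schema
  )
}

#' Construct a feature table object
#'
#' @param ids Character vector of record ids.
#' @param values Numeric matrix, records x named attributes.
#' @param nterm Character vector of N-terminal residues (or `NULL`).
#' @param labels Character vector of `"T"`/`"F"`/`NA` labels (or `NULL`).
#' @param schema Schema `data.frame` restricted to the columns present; if
#'   `NULL`, inferred from the canonical schema by column name.
#' @return A `feature_table` object.
#' @export
feature_table <- function(ids, values, nterm = NULL, labels = NULL,
                          schema = NULL) {
  stopifnot(is.matrix(values), nrow(values) == length(ids))
  if (is.null(schema)) {
    full <- feature_schema()
    schema <- full[match(c(colnames(values),
                           if (!is.null(nterm)) "nterm"), full$name), ]
    if (anyNA(schema$name)) {
      extra <- setdiff(colnames(values), full$name)
      schema[is.na(schema$name), ] <-
        data.frame(name = extra, family = "physchem", kind = "numeric")
    }
  }
  structure(
    list(ids = as.character(ids), values = values, nterm = nterm,
         labels = if (is.null(labels)) rep(NA_character_, length(ids))
                  else as.character(labels),
         schema = schema),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "records x",
      ncol(x$values), "numeric attributes\n")
  lab <- table(factor(x$labels, levels = c("T", "F")), useNA = "ifany")
  cat("labels: T =", lab[["T"]], " F =", lab[["F"]], "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset the columns of a feature table
#'
#' @param ft A `feature_table`.
#' @param cols Character vector of attribute names to keep (schema order is
#'   preserved regardless of the order given).
#' @return A `feature_table` with the selected numeric columns.
#' @export
ft_select <- function(ft, cols) {
  keep <- colnames(ft$values)[colnames(ft$values) %in% cols]
  feature_table(ft$ids, ft$values[, keep, drop = FALSE], ft$nterm,
                ft$labels, ft$schema[ft$schema$name %in% c(keep, "nterm"), ])
}

#' Subset the rows of a feature table
#'
#' @param ft A `feature_table`.
#' @param idx Integer or logical row index.
#' @return A `feature_table` with the selected records.
#' @export
ft_rows <- function(ft, idx) {
  feature_table(ft$ids[idx], ft$values[idx, , drop = FALSE],
                if (!is.null(ft$nterm)) ft$nterm[idx], ft$labels[idx],
                ft$schema)
}

#' Write a feature table to TSV with a JSON schema manifest
#'
#' The TSV has the record id as its first column and the label as its last;
#' the manifest (same path with `.schema.json` appended) records name, family,
#' kind and order of every attribute.
#'
#' @param ft A `feature_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(id = ft$ids, ft$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(ft$nterm)) df$nterm <- ft$nterm
  df$label <- ft$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- ft$schema[ft$schema$name %in% c(colnames(ft$values), "nterm"), ]
  manifest$order <- seq_len(nrow(manifest))
  jsonlite::write_json(manifest, paste0(path, ".schema.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  classes <- ifelse(hdr %in% c("id", "label", "nterm"), "character", "numeric")
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = classes)
  ids <- df$id
  labels <- df$label
  nterm <- if ("nterm" %in% colnames(df)) df$nterm else NULL
  drop <- c("id", "label", "nterm")
  values <- as.matrix(df[, setdiff(colnames(df), drop), drop = FALSE])
  rownames(values) <- ids
  feature_table(ids, values, nterm, labels)
}
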