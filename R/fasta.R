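.aa_alphabet <- function() c(AA_STANDARD, AA_OTHER)

#' Construct a table of protein records
#'
#' A protein record holds an identifier, an amino acid sequence (IUPAC
#' one-letter codes, the standard 20 plus the ambiguity letters B, Z, X, U, O,
#' J), an optional optimum temperature in degrees Celsius and an optional
#' stability class label: `"T"` for mesostable (optimum temperature below 70)
#' or `"F"` for thermostable (above 70).
#'
#' When a temperature is given but no label, the label is derived from the
#' 70 degree cutoff. A temperature of exactly 70 cannot be labelled; such
#' records are kept with label `NA` and their ids are recorded in the
#' `"unlabelable"` attribute of the result.
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of sequences (case-insensitive).
#' @param opt_temp Optional numeric vector of optimum temperatures (Celsius).
#' @param label Optional character vector of class labels `"T"`/`"F"`.
#' @return A `data.frame` with columns `id`, `sequence`, `opt_temp`, `label`,
#'   and an `"unlabelable"` attribute listing ids that could not be labelled.
#' @export
protein_records <- function(id, sequence, opt_temp = NULL, label = NULL) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- vapply(
    strsplit(sequence, ""),
    function(ch) any(!ch %in% .aa_alphabet()),
    logical(1)
  )
  if (any(bad)) {
    stop("invalid residue letters in record(s): ",
         paste(id[bad], collapse = ", "))
  }
  n <- length(id)
  if (is.null(opt_temp)) opt_temp <- rep(NA_real_, n)
  if (is.null(label)) label <- rep(NA_character_, n)
  label <- as.character(label)
  if (any(!is.na(label) & !label %in% c("T", "F"))) {
    stop("labels must be 'T' or 'F'")
  }
  derive <- is.na(label) & !is.na(opt_temp)
  label[derive & opt_temp < 70] <- "T"
  label[derive & opt_temp > 70] <- "F"
  unlabelable <- id[derive & opt_temp == 70]
  out <- data.frame(
    id = as.character(id), sequence = sequence,
    opt_temp = as.numeric(opt_temp), label = label,
    stringsAsFactors = FALSE
  )
  attr(out, "unlabelable") <- unlabelable
  out
}

#' Read labelled protein sequences from a FASTA file
#'
#' Headers may carry the class in one of two suffix forms, separated from the
#' id by `|`: a direct tag (`>prot1|T`, `>prot1|F`) or an optimum temperature
#' (`>prot1|temp=85`), from which the label is derived with the 70 degree
#' cutoff (below 70 mesostable `T`, above 70 thermostable `F`; exactly 70 is
#' unlabelable and reported). Alternatively a two-column sidecar TSV
#' (`id<TAB>label`, no header) may supply the labels.
#'
#' @param path Path to a FASTA file (single-line or wrapped).
#' @param labels Optional path to a two-column TSV of id and label.
#' @return A record table as returned by [protein_records()]; records whose
#'   header carries no usable label keep `NA` and are listed in the
#'   `"unlabelable"` attribute.
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  tag <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_,
                character(1))
  lab <- rep(NA_character_, length(ids))
  temp <- rep(NA_real_, length(ids))
  is_tag <- !is.na(tag) & tag %in% c("T", "F")
  lab[is_tag] <- tag[is_tag]
  is_temp <- !is.na(tag) & grepl("^temp=", tag)
  temp[is_temp] <- as.numeric(sub("^temp=", "", tag[is_temp]))
  if (any(is_temp & is.na(temp))) {
    stop("unparseable temperature in header(s): ",
         paste(headers[is_temp & is.na(temp)], collapse = ", "))
  }
  if (!is.null(labels)) {
    side <- utils::read.table(labels, sep = "\t", header = FALSE,
                              col.names = c("id", "label"),
                              colClasses = "character")
    m <- match(ids, side$id)
    lab[!is.na(m)] <- side$label[m[!is.na(m)]]
  }
  rec <- protein_records(ids, as.character(seqs), opt_temp = temp, label = lab)
  no_label <- rec$id[is.na(rec$label)]
  attr(rec, "unlabelable") <- no_label
  if (length(no_label) > 0) {
    message(length(no_label), " record(s) without a usable label: ",
            paste(utils::head(no_label, 5), collapse = ", "),
            if (length(no_label) > 5) ", ..." else "")
  }
  rec
}

#' Write protein records to FASTA
#'
#' Headers are written as `id|T`, `id|F` (or bare `id` when unlabelled), the
#' format [read_fasta()] parses.
#'
#' @param records A record table from [protein_records()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(is.na(records$label), records$id,
                paste0(records$id, "|", records$label))
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
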