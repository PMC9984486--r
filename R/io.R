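#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the package alphabet: the 20
#' standard amino-acid letters plus the dummy letter `O` used for padding.
#' Any other letter is a parse error that names the offending record and
#' position.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the FASTA record
#'   identifiers (first whitespace-delimited token of each header).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "ACDE", ">P2", "GGGG"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) {
    if (all(!nzchar(trimws(raw)))) return(character(0))
    stop("not a FASTA file (no '>' header found): ", path)
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  names(seqs) <- ids
  for (i in seq_along(seqs)) validate_sequence(seqs[[i]], ids[[i]])
  seqs
}

validate_sequence <- function(seq, id = "<sequence>") {
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  ok <- .split_residues(seq) %in% AA21
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop("record '", id, "': invalid letter '",
         substr(seq, pos, pos), "' at position ", pos)
  }
  invisible(TRUE)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) > 0, !is.null(names(seqs)))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- names(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the plain-text profile dialect written by PSI-BLAST: a few header
#' lines, then one row per residue carrying the position index, the residue
#' letter and at least 20 integer substitution scores. Only the first 20 score
#' columns are kept (files frequently carry 40: scores plus weighted
#' percentages).
#'
#' @param path Path to the PSSM file.
#' @param protein_id Identifier stored with the matrix; defaults to the file
#'   base name.
#' @return An integer matrix with L rows and 20 columns, residue letters as
#'   row names, and attributes `protein_id` and `residues`.
#' @export
read_pssm <- function(path, protein_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  col_letters <- NULL
  rows <- list()
  residues <- character(0)
  for (ln in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(fields) == 0 || !nzchar(fields[[1]])) next
    # header line listing residue letters (possibly twice for 40-col files)
    if (is.null(col_letters) && all(fields %in% c(LETTERS, "*")) &&
        length(fields) >= 20) {
      col_letters <- fields[1:20]
      next
    }
    if (grepl("^[0-9]+$", fields[[1]])) {
      if (length(fields) < 22)
        stop("PSSM row at line ", ln, " has fewer than 20 score columns")
      scores <- suppressWarnings(as.integer(fields[3:22]))
      if (anyNA(scores))
        stop("non-integer PSSM score at line ", ln)
      rows[[length(rows) + 1L]] <- scores
      residues <- c(residues, toupper(fields[[2]]))
    }
  }
  if (length(rows) == 0) stop("no PSSM data rows found in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- if (!is.null(col_letters)) col_letters else PSIBLAST_COLS
  rownames(m) <- NULL
  structure(m, protein_id = protein_id, residues = residues)
}

#' Read an 881-bit drug fingerprint table
#'
#' Delimited table whose first column is the drug identifier and whose
#' remaining 881 columns are the PubChem substructure fingerprint bits
#' (0/1). A header row is auto-detected (non-numeric second field of the
#' first line).
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected among `,`,
#'   tab and `;`).
#' @return A binary integer matrix, one row per drug, 881 columns named
#'   `FP0001`..`FP0881`; row names are the drug identifiers.
#' @export
read_fingerprints <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else
    if (grepl(";", first)) ";" else stop("cannot detect delimiter in ", path)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- length(fields) >= 2 &&
    is.na(suppressWarnings(as.numeric(fields[[2]])))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 882)
    stop("fingerprint table must have 1 id + 881 bit columns, found ",
         ncol(tab) - 1L, " bit columns")
  ids <- tab[[1]]
  bits <- as.matrix(tab[, -1, drop = FALSE])
  mode(bits) <- "numeric"
  if (anyNA(bits) || !all(bits %in% c(0, 1))) {
    bad <- which(apply(bits, 1, function(r) anyNA(r) || !all(r %in% c(0, 1))))[1]
    stop("non-binary fingerprint entry in row ", bad, " (drug '", ids[bad], "')")
  }
  storage.mode(bits) <- "integer"
  dimnames(bits) <- list(ids, sprintf("FP%04d", 1:881))
  bits
}

#' Read a two-column drug-protein interaction list
#'
#' Whitespace- or tab-delimited lines of `drug_id protein_id`. Blank lines are
#' ignored; duplicate pairs are collapsed (with a message giving the unique
#' pair count).
#'
#' @param path Path to the interaction file.
#' @param quiet Suppress the pair-count message.
#' @return A data frame with character columns `drug_id` and `protein_id`.
#' @export
read_interactions <- function(path, quiet = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(drug_id = character(0), protein_id = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 2))
    stop("interaction line ", which(nf != 2)[1], " does not have 2 fields")
  df <- data.frame(drug_id = vapply(parts, `[[`, character(1), 1L),
                   protein_id = vapply(parts, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$drug_id)) || any(!nzchar(df$protein_id)))
    stop("empty identifier in interaction list")
  df <- unique(df)
  rownames(df) <- NULL
  if (!quiet) message(nrow(df), " unique interaction pairs")
  df
}

#' Write / read the labeled pair feature matrix artifact
#'
#' CSV with header `pair_id,label,<feature names...>`; round-trips losslessly
#' with [read_feature_matrix()].
#'
#' @param pairs A `dti_pairs` object (see [build_pairs()]), or a list with
#'   elements `X` (numeric matrix with column names and row names = pair ids)
#'   and `y` (0/1 labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(pairs, path) {
  X <- pairs$X
  y <- pairs$y
  stopifnot(is.matrix(X), !is.null(colnames(X)), !is.null(rownames(X)),
            length(y) == nrow(X))
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature column name: ",
         colnames(X)[duplicated(colnames(X))][1])
  df <- data.frame(pair_id = rownames(X), label = y, X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(colnames(df)[1:2] == c("pair_id", "label"))
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(X) <- df$pair_id
  new_dti_pairs(X = X, y = as.integer(df$label),
                pair_ids = .split_pair_ids(df$pair_id))
}
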