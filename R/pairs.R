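#' Encoder lists of the feature combination modes
#'
#' Mode `A` concatenates PSSM, EGAAC and EAAC (2125 protein features under
#' the default configuration); mode `B` adds DDE and BINA (4625); mode `C`
#' concatenates all ten encoders.
#'
#' @param mode `"A"`, `"B"` or `"C"`.
#' @return Character vector of encoder registry names, in concatenation
#'   order.
#' @export
combination_mode <- function(mode) {
  switch(toupper(as.character(mode)),
    A = c("PSSM", "EGAAC", "EAAC"),
    B = c("PSSM", "EGAAC", "EAAC", "DDE", "BINA"),
    C = c("PSSM", "EGAAC", "EAAC", "DDE", "BINA", "1GRAM", "2GRAM",
          "TFIDF", "NUM", "PSEPSSM", "PSEAAC"),
    stop("unknown combination mode '", mode, "' (expected A, B or C)"))
}

#' Protein feature vector for a combination mode
#'
#' @param seq Amino-acid sequence.
#' @param pssm Original-length PSSM matrix (required by all modes).
#' @param mode Combination mode (see [combination_mode()]) or a character
#'   vector of encoder names.
#' @param config An [encoder_config()].
#' @param tfidf_model Fitted [fit_tfidf()] model (mode `C`).
#' @return Named numeric vector of the concatenated encoder blocks.
#' @export
protein_feature_vector <- function(seq, pssm = NULL, mode = "A",
                                   config = encoder_config(),
                                   tfidf_model = NULL) {
  enc <- if (length(mode) == 1 && toupper(mode) %in% c("A", "B", "C"))
    combination_mode(mode) else mode
  encode_protein(seq, enc, config, pssm = pssm, tfidf_model = tfidf_model)
}

#' Protein feature matrix for a set of proteins
#'
#' @param proteins Named character vector of sequences.
#' @param pssms Named list of PSSM matrices (names matching `proteins`).
#' @param mode Combination mode or encoder name vector.
#' @param config An [encoder_config()].
#' @param tfidf_model Optional fitted TF-IDF model; if `NULL` and the mode
#'   needs one, it is fitted on `proteins`.
#' @return Numeric matrix, one row per protein (row names = protein ids).
#' @export
protein_feature_matrix <- function(proteins, pssms = NULL, mode = "A",
                                   config = encoder_config(),
                                   tfidf_model = NULL) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  enc <- if (length(mode) == 1 && toupper(mode) %in% c("A", "B", "C"))
    combination_mode(mode) else mode
  if ("TFIDF" %in% enc && is.null(tfidf_model))
    tfidf_model <- fit_tfidf(proteins, config)
  needs_pssm <- any(c("PSSM", "PSEPSSM") %in% enc)
  if (needs_pssm && is.null(pssms))
    stop("mode requires PSSMs but none were given")
  rows <- lapply(names(proteins), function(id) {
    p <- if (needs_pssm) {
      if (is.null(pssms[[id]])) stop("missing PSSM for protein '", id, "'")
      pssms[[id]]
    } else NULL
    encode_protein(proteins[[id]], enc, config, pssm = p,
                   tfidf_model = tfidf_model)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(proteins)
  m
}

.pair_id <- function(drug_id, protein_id) paste(drug_id, protein_id, sep = "|")

.split_pair_ids <- function(pair_ids) {
  parts <- strsplit(pair_ids, "|", fixed = TRUE)
  data.frame(drug_id = vapply(parts, `[[`, character(1), 1L),
             protein_id = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

new_dti_pairs <- function(X, y, pair_ids, mode = NULL) {
  stopifnot(nrow(X) == length(y), nrow(X) == nrow(pair_ids),
            all(y %in% c(0L, 1L)))
  structure(list(X = X, y = as.integer(y), pair_ids = pair_ids, mode = mode),
            class = "dti_pairs")
}

#' @export
print.dti_pairs <- function(x, ...) {
  cat("Labeled drug-protein pair set\n")
  cat("  pairs:    ", nrow(x$X), " (", sum(x$y == 1), " positive, ",
      sum(x$y == 0), " negative)\n", sep = "")
  cat("  features: ", ncol(x$X), if (!is.null(x$mode))
    paste0(" (mode ", x$mode, " + 881 fingerprint bits)") else "", "\n",
    sep = "")
  invisible(x)
}

#' Assemble a labeled drug-protein pair feature matrix
#'
#' Listed interactions become positive examples (label 1). Negatives are a
#' seeded uniform sample, without replacement, from the unlisted
#' drug-protein pairs (`round(neg_ratio * n_positive)` of them); candidate
#' negatives are enumerated in lexicographic `(drug_id, protein_id)` order
#' before sampling so the draw is reproducible across platforms. Each row's
#' feature vector is the protein combination-mode vector followed by the
#' drug's 881-bit fingerprint; rows are sorted by `(drug_id, protein_id)`.
#'
#' @param proteins Named character vector of sequences.
#' @param drugs Binary fingerprint matrix, rows named by drug id (see
#'   [read_fingerprints()]).
#' @param interactions Data frame with columns `drug_id`, `protein_id`.
#' @param mode Combination mode (`"A"`, `"B"`, `"C"`).
#' @param pssms Named list of PSSM matrices.
#' @param neg_ratio Negatives drawn per positive.
#' @param seed Integer seed for the negative sample.
#' @param config An [encoder_config()].
#' @param tfidf_model Optional fitted TF-IDF model.
#' @return A `dti_pairs` object: feature matrix `X` (row names are
#'   `drug|protein` pair ids), labels `y`, and the pair id table.
#' @export
build_pairs <- function(proteins, drugs, interactions, mode = "A",
                        pssms = NULL, neg_ratio = 1, seed = 1L,
                        config = encoder_config(), tfidf_model = NULL) {
  stopifnot(is.matrix(drugs), ncol(drugs) == 881, !is.null(rownames(drugs)),
            neg_ratio > 0)
  interactions <- unique(interactions[, c("drug_id", "protein_id")])
  unknown_d <- setdiff(interactions$drug_id, rownames(drugs))
  if (length(unknown_d)) stop("unknown drug id '", unknown_d[1], "'")
  unknown_p <- setdiff(interactions$protein_id, names(proteins))
  if (length(unknown_p)) stop("unknown protein id '", unknown_p[1], "'")

  pos_ids <- .pair_id(interactions$drug_id, interactions$protein_id)
  grid <- expand.grid(drug_id = rownames(drugs), protein_id = names(proteins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$drug_id, grid$protein_id, method = "radix"), ]
  all_ids <- .pair_id(grid$drug_id, grid$protein_id)
  cand <- all_ids[!(all_ids %in% pos_ids)]
  n_neg <- round(neg_ratio * length(pos_ids))
  if (n_neg > length(cand))
    stop("requested ", n_neg, " negatives but only ", length(cand),
         " unlisted pairs exist")
  neg_ids <- with_seed(seed, sample(cand, n_neg))

  ids <- c(pos_ids, neg_ids)
  y <- c(rep(1L, length(pos_ids)), rep(0L, length(neg_ids)))
  ord <- order(ids, method = "radix")
  ids <- ids[ord]; y <- y[ord]
  pair_tab <- .split_pair_ids(ids)

  prot_feats <- protein_feature_matrix(proteins, pssms, mode, config,
                                       tfidf_model)
  X <- cbind(prot_feats[pair_tab$protein_id, , drop = FALSE],
             drugs[pair_tab$drug_id, , drop = FALSE])
  rownames(X) <- ids
  if (anyDuplicated(colnames(X)))
    stop("feature column name collision between protein and drug blocks")
  new_dti_pairs(X = X, y = y, pair_ids = pair_tab, mode = mode)
}
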