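#' Specification of a synthetic planted-signal study
#'
#' Defines the conditions under which the synthetic generators emulate the
#' four pipeline inputs (sequences, PSSMs, fingerprints, interactions) with
#' a known feature-to-label signal: `n_informative` assembled feature
#' columns are chosen at random, standardized, and drive a logistic label
#' model with `effect_size` log-odds per unit each; labels are flipped with
#' probability `noise_rate`.
#'
#' @param n_proteins,n_drugs Entity counts.
#' @param seq_length_range Integer `(min, max)` of uniform sequence lengths.
#' @param n_informative Number of planted predictive feature columns.
#' @param effect_size Log-odds per standardized unit of each planted column.
#' @param noise_rate Label-flip probability (in `[0, 0.5)`).
#' @param seed Integer seed; every generator is a pure function of
#'   `(spec, seed)`.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(n_proteins = 40L, n_drugs = 30L,
                         seq_length_range = c(80L, 140L),
                         n_informative = 5L, effect_size = 2.0,
                         noise_rate = 0.05, seed = 1L) {
  stopifnot(n_proteins >= 1, n_drugs >= 1, n_informative >= 1,
            noise_rate >= 0, noise_rate < 0.5,
            length(seq_length_range) == 2,
            seq_length_range[1] <= seq_length_range[2])
  structure(list(n_proteins = as.integer(n_proteins),
                 n_drugs = as.integer(n_drugs),
                 seq_length_range = as.integer(seq_length_range),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate random protein sequences
#'
#' I.i.d. uniform sequences over the 20 standard residues with lengths
#' uniform in `spec$seq_length_range`.
#'
#' @param spec A [planted_spec()].
#' @return Named character vector (`P001`, `P002`, ...).
#' @export
gen_proteins <- function(spec) {
  with_seed(spec$seed, {
    lens <- sample(spec$seq_length_range[1]:spec$seq_length_range[2],
                   spec$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  })
  names(seqs) <- sprintf("P%03d", seq_len(spec$n_proteins))
  seqs
}

#' Generate a synthetic PSSM for one sequence
#'
#' Integer scores: +5 added at the observed residue's column on top of small
#' uniform noise in `-2..2` elsewhere. A stand-in profile for pipelines
#' without alignment-derived PSSMs (synthetic, not a PSI-BLAST product).
#'
#' @param seq Amino-acid sequence.
#' @param seed Integer seed.
#' @param protein_id Identifier attribute.
#' @return Integer `L x 20` matrix, columns in the A..Y alphabet order.
#' @export
gen_pssm <- function(seq, seed = 1L, protein_id = NULL) {
  res <- .split_residues(seq)
  L <- length(res)
  m <- with_seed(seed,
                 matrix(sample(-2:2, L * 20L, replace = TRUE), L, 20L))
  colnames(m) <- AA20
  hit <- match(res, AA20)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- m[cbind(which(ok), hit[ok])] + 5L
  structure(m, protein_id = protein_id, residues = res)
}

#' Generate synthetic PSSMs for a protein collection
#'
#' @param proteins Named character vector of sequences.
#' @param seed Base seed (protein `i` uses `seed + i`).
#' @return Named list of PSSM matrices.
#' @export
gen_pssms <- function(proteins, seed = 1L) {
  out <- lapply(seq_along(proteins), function(i)
    gen_pssm(proteins[[i]], seed = seed + i, protein_id = names(proteins)[i]))
  names(out) <- names(proteins)
  out
}

#' Generate random drug fingerprints
#'
#' 881-bit vectors with independent per-bit activation probability 0.1.
#'
#' @param spec A [planted_spec()].
#' @param density Per-bit activation probability.
#' @return Binary integer matrix `n_drugs x 881` (`D001`, ...; columns
#'   `FP0001`..`FP0881`).
#' @export
gen_drugs <- function(spec, density = 0.1) {
  m <- with_seed(spec$seed + 1000L,
                 matrix(stats::rbinom(spec$n_drugs * 881L, 1L, density),
                        spec$n_drugs, 881L))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sprintf("D%03d", seq_len(spec$n_drugs)),
                      sprintf("FP%04d", 1:881))
  m
}

#' Generate an interaction network with a planted feature signal
#'
#' Assembles the full candidate pair feature matrix (every drug x protein
#' pair under the given combination mode), picks `spec$n_informative`
#' non-degenerate columns at random, standardizes them, and labels each pair
#' by a logistic model with coefficient `spec$effect_size` on every planted
#' column (no intercept, so the expected positive rate is 1/2). Labels are
#' then flipped with probability `spec$noise_rate`. Pairs labeled 1 form the
#' interaction list.
#'
#' @param proteins,drugs,pssms Generated inputs (see [gen_proteins()],
#'   [gen_drugs()], [gen_pssms()]).
#' @param spec A [planted_spec()].
#' @param mode Combination mode for the assembled columns.
#' @param config An [encoder_config()].
#' @return List: `interactions` (data frame `drug_id`, `protein_id` of the
#'   positive pairs), `informative` (planted column names), `labels`
#'   (0/1 for every candidate pair) and `pair_ids` (the candidate grid, in
#'   lexicographic order).
#' @export
gen_interactions <- function(proteins, drugs, pssms, spec, mode = "A",
                             config = encoder_config()) {
  prot_feats <- protein_feature_matrix(proteins, pssms, mode, config)
  grid <- expand.grid(drug_id = rownames(drugs), protein_id = names(proteins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$drug_id, grid$protein_id, method = "radix"), ]
  rownames(grid) <- NULL
  X <- cbind(prot_feats[grid$protein_id, , drop = FALSE],
             drugs[grid$drug_id, , drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  eligible <- which(sds > .Machine$double.eps^0.5)
  if (length(eligible) < spec$n_informative)
    stop("not enough non-degenerate columns to plant the signal")
  labels <- with_seed(spec$seed + 2000L, {
    planted <- sample(eligible, spec$n_informative)
    Z <- scale(X[, planted, drop = FALSE])
    eta <- as.vector(Z %*% rep(spec$effect_size, spec$n_informative))
    y <- stats::rbinom(nrow(X), 1L, stats::plogis(eta))
    flip <- stats::rbinom(nrow(X), 1L, spec$noise_rate) == 1L
    y[flip] <- 1L - y[flip]
    list(y = y, planted = colnames(X)[planted])
  })
  pos <- grid[labels$y == 1L, , drop = FALSE]
  rownames(pos) <- NULL
  list(interactions = pos, informative = labels$planted,
       labels = labels$y, pair_ids = grid)
}

#' Write a full synthetic study to disk
#'
#' Produces the four standard input artifacts (FASTA, per-protein PSSM
#' files, fingerprint CSV, two-column interaction TSV) plus a ground-truth
#' JSON naming the planted feature columns.
#'
#' @param spec A [planted_spec()].
#' @param out_dir Output directory (created if needed).
#' @param mode Combination mode used when planting the signal.
#' @param config An [encoder_config()].
#' @return Invisibly, the list of generated objects (as from the individual
#'   generators) plus the written paths.
#' @export
simulate_dti_data <- function(spec, out_dir, mode = "A",
                              config = encoder_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- gen_proteins(spec)
  pssms <- gen_pssms(proteins, spec$seed)
  drugs <- gen_drugs(spec)
  net <- gen_interactions(proteins, drugs, pssms, spec, mode, config)

  fasta <- file.path(out_dir, "proteins.fasta")
  write_fasta(proteins, fasta)
  pssm_dir <- file.path(out_dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (id in names(pssms)) write_pssm(pssms[[id]], file.path(pssm_dir,
                                                             paste0(id, ".pssm")))
  fp <- file.path(out_dir, "fingerprints.csv")
  utils::write.table(data.frame(drug_id = rownames(drugs), drugs,
                                check.names = FALSE),
                     fp, sep = ",", row.names = FALSE, quote = FALSE)
  pairs_path <- file.path(out_dir, "interactions.tsv")
  utils::write.table(net$interactions, pairs_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  truth <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(informative = net$informative,
                            spec = unclass(spec)),
                       truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(proteins = proteins, pssms = pssms, drugs = drugs,
                 network = net,
                 paths = list(fasta = fasta, pssm_dir = pssm_dir,
                              fingerprints = fp, interactions = pairs_path,
                              ground_truth = truth)))
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Round-trips with [read_pssm()].
#'
#' @param pssm `L x 20` integer matrix with a `residues` attribute (or row
#'   letters defaulting to `X`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(is.matrix(pssm), ncol(pssm) == 20)
  res <- attr(pssm, "residues")
  if (is.null(res)) res <- rep("X", nrow(pssm))
  cols <- colnames(pssm)
  if (is.null(cols)) cols <- PSIBLAST_COLS
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("            ", paste(cols, collapse = "   "))), con)
  for (i in seq_len(nrow(pssm)))
    writeLines(sprintf("%5d %s %s", i, res[i],
                       paste(sprintf("%3d", pssm[i, ]), collapse = " ")), con)
  invisible(path)
}
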