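#' Encoder configuration
#'
#' Shared tuning parameters of the protein sequence encoders.
#'
#' @param L_fixed Fixed sequence length for the positional encoders (EAAC,
#'   EGAAC, NUM, BINA, PSSM flattening): longer sequences are truncated,
#'   shorter ones padded with the dummy residue `O`. Must be divisible by
#'   `eaac_windows`.
#' @param eaac_windows Number of equal non-overlapping windows used by EAAC
#'   and EGAAC.
#' @param pseaac_lambda Number of sequence-order correlation factors of
#'   PseAAC (its dimension is `20 + pseaac_lambda`).
#' @param pseaac_weight Weight `w` of the correlation factors in the PseAAC
#'   normalization.
#' @param tfidf_log_base Logarithm base of the inverse document frequency.
#' @param psepssm_epsilon Largest lag of the PsePSSM correlation terms (its
#'   dimension is `20 * (1 + psepssm_epsilon)`); must be smaller than the
#'   length of every input PSSM.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(L_fixed = 100L, eaac_windows = 5L,
                           pseaac_lambda = 8L, pseaac_weight = 0.05,
                           tfidf_log_base = 10, psepssm_epsilon = 10L) {
  stopifnot(L_fixed >= 1, eaac_windows >= 1, L_fixed %% eaac_windows == 0,
            pseaac_lambda >= 1, pseaac_weight > 0, tfidf_log_base > 1,
            psepssm_epsilon >= 1)
  structure(list(L_fixed = as.integer(L_fixed),
                 eaac_windows = as.integer(eaac_windows),
                 pseaac_lambda = as.integer(pseaac_lambda),
                 pseaac_weight = pseaac_weight,
                 tfidf_log_base = tfidf_log_base,
                 psepssm_epsilon = as.integer(psepssm_epsilon)),
            class = "encoder_config")
}

#' Truncate or pad a sequence to a fixed length
#'
#' Longer sequences keep their first `L_fixed` residues; shorter ones are
#' right-padded with the dummy residue `O`.
#'
#' @param seq Amino-acid string.
#' @param L_fixed Target length.
#' @return A string of exactly `L_fixed` characters.
#' @export
normalize_sequence <- function(seq, L_fixed = 100L) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  n <- nchar(seq)
  if (n >= L_fixed) substr(seq, 1L, L_fixed)
  else paste0(seq, strrep("O", L_fixed - n))
}

.window_bounds <- function(L_fixed, n_windows) {
  w <- L_fixed %/% n_windows
  cbind(start = seq(1L, L_fixed, by = w), end = seq(w, L_fixed, by = w))
}

#' Enhanced amino acid composition (EAAC)
#'
#' The normalized sequence is split into `eaac_windows` equal non-overlapping
#' windows; within each window the relative frequency of each of the 20
#' standard residues is computed with the full window length as denominator
#' (padding `O` counts in the denominator only).
#'
#' @param seq_norm Sequence of length `config$L_fixed` (see
#'   [normalize_sequence()]).
#' @param config An [encoder_config()].
#' @return Named numeric vector of length `20 * eaac_windows` (100 by
#'   default), window-major, names `EAAC_w<window>_<residue>`.
#' @export
encode_eaac <- function(seq_norm, config = encoder_config()) {
  stopifnot(nchar(seq_norm) == config$L_fixed)
  res <- .split_residues(seq_norm)
  b <- .window_bounds(config$L_fixed, config$eaac_windows)
  out <- numeric(0)
  for (w in seq_len(nrow(b))) {
    win <- res[b[w, 1]:b[w, 2]]
    cnt <- vapply(AA20, function(a) sum(win == a), numeric(1))
    v <- cnt / length(win)
    names(v) <- paste0("EAAC_w", w, "_", AA20)
    out <- c(out, v)
  }
  out
}

#' Enhanced grouped amino acid composition (EGAAC)
#'
#' Like [encode_eaac()] but over five physicochemical groups: aliphatic
#' (GAVLMI), aromatic (FYW), positively charged (KRH), negatively charged
#' (DE) and uncharged (STCPNQ).
#'
#' @inheritParams encode_eaac
#' @return Named numeric vector of length `5 * eaac_windows` (25 by default),
#'   names `EGAAC_w<window>_<group>`.
#' @export
encode_egaac <- function(seq_norm, config = encoder_config()) {
  stopifnot(nchar(seq_norm) == config$L_fixed)
  res <- .split_residues(seq_norm)
  b <- .window_bounds(config$L_fixed, config$eaac_windows)
  out <- numeric(0)
  for (w in seq_len(nrow(b))) {
    win <- res[b[w, 1]:b[w, 2]]
    v <- vapply(AA_GROUPS, function(g) sum(win %in% g), numeric(1)) /
      length(win)
    names(v) <- paste0("EGAAC_w", w, "_", names(AA_GROUPS))
    out <- c(out, v)
  }
  out
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' Dipeptide composition standardized against a codon-based expectation.
#' For each ordered standard-residue dipeptide `(m, n)`:
#' `DC = H_mn / (H - 1)` (adjacent-pair count over standard residues, pairs
#' containing the dummy `O` skipped), `TM = (C_m / 61) * (C_n / 61)` with
#' `C_m` the sense-codon count of residue `m`, `TV = TM (1 - TM) / (H - 1)`
#' and `DDE = (DC - TM) / sqrt(TV)`.
#'
#' @param seq Original (un-normalized) sequence with at least two standard
#'   residues.
#' @return Named numeric vector of length 400, names `DDE_<mn>`.
#' @export
encode_dde <- function(seq) {
  res <- .split_residues(seq)
  std <- res[res %in% AA20]
  H <- length(std)
  if (H < 2) stop("DDE needs at least 2 standard residues")
  n <- length(res)
  left <- res[-n]; right <- res[-1]
  keep <- left %in% AA20 & right %in% AA20
  dip <- paste0(left[keep], right[keep])
  all_dip <- paste0(rep(AA20, each = 20L), rep(AA20, times = 20L))
  counts <- vapply(all_dip, function(d) sum(dip == d), numeric(1))
  DC <- counts / (H - 1)
  cm <- CODON_COUNTS[substr(all_dip, 1, 1)] / CODON_TOTAL
  cn <- CODON_COUNTS[substr(all_dip, 2, 2)] / CODON_TOTAL
  TM <- cm * cn
  TV <- TM * (1 - TM) / (H - 1)
  out <- (DC - TM) / sqrt(TV)
  names(out) <- paste0("DDE_", all_dip)
  out
}

#' Fit residue-level inverse document frequencies (TF-IDF)
#'
#' For each of the 20 standard residues `t`, `DF(t)` is the number of corpus
#' sequences containing `t` and `IDF(t) = log_base(|D| / max(DF(t), 1))`
#' (smoothing floor of 1 for residues absent from the corpus).
#'
#' @param corpus Named character vector of sequences.
#' @param config An [encoder_config()] (`tfidf_log_base`).
#' @return Object of class `tfidf_model` holding the 20 IDF values.
#' @export
fit_tfidf <- function(corpus, config = encoder_config()) {
  stopifnot(is.character(corpus), length(corpus) > 0)
  D <- length(corpus)
  df <- vapply(AA20, function(a)
    sum(vapply(corpus, function(s) grepl(a, s, fixed = TRUE), logical(1))),
    numeric(1))
  idf <- log(D / pmax(df, 1), base = config$tfidf_log_base)
  structure(list(idf = idf, n_docs = D, log_base = config$tfidf_log_base),
            class = "tfidf_model")
}

#' TF-IDF encoding of a sequence
#'
#' Component `t` is `TF(t, d) * IDF(t)` where `TF` is the count of residue
#' `t` divided by the sequence length.
#'
#' @param seq Original sequence.
#' @param model A fitted [fit_tfidf()] model.
#' @return Named numeric vector of length 20, names `TFIDF_<residue>`.
#' @export
encode_tfidf <- function(seq, model) {
  if (!inherits(model, "tfidf_model")) stop("model must be a fitted tfidf_model")
  res <- .split_residues(seq)
  tf <- vapply(AA20, function(a) sum(res == a), numeric(1)) / length(res)
  out <- tf * model$idf
  names(out) <- paste0("TFIDF_", AA20)
  out
}

#' k-gram relative frequencies
#'
#' `k = 1`: relative frequency of each of the 21 letters (the 20 standard
#' residues plus the dummy `O`), denominator the sequence length. `k = 2`:
#' relative frequency of each of the 400 ordered standard-residue dipeptides,
#' denominator `N - 1` (pairs containing `O` are skipped in the numerator
#' only).
#'
#' @param seq Original sequence.
#' @param k 1 or 2.
#' @return Named numeric vector of length 21 (`G1_<letter>`) or 400
#'   (`G2_<mn>`).
#' @export
encode_kgram <- function(seq, k) {
  res <- .split_residues(seq)
  N <- length(res)
  if (identical(as.integer(k), 1L)) {
    out <- vapply(AA21, function(a) sum(res == a), numeric(1)) / N
    names(out) <- paste0("G1_", AA21)
    return(out)
  }
  if (identical(as.integer(k), 2L)) {
    if (N < 2) stop("2-gram needs length >= 2")
    left <- res[-N]; right <- res[-1]
    keep <- left %in% AA20 & right %in% AA20
    dip <- paste0(left[keep], right[keep])
    all_dip <- paste0(rep(AA20, each = 20L), rep(AA20, times = 20L))
    out <- vapply(all_dip, function(d) sum(dip == d), numeric(1)) / (N - 1)
    names(out) <- paste0("G2_", all_dip)
    return(out)
  }
  stop("k must be 1 or 2")
}

#' Integer positional encoding (NUM)
#'
#' Each position of the normalized sequence is mapped to its alphabetical
#' code: A=1, C=2, ..., Y=20, dummy O=21.
#'
#' @inheritParams encode_eaac
#' @return Named numeric vector of length `L_fixed`, names `NUM_p<i>`.
#' @export
encode_num <- function(seq_norm, config = encoder_config()) {
  stopifnot(nchar(seq_norm) == config$L_fixed)
  out <- as.numeric(match(.split_residues(seq_norm), AA21))
  names(out) <- paste0("NUM_p", seq_len(config$L_fixed))
  out
}

#' One-hot positional encoding (BINA)
#'
#' Each position of the normalized sequence becomes a 21-dimensional
#' orthogonal binary vector in the NUM alphabet order (`A` is
#' `1,0,...,0`; the dummy `O` is `0,...,0,1`), concatenated position-major.
#'
#' @inheritParams encode_eaac
#' @return Named numeric vector of length `21 * L_fixed`, names
#'   `BINA_p<i>_<letter>`.
#' @export
encode_bina <- function(seq_norm, config = encoder_config()) {
  stopifnot(nchar(seq_norm) == config$L_fixed)
  codes <- match(.split_residues(seq_norm), AA21)
  L <- config$L_fixed
  m <- matrix(0, nrow = L, ncol = 21L)
  m[cbind(seq_len(L), codes)] <- 1
  out <- as.vector(t(m))
  names(out) <- paste0("BINA_p", rep(seq_len(L), each = 21L), "_",
                       rep(AA21, times = L))
  out
}

#' Pseudo amino acid composition (PseAAC)
#'
#' Chou's classic formulation: the first 20 components are the standard
#' amino-acid composition and the last `lambda` components are sequence-order
#' correlation factors, jointly normalized so the vector sums to 1:
#' component `u <= 20` is `f_u / (sum(f) + w * sum(theta))`, component
#' `20 + k` is `w * theta_k / (sum(f) + w * sum(theta))`. `theta_k` is the
#' average, over residue pairs `k` apart, of the mean squared difference of
#' three standardized property scales (hydrophobicity, hydrophilicity,
#' side-chain mass). Dummy `O` residues are removed before computation.
#'
#' @param seq Original sequence with more than `pseaac_lambda` standard
#'   residues.
#' @param config An [encoder_config()] (`pseaac_lambda`, `pseaac_weight`).
#' @return Named numeric vector of length `20 + pseaac_lambda` (28 by
#'   default), names `PSEAAC_f_<residue>` and `PSEAAC_theta<k>`.
#' @export
encode_pseaac <- function(seq, config = encoder_config()) {
  lam <- config$pseaac_lambda
  w <- config$pseaac_weight
  res <- .split_residues(seq)
  res <- res[res %in% AA20]
  L <- length(res)
  if (L <= lam)
    stop("PseAAC needs more than lambda = ", lam, " standard residues")
  scales <- list(.standardize_scale(PSEAAC_HYDROPHOBICITY),
                 .standardize_scale(PSEAAC_HYDROPHILICITY),
                 .standardize_scale(PSEAAC_SIDECHAIN_MASS))
  props <- vapply(scales, function(s) s[res], numeric(L))  # L x 3
  theta <- vapply(seq_len(lam), function(k) {
    d <- props[seq_len(L - k), , drop = FALSE] -
      props[seq_len(L - k) + k, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
  f <- vapply(AA20, function(a) sum(res == a), numeric(1)) / L
  denom <- sum(f) + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(paste0("PSEAAC_f_", AA20), paste0("PSEAAC_theta", seq_len(lam)))
  out
}

# ---- registry ---------------------------------------------------------------

#' Protein encoder registry
#'
#' Encoders addressable by name, with their output dimensions under a given
#' configuration. Positional encoders (EAAC, EGAAC, NUM, BINA, PSSM) operate
#' on the length-normalized sequence/PSSM; global-composition encoders (DDE,
#' TFIDF, 1GRAM, 2GRAM, PSEAAC) and PSEPSSM operate on the original input.
#'
#' @param config An [encoder_config()].
#' @return Named integer vector of encoder dimensions, in registry order.
#' @export
encoder_dimensions <- function(config = encoder_config()) {
  c(EAAC = 20L * config$eaac_windows,
    EGAAC = 5L * config$eaac_windows,
    DDE = 400L,
    TFIDF = 20L,
    `1GRAM` = 21L,
    `2GRAM` = 400L,
    NUM = config$L_fixed,
    BINA = 21L * config$L_fixed,
    PSSM = 20L * config$L_fixed,
    PSEPSSM = 20L * (1L + config$psepssm_epsilon),
    PSEAAC = 20L + config$pseaac_lambda)
}

#' Encode a protein with a list of named encoders
#'
#' @param seq Original amino-acid sequence.
#' @param encoders Character vector of registry names (see
#'   [encoder_dimensions()]).
#' @param config An [encoder_config()].
#' @param pssm Original-length PSSM matrix (required for `PSSM`/`PSEPSSM`).
#' @param tfidf_model A fitted [fit_tfidf()] model (required for `TFIDF`).
#' @return Named numeric vector: the concatenated encoder blocks in the
#'   requested order.
#' @export
encode_protein <- function(seq, encoders, config = encoder_config(),
                           pssm = NULL, tfidf_model = NULL) {
  validate_sequence(seq)
  seq_norm <- normalize_sequence(seq, config$L_fixed)
  blocks <- lapply(encoders, function(e) {
    switch(e,
      EAAC = encode_eaac(seq_norm, config),
      EGAAC = encode_egaac(seq_norm, config),
      DDE = encode_dde(seq),
      TFIDF = {
        if (is.null(tfidf_model)) stop("encoder TFIDF requires a fitted model")
        encode_tfidf(seq, tfidf_model)
      },
      `1GRAM` = encode_kgram(seq, 1L),
      `2GRAM` = encode_kgram(seq, 2L),
      NUM = encode_num(seq_norm, config),
      BINA = encode_bina(seq_norm, config),
      PSSM = {
        if (is.null(pssm)) stop("encoder PSSM requires a PSSM matrix")
        flatten_pssm(normalize_pssm_length(pssm, config$L_fixed))
      },
      PSEPSSM = {
        if (is.null(pssm)) stop("encoder PSEPSSM requires a PSSM matrix")
        encode_psepssm(pssm, config)
      },
      PSEAAC = encode_pseaac(seq, config),
      stop("unknown encoder '", e, "'"))
  })
  do.call(c, blocks)
}
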