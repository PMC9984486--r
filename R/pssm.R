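#' Truncate or zero-pad a PSSM to a fixed number of rows
#'
#' @param pssm L x 20 score matrix (see [read_pssm()]).
#' @param L_fixed Target row count.
#' @return An `L_fixed` x 20 matrix; extra rows dropped or zero rows appended.
#' @export
normalize_pssm_length <- function(pssm, L_fixed = 100L) {
  stopifnot(is.matrix(pssm), ncol(pssm) == 20, nrow(pssm) >= 1)
  L <- nrow(pssm)
  out <- if (L >= L_fixed) pssm[seq_len(L_fixed), , drop = FALSE]
  else rbind(pssm, matrix(0, nrow = L_fixed - L, ncol = 20,
                          dimnames = list(NULL, colnames(pssm))))
  attr(out, "protein_id") <- attr(pssm, "protein_id")
  out
}

#' Flatten a length-normalized PSSM into a feature vector
#'
#' Row-major: the 20 scores of position 1 come first.
#'
#' @param pssm_norm Matrix from [normalize_pssm_length()].
#' @return Named numeric vector of length `20 * nrow(pssm_norm)`, names
#'   `PSSM_p<i>_<column>`.
#' @export
flatten_pssm <- function(pssm_norm) {
  stopifnot(is.matrix(pssm_norm), ncol(pssm_norm) == 20)
  L <- nrow(pssm_norm)
  cols <- colnames(pssm_norm)
  if (is.null(cols)) cols <- PSIBLAST_COLS
  out <- as.vector(t(pssm_norm))
  names(out) <- paste0("PSSM_p", rep(seq_len(L), each = 20L), "_",
                       rep(cols, times = L))
  out
}

#' Pseudo position-specific scoring matrix (PsePSSM)
#'
#' Fixed-length summary of a variable-length PSSM: the first 20 components
#' are the per-column mean scores; for each lag `eps` in `1..epsilon_max` and
#' each column `j`, component `p_j^eps` is the mean squared difference of
#' scores `eps` positions apart,
#' `(1 / (L - eps)) * sum_i (P[i, j] - P[i + eps, j])^2`. Computed on the
#' original-length matrix (no truncation or padding); raw scores are used.
#'
#' @param pssm L x 20 score matrix with `L > epsilon_max`.
#' @param config An [encoder_config()] (`psepssm_epsilon`).
#' @return Named numeric vector of length `20 * (1 + epsilon_max)` (220 by
#'   default), ordered mean block first, then the lag blocks; names
#'   `PSEPSSM_mean_<col>` and `PSEPSSM_e<lag>_<col>`.
#' @export
encode_psepssm <- function(pssm, config = encoder_config()) {
  stopifnot(is.matrix(pssm), ncol(pssm) == 20)
  eps_max <- config$psepssm_epsilon
  L <- nrow(pssm)
  if (L <= eps_max)
    stop("PsePSSM needs L > epsilon_max = ", eps_max, " (got L = ", L, ")")
  cols <- colnames(pssm)
  if (is.null(cols)) cols <- PSIBLAST_COLS
  means <- colMeans(pssm)
  names(means) <- paste0("PSEPSSM_mean_", cols)
  lags <- lapply(seq_len(eps_max), function(eps) {
    d <- pssm[seq_len(L - eps), , drop = FALSE] -
      pssm[seq_len(L - eps) + eps, , drop = FALSE]
    v <- colSums(d^2) / (L - eps)
    names(v) <- paste0("PSEPSSM_e", eps, "_", cols)
    v
  })
  c(means, do.call(c, lags))
}
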