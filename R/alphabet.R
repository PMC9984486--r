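# Internal alphabet and physicochemical constants shared by the encoders.

# 20 standard amino acids in alphabetical (one-letter) order; positions define
# the NUM codes 1..20. The dummy residue 'O' (code 21) pads short sequences.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "O")

# Physicochemical groups for grouped composition (EGAAC). The aromatic group
# is FYW: G belongs to the aliphatic group and cannot be aromatic as well.
AA_GROUPS <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

# Sense-codon counts of the standard genetic code (61 sense codons total);
# expectation model for the DDE encoder.
CODON_COUNTS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                  K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                  T = 4, V = 4, W = 1, Y = 2)
CODON_TOTAL <- 61

# Chou's three property scales used by the PseAAC sequence-order terms:
# hydrophobicity, hydrophilicity and side-chain mass. Standardized (population
# mean 0 / sd 1 over the 20 residues) before use.
PSEAAC_HYDROPHOBICITY <- c(
  A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
  I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
  R = -2.53, S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
PSEAAC_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
  I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
  R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
PSEAAC_SIDECHAIN_MASS <- c(
  A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0, G = 1.0, H = 82.0,
  I = 57.0, K = 73.0, L = 57.0, M = 75.0, N = 58.0, P = 42.0, Q = 72.0,
  R = 101.0, S = 31.0, T = 45.0, V = 43.0, W = 130.0, Y = 107.0)

# PSI-BLAST ASCII profile column order (used when a PSSM file carries no
# parseable header).
PSIBLAST_COLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# standardize a named 20-residue property scale (population sd, Chou convention)
.standardize_scale <- function(x) {
  x <- x[AA20]
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

.split_residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# evaluate expr with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
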