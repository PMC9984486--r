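# Independent naive-counting oracles used to cross-check the encoders and
# evaluation primitives. Everything here is implemented with plain loops and
# its own constants, deliberately not sharing code with the package.

ORA_AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ORA_AA21 <- c(ORA_AA20, "O")
ORA_GROUPS <- list(aliphatic = strsplit("GAVLMI", "")[[1]],
                   aromatic = strsplit("FYW", "")[[1]],
                   positive = strsplit("KRH", "")[[1]],
                   negative = strsplit("DE", "")[[1]],
                   uncharged = strsplit("STCPNQ", "")[[1]])
ORA_CODONS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                T = 4, V = 4, W = 1, Y = 2)

rand_seq <- function(len, include_o = FALSE) {
  alpha <- if (include_o) ORA_AA21 else ORA_AA20
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

ora_chars <- function(seq) strsplit(seq, "")[[1]]

ora_pad <- function(seq, L) {
  if (nchar(seq) >= L) substr(seq, 1, L)
  else paste0(seq, paste(rep("O", L - nchar(seq)), collapse = ""))
}

ora_eaac <- function(seq_norm, n_win = 5) {
  ch <- ora_chars(seq_norm)
  w <- length(ch) / n_win
  out <- numeric(0)
  for (i in seq_len(n_win)) {
    win <- ch[((i - 1) * w + 1):(i * w)]
    for (a in ORA_AA20) out <- c(out, sum(win == a) / w)
  }
  out
}

ora_egaac <- function(seq_norm, n_win = 5) {
  ch <- ora_chars(seq_norm)
  w <- length(ch) / n_win
  out <- numeric(0)
  for (i in seq_len(n_win)) {
    win <- ch[((i - 1) * w + 1):(i * w)]
    for (g in ORA_GROUPS) out <- c(out, sum(win %in% g) / w)
  }
  out
}

ora_dde <- function(seq) {
  ch <- ora_chars(seq)
  H <- sum(ch %in% ORA_AA20)
  out <- numeric(0)
  for (m in ORA_AA20) for (n in ORA_AA20) {
    cnt <- 0
    for (i in seq_len(length(ch) - 1))
      if (ch[i] == m && ch[i + 1] == n) cnt <- cnt + 1
    dc <- cnt / (H - 1)
    tm <- (ORA_CODONS[[m]] / 61) * (ORA_CODONS[[n]] / 61)
    tv <- tm * (1 - tm) / (H - 1)
    out <- c(out, (dc - tm) / sqrt(tv))
  }
  out
}

ora_tfidf <- function(corpus, seq, base = 10) {
  D <- length(corpus)
  ch <- ora_chars(seq)
  out <- numeric(0)
  for (a in ORA_AA20) {
    df <- 0
    for (s in corpus) if (a %in% ora_chars(s)) df <- df + 1
    idf <- log(D / max(df, 1), base = base)
    out <- c(out, (sum(ch == a) / length(ch)) * idf)
  }
  out
}

ora_kgram1 <- function(seq) {
  ch <- ora_chars(seq)
  vapply(ORA_AA21, function(a) sum(ch == a) / length(ch), numeric(1))
}

ora_kgram2 <- function(seq) {
  ch <- ora_chars(seq)
  N <- length(ch)
  out <- numeric(0)
  for (m in ORA_AA20) for (n in ORA_AA20) {
    cnt <- 0
    for (i in seq_len(N - 1)) if (ch[i] == m && ch[i + 1] == n) cnt <- cnt + 1
    out <- c(out, cnt / (N - 1))
  }
  out
}

ora_num <- function(seq_norm) {
  ch <- ora_chars(seq_norm)
  vapply(ch, function(a) which(ORA_AA21 == a), numeric(1))
}

ora_bina <- function(seq_norm) {
  ch <- ora_chars(seq_norm)
  out <- numeric(0)
  for (a in ch) {
    v <- rep(0, 21)
    v[which(ORA_AA21 == a)] <- 1
    out <- c(out, v)
  }
  out
}

ORA_HPHOB <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
               H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
               P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
               W = 0.81, Y = 0.26)
ORA_HPHIL <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
               H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
               P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
               W = -3.4, Y = -2.3)
ORA_MASS <- c(A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0, G = 1.0,
              H = 82.0, I = 57.0, K = 73.0, L = 57.0, M = 75.0, N = 58.0,
              P = 42.0, Q = 72.0, R = 101.0, S = 31.0, T = 45.0, V = 43.0,
              W = 130.0, Y = 107.0)

ora_pseaac <- function(seq, lambda = 8, w = 0.05) {
  std <- function(x) {
    x <- x[ORA_AA20]
    (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  }
  sc <- list(std(ORA_HPHOB), std(ORA_HPHIL), std(ORA_MASS))
  ch <- ora_chars(seq)
  ch <- ch[ch %in% ORA_AA20]
  L <- length(ch)
  corr <- function(a, b)
    mean(c((sc[[1]][a] - sc[[1]][b])^2, (sc[[2]][a] - sc[[2]][b])^2,
           (sc[[3]][a] - sc[[3]][b])^2))
  theta <- numeric(lambda)
  for (k in seq_len(lambda)) {
    tot <- 0
    for (i in seq_len(L - k)) tot <- tot + corr(ch[i], ch[i + k])
    theta[k] <- tot / (L - k)
  }
  f <- vapply(ORA_AA20, function(a) sum(ch == a) / L, numeric(1))
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

ora_psepssm <- function(m, eps_max = 10) {
  L <- nrow(m)
  out <- numeric(0)
  for (j in 1:20) out <- c(out, sum(m[, j]) / L)
  for (eps in seq_len(eps_max)) for (j in 1:20) {
    tot <- 0
    for (i in seq_len(L - eps)) tot <- tot + (m[i, j] - m[i + eps, j])^2
    out <- c(out, tot / (L - eps))
  }
  out
}

# AUC by explicit pairwise comparison (ties count 1/2)
ora_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# SU from the joint distribution via mutual information
ora_su <- function(f, c) {
  pf <- table(f) / length(f)
  pc <- table(c) / length(c)
  pj <- table(f, c) / length(f)
  hf <- -sum(pf * log2(pf))
  hc <- -sum(pc * log2(pc))
  mi <- 0
  for (i in rownames(pj)) for (j in colnames(pj)) {
    p <- pj[i, j]
    if (p > 0) mi <- mi + p * log2(p / (pf[[i]] * pc[[j]]))
  }
  if (hf + hc == 0) 0 else 2 * mi / (hf + hc)
}
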