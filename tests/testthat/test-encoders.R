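cfg <- encoder_config()

test_that("sequence normalization truncates and pads with the dummy residue", {
  long <- paste(rep("ACDEF", 24), collapse = "")   # 120-mer
  expect_equal(normalize_sequence(long, 100), substr(long, 1, 100))
  expect_equal(normalize_sequence("ACD", 5), "ACDOO")
  s100 <- strrep("A", 100)
  expect_equal(normalize_sequence(s100, 100), s100)
  expect_error(normalize_sequence("", 5))
})

test_that("EAAC computes windowed residue frequencies with padding in the denominator only", {
  v <- encode_eaac(strrep("A", 100), cfg)
  expect_length(v, 100)
  expect_equal(unname(v[paste0("EAAC_w", 1:5, "_A")]), rep(1, 5))
  expect_equal(sum(v), 5)

  seq2 <- paste0(strrep("A", 10), strrep("C", 10), strrep("G", 80))
  v2 <- encode_eaac(seq2, cfg)
  expect_equal(v2[["EAAC_w1_A"]], 0.5)
  expect_equal(v2[["EAAC_w1_C"]], 0.5)

  # last window all padding -> zero block; window sums <= 1 with equality iff no padding
  seq3 <- normalize_sequence(strrep("M", 80), 100)
  v3 <- encode_eaac(seq3, cfg)
  expect_equal(unname(v3[grep("w5", names(v3))]), rep(0, 20))
  win_sums <- vapply(1:5, function(w) sum(v3[grep(paste0("w", w, "_"),
                                                  names(v3))]), numeric(1))
  expect_equal(win_sums, c(1, 1, 1, 1, 0))
})

test_that("EGAAC groups residues into the five physicochemical classes", {
  vG <- encode_egaac(strrep("G", 100), cfg)
  expect_length(vG, 25)
  expect_equal(unname(vG[grep("aliphatic", names(vG))]), rep(1, 5))

  vD <- encode_egaac(strrep("D", 100), cfg)
  expect_equal(unname(vD[grep("negative", names(vD))]), rep(1, 5))

  seq <- paste0(strrep("K", 10), strrep("S", 10), strrep("G", 80))
  v <- encode_egaac(seq, cfg)
  expect_equal(v[["EGAAC_w1_positive"]], 0.5)
  expect_equal(v[["EGAAC_w1_uncharged"]], 0.5)
})

test_that("DDE standardizes dipeptide composition against codon expectation", {
  v <- encode_dde("AAA")
  tm <- (4 / 61)^2
  expect_equal(v[["DDE_AA"]], (1 - tm) / sqrt(tm * (1 - tm) / 2))
  # absent dipeptides are strictly negative
  expect_true(all(v[names(v) != "DDE_AA"] < 0))
  expect_length(v, 400)
  expect_error(encode_dde("A"), "at least 2")
})

test_that("TF-IDF weights term frequency by corpus rarity", {
  corpus <- c(d1 = "AACC", d2 = "AGGG")
  model <- fit_tfidf(corpus, cfg)
  expect_length(model$idf, 20)
  expect_equal(model$idf[["A"]], 0)            # in every document
  expect_equal(model$idf[["C"]], log10(2))     # in one of two

  v <- encode_tfidf("AACC", model)
  expect_equal(v[["TFIDF_A"]], 0)
  expect_equal(v[["TFIDF_C"]], 0.5 * log10(2))
  expect_equal(v[["TFIDF_W"]], 0)              # absent from sequence
  expect_error(encode_tfidf("AA", list()), "fitted")
})

test_that("k-gram frequencies normalize by section length", {
  v1 <- encode_kgram("AAAA", 1)
  expect_length(v1, 21)
  expect_equal(v1[["G1_A"]], 1)
  expect_equal(sum(v1), 1)

  v2 <- encode_kgram("ACAC", 2)
  expect_length(v2, 400)
  expect_equal(v2[["G2_AC"]], 2 / 3)
  expect_equal(v2[["G2_CA"]], 1 / 3)
  expect_equal(sum(v2), 1)

  expect_error(encode_kgram("AAAA", 3), "1 or 2")
})

test_that("NUM and BINA encode positions in the alphabetical code", {
  seq <- normalize_sequence("ACD", 100)
  n <- encode_num(seq, cfg)
  expect_equal(unname(n), c(1, 2, 3, rep(21, 97)))

  b <- encode_bina(seq, cfg)
  expect_length(b, 2100)
  expect_equal(unname(b[1:21]), c(1, rep(0, 20)))              # 'A'
  expect_equal(unname(b[(3 * 21 + 1):(4 * 21)]), c(rep(0, 20), 1))  # 'O'
  blocks <- matrix(b, ncol = 21, byrow = TRUE)
  expect_true(all(rowSums(blocks) == 1))
})

test_that("PseAAC is a normalized composition plus sequence-order factors", {
  v <- encode_pseaac(strrep("A", 50), cfg)
  expect_length(v, 28)
  expect_equal(v[["PSEAAC_f_A"]], 1)
  expect_equal(unname(v[grep("theta", names(v))]), rep(0, 8))

  alt <- paste(rep(c("A", "R"), 30), collapse = "")
  expect_equal(unname(encode_pseaac(alt, cfg)), ora_pseaac(alt))

  expect_error(encode_pseaac("ACDEFGHI", cfg), "lambda")
  # components non-negative, sum to 1
  set.seed(42)
  s <- rand_seq(60)
  v2 <- encode_pseaac(s, cfg)
  expect_true(all(v2 >= 0))
  expect_equal(sum(v2), 1)
})

test_that("encoders match naive re-counting oracles on random sequences", {
  set.seed(7)
  corpus <- vapply(1:8, function(i) rand_seq(sample(40:140, 1)), character(1))
  names(corpus) <- paste0("P", 1:8)
  model <- fit_tfidf(corpus, cfg)
  for (i in 1:20) {
    seq <- rand_seq(sample(30:140, 1), include_o = (i %% 4 == 0))
    sn <- normalize_sequence(seq, 100)
    expect_equal(unname(encode_eaac(sn, cfg)), ora_eaac(sn))
    expect_equal(unname(encode_egaac(sn, cfg)), ora_egaac(sn))
    expect_equal(unname(encode_dde(seq)), unname(ora_dde(seq)))
    expect_equal(unname(encode_tfidf(seq, model)), unname(ora_tfidf(corpus, seq)))
    expect_equal(unname(encode_kgram(seq, 1)), unname(ora_kgram1(seq)))
    expect_equal(unname(encode_kgram(seq, 2)), ora_kgram2(seq))
    expect_equal(unname(encode_num(sn, cfg)), unname(ora_num(sn)))
    expect_equal(unname(encode_bina(sn, cfg)), ora_bina(sn))
    if (!grepl("O", seq))
      expect_equal(unname(encode_pseaac(seq, cfg)), ora_pseaac(seq))
  }
})

test_that("every encoder output length equals its declared dimension", {
  set.seed(11)
  dims <- encoder_dimensions(cfg)
  seq <- rand_seq(73)
  pssm <- gen_pssm(seq, seed = 1)
  model <- fit_tfidf(c(a = seq), cfg)
  for (e in names(dims)) {
    v <- encode_protein(seq, e, cfg, pssm = pssm, tfidf_model = model)
    expect_length(v, dims[[e]])
  }
})
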