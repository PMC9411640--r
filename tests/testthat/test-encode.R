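lex <- fixture_lexicon()

test_that("mean_vector averages found words and reports contribution flags", {
  emb <- embedding_source(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                                 dimnames = list(c("a", "b"), NULL)))
  mv <- mean_vector(c("a", "b"), emb)
  expect_equal(mv$vector, c(0.5, 0.5))
  expect_identical(mv$contributing$found, c(TRUE, TRUE))
  expect_equal(mean_vector("a", emb)$vector, c(1, 0))
  mv <- mean_vector(c("zz", "qq"), emb)
  expect_null(mv$vector)
  expect_identical(mv$contributing$found, c(FALSE, FALSE))
  # missing words are skipped, not fatal
  expect_equal(mean_vector(c("a", "qq"), emb)$vector, c(1, 0))
})

test_that("mean vectors stay inside the coordinate-wise convex hull", {
  emb <- toy_embedding(letters[1:6], dim = 5, seed = 2)
  set.seed(2)
  for (i in 1:25) {
    ws <- sample(letters[1:6], sample(2:5, 1))
    v <- mean_vector(ws, emb)$vector
    mat <- do.call(rbind, lapply(ws, function(w) emb_lookup(emb, w)))
    expect_true(all(v >= apply(mat, 2, min) - 1e-12))
    expect_true(all(v <= apply(mat, 2, max) + 1e-12))
  }
})

test_that("the encoder chain stops at the first resolving stage", {
  seg <- train_segmenter(c("sea", "sick"), counts = c(5, 5))
  emb <- toy_embedding(c("heart", "vertebra", "painful", "breathing",
                         "sea", "sick"), dim = 6, seed = 4)

  e <- encode_token("heart", emb, lex, seg)
  expect_identical(e$provenance, "direct")
  expect_equal(e$vector, emb_lookup(emb, "heart"))

  e <- encode_token("vertebrae", emb, lex, seg)
  expect_identical(e$provenance, "inflection")
  expect_equal(e$vector, emb_lookup(emb, "vertebra"))

  e <- encode_token("dyspnea", emb, lex, seg)
  expect_identical(e$provenance, "parser")
  expect_equal(e$vector, colMeans(rbind(emb_lookup(emb, "painful"),
                                        emb_lookup(emb, "breathing"))))
  expect_identical(e$contributing_words$word, c("painful", "breathing"))

  e <- encode_token("seasickness", emb, lex, seg)
  expect_identical(e$provenance, "segmenter")
  expect_equal(e$vector, colMeans(rbind(emb_lookup(emb, "sea"),
                                        emb_lookup(emb, "sick"))))

  e <- encode_token("qqqq", emb, lex, seg)
  expect_identical(e$provenance, "unresolved")
  expect_null(e$vector)
})

test_that("disabled stages are skipped and direct is mandatory", {
  emb <- toy_embedding(c("painful", "breathing"), dim = 4, seed = 1)
  e <- encode_token("dyspnea", emb, lex, stages = c("direct", "inflection"))
  expect_identical(e$provenance, "unresolved")
  e <- encode_token("dyspnea", emb, lex, stages = c("direct", "parser"))
  expect_identical(e$provenance, "parser")
  expect_error(encode_token("x", emb, lex, stages = c("inflection")),
               "direct")
  expect_error(encode_token("x", emb, lex, stages = c("direct", "bogus")),
               "bogus")
})

test_that("coverage is monotone in the enabled stage set", {
  seg <- fixture_segmenter(lex)
  emb <- meaning_word_embedding(lex, dim = 6, seed = 8)
  terms <- generate_terms(synth_config(40, seed = 8), lex)
  stage_sets <- list(c("direct"),
                     c("direct", "inflection"),
                     c("direct", "inflection", "parser"),
                     c("direct", "inflection", "parser", "segmenter"))
  covered <- vapply(stage_sets, function(st)
    token_coverage(terms$term, emb, lex, seg, st)$n_covered, 0L)
  expect_true(all(diff(covered) >= 0))
})

test_that("terms built from fixture components never go unresolved with all stages", {
  emb <- meaning_word_embedding(lex, dim = 6, seed = 10)
  terms <- generate_terms(synth_config(50, seed = 10), lex)
  for (t in terms$term)
    expect_false(encode_token(t, emb, lex, fixture_segmenter(lex))$provenance ==
                 "unresolved")
})

test_that("multi-word terms average word vectors and take the worst provenance", {
  emb <- toy_embedding(c("attack", "painful", "breathing"), dim = 5, seed = 3)
  e <- encode_term("dyspnea attack", emb, lex)
  expect_identical(e$provenance, "parser")
  v_attack <- emb_lookup(emb, "attack")
  v_dysp <- encode_token("dyspnea", emb, lex)$vector
  expect_equal(e$vector, colMeans(rbind(v_dysp, v_attack)))

  both <- encode_term("painful breathing", emb, lex)
  expect_identical(both$provenance, "direct")

  none <- encode_term("qq zz", emb, lex)
  expect_identical(none$provenance, "unresolved")
  expect_null(none$vector)
  zeroed <- encode_term("qq zz", emb, lex, unresolved_zero = TRUE)
  expect_equal(zeroed$vector, numeric(emb_dim(emb)))

  expect_error(encode_term("   ", emb, lex), "empty")
})

test_that("encoding is a pure function of its arguments", {
  emb <- meaning_word_embedding(lex, dim = 6, seed = 12)
  seg <- fixture_segmenter(lex)
  a <- encode_token("mastodynia", emb, lex, seg)
  b <- encode_token("mastodynia", emb, lex, seg)
  expect_identical(a, b)
})

test_that("word2vec text reading handles headers, dialects and bad rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 2", "a 1 0", "b 0 1"), f)
  emb <- read_word2vec_text(f)
  expect_setequal(emb_vocab(emb), c("a", "b"))
  expect_identical(emb_dim(emb), 2L)
  expect_equal(emb_lookup(emb, "a"), c(1, 0))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a 1 0", "b 0 1"), f2)
  emb2 <- read_word2vec_text(f2)
  expect_equal(emb2$vectors, emb$vectors)

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 2", "a 1 0", "b 0 1 5"), f3)
  expect_error(read_word2vec_text(f3), "line 3")
})

test_that("word2vec writing round-trips through the reader", {
  emb <- toy_embedding(c("alpha", "beta", "gamma"), dim = 4, seed = 6)
  f <- withr::local_tempfile(fileext = ".txt")
  write_word2vec_text(emb, f)
  back <- read_word2vec_text(f)
  expect_setequal(emb_vocab(back), emb_vocab(emb))
  for (w in emb_vocab(emb))
    expect_equal(emb_lookup(back, w), unname(emb_lookup(emb, w)),
                 tolerance = 1e-6)
})
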