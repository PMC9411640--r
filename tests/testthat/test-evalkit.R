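test_that("cosine similarity matches closed forms", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("cosine similarity is symmetric and self-similarity is one", {
  set.seed(17)
  for (i in 1:30) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(cosine_similarity(a, a), 1.0, tolerance = 1e-12)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_lte(abs(cosine_similarity(a, b)), 1 + 1e-12)
  }
})

test_that("Spearman correlation matches hand-computable cases", {
  expect_equal(spearman_correlation(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_correlation(1:3, c(30, 20, 10)), -1.0)
  expect_equal(spearman_correlation(1:4, c(2, 1, 4, 3)), 0.6,
               tolerance = 1e-9)
  expect_error(spearman_correlation(1:3, c(1, 1, 1)), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("Spearman agrees with a brute-force rank implementation, with ties", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01)
    y <- sample(1:8, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearman_correlation(x, y), brute_force_spearman(x, y),
                 tolerance = 1e-9)
  }
})

test_that("precision, recall and F1 follow the confusion-count formulas", {
  expect_equal(precision_recall_f1(1, 0, 0),
               list(precision = 1.0, recall = 1.0, f1 = 1.0))
  r <- precision_recall_f1(0, 5, 5)
  expect_equal(r$precision, 0)
  expect_equal(r$recall, 0)
  expect_true(is.na(r$f1))
  r <- precision_recall_f1(3, 1, 2)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 / 3, tolerance = 1e-4)
  # undefined metrics propagate as NA, not errors
  expect_true(is.na(precision_recall_f1(0, 0, 3)$precision))
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("F1 is the harmonic mean: bounded by its components", {
  set.seed(23)
  for (i in 1:100) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    r <- precision_recall_f1(tp, fp, fn)
    if (is.na(r$f1)) next
    expect_lte(r$f1, min(2 * r$precision, 2 * r$recall) + 1e-12)
    expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
    expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
  }
})

test_that("pair evaluation reports coverage and rank agreement", {
  lex <- fixture_lexicon()
  ds <- generate_pair_dataset(synth_config(30, seed = 31), lex)
  rep <- evaluate_pairs(ds$pairs, ds$emb, lex, fixture_segmenter(lex))
  expect_identical(rep$n_total, 30L)
  expect_identical(rep$n_covered, 30L)
  expect_equal(rep$coverage_pct, 100)
  expect_equal(rep$spearman, 1.0, tolerance = 1e-9)

  # an unresolvable nonsense pair is excluded from coverage, direct-only
  pairs <- rbind(ds$pairs,
                 data.frame(term1 = "qqqqq", term2 = "zzzzz",
                            human_score = 1))
  rep2 <- evaluate_pairs(pairs, ds$emb, lex, NULL, stages = "direct")
  expect_lt(rep2$coverage_pct, 100)

  # coverage is monotone as stages are enabled
  rep_direct <- evaluate_pairs(ds$pairs, ds$emb, lex, NULL, stages = "direct")
  expect_lte(rep_direct$n_covered, rep$n_covered)
})

test_that("pair-evaluation coverage is invariant to pair order and score monotone transforms", {
  lex <- fixture_lexicon()
  ds <- generate_pair_dataset(synth_config(20, seed = 37), lex)
  seg <- fixture_segmenter(lex)
  rep <- evaluate_pairs(ds$pairs, ds$emb, lex, seg)
  shuffled <- ds$pairs[rev(seq_len(nrow(ds$pairs))), ]
  rep_rev <- evaluate_pairs(shuffled, ds$emb, lex, seg)
  expect_identical(rep$coverage_pct, rep_rev$coverage_pct)
  transformed <- ds$pairs
  transformed$human_score <- exp(3 * transformed$human_score) + 2
  rep_tr <- evaluate_pairs(transformed, ds$emb, lex, seg)
  expect_equal(rep$spearman, rep_tr$spearman, tolerance = 1e-9)
})

test_that("term-pair files parse in comma and tab dialects with header skip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("heart,cardiac,3.5", "lung,renal,1.2"), f)
  pairs <- read_term_pairs(f)
  expect_identical(pairs$term1, c("heart", "lung"))
  expect_equal(pairs$human_score, c(3.5, 1.2))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term1\tterm2\tscore", "heart\tcardiac\t3.5"), f2)
  pairs2 <- read_term_pairs(f2)
  expect_identical(nrow(pairs2), 1L)
  expect_equal(pairs2$human_score, 3.5)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("heart,cardiac,3.5", "broken line", "lung,renal,oops"), f3)
  expect_message(pairs3 <- read_term_pairs(f3), "skipped 2")
  expect_identical(nrow(pairs3), 1L)

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), f4)
  expect_error(read_term_pairs(f4), "no parsable rows")
})

test_that("token-level coverage reports a provenance histogram", {
  lex <- fixture_lexicon()
  emb <- toy_embedding(c("heart", "painful", "breathing"), dim = 4, seed = 41)
  cov <- token_coverage(c("heart", "dyspnea", "qqqq"), emb, lex)
  expect_identical(cov$n_total, 3L)
  expect_identical(cov$n_covered, 2L)
  expect_identical(unname(cov$provenance[c("direct", "parser", "unresolved")]),
                   c(1L, 1L, 1L))
})
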