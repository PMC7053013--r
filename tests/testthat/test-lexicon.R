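test_that("collocation mining keeps genuine phrases and rejects chance co-occurrence", {
  # "t cell" in 50/100 docs, parts never apart elsewhere
  corpus <- c(replicate(50, c("t", "cell", "signal", "pathway"),
                        simplify = FALSE),
              replicate(50, list(c("unrelated", "filler", "tokens", "only"))))
  phrases <- mine_phrases(corpus, min_count = 5)
  expect_true("t cell" %in% phrases)
  expect_true(all(lengths(strsplit(phrases, " ")) %in% 2:4))

  # independently shuffled tokens: nothing collocates
  set.seed(42)
  vocab <- paste0("w", 1:25)
  shuffled <- replicate(120, sample(vocab, 30, replace = TRUE),
                        simplify = FALSE)
  expect_length(mine_phrases(shuffled, min_count = 5), 0)

  # below the count floor
  rare <- c(replicate(4, c("rare", "pair"), simplify = FALSE),
            replicate(40, list(c("aa", "bb", "cc", "dd", "ee", "ff"))))
  expect_false("rare pair" %in% mine_phrases(rare, min_count = 5))

  expect_error(mine_phrases(list()), "non-empty")
})

test_that("phrase mining is invariant to document order", {
  set.seed(7)
  docs <- c(replicate(30, c("ion", "channel", "x", "y"), simplify = FALSE),
            replicate(30, list(sample(paste0("t", 1:10), 8, replace = TRUE))))
  expect_identical(mine_phrases(docs, min_count = 5),
                   mine_phrases(rev(docs), min_count = 5))
})

test_that("document frequencies and IDF follow ln(N/df)", {
  corpus <- toy_corpus(
    c("the gene gene appears twice", rep("no target word here", 9)),
    titles = c("gene study", rep("plain", 9)))
  lex <- build_document_frequencies(corpus, c("gene", "plain", "appears"))
  # in 1 of 10 docs -> idf = ln(10); twice in one doc counts once
  expect_equal(idf_weight(lex, "appears"), log(10))
  expect_equal(doc_frequency(lex, "gene"), 1)
  # in every doc -> idf 0
  lex2 <- build_document_frequencies(
    toy_corpus(rep("ubiquitous term", 5)), c("ubiquitous"))
  expect_equal(idf_weight(lex2, "ubiquitous"), 0)
  # zero-frequency surfaces are omitted
  expect_false(in_vocabulary(lex, "absent"))
  expect_error(build_document_frequencies(corpus, character()), "non-empty")
})

test_that("idf decreases as document frequency rises, N fixed", {
  n <- 50
  dfs <- c(1, 2, 5, 10, 25, 50)
  idfs <- log(n / dfs)
  expect_true(all(diff(idfs) < 0))
  lex <- litqa:::new_lexicon(paste0("s", seq_along(dfs)), dfs, n)
  got <- vapply(paste0("s", seq_along(dfs)), function(s) idf_weight(lex, s), 0)
  expect_equal(unname(got), idfs)
})

test_that("phrase matching agrees with a brute-force token-list scan", {
  set.seed(11)
  vocab <- c("alpha", "beta", "gamma", "delta")
  for (case in 1:20) {
    corpus <- toy_corpus(vapply(1:6, function(i)
      paste(sample(vocab, sample(3:6, 1), replace = TRUE), collapse = " "), ""))
    phrase <- paste(sample(vocab, 2), collapse = " ")
    lex <- build_document_frequencies(corpus, c(vocab, phrase))
    brute <- sum(vapply(seq_len(nrow(corpus)), function(i) {
      toks <- tolower(litqa:::tokenize_text(corpus$abstract[i])$surface)
      oracle_phrase_present(toks, strsplit(phrase, " ")[[1]])
    }, TRUE))
    expect_equal(doc_frequency(lex, phrase), brute)
  }
})

test_that("GloVe-format embeddings round-trip with the underscore convention", {
  path <- write_tmp_lines(c("alpha 0.1 0.2 0.3 0.4",
                            "t_cell 0.5 0.6 0.7 0.8",
                            "beta 1 0 0 0"))
  emb <- load_embeddings(path)
  expect_equal(emb$dimension, 4)
  expect_equal(nrow(emb$matrix), 3)
  expect_equal(unname(embedding_vector(emb, "t cell")), c(0.5, 0.6, 0.7, 0.8))
  expect_null(embedding_vector(emb, "missing"))

  expect_error(load_embeddings(write_tmp_lines(c("a 0.1 0.2", "b 0.3"))),
               "line 2")
  expect_error(load_embeddings(write_tmp_lines(character())), "empty")

  out <- tempfile()
  write_embeddings(emb, out)
  again <- load_embeddings(out)
  expect_equal(again$matrix, emb$matrix, tolerance = 1e-7)
})

test_that("cosine similarity is the standard symmetric cosine with a safe zero case", {
  x <- c(0.3, -1.2, 2.5)
  expect_equal(cosine_similarity(x, x), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)),
               cosine_similarity(c(1, 0), c(1, 1)))
  expect_warning(z <- cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
  expect_equal(z, 0)
})

test_that("lexicon TSV round-trips", {
  lex <- litqa:::new_lexicon(c("alpha", "beta", "t cell"), c(2L, 5L, 1L), 10L)
  path <- tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, path)
  back <- read_lexicon_tsv(path)
  expect_equal(idf_weight(back, "t cell"), idf_weight(lex, "t cell"),
               tolerance = 1e-9)
  expect_equal(back$n_docs, lex$n_docs)
  expect_setequal(lexicon_surfaces(back), lexicon_surfaces(lex))
})
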