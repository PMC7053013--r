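test_that("sentence segmentation emits the title first and respects abbreviations", {
  doc <- list(title = "A title.", abstract = "First sentence. Second one. Third here.")
  s <- segment_sentences(doc)
  expect_length(s, 4)
  expect_equal(s[1], "A title.")
  s2 <- segment_sentences(list(title = "T.",
                               abstract = "Markers, e.g. CD52, help. Next sentence."))
  expect_length(s2, 3)
  expect_length(segment_sentences(list(title = "Only title.", abstract = "")), 1)
})

test_that("wRWMD is the weighted mean of per-term maximum cosines", {
  # engineered cosines: maxcos(a)=0.9 via x, maxcos(b)=0.3 via y
  m <- rbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0),
             x = c(0.9, 0, sqrt(1 - 0.81), 0),
             y = c(0, 0.3, 0, sqrt(1 - 0.09)))
  emb <- embeddings_from_matrix(m)
  expect_equal(wrwmd_similarity(c(a = 2, b = 1), c("x", "y"), emb),
               (2 * 0.9 + 1 * 0.3) / 3, tolerance = 1e-12)
  # answer containing all question terms -> 1
  expect_equal(wrwmd_similarity(c(a = 1, b = 2), c("a", "b", "x"), emb), 1)
  # fully orthogonal -> 0
  m2 <- diag(1, 4); rownames(m2) <- c("q1", "q2", "a1", "a2")
  emb2 <- embeddings_from_matrix(m2)
  expect_equal(wrwmd_similarity(c(q1 = 1, q2 = 1), c("a1", "a2"), emb2), 0)
  # empty answer -> 0
  expect_equal(wrwmd_similarity(c(a = 1), character(), emb), 0)
})

test_that("wRWMD ignores duplicated answer terms and irrelevant orthogonal additions", {
  emb <- toy_embeddings(c("p", "q", "r", "zz"))
  base <- wrwmd_similarity(c(p = 1, q = 2), c("p", "r"), emb)
  expect_equal(wrwmd_similarity(c(p = 1, q = 2), c("p", "p", "r", "r"), emb),
               base)
  expect_equal(wrwmd_similarity(c(p = 1, q = 2), c("p", "r", "zz"), emb),
               base)
  # out-of-embedding question term: exact surface match scores 1, else 0
  expect_equal(wrwmd_similarity(c(noemb = 1), c("noemb", "p"), emb), 1)
  expect_equal(wrwmd_similarity(c(noemb = 1), c("p"), emb), 0)
})

test_that("candidates are ranked by similarity descending with stable ties", {
  emb <- toy_embeddings(c("planted", "term", "other", "words", "title"))
  lex <- toy_lexicon(c(planted = 2, term = 1.5, other = 1, words = 1,
                       title = 0.2))
  docs <- toy_corpus(
    c("planted term here. other words only.",
      "other words again. planted term appears."),
    titles = c("title one", "title two"))
  cands <- rank_candidates("planted term?", docs, lex, emb)
  expect_equal(cands$wrwmd_score[1], 1)
  expect_true(all(diff(cands$wrwmd_score) <= 0))
  # stability: equal-scoring sentences keep document order
  ties <- cands[cands$wrwmd_score == cands$wrwmd_score[1], ]
  if (nrow(ties) > 1) {
    expect_true(all(diff(match(ties$doc_id, docs$id)) >= 0 |
                      diff(ties$sentence_index) >= 0))
  }
  # brute-force agreement on order
  brute <- c()
  for (d in 1:2) {
    for (s in segment_sentences(docs[d, ])) {
      toks <- litqa:::scoring_terms(litqa:::tokenize_text(s)$surface, lex)
      brute <- c(brute, wrwmd_similarity(
        litqa:::scoring_terms(litqa:::tokenize_text("planted term?")$surface, lex),
        toks, emb, lex))
    }
  }
  expect_equal(sort(cands$wrwmd_score, decreasing = TRUE),
               sort(brute, decreasing = TRUE), tolerance = 1e-12)
})

test_that("focus-type filtering retains typed sentences and falls back when none match", {
  gaz <- gazetteer_from_vectors(c("alemtuzumab", "melanoma"),
                                c("drug", "disease"))
  cands <- data.frame(
    sentence = c("Alemtuzumab helps patients.", "Nothing typed here.",
                 "Melanoma is a disease."),
    doc_id = "d", sentence_index = 0:2, wrwmd_score = c(0.9, 0.8, 0.7),
    rerank_prob = NA_real_, stringsAsFactors = FALSE)
  kept <- filter_by_focus_type(cands, "drug", gaz)
  expect_equal(kept$sentence, "Alemtuzumab helps patients.")
  expect_warning(all_back <- filter_by_focus_type(cands, "enzyme", gaz),
                 "unfiltered")
  expect_equal(nrow(all_back), 3)
  # NA focus type: filter skipped
  expect_equal(nrow(filter_by_focus_type(cands, NA, gaz)), 3)
})

test_that("definition patterns promote matching sentences keeping group order", {
  cands <- data.frame(
    sentence = c("Unrelated high scorer.",
                 "Another unrelated sentence.",
                 "LHCII is the most abundant membrane protein on earth."),
    doc_id = "d", sentence_index = 0:2, wrwmd_score = c(0.9, 0.8, 0.2),
    rerank_prob = NA_real_, stringsAsFactors = FALSE)
  out <- match_definition_patterns("LHCII", cands)
  expect_equal(out$sentence[1],
               "LHCII is the most abundant membrane protein on earth.")
  expect_equal(out$sentence[2:3], cands$sentence[1:2])
  # no hits anywhere: order unchanged
  out2 <- match_definition_patterns("absentfocus", cands)
  expect_equal(out2$sentence, cands$sentence)
})
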