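test_that("construct weights implement the averaged in-vocab/OOV-min formula", {
  lex <- toy_lexicon(c(alpha = 0.6, tok1 = 0.2, tok2 = 0.9, solo = 0.5))
  # |ST|=1, in-vocab
  c1 <- new_search_construct("solo", "np", lex)
  expect_equal(construct_weight(c1, lex), 0.5, tolerance = 1e-12)
  # |ST|=2: in-vocab 0.6 plus OOV phrase with token weights {0.2, 0.9}
  c2 <- new_search_construct(c("alpha", "tok1 tok2"), "np", lex)
  expect_equal(construct_weight(c2, lex), (0.6 + 0.2) / 2, tolerance = 1e-12)
  # all-OOV with zero token weights
  lex0 <- litqa:::new_lexicon(c("z1", "z2"), c(10, 10), 10)   # idf 0
  c3 <- new_search_construct(c("z1 z2", "z2 z1"), "np", lex0)
  expect_equal(construct_weight(c3, lex0), 0)
  expect_error(new_search_construct(character(), "np", lex),
               class = "litqa_empty_construct")
})

test_that("queries group NPs, verbs and words, protect entities, sort disjuncts", {
  lex <- toy_lexicon(c(alemtuzumab = 3, `remission induction` = 2.2,
                       patients = 0.5, diagnose = 1.1, leukemia = 1.8))
  gaz <- gazetteer_from_vectors("alemtuzumab", "drug")
  aq <- analyze_question(
    paste("Is alemtuzumab effective for remission induction in patients",
          "diagnosed with T-cell prolymphocytic leukemia?"), lex, gaz)
  qu <- build_query(aq, lex)
  kinds <- vapply(qu$constructs, `[[`, "", "kind")
  prot <- vapply(qu$constructs, `[[`, TRUE, "protected")
  prim <- vapply(qu$constructs, function(cs) cs$disjuncts[1], "")
  expect_true(any(kinds == "verb"))
  # the drug construct is protected
  alem <- which(vapply(qu$constructs, function(cs)
    "alemtuzumab" %in% cs$disjuncts, TRUE))
  expect_true(any(prot[alem]))
  # verb construct carries conjugations and the nominalization
  vb <- qu$constructs[[which(kinds == "verb")[1]]]
  expect_true(all(c("diagnosed", "diagnosis") %in% vb$disjuncts))
  # disjuncts are weight-descending in every construct
  for (cs in qu$constructs)
    expect_true(all(diff(cs$disjunct_weights) <= 0))
})

test_that("a single-NP question yields the NP construct plus its word constructs", {
  lex <- toy_lexicon(c(`membrane protein` = 2.1, membrane = 1.5, protein = 1.0))
  aq <- analyze_question("What is a membrane protein?", lex)
  qu <- build_query(aq, lex)
  prim <- vapply(qu$constructs, function(cs) cs$disjuncts[1], "")
  expect_true(any(grepl("membrane protein", prim)))
  expect_true("membrane" %in% unlist(lapply(qu$constructs, `[[`, "disjuncts")))
})

test_that("boolean evaluation enforces AND-of-OR semantics with phrase contiguity", {
  corpus <- toy_corpus(c("remission induction therapy works",
                         "induction of remission differs",
                         "plain text here",
                         "remission induction again",
                         "nothing relevant"))
  idx <- build_index(corpus)
  lex <- build_document_frequencies(corpus, c("remission", "induction",
                                              "remission induction", "text"))
  q1 <- litqa:::new_keyword_query(list(
    new_search_construct("remission induction", "np", lex)))
  r1 <- evaluate_boolean(q1, idx)
  expect_equal(r1$total_hits, 2)          # contiguity excludes doc 2
  expect_setequal(r1$ids, c("d01", "d04"))
  # AND of disjoint matchers -> empty
  q2 <- litqa:::new_keyword_query(list(
    new_search_construct("remission induction", "np", lex),
    new_search_construct("text", "word", lex)))
  expect_equal(evaluate_boolean(q2, idx)$total_hits, 0)
  expect_error(evaluate_boolean(litqa:::new_keyword_query(list()), idx),
               class = "litqa_empty_query")
})

test_that("boolean evaluation equals a brute-force scan on random toy queries", {
  set.seed(21)
  vocab <- c("alpha", "beta", "gamma", "delta", "epsilon")
  corpus <- toy_corpus(vapply(1:12, function(i)
    paste(sample(vocab, sample(3:7, 1), replace = TRUE), collapse = " "), ""))
  idx <- build_index(corpus)
  lex <- build_document_frequencies(corpus, vocab)
  for (rep in 1:40) {
    groups <- lapply(seq_len(sample(1:3, 1)), function(i) {
      k <- sample(1:2, 1)
      surfs <- replicate(k, if (stats::runif(1) < 0.3)
        paste(sample(vocab, 2), collapse = " ") else sample(vocab, 1))
      unique(surfs)
    })
    q <- litqa:::new_keyword_query(lapply(groups, function(g)
      new_search_construct(g, "np", lex)))
    got <- evaluate_boolean(q, idx)
    want <- oracle_boolean_scan(corpus, groups)
    expect_equal(got$total_hits, length(want))
    expect_setequal(got$ids, want)
  }
})

test_that("removing a construct never shrinks the result set", {
  set.seed(33)
  vocab <- c("alpha", "beta", "gamma", "delta")
  corpus <- toy_corpus(vapply(1:10, function(i)
    paste(sample(vocab, sample(2:5, 1), replace = TRUE), collapse = " "), ""))
  idx <- build_index(corpus)
  lex <- build_document_frequencies(corpus, vocab)
  for (rep in 1:20) {
    groups <- lapply(1:2, function(i) sample(vocab, sample(1:2, 1)))
    full <- litqa:::new_keyword_query(lapply(groups, function(g)
      new_search_construct(g, "np", lex)))
    reduced <- litqa:::new_keyword_query(list(
      new_search_construct(groups[[1]], "np", lex)))
    expect_true(all(evaluate_boolean(full, idx)$ids %in%
                      evaluate_boolean(reduced, idx)$ids))
  }
})

test_that("relaxation stops immediately when the initial query already matches", {
  corpus <- toy_corpus(c("alpha beta", "alpha beta gamma", "alpha beta delta",
                         "alpha beta x", "alpha beta y", "unrelated"))
  idx <- build_index(corpus)
  lex <- build_document_frequencies(corpus, c("alpha", "beta"))
  q <- with_query_lexicon(litqa:::new_keyword_query(list(
    new_search_construct("alpha", "np", lex),
    new_search_construct("beta", "np", lex))), lex)
  out <- iterative_retrieve(q, idx)
  expect_equal(out$query$iteration, 0)
  expect_equal(out$result$total_hits, 5)
  expect_false(out$exhausted)
})

test_that("verb constructs are dropped before noun constructs and entities survive longest", {
  corpus <- toy_corpus(c("alemtuzumab works", "other text entirely"))
  idx <- build_index(corpus)
  lex <- toy_lexicon(c(alemtuzumab = 3, missing1 = 2, treat = 0.9,
                       treats = 0.9, works = 0.4))
  q <- with_query_lexicon(litqa:::new_keyword_query(list(
    new_search_construct("alemtuzumab", "entity", lex, protected = TRUE,
                         position = 1),
    new_search_construct(c("treat", "treats"), "verb", lex, position = 2),
    new_search_construct("missing1", "np", lex, position = 3))), lex)
  out <- iterative_retrieve(q, idx)
  expect_false(out$exhausted)
  hist <- out$query$history$surface
  # verbs first (equal weights break lexicographically, later form first),
  # then the unmatched noun; the protected entity never drops
  expect_equal(hist, c("treats", "treat", "missing1"))
  expect_false("alemtuzumab" %in% hist)
  expect_equal(out$result$ids, "d01")
  expect_equal(out$query$iteration, nrow(out$query$history))
})

test_that("relaxation reports exhaustion when nothing can match", {
  corpus <- toy_corpus(c("totally different words"))
  idx <- build_index(corpus)
  lex <- toy_lexicon(c(absent1 = 2, absent2 = 1))
  q <- with_query_lexicon(litqa:::new_keyword_query(list(
    new_search_construct("absent1", "np", lex, position = 1),
    new_search_construct("absent2", "np", lex, position = 2))), lex)
  out <- iterative_retrieve(q, idx)
  expect_true(out$exhausted)
  expect_equal(out$result$total_hits, 0)
})

test_that("the drop sequence matches the independent policy simulator", {
  for (seed in 1:25) {
    case <- random_relaxation_case(seed)
    want <- oracle_relaxation(case$corpus, case$groups)
    q <- query_from_groups(case$groups, case$lexicon)
    got <- iterative_retrieve(q, build_index(case$corpus))
    expect_equal(got$query$history$surface, want$drops,
                 info = paste("seed", seed))
    expect_equal(got$exhausted, want$exhausted, info = paste("seed", seed))
  }
})

test_that("relaxation is deterministic and protected constructs stay out of early history", {
  case <- random_relaxation_case(99)
  q <- query_from_groups(case$groups, case$lexicon)
  idx <- build_index(case$corpus)
  a <- iterative_retrieve(q, idx)
  b <- iterative_retrieve(q, idx)
  expect_identical(a, b)
  expect_equal(a$query$iteration, nrow(a$query$history))
})
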