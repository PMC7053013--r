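make_lexicon <- function() {
  toy_lexicon(c(`prolymphocytic leukemia` = 2.5, `remission induction` = 2.2,
                alemtuzumab = 3, patients = 0.5, leukemia = 1.8,
                diagnose = 1.1, gene = 1.0, genes = 1.0,
                craniosynostosis = 2.9, `membrane protein` = 2.1))
}

test_that("question types split into definition, focus and other", {
  lex <- make_lexicon()
  t_of <- function(q) {
    ann <- annotate(q)
    detect_question_type(ann, lexicon = lex)
  }
  expect_equal(t_of("What is the mechanism of action of abiraterone?"),
               "definition")
  expect_equal(t_of("What is craniosynostosis?"), "definition")
  expect_equal(t_of("Is miR-21 related to carcinogenesis?"), "other")
  expect_equal(t_of("Which human genes are more commonly related to craniosynostosis?"),
               "focus")
  expect_error(annotate(""), "non-empty")
})

test_that("focus detection follows the wh-adjacent / post-copula / post-preposition rules", {
  lex <- make_lexicon()
  f_of <- function(q) detect_focus(annotate(q), lex)
  expect_equal(f_of("What memory problems are reported in the Gulf war syndrome?")$focus_phrase,
               "memory problems")
  expect_equal(f_of("Which is the most abundant membrane protein on Earth?")$focus_phrase,
               "membrane protein")
  expect_equal(f_of("Which human genes are more commonly related to craniosynostosis?")$focus_phrase,
               "human genes")
  # no NP at all -> no focus, type falls back
  ann <- annotate("Why?")
  expect_true(is.na(detect_focus(ann, lex)$focus_phrase))
  expect_equal(detect_question_type(ann, lexicon = lex), "other")
})

test_that("the focus never contains the wh word and maps to an entity type via triggers", {
  lex <- make_lexicon()
  qs <- c("Which human genes are more commonly related to craniosynostosis?",
          "What memory problems are reported in the Gulf war syndrome?",
          "Which drug inhibits something?")
  for (q in qs) {
    f <- detect_focus(annotate(q), lex)
    expect_false(grepl("\\b(what|which|who|where|when|why|how)\\b",
                       f$focus_phrase, ignore.case = TRUE))
  }
  aq <- analyze_question("Which human genes are more commonly related to craniosynostosis?",
                         lex)
  expect_equal(aq$focus_entity_type, "gene")
  expect_equal(aq$focus_phrase, "human genes")
})

test_that("candidate terms cover the NPs, verbs and expansions of a clinical question", {
  lex <- make_lexicon()
  aq <- analyze_question(
    paste("Is alemtuzumab effective for remission induction in patients",
          "diagnosed with T-cell prolymphocytic leukemia?"), lex)
  surfaces <- aq$candidates$surface
  expect_true(all(c("alemtuzumab", "remission induction", "patients",
                    "t-cell prolymphocytic leukemia") %in% surfaces))
  expect_true("diagnose" %in% surfaces[aq$candidates$kind == "verb"])
  # expansions: conjugations and the nominalization of "diagnose"
  exp_of_diag <- aq$candidates$surface[!is.na(aq$candidates$variant_of) &
                                         aq$candidates$variant_of == "diagnose"]
  expect_true(all(c("diagnosed", "diagnosing", "diagnosis") %in% exp_of_diag))
  # vocabulary-validated subphrase of the long NP
  expect_true("prolymphocytic leukemia" %in% surfaces)
})

test_that("slash words become separate candidates and copulas never do", {
  lex <- make_lexicon()
  aq <- analyze_question("Do drug/medication interactions matter?", lex)
  expect_true(all(c("drug", "medication") %in% aq$candidates$surface))
  aq2 <- analyze_question("What is craniosynostosis?", lex)
  expect_false(any(aq2$candidates$kind == "verb"))
  expect_false("be" %in% aq2$candidates$surface)
})

test_that("subphrase enumeration agrees with exhaustive both-ends enumeration", {
  lex <- make_lexicon()
  out <- enumerate_subphrases("t-cell prolymphocytic leukemia", lex)
  expect_true("prolymphocytic leukemia" %in% out)
  expect_true(all(c("t-cell", "prolymphocytic", "leukemia") %in% out))
  # 1-token NP: only the word itself
  expect_equal(enumerate_subphrases("alemtuzumab", lex), "alemtuzumab")
  # all sub-spans OOV: only individual words
  expect_setequal(enumerate_subphrases("foo bar baz", lex),
                  c("foo", "bar", "baz"))
  # oracle: every contiguous 2+-token subspan in the vocabulary appears
  toks <- c("t-cell", "prolymphocytic", "leukemia")
  brute <- character()
  for (len in 2:(length(toks) - 1)) {
    for (s in 1:(length(toks) - len + 1)) {
      cand <- paste(toks[s:(s + len - 1)], collapse = " ")
      if (in_vocabulary(lex, cand)) brute <- c(brute, cand)
    }
  }
  expect_true(all(brute %in% out))
})

test_that("every candidate is derivable from the question text (provenance audit)", {
  lex <- make_lexicon()
  q <- paste("Is alemtuzumab effective for remission induction in patients",
             "diagnosed with T-cell prolymphocytic leukemia?")
  aq <- analyze_question(q, lex)
  ann <- annotate(q)
  q_tokens <- unique(c(tolower(ann$tokens$surface), ann$tokens$lemma))
  derivable <- function(row) {
    if (!is.na(row$variant_of)) return(TRUE)     # expansion of another term
    toks <- strsplit(row$surface, " ")[[1]]
    all(toks %in% q_tokens)
  }
  for (i in seq_len(nrow(aq$candidates)))
    expect_true(derivable(aq$candidates[i, ]),
                info = aq$candidates$surface[i])
  # weights finite, non-negative, deduplicated surfaces
  expect_true(all(is.finite(aq$candidates$weight)))
  expect_true(all(aq$candidates$weight >= 0))
  expect_false(anyDuplicated(aq$candidates$surface) > 0)
})

test_that("out-of-vocabulary candidates receive the maximum observed IDF", {
  lex <- make_lexicon()
  aq <- analyze_question("Which drug inhibits xyzzyplex?", lex)
  oov <- aq$candidates[aq$candidates$surface == "xyzzyplex", ]
  expect_equal(nrow(oov), 1)
  expect_equal(oov$weight, lex$max_idf)
})
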