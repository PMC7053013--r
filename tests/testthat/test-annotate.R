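test_that("tokenization keeps hyphenated biomedical tokens and splits slash words", {
  ann <- annotate("Is miR-21 related to carcinogenesis?")
  expect_true("miR-21" %in% ann$tokens$surface)
  ann2 <- annotate("Do drug/medication interactions matter?")
  expect_true(all(c("drug", "medication") %in% ann2$tokens$surface))
  expect_error(annotate(""), "non-empty")
  expect_error(annotate("   "), "non-empty")
})

test_that("annotation is deterministic and offsets index the text exactly", {
  text <- "LHCII is the most abundant membrane protein on earth. It binds chlorophyll."
  a1 <- annotate(text)
  a2 <- annotate(text)
  expect_identical(a1, a2)
  for (i in seq_len(nrow(a1$tokens))) {
    expect_identical(substr(text, a1$tokens$char_start[i],
                            a1$tokens$char_end[i]),
                     a1$tokens$surface[i])
  }
  expect_equal(nrow(a1$sentences), 2)
})

test_that("token spans are ordered and noun phrases sit inside one sentence", {
  ann <- annotate("T-cell prolymphocytic leukemia is rare. Alemtuzumab treats it.")
  expect_true(all(diff(ann$tokens$char_start) > 0))
  for (i in seq_len(nrow(ann$noun_phrases))) {
    s <- ann$tokens$sentence[ann$noun_phrases$start_token[i]]
    e <- ann$tokens$sentence[ann$noun_phrases$end_token[i]]
    expect_identical(s, e)
  }
})

test_that("abbreviations do not split sentences", {
  ann <- annotate("Some markers, e.g. CD52, are informative. A second sentence follows.")
  expect_equal(nrow(ann$sentences), 2)
})

test_that("a failing annotator surfaces a typed error", {
  broken <- structure(list(annotate = function(text) stop("boom"),
                           name = "broken"), class = "litqa_annotator")
  expect_error(annotate("anything at all", broken),
               class = "litqa_annotator_error")
})

test_that("number inflection handles regular, -is and plural inputs idempotently", {
  expect_setequal(morph_variants("gene"), c("gene", "genes"))
  expect_setequal(morph_variants("craniosynostosis"),
                  c("craniosynostosis", "craniosynostoses"))
  expect_setequal(morph_variants("genes"), c("gene", "genes"))
  # closure: variants of a variant add nothing new
  for (w in c("gene", "diagnosis", "study", "craniosynostoses", "virus")) {
    v1 <- morph_variants(w)
    v2 <- sort(unique(unlist(lapply(v1, morph_variants))))
    expect_identical(sort(v1), v2)
  }
  # noun phrases inflect the head token
  expect_setequal(morph_variants("membrane protein"),
                  c("membrane protein", "membrane proteins"))
})

test_that("verb conjugation covers infinitive, 3rd singular, past and gerund", {
  expect_true(all(c("diagnose", "diagnoses", "diagnosed", "diagnosing")
                  %in% verb_forms("diagnose")))
  expect_true(all(c("induce", "induces", "induced", "inducing")
                  %in% verb_forms("induce")))
  expect_true(all(c("carry", "carries", "carried", "carrying")
                  %in% verb_forms("carry")))
  expect_true("bound" %in% verb_forms("bind"))
})

test_that("nominalization lookup returns packaged nominals or nothing", {
  lex <- load_nominalizations()
  expect_true("induction" %in% nominalizations("induce", lex))
  expect_true("treatment" %in% nominalizations("treat", lex))
  expect_length(nominalizations("zzzunknownverb", lex), 0)
})

test_that("acronym resolution finds parenthetical definitions and table entries", {
  ann <- annotate(paste("What is the role of the light-harvesting complex",
                        "of Photosystem II (LHC II)?"))
  res <- resolve_acronyms(ann)
  expect_equal(unname(res[["LHC II"]]),
               "light-harvesting complex of Photosystem II")

  plain <- annotate("what do these lowercase words resolve to?")
  expect_length(resolve_acronyms(plain), 0)

  tab <- c(WMD = "word movers distance")
  res2 <- resolve_acronyms(annotate("How does WMD relate to ranking?"), tab)
  expect_equal(unname(res2[["WMD"]]), "word movers distance")
})

test_that("noun-phrase normalization strips articles, degree words and possessives", {
  expect_equal(litqa:::normalize_np("the most abundant membrane protein"),
               "membrane protein")
  expect_equal(litqa:::normalize_np("a patient's prognosis"),
               "patient prognosis")
  expect_equal(litqa:::normalize_np("human genes"), "human genes")
})
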