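# End-to-end orchestration: question in, ranked answer sentences and
# (for factoid questions) exact answer phrases out.

#' Pipeline configuration
#'
#' @param top_k Number of ranked answers returned (default 10).
#' @param max_hits Retrieval result-size cap (default 1000).
#' @param focus_filter Apply focus-entity-type filtering (default TRUE).
#' @param definition_patterns Apply definition-pattern promotion for
#'   definition questions (default TRUE).
#' @param seed Integer seed routed to all stochastic components.
#' @return A `litqa_config`.
#' @export
pipeline_config <- function(top_k = 10L, max_hits = 1000L,
                            focus_filter = TRUE, definition_patterns = TRUE,
                            seed = 1L) {
  assert_that(top_k >= 1L, "top_k must be >= 1")
  structure(list(top_k = as.integer(top_k), max_hits = as.integer(max_hits),
                 focus_filter = isTRUE(focus_filter),
                 definition_patterns = isTRUE(definition_patterns),
                 seed = as.integer(seed)),
            class = "litqa_config")
}

#' Assemble a question-answering pipeline
#'
#' Builds (or accepts) the index and lexicon over the corpus and bundles
#' every component needed by [answer_question()].
#'
#' @param corpus Corpus data frame (`id`, `title`, `abstract`).
#' @param embeddings A `litqa_embeddings`.
#' @param gazetteer Optional `litqa_gazetteer`.
#' @param lexicon Optional `litqa_lexicon`; when missing it is built
#'   from the corpus (all words plus mined 2-4-gram phrases).
#' @param annotator Annotator handle.
#' @param nominalization_lexicon From [load_nominalizations()].
#' @param acronym_table Optional acronym table.
#' @param config A [pipeline_config()].
#' @return A `litqa_pipeline`.
#' @export
litqa_pipeline <- function(corpus, embeddings, gazetteer = NULL,
                           lexicon = NULL, annotator = default_annotator(),
                           nominalization_lexicon = load_nominalizations(),
                           acronym_table = NULL,
                           config = pipeline_config()) {
  assert_that(nrow(corpus) > 0L, "corpus must be non-empty")
  if (is.null(lexicon)) {
    doc_tokens <- lapply(seq_len(nrow(corpus)), function(i)
      tolower(tokenize_text(paste(corpus$title[i], corpus$abstract[i]))$surface))
    phrases <- mine_phrases(doc_tokens, min_count = 5L)
    words <- unique(unlist(doc_tokens))
    words <- words[grepl("[a-z0-9]", words)]
    lexicon <- build_document_frequencies(corpus, c(words, phrases))
  }
  structure(list(corpus = corpus, index = build_index(corpus),
                 lexicon = lexicon, embeddings = embeddings,
                 gazetteer = gazetteer, annotator = annotator,
                 nominalization_lexicon = nominalization_lexicon,
                 acronym_table = acronym_table, config = config),
            class = "litqa_pipeline")
}

#' @export
print.litqa_pipeline <- function(x, ...) {
  cat("<litqa_pipeline> ", nrow(x$corpus), " documents, ",
      length(ls(x$lexicon$env)), " vocabulary surfaces\n", sep = "")
  invisible(x)
}

#' Answer a natural-language question
#'
#' Runs the full pipeline: question analysis, candidate-term
#' generation, boolean query construction, (optional) keyword
#' force-inclusion, iterative retrieval, sentence segmentation, wRWMD
#' ranking, focus-type / definition-pattern filtering, optional
#' supervised reranking and, for factoid questions, exact-answer
#' extraction. Identical inputs yield identical output.
#'
#' @param pipeline A `litqa_pipeline`.
#' @param question Question string.
#' @param rerank_scorer Optional scorer from [fine_tune()].
#' @param selector Optional trained [train_selector()] model whose
#'   keywords are force-included in the initial query.
#' @param verbose Log each stage's decisions (default FALSE).
#' @return A `litqa_answer`: `question` (analysis), `candidates`
#'   (top-k data frame), `exact_answers`, `retrieval` (iterations,
#'   total hits, exhausted flag, drop history).
#' @export
answer_question <- function(pipeline, question, rerank_scorer = NULL,
                            selector = NULL, verbose = FALSE) {
  cfg <- pipeline$config
  say <- function(...) if (verbose) message(...)
  q <- analyze_question(question, pipeline$lexicon, pipeline$gazetteer,
                        pipeline$annotator, pipeline$nominalization_lexicon,
                        pipeline$acronym_table)
  say("question type: ", q$question_type, "; focus: ", q$focus_phrase)
  if (!nrow(q$candidates)) {
    return(structure(list(question = q, candidates = NULL,
                          exact_answers = NULL,
                          retrieval = list(iterations = 0L, total_hits = 0L,
                                           exhausted = TRUE, history = NULL)),
                     class = "litqa_answer"))
  }
  query <- build_query(q, pipeline$lexicon)
  if (!is.null(selector)) {
    kw <- select_keywords(q$annotated, selector, pipeline$embeddings)
    say("selector keywords: ", paste(kw, collapse = ", "))
    query <- force_include(query, kw)
  }
  ret <- iterative_retrieve(query, pipeline$index, cfg$max_hits)
  say("retrieval: ", ret$result$total_hits, " hits after ",
      ret$query$iteration, " relaxation step(s)")
  if (verbose && nrow(ret$query$history)) {
    for (i in seq_len(nrow(ret$query$history)))
      say("  dropped '", ret$query$history$surface[i], "' (construct ",
          ret$query$history$construct[i], ")")
  }
  if (ret$exhausted || !length(ret$result$ids)) {
    return(structure(list(question = q, candidates = NULL,
                          exact_answers = NULL,
                          retrieval = list(iterations = ret$query$iteration,
                                           total_hits = 0L, exhausted = TRUE,
                                           history = ret$query$history)),
                     class = "litqa_answer"))
  }
  docs <- pipeline$corpus[match(ret$result$ids, pipeline$corpus$id), ,
                          drop = FALSE]
  cands <- rank_candidates(q, docs, pipeline$lexicon, pipeline$embeddings,
                           pipeline$annotator, pipeline$gazetteer)
  if (cfg$definition_patterns && q$question_type == "definition") {
    cands <- match_definition_patterns(q$focus_phrase, cands)
  } else if (cfg$focus_filter && !is.na(q$focus_entity_type) &&
             !is.null(pipeline$gazetteer)) {
    cands <- filter_by_focus_type(cands, q$focus_entity_type,
                                  pipeline$gazetteer, pipeline$annotator)
  }
  if (!is.null(rerank_scorer)) cands <- rerank(cands, rerank_scorer, question)
  top <- utils::head(cands, cfg$top_k)
  exact <- NULL
  if (q$question_type == "focus" && !is.na(q$focus_entity_type)) {
    exact <- extract_exact_answers(top, q, pipeline$embeddings,
                                   pipeline$lexicon, pipeline$gazetteer,
                                   pipeline$annotator)
  }
  structure(list(question = q, candidates = top, exact_answers = exact,
                 retrieval = list(iterations = ret$query$iteration,
                                  total_hits = ret$result$total_hits,
                                  exhausted = FALSE,
                                  history = ret$query$history)),
            class = "litqa_answer")
}

#' @export
print.litqa_answer <- function(x, ...) {
  if (is.null(x$candidates)) {
    cat("<litqa_answer> no answer (retrieval exhausted)\n")
    return(invisible(x))
  }
  cat("<litqa_answer> top candidates:\n")
  for (i in seq_len(min(3L, nrow(x$candidates)))) {
    cat(sprintf("  %d. [%.3f] %s\n", i, x$candidates$wrwmd_score[i],
                x$candidates$sentence[i]))
  }
  invisible(x)
}

#' Serialise ranked answers as JSON
#' @param answer A `litqa_answer`.
#' @return JSON string `[{rank, score, doc_id, sentence_index,
#'   sentence}, ...]`.
#' @export
answers_as_json <- function(answer) {
  cands <- answer$candidates
  if (is.null(cands) || !nrow(cands)) return(jsonlite::toJSON(list()))
  recs <- lapply(seq_len(nrow(cands)), function(i)
    list(rank = i, score = cands$wrwmd_score[i], doc_id = cands$doc_id[i],
         sentence_index = cands$sentence_index[i],
         sentence = cands$sentence[i]))
  jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA)
}

#' Evaluate the pipeline against a gold question set
#'
#' Answers every gold question, aligns the ranked candidates against
#' the gold strings and reports MRR and Precision@1. Gold alignment is
#' heuristic; the report carries that flag.
#'
#' @param pipeline A `litqa_pipeline`.
#' @param gold List of question records (`body`, `gold`), e.g. from
#'   [read_bioasq_json()] or [generate_fixture()].
#' @param rerank_scorer,selector Optional components, see
#'   [answer_question()].
#' @param window Alignment window (default 200).
#' @return List with `judged` (data frame) and `report`
#'   (`litqa_eval_report`).
#' @export
run_eval <- function(pipeline, gold, rerank_scorer = NULL, selector = NULL,
                     window = 200L) {
  judged <- data.frame(question_id = seq_along(gold), rank = NA_integer_,
                       heuristic = TRUE)
  for (i in seq_along(gold)) {
    ans <- answer_question(pipeline, gold[[i]]$body, rerank_scorer, selector)
    if (!is.null(ans$candidates) && nrow(ans$candidates)) {
      al <- align_gold(ans$candidates$sentence, gold[[i]]$gold, window)
      judged$rank[i] <- al$rank
    }
  }
  list(judged = judged, report = eval_report(judged))
}
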