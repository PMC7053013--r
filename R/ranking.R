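# Answer-sentence ranking. Retrieved documents are segmented into
# sentences (the title is sentence 0) and each sentence is scored
# against the question by the IDF-weighted relaxed word mover's
# distance: the weighted mean, over unique question terms, of each
# term's maximum cosine similarity to any answer-sentence term,
#
#   wRWMD(Q, A) = sum_{i in I_Q} w_i * max_{j in I_A} cossim(v_i, v_j)
#                 / sum_{k in I_Q} w_k
#
# a closed-form optimum of the transport relaxation in which the
# answer-side capacity constraint is dropped. The value is a similarity
# in [-1, 1]; 1 - wRWMD is the corresponding distance and either
# convention yields the identical ranking.

#' Segment a document into sentences
#'
#' @param doc One-row document record (or list) with `title` and
#'   `abstract`.
#' @param annotator Annotator handle.
#' @return Character vector of sentences; the title is element 1.
#' @export
segment_sentences <- function(doc, annotator = default_annotator()) {
  title <- trimws(doc$title %||% "")
  abstract <- trimws(doc$abstract %||% "")
  out <- if (nzchar(title)) title else character()
  if (nzchar(abstract)) {
    ann <- annotate(abstract, annotator)
    for (s in seq_len(nrow(ann$sentences))) {
      i0 <- ann$sentences$start_token[s]; i1 <- ann$sentences$end_token[s]
      out <- c(out, trimws(substr(abstract, ann$tokens$char_start[i0],
                                  ann$tokens$char_end[i1])))
    }
  }
  out
}

# unique scoring terms of a text: stop-words removed, detected
# vocabulary phrases replace their constituent words
scoring_terms <- function(tokens, lexicon = NULL, stops = litqa_stopwords()) {
  toks <- tolower(tokens)
  toks <- toks[grepl("[a-z0-9]", toks)]
  terms <- character()
  consumed <- rep(FALSE, length(toks))
  if (!is.null(lexicon)) {
    n <- length(toks)
    i <- 1L
    while (i <= n) {
      matched <- 0L
      for (k in min(4L, n - i + 1L):2L) {
        if (k < 2L) break
        cand <- paste(toks[i:(i + k - 1L)], collapse = " ")
        if (in_vocabulary(lexicon, cand)) { matched <- k; break }
      }
      if (matched) {
        terms <- c(terms, paste(toks[i:(i + matched - 1L)], collapse = " "))
        i <- i + matched
      } else {
        terms <- c(terms, toks[i])
        i <- i + 1L
      }
    }
  } else terms <- toks
  terms <- terms[!(terms %in% stops)]
  unique(terms)
}

#' IDF-weighted relaxed word mover's distance similarity
#'
#' @param question_terms Character vector of unique question terms, or a
#'   named numeric vector of weights; unnamed terms are weighted by
#'   `lexicon` IDF.
#' @param answer_terms Character vector of unique answer-sentence terms.
#' @param embeddings A `litqa_embeddings` store.
#' @param lexicon Optional `litqa_lexicon` for IDF weights.
#' @return Similarity in \[-1, 1\]; 0 for an empty answer. A question
#'   term with no embedding contributes 1 when its exact surface occurs
#'   among the answer terms and 0 otherwise.
#' @export
wrwmd_similarity <- function(question_terms, answer_terms, embeddings,
                             lexicon = NULL) {
  if (is.numeric(question_terms)) {
    weights <- unname(question_terms)
    q_terms <- names(question_terms)
  } else {
    q_terms <- tolower(question_terms)
    weights <- if (!is.null(lexicon))
      vapply(q_terms, function(t) idf_weight(lexicon, t, oov = "max"), 0)
    else rep(1, length(q_terms))
  }
  keep <- !duplicated(q_terms)
  q_terms <- q_terms[keep]; weights <- weights[keep]
  assert_that(length(q_terms) >= 1L && sum(weights) > 0,
              "question must have at least one positively weighted term")
  a_terms <- unique(tolower(answer_terms))
  if (!length(a_terms)) return(0)
  a_vecs <- lapply(a_terms, phrase_vector, embeddings = embeddings)
  have_a <- !vapply(a_vecs, is.null, TRUE)
  a_mat <- if (any(have_a)) do.call(rbind, a_vecs[have_a]) else NULL
  maxcos <- vapply(seq_along(q_terms), function(i) {
    v <- phrase_vector(embeddings, q_terms[i])
    if (is.null(v)) return(as.numeric(q_terms[i] %in% a_terms))
    if (is.null(a_mat)) return(as.numeric(q_terms[i] %in% a_terms))
    nv <- sqrt(sum(v * v))
    if (nv == 0) return(0)
    na <- sqrt(rowSums(a_mat^2))
    sims <- as.numeric(a_mat %*% v) / (na * nv)
    sims[na == 0] <- 0
    best <- max(pmin(pmax(sims, -1), 1))
    # exact surface occurrence always counts as a perfect match
    if (q_terms[i] %in% a_terms) best <- max(best, 1)
    best
  }, 0)
  sum(weights * maxcos) / sum(weights)
}

#' Rank candidate answer sentences by wRWMD similarity
#'
#' Scores every sentence of every document against the question and
#' sorts descending, with stable tie-break by (document order, sentence
#' index).
#'
#' @param question A `litqa_question` or a character question string.
#' @param docs Data frame of document records (`id`, `title`,
#'   `abstract`).
#' @param lexicon A `litqa_lexicon`.
#' @param embeddings A `litqa_embeddings`.
#' @param annotator Annotator handle.
#' @param gazetteer Optional gazetteer: entity mentions are attached to
#'   each candidate.
#' @return A `litqa_candidates` data frame: `sentence`, `doc_id`,
#'   `sentence_index`, `wrwmd_score`, `rerank_prob` (NA), plus a list
#'   column `entities`.
#' @export
rank_candidates <- function(question, docs, lexicon, embeddings,
                            annotator = default_annotator(),
                            gazetteer = NULL) {
  assert_that(nrow(docs) > 0L, "docs must be non-empty")
  q_ann <- if (inherits(question, "litqa_question")) question$annotated
           else annotate(question, annotator)
  q_terms <- scoring_terms(q_ann$tokens$surface, lexicon)
  rows <- list()
  for (d in seq_len(nrow(docs))) {
    sents <- segment_sentences(docs[d, ], annotator)
    for (s in seq_along(sents)) {
      toks <- tokenize_text(sents[s])$surface
      a_terms <- scoring_terms(toks, lexicon)
      score <- if (length(a_terms))
        wrwmd_similarity(question_terms = q_terms, answer_terms = a_terms,
                         embeddings = embeddings, lexicon = lexicon)
      else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sentence = sents[s], doc_id = docs$id[d], sentence_index = s - 1L,
        wrwmd_score = score, rerank_prob = NA_real_, doc_order = d,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$wrwmd_score, out$doc_order, out$sentence_index), ]
  out$doc_order <- NULL
  rownames(out) <- NULL
  if (!is.null(gazetteer)) {
    out$entities <- lapply(out$sentence, function(s)
      tag_entities(annotate(s, annotator), gazetteer))
  }
  class(out) <- c("litqa_candidates", class(out))
  out
}

#' Filter candidates by the question focus entity type
#'
#' Retains candidates carrying at least one entity mention of the focus
#' type, preserving order. When no candidate carries the type the
#' unfiltered ranking is returned with a warning (an empty answer list
#' helps nobody).
#'
#' @param candidates A `litqa_candidates` data frame with an `entities`
#'   list column (or `gazetteer` supplied to compute it).
#' @param focus_entity_type One of [entity_types()].
#' @param gazetteer Optional gazetteer used when `entities` is absent.
#' @param annotator Annotator handle.
#' @return Filtered candidates.
#' @export
filter_by_focus_type <- function(candidates, focus_entity_type,
                                 gazetteer = NULL,
                                 annotator = default_annotator()) {
  if (is.null(focus_entity_type) || is.na(focus_entity_type))
    return(candidates)
  assert_that(focus_entity_type %in% entity_types(),
              paste0("unrecognized focus entity type: ", focus_entity_type))
  if (is.null(candidates$entities)) {
    assert_that(!is.null(gazetteer),
                "candidates carry no entities and no gazetteer was supplied")
    candidates$entities <- lapply(candidates$sentence, function(s)
      tag_entities(annotate(s, annotator), gazetteer))
  }
  has_type <- vapply(candidates$entities, function(e)
    nrow(e) > 0L && focus_entity_type %in% e$type, TRUE)
  if (!any(has_type)) {
    warning("no candidate carries the focus entity type; returning unfiltered ranking")
    return(candidates)
  }
  candidates[has_type, , drop = FALSE]
}

#' Default definition answer patterns
#' @return Character vector of regular-expression templates; `%s` is
#'   replaced by the escaped focus phrase.
#' @export
definition_patterns <- function() {
  c("\\b%s\\s+(is|are)\\s+(a|an|the)\\b",
    "\\b%s\\s*,\\s*(a|an)\\b",
    "\\b%s\\s+(is|are)\\s+defined\\s+as\\b",
    "\\b%s\\s+refers?\\s+to\\b")
}

#' Promote candidates matching definition answer patterns
#'
#' Candidates whose sentence matches any configured pattern for the
#' focus phrase are promoted above non-matching ones; each group keeps
#' its wRWMD order.
#'
#' @param focus_phrase Focus surface of the definition question.
#' @param candidates A `litqa_candidates` data frame.
#' @param patterns Pattern templates, see [definition_patterns()].
#' @return Reordered candidates.
#' @export
match_definition_patterns <- function(focus_phrase, candidates,
                                      patterns = definition_patterns()) {
  if (is.null(focus_phrase) || is.na(focus_phrase) || !nrow(candidates))
    return(candidates)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", focus_phrase)
  regexes <- sprintf(patterns, esc)
  hit <- vapply(candidates$sentence, function(s)
    any(vapply(regexes, function(rx)
      grepl(rx, s, ignore.case = TRUE, perl = TRUE), TRUE)), TRUE)
  out <- rbind(candidates[hit, , drop = FALSE],
               candidates[!hit, , drop = FALSE])
  rownames(out) <- NULL
  out
}
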