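# Exact answer phrase extraction for factoid questions, from the top 10
# ranked sentences. Entity path: when the focus maps to a recognized
# entity type, the unique entities of that type in first-occurrence
# order. NP path: noun phrases (leading determiners, demonstratives,
# predeterminers, comparatives/superlatives, cardinals and adverbs
# stripped), scored by cosine-to-focus times TF-IDF over the candidate
# sentences.

#' Default generic type-word stoplist
#'
#' Bare entity-type names are uninformative as exact answers and are
#' removed when occurring by themselves.
#'
#' @return Character vector.
#' @export
generic_type_words <- function() {
  unique(c("protein", "gene", "drug", "disease", "enzyme", "organism",
           "molecule", "molecular entity", "anatomical entity",
           "cellular component", "entity", "cell"))
}

strip_np_lead <- function(surface) {
  toks <- strsplit(trimws(surface), "[ ]+")[[1]]
  repeat {
    if (length(toks) <= 1L) break
    tag <- tag_token(toks[1L])
    lw <- tolower(toks[1L])
    strip <- tag %in% c("DT", "PDT", "PRP", "PRP$", "JJR", "JJS", "RBS",
                        "RB", "CD") || lw %in% .degree_words
    if (!strip) break
    was_degree <- lw %in% .degree_words
    toks <- toks[-1L]
    if (was_degree && length(toks) > 1L &&
        tag_token(toks[1L]) %in% c("JJ", "JJR", "JJS"))
      toks <- toks[-1L]
  }
  paste(toks, collapse = " ")
}

exact_row <- function(phrase, rank, path, score = NA_real_) {
  data.frame(phrase = phrase, sentence_rank = rank, path = path,
             score = score, stringsAsFactors = FALSE)
}

#' Harvest exact-answer candidates from the top ranked sentences
#'
#' @param top_sentences Character vector of at most 10 ranked sentences
#'   (rank order).
#' @param focus_entity_type One of [entity_types()], or `NA`/`NULL` for
#'   the NP path.
#' @param gazetteer A `litqa_gazetteer` (entity path).
#' @param annotator Annotator handle.
#' @param lexicon Optional lexicon (vocabulary-validated subphrases of
#'   long NPs).
#' @return Data frame with `phrase`, `sentence_rank`, `path`, `score`;
#'   entity-path rows are unique surfaces in first-occurrence order.
#' @export
harvest_candidates <- function(top_sentences, focus_entity_type = NULL,
                               gazetteer = NULL,
                               annotator = default_annotator(),
                               lexicon = NULL) {
  assert_that(length(top_sentences) >= 1L, "need at least one sentence")
  assert_that(length(top_sentences) <= 10L,
              "the exact-answer pool is the first 10 sentences")
  typed <- !is.null(focus_entity_type) && !is.na(focus_entity_type) &&
    focus_entity_type %in% entity_types()
  rows <- list()
  for (r in seq_along(top_sentences)) {
    ann <- annotate(top_sentences[r], annotator)
    if (typed) {
      assert_that(!is.null(gazetteer), "entity path requires a gazetteer")
      ments <- tag_entities(ann, gazetteer)
      ments <- ments[ments$type == focus_entity_type, , drop = FALSE]
      for (m in seq_len(nrow(ments)))
        rows[[length(rows) + 1L]] <- exact_row(ments$surface[m], r, "entity")
    } else {
      for (np in np_surfaces(ann)) {
        stripped <- strip_np_lead(tolower(np))
        if (!nzchar(stripped)) next
        rows[[length(rows) + 1L]] <- exact_row(stripped, r, "np")
        toks <- surface_tokens(stripped)
        if (length(toks) >= 3L && length(toks) <= 5L) {
          for (sp in setdiff(np_subspans(toks, lexicon), stripped))
            rows[[length(rows) + 1L]] <- exact_row(sp, r, "np")
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(phrase = character(), sentence_rank = integer(),
                      path = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$phrase), , drop = FALSE]  # first occurrence wins
  rownames(out) <- NULL
  out
}

# subphrases of a 3-5 token NP: contiguous subspans; restricted to
# vocabulary entries when a lexicon is available
np_subspans <- function(toks, lexicon = NULL) {
  n <- length(toks)
  out <- character()
  for (len in (n - 1L):1L) {
    for (s in 1L:(n - len + 1L)) {
      cand <- paste(toks[s:(s + len - 1L)], collapse = " ")
      if (is.null(lexicon) || len == 1L || in_vocabulary(lexicon, cand))
        out <- c(out, cand)
    }
  }
  unique(out)
}

#' Filter exact-answer candidates
#'
#' Removes bare generic type words and candidates whose embedding cosine
#' similarity to any question noun/NP reaches the threshold (the
#' question is assumed not to contain its own answer).
#'
#' @param candidates Data frame from [harvest_candidates()].
#' @param question_nps Character vector of question noun/NP surfaces.
#' @param embeddings A `litqa_embeddings`.
#' @param generic_words Stoplist, see [generic_type_words()].
#' @param similarity_threshold Cosine cut-off (default 0.8; a candidate
#'   at exactly the threshold is removed).
#' @return Filtered data frame.
#' @export
filter_candidates <- function(candidates, question_nps, embeddings,
                              generic_words = generic_type_words(),
                              similarity_threshold = 0.8) {
  if (!nrow(candidates)) return(candidates)
  keep <- rep(TRUE, nrow(candidates))
  q_vecs <- lapply(tolower(question_nps), phrase_vector,
                   embeddings = embeddings)
  q_nps <- tolower(question_nps)
  for (i in seq_len(nrow(candidates))) {
    ph <- tolower(candidates$phrase[i])
    if (ph %in% generic_words) { keep[i] <- FALSE; next }
    if (ph %in% q_nps) { keep[i] <- FALSE; next }   # identity, cosine 1
    v <- phrase_vector(embeddings, ph)
    if (is.null(v)) next
    for (qv in q_vecs) {
      if (is.null(qv)) next
      if (cosine_zero_safe(v, qv) >= similarity_threshold) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score and rank exact-answer candidates
#'
#' NP-path candidates are scored by
#' `cos(candidate, focus) * tf(candidate) * idf(candidate)` with term
#' frequencies counted over the candidate sentences, and sorted
#' descending (ties: sentence rank, then surface). Entity-path
#' candidates pass through unscored in first-occurrence order. A
#' candidate with no embedding falls back to the mean of its token
#' vectors; with none at all its score is 0.
#'
#' @param candidates Data frame from [filter_candidates()].
#' @param focus_term Focus phrase surface.
#' @param embeddings A `litqa_embeddings`.
#' @param lexicon A `litqa_lexicon` (IDF weights).
#' @param candidate_sentences The sentences the candidates came from
#'   (term-frequency counts).
#' @return Ranked data frame.
#' @export
score_and_rank <- function(candidates, focus_term, embeddings, lexicon,
                           candidate_sentences) {
  if (!nrow(candidates)) return(candidates)
  if (all(candidates$path == "entity")) return(candidates)
  fv <- phrase_vector(embeddings, focus_term)
  sent_tokens <- lapply(candidate_sentences, function(s)
    tolower(tokenize_text(s)$surface))
  tf_of <- function(phrase) {
    toks <- surface_tokens(phrase)
    sum(vapply(sent_tokens, function(st) {
      if (length(toks) == 1L) sum(st == toks)
      else {
        n <- length(st)
        if (n < length(toks)) return(0L)
        sum(vapply(seq_len(n - length(toks) + 1L), function(i)
          all(st[i:(i + length(toks) - 1L)] == toks), TRUE))
      }
    }, 0L))
  }
  sc <- vapply(seq_len(nrow(candidates)), function(i) {
    ph <- candidates$phrase[i]
    v <- phrase_vector(embeddings, ph)
    if (is.null(v) || is.null(fv)) return(0)
    cos <- cosine_zero_safe(v, fv)
    cos * tf_of(ph) * idf_weight(lexicon, ph, oov = "max")
  }, 0)
  candidates$score <- sc
  ord <- order(-candidates$score, candidates$sentence_rank, candidates$phrase)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end exact-answer extraction
#'
#' @param candidates A ranked `litqa_candidates` data frame (top 10
#'   used).
#' @param question A `litqa_question`.
#' @param embeddings,lexicon,gazetteer,annotator Pipeline components.
#' @return Ranked exact-answer data frame.
#' @export
extract_exact_answers <- function(candidates, question, embeddings, lexicon,
                                  gazetteer = NULL,
                                  annotator = default_annotator()) {
  top <- utils::head(candidates$sentence, 10L)
  if (!length(top)) {
    return(data.frame(phrase = character(), sentence_rank = integer(),
                      path = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  harvested <- harvest_candidates(top, question$focus_entity_type, gazetteer,
                                  annotator, lexicon)
  # entity-path candidates pass through in first-occurrence order; the
  # generic-word and question-similarity filters apply to the NP path
  if (nrow(harvested) && all(harvested$path == "entity")) return(harvested)
  q_nps <- unique(c(np_surfaces(question$annotated),
                    question$focus_phrase[!is.na(question$focus_phrase)]))
  filtered <- filter_candidates(harvested, q_nps, embeddings)
  score_and_rank(filtered, question$focus_phrase %||% "", embeddings,
                 lexicon, top)
}
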