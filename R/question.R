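# Question analysis: wh-word and question-type detection, focus phrase
# detection, and generation of the weighted candidate search-term set
# with all morphological, nominal and acronym expansions.

# relational head nouns that absorb a following "of"-NP into the focus
# ("mechanism of action", "role of X", ...)
.relational_heads <- c("mechanism", "mechanisms", "role", "roles",
                       "function", "functions", "cause", "causes",
                       "effect", "effects", "type", "types", "kind",
                       "kinds", "level", "levels", "rate", "rates",
                       "mode", "modes")

#' Default focus-to-entity-type trigger table
#'
#' Maps the (singularized) head noun of a focus phrase to one of the
#' nine entity types; user-extensible via the `triggers` argument of
#' [analyze_question()].
#'
#' @return Named character vector: head noun -> entity type.
#' @export
focus_trigger_table <- function() {
  c(gene = "gene", protein = "protein", enzyme = "enzyme",
    disease = "disease", disorder = "disease", syndrome = "disease",
    drug = "drug", medication = "drug", compound = "molecular entity",
    molecule = "molecular entity", metabolite = "molecular entity",
    organism = "organism", species = "organism", bacterium = "organism",
    virus = "organism", organ = "anatomical entity",
    tissue = "anatomical entity", organelle = "cellular component",
    receptor = "protein", kinase = "enzyme")
}

wh_index <- function(ann) {
  i <- which(ann$tokens$pos %in% c("WDT", "WP", "WRB"))
  if (length(i)) i[1L] else NA_integer_
}

first_np_after <- function(ann, tok_idx) {
  nps <- ann$noun_phrases
  cand <- which(nps$start_token > tok_idx)
  if (!length(cand)) return(NA_integer_)
  cand[which.min(nps$start_token[cand])]
}

next_nonpunct <- function(ann, tok_idx) {
  i <- which(seq_len(nrow(ann$tokens)) > tok_idx & ann$tokens$pos != "PUNCT")
  if (length(i)) i[1L] else NA_integer_
}

#' Detect the focus phrase of a question
#'
#' The focus is the first noun phrase after the wh-word; when a
#' copula/auxiliary immediately follows the wh-word, the first NP after
#' that verb. For "of"/"in" prepositional attachment the post-preposition
#' NP is the focus and the preceding NP a modifier, except that a
#' relational head noun (or a vocabulary phrase) absorbs the "of"-chain
#' into a single focus phrase. The returned phrase never contains the
#' wh-word.
#'
#' @param ann A `litqa_annotation` of the question.
#' @param lexicon Optional `litqa_lexicon` for vocabulary-phrase checks.
#' @return List with `focus_phrase` (normalized surface or `NA`),
#'   `focus_modifiers` (character vector), `focus_np_index`.
#' @export
detect_focus <- function(ann, lexicon = NULL) {
  none <- list(focus_phrase = NA_character_, focus_modifiers = character(),
               focus_np_index = NA_integer_)
  wh <- wh_index(ann)
  if (is.na(wh)) return(none)
  anchor <- wh
  nxt <- next_nonpunct(ann, wh)
  if (!is.na(nxt) && copula_or_aux(ann$tokens$surface[nxt])) anchor <- nxt
  np_i <- first_np_after(ann, anchor)
  if (is.na(np_i)) np_i <- first_np_after(ann, wh)
  if (is.na(np_i)) return(none)
  nps <- ann$noun_phrases
  focus_start <- nps$start_token[np_i]
  focus_end <- nps$end_token[np_i]
  modifiers <- character()
  # a single "of"/"in" prepositional-attachment decision: a relational
  # head (or a vocabulary phrase) absorbs the post-preposition NP into
  # the focus; otherwise the post-preposition NP becomes the focus and
  # the preceding NP a modifier
  after <- next_nonpunct(ann, focus_end)
  if (!is.na(after) && tolower(ann$tokens$surface[after]) %in% c("of", "in")) {
    nxt_np <- first_np_after(ann, after)
    if (!is.na(nxt_np) && nps$start_token[nxt_np] == after + 1L) {
      cur_surface <- np_surface(focus_start, focus_end, ann)
      nxt_surface <- np_surface(nps$start_token[nxt_np], nps$end_token[nxt_np], ann)
      head_tok <- tolower(ann$tokens$surface[focus_end])
      combined <- tolower(paste(cur_surface, ann$tokens$surface[after], nxt_surface))
      absorb <- head_tok %in% .relational_heads ||
        (!is.null(lexicon) && in_vocabulary(lexicon, combined))
      if (absorb) {
        focus_end <- nps$end_token[nxt_np]    # keep start, extend over chain
      } else {
        modifiers <- c(modifiers, normalize_np(tolower(cur_surface)))
        focus_start <- nps$start_token[nxt_np]
        focus_end <- nps$end_token[nxt_np]
      }
    }
  }
  phrase <- normalize_np(tolower(paste(
    ann$tokens$surface[focus_start:focus_end][ann$tokens$pos[focus_start:focus_end] != "PUNCT"],
    collapse = " ")))
  if (!nzchar(phrase)) return(none)
  list(focus_phrase = phrase, focus_modifiers = modifiers,
       focus_np_index = np_i)
}

#' Detect the question type
#'
#' `"definition"` for "what/which is/are X"-shaped questions with no
#' additional predicate after the focus chain, `"focus"` when a focus
#' phrase was detected, otherwise `"other"` (e.g. yes/no questions).
#'
#' @param ann A `litqa_annotation` of the question.
#' @param focus Result of [detect_focus()] (computed if missing).
#' @param lexicon Optional lexicon passed to [detect_focus()].
#' @return One of `"definition"`, `"focus"`, `"other"`.
#' @export
detect_question_type <- function(ann, focus = NULL, lexicon = NULL) {
  focus <- focus %||% detect_focus(ann, lexicon)
  wh <- wh_index(ann)
  if (!is.na(wh) && tolower(ann$tokens$surface[wh]) %in% c("what", "which")) {
    nxt <- next_nonpunct(ann, wh)
    if (!is.na(nxt) && tolower(ann$tokens$surface[nxt]) %in% .copulas &&
        !is.na(focus$focus_np_index)) {
      # definition-shaped iff everything after the copula is a bare NP
      # possibly chained by "of"/"in" (no further predicate)
      tail_idx <- which(seq_len(nrow(ann$tokens)) > nxt)
      pos <- ann$tokens$pos[tail_idx]
      surf <- tolower(ann$tokens$surface[tail_idx])
      ok <- pos %in% c("DT", "JJ", "JJR", "JJS", "RBS", "NN", "NNS", "CD",
                       "PUNCT") | (pos == "IN" & surf %in% c("of", "in"))
      if (all(ok)) return("definition")
    }
  }
  if (!is.na(focus$focus_phrase)) return("focus")
  "other"
}

#' Enumerate vocabulary-validated subphrases of a noun phrase
#'
#' All contiguous subspans of 2+ tokens reachable by dropping words from
#' either end that exist in the vocabulary, plus each individual word.
#'
#' @param np Noun-phrase surface (2+ tokens for subspan enumeration).
#' @param lexicon A `litqa_lexicon`.
#' @return Character vector of subphrase surfaces.
#' @export
enumerate_subphrases <- function(np, lexicon) {
  toks <- surface_tokens(np)
  n <- length(toks)
  out <- character()
  if (n >= 2L) {
    for (len in (n - 1L):2L) {
      if (len < 2L) break
      for (s in 1L:(n - len + 1L)) {
        cand <- paste(toks[s:(s + len - 1L)], collapse = " ")
        if (in_vocabulary(lexicon, cand)) out <- c(out, cand)
      }
    }
  }
  unique(c(out, toks))
}

#' Analyze a question
#'
#' Runs annotation, wh/focus/type detection, entity tagging and
#' candidate search-term generation.
#'
#' @param question Question string.
#' @param lexicon A `litqa_lexicon`.
#' @param gazetteer Optional `litqa_gazetteer` (entity tagging and focus
#'   typing).
#' @param annotator Annotator handle.
#' @param nominalization_lexicon From [load_nominalizations()].
#' @param acronym_table Optional named vector acronym -> expansion.
#' @param triggers Focus trigger table, see [focus_trigger_table()].
#' @return A `litqa_question`: annotation, `wh_word`, `question_type`,
#'   `focus_phrase`, `focus_modifiers`, `focus_entity_type`, question
#'   `entities`, and the `candidates` term table.
#' @export
analyze_question <- function(question, lexicon, gazetteer = NULL,
                             annotator = default_annotator(),
                             nominalization_lexicon = load_nominalizations(),
                             acronym_table = NULL,
                             triggers = focus_trigger_table()) {
  ann <- annotate(question, annotator)
  focus <- detect_focus(ann, lexicon)
  qtype <- detect_question_type(ann, focus, lexicon)
  focus_type <- NA_character_
  if (!is.na(focus$focus_phrase)) {
    head_tok <- singularize(utils::tail(surface_tokens(focus$focus_phrase), 1L))
    if (head_tok %in% names(triggers)) {
      focus_type <- unname(triggers[[head_tok]])
    } else if (!is.null(gazetteer)) {
      focus_type <- gazetteer_type(gazetteer, focus$focus_phrase)
    }
  }
  entities <- if (!is.null(gazetteer)) tag_entities(ann, gazetteer)
              else data.frame(surface = character(), type = character())
  acronyms <- resolve_acronyms(ann, acronym_table)
  candidates <- generate_candidate_terms(ann, lexicon, nominalization_lexicon,
                                         acronyms, entities)
  structure(list(annotated = ann, wh_word = if (!is.na(wh_index(ann)))
                   tolower(ann$tokens$surface[wh_index(ann)]) else NA_character_,
                 question_type = qtype,
                 focus_phrase = focus$focus_phrase,
                 focus_modifiers = focus$focus_modifiers,
                 focus_entity_type = focus_type,
                 entities = entities, acronyms = acronyms,
                 candidates = candidates),
            class = "litqa_question")
}

#' @export
print.litqa_question <- function(x, ...) {
  cat("<litqa_question> type=", x$question_type,
      " focus=", x$focus_phrase,
      if (!is.na(x$focus_entity_type)) paste0(" [", x$focus_entity_type, "]"),
      " (", nrow(x$candidates), " candidate terms)\n", sep = "")
  invisible(x)
}

candidate_row <- function(surface, kind, weight, variant_of = NA_character_) {
  data.frame(surface = surface, kind = kind, weight = weight,
             variant_of = variant_of, stringsAsFactors = FALSE)
}

#' Generate weighted candidate search terms for a question
#'
#' Emits non-copula verbs (with conjugations and nominalizations as
#' expansions), normalized noun phrases (with number variants and
#' acronym expansions), each NP's individual words, and
#' vocabulary-validated subphrases. Every term is weighted by its corpus
#' IDF; out-of-vocabulary terms receive the maximum observed IDF.
#' Identical surfaces are deduplicated keeping the maximum weight.
#'
#' @param ann A `litqa_annotation` of the question.
#' @param lexicon A `litqa_lexicon`.
#' @param nominalization_lexicon From [load_nominalizations()].
#' @param acronyms Named vector acronym -> expansion (may be empty).
#' @param entities Question entity mentions (data frame from
#'   [tag_entities()]).
#' @return Data frame with `surface`, `kind`, `weight`, `variant_of`.
#' @export
generate_candidate_terms <- function(ann, lexicon,
                                     nominalization_lexicon = load_nominalizations(),
                                     acronyms = character(),
                                     entities = NULL) {
  stops <- litqa_stopwords()
  w <- function(s) idf_weight(lexicon, s, oov = "max")
  rows <- list()
  add <- function(surface, kind, variant_of = NA_character_) {
    surface <- tolower(trimws(surface))
    if (!nzchar(surface)) return()
    if (length(surface_tokens(surface)) == 1L && surface %in% stops) return()
    rows[[length(rows) + 1L]] <<- candidate_row(surface, kind, w(surface),
                                                variant_of)
  }
  toks <- ann$tokens
  # verbs (non-copula/auxiliary)
  verb_idx <- which(toks$pos %in% c("VB", "VBD", "VBN", "VBG") &
                      !vapply(toks$surface, copula_or_aux, TRUE))
  verb_idx <- c(verb_idx,
                which(toks$pos == "VBZ" & !vapply(toks$surface, copula_or_aux, TRUE)))
  for (vi in verb_idx) {
    lemma <- toks$lemma[vi]
    add(lemma, "verb")
    for (f in setdiff(verb_forms(lemma), lemma)) add(f, "expansion", lemma)
    for (nom in nominalizations(lemma, nominalization_lexicon))
      add(nom, "expansion", lemma)
  }
  # noun phrases
  ent_surfaces <- if (!is.null(entities) && nrow(entities)) entities$surface
                  else character()
  nps <- np_surfaces(ann)
  for (np in nps) {
    np_norm <- normalize_np(tolower(np))
    if (!nzchar(np_norm)) next
    kind <- if (np_norm %in% ent_surfaces) "entity" else "np"
    add(np_norm, kind)
    for (v in setdiff(morph_variants(np_norm), np_norm))
      add(v, "expansion", np_norm)
    # acronym expansions attached to this NP
    for (acr in names(acronyms)) {
      if (tolower(acr) == np_norm || acronyms[[acr]] == np_norm) {
        other <- if (tolower(acr) == np_norm) acronyms[[acr]] else tolower(acr)
        add(other, "expansion", np_norm)
      }
    }
    np_toks <- surface_tokens(np_norm)
    if (length(np_toks) >= 2L) {
      for (word in np_toks) add(word, "np_word", np_norm)
      for (sp in enumerate_subphrases(np_norm, lexicon)) {
        if (length(surface_tokens(sp)) >= 2L && sp != np_norm)
          add(sp, "subphrase", np_norm)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(surface = character(), kind = character(),
                      weight = numeric(), variant_of = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # dedupe by surface keeping maximum weight; prefer the more specific kind
  kind_rank <- c(entity = 1, verb = 2, np = 3, subphrase = 4, np_word = 5,
                 expansion = 6)
  out <- out[order(out$surface, kind_rank[out$kind], -out$weight), ]
  out <- out[!duplicated(out$surface), ]
  rownames(out) <- NULL
  out
}
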